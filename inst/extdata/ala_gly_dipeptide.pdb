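REMARK  hand-built ALA-GLY dipeptide fixture (synthetic coordinates)
ATOM      1  N   ALA A   1       1.204   0.000   0.000  1.00  0.00           N
ATOM      2  CA  ALA A   1       2.628   0.000   0.000  1.00  0.00           C
ATOM      3  C   ALA A   1       3.200   1.400   0.000  1.00  0.00           C
ATOM      4  O   ALA A   1       2.500   2.400   0.000  1.00  0.00           O
ATOM      5  CB  ALA A   1       3.200  -0.700  -1.200  1.00  0.00           C
ATOM      6  N   GLY A   2       4.500   1.500   0.000  1.00  0.00           N
ATOM      7  CA  GLY A   2       5.200   2.800   0.000  1.00  0.00           C
ATOM      8  C   GLY A   2       6.700   2.600   0.000  1.00  0.00           C
ATOM      9  O   GLY A   2       7.300   1.500   0.000  1.00  0.00           O
ATOM     10  OXT GLY A   2       7.300   3.700   0.000  1.00  0.00           O
TER
END
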