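# Topology: ordered atoms with residue/chain structure and per-atom physical
# parameters (mass amu, charge e, Lennard-Jones sigma nm / epsilon kJ/mol).
# The frame-independent half of every computation.

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.97376,
  FE = 55.845, ZN = 65.38, MG = 24.305, CA = 40.078, `NA` = 22.98977,
  CL = 35.45, K = 39.0983, SE = 78.971, MN = 54.938, CU = 63.546, X = NA_real_
)

.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HIE", "HID", "HIP", "CYX", "ASH", "GLH", "LYN"
)

#' Construct a topology
#'
#' A topology holds the ordered atom table, the derived residue table, and
#' named atom groups (e.g. receptor and ligand selections). Atom and residue
#' indices are 1-based and contiguous; the original author (PDB) residue
#' numbering is retained in `author_resid` for reporting.
#'
#' @param atoms Data frame with one row per atom. Required columns: `name`,
#'   `element`, `residue_index` (1-based contiguous), `residue_name`,
#'   `chain_id`. Optional: `mass` (amu), `charge` (e), `lj_sigma` (nm),
#'   `lj_epsilon` (kJ/mol), `author_resid`, `insert`. `is_heavy` is derived
#'   from `element`.
#' @param groups Named list of integer atom-index vectors (or `NULL`).
#' @return An object of class `topology`.
#' @export
topology <- function(atoms, groups = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  need <- c("name", "element", "residue_index", "residue_name", "chain_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    abort_mdbind(paste("atoms table lacks columns:", paste(miss, collapse = ", ")),
                 "mdbind_format_error")
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$mass)) atoms$mass <- unname(.element_masses[toupper(atoms$element)])
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$lj_sigma)) atoms$lj_sigma <- NA_real_
  if (is.null(atoms$lj_epsilon)) atoms$lj_epsilon <- NA_real_
  if (is.null(atoms$author_resid)) atoms$author_resid <- atoms$residue_index
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$is_heavy <- toupper(atoms$element) != "H"
  atoms$index <- seq_len(nrow(atoms))

  atoms$residue_index <- as.integer(atoms$residue_index)
  ri <- atoms$residue_index
  if (anyNA(ri) || !identical(sort(unique(ri)), seq_len(max(ri)))) {
    abort_mdbind("residue_index must be 1-based and contiguous", "mdbind_format_error")
  }
  if (any(!is.na(atoms$mass) & atoms$mass <= 0)) {
    abort_mdbind("atom masses must be positive", "mdbind_format_error")
  }
  if (any(!is.na(atoms$lj_sigma) & atoms$lj_sigma < 0) ||
      any(!is.na(atoms$lj_epsilon) & atoms$lj_epsilon < 0)) {
    abort_mdbind("Lennard-Jones parameters must be non-negative", "mdbind_format_error")
  }

  first <- !duplicated(ri)
  residues <- data.frame(
    residue_index = ri[first],
    residue_name  = atoms$residue_name[first],
    chain_id      = atoms$chain_id[first],
    author_resid  = atoms$author_resid[first],
    insert        = atoms$insert[first],
    stringsAsFactors = FALSE
  )
  residues <- residues[order(residues$residue_index), , drop = FALSE]
  residues$n_atoms <- as.integer(table(factor(ri, levels = residues$residue_index)))
  residues$label <- paste0(
    residues$chain_id, ":", residues$residue_name, residues$author_resid, residues$insert
  )
  rownames(residues) <- NULL

  obj <- structure(
    list(atoms = atoms, residues = residues, groups = list()),
    class = "topology"
  )
  if (length(groups)) {
    for (g in names(groups)) obj <- set_group(obj, g, groups[[g]])
  }
  obj
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology> %d atoms, %d residues, %d chains\n",
              nrow(x$atoms), nrow(x$residues),
              length(unique(x$atoms$chain_id))))
  if (length(x$groups)) {
    for (g in names(x$groups)) {
      cat(sprintf("  group %-10s %d atoms\n", g, length(x$groups[[g]])))
    }
  }
  invisible(x)
}

#' Number of atoms in a topology
#' @param topology A [topology] object.
#' @return Integer atom count.
#' @export
n_atoms <- function(topology) nrow(topology$atoms)

#' Residue labels (chain:NAME + author number) for reporting
#' @param topology A [topology] object.
#' @return Character vector, one label per residue.
#' @export
residue_labels <- function(topology) topology$residues$label

#' Attach a named atom group to a topology
#'
#' Groups name the components of the complex (e.g. `"receptor"`, `"ligand"`);
#' energy decompositions require the two groups to be disjoint.
#'
#' @param topology A [topology] object.
#' @param name Group name.
#' @param selection Either an integer vector of atom indices or a selection
#'   expression string understood by [select_atoms()].
#' @return The updated topology.
#' @export
set_group <- function(topology, name, selection) {
  idx <- if (is.character(selection) && length(selection) == 1L) {
    select_atoms(topology, selection)
  } else {
    as.integer(selection)
  }
  if (any(idx < 1 | idx > n_atoms(topology))) {
    abort_mdbind(sprintf("group '%s' has out-of-range atom indices", name),
                 "mdbind_selection_error")
  }
  topology$groups[[name]] <- unique(idx)
  topology
}

# --- element inference ----------------------------------------------------

infer_element <- function(name, residue_name, elesy = NULL) {
  name <- trimws(name)
  if (!is.null(elesy)) {
    elesy <- trimws(elesy)
    if (nzchar(elesy) && !is.na(elesy)) return(toupper(elesy))
  }
  up <- toupper(name)
  # Ambiguous "CA": alpha-carbon in standard amino acids, calcium otherwise
  if (up == "CA") {
    return(if (toupper(residue_name) %in% .standard_aa) "C" else "CA")
  }
  if (up %in% c("FE", "ZN", "MG", "CL", "NA", "SE", "MN", "CU", "BR", "K")) return(up)
  lead <- sub("^[0-9']*", "", up)
  substr(lead, 1, 1)
}

# --- PDB reading ----------------------------------------------------------

validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) {
    abort_mdbind(sprintf("'%s' contains no ATOM/HETATM records", path),
                 "mdbind_empty_input_error")
  }
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort_mdbind(sprintf("PDB format error at line %d: record too short", i),
                   "mdbind_format_error")
    }
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    num <- suppressWarnings(as.numeric(xyz))
    if (any(is.na(num))) {
      abort_mdbind(sprintf(
        "PDB format error at line %d: non-numeric coordinate field '%s'",
        i, trimws(xyz[which(is.na(num))[1]])), "mdbind_format_error")
    }
  }
  invisible(length(idx))
}

#' Read a PDB structure
#'
#' Reads a (single-model) PDB file into a [topology] and a coordinate
#' [frame]. Coordinates are converted from Angstrom to nm. Elements are taken
#' from the PDB element column when present, otherwise inferred from the atom
#' name with residue context (so `CA` in a standard amino acid is carbon, not
#' calcium). When alternate locations are present, the highest-occupancy
#' conformer is kept.
#'
#' @param path Path to a PDB file.
#' @return A list with components `topology` and `frame`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) {
    abort_mdbind(sprintf("file '%s' does not exist", path), "mdbind_io_error")
  }
  validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0) {
    abort_mdbind(sprintf("'%s' contains zero atoms", path), "mdbind_empty_input_error")
  }
  # alternate locations: keep the highest-occupancy conformer per atom site
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(ii) {
      ii[which.max(occ[ii])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  at$chain[is.na(at$chain)] <- " "
  res_key <- paste(at$chain, at$resno, at$insert, at$resid, sep = "\r")
  residue_index <- cumsum(c(TRUE, res_key[-1] != res_key[-length(res_key)]))
  element <- vapply(seq_len(nrow(at)), function(i) {
    infer_element(at$elety[i], at$resid[i], at$elesy[i])
  }, character(1))

  atoms <- data.frame(
    name = at$elety, element = element,
    residue_index = residue_index, residue_name = at$resid,
    chain_id = at$chain, author_resid = at$resno, insert = at$insert,
    stringsAsFactors = FALSE
  )
  top <- topology(atoms)
  coords <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  list(topology = top, frame = frame(coords, time = 0))
}

#' Write a structure (or trajectory) as a PDB file
#'
#' Inverse of [read_structure()]: coordinates are converted nm to Angstrom.
#' When `coords` is a [trajectory_ensemble] the frames of the chosen replica
#' are written as a multi-model PDB.
#'
#' @param path Output path.
#' @param topology A [topology].
#' @param coords A [frame], or a [trajectory_ensemble].
#' @param replica Replica index used when `coords` is an ensemble.
#' @return `path`, invisibly.
#' @export
write_structure <- function(path, topology, coords, replica = 1L) {
  at <- topology$atoms
  xyz_from_frame <- function(fr) as.vector(t(fr$coordinates * 10))
  if (inherits(coords, "trajectory_ensemble")) {
    arr <- coords$replicas[[replica]]$coords
    xyz <- do.call(rbind, lapply(seq_len(dim(arr)[1]), function(i) {
      as.vector(t(arr[i, , ] * 10))
    }))
  } else {
    xyz <- xyz_from_frame(coords)
  }
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(at)),
    resno = at$author_resid, resid = at$residue_name,
    chain = ifelse(at$chain_id == " ", "", at$chain_id),
    insert = at$insert,
    elety = at$name, elesy = at$element
  )
  invisible(path)
}

# --- parameter tables -----------------------------------------------------

#' Attach per-atom physical parameters from a delimited table
#'
#' The table (whitespace- or tab-delimited, with a header) must contain the
#' columns `chain`, `residue_index` (author numbering as in the PDB file),
#' `atom_name`, `mass`, `charge`, `sigma`, `epsilon`, and must cover every
#' atom of the topology exactly once. Reports the net charge of each defined
#' group.
#'
#' @param path Path to the parameter table.
#' @param topology A [topology].
#' @return The topology with `mass`, `charge`, `lj_sigma`, `lj_epsilon`
#'   filled; net group charges are attached as attribute `group_charges`.
#' @export
read_atom_parameters <- function(path, topology) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chain", "residue_index", "atom_name", "mass", "charge", "sigma", "epsilon")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort_mdbind(paste("parameter table lacks columns:", paste(miss, collapse = ", ")),
                 "mdbind_format_error")
  }
  key_tab <- paste(tab$chain, tab$residue_index, tab$atom_name, sep = "\r")
  if (anyDuplicated(key_tab)) {
    d <- key_tab[duplicated(key_tab)][1]
    abort_mdbind(sprintf("duplicate parameter row for atom '%s'", gsub("\r", "/", d)),
                 "mdbind_ambiguity_error")
  }
  at <- topology$atoms
  key_top <- paste(at$chain_id, at$author_resid, at$name, sep = "\r")
  m <- match(key_top, key_tab)
  if (anyNA(m)) {
    i <- which(is.na(m))[1]
    abort_mdbind(sprintf(
      "missing parameters for atom chain=%s resid=%s name=%s",
      at$chain_id[i], at$author_resid[i], at$name[i]), "mdbind_missing_parameter_error")
  }
  topology$atoms$mass <- tab$mass[m]
  topology$atoms$charge <- tab$charge[m]
  topology$atoms$lj_sigma <- tab$sigma[m]
  topology$atoms$lj_epsilon <- tab$epsilon[m]
  if (any(topology$atoms$mass <= 0)) {
    abort_mdbind("parameter table contains non-positive masses", "mdbind_format_error")
  }
  gq <- vapply(topology$groups, function(idx) sum(topology$atoms$charge[idx]),
               numeric(1))
  attr(topology, "group_charges") <- gq
  if (length(gq)) {
    message(paste(sprintf("group %s: net charge %+.3f e", names(gq), gq),
                  collapse = "\n"))
  }
  topology
}

#' Write a parameter table for a topology
#'
#' Companion to [read_atom_parameters()]; useful for exporting synthetic
#' systems so they can be consumed like real data.
#'
#' @param path Output path.
#' @param topology A parameterized [topology].
#' @return `path`, invisibly.
#' @export
write_atom_parameters <- function(path, topology) {
  at <- topology$atoms
  tab <- data.frame(
    chain = at$chain_id, residue_index = at$author_resid, atom_name = at$name,
    mass = at$mass, charge = at$charge, sigma = at$lj_sigma,
    epsilon = at$lj_epsilon, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

# --- selection grammar ----------------------------------------------------

# Grammar (whitespace-tokenized, left-associative):
#   expr    := term (("and" | "or") term)*
#   term    := "heavy" | "chain" <id> | "name" <id> | "group" <id>
#            | "resid" <n> | "resid" <a>-<b>
# resid refers to author (PDB) numbering.

#' Select atoms with a small selection grammar
#'
#' Supported terms: `heavy` (element != H), `chain <id>`, `name <atom name>`,
#' `resid <n>` or `resid <a>-<b>` (author numbering, inclusive), and
#' `group <name>`; terms combine left-associatively with `and` / `or`.
#'
#' @param topology A [topology].
#' @param expression Selection string, e.g. `"chain A and name CA"`.
#' @return Ordered, duplicate-free integer vector of atom indices (a
#'   `Selection`). An empty result raises a warning, not an error.
#' @export
#' @examples
#' ## select_atoms(top, "name CA")
#' ## select_atoms(top, "chain B and resid 30-40 and heavy")
select_atoms <- function(topology, expression) {
  toks <- gregexpr("\\S+", expression)[[1]]
  if (identical(as.integer(toks[1]), -1L)) {
    abort_mdbind("empty selection expression", "mdbind_parse_error")
  }
  words <- regmatches(expression, gregexpr("\\S+", expression))[[1]]
  pos <- as.integer(toks)
  n <- n_atoms(topology)
  at <- topology$atoms
  i <- 1L

  parse_err <- function(msg, k) {
    abort_mdbind(sprintf("selection parse error at position %d ('%s'): %s",
                         pos[min(k, length(pos))], words[min(k, length(words))], msg),
                 "mdbind_parse_error")
  }
  need_arg <- function(k, what) {
    if (k > length(words)) parse_err(sprintf("expected %s", what), k - 1L)
  }

  parse_term <- function() {
    if (i > length(words)) parse_err("expected a term", i)
    w <- tolower(words[i])
    if (w == "heavy") {
      i <<- i + 1L
      return(which(at$is_heavy))
    }
    if (w %in% c("chain", "name", "group", "resid")) {
      need_arg(i + 1L, paste(w, "argument"))
      arg <- words[i + 1L]
      i <<- i + 2L
      if (w == "chain") return(which(at$chain_id == arg))
      if (w == "name") return(which(at$name == arg))
      if (w == "group") {
        if (is.null(topology$groups[[arg]])) {
          parse_err(sprintf("unknown group '%s'", arg), i - 1L)
        }
        return(topology$groups[[arg]])
      }
      # resid
      if (grepl("^-?[0-9]+--?[0-9]+$", arg)) {
        ab <- as.integer(strsplit(sub("(-?[0-9]+)-(-?[0-9]+)", "\\1\r\\2", arg),
                                  "\r")[[1]])
        if (ab[1] > ab[2]) parse_err("reversed resid range", i - 1L)
        return(which(at$author_resid >= ab[1] & at$author_resid <= ab[2]))
      }
      if (grepl("^-?[0-9]+$", arg)) {
        return(which(at$author_resid == as.integer(arg)))
      }
      parse_err("resid expects <n> or <a>-<b>", i - 1L)
    }
    parse_err("unknown term", i)
  }

  res <- parse_term()
  while (i <= length(words)) {
    op <- tolower(words[i])
    if (!op %in% c("and", "or")) parse_err("expected 'and' or 'or'", i)
    i <- i + 1L
    rhs <- parse_term()
    res <- if (op == "and") intersect(res, rhs) else union(res, rhs)
  }
  res <- sort(unique(as.integer(res)))
  if (!length(res)) warning("selection matched no atoms")
  res
}

#' Map a selection of atoms to their residue indices
#' @param topology A [topology].
#' @param selection Integer atom indices.
#' @return Integer residue indices (one per selected atom).
#' @export
selection_residues <- function(topology, selection) {
  topology$atoms$residue_index[selection]
}
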