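#' Residue keys
#'
#' Residues are identified throughout the package by a compact label
#' `"chain:number"` (with an optional trailing insertion code, e.g.
#' `"A:100A"`). Author (PDB) numbering is preserved verbatim so that mutation
#' labels such as `M154E` match the conventions used in structural
#' immunology.
#'
#' @param chain chain identifier(s)
#' @param resno author residue number(s)
#' @param icode insertion code(s), `""` if absent
#' @return character vector of residue keys
#' @export
res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste0(chain, ":", resno, icode)
}

#' Split residue keys back into their components
#'
#' @param keys character vector of `"chain:number[icode]"` labels
#' @return a tibble with columns `chain`, `resno`, `icode`
#' @export
parse_res_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):(-?[0-9]+)([A-Za-z]?)$", keys))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed residue key(s): ", paste(keys[bad], collapse = ", "))
  }
  tibble::tibble(
    chain = vapply(m, `[[`, "", 2L),
    resno = as.integer(vapply(m, `[[`, "", 3L)),
    icode = vapply(m, `[[`, "", 4L)
  )
}

#' Build an antigen structure from an atom table
#'
#' The package represents a (single-partner) protein structure as a tibble of
#' heavy atoms plus a derived residue table and one-letter sequence. Atoms
#' are ordered by `(chain, resno, icode)`; hydrogens and waters are expected
#' to have been removed already (see [read_structure()]).
#'
#' @param atoms a data frame with columns `chain`, `resno`, `icode`
#'   (optional, `""` if absent), `aa` (one-letter amino-acid code), `elety`
#'   (atom name, e.g. `"CA"`), `element` (e.g. `"C"`), and coordinates
#'   `x`, `y`, `z` in Angstroms
#' @return an object of class `ag_structure` with elements `atoms`
#'   (tibble), `residues` (tibble with `key`, `chain`, `resno`, `icode`,
#'   `aa`) and `sequence` (one-letter string)
#' @export
ag_structure <- function(atoms) {
  atoms <- tibble::as_tibble(atoms)
  if (!"icode" %in% names(atoms)) atoms$icode <- ""
  need <- c("chain", "resno", "icode", "aa", "elety", "element", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure has no heavy atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms <- dplyr::arrange(atoms, .data$chain, .data$resno, .data$icode)
  atoms$key <- res_key(atoms$chain, atoms$resno, atoms$icode)
  residues <- dplyr::distinct(
    atoms, .data$key, .data$chain, .data$resno, .data$icode, .data$aa
  )
  if (anyDuplicated(residues$key)) {
    dup <- residues$key[duplicated(residues$key)]
    stop("residue key(s) with conflicting amino-acid codes: ",
         paste(unique(dup), collapse = ", "))
  }
  structure(
    list(
      atoms = atoms,
      residues = residues,
      sequence = paste(residues$aa, collapse = "")
    ),
    class = "ag_structure"
  )
}

#' @export
print.ag_structure <- function(x, ...) {
  cat(sprintf(
    "<ag_structure> %d residues, %d heavy atoms, chain(s) %s\n",
    nrow(x$residues), nrow(x$atoms),
    paste(unique(x$residues$chain), collapse = ",")
  ))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records with [bio3d::read.pdb()], drops hydrogens, waters and
#' hetero groups (selenomethionine `MSE` is kept and treated as `MET`),
#' resolves alternate locations to the highest-occupancy conformer, and
#' reports residues with missing backbone atoms.
#'
#' @param path path to a PDB file
#' @param chain optional chain identifier; if given, only that chain is kept
#' @return an [ag_structure()]
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("could not parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  # MSE arrives as HETATM in deposited structures; fold it into MET
  mse <- at$resid == "MSE"
  at$resid[mse] <- "MET"
  at$type[mse] <- "ATOM"
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  at <- at[is.na(at$elesy) | !(at$elesy %in% c("H", "D")), , drop = FALSE]
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
    if (nrow(at) == 0L) stop("chain '", chain, "' not found in ", path)
  }
  if (nrow(at) == 0L) stop("no heavy atoms in ", path)
  # altloc: keep the highest-occupancy conformer per atom slot
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  slot <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(at)), slot), function(i) {
    i[which.max(at$o[i])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  aa1 <- bio3d::aa321(at$resid)
  known <- !is.na(aa1) & aa1 != "X"
  at <- at[known, , drop = FALSE]
  aa1 <- aa1[known]
  if (nrow(at) == 0L) stop("no standard amino-acid residues in ", path)
  element <- at$elesy
  noel <- is.na(element) | element == ""
  element[noel] <- substr(gsub("^[0-9]+", "", at$elety[noel]), 1, 1)
  s <- ag_structure(tibble::tibble(
    chain = at$chain,
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    aa = aa1,
    elety = at$elety,
    element = element,
    x = at$x, y = at$y, z = at$z
  ))
  bb <- c("N", "CA", "C", "O")
  n_bb <- vapply(split(s$atoms$elety, s$atoms$key), function(e) sum(bb %in% e), 1L)
  incomplete <- names(n_bb)[n_bb < 4L]
  if (length(incomplete)) {
    message(length(incomplete), " residue(s) with missing backbone atoms: ",
            paste(utils::head(incomplete, 8), collapse = ", "),
            if (length(incomplete) > 8) " ..." else "")
  }
  s
}

#' Write a structure (or a complex) to a PDB file
#'
#' Thin wrapper over [bio3d::write.pdb()]; used mainly to materialize
#' synthetic scenarios as ordinary PDB inputs.
#'
#' @param ... one or more [ag_structure()] objects, concatenated in order
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(..., path) {
  parts <- list(...)
  at <- dplyr::bind_rows(lapply(parts, function(s) s$atoms))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    resno = at$resno,
    chain = at$chain,
    insert = ifelse(at$icode == "", "", at$icode),
    resid = bio3d::aa123(at$aa),
    elety = at$elety,
    elesy = at$element,
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at))
  )
  invisible(path)
}

#' Extract the atom table for a subset of residues
#'
#' @param s an [ag_structure()]
#' @param keys residue keys to keep; `NULL` keeps all
#' @return tibble of atoms
#' @export
atoms_of <- function(s, keys = NULL) {
  stopifnot(inherits(s, "ag_structure"))
  if (is.null(keys)) return(s$atoms)
  missing <- setdiff(keys, s$residues$key)
  if (length(missing)) stop("unknown residue key(s): ", paste(missing, collapse = ", "))
  s$atoms[s$atoms$key %in% keys, , drop = FALSE]
}

# all-pairs Euclidean distances between the rows of two coordinate matrices
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

coords_mat <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Residue pairs in heavy-atom contact between two selections
#'
#' A residue pair is in contact when the minimum distance over all of its
#' heavy-atom pairs is at or below `cutoff` (the 5 Angstrom inter-heavy-atom
#' criterion commonly used to define binding-interface residues).
#'
#' @param a,b atom tibbles (as from [atoms_of()]) or `ag_structure` objects;
#'   their residue sets must be disjoint
#' @param cutoff contact distance in Angstroms
#' @return a tibble with columns `key_a`, `key_b`, `dist` (the minimum
#'   heavy-atom distance for the pair)
#' @export
heavy_atom_contacts <- function(a, b, cutoff = 5) {
  if (inherits(a, "ag_structure")) a <- a$atoms
  if (inherits(b, "ag_structure")) b <- b$atoms
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(tibble::tibble(key_a = character(), key_b = character(),
                          dist = numeric()))
  }
  if (length(intersect(unique(a$key), unique(b$key)))) {
    stop("selections overlap: contact detection requires disjoint residue sets")
  }
  D <- cross_dist(coords_mat(a), coords_mat(b))
  hit <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(tibble::tibble(key_a = character(), key_b = character(),
                          dist = numeric()))
  }
  tibble::tibble(
    key_a = a$key[hit[, 1L]],
    key_b = b$key[hit[, 2L]],
    dist = D[hit]
  ) |>
    dplyr::group_by(.data$key_a, .data$key_b) |>
    dplyr::summarise(dist = min(.data$dist), .groups = "drop")
}

#' C-alpha coordinates for a set of residues
#'
#' @param s an [ag_structure()]
#' @param keys residue keys
#' @return numeric matrix with one row per key (in `keys` order)
#' @export
ca_coords <- function(s, keys) {
  at <- atoms_of(s, keys)
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing <- setdiff(keys, ca$key)
  if (length(missing)) {
    stop("residue(s) without a C-alpha atom: ", paste(missing, collapse = ", "))
  }
  m <- coords_mat(ca)
  rownames(m) <- ca$key
  m[keys, , drop = FALSE]
}

#' Mean pairwise C-alpha distance of a set of positions
#'
#' The geometric "spread" of a mutation set: the arithmetic mean of
#' C-alpha--C-alpha distances over all unordered pairs of positions.
#' Defined as 0 for a single position.
#'
#' @param s an [ag_structure()]
#' @param positions residue keys (at least one)
#' @return distance in Angstroms
#' @export
mean_pairwise_ca_distance <- function(s, positions) {
  positions <- unique(positions)
  if (length(positions) < 1L) stop("need at least one position")
  if (length(positions) == 1L) return(0)
  mean(stats::dist(ca_coords(s, positions)))
}
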