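# Docking-ensemble ingestion, antigen footprints, coverage, overlap and
# interface-quality (f_nat) metrics. A docking model is one rigid-body pose
# of an antibody against a fixed antigen; its footprint is the set of
# antigen residues within heavy-atom contact distance of the pose.

#' Construct a docking model
#'
#' @param id model label
#' @param ab antibody pose as an [ag_structure()]
#' @param ag the shared antigen [ag_structure()]
#' @param cutoff heavy-atom contact cutoff in Angstroms used for the cached
#'   footprint
#' @return an object of class `docking_model` with elements `id`, `ab`,
#'   `ag` and `footprint` (character vector of antigen residue keys)
#' @export
docking_model <- function(id, ab, ag, cutoff = 5) {
  stopifnot(inherits(ab, "ag_structure"), inherits(ag, "ag_structure"))
  m <- structure(list(id = id, ab = ab, ag = ag, cutoff = cutoff,
                      footprint = character(), contact_aas = list()),
                 class = "docking_model")
  ct <- heavy_atom_contacts(ag$atoms, ab$atoms, cutoff)
  m$footprint <- ag$residues$key[ag$residues$key %in% unique(ct$key_a)]
  ab_aa <- stats::setNames(ab$residues$aa, ab$residues$key)
  m$contact_aas <- split(unname(ab_aa[ct$key_b]), ct$key_a)
  m
}

#' @export
print.docking_model <- function(x, ...) {
  cat(sprintf("<docking_model> %s: %d-residue footprint\n",
              x$id, length(x$footprint)))
  invisible(x)
}

#' Antigen footprint of a docking model
#'
#' Antigen residues with at least one heavy atom within `cutoff` of any
#' antibody heavy atom in the pose.
#'
#' @param m a [docking_model()]
#' @param cutoff contact distance in Angstroms
#' @return character vector of antigen residue keys, in antigen order
#' @export
footprint <- function(m, cutoff = 5) {
  stopifnot(inherits(m, "docking_model"))
  ct <- heavy_atom_contacts(m$ag$atoms, m$ab$atoms, cutoff)
  keys <- unique(ct$key_a)
  m$ag$residues$key[m$ag$residues$key %in% keys]
}

#' Construct a docking ensemble
#'
#' @param ag shared antigen [ag_structure()]
#' @param models list of [docking_model()] objects (all against `ag`)
#' @param source_label provenance string (e.g. the antibody name)
#' @return object of class `docking_ensemble`
#' @export
docking_ensemble <- function(ag, models, source_label = "ensemble") {
  stopifnot(inherits(ag, "ag_structure"), length(models) >= 1L)
  ids <- vapply(models, function(m) as.character(m$id), "")
  if (anyDuplicated(ids)) stop("duplicate model ids in ensemble")
  names(models) <- ids
  structure(list(ag = ag, models = models, source_label = source_label),
            class = "docking_ensemble")
}

#' @export
print.docking_ensemble <- function(x, ...) {
  cat(sprintf("<docking_ensemble> '%s': %d models on a %d-residue antigen\n",
              x$source_label, length(x$models), nrow(x$ag$residues)))
  invisible(x)
}

#' Model ids of an ensemble
#' @param e a [docking_ensemble()]
#' @return character vector
#' @export
model_ids <- function(e) names(e$models)

#' Load a docking ensemble from a directory of pose files
#'
#' Each pose file must contain the antigen chain plus the antibody pose;
#' antigen coordinates must agree across files to within `ag_tol` (poses
#' are rigid-body placements against one fixed antigen). Models are ordered
#' by filename.
#'
#' @param dir directory containing `.pdb` pose files
#' @param ag_chain antigen chain identifier
#' @param ab_chains antibody chain identifier(s); defaults to every chain
#'   other than `ag_chain`
#' @param cutoff footprint contact cutoff in Angstroms
#' @param source_label provenance string
#' @param ag_tol maximal allowed antigen coordinate deviation (A)
#' @return a [docking_ensemble()]
#' @export
load_ensemble <- function(dir, ag_chain, ab_chains = NULL, cutoff = 5,
                          source_label = basename(dir), ag_tol = 1e-3) {
  files <- sort(list.files(dir, pattern = "\\.pdb$", full.names = TRUE))
  if (length(files) == 0L) stop("no .pdb pose files in ", dir)
  ag_ref <- NULL
  models <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    s <- read_structure(f)
    ag_i <- ag_structure(s$atoms[s$atoms$chain == ag_chain, , drop = FALSE])
    if (nrow(ag_i$atoms) == 0L) stop("antigen chain '", ag_chain,
                                     "' missing in ", basename(f))
    ab_at <- if (is.null(ab_chains)) {
      s$atoms[s$atoms$chain != ag_chain, , drop = FALSE]
    } else {
      s$atoms[s$atoms$chain %in% ab_chains, , drop = FALSE]
    }
    if (nrow(ab_at) == 0L) stop("antibody chain(s) missing in ", basename(f))
    if (is.null(ag_ref)) {
      ag_ref <- ag_i
    } else {
      same <- identical(ag_ref$residues$key, ag_i$residues$key) &&
        identical(ag_ref$residues$aa, ag_i$residues$aa) &&
        nrow(ag_ref$atoms) == nrow(ag_i$atoms) &&
        max(abs(coords_mat(ag_ref$atoms) - coords_mat(ag_i$atoms))) <= ag_tol
      if (!same) stop("antigen coordinates in ", basename(f),
                      " differ from the first pose beyond ", ag_tol, " A")
    }
    models[[i]] <- docking_model(
      id = sub("\\.pdb$", "", basename(f)),
      ab = ag_structure(ab_at), ag = ag_ref, cutoff = cutoff
    )
  }
  docking_ensemble(ag_ref, models, source_label)
}

#' Per-model footprint table
#'
#' @param e a [docking_ensemble()]
#' @return tibble with `model_id`, `footprint` (list-column of residue
#'   keys) and `n_footprint`
#' @export
footprint_table <- function(e) {
  tibble::tibble(
    model_id = model_ids(e),
    footprint = lapply(e$models, function(m) m$footprint),
    n_footprint = vapply(e$models, function(m) length(m$footprint), 1L)
  )
}

#' Write per-model footprints as TSV
#'
#' One row per model: model id and comma-separated antigen residue labels.
#'
#' @param e a [docking_ensemble()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_footprints_tsv <- function(e, path) {
  ft <- footprint_table(e)
  utils::write.table(
    data.frame(model_id = ft$model_id,
               footprint = vapply(ft$footprint, paste, "", collapse = ",")),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Fraction of the antigen surface covered by an ensemble's footprints
#'
#' @param e a [docking_ensemble()]
#' @param surface character vector of surface residue keys (non-empty)
#' @return fraction in `[0, 1]`
#' @export
surface_coverage <- function(e, surface) {
  if (length(surface) == 0L) stop("empty surface")
  fp <- unique(unlist(lapply(e$models, function(m) m$footprint)))
  length(intersect(fp, surface)) / length(unique(surface))
}

#' Fraction of native interface contacts reproduced by a model (f_nat)
#'
#' The CAPRI-style interface quality metric: the fraction of
#' antigen-antibody residue pairs in heavy-atom contact in the reference
#' complex that are also in contact in the docking model. Antibody residue
#' identity is matched by residue key, so reference and model must share
#' both antigen and antibody numbering.
#'
#' @param m a [docking_model()]
#' @param reference the reference complex, as a [docking_model()] (antigen
#'   plus the native antibody placement)
#' @param cutoff contact distance in Angstroms
#' @return fraction in `[0, 1]`
#' @export
fnat <- function(m, reference, cutoff = 5) {
  stopifnot(inherits(m, "docking_model"), inherits(reference, "docking_model"))
  ref <- heavy_atom_contacts(reference$ag$atoms, reference$ab$atoms, cutoff)
  if (nrow(ref) == 0L) stop("reference complex has no interface contacts")
  mod <- heavy_atom_contacts(m$ag$atoms, m$ab$atoms, cutoff)
  ref_pairs <- paste(ref$key_a, ref$key_b)
  mod_pairs <- paste(mod$key_a, mod$key_b)
  sum(ref_pairs %in% mod_pairs) / length(ref_pairs)
}

footprint_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Footprint overlap between two docking ensembles
#'
#' The fraction of `a`'s models whose footprint matches some model of `b`,
#' where "matches" means footprint Jaccard similarity at or above
#' `min_jaccard`. This is the package's proxy for percent dock overlap used
#' in epitope-binning matrices; the matching rule is configurable and is
#' labeled in outputs.
#'
#' @param a,b [docking_ensemble()] objects sharing one antigen
#' @param min_jaccard Jaccard threshold for a model-to-model match
#' @return fraction in `[0, 1]`
#' @export
ensemble_overlap <- function(a, b, min_jaccard = 0.25) {
  stopifnot(inherits(a, "docking_ensemble"), inherits(b, "docking_ensemble"))
  fps_b <- lapply(b$models, function(m) m$footprint)
  hit <- vapply(a$models, function(m) {
    any(vapply(fps_b, function(fb) footprint_jaccard(m$footprint, fb) >= min_jaccard,
               TRUE))
  }, TRUE)
  mean(hit)
}

#' Pairwise dock-overlap matrix for several antibodies
#'
#' @param ensembles named list of [docking_ensemble()] objects on one antigen
#' @param min_jaccard Jaccard threshold passed to [ensemble_overlap()]
#' @return symmetric-ish numeric matrix (row i, column j = overlap of i's
#'   models with j's); the measure itself is directional, so small
#'   asymmetries are expected
#' @export
dock_overlap_matrix <- function(ensembles, min_jaccard = 0.25) {
  n <- length(ensembles)
  stopifnot(n >= 2L, !is.null(names(ensembles)))
  M <- matrix(NA_real_, n, n, dimnames = list(names(ensembles), names(ensembles)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- ensemble_overlap(ensembles[[i]], ensembles[[j]], min_jaccard)
  }
  M
}
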