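# Epitope definitions, localization-success scoring, filtering of docking
# models consistent with experimentally disruptive variants, the
# random-design baseline, and summary statistics over the packaged
# retrospective table.

#' Define an epitope as a set of antigen residues
#'
#' @param residues character vector of residue keys (non-empty)
#' @param provenance `"curated-list"` for an experimentally curated residue
#'   list or `"interface-5A"` for a computed co-crystal interface
#' @param antigen optional [ag_structure()]; when given, residues are
#'   checked to exist on it
#' @return object of class `epitope_spec`
#' @export
epitope_spec <- function(residues,
                         provenance = c("curated-list", "interface-5A"),
                         antigen = NULL) {
  provenance <- match.arg(provenance)
  residues <- unique(residues)
  if (length(residues) == 0L) stop("empty epitope")
  if (!is.null(antigen)) {
    missing <- setdiff(residues, antigen$residues$key)
    if (length(missing)) stop("epitope residue(s) not on the antigen: ",
                              paste(missing, collapse = ", "))
  }
  structure(list(residues = residues, provenance = provenance),
            class = "epitope_spec")
}

#' @export
print.epitope_spec <- function(x, ...) {
  cat(sprintf("<epitope_spec> %d residues (%s)\n",
              length(x$residues), x$provenance))
  invisible(x)
}

#' Read an epitope residue list from a text file
#'
#' One residue label (`chain:number`) per line; blank lines and `#`
#' comments are skipped.
#'
#' @param path input file
#' @param antigen optional [ag_structure()] for validation
#' @return an [epitope_spec()] with provenance `"curated-list"`
#' @export
read_epitope_list <- function(path, antigen = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parse_res_key(lines)  # validates the format
  epitope_spec(lines, "curated-list", antigen)
}

#' Binding-interface epitope from a reference complex
#'
#' Antigen residues with any heavy atom within `cutoff` of any antibody
#' heavy atom in the co-crystal (or reference) complex.
#'
#' @param complex the reference complex as a [docking_model()]
#' @param cutoff inter-heavy-atom distance in Angstroms
#' @return an [epitope_spec()] with provenance `"interface-5A"`
#' @export
interface_epitope <- function(complex, cutoff = 5) {
  stopifnot(inherits(complex, "docking_model"))
  res <- footprint(complex, cutoff)
  if (length(res) == 0L) {
    stop("partners make no heavy-atom contact at ", cutoff,
         " A: not a complex")
  }
  epitope_spec(res, "interface-5A", complex$ag)
}

#' Score epitope localization success of a panel
#'
#' An epitope counts as successfully localized when at least one design in
#' the panel contains a mutation at an epitope residue.
#'
#' @param panel an `episcope_panel` (or a design tibble)
#' @param epitope an [epitope_spec()]
#' @return one-row tibble with `success`, `hit_designs` (list-column of
#'   design ids, ordered), `n_hit`
#' @export
localization_success <- function(panel, epitope) {
  d <- if (inherits(panel, "episcope_panel")) panel$designs else panel
  if (nrow(d) == 0L) stop("empty panel")
  hit <- vapply(d$mutations, function(mu) any(mu$key %in% epitope$residues),
                TRUE)
  ids <- sort(d$design_id[hit])
  tibble::tibble(success = length(ids) > 0, hit_designs = list(ids),
                 n_hit = length(ids))
}

#' Docking models consistent with experimentally disruptive designs
#'
#' Once binding assays identify which panel variants ablate antibody
#' binding, the docking ensemble can be filtered to the models whose
#' footprint contains at least one mutated position of a disruptive design;
#' the union of their footprints bounds the possible epitope region.
#'
#' @param panel an `episcope_panel`
#' @param disruptive_design_ids design ids observed to ablate binding
#' @param e the [docking_ensemble()]
#' @param surface surface residue keys (for the surface-fraction readout)
#' @return list with `model_ids` (consistent models) and
#'   `surface_fraction` (fraction of the surface inside the union of their
#'   footprints)
#' @export
consistent_models <- function(panel, disruptive_design_ids, e, surface) {
  d <- panel$designs
  unknown <- setdiff(disruptive_design_ids, d$design_id)
  if (length(unknown)) stop("unknown design id(s): ",
                            paste(unknown, collapse = ", "))
  if (length(disruptive_design_ids) == 0L) {
    return(list(model_ids = character(), surface_fraction = 0))
  }
  pos <- unique(unlist(lapply(
    d$mutations[d$design_id %in% disruptive_design_ids],
    function(mu) mu$key
  )))
  keep <- vapply(e$models, function(m) any(pos %in% m$footprint), TRUE)
  ids <- model_ids(e)[keep]
  fp <- unique(unlist(lapply(e$models[keep], function(m) m$footprint)))
  list(model_ids = ids,
       surface_fraction = length(intersect(fp, surface)) /
         length(unique(surface)))
}

# rejection-sample `pool` random k-position subsets of the surface with
# mean pairwise C-alpha distance strictly below max_spread; returns a
# pool x k index matrix into `keys`
sample_position_sets <- function(cad, keys, k, max_spread, pool) {
  n <- length(keys)
  pr <- utils::combn(k, 2L)
  got <- matrix(0L, 0L, k)
  tries <- 0L
  while (nrow(got) < pool) {
    tries <- tries + 1L
    if (tries > 2000L) stop("spread constraint looks infeasible on this surface")
    m <- max(2L * (pool - nrow(got)), 256L)
    batch <- matrix(sample.int(n, m * k, replace = TRUE), nrow = m)
    dup <- vapply(seq_len(k - 1L), function(a) {
      rowSums(batch[, (a + 1L):k, drop = FALSE] == batch[, a]) > 0
    }, logical(nrow(batch)))
    batch <- batch[rowSums(as.matrix(dup)) == 0, , drop = FALSE]
    if (nrow(batch) == 0L) next
    spread <- rowMeans(vapply(seq_len(ncol(pr)), function(j) {
      cad[cbind(batch[, pr[1L, j]], batch[, pr[2L, j]])]
    }, numeric(nrow(batch))))
    got <- rbind(got, batch[spread < max_spread, , drop = FALSE])
  }
  got[seq_len(pool), , drop = FALSE]
}

#' Random-design baseline success rate
#'
#' Emulates the docking-free control: per replicate, `pool` random
#' k-position surface mutation sets are drawn under the same mean
#' C-alpha-spread constraint as designed variants, `n_designs` of them are
#' selected by the same Hausdorff/K-medoids clustering (the cluster
#' medoids), and the replicate succeeds when any selected set touches the
#' epitope. Positions alone determine success, so amino-acid identities are
#' not sampled.
#'
#' @param s antigen [ag_structure()]
#' @param surface surface residue keys (at least `k`)
#' @param n_designs number of selected sets, matched to the docking-guided
#'   panel size
#' @param epitope an [epitope_spec()]
#' @param k positions per random set
#' @param max_spread spread constraint in Angstroms (strict `<`)
#' @param reps number of replicates
#' @param pool random sets drawn per replicate
#' @param seed RNG seed (sampling is fully reproducible)
#' @return list with `success_rate`, `ci` (exact binomial 95% interval),
#'   `successes`, `reps`
#' @export
random_baseline <- function(s, surface, n_designs, epitope, k = 3,
                            max_spread = 12, reps = 1000, pool = 1000,
                            seed = 1L) {
  surface <- unique(surface)
  stopifnot(length(surface) >= k, n_designs >= 1L)
  ca <- ca_coords(s, surface)
  cad <- as.matrix(stats::dist(ca))
  in_epi <- surface %in% epitope$residues
  successes <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      sets <- sample_position_sets(cad, surface, k, max_spread, pool)
      # every sampled set draws its points from the shared surface, so the
      # Hausdorff matrix comes from index lookups into one distance table
      D <- .hausdorff_matrix_idx_cpp(sets, cad)
      med <- kmedoids(D, min(n_designs, nrow(sets)))$medoids
      any(in_epi[as.vector(sets[med, , drop = FALSE])])
    }, TRUE)
  })
  n_succ <- sum(successes)
  ci <- stats::binom.test(n_succ, reps)$conf.int
  list(success_rate = n_succ / reps, ci = as.numeric(ci),
       successes = n_succ, reps = reps)
}

#' Summary statistics over a retrospective results table
#'
#' Computes column means and standard deviations, localization success
#' counts and rates per epitope definition (curated vs binding interface)
#' and antigen structure source (crystal vs homology model), the Kendall
#' rank correlation (tau-b, tie-corrected) between the number of docking
#' decoys and the number of designs per structure source, and the Pearson
#' correlation between antigen size and the number of designs (whole-chain
#' residue count is the primary size measure; the surface count variant is
#' also emitted). Degenerate (constant) columns yield `NA` correlations
#' with a flag.
#'
#' @param tbl a retrospective table as returned by
#'   [packaged_retrospective()]
#' @return object of class `retro_summary`: list of tibbles
#'   `column_stats`, `success_rates`, `correlations`
#' @export
summarize_retrospective <- function(tbl) {
  num_cols <- names(tbl)[vapply(tbl, is.numeric, TRUE)]
  if (anyNA(tbl[num_cols])) stop("missing cells in the retrospective table")
  column_stats <- tibble::tibble(
    column = num_cols,
    mean = unname(vapply(num_cols, function(cn) mean(tbl[[cn]]), 0)),
    sd = unname(vapply(num_cols, function(cn) stats::sd(tbl[[cn]]), 0))
  )
  flag_cols <- list(
    c("curated-list", "crystal", "success_iedb_crystal"),
    c("curated-list", "model", "success_iedb_model"),
    c("interface-5A", "crystal", "success_interface_crystal"),
    c("interface-5A", "model", "success_interface_model")
  )
  success_rates <- dplyr::bind_rows(lapply(flag_cols, function(fc) {
    flags <- tbl[[fc[3L]]]
    if (is.character(flags)) flags <- flags == "T"
    tibble::tibble(epitope_definition = fc[1L], structure_source = fc[2L],
                   n_success = sum(flags), n = length(flags),
                   rate = mean(flags))
  }))
  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y, method = method)
  }
  correlations <- tibble::tibble(
    statistic = c("kendall_decoys_designs", "kendall_decoys_designs",
                  "pearson_size_designs", "pearson_size_designs",
                  "pearson_surface_designs", "pearson_surface_designs"),
    structure_source = rep(c("crystal", "model"), 3L),
    value = c(
      safe_cor(tbl$n_decoys_crystal, tbl$n_designs_crystal, "kendall"),
      safe_cor(tbl$n_decoys_model, tbl$n_designs_model, "kendall"),
      safe_cor(tbl$n_residues_whole, tbl$n_designs_crystal, "pearson"),
      safe_cor(tbl$n_residues_whole, tbl$n_designs_model, "pearson"),
      safe_cor(tbl$n_residues_surface, tbl$n_designs_crystal, "pearson"),
      safe_cor(tbl$n_residues_surface, tbl$n_designs_model, "pearson")
    ),
    primary = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  correlations$degenerate <- is.na(correlations$value)
  structure(list(column_stats = column_stats, success_rates = success_rates,
                 correlations = correlations),
            class = "retro_summary")
}

#' @export
print.retro_summary <- function(x, ...) {
  cat("<retro_summary>\n\nColumn means:\n")
  print(x$column_stats, n = Inf)
  cat("\nSuccess rates:\n")
  print(x$success_rates)
  cat("\nCorrelations:\n")
  print(x$correlations)
  invisible(x)
}
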