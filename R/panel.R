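# Clustering of candidate designs by the Hausdorff distance between their
# mutated C-alpha point sets, and selection of a minimal covering panel:
# K is grown from 1 until some combination of designs, one per cluster,
# disrupts every coverable docking model; among covering combinations the
# one with the highest summed disruptiveness wins.

#' Hausdorff distance between two point sets
#'
#' `h(A, B) = max( max_a min_b d(a, b), max_b min_a d(a, b) )` with
#' Euclidean `d`; symmetric, zero iff the sets coincide.
#'
#' @param A,B numeric matrices (rows are 3D points, non-empty)
#' @return distance in the coordinate units (Angstroms here)
#' @export
hausdorff <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) >= 1L, nrow(B) >= 1L, ncol(A) == 3L, ncol(B) == 3L)
  .hausdorff_cpp(A, B)
}

#' Pairwise Hausdorff distance matrix over a list of point sets
#'
#' @param sets list of numeric n x 3 matrices
#' @return symmetric matrix of distances
#' @export
hausdorff_matrix <- function(sets) {
  stopifnot(length(sets) >= 1L)
  sets <- lapply(sets, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) >= 1L, ncol(m) == 3L)
    storage.mode(m) <- "double"
    m
  })
  .hausdorff_matrix_cpp(sets)
}

#' Mutated-position C-alpha point sets of a design table
#'
#' @param designs a design tibble (see [merge_and_annotate()])
#' @param s the antigen [ag_structure()]
#' @return list of k x 3 coordinate matrices, one per design
#' @export
design_point_sets <- function(designs, s) {
  lapply(designs$mutations, function(mu) ca_coords(s, mu$key))
}

#' K-medoids clustering under a precomputed distance matrix
#'
#' Partitioning Around Medoids: deterministic BUILD initialization
#' followed by SWAP to a local optimum, in compiled code (the baseline
#' clusters a thousand sets per replicate, so this sits on a hot path).
#' Every cluster is non-empty and centered on an actual data point; ties
#' break toward the lowest index, so results are exactly reproducible.
#'
#' @param D symmetric distance matrix
#' @param K number of clusters (at most `nrow(D)`)
#' @param seed accepted for interface stability; BUILD+SWAP is
#'   deterministic, so the result does not depend on it
#' @return list with `clusters` (integer assignment vector), `medoids`
#'   (indices into the rows of `D`) and `cost` (summed distance to the
#'   assigned medoids)
#' @export
kmedoids <- function(D, K, seed = 1L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (K > n) stop("K (", K, ") exceeds the number of items (", n, ")")
  if (K == n) {
    return(list(clusters = seq_len(n), medoids = seq_len(n), cost = 0))
  }
  fit <- .pam_cpp(D, as.integer(K), integer())
  list(clusters = fit$clusters, medoids = unname(fit$medoids),
       cost = fit$cost)
}

# alternative K-medoids local optima at the same K: the deterministic
# BUILD+SWAP solution first, then seeded random-initialization restarts
# (SWAP-only), with duplicate partitions dropped
kmedoids_restarts <- function(D, K, seed = 1L, restarts = 10L) {
  n <- nrow(D)
  fits <- list(kmedoids(D, K, seed))
  if (K < n && restarts > 0L) {
    inits <- withr::with_seed(seed, {
      lapply(seq_len(restarts), function(r) sort(sample.int(n, K)))
    })
    for (ini in inits) {
      fit <- .pam_cpp(as.matrix(D), as.integer(K), as.integer(ini))
      fits[[length(fits) + 1L]] <-
        list(clusters = fit$clusters, medoids = unname(fit$medoids),
             cost = fit$cost)
    }
  }
  seen <- character()
  keep <- list()
  for (f in fits) {
    sig <- paste(f$clusters, collapse = ",")
    if (!sig %in% seen) {
      seen <- c(seen, sig)
      keep[[length(keep) + 1L]] <- f
    }
  }
  keep
}

# logical designs x models coverage matrix
coverage_matrix <- function(designs, mids) {
  M <- matrix(FALSE, nrow(designs), length(mids),
              dimnames = list(designs$design_id, mids))
  for (i in seq_len(nrow(designs))) {
    M[i, intersect(designs$covered_models[[i]], mids)] <- TRUE
  }
  M
}

# greedy max-coverage fallback for combination counts beyond the budget
greedy_cover <- function(covmat, need, designs) {
  chosen <- integer()
  left <- need
  while (length(left)) {
    gain <- rowSums(covmat[, left, drop = FALSE])
    gain[chosen] <- -1
    best <- which(gain == max(gain))
    best <- best[order(designs$design_id[best])][1L]
    if (gain[best] <= 0) break
    chosen <- c(chosen, best)
    left <- left[!covmat[best, left]]
  }
  chosen
}

#' Select a minimal covering panel of designs
#'
#' Clusters the designs by the Hausdorff distance between their mutated
#' C-alpha point sets and, starting at `K = 1`, increases K until some
#' combination of designs, one drawn from each cluster, jointly covers
#' every coverable docking model. At each K, the deterministic clustering
#' and a fixed number of seeded random-restart local optima are probed, so
#' K only grows when no clustering at the current K admits a covering
#' combination. Among covering combinations the one with the largest
#' summed disruptiveness is returned (ties broken by the lexicographically
#' smallest design-id tuple). Models covered by no design at all are
#' excluded from the requirement and reported as `uncovered`.
#' When the number of one-per-cluster combinations exceeds
#' `params$combo_budget`, selection falls back to greedy max-coverage with
#' a warning.
#'
#' @param designs design tibble from [merge_and_annotate()] /
#'   [design_variants()]
#' @param e the [docking_ensemble()] the designs were built against
#' @param params a [design_params()] (for the combination budget)
#' @param seed accepted for interface stability; the search is
#'   deterministic
#' @return an object of class `episcope_panel`: list with `designs` (the
#'   selected rows), `K`, `coverage` (tibble `model_id`, `design_ids`
#'   list-column), `uncovered` (model ids), `objective` (summed
#'   disruptiveness) and `method` (`"exhaustive"` or `"greedy"`)
#' @export
select_panel <- function(designs, e, params = design_params(), seed = 1L) {
  if (nrow(designs) == 0L) stop("empty design list")
  mids <- model_ids(e)
  covmat <- coverage_matrix(designs, mids)
  coverable <- mids[colSums(covmat) > 0]
  uncovered <- setdiff(mids, coverable)
  need <- match(coverable, mids)

  finish <- function(sel_idx, K, method) {
    sel <- designs[sel_idx, , drop = FALSE]
    sel <- sel[order(sel$design_id), , drop = FALSE]
    cov <- lapply(mids, function(mid) {
      sel$design_id[vapply(sel$covered_models, function(cm) mid %in% cm, TRUE)]
    })
    structure(list(
      designs = sel,
      K = K,
      coverage = tibble::tibble(model_id = mids, design_ids = cov),
      uncovered = uncovered,
      objective = sum(sel$total_disruption),
      method = method
    ), class = "episcope_panel")
  }

  if (length(coverable) == 0L) {
    warning("no docking model is coverable by any design", call. = FALSE)
    best <- which.max(designs$total_disruption)
    return(finish(best, 1L, "exhaustive"))
  }

  pts <- design_point_sets(designs, e$ag)
  D <- hausdorff_matrix(pts)
  n <- nrow(designs)
  for (K in seq_len(n)) {
    # alternative clusterings at this K (deterministic solution plus
    # seeded restarts): a covering combination under any of them keeps K
    # from growing unnecessarily
    for (fit in kmedoids_restarts(D, K, seed)) {
      groups <- split(seq_len(n), fit$clusters)
      n_combo <- prod(lengths(groups))
      if (n_combo > params$combo_budget) {
        warning("combination count ", format(n_combo, big.mark = ","),
                " exceeds the budget; falling back to greedy max-coverage",
                call. = FALSE)
        sel <- greedy_cover(covmat, need, designs)
        return(finish(sel, K, "greedy"))
      }
      combos <- as.matrix(expand.grid(groups, KEEP.OUT.ATTRS = FALSE))
      covers <- vapply(seq_len(nrow(combos)), function(r) {
        idx <- combos[r, ]
        all(colSums(covmat[idx, need, drop = FALSE]) > 0)
      }, TRUE)
      if (any(covers)) {
        hits <- combos[covers, , drop = FALSE]
        obj <- vapply(seq_len(nrow(hits)), function(r) {
          sum(designs$total_disruption[hits[r, ]])
        }, 0)
        top <- which(obj == max(obj))
        if (length(top) > 1L) {
          tuples <- vapply(top, function(r) {
            paste(sort(designs$design_id[hits[r, ]]), collapse = "|")
          }, "")
          top <- top[order(tuples)][1L]
        }
        return(finish(unique(hits[top, ]), K, "exhaustive"))
      }
    }
  }
  # unreachable when coverable is non-empty: at K = n every design is its
  # own cluster and the single combination is the full design set
  stop("internal error: no covering combination found at K = n")
}

#' @export
print.episcope_panel <- function(x, ...) {
  cat(sprintf(
    "<episcope_panel> %d design(s) at K = %d covering %d/%d model(s)%s\n",
    nrow(x$designs), x$K,
    sum(lengths(x$coverage$design_ids) > 0),
    nrow(x$coverage),
    if (length(x$uncovered)) paste0(" (", length(x$uncovered), " uncoverable)")
    else ""
  ))
  print(x$designs[, c("design_id", "label", "n_covered", "total_disruption")])
  invisible(x)
}

#' Pool docking ensembles from several antibodies against one antigen
#'
#' Concatenates the model lists, tagging model ids with their antibody
#' label, so that design and panel selection run unchanged on the combined
#' hypothesis set (one variant panel interrogating all antibodies at once).
#'
#' @param ensembles named list of [docking_ensemble()] objects sharing one
#'   antigen (coordinates equal within `ag_tol`)
#' @param ag_tol maximal allowed antigen coordinate deviation (A)
#' @return a pooled [docking_ensemble()] with ids `"<label>:<model id>"`
#' @export
pool_ensembles <- function(ensembles, ag_tol = 1e-3) {
  stopifnot(length(ensembles) >= 1L)
  labs <- names(ensembles)
  if (is.null(labs) || any(labs == "")) {
    labs <- vapply(ensembles, function(e) e$source_label, "")
  }
  ref <- ensembles[[1L]]$ag
  models <- list()
  for (i in seq_along(ensembles)) {
    e <- ensembles[[i]]
    same <- identical(ref$residues$key, e$ag$residues$key) &&
      identical(ref$residues$aa, e$ag$residues$aa) &&
      nrow(ref$atoms) == nrow(e$ag$atoms) &&
      max(abs(coords_mat(ref$atoms) - coords_mat(e$ag$atoms))) <= ag_tol
    if (!same) stop("ensemble '", labs[i], "' has a different antigen")
    for (m in e$models) {
      m$id <- paste0(labs[i], ":", m$id)
      m$ag <- ref
      models[[length(models) + 1L]] <- m
    }
  }
  docking_ensemble(ref, models,
                   source_label = paste(labs, collapse = "+"))
}

#' Average Hausdorff distance between per-antibody design sets
#'
#' Entry (i, j) is the mean Hausdorff distance over all pairs of designs
#' (one from antibody i, one from antibody j), computed on the mutated
#' C-alpha point sets; diagonal entries average over distinct pairs within
#' the antibody (0 when it has a single design). Low off-diagonal values
#' flag antibodies whose designs target the same antigen region (in-silico
#' epitope binning).
#'
#' @param per_ab_designs named list (>= 2 entries) of design tibbles
#' @param s the shared antigen [ag_structure()]
#' @return symmetric numeric matrix with antibody labels as dimnames
#' @export
design_distance_matrix <- function(per_ab_designs, s) {
  labs <- names(per_ab_designs)
  stopifnot(length(per_ab_designs) >= 2L, !is.null(labs))
  empty <- vapply(per_ab_designs, function(d) nrow(d) == 0L, TRUE)
  if (any(empty)) stop("empty design list for: ",
                       paste(labs[empty], collapse = ", "))
  pts <- lapply(per_ab_designs, design_point_sets, s = s)
  all_pts <- unlist(pts, recursive = FALSE)
  sizes <- lengths(pts)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  D <- hausdorff_matrix(all_pts)
  M <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    ri <- offs[i] + seq_len(sizes[i])
    rj <- offs[j] + seq_len(sizes[j])
    if (i == j) {
      M[i, j] <- if (sizes[i] < 2L) 0 else mean(D[ri, rj][upper.tri(D[ri, rj])])
    } else {
      M[i, j] <- mean(D[ri, rj])
    }
  }
  M
}

#' Write a selected panel as TSV
#'
#' @param panel an `episcope_panel`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_panel_tsv <- function(panel, path) {
  d <- panel$designs
  utils::write.table(
    data.frame(
      design_id = d$design_id,
      mutations = d$label,
      covered_model_ids = vapply(d$covered_models, paste, "", collapse = ","),
      disruptiveness = sprintf("%.6g", d$total_disruption),
      stability_delta = sprintf("%.6g", d$stability_delta),
      spread_A = sprintf("%.4f", d$spread)
    ),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a panel selection report as JSON
#'
#' @param panel an `episcope_panel`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_panel_json <- function(panel, path) {
  jsonlite::write_json(
    list(
      K = panel$K,
      method = panel$method,
      objective = panel$objective,
      designs = panel$designs$design_id,
      coverage = stats::setNames(panel$coverage$design_ids,
                                 panel$coverage$model_id),
      uncovered = panel$uncovered
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
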