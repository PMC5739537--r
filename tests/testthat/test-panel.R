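# Hausdorff geometry, K-medoids, covering-panel selection, pooling and
# the antibody design-distance matrix.

test_that("hausdorff matches hand-evaluated cases", {
  p <- rbind(c(1, 2, 3))
  expect_equal(hausdorff(p, p), 0)
  expect_equal(hausdorff(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  # directed terms: 0 forward, 10 backward
  expect_equal(hausdorff(rbind(c(0, 0, 0), c(10, 0, 0)), rbind(c(0, 0, 0))),
               10)
  expect_error(hausdorff(matrix(0, 0, 3), p))
})

test_that("hausdorff equals the double-loop oracle on random point sets", {
  withr::with_seed(31, {
    for (i in 1:100) {
      A <- matrix(stats::runif(3 * sample(1:6, 1L), 0, 30), ncol = 3)
      B <- matrix(stats::runif(3 * sample(1:6, 1L), 0, 30), ncol = 3)
      # agreement to floating accumulation order (R sums in long double)
      expect_equal(hausdorff(A, B), bf_hausdorff(A, B), tolerance = 1e-12)
    }
  })
})

test_that("hausdorff is symmetric and satisfies the triangle inequality", {
  withr::with_seed(77, {
    for (i in 1:40) {
      A <- matrix(stats::runif(9, 0, 20), ncol = 3)
      B <- matrix(stats::runif(12, 0, 20), ncol = 3)
      C <- matrix(stats::runif(6, 0, 20), ncol = 3)
      expect_equal(hausdorff(A, B), hausdorff(B, A), tolerance = 1e-12)
      expect_lte(hausdorff(A, C),
                 hausdorff(A, B) + hausdorff(B, C) + 1e-9)
    }
  })
})

test_that("the pairwise matrix agrees with one-at-a-time evaluation", {
  withr::with_seed(8, {
    sets <- lapply(1:12, function(i) matrix(stats::runif(9, 0, 15), ncol = 3))
    D <- hausdorff_matrix(sets)
    for (i in 1:12) for (j in 1:12) {
      expect_equal(D[i, j], if (i == j) 0 else hausdorff(sets[[i]], sets[[j]]))
    }
    # the index-based kernel gives the same matrix when all sets draw from
    # one shared point pool
    pool <- matrix(stats::runif(60, 0, 15), ncol = 3)
    idx <- t(replicate(10, sample.int(20, 3)))
    Dp <- as.matrix(stats::dist(pool))
    D1 <- episcope:::.hausdorff_matrix_idx_cpp(idx, Dp)
    D2 <- hausdorff_matrix(lapply(seq_len(10), function(r) {
      pool[idx[r, ], , drop = FALSE]
    }))
    expect_equal(D1, D2, tolerance = 1e-12)
  })
})

test_that("K-medoids degenerate and constructed cases behave", {
  withr::with_seed(12, {
    X <- matrix(stats::runif(30), ncol = 3)
    D <- as.matrix(stats::dist(X))
    n <- nrow(D)
    all_self <- kmedoids(D, n)
    expect_equal(sort(all_self$medoids), 1:n)
    expect_equal(all_self$cost, 0)
    expect_error(kmedoids(D, n + 1L), "exceeds")
    # K = 1: the medoid minimizes the summed distance (exhaustive check)
    one <- kmedoids(D, 1L)
    expect_equal(one$medoids, unname(which.min(colSums(D))))
    # two well-separated groups are recovered at K = 2
    Y <- rbind(matrix(stats::rnorm(15, 0, 0.3), ncol = 3),
               matrix(stats::rnorm(15, 50, 0.3), ncol = 3))
    cl <- kmedoids(as.matrix(stats::dist(Y)), 2L)$clusters
    expect_equal(length(unique(cl[1:5])), 1L)
    expect_equal(length(unique(cl[6:10])), 1L)
    expect_true(cl[1] != cl[6])
  })
})

test_that("compiled PAM reaches swap-local optima comparable to
           cluster::pam", {
  skip_if_not_installed("cluster")
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(6:16, 1L)
      K <- sample(1:4, 1L)
      D <- as.matrix(stats::dist(matrix(stats::runif(3 * n), ncol = 3)))
      mine <- kmedoids(D, K)
      # reported cost is consistent with the medoid set
      expect_equal(sum(apply(D[, mine$medoids, drop = FALSE], 1L, min)),
                   mine$cost)
      # every point sits with its nearest medoid
      expect_equal(mine$clusters,
                   unname(apply(D[, mine$medoids, drop = FALSE], 1L,
                                which.min)))
      # no single medoid/non-medoid exchange improves the cost: the PAM
      # convergence criterion, checked exhaustively
      for (m in seq_len(K)) {
        for (h in setdiff(seq_len(n), mine$medoids)) {
          swapped <- mine$medoids
          swapped[m] <- h
          expect_gte(sum(apply(D[, swapped, drop = FALSE], 1L, min)),
                     mine$cost - 1e-9)
        }
      }
      # both implementations are local optima of the same objective:
      # costs agree to within a few percent either way
      ref <- cluster::pam(stats::as.dist(D), K)
      ref_cost <- sum(apply(D[, ref$id.med, drop = FALSE], 1L, min))
      expect_lte(abs(mine$cost - ref_cost), 0.05 * max(ref_cost, 1e-9))
    }
  })
})

test_that("panel selection solves the textbook cover case", {
  inst <- random_cover_instance(1, n_designs = 3, n_models = 3)
  d <- inst$designs
  d$covered_models <- list(c("M01", "M02"), c("M02", "M03"), c("M01", "M03"))
  d$n_covered <- 2L
  e <- fake_ensemble(inst$s, c("M01", "M02", "M03"))
  panel <- select_panel(d, e)
  expect_equal(nrow(panel$designs), 2L)
  expect_length(panel$uncovered, 0L)
  # one design covering everything wins at K = 1
  d2 <- d
  d2$covered_models[[1L]] <- c("M01", "M02", "M03")
  p2 <- select_panel(d2, e)
  expect_equal(p2$K, 1L)
  expect_identical(p2$designs$design_id, "D01")
  expect_error(select_panel(d[0L, ], e), "empty design list")
})

test_that("models no design can touch are reported, not demanded", {
  inst <- random_cover_instance(2, n_designs = 2, n_models = 2)
  d <- inst$designs
  d$covered_models <- list("M01", "M01")
  e <- fake_ensemble(inst$s, c("M01", "MX"))
  panel <- select_panel(d, e)
  expect_identical(panel$uncovered, "MX")
  expect_true(all(lengths(panel$coverage$design_ids[
    panel$coverage$model_id == "M01"]) > 0))
  # adding a strictly uncoverable model changes only the uncovered list
  e2 <- fake_ensemble(inst$s, "M01")
  p2 <- select_panel(d, e2)
  expect_identical(p2$designs$design_id, panel$designs$design_id)
})

test_that("panels always cover every coverable model and K matches the
           panel size", {
  for (seed in 1:25) {
    inst <- random_cover_instance(seed)
    e <- fake_ensemble(inst$s, inst$model_ids)
    panel <- suppressWarnings(select_panel(inst$designs, e))
    coverable <- intersect(unlist(inst$designs$covered_models),
                           inst$model_ids)
    expect_true(all(coverable %in% unlist(panel$designs$covered_models)))
    expect_setequal(panel$uncovered, setdiff(inst$model_ids, coverable))
    if (panel$method == "exhaustive" && length(coverable)) {
      expect_equal(nrow(panel$designs), panel$K)
      # never larger than the greedy cover, never smaller than the
      # brute-force minimum
      want <- bf_min_cover_size(inst$designs$covered_models,
                                inst$model_ids)
      expect_gte(nrow(panel$designs), want)
    }
  }
})

test_that("ties in the objective break to the smallest design-id tuple", {
  s <- episcope:::helix_antigen(40, strrep("A", 40))
  mk <- function(id, pos, covered, disr) {
    tibble::tibble(
      design_id = id, label = paste(pos, collapse = ";"),
      mutations = list(tibble::tibble(key = pos, wt = "A", mut = "G")),
      n_mutations = length(pos),
      spread = mean_pairwise_ca_distance(s, pos), stability_delta = -1,
      total_disruption = disr, covered_models = list(covered),
      n_covered = length(covered), source_models = list(character())
    )
  }
  # two spatial groups, so K = 2 clusters them cleanly; all covering
  # pairs tie at objective 3 and the smallest id tuple must win
  d <- dplyr::bind_rows(
    mk("D01", res_key("A", 1:3), "M01", 1),
    mk("D02", res_key("A", 2:4), "M01", 1),
    mk("D03", res_key("A", 30:32), "M02", 2),
    mk("D04", res_key("A", 31:33), "M02", 2)
  )
  e <- fake_ensemble(s, c("M01", "M02"))
  panel <- select_panel(d, e)
  expect_identical(panel$designs$design_id, c("D01", "D03"))
  expect_equal(panel$objective, 3)
})

test_that("exceeding the combination budget falls back to greedy cover", {
  inst <- random_cover_instance(4, n_designs = 6, n_models = 4)
  d <- inst$designs
  d$covered_models <- rep(list(inst$model_ids[1:4]), 6L)
  e <- fake_ensemble(inst$s, inst$model_ids[1:4])
  params <- design_params(combo_budget = 1)
  expect_warning(panel <- select_panel(d, e, params), "greedy")
  expect_identical(panel$method, "greedy")
  expect_true(all(inst$model_ids[1:4] %in%
                    unlist(panel$designs$covered_models)))
})

test_that("panel TSV output is byte-identical across reruns", {
  sc <- make_scenario(n_res = 40, n_models = 6, seed = 19)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  r1 <- suppressWarnings(run_scenario(sc))
  r2 <- suppressWarnings(run_scenario(sc))
  write_panel_tsv(r1$panel, f1)
  write_panel_tsv(r2$panel, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 1L)
})

test_that("pooling concatenates ensembles over one antigen and tags ids", {
  ms <- scenario_multi_ab(n_abs = 2, n_groups = 2, seed = 6, n_res = 60,
                          n_models = 5)
  pooled <- pool_ensembles(ms$ensembles)
  expect_length(pooled$models, 10L)
  expect_true(all(grepl("^Ab0[12]:", model_ids(pooled))))
  # pooling a single ensemble keeps its models unchanged (modulo the tag)
  one <- pool_ensembles(ms$ensembles[1L])
  expect_length(one$models, 5L)
  expect_setequal(
    unname(vapply(one$models, function(m) length(m$footprint), 1L)),
    unname(vapply(ms$ensembles[[1L]]$models,
                  function(m) length(m$footprint), 1L))
  )
  # a different antigen is rejected
  other <- make_scenario(n_res = 60, n_models = 1, seed = 7)
  expect_error(pool_ensembles(list(a = ms$ensembles[[1L]],
                                   b = other$ensemble)),
               "different antigen")
})

test_that("a pooled panel is never larger than the per-antibody panels
           combined", {
  for (seed in c(2, 5, 9)) {
    ms <- scenario_multi_ab(n_abs = 2, n_groups = 2, seed = seed,
                            n_res = 60, n_models = 5)
    singles <- lapply(ms$ensembles, function(e) {
      suppressWarnings(run_episcope(e, msa = ms$msa))
    })
    pooled <- suppressWarnings(run_episcope(pool_ensembles(ms$ensembles),
                                            msa = ms$msa))
    expect_lte(nrow(pooled$panel$designs),
               sum(vapply(singles, function(r) nrow(r$panel$designs), 1L)))
  }
})

test_that("design distance matrices average pairwise Hausdorff distances", {
  sc <- make_scenario(n_res = 40, n_models = 2, seed = 23)
  s <- sc$antigen
  mk_design <- function(id, pos) {
    tibble::tibble(
      design_id = id, label = paste(pos, collapse = ";"),
      mutations = list(tibble::tibble(
        key = pos, wt = s$residues$aa[match(pos, s$residues$key)], mut = "A"
      )),
      n_mutations = length(pos), spread = 0, stability_delta = -1,
      total_disruption = 1, covered_models = list(character()),
      n_covered = 0L, source_models = list(character())
    )
  }
  dA <- mk_design("A1", res_key("A", 1:3))
  dB <- mk_design("B1", res_key("A", 10:12))
  M <- design_distance_matrix(list(x = dA, y = dB), s)
  expect_equal(M["x", "x"], 0)
  expect_equal(M["x", "y"],
               hausdorff(ca_coords(s, res_key("A", 1:3)),
                         ca_coords(s, res_key("A", 10:12))))
  expect_equal(M, t(M))
  # identical single-design lists give a zero entry
  M0 <- design_distance_matrix(list(x = dA, y = dA), s)
  expect_equal(M0["x", "y"], 0)
  # 3 x 2 design lists equal the hand-averaged 6-entry pair table
  dX <- dplyr::bind_rows(mk_design("X1", res_key("A", 1:3)),
                         mk_design("X2", res_key("A", 5:7)),
                         mk_design("X3", res_key("A", 20:22)))
  dY <- dplyr::bind_rows(mk_design("Y1", res_key("A", 9:11)),
                         mk_design("Y2", res_key("A", 30:32)))
  M2 <- design_distance_matrix(list(x = dX, y = dY), s)
  pts_x <- design_point_sets(dX, s)
  pts_y <- design_point_sets(dY, s)
  acc <- 0
  for (i in 1:3) for (j in 1:2) acc <- acc + bf_hausdorff(pts_x[[i]],
                                                          pts_y[[j]])
  expect_equal(M2["x", "y"], acc / 6)
  expect_error(design_distance_matrix(list(x = dX, y = dY[0L, ]), s),
               "empty design list")
})
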