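# Homolog substitution filter, disruptiveness, stability, candidate
# enumeration, Pareto design and the cross-model merge rules.

test_that("allowed substitutions are the non-wild-type homolog residues", {
  msa <- c(ag = "AC", h1 = "AC", h2 = "SC", h3 = "-C")
  subs <- allowed_substitutions(msa, "AC")
  expect_identical(subs$allowed[[1L]], "S")
  expect_identical(subs$allowed[[2L]], character())  # undesignable
  expect_error(allowed_substitutions(c(ag = "ACD", h = "ACD"), "AC"),
               "does not match")
})

test_that("gapped antigen rows map columns back to antigen positions", {
  msa <- c(ag = "A-CD", h1 = "ASCE", h2 = "A-FD")
  subs <- allowed_substitutions(msa, "ACD")
  expect_equal(nrow(subs), 3L)
  expect_identical(subs$allowed[[2L]], "F")
  expect_identical(subs$allowed[[3L]], "E")
})

test_that("per-column tallies match a brute-force count on a 5-row MSA", {
  withr::with_seed(21, {
    sc <- make_scenario(n_res = 24, n_models = 1, msa_depth = 4, seed = 21)
    subs <- allowed_substitutions(sc$msa, sc$antigen)
    M <- do.call(rbind, strsplit(unname(sc$msa), ""))
    for (j in seq_len(ncol(M))) {
      col <- M[-1L, j]
      want <- sort(unique(col[col != "-" & col != M[1L, j]]))
      expect_identical(subs$allowed[[j]], want)
    }
    # min_count = 2 keeps only substitutions seen at least twice
    subs2 <- allowed_substitutions(sc$msa, sc$antigen, min_count = 2)
    for (j in seq_len(ncol(M))) {
      col <- M[-1L, j]
      tab <- table(col[col != "-" & col != M[1L, j]])
      expect_identical(subs2$allowed[[j]],
                       sort(as.character(names(which(tab >= 2)))))
    }
  })
})

test_that("disruptiveness is the contact-energy change toward the pose", {
  ag <- point_structure(cbind(8 * (1:5), 0, 0), aa = "A")
  # three antibody pseudo-residues all contacting antigen residue 3
  ab <- toy_structure(chain = "H", resno = 1:3, aa = c("Y", "S", "D"),
                      elety = rep("CA", 3), element = rep("C", 3),
                      xyz = rbind(c(24, 4, 0), c(24, -4, 0), c(24, 0, 4)))
  m <- docking_model("m", ab, ag)
  expect_identical(m$footprint, "A:3")
  # constructed potential: every contact of the mutant costs exactly 1 more
  mat <- matrix(0, 20, 20, dimnames = list(episcope:::AA1, episcope:::AA1))
  mat["W", ] <- 1; mat[, "W"] <- 1; mat["W", "W"] <- 2
  pot <- pair_potential(mat, "constructed")
  expect_equal(disruptiveness("A:3", "W", m, pot), 3)
  expect_equal(disruptiveness("A:3", "A", m, pot), 0)  # identity
  expect_error(disruptiveness("A:1", "W", m, pot), "outside the footprint")
  # swapping wild type and mutant flips the sign
  ag_w <- point_structure(cbind(8 * (1:5), 0, 0), aa = "W")
  m_w <- docking_model("m", ab, ag_w)
  expect_equal(disruptiveness("A:3", "A", m_w, pot),
               -disruptiveness("A:3", "W", m, pot))
})

test_that("stability deltas sum contact-potential changes over neighbors", {
  pot <- default_pair_potential()
  s <- point_structure(rbind(c(0, 0, 0), c(3, 0, 0), c(4, 3, 0),
                             c(50, 0, 0)),
                       aa = c("L", "K", "E", "V"))
  expect_equal(stability_delta(s, tibble::tibble(key = character(),
                                                 wt = character(),
                                                 mut = character()),
                               pot = pot), 0)
  # the isolated residue A:4 has no neighbors within 5 A
  expect_equal(stability_delta(s, tibble::tibble(key = "A:4", wt = "V",
                                                 mut = "D"), pot = pot), 0)
  # hand-summed delta for mutating A:1 (neighbors A:2 at 3 A, A:3 at 5 A)
  want <- (pot["F", "K"] - pot["L", "K"]) + (pot["F", "E"] - pot["L", "E"])
  expect_equal(stability_delta(s, tibble::tibble(key = "A:1", wt = "L",
                                                 mut = "F"), pot = pot),
               want)
  expect_error(stability_delta(s, tibble::tibble(key = "A:1", wt = "Q",
                                                 mut = "F"), pot = pot),
               "wild-type mismatch")
  # a failing custom scorer is reported with position context
  expect_error(
    stability_delta(s, tibble::tibble(key = "A:1", wt = "L", mut = "F"),
                    scorer = function(s, mu) stop("boom")),
    "A:1"
  )
})

test_that("steric clashes force rejection through an infinite delta", {
  s <- toy_structure(chain = "A", resno = c(1L, 1L, 2L),
                     aa = c("A", "A", "G"),
                     elety = c("CA", "CB", "CA"),
                     element = c("C", "C", "C"),
                     xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(3, 0, 0)))
  # CB of residue 1 sits 1.5 A from residue 2: below the 2.5 A proxy limit
  expect_identical(stability_delta(s, tibble::tibble(key = "A:1", wt = "A",
                                                     mut = "W")), Inf)
})

test_that("candidate mutations keep only positive disruptiveness at
           surface footprint positions", {
  sc <- make_scenario(n_res = 30, n_models = 2, seed = 13)
  m <- sc$ensemble$models[[1L]]
  subs <- allowed_substitutions(sc$msa, sc$antigen)
  pot <- default_pair_potential()
  # no surface overlap -> no candidates
  expect_equal(nrow(candidate_mutations(m, character(), subs, pot)), 0L)
  surf <- surface_residues(relative_accessibility(sc$antigen))
  cand <- candidate_mutations(m, surf, subs, pot)
  expect_true(all(cand$key %in% intersect(m$footprint, surf)))
  expect_true(all(cand$disruptiveness > 0))
  # brute-force enumeration over every footprint position and allowed
  # substitution reproduces the candidate list exactly
  want <- list()
  for (key in intersect(m$footprint, surf)) {
    i <- match(key, subs$key)
    for (aa in subs$allowed[[i]]) {
      d <- disruptiveness(key, aa, m, pot)
      if (d > 0) want[[length(want) + 1L]] <-
          data.frame(key = key, mut = aa, disruptiveness = d)
    }
  }
  want <- do.call(rbind, want)
  got <- cand[order(cand$key, cand$mut), ]
  want <- want[order(want$key, want$mut), ]
  expect_equal(got$key, want$key)
  expect_equal(got$mut, want$mut)
  expect_equal(got$disruptiveness, want$disruptiveness)
})

test_that("pareto designs equal the exhaustive frontier", {
  pot <- default_pair_potential()
  for (seed in c(2, 4, 8, 16)) {
    sc <- make_scenario(n_res = 40, n_models = 1, seed = seed)
    m <- sc$ensemble$models[[1L]]
    subs <- allowed_substitutions(sc$msa, sc$antigen)
    surf <- surface_residues(relative_accessibility(sc$antigen))
    cand <- candidate_mutations(m, surf, subs, pot)
    if (nrow(cand) == 0L) next
    for (k in 1:4) {
      params <- design_params(k = k, pareto_cap = 10000)
      got <- suppressWarnings(pareto_designs(m, cand, params, pot))
      want <- bf_pareto(cand, k, params$max_spread, sc$antigen, pot)
      got_lab <- sort(vapply(got$mutations, function(mu) {
        paste(sort(paste0(mu$key, ">", mu$mut)), collapse = ";")
      }, ""))
      expect_identical(got_lab, sort(want$label))
    }
  }
})

test_that("infeasible spread yields an empty design list with a warning", {
  # two candidate positions 40 A apart, k = 2: spread filter rejects all
  ag <- point_structure(cbind(c(0, 40), 0, 0), aa = "A")
  ab <- toy_structure(chain = "H", resno = 1:2, aa = c("Y", "Y"),
                      elety = rep("CA", 2), element = rep("C", 2),
                      xyz = rbind(c(0, 4, 0), c(40, 4, 0)))
  m <- docking_model("m", ab, ag)
  cand <- tibble::tibble(model_id = "m", key = c("A:1", "A:2"),
                         wt = c("A", "A"), mut = c("W", "W"),
                         disruptiveness = c(1, 1))
  expect_warning(out <- pareto_designs(m, cand, design_params(k = 2)),
                 "no feasible design")
  expect_equal(nrow(out), 0L)
  # a single candidate at k = 1 gives one design with zero spread
  got <- pareto_designs(m, cand[1L, ], design_params(k = 1))
  expect_equal(nrow(got), 1L)
  expect_equal(got$spread, 0)
  expect_equal(got$n_mutations, 1L)
})

test_that("merge removes mutations that fail any contacted pose and
           unifies repeated positions to the strongest substitution", {
  # antigen beads; two poses with opposite-charge paratopes over residue 3
  ag <- point_structure(cbind(8 * (1:6), 0, 0), aa = "A")
  mk <- function(id, targets, aa) {
    ab <- toy_structure(chain = "H", resno = seq_along(targets),
                        aa = rep(aa, length(targets)),
                        elety = rep("CA", length(targets)),
                        element = rep("C", length(targets)),
                        xyz = cbind(8 * targets, 4, 0))
    docking_model(id, ab, ag)
  }
  m1 <- mk("M1", c(2, 3), "K")  # positive paratope: D/E substitutions bind tighter
  m2 <- mk("M2", c(3, 4), "D")  # negative paratope: D/E substitutions repel
  e <- docking_ensemble(ag, list(m1, m2))
  pot <- default_pair_potential()
  # A->E at position 3 disrupts M2 (like charges) but stabilizes binding
  # to M1 (opposite charges): the merge must drop it
  expect_lt(disruptiveness("A:3", "E", m1, pot), 0)
  expect_gt(disruptiveness("A:3", "E", m2, pot), 0)
  d_in <- tibble::tibble(
    source_model = "M2", label = "A3E",
    mutations = list(tibble::tibble(key = "A:3", wt = "A", mut = "E")),
    n_mutations = 1L, spread = 0, stability_delta = -1,
    disruption = disruptiveness("A:3", "E", m2, pot)
  )
  out <- merge_and_annotate(d_in, e, pot)
  expect_equal(nrow(out), 0L)

  # position 2 contacts only M1; two designs propose different positive
  # (hydrophobicity-raising) substitutions there and both should end up
  # carrying the stronger one
  d1 <- disruptiveness("A:2", "I", m1, pot)
  d2 <- disruptiveness("A:2", "V", m1, pot)
  expect_true(d1 > 0 && d2 > 0)
  stronger <- if (d1 >= d2) "I" else "V"
  din <- dplyr::bind_rows(
    tibble::tibble(source_model = "M1", label = "A2I",
                   mutations = list(tibble::tibble(key = "A:2", wt = "A",
                                                   mut = "I")),
                   n_mutations = 1L, spread = 0, stability_delta = -1,
                   disruption = d1),
    tibble::tibble(source_model = "M1", label = "A2V",
                   mutations = list(tibble::tibble(key = "A:2", wt = "A",
                                                   mut = "V")),
                   n_mutations = 1L, spread = 0, stability_delta = -1,
                   disruption = d2)
  )
  out <- merge_and_annotate(din, e, pot)
  # both designs collapse to one carrying the stronger substitution
  expect_equal(nrow(out), 1L)
  expect_identical(out$mutations[[1L]]$mut, stronger)
  expect_identical(out$covered_models[[1L]], "M1")
})

test_that("merged coverage maps equal a brute-force recomputation", {
  pot <- default_pair_potential()
  sc <- make_scenario(n_res = 40, n_models = 4, seed = 17)
  designs <- suppressWarnings(design_variants(sc$ensemble, msa = sc$msa,
                                              pot = pot))
  expect_gt(nrow(designs), 0L)
  for (i in seq_len(nrow(designs))) {
    mu <- designs$mutations[[i]]
    covered <- character()
    for (m in sc$ensemble$models) {
      hit <- FALSE
      for (r in seq_len(nrow(mu))) {
        if (mu$key[r] %in% m$footprint &&
              disruptiveness(mu$key[r], mu$mut[r], m, pot) > 0) hit <- TRUE
      }
      if (hit) covered <- c(covered, m$id)
    }
    expect_setequal(designs$covered_models[[i]], covered)
  }
})

test_that("every emitted design respects the declared filters", {
  pot <- default_pair_potential()
  for (seed in c(1, 2, 3)) {
    sc <- make_scenario(n_res = 50, n_models = 8, seed = seed)
    designs <- suppressWarnings(design_variants(sc$ensemble, msa = sc$msa,
                                                pot = pot))
    expect_gt(nrow(designs), 0L)
    expect_true(all(designs$n_mutations >= 1 & designs$n_mutations <= 4))
    expect_true(all(designs$spread <= 12))
    expect_true(all(designs$stability_delta <= 0))
    # every mutation is disruptive toward every pose its position contacts
    for (i in seq_len(nrow(designs))) {
      mu <- designs$mutations[[i]]
      for (m in sc$ensemble$models) {
        for (r in seq_len(nrow(mu))) {
          if (mu$key[r] %in% m$footprint) {
            expect_gt(disruptiveness(mu$key[r], mu$mut[r], m, pot), 0)
          }
        }
      }
    }
  }
})
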