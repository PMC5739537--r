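# Brute-force oracles and tiny structure builders shared across the tests.
# Oracles are deliberately naive (double loops, exhaustive enumeration) and
# independent of the package's vectorized/compiled code paths.

# a bare structure from a compact atom spec
toy_structure <- function(chain, resno, aa, elety, element, xyz) {
  ag_structure(tibble::tibble(
    chain = chain, resno = resno, icode = "", aa = aa,
    elety = elety, element = element,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
  ))
}

# n single-atom "residues" (CA only) at given coordinates
point_structure <- function(xyz, chain = "A", aa = "A") {
  n <- nrow(xyz)
  toy_structure(chain = rep(chain, n), resno = seq_len(n),
                aa = rep(aa, length.out = n), elety = rep("CA", n),
                element = rep("C", n), xyz = xyz)
}

# all residue pairs within cutoff, by explicit double loop over atoms
bf_contacts <- function(at_a, at_b, cutoff) {
  pairs <- character()
  for (i in seq_len(nrow(at_a))) {
    for (j in seq_len(nrow(at_b))) {
      d <- sqrt((at_a$x[i] - at_b$x[j])^2 + (at_a$y[i] - at_b$y[j])^2 +
                  (at_a$z[i] - at_b$z[j])^2)
      if (d <= cutoff) pairs <- c(pairs, paste(at_a$key[i], at_b$key[j]))
    }
  }
  sort(unique(pairs))
}

bf_hausdorff <- function(A, B) {
  dmat <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    dmat[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  }
  max(max(apply(dmat, 1L, min)), max(apply(dmat, 2L, min)))
}

# smallest number of designs whose covered-model union equals the coverable
# set, by exhaustive subset enumeration
bf_min_cover_size <- function(covered_list, model_ids) {
  coverable <- sort(unique(unlist(covered_list)))
  coverable <- intersect(coverable, model_ids)
  if (length(coverable) == 0L) return(NA_integer_)
  n <- length(covered_list)
  for (size in seq_len(n)) {
    for (rows in utils::combn(n, size, simplify = FALSE)) {
      if (all(coverable %in% unlist(covered_list[rows]))) return(size)
    }
  }
  NA_integer_
}

# exhaustive Pareto frontier over position subsets x substitution choices:
# returns the set of non-dominated (disruption, stability) labelled designs
bf_pareto <- function(cand, k, max_spread, s, pot, cutoff = 5) {
  keys <- unique(cand$key)
  size <- min(k, length(keys))
  aa_of <- stats::setNames(s$residues$aa, s$residues$key)
  stab_of_one <- function(key, wt, mut) {
    # naive neighbor scan
    pos_at <- s$atoms[s$atoms$key == key, , drop = FALSE]
    nb <- character()
    for (other in setdiff(s$residues$key, key)) {
      oat <- s$atoms[s$atoms$key == other, , drop = FALSE]
      dmin <- Inf
      for (i in seq_len(nrow(pos_at))) for (j in seq_len(nrow(oat))) {
        dmin <- min(dmin, sqrt((pos_at$x[i] - oat$x[j])^2 +
                                 (pos_at$y[i] - oat$y[j])^2 +
                                 (pos_at$z[i] - oat$z[j])^2))
      }
      if (dmin <= cutoff) nb <- c(nb, other)
    }
    if (length(nb) == 0L) return(0)
    sum(pot[mut, aa_of[nb]] - pot[wt, aa_of[nb]])
  }
  rows <- list()
  for (subset in utils::combn(keys, size, simplify = FALSE)) {
    spread <- mean_pairwise_ca_distance(s, subset)
    if (spread > max_spread) next
    per_pos <- lapply(subset, function(kk) which(cand$key == kk))
    eg <- as.matrix(expand.grid(per_pos))
    for (r in seq_len(nrow(eg))) {
      idx <- as.integer(eg[r, ])
      stab <- sum(vapply(idx, function(i) {
        stab_of_one(cand$key[i], cand$wt[i], cand$mut[i])
      }, 0))
      if (!is.finite(stab) || stab > 0) next
      lab <- paste(sort(paste0(cand$key[idx], ">", cand$mut[idx])),
                   collapse = ";")
      rows[[length(rows) + 1L]] <-
        data.frame(label = lab, disruption = sum(cand$disruptiveness[idx]),
                   stability = stab)
    }
  }
  if (length(rows) == 0L) return(data.frame(label = character(),
                                            disruption = numeric(),
                                            stability = numeric()))
  df <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    dominated <- any(df$disruption >= df$disruption[i] &
                       df$stability <= df$stability[i] &
                       (df$disruption > df$disruption[i] |
                          df$stability < df$stability[i]))
    if (dominated) keep[i] <- FALSE
  }
  df[keep, , drop = FALSE]
}

# random covering instance with spatial structure: designs and model
# footprints both live on a toy helix, and a design covers a model when it
# mutates inside the model's patch (nearby designs cover similar models,
# as in the real pipeline)
random_cover_instance <- function(seed, n_designs = NULL, n_models = NULL) {
  withr::with_seed(seed, {
    n_res <- 40L
    s <- episcope:::helix_antigen(
      n_res, paste(sample(episcope:::AA1, n_res, TRUE), collapse = "")
    )
    nd <- if (is.null(n_designs)) sample(4:12, 1L) else n_designs
    nm <- if (is.null(n_models)) sample(3:8, 1L) else n_models
    model_ids <- sprintf("M%02d", seq_len(nm))
    patches <- lapply(seq_len(nm), function(j) {
      episcope:::patch_around(s, res_key("A", sample(3:(n_res - 2), 1L)), 6L)
    })
    designs <- lapply(seq_len(nd), function(i) {
      pos <- episcope:::patch_around(s, res_key("A", sample(3:(n_res - 2), 1L)), 3L)
      covered <- model_ids[vapply(patches, function(p) any(pos %in% p), TRUE)]
      tibble::tibble(
        design_id = sprintf("D%02d", i),
        label = paste(pos, collapse = ";"),
        mutations = list(tibble::tibble(
          key = pos,
          wt = s$residues$aa[match(pos, s$residues$key)],
          mut = "A"
        )),
        n_mutations = 3L,
        spread = mean_pairwise_ca_distance(s, pos),
        stability_delta = -stats::runif(1L),
        total_disruption = stats::runif(1L, 1, 5),
        covered_models = list(covered),
        n_covered = length(covered),
        source_models = list(character())
      )
    })
    list(s = s, designs = dplyr::bind_rows(designs), model_ids = model_ids,
         patches = patches)
  })
}

# minimal stand-in ensemble for select_panel: only model ids and the shared
# antigen are consulted by the selection routine
fake_ensemble <- function(s, model_ids) {
  models <- lapply(model_ids, function(id) {
    structure(list(id = id, ab = NULL, ag = s, cutoff = 5,
                   footprint = character(), contact_aas = list()),
              class = "docking_model")
  })
  names(models) <- model_ids
  structure(list(ag = s, models = models, source_label = "fake"),
            class = "docking_ensemble")
}
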