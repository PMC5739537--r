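# Per-docking-model design of disruptive antigen variants: homolog-derived
# substitution choices, contact-potential disruptiveness toward each pose,
# a stability filter, a geometric spread filter, Pareto selection per model,
# and the cross-model merge rules.

#' Design-stage parameters
#'
#' @param k mutations per design (1-4; the prospective and retrospective
#'   applications use triple mutants)
#' @param max_spread maximal mean pairwise C-alpha distance of a design's
#'   mutations, in Angstroms
#' @param contact_cutoff heavy-atom contact cutoff (A) for footprints,
#'   disruptiveness and the stability neighborhood
#' @param pareto_cap maximal number of Pareto designs kept per docking model
#' @param min_homolog_count minimal number of homolog sequences in which a
#'   substitution must appear to be considered evolutionarily accepted
#' @param surface_threshold RSA threshold defining surface residues
#' @param combo_budget maximal number of one-design-per-cluster combinations
#'   enumerated exhaustively during panel selection before falling back to
#'   greedy max-coverage
#' @return a list of class `design_params`
#' @export
design_params <- function(k = 3, max_spread = 12, contact_cutoff = 5,
                          pareto_cap = 50, min_homolog_count = 1,
                          surface_threshold = 0.07, combo_budget = 1e6) {
  stopifnot(k >= 1, k <= 4, max_spread > 0, contact_cutoff > 0,
            pareto_cap >= 1, min_homolog_count >= 1)
  structure(list(k = as.integer(k), max_spread = max_spread,
                 contact_cutoff = contact_cutoff,
                 pareto_cap = as.integer(pareto_cap),
                 min_homolog_count = as.integer(min_homolog_count),
                 surface_threshold = surface_threshold,
                 combo_budget = combo_budget),
            class = "design_params")
}

#' Read an aligned FASTA file as a named character vector
#'
#' @param path aligned FASTA (all records equal length)
#' @return named character vector of aligned sequences
#' @export
read_msa_fasta <- function(path) {
  aln <- bio3d::read.fasta(path)
  seqs <- apply(aln$ali, 1L, paste, collapse = "")
  stats::setNames(toupper(seqs), rownames(aln$ali))
}

#' Evolutionarily-accepted substitutions from a homolog alignment
#'
#' The first alignment row must be the antigen itself (gaps allowed). For
#' every antigen position, the allowed substitutions are the non-wild-type
#' standard amino acids observed at the aligned column in at least
#' `min_count` homolog rows; gaps and unknowns are ignored. Positions where
#' the homologs all agree with the wild type are undesignable (empty set).
#'
#' @param msa character vector of aligned sequences, the antigen row first
#' @param antigen an [ag_structure()] (keys are attached) or a plain
#'   sequence string
#' @param min_count minimal homolog count for an accepted substitution
#' @return tibble with columns `key`, `pos`, `wt`, `allowed` (list-column
#'   of character vectors)
#' @export
allowed_substitutions <- function(msa, antigen, min_count = 1) {
  stopifnot(length(msa) >= 1L)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("alignment rows have unequal length")
  M <- do.call(rbind, strsplit(toupper(msa), ""))
  ref <- M[1L, ]
  keep <- ref != "-"
  if (inherits(antigen, "ag_structure")) {
    ag_seq <- antigen$sequence
    keys <- antigen$residues$key
  } else {
    ag_seq <- toupper(antigen)
    keys <- as.character(seq_len(nchar(ag_seq)))
  }
  if (paste(ref[keep], collapse = "") != ag_seq) {
    stop("first alignment row does not match the antigen sequence after gap removal")
  }
  cols <- which(keep)
  allowed <- lapply(seq_along(cols), function(i) {
    col <- M[-1L, cols[i]]
    col <- col[col %in% AA1 & col != ref[cols[i]]]
    if (length(col) == 0L) return(character())
    tab <- table(col)
    sort(names(tab)[tab >= min_count])
  })
  tibble::tibble(
    key = keys,
    pos = seq_along(cols),
    wt = ref[cols],
    allowed = allowed
  )
}

# antibody residues (and their amino acids) contacting each antigen residue
# of a model's footprint: named list key -> character vector of ab amino
# acids. Cached on the model at construction time for its own cutoff.
model_contact_aas <- function(m, cutoff = 5) {
  if (isTRUE(all.equal(cutoff, m$cutoff))) return(m$contact_aas)
  ct <- heavy_atom_contacts(m$ag$atoms, m$ab$atoms, cutoff)
  if (nrow(ct) == 0L) return(list())
  ab_aa <- stats::setNames(m$ab$residues$aa, m$ab$residues$key)
  split(unname(ab_aa[ct$key_b]), ct$key_a)
}

# intra-antigen neighborhoods: for each residue, the amino acids of the
# other residues with any heavy atom within `cutoff`, plus the minimal
# side-chain-proxy (CB, CA for GLY) distance to any other residue's heavy
# atom. Computed once per antigen and reused across subsets and models.
residue_neighborhoods <- function(s, cutoff = 5) {
  at <- s$atoms
  D <- cross_dist(coords_mat(at), coords_mat(at))
  keys <- s$residues$key
  aa_of <- stats::setNames(s$residues$aa, keys)
  idx <- split(seq_len(nrow(at)), at$key)
  nb <- vector("list", length(keys))
  names(nb) <- keys
  proxy_min <- stats::setNames(rep(Inf, length(keys)), keys)
  for (k in keys) {
    rows <- idx[[k]]
    sub <- D[rows, , drop = FALSE]
    near <- unique(at$key[apply(sub <= cutoff, 2L, any)])
    nb[[k]] <- unname(aa_of[setdiff(near, k)])
    cb_row <- rows[at$elety[rows] == "CB"]
    if (length(cb_row) == 0L) cb_row <- rows[at$elety[rows] == "CA"]
    if (length(cb_row)) {
      other <- which(!(at$key %in% k))
      if (length(other)) proxy_min[k] <- min(D[cb_row[1L], other])
    }
  }
  list(aas = nb, proxy_min = proxy_min)
}

#' Predicted binding disruptiveness of a point substitution toward a model
#'
#' The summed change in contact energy, over the antibody residues touching
#' the position in the given pose, when the wild-type amino acid is replaced
#' by `aa`. The sign is normalized so that positive values are
#' binding-disruptive (the mutant packs worse against the paratope than the
#' wild type). Identity substitutions score 0.
#'
#' @param pos antigen residue key; must lie in the model's footprint
#' @param aa substituting amino acid (one-letter)
#' @param m a [docking_model()]
#' @param pot a [pair_potential()]
#' @param cutoff contact distance in Angstroms
#' @return numeric score (positive = disruptive)
#' @export
disruptiveness <- function(pos, aa, m, pot = default_pair_potential(),
                           cutoff = 5) {
  if (!pos %in% m$footprint) {
    stop("position ", pos, " is outside the footprint of model ", m$id)
  }
  wt <- m$ag$residues$aa[match(pos, m$ag$residues$key)]
  if (aa == wt) return(0)
  env <- model_contact_aas(m, cutoff)[[pos]]
  if (is.null(env)) return(0)
  sum(pot[aa, env] - pot[wt, env])
}

# default coarse stability scorer: intra-antigen contact-potential delta
# over the residues within `cutoff` of each mutated position (wild-type
# identities, so the score is additive over mutations), plus a hard steric
# penalty when a mutated residue's side-chain proxy (CB, CA for GLY) sits
# within `clash_dist` of another residue's heavy atom. No repacking.
default_stability_scorer <- function(s, mutations,
                                     pot = default_pair_potential(),
                                     cutoff = 5, clash_dist = 2.5,
                                     nbhd = NULL) {
  if (nrow(mutations) == 0L) return(0)
  aa_of <- stats::setNames(s$residues$aa, s$residues$key)
  unknown <- setdiff(mutations$key, names(aa_of))
  if (length(unknown)) stop("unknown position(s): ",
                            paste(unknown, collapse = ", "))
  bad_wt <- mutations$wt != unname(aa_of[mutations$key])
  if (any(bad_wt)) {
    stop("wild-type mismatch at ", paste(mutations$key[bad_wt], collapse = ", "))
  }
  if (is.null(nbhd)) nbhd <- residue_neighborhoods(s, cutoff)
  if (any(nbhd$proxy_min[mutations$key] < clash_dist)) return(Inf)
  delta <- 0
  for (r in seq_len(nrow(mutations))) {
    nb_aa <- nbhd$aas[[mutations$key[r]]]
    if (length(nb_aa)) {
      delta <- delta +
        sum(pot[mutations$mut[r], nb_aa] - pot[mutations$wt[r], nb_aa])
    }
  }
  delta
}

#' Predicted stability change of a mutation set
#'
#' Scorer-defined estimate of mutant-minus-wild-type stability; more
#' negative is more stable, and designs with positive values are filtered
#' out downstream (a variant predicted less stable than the wild type is
#' rejected). The default scorer is a coarse contact-potential delta over
#' the structural neighborhood of each mutated position plus a hard steric
#' clash penalty; any function of `(s, mutations)` can be substituted.
#'
#' @param s antigen [ag_structure()]
#' @param mutations tibble with columns `key`, `wt`, `mut` (0 rows gives 0)
#' @param scorer stability scorer function; default
#'   [default_stability_scorer()] with `pot` and `cutoff` applied
#' @param pot pair potential for the default scorer
#' @param cutoff contact distance (A) for the default scorer
#' @param nbhd optional precomputed intra-antigen neighborhoods (internal
#'   speed-up for the default scorer)
#' @return numeric energy difference (`Inf` for steric clashes)
#' @export
stability_delta <- function(s, mutations, scorer = NULL,
                            pot = default_pair_potential(), cutoff = 5,
                            nbhd = NULL) {
  if (is.null(scorer)) {
    return(default_stability_scorer(s, mutations, pot, cutoff, nbhd = nbhd))
  }
  tryCatch(scorer(s, mutations), error = function(e) {
    stop("stability scorer failed for positions ",
         paste(mutations$key, collapse = ", "), ": ", conditionMessage(e))
  })
}

#' Candidate disruptive point mutations for one docking model
#'
#' Enumerates allowed substitutions at surface positions inside the model's
#' footprint and keeps those predicted to disrupt the pose
#' (disruptiveness strictly positive); substitutions that do not disrupt
#' the model are removed from the list of choices.
#'
#' @param m a [docking_model()]
#' @param surface character vector of surface residue keys
#' @param subs output of [allowed_substitutions()]
#' @param pot a [pair_potential()]
#' @param cutoff contact distance in Angstroms
#' @return tibble with `model_id`, `key`, `wt`, `mut`, `disruptiveness`
#' @export
candidate_mutations <- function(m, surface, subs,
                                pot = default_pair_potential(), cutoff = 5) {
  empty <- tibble::tibble(model_id = character(), key = character(),
                          wt = character(), mut = character(),
                          disruptiveness = numeric())
  pos <- intersect(intersect(m$footprint, surface), subs$key)
  if (length(pos) == 0L) return(empty)
  env <- model_contact_aas(m, cutoff)
  rows <- lapply(pos, function(p) {
    i <- match(p, subs$key)
    alts <- subs$allowed[[i]]
    if (length(alts) == 0L || is.null(env[[p]])) return(NULL)
    wt <- subs$wt[i]
    d <- vapply(alts, function(a) sum(pot[a, env[[p]]] - pot[wt, env[[p]]]), 0)
    keep <- d > 0
    if (!any(keep)) return(NULL)
    tibble::tibble(model_id = as.character(m$id), key = p, wt = wt,
                   mut = alts[keep], disruptiveness = unname(d[keep]))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) empty else out
}

mutation_label <- function(key, wt, mut) {
  k <- parse_res_key(key)
  paste0(wt, k$resno, k$icode, mut)
}

design_label <- function(mutations) {
  k <- parse_res_key(mutations$key)
  o <- order(k$chain, k$resno, k$icode)
  paste(mutation_label(mutations$key[o], mutations$wt[o], mutations$mut[o]),
        collapse = ";")
}

# strict Pareto frontier over (maximize gain, minimize cost): sweep in
# descending gain keeping the running cost minimum; points tied on both
# coordinates are mutually non-dominating and all kept
pareto_front <- function(gain, cost) {
  n <- length(gain)
  keep <- logical(n)
  ord <- order(-gain, cost)
  best <- Inf
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && gain[ord[j + 1L]] == gain[ord[i]]) j <- j + 1L
    grp <- ord[i:j]
    gmin <- min(cost[grp])
    if (gmin < best) keep[grp[cost[grp] == gmin]] <- TRUE
    best <- min(best, gmin)
    i <- j + 1L
  }
  keep
}

#' Pareto-optimal variant designs for one docking model
#'
#' Enumerates position subsets of size `k` (or of the full candidate set
#' when fewer than `k` positions are available) together with the allowed
#' disruptive substitution choices at each position (one substitution per
#' position within a design), applies the spread and stability filters,
#' and returns the Pareto frontier over (maximize total disruptiveness
#' toward the model, minimize the stability change), truncated at
#' `pareto_cap` designs in descending-disruptiveness, then lexicographic,
#' order.
#'
#' @param m a [docking_model()]
#' @param candidates output of [candidate_mutations()] for this model
#' @param params a [design_params()]
#' @param pot pair potential used by the stability scorer
#' @param scorer optional stability scorer override (see [stability_delta()])
#' @param nbhd optional precomputed intra-antigen neighborhoods (internal
#'   speed-up for the default scorer)
#' @return tibble of per-model designs with columns `source_model`, `label`,
#'   `mutations` (list-column), `n_mutations`, `spread`, `stability_delta`,
#'   `disruption`; empty (with a warning) when no subset passes the filters
#' @export
pareto_designs <- function(m, candidates, params = design_params(),
                           pot = default_pair_potential(), scorer = NULL,
                           nbhd = NULL) {
  empty <- tibble::tibble(source_model = character(), label = character(),
                          mutations = list(), n_mutations = integer(),
                          spread = numeric(), stability_delta = numeric(),
                          disruption = numeric())
  if (nrow(candidates) == 0L) return(empty)
  s <- m$ag
  cand <- dplyr::arrange(candidates, .data$key,
                         dplyr::desc(.data$disruptiveness), .data$mut)
  keys <- unique(cand$key)
  rk <- parse_res_key(keys)
  keys <- keys[order(rk$chain, rk$resno, rk$icode)]
  by_pos <- lapply(keys, function(k) cand[cand$key == k, , drop = FALSE])
  npos <- length(keys)
  size <- min(params$k, npos)
  combos <- utils::combn(seq_len(npos), size)
  ca <- ca_coords(s, keys)
  cad <- as.matrix(stats::dist(ca))
  if (is.null(scorer) && is.null(nbhd)) {
    nbhd <- residue_neighborhoods(s, params$contact_cutoff)
  }
  # the default scorer is additive over mutations, so per-candidate deltas
  # can be precomputed and summed per design
  stab_cand <- if (is.null(scorer)) {
    lapply(by_pos, function(b) {
      vapply(seq_len(nrow(b)), function(i) {
        default_stability_scorer(
          s, tibble::tibble(key = b$key[i], wt = b$wt[i], mut = b$mut[i]),
          pot, params$contact_cutoff, nbhd = nbhd
        )
      }, 0)
    })
  } else NULL
  n_cand <- vapply(by_pos, nrow, 1L)
  # per-candidate mutation labels, so design labels come from paste()
  lab_cand <- lapply(by_pos, function(b) mutation_label(b$key, b$wt, b$mut))
  # numeric pass over every (position subset) x (substitution choice):
  # mutation tables are materialized only for frontier members below
  acc <- vector("list", ncol(combos))
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    spread <- if (length(idx) == 1L) 0 else
      mean(cad[idx, idx][upper.tri(cad[idx, idx])])
    if (spread > params$max_spread) next
    picks <- as.matrix(expand.grid(lapply(idx, function(i) {
      seq_len(n_cand[i])
    }), KEEP.OUT.ATTRS = FALSE))
    disr <- numeric(nrow(picks))
    stab <- numeric(nrow(picks))
    for (q in seq_along(idx)) {
      disr <- disr + by_pos[[idx[q]]]$disruptiveness[picks[, q]]
      if (is.null(scorer)) {
        stab <- stab + stab_cand[[idx[q]]][picks[, q]]
      }
    }
    if (!is.null(scorer)) {
      stab <- vapply(seq_len(nrow(picks)), function(r) {
        mu <- dplyr::bind_rows(lapply(seq_along(idx), function(q) {
          by_pos[[idx[q]]][picks[r, q], c("key", "wt", "mut")]
        }))
        stability_delta(s, mu, scorer = scorer, pot = pot,
                        cutoff = params$contact_cutoff)
      }, 0)
    }
    ok <- is.finite(stab) & stab <= 0
    if (!any(ok)) next
    acc[[j]] <- list(idx = idx, picks = picks[ok, , drop = FALSE],
                     disr = disr[ok], stab = stab[ok], spread = spread)
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  if (length(acc) == 0L) {
    warning("no feasible design for model ", m$id,
            " under spread <= ", params$max_spread, " and stability <= 0",
            call. = FALSE)
    return(empty)
  }
  all_disr <- unlist(lapply(acc, `[[`, "disr"))
  all_stab <- unlist(lapply(acc, `[[`, "stab"))
  block <- rep(seq_along(acc), vapply(acc, function(a) length(a$disr), 1L))
  within <- unlist(lapply(acc, function(a) seq_along(a$disr)))
  front <- which(pareto_front(all_disr, all_stab))
  rows <- lapply(front, function(r) {
    a <- acc[[block[r]]]
    pick <- a$picks[within[r], ]
    mu <- dplyr::bind_rows(lapply(seq_along(a$idx), function(q) {
      by_pos[[a$idx[q]]][pick[q], c("key", "wt", "mut")]
    }))
    tibble::tibble(
      source_model = as.character(m$id),
      label = paste(vapply(seq_along(a$idx), function(q) {
        lab_cand[[a$idx[q]]][pick[q]]
      }, ""), collapse = ";"),
      mutations = list(mu),
      n_mutations = length(a$idx),
      spread = a$spread,
      stability_delta = a$stab[within[r]],
      disruption = a$disr[within[r]]
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$disruption, out$label), , drop = FALSE]
  utils::head(out, params$pareto_cap)
}

#' Merge per-model designs into a single annotated design list
#'
#' Applies the cross-model consistency rules: (i) a mutation whose position
#' touches a docking pose toward which it is not disruptive is removed
#' (designs left with no mutations are dropped); (ii) identical positions
#' carrying different substitutions across designs are unified to the most
#' disruptive surviving substitution; (iii) duplicate designs are collapsed,
#' the stability filter is re-checked, and the set of covered models is
#' recomputed (a design covers a model when at least one of its mutations
#' lies in that model's footprint with positive disruptiveness).
#'
#' @param designs row-bound output of [pareto_designs()] over the models of
#'   `e`
#' @param e the [docking_ensemble()]
#' @param pot pair potential (must match the one used upstream)
#' @param params a [design_params()]
#' @param scorer optional stability scorer override
#' @param nbhd optional precomputed intra-antigen neighborhoods
#' @return tibble of final designs: `design_id`, `label`, `mutations`
#'   (list-column), `n_mutations`, `spread`, `stability_delta`,
#'   `total_disruption`, `covered_models` (list-column), `n_covered`,
#'   `source_models` (list-column)
#' @export
merge_and_annotate <- function(designs, e, pot = default_pair_potential(),
                               params = design_params(), scorer = NULL,
                               nbhd = NULL) {
  empty <- tibble::tibble(design_id = character(), label = character(),
                          mutations = list(), n_mutations = integer(),
                          spread = numeric(), stability_delta = numeric(),
                          total_disruption = numeric(),
                          covered_models = list(), n_covered = integer(),
                          source_models = list())
  if (nrow(designs) == 0L) return(empty)
  cutoff <- params$contact_cutoff
  envs <- lapply(e$models, model_contact_aas, cutoff = cutoff)
  mids <- model_ids(e)

  inst <- designs |>
    dplyr::mutate(.design = dplyr::row_number()) |>
    dplyr::select(".design", "mutations") |>
    tidyr::unnest("mutations")
  uinst <- dplyr::distinct(inst, .data$key, .data$wt, .data$mut)

  # disruptiveness of each unique substitution toward every model whose
  # footprint contains its position
  disr_of <- function(key, wt, mut) {
    d <- stats::setNames(rep(NA_real_, length(mids)), mids)
    for (mid in mids) {
      env <- envs[[mid]][[key]]
      if (key %in% e$models[[mid]]$footprint && !is.null(env)) {
        d[mid] <- sum(pot[mut, env] - pot[wt, env])
      }
    }
    d
  }
  dmat <- t(vapply(seq_len(nrow(uinst)),
                   function(i) disr_of(uinst$key[i], uinst$wt[i], uinst$mut[i]),
                   stats::setNames(numeric(length(mids)), mids)))
  contacted <- !is.na(dmat)
  valid <- vapply(seq_len(nrow(uinst)), function(i) {
    all(dmat[i, contacted[i, ]] > 0)
  }, TRUE)
  uinst$valid <- valid
  uinst$total_disr <- rowSums(ifelse(contacted & !is.na(dmat), dmat, 0))

  # per position, the most disruptive surviving substitution
  unified <- uinst[uinst$valid, , drop = FALSE] |>
    dplyr::arrange(.data$key, dplyr::desc(.data$total_disr), .data$mut) |>
    dplyr::distinct(.data$key, .keep_all = TRUE)
  if (nrow(unified) == 0L) return(empty)

  valid_instance <- stats::setNames(uinst$valid,
                                    paste(uinst$key, uinst$wt, uinst$mut))
  rebuilt <- vector("list", nrow(designs))
  for (i in seq_len(nrow(designs))) {
    mu <- designs$mutations[[i]]
    keep <- valid_instance[paste(mu$key, mu$wt, mu$mut)]
    mu <- mu[keep, , drop = FALSE]
    if (nrow(mu) == 0L) next
    j <- match(mu$key, unified$key)
    mu$mut <- unified$mut[j]
    rebuilt[[i]] <- tibble::tibble(
      label = design_label(mu), mutations = list(mu),
      source_model = designs$source_model[i], spread = designs$spread[i]
    )
  }
  out <- dplyr::bind_rows(rebuilt)
  if (nrow(out) == 0L) return(empty)
  out <- out |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      mutations = list(.data$mutations[[1L]]),
      spread = .data$spread[1L],
      source_models = list(sort(unique(.data$source_model))),
      .groups = "drop"
    )

  # unified substitutions may differ from the originals: re-check stability
  if (is.null(scorer) && is.null(nbhd)) {
    nbhd <- residue_neighborhoods(e$ag, cutoff)
  }
  out$stability_delta <- vapply(out$mutations, function(mu) {
    stability_delta(e$ag, mu, scorer = scorer, pot = pot, cutoff = cutoff,
                    nbhd = nbhd)
  }, 0)
  out <- out[is.finite(out$stability_delta) & out$stability_delta <= 0, ,
             drop = FALSE]
  if (nrow(out) == 0L) return(empty)

  cover <- lapply(out$mutations, function(mu) {
    i <- match(paste(mu$key, mu$mut), paste(uinst$key, uinst$mut))
    sub <- dmat[i, , drop = FALSE]
    mids[colSums(!is.na(sub) & sub > 0) > 0]
  })
  out$covered_models <- cover
  out$n_covered <- lengths(cover)
  out$total_disruption <- vapply(seq_len(nrow(out)), function(r) {
    mu <- out$mutations[[r]]
    i <- match(paste(mu$key, mu$mut), paste(uinst$key, uinst$mut))
    sub <- dmat[i, , drop = FALSE]
    sum(sub[!is.na(sub) & sub > 0])
  }, 0)
  out$n_mutations <- vapply(out$mutations, nrow, 1L)

  out <- out[order(out$label), , drop = FALSE]
  out$design_id <- sprintf("D%0*d", max(2L, nchar(nrow(out))), seq_len(nrow(out)))
  out[, c("design_id", "label", "mutations", "n_mutations", "spread",
          "stability_delta", "total_disruption", "covered_models",
          "n_covered", "source_models")]
}

#' Design disruptive antigen variants for every model of an ensemble
#'
#' Convenience wrapper running surface detection, the homolog substitution
#' filter, per-model candidate enumeration and Pareto design, and the
#' cross-model merge. Returns the final annotated design table used for
#' clustering and panel selection.
#'
#' @param e a [docking_ensemble()]
#' @param msa aligned homolog sequences (antigen row first); ignored when
#'   `subs` is given
#' @param subs optional precomputed [allowed_substitutions()] table
#' @param pot a [pair_potential()]
#' @param params a [design_params()]
#' @param surface optional precomputed surface residue keys
#' @param scorer optional stability scorer override
#' @return the [merge_and_annotate()] design tibble
#' @export
design_variants <- function(e, msa = NULL, subs = NULL,
                            pot = default_pair_potential(),
                            params = design_params(), surface = NULL,
                            scorer = NULL) {
  stopifnot(inherits(e, "docking_ensemble"))
  if (is.null(subs)) {
    if (is.null(msa)) stop("provide either an MSA or a substitution table")
    subs <- allowed_substitutions(msa, e$ag, params$min_homolog_count)
  }
  if (is.null(surface)) {
    acc <- relative_accessibility(e$ag)
    surface <- surface_residues(acc, params$surface_threshold)
  }
  nbhd <- if (is.null(scorer)) {
    residue_neighborhoods(e$ag, params$contact_cutoff)
  } else NULL
  per_model <- lapply(e$models, function(m) {
    cand <- candidate_mutations(m, surface, subs, pot, params$contact_cutoff)
    pareto_designs(m, cand, params, pot, scorer, nbhd = nbhd)
  })
  merge_and_annotate(dplyr::bind_rows(per_model), e, pot, params, scorer,
                     nbhd = nbhd)
}
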