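# Synthetic test scenarios: a toy helical antigen with backbone + CB
# pseudo-atoms, antibody pseudo-bodies parked over chosen surface patches
# (one of which can be declared the true pose), and a synthetic homolog
# alignment. Everything is deterministic under a seed, so full pipelines
# can be exercised with no structure downloads. Also the packaged
# result-table transcriptions.

helix_antigen <- function(n_res, seq_aa, chain = "A") {
  stopifnot(n_res >= 2L, nchar(seq_aa) == n_res)
  theta <- (seq_len(n_res) - 1L) * 100 * pi / 180
  rise <- 1.5
  r_ca <- 2.3
  ca <- cbind(r_ca * cos(theta), r_ca * sin(theta), rise * (seq_len(n_res) - 1L))
  u <- cbind(cos(theta), sin(theta), 0)  # outward radial unit vectors
  unitize <- function(v) v / sqrt(sum(v^2))
  rows <- vector("list", n_res)
  aa <- strsplit(seq_aa, "")[[1L]]
  for (i in seq_len(n_res)) {
    to_prev <- if (i > 1L) unitize(ca[i - 1L, ] - ca[i, ]) else
      unitize(ca[i, ] - ca[i + 1L]) * -1
    to_next <- if (i < n_res) unitize(ca[i + 1L, ] - ca[i, ]) else
      unitize(ca[i, ] - ca[i - 1L]) * -1
    xyz <- rbind(
      N = ca[i, ] + 1.46 * to_prev,
      CA = ca[i, ],
      C = ca[i, ] + 1.52 * to_next,
      O = ca[i, ] + 1.52 * to_next + 1.23 * u[i, ],
      CB = ca[i, ] + 1.53 * u[i, ]
    )
    rows[[i]] <- tibble::tibble(
      chain = chain, resno = i, icode = "", aa = aa[i],
      elety = rownames(xyz),
      element = c("N", "C", "C", "O", "C"),
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L]
    )
  }
  ag_structure(dplyr::bind_rows(rows))
}

# residues whose CB atoms are nearest in 3D to the patch center's CB
patch_around <- function(s, center_key, size) {
  cb <- s$atoms[s$atoms$elety == "CB", , drop = FALSE]
  ctr <- as.numeric(cb[cb$key == center_key, c("x", "y", "z")])
  d <- sqrt((cb$x - ctr[1L])^2 + (cb$y - ctr[2L])^2 + (cb$z - ctr[3L])^2)
  cb$key[order(d)][seq_len(size)]
}

# amino-acid composition typical of antibody paratopes (CDR loops are
# enriched in Tyr/Ser/Gly/Trp and polar residues)
PARATOPE_AA <- c("Y", "Y", "Y", "S", "S", "G", "W", "N", "D", "T", "R", "E")

# antigen sequence composition: aliphatic/aromatic residues up-weighted so
# the toy surface resembles the mildly hydrophobic patches that make good
# antibody binding sites, rather than a uniform draw over the alphabet
sample_antigen_seq <- function(n_res) {
  w <- stats::setNames(rep(1, length(AA1)), AA1)
  w[c("A", "I", "L", "V", "F", "M")] <- 3
  paste(sample(AA1, n_res, replace = TRUE, prob = w), collapse = "")
}

# rigid antibody pseudo-body over a patch: one 3-atom contact pseudo-residue
# ~3.2 A outside each targeted CB, plus a non-contacting bulk shell so the
# body has ~50 atoms
pseudo_antibody <- function(s, patch, chain = "H") {
  cb <- s$atoms[s$atoms$elety == "CB", , drop = FALSE]
  rows <- list()
  resno <- 0L
  add_res <- function(center, aa) {
    resno <<- resno + 1L
    offs <- rbind(c(0, 0, 0), c(0.7, 0, 0.4), c(-0.5, 0.6, -0.3))
    tibble::tibble(
      chain = chain, resno = resno, icode = "", aa = aa,
      elety = c("CA", "CB", "CG"), element = "C",
      x = center[1L] + offs[, 1L], y = center[2L] + offs[, 2L],
      z = center[3L] + offs[, 3L]
    )
  }
  for (key in patch) {
    b <- cb[cb$key == key, , drop = FALSE]
    pos <- as.numeric(b[, c("x", "y", "z")])
    dir <- c(pos[1L], pos[2L], 0)
    dir <- dir / sqrt(sum(dir^2))
    rows[[length(rows) + 1L]] <-
      add_res(pos + 3.2 * dir, sample(PARATOPE_AA, 1L))
  }
  centroid <- colMeans(do.call(rbind, lapply(rows, function(r) {
    as.matrix(r[, c("x", "y", "z")])
  })))
  out_dir <- c(centroid[1L], centroid[2L], 0)
  out_dir <- out_dir / sqrt(sum(out_dir^2))
  n_bulk <- max(0L, ceiling((50L - 3L * length(patch)) / 3L))
  for (b in seq_len(n_bulk)) {
    jitter <- stats::rnorm(3L, sd = 1.5)
    rows[[length(rows) + 1L]] <-
      add_res(centroid + (6 + 1.2 * b) * out_dir + jitter,
              sample(PARATOPE_AA, 1L))
  }
  ag_structure(dplyr::bind_rows(rows))
}

synth_msa <- function(ag_seq, depth, sub_rate, gap_rate = 0.02) {
  n <- nchar(ag_seq)
  wt <- strsplit(ag_seq, "")[[1L]]
  rows <- c(antigen = ag_seq)
  for (h in seq_len(depth)) {
    r <- wt
    u <- stats::runif(n)
    subs <- which(u < sub_rate)
    for (j in subs) r[j] <- sample(setdiff(AA1, wt[j]), 1L)
    gaps <- which(u >= sub_rate & u < sub_rate + gap_rate)
    r[gaps] <- "-"
    rows[paste0("homolog", h)] <- paste(r, collapse = "")
  }
  rows
}

#' Generate a synthetic epitope-localization scenario
#'
#' Builds a helical toy antigen (N, CA, C, O, CB pseudo-atoms; random
#' sequence), an ensemble of antibody pseudo-bodies parked over randomly
#' centered surface patches of the requested footprint size, and a
#' synthetic homolog alignment. When `include_true_pose` is set, one model
#' is designated the true binding mode and the scenario's epitope is
#' defined as exactly that model's footprint. Fully determined by `seed`.
#'
#' @param n_res antigen length (>= 20)
#' @param n_models number of docking poses
#' @param footprint_size target antigen residues per pose footprint
#' @param include_true_pose designate one model as the true pose?
#' @param msa_depth number of homolog rows in the synthetic alignment
#' @param sub_rate per-column substitution probability in homolog rows
#' @param seed RNG seed
#' @param contact_cutoff footprint cutoff in Angstroms
#' @return object of class `episcope_scenario`: list with `antigen`,
#'   `ensemble`, `true_model_id` (or `NULL`), `epitope` (or `NULL`),
#'   `msa`, `seed`
#' @export
make_scenario <- function(n_res = 60, n_models = 20, footprint_size = 8,
                          include_true_pose = TRUE, msa_depth = 10,
                          sub_rate = 0.3, seed = 1L, contact_cutoff = 5) {
  stopifnot(n_res >= 20L, n_models >= 1L)
  if (footprint_size > n_res) stop("footprint_size exceeds the antigen size")
  withr::with_seed(seed, {
    ag_seq <- sample_antigen_seq(n_res)
    ag <- helix_antigen(n_res, ag_seq)
    # keep patch centers away from the helix termini so patches are compact
    margin <- max(3L, ceiling(footprint_size / 2L))
    centers <- sample(seq(margin, n_res - margin), n_models, replace = TRUE)
    models <- lapply(seq_len(n_models), function(i) {
      patch <- patch_around(ag, res_key("A", centers[i]), footprint_size)
      docking_model(sprintf("M%02d", i), pseudo_antibody(ag, patch), ag,
                    cutoff = contact_cutoff)
    })
    e <- docking_ensemble(ag, models, source_label = sprintf("synthetic-%d", seed))
    msa <- synth_msa(ag_seq, msa_depth, sub_rate)
    true_id <- if (include_true_pose) "M01" else NULL
    epi <- if (include_true_pose) {
      epitope_spec(models[[1L]]$footprint, "interface-5A", ag)
    } else NULL
    structure(list(antigen = ag, ensemble = e, true_model_id = true_id,
                   epitope = epi, msa = msa, seed = seed),
              class = "episcope_scenario")
  })
}

#' @export
print.episcope_scenario <- function(x, ...) {
  cat(sprintf(
    "<episcope_scenario> seed %d: %d-residue antigen, %d pose(s)%s\n",
    x$seed, nrow(x$antigen$residues), length(x$ensemble$models),
    if (!is.null(x$true_model_id)) paste0(", true pose ", x$true_model_id)
    else ""
  ))
  invisible(x)
}

#' Consistency checks for a synthetic scenario
#'
#' Verifies the generator's declared invariants: footprint sizes within
#' +/- 2 of the request, all footprints within the antigen surface, the
#' epitope equal to the true pose's footprint, and at least one allowed
#' substitution at >= 80% of surface positions.
#'
#' @param sc an `episcope_scenario`
#' @param footprint_size the requested footprint size
#' @return `TRUE` invisibly; stops with a message on violation
#' @export
scenario_self_check <- function(sc, footprint_size = 8) {
  sizes <- vapply(sc$ensemble$models, function(m) length(m$footprint), 1L)
  if (any(abs(sizes - footprint_size) > 2L)) {
    stop("footprint size out of band: ", paste(sizes, collapse = ","))
  }
  acc <- relative_accessibility(sc$antigen)
  surf <- surface_residues(acc)
  fp_all <- unique(unlist(lapply(sc$ensemble$models, function(m) m$footprint)))
  if (!all(fp_all %in% surf)) stop("footprint residue below the surface threshold")
  if (!is.null(sc$true_model_id)) {
    if (!setequal(sc$epitope$residues,
                  sc$ensemble$models[[sc$true_model_id]]$footprint)) {
      stop("epitope does not equal the true pose's footprint")
    }
  }
  subs <- allowed_substitutions(sc$msa, sc$antigen)
  frac <- mean(lengths(subs$allowed[subs$key %in% surf]) > 0)
  if (frac < 0.8) stop("allowed substitutions cover only ",
                       round(100 * frac), "% of surface positions")
  invisible(TRUE)
}

#' Generate a multi-antibody scenario with grouped epitopes
#'
#' One shared antigen; antibodies are assigned to `n_groups` epitope groups
#' with well-separated dominant surface patches. Most of each antibody's
#' docking models target its group patch (with small jitter); the rest are
#' scattered. Supports in-silico binning tests: design-set Hausdorff
#' distances within a group are small compared to between groups.
#'
#' @param n_abs number of antibodies
#' @param n_groups number of epitope groups (<= `n_abs`)
#' @param seed RNG seed
#' @param n_res antigen length
#' @param n_models docking models per antibody
#' @param footprint_size footprint size per pose
#' @param dominant_frac fraction of each antibody's models on its group
#'   patch
#' @param msa_depth,sub_rate homolog alignment parameters
#' @return object of class `episcope_multi_scenario`: list with `antigen`,
#'   `ensembles` (named list), `groups` (named integer vector), `msa`,
#'   `seed`
#' @export
scenario_multi_ab <- function(n_abs = 4, n_groups = 4, seed = 1L,
                              n_res = 80, n_models = 8, footprint_size = 8,
                              dominant_frac = 0.75, msa_depth = 10,
                              sub_rate = 0.3) {
  stopifnot(n_groups <= n_abs, n_groups >= 1L)
  spacing <- floor((n_res - 10L) / n_groups)
  if (spacing < footprint_size + 4L) {
    stop("cannot place ", n_groups, " disjoint patches on ", n_res, " residues")
  }
  withr::with_seed(seed, {
    ag_seq <- sample_antigen_seq(n_res)
    ag <- helix_antigen(n_res, ag_seq)
    centers <- 5L + spacing * (seq_len(n_groups) - 1L) + floor(spacing / 2L)
    groups <- stats::setNames(rep(seq_len(n_groups), length.out = n_abs),
                              sprintf("Ab%02d", seq_len(n_abs)))
    ensembles <- lapply(names(groups), function(ab) {
      g <- groups[[ab]]
      n_dom <- max(1L, round(dominant_frac * n_models))
      ctrs <- c(
        pmin(pmax(centers[g] + sample(-1:1, n_dom, replace = TRUE), 4L),
             n_res - 4L),
        sample(seq(4L, n_res - 4L), n_models - n_dom, replace = TRUE)
      )
      models <- lapply(seq_along(ctrs), function(i) {
        patch <- patch_around(ag, res_key("A", ctrs[i]), footprint_size)
        docking_model(sprintf("M%02d", i), pseudo_antibody(ag, patch), ag)
      })
      docking_ensemble(ag, models, source_label = ab)
    })
    names(ensembles) <- names(groups)
    msa <- synth_msa(ag_seq, msa_depth, sub_rate)
    structure(list(antigen = ag, ensembles = ensembles, groups = groups,
                   msa = msa, seed = seed),
              class = "episcope_multi_scenario")
  })
}

#' Materialize a scenario as ordinary input files
#'
#' Writes `antigen.pdb`, one PDB per pose under `poses/` (antigen chain A
#' plus antibody chain H), the homolog alignment as `msa.fasta`, and, when
#' the scenario has an epitope, `epitope.txt` (one residue label per line).
#'
#' @param sc an `episcope_scenario`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_scenario <- function(sc, dir) {
  dir.create(file.path(dir, "poses"), recursive = TRUE, showWarnings = FALSE)
  write_structure(sc$antigen, path = file.path(dir, "antigen.pdb"))
  for (m in sc$ensemble$models) {
    write_structure(sc$antigen, m$ab,
                    path = file.path(dir, "poses", paste0(m$id, ".pdb")))
  }
  fa <- file.path(dir, "msa.fasta")
  writeLines(paste0(">", names(sc$msa), "\n", unname(sc$msa)), fa)
  if (!is.null(sc$epitope)) {
    writeLines(sc$epitope$residues, file.path(dir, "epitope.txt"))
  }
  invisible(dir)
}

retro_path <- function() {
  system.file("extdata", "retrospective_33.csv", package = "episcope",
              mustWork = TRUE)
}

#' Packaged retrospective results table (33 antibody-antigen pairs)
#'
#' The transcribed per-target table of the retrospective benchmark: antigen
#' residue counts (whole chain, surface, curated epitope), the number of
#' designed variants and localization outcome per antigen structure source
#' (crystal vs homology model), the best-available docking-model quality
#' (f_nat) per source, antibody/antigen model quality (TM-score), docking
#' decoy counts, and success flags under both epitope definitions.
#'
#' @return a 33-row tibble; success flags are logicals
#' @export
packaged_retrospective <- function() {
  tbl <- utils::read.csv(retro_path(), stringsAsFactors = FALSE,
                         colClasses = c(pdb_id = "character"))
  for (cn in grep("^success_", names(tbl), value = TRUE)) {
    if (is.character(tbl[[cn]])) tbl[[cn]] <- tbl[[cn]] == "T"
  }
  tibble::as_tibble(tbl)
}

#' Packaged prospective design tables (B7H6 antibodies TZ47 and PB11)
#'
#' The variant panels designed against the tumor antigen B7H6 for two
#' antibodies, separately (4 + 5 triple mutants) and as one integrated
#' 6-variant panel probing both antibodies' 56 docking models at once;
#' regression fixtures for the design-output format.
#'
#' @return tibble with `panel` (`"single"` or `"multi"`), `design_id`,
#'   `antibody` (targeted antibody or `"both"`), `mutations`
#'   (semicolon-separated labels), `disruptive` (experimentally observed
#'   binding ablation), `disrupted_ab`
#' @export
packaged_prospective <- function() {
  path <- system.file("extdata", "prospective_designs.csv",
                      package = "episcope", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
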