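# End-to-end driver: surface detection -> homolog filter -> per-model
# design -> merge -> clustering/covering panel.

#' Run the full localization-design pipeline on an ensemble
#'
#' @param e a [docking_ensemble()]
#' @param msa aligned homolog sequences (antigen first); or supply `subs`
#' @param subs optional precomputed [allowed_substitutions()] table
#' @param pot a [pair_potential()]
#' @param params a [design_params()]
#' @param seed seed recorded with the run (the pipeline is deterministic
#'   given its inputs)
#' @param scorer optional stability scorer override
#' @return object of class `episcope_run`: list with `ensemble`, `surface`,
#'   `designs` (full merged design table), `panel` (`episcope_panel`),
#'   `params`, `seed`
#' @export
run_episcope <- function(e, msa = NULL, subs = NULL,
                         pot = default_pair_potential(),
                         params = design_params(), seed = 1L,
                         scorer = NULL) {
  acc <- relative_accessibility(e$ag)
  surface <- surface_residues(acc, params$surface_threshold)
  designs <- design_variants(e, msa = msa, subs = subs, pot = pot,
                             params = params, surface = surface,
                             scorer = scorer)
  if (nrow(designs) == 0L) {
    stop("no designs survived the filters; nothing to select from")
  }
  panel <- select_panel(designs, e, params, seed)
  structure(list(ensemble = e, surface = surface, designs = designs,
                 panel = panel, params = params, seed = seed),
            class = "episcope_run")
}

#' Run the pipeline on a synthetic scenario
#'
#' @param sc an `episcope_scenario` from [make_scenario()]
#' @param ... passed to [run_episcope()]
#' @return an `episcope_run`
#' @export
run_scenario <- function(sc, ...) {
  stopifnot(inherits(sc, "episcope_scenario"))
  run_episcope(sc$ensemble, msa = sc$msa, seed = sc$seed, ...)
}

#' @export
print.episcope_run <- function(x, ...) {
  cat(sprintf(
    "<episcope_run> %d candidate design(s) over %d model(s); panel:\n",
    nrow(x$designs), length(x$ensemble$models)
  ))
  print(x$panel)
  invisible(x)
}
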