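#' Published cutoffs for the PET prognostic features
#'
#' The optimal PFS cutoffs reported for the development cohort: SUVmax
#' 17.60, TMTV 408.72 cm^3, TLG 1446.98, Dmax 56.73 cm. They are shipped as
#' a configurable preset — without per-patient data they cannot be
#' re-derived, so [optimal_cutoff()] is provided for deriving cohort-specific
#' values instead.
#'
#' @return Named list with `suv_max`, `tmtv_cm3`, `tlg`, `d_max_cm`.
#' @export
fl_cutoffs <- function() {
  list(suv_max = 17.60, tmtv_cm3 = 408.72, tlg = 1446.98, d_max_cm = 56.73)
}

#' Default pipeline configuration
#'
#' Collects every tunable of the pipeline in one list: lesion detection
#' threshold and minimum lesion volume, the delineation isocontour fraction,
#' the published feature cutoffs, Cox
#' tie handling, evaluation horizons (months), bootstrap replicates, and the
#' RNG seed.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
fl_config <- function(...) {
  cfg <- list(
    detect_suv = 2.5,
    isocontour_frac = 0.41,
    min_volume_cm3 = 0,
    cutoffs = fl_cutoffs(),
    ties = "efron",
    horizons_months = c(36, 60),
    n_boot = 2000,
    days_per_month = 30.44,
    seed = 1L
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) abort(paste0("unknown config fields: ", paste(bad, collapse = ", ")))
  utils::modifyList(cfg, dots)
}
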