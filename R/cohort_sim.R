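#' Specify a synthetic follicular-lymphoma cohort
#'
#' Describes a simulated baseline cohort: binary adverse factors drawn at
#' given prevalences (defaults follow the development cohort's marginal
#' frequencies), log-normal PET features (SUVmax, TMTV, TLG, Dmax),
#' progression-free survival times generated under a proportional-hazards
#' model with user-specified log hazard ratios, and uniform administrative
#' censoring.
#'
#' The default prevalences are: age >= 60 0.302, male 0.500, B symptoms
#' 0.119, grade 3A 0.286, bone-marrow involvement 0.484, Ann Arbor III–IV
#' 0.825, > 4 nodal sites 0.635, LodLIN > 6 cm 0.270, Hb < 12 g/dl 0.357,
#' platelet < 150e9/L 0.270, elevated LDH 0.214, elevated beta2-microglobulin
#' 0.325, immunochemotherapy 0.825. PET feature defaults are log-normals
#' whose medians sit near the cohort's published medians; the high/low flags
#' used in the hazard are obtained by thresholding at the published cutoffs
#' ([fl_cutoffs()]). Default log hazard ratios put the hazard on elevated
#' LDH (HR 2.287), high TLG (HR 3.612) and high Dmax (HR 2.877) — the
#' adverse factors of the three-factor risk score — and 0 elsewhere.
#'
#' @param n Number of patients (>= 2).
#' @param prevalences Named list overriding any default prevalence (all in
#'   \[0, 1\]).
#' @param feature_params Named list per feature (`suv_max`, `tmtv_cm3`,
#'   `tlg`, `d_max_cm`), each `list(median =, sdlog =)`.
#' @param log_hr Named numeric of true log hazard ratios; recognised names
#'   are the binary-factor names plus `suv_high`, `tmtv_high`, `tlg_high`,
#'   `dmax_high`.
#' @param baseline `list(dist = "exponential", rate = )` (per month) or
#'   `list(dist = "weibull", shape = , scale = )`.
#' @param censor_window_months Length-2 positive vector, the uniform
#'   administrative censoring window.
#' @param p_single_lesion Probability a patient has a single lesion, forcing
#'   Dmax = 0 (default 0.05).
#' @param factor_correlation Optional correlation matrix for a Gaussian
#'   copula across the binary factors (rows/columns named by factor);
#'   default independent.
#' @param cutoffs Cutoffs used to define the high/low PET flags.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 126,
                        prevalences = list(),
                        feature_params = list(),
                        log_hr = NULL,
                        baseline = list(dist = "exponential", rate = 0.0022),
                        censor_window_months = c(12, 96),
                        p_single_lesion = 0.05,
                        factor_correlation = NULL,
                        cutoffs = fl_cutoffs(),
                        seed = 1L) {
  if (!is_scalar_number(n) || n < 2) abort("`n` must be at least 2.")
  prev <- utils::modifyList(list(
    age_ge60 = 0.302, male = 0.500, b_symptoms = 0.119, grade_3a = 0.286,
    bm_involved = 0.484, ann_arbor_34 = 0.825, nodal_gt4 = 0.635,
    lodlin_gt6 = 0.270, hb_lt12 = 0.357, plt_lt150 = 0.270,
    ldh_elevated = 0.214, b2mg_elevated = 0.325, immunochemo = 0.825
  ), prevalences)
  if (any(unlist(prev) < 0 | unlist(prev) > 1)) {
    abort("every prevalence must lie in [0, 1].")
  }
  fp <- utils::modifyList(list(
    suv_max = list(median = 12, sdlog = 0.45),
    tmtv_cm3 = list(median = 215, sdlog = 1.1),
    tlg = list(median = 1020, sdlog = 1.1),
    d_max_cm = list(median = 60, sdlog = 0.6)
  ), feature_params)
  lhr <- c(ldh_elevated = log(2.287), tlg_high = log(3.612),
           dmax_high = log(2.877))
  if (!is.null(log_hr)) {
    lhr <- unlist(utils::modifyList(as.list(lhr), as.list(log_hr)))
  }
  cw <- as.numeric(censor_window_months)
  if (length(cw) != 2L || any(cw <= 0) || cw[2] < cw[1]) {
    abort("`censor_window_months` must be a positive (min, max) pair.")
  }
  structure(
    list(n = as.integer(n), prevalences = prev, feature_params = fp,
         log_hr = lhr, baseline = baseline,
         censor_window_months = cw, p_single_lesion = p_single_lesion,
         factor_correlation = factor_correlation, cutoffs = cutoffs,
         seed = seed),
    class = "cohort_spec"
  )
}

#' Simulate a cohort of patient records
#'
#' Draws one patient per row under the structure described by a
#' [cohort_spec()]: binary factors (independent, or Gaussian-copula
#' correlated if a correlation matrix is given), log-normal PET features
#' with high/low flags at the configured cutoffs, latent event times from
#' the proportional-hazards model `h(t) = h0(t) * exp(lp)` with `lp` the sum
#' of `log_hr` over present factors, and uniform administrative censoring.
#' Observed `time_months` is the minimum of event and censoring time;
#' `event` is 1 when the event came first.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per patient. The attribute `"truth"` holds
#'   the true log hazard ratios and the uncensored event times.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  prev <- spec$prevalences
  fnames <- names(prev)

  with_seed(spec$seed, {
    # binary factors via Gaussian copula (identity copula when independent)
    z <- matrix(rnorm(n * length(fnames)), n, length(fnames),
                dimnames = list(NULL, fnames))
    if (!is.null(spec$factor_correlation)) {
      cm <- spec$factor_correlation
      sub <- intersect(colnames(cm), fnames)
      ch <- chol(cm[sub, sub, drop = FALSE])
      z[, sub] <- matrix(rnorm(n * length(sub)), n) %*% ch
    }
    flags <- sweep(z, 2, qnorm(unlist(prev)), "<")
    storage.mode(flags) <- "integer"
    flags <- tibble::as_tibble(flags)

    rlnorm_med <- function(p) exp(rnorm(n, log(p$median), p$sdlog))
    fp <- spec$feature_params
    suv_max <- rlnorm_med(fp$suv_max)
    tmtv_cm3 <- rlnorm_med(fp$tmtv_cm3)
    tlg <- rlnorm_med(fp$tlg)
    d_max_cm <- rlnorm_med(fp$d_max_cm)
    d_max_cm[runif(n) < spec$p_single_lesion] <- 0

    cut <- spec$cutoffs
    hi <- tibble::tibble(
      suv_high = as.integer(suv_max > cut$suv_max),
      tmtv_high = as.integer(tmtv_cm3 > cut$tmtv_cm3),
      tlg_high = as.integer(tlg > cut$tlg),
      dmax_high = as.integer(d_max_cm > cut$d_max_cm)
    )

    design <- dplyr::bind_cols(flags, hi)
    lhr <- spec$log_hr
    known <- intersect(names(lhr), names(design))
    lp <- as.numeric(as.matrix(design[known]) %*% lhr[known])

    bl <- spec$baseline
    u <- runif(n)
    t_event <- switch(bl$dist,
      exponential = -log(u) / (bl$rate * exp(lp)),
      weibull = bl$scale * (-log(u) / exp(lp))^(1 / bl$shape),
      abort("baseline `dist` must be 'exponential' or 'weibull'")
    )
    t_cens <- runif(n, spec$censor_window_months[1], spec$censor_window_months[2])

    out <- tibble::tibble(
      patient_id = seq_len(n),
      age_years = ifelse(flags$age_ge60 == 1L,
                         sample(60:76, n, replace = TRUE),
                         sample(21:59, n, replace = TRUE)),
      sex = ifelse(flags$male == 1L, "male", "female"),
      b_symptoms = flags$b_symptoms,
      grade_3a = flags$grade_3a,
      bm_involved = flags$bm_involved,
      ann_arbor_34 = flags$ann_arbor_34,
      n_nodal_sites = ifelse(flags$nodal_gt4 == 1L,
                             sample(5:10, n, replace = TRUE),
                             sample(0:4, n, replace = TRUE)),
      lodlin_cm = round(ifelse(flags$lodlin_gt6 == 1L,
                               runif(n, 6.1, 12), runif(n, 0.5, 6)), 1),
      hb_g_dl = round(ifelse(flags$hb_lt12 == 1L,
                             runif(n, 8, 11.9), runif(n, 12, 16.5)), 1),
      platelet_1e9_l = round(ifelse(flags$plt_lt150 == 1L,
                                    runif(n, 80, 149), runif(n, 150, 320))),
      ldh_elevated = flags$ldh_elevated,
      b2mg_elevated = flags$b2mg_elevated,
      immunochemo = flags$immunochemo,
      suv_max = suv_max, tmtv_cm3 = tmtv_cm3, tlg = tlg,
      d_max_cm = d_max_cm,
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
    attr(out, "truth") <- list(log_hr = lhr, event_time_months = t_event,
                               linear_predictor = lp)
    out
  })
}
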