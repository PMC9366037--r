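#' Progression-free survival from dates
#'
#' PFS runs from initial diagnosis until relapse, progression or death
#' (event = 1) or the last follow-up (censored). Time is reported in months
#' using a fixed day count per month (default 30.44).
#'
#' @param data Data frame.
#' @param diagnosis_date,end_date Names of `Date` columns: diagnosis, and
#'   event date or last follow-up.
#' @param event Name of the 0/1 event-flag column.
#' @param days_per_month Days per month for the conversion (default 30.44).
#' @return The data frame with `time_months` appended (the `event` column is
#'   coerced to integer).
#' @export
compute_pfs <- function(data, diagnosis_date = "diagnosis_date",
                        end_date = "end_date", event = "event",
                        days_per_month = 30.44) {
  d0 <- as.Date(data[[diagnosis_date]])
  d1 <- as.Date(data[[end_date]])
  days <- as.numeric(d1 - d0)
  if (any(days < 0, na.rm = TRUE)) {
    abort("end date precedes diagnosis date for at least one patient")
  }
  data$time_months <- days / days_per_month
  data$event <- as.integer(data[[event]])
  tibble::as_tibble(data)
}

#' Kaplan–Meier estimate
#'
#' Product-limit estimator with Greenwood standard errors (log-transformed
#' 95% confidence intervals, the `survfit` default). The step function is
#' right-continuous: `S(t)` multiplies the factors of all event times `<=
#' t`, so querying exactly at an event time returns the post-drop value.
#'
#' @param data Data frame.
#' @param time,event Column names (defaults `"time_months"`, `"event"`).
#' @param group Optional grouping column name for stratified curves.
#' @return An object of class `fl_km` wrapping the `survfit` fit.
#' @export
km_estimate <- function(data, time = "time_months", event = "event",
                        group = NULL) {
  df <- data.frame(.time = data[[time]], .event = data[[event]])
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = df)
  } else {
    df$.group <- factor(data[[group]])
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  }
  structure(list(fit = fit, group = group), class = "fl_km")
}

#' @export
print.fl_km <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Query a Kaplan–Meier curve at given times
#'
#' @param km An [km_estimate()] result.
#' @param t Numeric vector of query times.
#' @return A tibble with `time`, `surv`, `conf.low`, `conf.high` (and
#'   `group` when the fit is stratified).
#' @export
surv_at <- function(km, t) {
  stopifnot(inherits(km, "fl_km"))
  s <- summary(km$fit, times = t, extend = TRUE)
  out <- tibble::tibble(
    time = s$time, surv = s$surv,
    conf.low = s$lower, conf.high = s$upper
  )
  if (!is.null(s$strata)) {
    out$group <- sub("^\\.group=", "", as.character(s$strata))
  }
  out
}

#' Broom-style tidier for Kaplan–Meier curves
#' @param x An `fl_km` object.
#' @param ... Unused.
#' @return Tibble of the step function: `time`, `n.risk`, `n.event`,
#'   `surv`, `conf.low`, `conf.high`, optional `group`.
#' @method tidy fl_km
#' @export
tidy.fl_km <- function(x, ...) {
  f <- x$fit
  out <- tibble::tibble(
    time = f$time, n.risk = f$n.risk, n.event = f$n.event,
    surv = f$surv, conf.low = f$lower, conf.high = f$upper
  )
  if (!is.null(f$strata)) {
    out$group <- sub("^\\.group=", "", rep(names(f$strata), f$strata))
  }
  out
}

#' Log-rank test across groups
#'
#' @param data Data frame.
#' @param group Grouping column name.
#' @param time,event Column names.
#' @return One-row tibble: `chi2`, `df`, `p`.
#' @export
logrank_test <- function(data, group, time = "time_months", event = "event") {
  g <- factor(data[[group]])
  if (any(table(g) == 0) || nlevels(g) < 2) {
    abort("need at least two non-empty groups")
  }
  df <- data.frame(.time = data[[time]], .event = data[[event]], .group = g)
  if (sum(df$.event) < 1) abort("need at least one event")
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
  k <- length(sd$n) - 1
  tibble::tibble(chi2 = sd$chisq, df = k,
                 p = pchisq(sd$chisq, df = k, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the partial likelihood (Efron tie handling by default, Breslow
#' optional) and reports per-covariate hazard ratios with Wald 95%
#' confidence intervals, matching the layout of univariate/multivariate
#' survival tables.
#'
#' @param data Data frame.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `fl_cox` wrapping the `coxph` fit; use
#'   [tidy.fl_cox()] / [glance.fl_cox()] for tabular results.
#' @export
cox_fit <- function(data, covariates, time = "time_months", event = "event",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.null(v)) abort(paste0("covariate `", cv, "` not found"))
    if (is.numeric(v) && length(unique(v[!is.na(v)])) < 2) {
      abort(paste0("covariate `", cv, "` is constant"))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(", time, ",", event, ") ~",
    paste(covariates, collapse = " + ")
  ))
  fit <- survival::coxph(fml, data = data, ties = ties)
  if (any(!is.finite(coef(fit)))) {
    abort("Cox fit did not converge (non-finite coefficient); possible separation")
  }
  if (any(sqrt(diag(vcov(fit))) > 1e3)) {
    warn("very large coefficient standard error; possible (near-)complete separation")
  }
  structure(list(fit = fit, covariates = covariates, ties = ties),
            class = "fl_cox")
}

#' @export
print.fl_cox <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Tidy a Cox fit
#' @param x An `fl_cox` object.
#' @param conf.level Confidence level (default 0.95, as in the published
#'   tables).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log HR), `std.error`, `hr`,
#'   `conf.low`, `conf.high` (on the HR scale), `p.value` (Wald).
#' @method tidy fl_cox
#' @export
tidy.fl_cox <- function(x, conf.level = 0.95, ...) {
  f <- x$fit
  b <- coef(f)
  se <- sqrt(diag(vcov(f)))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(b), estimate = unname(b), std.error = unname(se),
    hr = exp(unname(b)),
    conf.low = exp(unname(b - z * se)), conf.high = exp(unname(b + z * se)),
    p.value = 2 * pnorm(-abs(unname(b) / unname(se)))
  )
}

#' Model-level summary of a Cox fit
#' @param x An `fl_cox` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_events`, `loglik`, `concordance`.
#' @method glance fl_cox
#' @export
glance.fl_cox <- function(x, ...) {
  f <- x$fit
  tibble::tibble(
    n = f$n, n_events = f$nevent,
    loglik = as.numeric(f$loglik[length(f$loglik)]),
    concordance = unname(f$concordance["concordance"])
  )
}

#' Univariate screening for the multivariate model
#'
#' Fits one univariate Cox model per candidate and keeps those with Wald
#' p < `alpha`, in the candidates' original order — the standard screening
#' step before a multivariate model. The three metabolic parameters are
#' typically entered into separate multivariate models afterwards (see
#' [fit_metabolic_models()]).
#'
#' @param data Data frame.
#' @param candidates Character vector of candidate covariates.
#' @param time,event Column names.
#' @param alpha Screening threshold (default 0.05).
#' @return Tibble with one row per candidate: `term`, `hr`, `conf.low`,
#'   `conf.high`, `p.value`, `selected`.
#' @export
screen_univariate <- function(data, candidates, time = "time_months",
                              event = "event", alpha = 0.05) {
  if (length(candidates) == 0) abort("`candidates` must be nonempty")
  purrr::map_dfr(candidates, function(cv) {
    td <- tidy(cox_fit(data, cv, time, event))
    tibble::tibble(term = cv, hr = td$hr[1], conf.low = td$conf.low[1],
                   conf.high = td$conf.high[1], p.value = td$p.value[1])
  }) |>
    dplyr::mutate(selected = .data$p.value < alpha)
}

#' Separate multivariate models per metabolic parameter
#'
#' Builds one multivariate Cox model per metabolic parameter (each entered
#' alongside the shared clinical covariates), the design used when SUVmax,
#' TMTV and TLG are too collinear to enter one joint model.
#'
#' @param data Data frame.
#' @param clinical Character vector of shared covariates (e.g. screened
#'   clinical factors plus the dissemination flag).
#' @param metabolic Character vector of metabolic covariates, one model
#'   each.
#' @param time,event,ties Passed to [cox_fit()].
#' @return Named list of `fl_cox` fits, one per metabolic parameter.
#' @export
fit_metabolic_models <- function(data, clinical, metabolic,
                                 time = "time_months", event = "event",
                                 ties = "efron") {
  setNames(
    lapply(metabolic, function(m) {
      cox_fit(data, c(clinical, m), time, event, ties)
    }),
    metabolic
  )
}
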