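#' Harrell's concordance index
#'
#' Probability that, of a usable patient pair (the member with the shorter
#' follow-up had the event), the model assigns the higher risk to the
#' earlier-failing patient; ties in risk count one half. The point estimate
#' is computed by direct enumeration of all pairs; the standard error comes
#' from `survival::concordance` (infinitesimal-jackknife), with a normal
#' 95% confidence interval.
#'
#' @param data Data frame.
#' @param risk Name of the risk-score column (higher = worse). Ordered
#'   factors are converted to their integer codes.
#' @param time,event Column names.
#' @return One-row tibble: `c_index`, `se`, `conf.low`, `conf.high`,
#'   `n_pairs`.
#' @export
c_index <- function(data, risk, time = "time_months", event = "event") {
  r <- risk_as_numeric(data[[risk]])
  ci <- cindex_core(r, data[[time]], data[[event]])
  df <- data.frame(.t = data[[time]], .e = data[[event]], .r = r)
  se <- tryCatch({
    cf <- survival::concordance(survival::Surv(.t, .e) ~ .r, data = df,
                                reverse = TRUE)
    sqrt(cf$var)
  }, error = function(e) NA_real_)
  tibble::tibble(
    c_index = ci$c, se = se,
    conf.low = ci$c - qnorm(0.975) * se, conf.high = ci$c + qnorm(0.975) * se,
    n_pairs = ci$n_pairs
  )
}

risk_as_numeric <- function(r) {
  if (is.factor(r)) as.numeric(r) else as.numeric(r)
}

#' Direct O(n^2) concordance computation
#' @noRd
cindex_core <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(n >= 2, sum(event) >= 1)
  t_i <- matrix(time, n, n)
  e_i <- matrix(event == 1, n, n)
  t_j <- t(t_i)
  e_j <- t(e_i)
  # i is the usable shorter-event member of the pair
  usable <- (t_i < t_j & e_i) | (t_i == t_j & e_i & !e_j)
  r_i <- matrix(risk, n, n)
  r_j <- t(r_i)
  conc <- sum(usable & r_i > r_j)
  disc <- sum(usable & r_i < r_j)
  ties <- sum(usable & r_i == r_j)
  denom <- conc + disc + ties
  if (denom == 0) abort("no usable pairs for concordance")
  list(c = (conc + 0.5 * ties) / denom, n_pairs = denom)
}

#' Paired bootstrap comparison of two C-indexes
#'
#' Resamples patients with replacement, recomputing both models' C-index on
#' each replicate; reports the observed difference `C_a - C_b`, the
#' percentile confidence interval and a two-sided bootstrap p-value.
#'
#' @param data Data frame.
#' @param risk_a,risk_b Risk-score column names for the two models
#'   (evaluated on the same patients).
#' @param time,event Column names.
#' @param n_boot Bootstrap replicates (default 2000; below 100 a warning is
#'   issued).
#' @param conf.level CI level (default 0.95).
#' @param seed RNG seed for the resampling.
#' @return One-row tibble: `delta_c`, `conf.low`, `conf.high`, `p.value`,
#'   `c_a`, `c_b`, `n_boot`.
#' @export
compare_c <- function(data, risk_a, risk_b, time = "time_months",
                      event = "event", n_boot = 2000, conf.level = 0.95,
                      seed = 1L) {
  if (n_boot < 100) warn("n_boot < 100: bootstrap CI and p-value are unstable")
  ra <- risk_as_numeric(data[[risk_a]])
  rb <- risk_as_numeric(data[[risk_b]])
  tt <- data[[time]]
  ee <- data[[event]]
  n <- length(tt)
  d_obs <- cindex_core(ra, tt, ee)$c - cindex_core(rb, tt, ee)$c
  d_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(
        cindex_core(ra[idx], tt[idx], ee[idx])$c -
          cindex_core(rb[idx], tt[idx], ee[idx])$c,
        error = function(e) NA_real_
      )
    }, numeric(1))
  })
  d_boot <- d_boot[!is.na(d_boot)]
  a <- (1 - conf.level) / 2
  qs <- quantile(d_boot, c(a, 1 - a), names = FALSE)
  p <- 2 * min(mean(d_boot <= 0), mean(d_boot >= 0))
  tibble::tibble(
    delta_c = d_obs, conf.low = qs[1], conf.high = qs[2],
    p.value = min(1, p),
    c_a = cindex_core(ra, tt, ee)$c, c_b = cindex_core(rb, tt, ee)$c,
    n_boot = length(d_boot)
  )
}

# censoring-distribution KM, queried as G(t) = P(C > t); `minus` gives the
# left limit G(t-)
censoring_km <- function(time, event) {
  df <- data.frame(.t = time, .c = 1 - event)
  fit <- survival::survfit(survival::Surv(.t, .c) ~ 1, data = df)
  function(t, minus = FALSE) {
    tq <- if (minus) t - 1e-9 else t
    vapply(tq, function(x) {
      i <- findInterval(x, fit$time)
      if (i == 0) 1 else fit$surv[i]
    }, numeric(1))
  }
}

#' Time-dependent (cumulative/dynamic) AUC at a horizon
#'
#' AUC for discriminating patients who fail by the horizon (cases: event
#' observed at or before it) from those still event-free beyond it
#' (controls), weighting both by the inverse probability of censoring from
#' the Kaplan–Meier estimate of the censoring distribution.
#'
#' @param data Data frame.
#' @param risk Risk-score column name (higher = worse); ordered factors are
#'   converted to integer codes.
#' @param horizon_months Evaluation horizon.
#' @param time,event Column names.
#' @return One-row tibble: `horizon_months`, `auc`, `n_cases`, `n_controls`.
#' @export
td_auc <- function(data, risk, horizon_months, time = "time_months",
                   event = "event") {
  r <- risk_as_numeric(data[[risk]])
  tt <- data[[time]]
  ee <- data[[event]]
  if (horizon_months >= max(tt)) {
    abort("horizon must lie within the follow-up range")
  }
  cases <- which(tt <= horizon_months & ee == 1)
  controls <- which(tt > horizon_months)
  if (length(cases) == 0) abort("no events before the horizon")
  if (length(controls) == 0) abort("no patients at risk beyond the horizon")
  g <- censoring_km(tt, ee)
  w_case <- 1 / g(tt[cases], minus = TRUE)
  w_ctrl <- rep(1 / g(horizon_months), length(controls))
  cmp <- outer(r[cases], r[controls], function(a, b) (a > b) + 0.5 * (a == b))
  wmat <- outer(w_case, w_ctrl)
  tibble::tibble(
    horizon_months = horizon_months,
    auc = sum(cmp * wmat) / sum(wmat),
    n_cases = length(cases), n_controls = length(controls)
  )
}

#' Decision-curve analysis at a horizon
#'
#' Net benefit of treating patients whose predicted event probability at
#' the horizon reaches each threshold, against treat-all and treat-none:
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)`. Under censoring, TP and FP among
#' the treated are estimated from the Kaplan–Meier event probability at the
#' horizon within the treated subset.
#'
#' @param data Data frame.
#' @param prob Column of predicted event probabilities at the horizon (in
#'   \[0, 1\]; see [predict_category_risk()] for category-based models).
#' @param horizon_months Evaluation horizon (must lie within follow-up).
#' @param thresholds Threshold probabilities (default 0.01–0.99 by 0.01).
#' @param time,event Column names.
#' @return A tibble of class `fl_dca`, long over `threshold` and `strategy`
#'   (`"model"`, `"treat_all"`, `"treat_none"`) with `net_benefit`.
#' @export
decision_curve <- function(data, prob, horizon_months,
                           thresholds = seq(0.01, 0.99, by = 0.01),
                           time = "time_months", event = "event") {
  p <- data[[prob]]
  tt <- data[[time]]
  ee <- data[[event]]
  if (any(thresholds <= 0 | thresholds >= 1)) {
    abort("thresholds must lie strictly inside (0, 1)")
  }
  if (horizon_months > max(tt)) abort("horizon beyond observed follow-up")
  n <- length(p)
  km_event_at <- function(idx) {
    if (length(idx) == 0) return(NA_real_)
    km <- km_estimate(data.frame(time_months = tt[idx], event = ee[idx]))
    1 - surv_at(km, horizon_months)$surv
  }
  overall <- km_event_at(seq_len(n))
  rows <- purrr::map_dfr(thresholds, function(pt) {
    odds <- pt / (1 - pt)
    pos <- which(p >= pt)
    nb_model <- if (length(pos) == 0) 0 else {
      er <- km_event_at(pos)
      (length(pos) / n) * (er - (1 - er) * odds)
    }
    nb_all <- overall - (1 - overall) * odds
    tibble::tibble(
      threshold = pt,
      strategy = c("model", "treat_all", "treat_none"),
      net_benefit = c(nb_model, nb_all, 0)
    )
  })
  class(rows) <- c("fl_dca", class(rows))
  rows
}

#' Calibration of predicted survival at a horizon
#'
#' Bins patients by predicted survival probability (quantile bins, or an
#' explicit grouping column such as the risk category) and compares the
#' mean prediction in each bin with the observed Kaplan–Meier survival at
#' the horizon.
#'
#' @param data Data frame.
#' @param pred_surv Column of predicted survival probabilities at the
#'   horizon (in \[0, 1\]).
#' @param horizon_months Evaluation horizon.
#' @param bins Optional grouping column name; overrides `n_bins`.
#' @param n_bins Number of quantile bins when `bins` is not given
#'   (default 10; reduced with a warning when the cohort is too small).
#' @param time,event Column names.
#' @return A tibble of class `fl_calibration`: `bin`, `n`, `pred_surv`
#'   (bin mean), `obs_surv`, `conf.low`, `conf.high`. Empty bins are
#'   dropped with a warning.
#' @export
calibration <- function(data, pred_surv, horizon_months, bins = NULL,
                        n_bins = 10, time = "time_months", event = "event") {
  p <- data[[pred_surv]]
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("predicted survival probabilities must lie in [0, 1]")
  }
  if (is.null(bins)) {
    if (n_bins > length(p)) {
      warn("n_bins exceeds the number of patients; using one bin per distinct prediction")
      n_bins <- min(n_bins, length(unique(p)))
    }
    br <- unique(quantile(p, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) br <- c(-Inf, Inf)
    grp <- cut(p, breaks = br, include.lowest = TRUE)
  } else {
    grp <- factor(data[[bins]])
  }
  tt <- data[[time]]
  ee <- data[[event]]
  rows <- purrr::map_dfr(levels(droplevels(grp)), function(g) {
    idx <- which(grp == g)
    if (length(idx) == 0) return(NULL)
    km <- km_estimate(data.frame(time_months = tt[idx], event = ee[idx]))
    s <- surv_at(km, horizon_months)
    tibble::tibble(bin = g, n = length(idx), pred_surv = mean(p[idx]),
                   obs_surv = s$surv, conf.low = s$conf.low,
                   conf.high = s$conf.high)
  })
  dropped <- setdiff(levels(grp), rows$bin)
  if (length(dropped) > 0) warn(paste("empty bins dropped:", paste(dropped, collapse = ", ")))
  class(rows) <- c("fl_calibration", class(rows))
  rows
}

#' Category-level predicted event probabilities
#'
#' For ordinal risk-category models, the predicted event probability at a
#' horizon is the category's own Kaplan–Meier event probability; this maps
#' it back onto patients for use in decision-curve and calibration
#' analyses.
#'
#' @param data Data frame.
#' @param category Risk-category column name.
#' @param horizon_months Horizon.
#' @param time,event Column names.
#' @param name Name of the appended column (default `"pred_event_prob"`).
#' @return The data with the predicted event-probability column appended.
#' @export
predict_category_risk <- function(data, category, horizon_months,
                                  time = "time_months", event = "event",
                                  name = "pred_event_prob") {
  grp <- factor(data[[category]])
  pr <- rep(NA_real_, nrow(data))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 0) next
    km <- km_estimate(data.frame(time_months = data[[time]][idx],
                                 event = data[[event]][idx]))
    pr[idx] <- 1 - surv_at(km, horizon_months)$surv
  }
  data[[name]] <- pr
  tibble::as_tibble(data)
}
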