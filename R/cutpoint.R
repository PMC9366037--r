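#' Optimal survival cutpoint by maximally selected log-rank statistic
#'
#' Scans candidate cutoffs at the midpoints between consecutive sorted
#' unique feature values, keeps those where both resulting groups contain at
#' least `floor(min_frac * n)` patients, and returns the cutoff maximizing
#' the two-group log-rank chi-square. Because the statistic is maximized
#' over many looks, the naive chi-square p-value is anti-conservative; the
#' corrected p-value uses the Miller–Siegmund approximation for maximally
#' selected statistics over the scanned quantile range (and is never
#' reported below the uncorrected value).
#'
#' The scan is deterministic; ties in the maximal chi-square resolve to the
#' smallest cutoff.
#'
#' @param data Data frame of one patient per row.
#' @param feature Name of the continuous feature column.
#' @param time,event Names of the follow-up time and event-indicator
#'   columns (defaults `"time_months"`, `"event"`).
#' @param min_frac Minimum fraction of the cohort in each group
#'   (0 < min_frac < 0.5; default 0.1).
#' @return A one-row tibble of class `fl_cutpoint`: `feature`, `cutoff`,
#'   `chi2`, `p_uncorrected`, `p_corrected`, `n_low`, `n_high`. The
#'   attribute `"scan"` holds the full candidate table (`cutoff`, `chi2`,
#'   `n_low`) for plotting and verification.
#' @export
optimal_cutoff <- function(data, feature, time = "time_months",
                           event = "event", min_frac = 0.1) {
  values <- data[[feature]]
  times <- data[[time]]
  events <- data[[event]]
  n <- length(values)
  if (is.null(values)) abort(paste0("column `", feature, "` not found"))
  if (n < 10) abort("need at least 10 observations")
  if (sum(events) < 1) abort("need at least one event")
  if (!is_scalar_number(min_frac) || min_frac <= 0 || min_frac >= 0.5) {
    abort("`min_frac` must lie in (0, 0.5)")
  }
  u <- sort(unique(values))
  if (length(u) < 2) abort("all feature values are identical")
  cand <- (u[-1] + u[-length(u)]) / 2
  n_low <- vapply(cand, function(cc) sum(values <= cc), integer(1))
  min_n <- floor(min_frac * n)
  ok <- n_low >= min_n & (n - n_low) >= min_n
  if (!any(ok)) abort("no admissible cutoff satisfies the group-size constraint")
  cand <- cand[ok]
  n_low <- n_low[ok]

  chi2 <- logrank_scan(values, times, events, cand)
  best <- which.max(chi2)  # first (smallest cutoff) on ties
  b <- sqrt(chi2[best])
  p_unc <- pchisq(chi2[best], df = 1, lower.tail = FALSE)
  eps1 <- min(n_low) / n
  eps2 <- max(n_low) / n
  # Miller-Siegmund improved Bonferroni bound for the maximally selected
  # standardized log-rank statistic over quantile range [eps1, eps2]
  p_ms <- dnorm(b) * (b - 1 / b) * log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2))) +
    4 * dnorm(b) / b
  p_cor <- min(1, max(p_ms, p_unc))

  n_low_best <- n_low[best]
  out <- tibble::tibble(
    feature = feature, cutoff = cand[best], chi2 = chi2[best],
    p_uncorrected = p_unc, p_corrected = p_cor,
    n_low = n_low_best, n_high = n - n_low_best
  )
  attr(out, "scan") <- tibble::tibble(cutoff = cand, chi2 = chi2, n_low = n_low)
  class(out) <- c("fl_cutpoint", class(out))
  out
}

#' Two-group log-rank chi-square for every candidate cutoff at once
#'
#' Vectorized over cutoffs: the numerator is the inner product of the group
#' indicator with the null martingale residuals, the hypergeometric variance
#' is accumulated over distinct event times via matrix products.
#' @noRd
logrank_scan <- function(values, times, events, cutoffs) {
  et <- sort(unique(times[events == 1]))
  at_risk <- outer(et, times, "<=")                       # T x n
  d_mat <- outer(et, times, "==") * rep(events, each = length(et))
  n_i <- rowSums(at_risk)
  d_i <- rowSums(d_mat)
  g <- outer(values, cutoffs, ">") * 1                    # n x K, 1 = high group
  n1 <- at_risk %*% g                                     # T x K
  d1 <- d_mat %*% g
  frac <- n1 / n_i
  o_minus_e <- colSums(d1 - d_i * frac)
  vterm <- d_i * frac * (1 - frac) * ifelse(n_i > 1, (n_i - d_i) / (n_i - 1), 0)
  v <- colSums(vterm)
  chi2 <- ifelse(v > 0, o_minus_e^2 / v, 0)
  chi2
}

#' Dichotomize a feature at a cutoff
#'
#' Adds `<feature>_high = as.integer(feature > cutoff)` (strict inequality:
#' a value exactly at the cutoff belongs to the low group).
#'
#' @param data Data frame.
#' @param feature Feature column name.
#' @param cutoff Numeric cutoff.
#' @param name Name of the new column (default `paste0(feature, "_high")`).
#' @return The data frame with the indicator column appended.
#' @export
cut_feature <- function(data, feature, cutoff, name = NULL) {
  name <- name %||% paste0(feature, "_high")
  data[[name]] <- as.integer(data[[feature]] > cutoff)
  tibble::as_tibble(data)
}
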