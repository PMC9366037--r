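#' 2x2 contingency-table test with automatic method routing
#'
#' Pearson chi-square without continuity correction when every expected
#' count is at least 5, otherwise Fisher's exact test. Omitting the
#' continuity correction is what reproduces the published group-comparison
#' p-values from their printed counts; either method can also be forced.
#'
#' @param tab 2x2 integer matrix of counts (e.g. grade group by factor
#'   status), or a length-4 vector `c(a, b, c, d)` filled by row.
#' @param method `"auto"` (default), `"pearson"`, or `"fisher"`.
#' @return One-row tibble: `statistic` (chi-square, `NA` for Fisher),
#'   `p.value`, `method_used`, `min_expected`.
#' @export
contingency_test <- function(tab, method = c("auto", "pearson", "fisher")) {
  method <- match.arg(method)
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (!all(dim(tab) == 2L)) abort("`tab` must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) abort("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("zero margin: the test is undefined")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use <- switch(method,
    auto = if (min(expected) >= 5) "pearson" else "fisher",
    method
  )
  if (use == "pearson") {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(statistic = unname(ct$statistic), p.value = ct$p.value,
                   method_used = "pearson", min_expected = min(expected))
  } else {
    ft <- fisher.test(tab)
    tibble::tibble(statistic = NA_real_, p.value = ft$p.value,
                   method_used = "fisher", min_expected = min(expected))
  }
}

#' Mann–Whitney U test
#'
#' Two-sided comparison of two independent samples: exact when both samples
#' have at most 8 observations and no ties, otherwise the normal
#' approximation with tie correction.
#'
#' @param x,y Numeric samples (both nonempty).
#' @return One-row tibble: `u` (the U statistic of `x`), `p.value`,
#'   `method_used`.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  tibble::tibble(u = unname(wt$statistic), p.value = wt$p.value,
                 method_used = if (exact) "exact" else "normal_approx")
}

#' Empirical ROC analysis of a continuous marker against a binary label
#'
#' Builds the empirical ROC curve (positive call when the marker value is
#' at or above a cutoff; higher values are assumed to indicate the positive
#' class), computes the trapezoid AUC — identical to the normalized
#' Mann–Whitney rank-sum — selects the cutoff maximizing Youden's J
#' (sensitivity + specificity − 1, ties resolved toward higher
#' specificity), and reports sensitivity, specificity, PPV and NPV at that
#' cutoff plus the AUC p-value against 0.5 from the Hanley–McNeil normal
#' approximation.
#'
#' @param data Data frame.
#' @param value Marker column name.
#' @param label Binary label column name (1/TRUE = positive class).
#' @return One-row tibble of class `fl_roc`: `auc`, `p_auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `n_pos`, `n_neg`. The
#'   `"curve"` attribute holds the full ROC (`cutoff`, `tpr`, `fpr`).
#' @export
roc_binary <- function(data, value, label) {
  v <- data[[value]]
  y <- as.integer(data[[label]])
  if (length(unique(y)) < 2) abort("both classes must be present")
  pos <- v[y == 1]
  neg <- v[y == 0]
  n_pos <- length(pos)
  n_neg <- length(neg)

  cuts <- sort(unique(v))
  tpr <- vapply(cuts, function(cc) mean(pos >= cc), numeric(1))
  fpr <- vapply(cuts, function(cc) mean(neg >= cc), numeric(1))
  # AUC via the rank-sum (equals the trapezoid area under the empirical ROC)
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n_pos)]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  j <- tpr + (1 - fpr) - 1
  best <- which(j == max(j))
  best <- best[which.max(1 - fpr[best])]  # prefer higher specificity on ties
  sens <- tpr[best]
  spec <- 1 - fpr[best]
  tp <- sum(pos >= cuts[best]); fp <- sum(neg >= cuts[best])
  fn <- n_pos - tp; tn <- n_neg - fp
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
              (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  p_auc <- 2 * pnorm(-abs(auc - 0.5) / se)

  out <- tibble::tibble(
    auc = auc, p_auc = p_auc, cutoff = cuts[best],
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    n_pos = n_pos, n_neg = n_neg
  )
  attr(out, "curve") <- tibble::tibble(cutoff = cuts, tpr = tpr, fpr = fpr)
  class(out) <- c("fl_roc", class(out))
  out
}

#' Reconstruct PPV/NPV from sensitivity, specificity and the class split
#'
#' Confusion-matrix arithmetic at a reported operating point:
#' `TP = round(sens * n_pos)`, `FP = round((1 - spec) * n_neg)`, the rest by
#' subtraction, then `PPV = TP / (TP + FP)` and `NPV = TN / (TN + FN)`.
#'
#' @param sens,spec Sensitivity and specificity in \[0, 1\].
#' @param n_pos,n_neg Positive/negative class sizes (> 0).
#' @return One-row tibble: `ppv`, `npv`, `tp`, `fp`, `fn`, `tn`. Undefined
#'   PPV (no predicted positives) yields `NA` with a warning.
#' @export
ppv_npv_from_sens_spec <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1, n_pos > 0, n_neg > 0)
  tp <- round(sens * n_pos)
  fp <- round((1 - spec) * n_neg)
  fn <- n_pos - tp
  tn <- n_neg - fp
  ppv <- if (tp + fp > 0) tp / (tp + fp) else {
    warn("no predicted positives; PPV undefined")
    NA_real_
  }
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  tibble::tibble(ppv = ppv, npv = npv, tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Multivariable logistic regression
#'
#' Maximum-likelihood logistic fit with Wald inference, for identifying
#' independent predictors of a binary outcome such as pathologic grade.
#' Complete or quasi-complete separation is flagged as an error.
#'
#' @param data Data frame.
#' @param covariates Character vector of covariate column names.
#' @param label Binary outcome column name.
#' @return An object of class `fl_logit`; see [tidy.fl_logit()].
#' @export
logistic_fit <- function(data, covariates, label) {
  fml <- stats::as.formula(paste(label, "~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = data, family = binomial()))
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15)) {
    abort("logistic fit flagged: possible complete separation or non-convergence")
  }
  structure(list(fit = fit, covariates = covariates, label = label),
            class = "fl_logit")
}

#' @export
print.fl_logit <- function(x, ...) {
  print(tidy(x))
  invisible(x)
}

#' Tidy a logistic fit
#' @param x An `fl_logit` object.
#' @param conf.level Confidence level (default 0.95).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (log OR), `std.error`, `or`,
#'   `conf.low`, `conf.high` (OR scale), `p.value` (Wald).
#' @method tidy fl_logit
#' @export
tidy.fl_logit <- function(x, conf.level = 0.95, ...) {
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(
    term = names(b), estimate = unname(b), std.error = unname(se),
    or = exp(unname(b)),
    conf.low = exp(unname(b - z * se)), conf.high = exp(unname(b + z * se)),
    p.value = 2 * pnorm(-abs(unname(b) / unname(se)))
  )
}

#' Model-level summary of a logistic fit
#' @param x An `fl_logit` object.
#' @param ... Unused.
#' @return One-row tibble: `n`, `deviance`, `aic`.
#' @method glance fl_logit
#' @export
glance.fl_logit <- function(x, ...) {
  tibble::tibble(n = length(x$fit$y), deviance = x$fit$deviance,
                 aic = x$fit$aic)
}
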