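test_that("concordance handles perfect ranking and pure ties", {
  d <- tibble::tibble(risk = c(3, 2, 1), time_months = c(1, 2, 3),
                      event = c(1L, 1L, 1L))
  expect_equal(c_index(d, "risk")$c_index, 1.0)
  d$risk <- c(2, 2, 2)
  expect_equal(c_index(d, "risk")$c_index, 0.5)
})

test_that("concordance equals the brute-force pair count and the survival package", {
  d <- sim_surv(200, seed = 17)
  d$risk <- -d$time_months + rnorm(200, sd = 5)
  got <- c_index(d, "risk")$c_index
  expect_equal(got, bf_cindex(d$risk, d$time_months, d$event))
  cf <- survival::concordance(
    survival::Surv(time_months, event) ~ risk, data = d, reverse = TRUE
  )
  expect_equal(got, unname(cf$concordance), tolerance = 1e-12)
})

test_that("paired bootstrap comparison is coherent and seed-deterministic", {
  d <- sim_surv(120, seed = 23)
  d$a <- -d$time_months
  d$b <- d$a
  same <- compare_c(d, "a", "b", n_boot = 300, seed = 2)
  expect_equal(same$delta_c, 0)
  expect_gte(same$p.value, 0.99)
  # identical call, identical result
  expect_identical(same, compare_c(d, "a", "b", n_boot = 300, seed = 2))
  # a perfect model clearly beats noise
  set.seed(5)
  d$noise <- rnorm(120)
  gap <- compare_c(d, "a", "noise", n_boot = 500, seed = 3)
  expect_gt(gap$conf.low, 0)
  expect_warning(compare_c(d, "a", "b", n_boot = 50, seed = 1), "unstable")
})

test_that("time-dependent AUC matches a direct IPCW double sum", {
  # perfect ordering without censoring gives AUC 1 at any usable horizon
  d <- tibble::tibble(time_months = 1:20, event = rep(1L, 20),
                      risk = 20:1)
  expect_equal(td_auc(d, "risk", 10)$auc, 1.0)
  # independent risks hover near 1/2
  big <- sim_surv(1500, seed = 31)
  big$risk <- rnorm(1500)
  expect_lt(abs(td_auc(big, "risk", 15)$auc - 0.5), 0.05)
  # small worked example against an independent double-sum oracle
  d2 <- sim_surv(40, seed = 13)
  d2$risk <- -d2$time_months + rnorm(40, sd = 8)
  tau <- 15
  got <- td_auc(d2, "risk", tau)$auc
  cfit <- survival::survfit(survival::Surv(time_months, 1 - event) ~ 1, data = d2)
  gfun <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  num <- den <- 0
  for (i in seq_len(40)) {
    for (j in seq_len(40)) {
      if (d2$time_months[i] <= tau && d2$event[i] == 1 && d2$time_months[j] > tau) {
        w <- (1 / gfun(d2$time_months[i] - 1e-9)) * (1 / gfun(tau))
        num <- num + w * ((d2$risk[i] > d2$risk[j]) + 0.5 * (d2$risk[i] == d2$risk[j]))
        den <- den + w
      }
    }
  }
  expect_equal(got, num / den, tolerance = 1e-10)
  expect_error(td_auc(d2, "risk", 1000), "follow-up")
})

test_that("net benefit matches hand tallies on an uncensored toy cohort", {
  d <- tibble::tibble(
    time_months = c(rep(5, 6), rep(40, 14)),
    event = c(rep(1L, 6), rep(0L, 14)),
    prob = c(rep(0.8, 4), 0.2, 0.2, rep(0.8, 2), rep(0.2, 12))
  )
  dc <- decision_curve(d, "prob", 30, thresholds = c(0.5))
  # at pt 0.5: positives are the 6 with prob .8 -> TP 4, FP 2 (n 20)
  nb_model <- 4 / 20 - (2 / 20) * (0.5 / 0.5)
  expect_equal(dc$net_benefit[dc$strategy == "model"], nb_model)
  # treat-all closed form from the overall event rate 6/20
  er <- 6 / 20
  expect_equal(dc$net_benefit[dc$strategy == "treat_all"], er - (1 - er))
  expect_equal(dc$net_benefit[dc$strategy == "treat_none"], 0)
  expect_error(decision_curve(d, "prob", 30, thresholds = c(0, 0.5)), "strictly")
})

test_that("calibration bins recover whole-cohort survival when degenerate", {
  d <- sim_surv(80, seed = 41)
  d$pred <- rep(0.6, 80)
  expect_warning(cal <- calibration(d, "pred", 15, n_bins = 4), NA)
  km <- km_estimate(d)
  expect_equal(nrow(cal), 1)
  expect_equal(cal$obs_surv, surv_at(km, 15)$surv)
  # n_bins beyond n triggers the degenerate-input warning path
  small <- sim_surv(5, seed = 2)
  small$pred <- runif(5)
  expect_warning(calibration(small, "pred", 5, n_bins = 50), "n_bins")
})

test_that("well-calibrated predictions fall along the diagonal", {
  set.seed(19)
  n <- 4000
  rate <- exp(rnorm(n, log(0.03), 0.8))
  te <- rexp(n, rate)
  d <- tibble::tibble(time_months = pmin(te, 60), event = as.integer(te <= 60),
                      pred = exp(-rate * 24))  # true S(24) per patient
  cal <- calibration(d, "pred", 24, n_bins = 4)
  expect_true(all(cal$obs_surv >= cal$conf.low & cal$obs_surv <= cal$conf.high))
  expect_true(all(abs(cal$pred_surv - cal$obs_surv) < 0.05))
})

test_that("category-level predicted probabilities mirror each group's KM", {
  co <- gen_cohort(cohort_spec(n = 400, seed = 8)) |> score_patients()
  out <- predict_category_risk(co, "risk_category", 36)
  for (g in levels(co$risk_category)) {
    idx <- out$risk_category == g
    if (!any(idx)) next
    km <- km_estimate(out[idx, ])
    expect_equal(unique(out$pred_event_prob[idx]),
                 1 - surv_at(km, 36)$surv, tolerance = 1e-12)
  }
})
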