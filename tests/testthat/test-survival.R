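test_that("PFS intervals convert dates to months", {
  d <- tibble::tibble(
    diagnosis_date = as.Date(c("2015-01-01", "2016-03-10")),
    end_date = as.Date(c("2016-01-01", "2016-03-10")),
    event = c(1L, 0L)
  )
  out <- compute_pfs(d)
  expect_equal(out$time_months[1], 365 / 30.44, tolerance = 1e-12)
  expect_equal(round(out$time_months[1]), 12)
  expect_equal(out$time_months[2], 0)  # same-day follow-up, censored
  expect_equal(out$event, c(1L, 0L))
  bad <- d
  bad$end_date[1] <- as.Date("2014-01-01")
  expect_error(compute_pfs(bad), "precedes")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  d <- tibble::tibble(time_months = c(1, 2, 3), event = c(1L, 1L, 1L))
  km <- km_estimate(d)
  expect_equal(surv_at(km, 1.5)$surv, 2 / 3)
  expect_equal(surv_at(km, 2.5)$surv, 1 / 3)
  # all censored: S = 1 everywhere
  cns <- km_estimate(tibble::tibble(time_months = c(1, 5, 9), event = c(0L, 0L, 0L)))
  expect_equal(surv_at(cns, c(0.5, 6, 20))$surv, c(1, 1, 1))
  # censor before an event: S(3) = (1 - 1/3) * (1 - 1/1) = 0
  mix <- km_estimate(tibble::tibble(time_months = c(1, 2, 3),
                                    event = c(1L, 0L, 1L)))
  expect_equal(surv_at(mix, 2.5)$surv, 2 / 3)
  expect_equal(surv_at(mix, 3)$surv, 0)
})

test_that("KM without censoring is the empirical survival function", {
  d <- sim_surv(60, seed = 9)
  d$event <- 1L
  km <- km_estimate(d)
  ts <- c(2, 7, 15, 30)
  expect_equal(surv_at(km, ts)$surv,
               vapply(ts, function(t) mean(d$time_months > t), numeric(1)))
})

test_that("log-rank statistic behaves as the O-E computation dictates", {
  d <- sim_surv(20, seed = 3)
  two <- dplyr::bind_rows(dplyr::mutate(d, g = "a"), dplyr::mutate(d, g = "b"))
  expect_equal(logrank_test(two, "g")$chi2, 0, tolerance = 1e-12)
  # three groups -> df 2
  d3 <- sim_surv(30, seed = 5)
  d3$g <- rep(c("a", "b", "c"), 10)
  expect_equal(logrank_test(d3, "g")$df, 2)
  # hand computation on a tiny worked two-group sample (no ties):
  # group A times 1,3 both events; group B times 2,4, event then censor
  h <- tibble::tibble(time_months = c(1, 3, 2, 4),
                      event = c(1L, 1L, 1L, 0L),
                      g = c("A", "A", "B", "B"))
  # O-E for group A: t=1: 1-2/4; t=2: 0-1/3; t=3: 1-1/2 -> sum = 2/3
  # V: t=1 (1/2)(1/2); t=2 (1/3)(2/3); t=3 (1/2)(1/2) -> 1/4+2/9+1/4 = 13/18
  sd <- logrank_test(h, "g")
  expect_equal(sd$chi2, (2 / 3)^2 / (13 / 18), tolerance = 1e-10)
})

test_that("Cox coefficient matches a grid search of the partial likelihood", {
  d <- tibble::tibble(
    time_months = c(2, 5, 7, 11, 13, 17),
    event = c(1L, 1L, 0L, 1L, 1L, 0L),
    x = c(1, 0, 1, 1, 0, 0)
  )
  fit <- cox_fit(d, "x")
  expect_equal(tidy(fit)$estimate, bf_cox_coef(d$x, d$time_months, d$event),
               tolerance = 1e-5)
  # Efron equals Breslow when there are no tied event times
  fb <- cox_fit(d, "x", ties = "breslow")
  expect_equal(tidy(fit)$estimate, tidy(fb)$estimate, tolerance = 1e-8)
})

test_that("Cox inference is sane under null and strong signals", {
  set.seed(77)
  d <- sim_surv(400, seed = 77)
  d$x <- rnorm(400)  # independent of outcome
  td <- tidy(cox_fit(d, "x"))
  expect_lt(abs(td$hr - 1), 0.2)
  expect_true(td$conf.low < td$hr && td$hr < td$conf.high)
  expect_error(cox_fit(dplyr::mutate(d, cst = 1), "cst"), "constant")
})

test_that("univariate screening keeps covariates below alpha", {
  co <- gen_cohort(cohort_spec(n = 500, seed = 12)) |>
    cut_feature("tlg", fl_cutoffs()$tlg)
  sel <- screen_univariate(co, c("tlg_high", "b_symptoms", "bm_involved"))
  expect_true(sel$selected[sel$term == "tlg_high"])  # planted HR 3.6
  expect_equal(sel$term, c("tlg_high", "b_symptoms", "bm_involved"))
  none <- screen_univariate(co, c("tlg_high"), alpha = 0)
  expect_false(any(none$selected))
})

test_that("separate multivariate models are built per metabolic parameter", {
  co <- gen_cohort(cohort_spec(n = 400, seed = 3)) |>
    cut_feature("suv_max", fl_cutoffs()$suv_max) |>
    cut_feature("tlg", fl_cutoffs()$tlg) |>
    cut_feature("tmtv_cm3", fl_cutoffs()$tmtv_cm3, name = "tmtv_high") |>
    cut_feature("d_max_cm", fl_cutoffs()$d_max_cm, name = "dmax_high")
  mods <- fit_metabolic_models(co, c("ldh_elevated", "dmax_high"),
                               c("suv_max_high", "tmtv_high", "tlg_high"))
  expect_named(mods, c("suv_max_high", "tmtv_high", "tlg_high"))
  for (m in mods) {
    expect_s3_class(m, "fl_cox")
    expect_equal(nrow(tidy(m)), 3)
  }
})
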