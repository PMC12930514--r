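test_that("survivor functions obey closed forms and S(0) = 1", {
  expect_equal(survival_at(list(family = "exponential", params = 0.5), 0), 1)
  expect_equal(survival_at(list(family = "exponential", params = 0.5), 2),
               exp(-1), tolerance = 1e-12)
  # Weibull with shape 1 degenerates to the exponential
  wb <- list(family = "weibull", params = c(1, 1 / 0.5))
  ex <- list(family = "exponential", params = 0.5)
  expect_equal(survival_at(wb, 2), survival_at(ex, 2), tolerance = 1e-12)

  cases <- list(
    exponential = 0.1, weibull = c(1.4, 12), gompertz = c(0.05, 0.02),
    log_normal = c(2, 0.6), log_logistic = c(1.5, 10),
    generalized_gamma = c(2, 0.8, 0.5)
  )
  t <- seq(0, 200, by = 0.5)
  for (fam in names(cases)) {
    s <- survival_at(list(family = fam, params = cases[[fam]]), t)
    expect_equal(s[1], 1, info = fam)
    expect_true(all(diff(s) <= 1e-12), info = fam)
    expect_true(all(s >= 0 & s <= 1), info = fam)
  }
})

test_that("invalid parameter vectors are rejected", {
  expect_error(survival_at(list(family = "exponential", params = -1), 1),
               "parameter-domain")
  expect_error(survival_at(list(family = "weibull", params = c(1, 0)), 1),
               "parameter-domain")
  expect_error(survival_at(list(family = "weibull", params = 1), 1),
               "needs 2")
  expect_error(survival_at(list(family = "nope", params = 1), 1),
               "unknown parametric family")
  expect_error(survival_at(list(family = "exponential", params = 1), -1),
               "non-negative")
})

test_that("exponential MLE equals events over exposure", {
  # 10 subjects, all events, total follow-up 20 months -> rate 0.5
  ipd <- data.frame(time = rep(2, 10), event = 1)
  f <- fit_parametric(ipd, "exponential")
  expect_equal(f$params, 0.5, tolerance = 1e-6)

  ipd2 <- sim_surv_ipd(400, "exponential", 0.1, censor_frac = 0.3,
                       seed = 21)
  f2 <- fit_parametric(ipd2, "exponential")
  expect_equal(f2$params, sum(ipd2$event) / sum(ipd2$time),
               tolerance = 1e-8)
  # information-criterion identities
  expect_equal(f2$aic, -2 * f2$log_likelihood + 2, tolerance = 1e-10)
  expect_equal(f2$bic, -2 * f2$log_likelihood + log(400),
               tolerance = 1e-10)
})

test_that("fitting recovers simulated Weibull parameters", {
  ipd <- sim_surv_ipd(2000, "weibull", c(1.5, 10), seed = 7)
  f <- fit_parametric(ipd, "weibull")
  expect_lt(abs(f$params[1] - 1.5) / 1.5, 0.1)
  expect_lt(abs(f$params[2] - 10) / 10, 0.1)
})

test_that("degenerate inputs raise fitting errors", {
  expect_error(fit_parametric(data.frame(time = 3, event = 0),
                              "exponential"), "at least 2")
  expect_error(fit_parametric(data.frame(time = c(3, 5), event = c(0, 0)),
                              "exponential"), "zero observed events")
  expect_error(fit_parametric(data.frame(time = c(-1, 2), event = c(1, 1)),
                              "exponential"), "non-negative")
})

test_that("distribution selection ranks by AIC with tie-breaks", {
  ipd <- sim_surv_ipd(2000, "exponential", 0.1, seed = 3)
  fits <- fit_all_families(ipd, c("exponential", "generalized_gamma"))
  ranked <- select_distribution(fits)
  expect_equal(ranked$family[1], "exponential")
  expect_equal(ranked$rank, seq_len(nrow(ranked)))

  single <- select_distribution(fit_parametric(ipd, "weibull"))
  expect_equal(nrow(single), 1)
  expect_equal(single$family, "weibull")

  # identical AIC: fewer parameters first
  mk <- function(fam, k, ll) {
    structure(list(family = fam, params = rep(1, k), se = rep(0.1, k),
                   log_likelihood = ll, aic = -2 * ll + 2 * k,
                   bic = -2 * ll + k * log(100), n_subjects = 100L,
                   n_events = 80L),
              class = c("fitted_survival", "parametric_curve"))
  }
  tied <- select_distribution(list(mk("weibull", 2, -100),
                                   mk("exponential", 1, -101)))
  expect_equal(tied$aic[1], tied$aic[2])
  expect_equal(tied$family[1], "exponential")
  expect_error(select_distribution(list()), "no fits")
})

test_that("background-mortality adjustment floors the hazard correctly", {
  grid <- time_grid(1, 120)
  ages <- 50:80
  sex_mix <- c(female = 0.5, male = 0.5)
  zero_lt <- life_table(rep(ages, 2), rep(c("female", "male"),
                                          each = length(ages)),
                        rep(0, 2 * length(ages)))
  s_model <- survival_at(list(family = "exponential", params = 0.02),
                         grid$times)
  adj <- apply_background_mortality(s_model, zero_lt, 55, sex_mix, grid)
  expect_equal(as.numeric(adj), as.numeric(s_model), tolerance = 1e-10)
  expect_equal(attr(adj, "convention"), "hazard_max")

  # immortal disease model + constant background -> population curve
  qx <- 0.12
  const_lt <- life_table(rep(ages, 2), rep(c("female", "male"),
                                           each = length(ages)),
                         rep(qx, 2 * length(ages)))
  adj2 <- apply_background_mortality(rep(1, 121), const_lt, 55, sex_mix,
                                     grid)
  h_m <- -log(1 - qx) / 12
  expect_equal(as.numeric(adj2), exp(-h_m * grid$times), tolerance = 1e-10)

  # hazard-max picks the larger of the two: 0.005 model vs 0.01 population
  qx2 <- 1 - exp(-0.12)
  lt2 <- life_table(rep(ages, 2), rep(c("female", "male"),
                                      each = length(ages)),
                    rep(qx2, 2 * length(ages)))
  s3 <- survival_at(list(family = "exponential", params = 0.005),
                    grid$times)
  adj3 <- apply_background_mortality(s3, lt2, 55, sex_mix, grid)
  expect_equal(as.numeric(adj3), exp(-0.01 * grid$times),
               tolerance = 1e-9)
})

test_that("background adjustment is idempotent and bounded", {
  grid <- time_grid(1, 120)
  ages <- 50:90
  sex_mix <- c(female = 0.6, male = 0.4)
  lt <- life_table(rep(ages, 2), rep(c("female", "male"),
                                     each = length(ages)),
                   rep(pmin(0.01 + 0.002 * (ages - 50), 1), 2))
  s <- survival_at(list(family = "weibull", params = c(1.3, 30)),
                   grid$times)
  once <- apply_background_mortality(s, lt, 60, sex_mix, grid)
  twice <- apply_background_mortality(as.numeric(once), lt, 60, sex_mix,
                                      grid)
  expect_equal(as.numeric(twice), as.numeric(once), tolerance = 1e-12)
  expect_true(all(once <= s + 1e-12))
  pop <- basketpsm:::population_survival(lt, 60, sex_mix, grid)
  expect_true(all(once <= pop + 1e-12))

  expect_error(
    apply_background_mortality(s, lt, 88, sex_mix, grid),
    "life-table coverage")
})
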