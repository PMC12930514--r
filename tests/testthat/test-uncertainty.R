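test_that("parameter specs validate targets and distributions", {
  expect_error(parameter_spec("x", "intervention.bogus", "normal",
                              list(mean = 1, sd = 1)), "unresolvable")
  expect_error(parameter_spec("x", "elsewhere.utility_pf", "beta",
                              list(shape1 = 1, shape2 = 1)),
               "unresolvable")
  expect_error(parameter_spec("u", "both.utility_pf", "gamma",
                              list(shape = 1, rate = 1)), "beta")
  expect_error(parameter_spec("c", "both.drug_cost_per_cycle", "beta",
                              list(shape1 = 1, shape2 = 1)),
               "cannot use a beta")
  expect_error(parameter_spec("u", "both.utility_pf", "beta",
                              list(shape1 = 1)), "hyperparameters")
  expect_error(parameter_spec("u", "both.utility_pf", "beta",
                              list(shape1 = 1, shape2 = -2)), "positive")
  expect_error(parameter_spec("u", "both.utility_pf", "beta",
                              list(shape1 = 1, shape2 = 2),
                              scope = "site_specific"), "site_id")
  expect_error(dsa(tiny_model(),
                   list(parameter_spec("u", "both.utility_pf", "beta",
                                       list(shape1 = 1, shape2 = 2)))),
               "DSA bounds")
})

test_that("all-fixed specs collapse to the deterministic result", {
  m <- tiny_model()
  det <- run_model(m)
  fx <- list(
    parameter_spec("u", "both.utility_pf", "fixed", list(value = 0.8)),
    parameter_spec("c", "intervention.drug_cost_per_cycle", "fixed",
                   list(value = 4000))
  )
  psa <- run_psa(m, fx, n_iterations = 4, seed = 10)
  agg <- psa$samples[psa$samples$site == "aggregate", ]
  expect_lt(max(abs(agg$delta_qaly - det$delta_qaly_agg)), 1e-12)
  expect_lt(max(abs(agg$delta_cost - det$delta_cost_agg)), 1e-12)
})

test_that("shared draws are identical across sites within iterations", {
  m <- tiny_model()
  specs <- list(
    parameter_spec("u_pf", "both.utility_pf", "beta",
                   list(shape1 = 60, shape2 = 20), "shared"),
    parameter_spec("mgmt_beta", "comparator.disease_mgmt_cost_pd",
                   "gamma", list(shape = 36, rate = 0.06),
                   "site_specific", site_id = "beta")
  )
  psa <- run_psa(m, specs, n_iterations = 30, seed = 4)
  pd <- psa$param_draws
  shared <- pd[pd$parameter == "u_pf", ]
  per_iter <- tapply(shared$value, shared$iteration,
                     function(v) length(unique(v)))
  expect_true(all(per_iter == 1))
  spec_draws <- pd[pd$parameter == "mgmt_beta", ]
  expect_true(all(spec_draws$site == "beta"))
  expect_equal(psa$n_iterations, 30)
  expect_equal(nrow(psa$convergence), 30)
})

test_that("identical seeds give bit-identical PSA results", {
  m <- tiny_model(horizon = 60)
  specs <- list(parameter_spec("u", "both.utility_pd", "beta",
                               list(shape1 = 22, shape2 = 18), "shared"))
  a <- run_psa(m, specs, 25, seed = 123)
  b <- run_psa(m, specs, 25, seed = 123)
  expect_identical(a$samples, b$samples)
  expect_identical(a$param_draws, b$param_draws)
  c2 <- run_psa(m, specs, 25, seed = 124)
  expect_false(identical(a$samples, c2$samples))
})

test_that("CEAC limits behave as probabilities of positive NMB", {
  psa <- psa_from_samples(delta_cost = rep(-5, 40),
                          delta_qaly = rep(0.2, 40))
  cc <- ceac(psa, c(0, 1e4, 1e5))
  expect_true(all(cc$probability == 1))

  set.seed(2)
  dc <- rnorm(500, 0, 1)
  psa2 <- psa_from_samples(dc, rep(1, 500))
  c0 <- ceac(psa2, 0)
  expect_equal(c0$probability, mean(dc < 0))
  chuge <- ceac(psa2, 1e12)
  expect_equal(chuge$probability, 1)
  expect_error(ceac(psa2, numeric(0)), "empty")
})

test_that("tornado ordering and locality are correct", {
  m <- tiny_model(horizon = 60)
  specs <- list(
    parameter_spec("inert", "comparator.ae_cost_oneoff", "fixed",
                   list(value = 1000), dsa_low = 1000, dsa_high = 1000),
    parameter_spec("u_pf", "both.utility_pf", "beta",
                   list(shape1 = 80, shape2 = 20), "shared",
                   dsa_low = 0.6, dsa_high = 0.95),
    parameter_spec("drug", "intervention.drug_cost_per_cycle", "gamma",
                   list(shape = 100, rate = 0.025), "site_specific",
                   site_id = "alpha", dsa_low = 3000, dsa_high = 5000)
  )
  tab <- dsa(m, specs, wtp = 1e5)
  expect_equal(tab$parameter[nrow(tab)], "inert")
  expect_equal(tab$nmb_range[tab$parameter == "inert"], 0)
  expect_true(all(diff(tab$nmb_range) <= 1e-9))

  # site-specific parameter only perturbs its own site
  base <- run_model(m)
  spec_drug <- specs[[3]]
  pert <- run_model(basketpsm:::.apply_param(m, spec_drug, 5000, "alpha"))
  expect_equal(pert$per_site[pert$per_site$site == "beta", -1],
               base$per_site[base$per_site$site == "beta", -1])
  expect_gt(pert$per_site$delta_cost[pert$per_site$site == "alpha"],
            base$per_site$delta_cost[base$per_site$site == "alpha"])
})

test_that("a cost entering one arm scales incremental cost linearly", {
  m <- tiny_model(horizon = 120)
  # per-unit discounted progression-free drug exposure of the arm
  unit <- m$sites$alpha$intervention
  for (f in basketpsm:::.arm_scalar_fields) unit[[f]] <- 0
  unit$drug_cost_per_cycle <- 1
  exposure <- evaluate_arm(unit, m$grid, m$econ)$total_cost

  spec_drug <- parameter_spec("drug", "intervention.drug_cost_per_cycle",
                              "fixed", list(value = 4000),
                              "site_specific", site_id = "alpha",
                              dsa_low = 4000, dsa_high = 8000)
  base <- run_model(m)
  doubled <- run_model(basketpsm:::.apply_param(m, spec_drug, 8000,
                                                "alpha"))
  got <- doubled$per_site$delta_cost[doubled$per_site$site == "alpha"] -
    base$per_site$delta_cost[base$per_site$site == "alpha"]
  expect_equal(got, 4000 * exposure, tolerance = 1e-9)
})
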