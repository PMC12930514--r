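test_that("weight normalisation matches hand arithmetic", {
  expect_equal(as.numeric(normalize_weights(c(A = 50, B = 50))),
               c(0.5, 0.5))
  expect_equal(as.numeric(normalize_weights(c(A = 1))), 1)
  w <- normalize_weights(c(A = 30, B = 45, C = 75))
  expect_equal(as.numeric(w), c(0.2, 0.3, 0.5))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_error(normalize_weights(c(A = 0, B = 0)), "positive")
  expect_error(normalize_weights(c(10, 20)), "named")
})

test_that("aggregation sums increments first and never averages ICERs", {
  per_site <- list(A = stub_incremental(100000, 2.0),
                   B = stub_incremental(50000, 0.5))
  agg <- aggregate_sites(per_site, normalize_weights(c(A = 1, B = 1)),
                         wtp = 1e5)
  expect_equal(agg$delta_cost_agg, 75000)
  expect_equal(agg$delta_qaly_agg, 1.25)
  expect_equal(agg$icer_agg, 60000)
  # the naive mean of site ICERs (50k, 100k) would be 75k
  expect_false(isTRUE(all.equal(agg$icer_agg,
                                mean(agg$per_site$icer))))
  expect_error(
    aggregate_sites(per_site, normalize_weights(c(A = 1, C = 1))),
    "missing")
})

test_that("aggregated ICER respects the mediant bound", {
  set.seed(99)
  for (i in 1:200) {
    k <- sample(2:5, 1)
    ids <- paste0("s", seq_len(k))
    de <- runif(k, 0.05, 2)
    dc <- rnorm(k, 5e4, 5e4)
    per_site <- setNames(lapply(seq_len(k), function(j)
      stub_incremental(dc[j], de[j])), ids)
    w <- normalize_weights(setNames(runif(k, 0.1, 10), ids))
    agg <- aggregate_sites(per_site, w)
    icers <- dc / de
    ratio <- agg$delta_cost_agg / agg$delta_qaly_agg
    expect_gte(ratio, min(icers) - 1e-9)
    expect_lte(ratio, max(icers) + 1e-9)
  }
})

test_that("degenerate weights and permutations are identities", {
  per_site <- list(A = stub_incremental(80000, 1.2),
                   B = stub_incremental(20000, 0.4))
  w1 <- normalize_weights(c(A = 10, B = 0))
  agg <- aggregate_sites(per_site, w1)
  expect_identical(agg$delta_cost_agg, 80000)
  expect_identical(agg$delta_qaly_agg, 1.2)
  expect_equal(agg$icer_agg, 80000 / 1.2)

  w <- normalize_weights(c(A = 3, B = 7))
  a1 <- aggregate_sites(per_site, w)
  a2 <- aggregate_sites(rev(per_site), w)
  expect_equal(a1$delta_cost_agg, a2$delta_cost_agg)
  expect_equal(a1$delta_qaly_agg, a2$delta_qaly_agg)
  expect_equal(a1$icer_agg, a2$icer_agg)
})

test_that("dominance classification applies to the aggregate", {
  dom <- aggregate_sites(list(A = stub_incremental(-10, 0.1)),
                         normalize_weights(c(A = 1)))
  expect_equal(dom$icer_status, "dominant")
  expect_true(is.na(dom$icer_agg))
  zero <- aggregate_sites(list(A = stub_incremental(0, 0)),
                          normalize_weights(c(A = 1)))
  expect_equal(zero$icer_status, "zero_effect")
})

test_that("no-op break-out leaves the aggregate unchanged", {
  m <- tiny_model()
  before <- run_model(m)
  s <- m$sites$alpha
  m2 <- breakout(m, "alpha", list(intervention = s$intervention,
                                  comparator = s$comparator))
  after <- m2$versions[[length(m2$versions)]]$results
  expect_lt(abs(after$delta_cost_agg - before$delta_cost_agg), 1e-9)
  expect_lt(abs(after$delta_qaly_agg - before$delta_qaly_agg), 1e-12)
  expect_equal(m2$sites$alpha$evidence_level, "site_specific")
})

test_that("break-out shifts the aggregate by the weighted site delta", {
  m <- tiny_model()
  before <- run_model(m)
  new_int <- m$sites$beta$intervention
  new_int$os <- parametric_curve("exponential", 0.04) # better OS
  m2 <- breakout(m, "beta", list(intervention = new_int,
                                 comparator = m$sites$beta$comparator))
  after <- m2$versions[[length(m2$versions)]]$results
  w <- m$weights[["beta"]]
  de_old <- before$per_site$delta_qaly[before$per_site$site == "beta"]
  de_new <- after$per_site$delta_qaly[after$per_site$site == "beta"]
  expect_gt(de_new, de_old)
  expect_equal(after$delta_qaly_agg - before$delta_qaly_agg,
               w * (de_new - de_old), tolerance = 1e-12)
  # locality: the other site's incrementals are untouched
  expect_equal(after$per_site[after$per_site$site == "alpha", -1],
               before$per_site[before$per_site$site == "alpha", -1],
               tolerance = 1e-12)
})

test_that("break-out validates its inputs", {
  m <- tiny_model()
  expect_error(breakout(m, "gamma", list()), "unknown site")
  expect_error(breakout(m, "alpha",
                        list(intervention = m$sites$alpha$intervention)),
               "missing: comparator")
  expect_error(breakout(m, "alpha", list(intervention = 1, comparator = 2)),
               "arm_inputs")
})

test_that("re-analysis triggers fire at the sample-size boundary", {
  m <- tiny_model() # evidence_n: alpha 100, beta 80
  expect_equal(check_reanalysis_triggers(m, c(alpha = 150L)), "alpha")
  expect_equal(check_reanalysis_triggers(m, c(alpha = 149L)), character(0))
  expect_equal(
    check_reanalysis_triggers(m, c(alpha = 160L, beta = 90L)), "alpha")
  expect_error(check_reanalysis_triggers(m, c(alpha = -1L)), "negative")
  expect_error(check_reanalysis_triggers(m, c(alpha = 10L),
                                         list(min_new_n = 0)), "positive")
  expect_error(check_reanalysis_triggers(m, c(nope = 10L)), "unknown site")
})

test_that("version diffs localise changes and recompute consistently", {
  m <- tiny_model()
  s <- m$sites$alpha
  m2 <- breakout(m, "alpha", list(intervention = s$intervention,
                                  comparator = s$comparator))
  v <- m2$versions
  d0 <- diff_versions(v[[1]], v[[2]])
  expect_equal(unname(d0$aggregate["d_delta_qaly"]), 0, tolerance = 1e-12)

  new_int <- s$intervention
  new_int$drug_cost_per_cycle <- 5000
  m3 <- breakout(m2, "alpha", list(intervention = new_int,
                                   comparator = s$comparator))
  v3 <- m3$versions
  d <- diff_versions(v3[[2]], v3[[3]])
  expect_equal(d$per_site$d_delta_qaly, c(0, 0), tolerance = 1e-12)
  expect_gt(d$per_site$d_delta_cost[d$per_site$site == "alpha"], 0)
  expect_equal(d$per_site$d_delta_cost[d$per_site$site == "beta"], 0)
  # aggregate delta consistent with per-site deltas and weights
  expect_equal(unname(d$aggregate["d_delta_cost"]),
               sum(as.numeric(m$weights[d$per_site$site]) *
                     d$per_site$d_delta_cost),
               tolerance = 1e-9)
  expect_true(any(grepl("sites.alpha", d$changed_fields)))
  expect_error(diff_versions(v3[[2]], v3[[2]]), "itself")
})

test_that("stored versions recompute bit-for-bit from their snapshots", {
  m <- tiny_model()
  s <- m$sites$alpha
  m2 <- breakout(m, "alpha", list(intervention = s$intervention,
                                  comparator = s$comparator))
  for (v in m2$versions) {
    snap <- v$snapshot
    snap$versions <- list()
    class(snap) <- "psm_model"
    re <- run_model(snap)
    expect_identical(re$delta_cost_agg, v$results$delta_cost_agg)
    expect_identical(re$delta_qaly_agg, v$results$delta_qaly_agg)
    expect_identical(re$per_site, v$results$per_site)
  }
})
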