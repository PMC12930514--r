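# shared fixtures, all generated in code

# right-censored draws from a parametric family with roughly the
# requested censoring fraction (exponential censoring clock)
sim_surv_ipd <- function(n, family, params, censor_frac = 0, seed = 1) {
  set.seed(seed)
  t_event <- rsurv(n, family, params)
  if (censor_frac > 0) {
    rate_c <- censor_frac / ((1 - censor_frac) * mean(t_event))
    cens <- rexp(n, rate_c)
  } else {
    cens <- rep(Inf, n)
  }
  data.frame(time = pmin(t_event, cens),
             event = as.integer(t_event <= cens))
}

# incremental-result stub for aggregation arithmetic on stated dC / dE
stub_incremental <- function(delta_cost, delta_qaly, wtp = 1e5) {
  if (delta_qaly == 0) {
    status <- "zero_effect"; icer <- NA_real_
  } else if (delta_qaly > 0 && delta_cost <= 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (delta_qaly < 0 && delta_cost >= 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "icer_defined"; icer <- delta_cost / delta_qaly
  }
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 delta_ly = delta_qaly, icer = icer, icer_status = status,
                 nmb = wtp * delta_qaly - delta_cost, wtp = wtp),
            class = "incremental_result")
}

# small fully parametric two-site model (fast, deterministic)
tiny_model <- function(horizon = 120, wtp = 1e5) {
  grid <- time_grid(1, horizon)
  arm <- function(os_rate, pfs_rate, drug) {
    arm_inputs(os = parametric_curve("exponential", os_rate),
               pfs = parametric_curve("exponential", pfs_rate),
               utility_pf = 0.8, utility_pd = 0.6,
               drug_cost_per_cycle = drug, admin_cost_per_cycle = 100,
               disease_mgmt_cost_pf = 200, disease_mgmt_cost_pd = 600,
               ae_cost_oneoff = 1000, eol_cost_oneoff = 5000)
  }
  sites <- list(
    site_submodel("alpha", arm(0.05, 0.09, 4000), arm(0.08, 0.14, 800),
                  weight_source_count = 60, evidence_n = 100L),
    site_submodel("beta", arm(0.06, 0.10, 4000), arm(0.09, 0.15, 800),
                  weight_source_count = 40, evidence_n = 80L)
  )
  psm_model(sites, grid = grid, econ = economic_params(0.03, 0.03, TRUE),
            wtp = wtp)
}

# scenario whose marginal OS/PFS are exactly exponential (equal death
# hazard before and after progression), so exponential fitting is
# correctly specified for recovery checks
exp_recovery_scenario <- function(n_per_arm) {
  base <- list(prog_rate = 0.08, death_rate_pf = 0.07,
               death_rate_pd = 0.07)
  trt <- list(prog_rate = 0.048, death_rate_pf = 0.042,
              death_rate_pd = 0.042)
  mk <- function(id, count) {
    list(site_id = id, n_per_arm = n_per_arm,
         biomarker_positive_count = count, dropout_rate = 0.005,
         admin_censor_months = 36, evidence_level = "pooled",
         arms = list(intervention = trt, comparator = base))
  }
  scenario_config("exp_recovery",
                  sites = list(mk("siteA", 60), mk("siteB", 40)),
                  economics = basketpsm:::.default_economics(),
                  grid = time_grid(1, 240))
}

# strip volatile timestamp fields before hashing CLI outputs
file_digest_no_timestamps <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- gsub('"timestamp":"[^"]*"', '"timestamp":""', txt)
  tmp <- tempfile()
  writeLines(txt, tmp)
  on.exit(unlink(tmp))
  unname(tools::md5sum(tmp))
}

dir_digests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(vapply(files, file_digest_no_timestamps, character(1)),
                  basename(files))
}
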