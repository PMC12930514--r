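#' Scenario configuration for the synthetic basket-trial generator
#'
#' Describes a multi-site basket trial plus the economic inputs of the
#' resulting model. Each subject's progression and death are coupled
#' through three latent exponential clocks — progression (`prog_rate`),
#' death before progression (`death_rate_pf`) and death after
#' progression (`death_rate_pd`), all per month — which guarantees
#' PFS <= OS for every subject (independent marginal simulation would
#' not). With `death_rate_pf == death_rate_pd` the marginal OS is
#' exactly exponential with that rate; marginal PFS is always
#' exponential with rate `prog_rate + death_rate_pf`.
#'
#' @param name Scenario label.
#' @param sites List of per-site lists with fields `site_id`,
#'   `n_per_arm`, `biomarker_positive_count`, `dropout_rate` (per-month
#'   exponential censoring hazard), `admin_censor_months`,
#'   `evidence_level`, and `arms = list(intervention =, comparator =)`
#'   where each arm is `list(prog_rate, death_rate_pf, death_rate_pd)`.
#' @param economics List with `intervention` and `comparator` blocks of
#'   [arm_inputs] scalar fields (utilities and costs).
#' @param grid A [time_grid].
#' @param econ An [economic_params].
#' @param wtp Willingness to pay per QALY.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(name, sites, economics,
                            grid = time_grid(cycle_length = 1,
                                             horizon = 240),
                            econ = economic_params(), wtp = 100000) {
  for (s in sites) {
    stopifnot(!is.null(s$site_id), s$n_per_arm >= 1,
              s$biomarker_positive_count >= 0)
    for (arm in c("intervention", "comparator")) {
      a <- s$arms[[arm]]
      if (is.null(a) || any(c(a$prog_rate, a$death_rate_pf,
                              a$death_rate_pd) <= 0)) {
        stop("site '", s$site_id, "' arm '", arm,
             "': prog_rate, death_rate_pf, death_rate_pd must be ",
             "positive", call. = FALSE)
      }
    }
  }
  structure(list(name = name, sites = sites, economics = economics,
                 grid = grid, econ = econ, wtp = wtp),
            class = "scenario_config")
}

.default_economics <- function() {
  list(
    intervention = list(utility_pf = 0.75, utility_pd = 0.55,
                        drug_cost_per_cycle = 5000,
                        admin_cost_per_cycle = 150,
                        disease_mgmt_cost_pf = 250,
                        disease_mgmt_cost_pd = 800,
                        ae_cost_oneoff = 2000, eol_cost_oneoff = 9000),
    comparator = list(utility_pf = 0.75, utility_pd = 0.55,
                      drug_cost_per_cycle = 1200,
                      admin_cost_per_cycle = 100,
                      disease_mgmt_cost_pf = 250,
                      disease_mgmt_cost_pd = 800,
                      ae_cost_oneoff = 500, eol_cost_oneoff = 9000)
  )
}

.hr_arm <- function(base, hr) {
  list(prog_rate = base$prog_rate * hr,
       death_rate_pf = base$death_rate_pf * hr,
       death_rate_pd = base$death_rate_pd * hr)
}

#' Built-in synthetic scenarios
#'
#' Three fully specified fixtures emulating the evidence structure of
#' tumour-agnostic basket trials:
#' \describe{
#'   \item{homogeneous_effect}{Three sites with identical baseline
#'     hazards and one common hazard ratio (0.6); sites differ only in
#'     size and epidemiological weight, so pooling is unbiased.}
#'   \item{heterogeneous_effect}{Three sites with site-specific
#'     baselines; one site receives no benefit (hazard ratio 1.0).}
#'   \item{small_n_site}{As homogeneous, but one site enrols only 10
#'     subjects per arm — the sparse-evidence situation in which pooled
#'     estimation is the only option.}
#' }
#'
#' @return Named list of [scenario_config] objects.
#' @export
builtin_scenarios <- function() {
  base <- list(prog_rate = 0.09, death_rate_pf = 0.02,
               death_rate_pd = 0.10)
  mk_site <- function(id, n, count, comp, hr, dropout = 0.01,
                      admin = 30, n_small = NULL) {
    list(site_id = id, n_per_arm = n, biomarker_positive_count = count,
         dropout_rate = dropout, admin_censor_months = admin,
         evidence_level = "pooled",
         arms = list(intervention = .hr_arm(comp, hr), comparator = comp))
  }
  list(
    homogeneous_effect = scenario_config(
      "homogeneous_effect",
      sites = list(
        mk_site("colorectal", 200, 75, base, 0.6),
        mk_site("lung", 200, 45, base, 0.6),
        mk_site("thyroid", 200, 30, base, 0.6)
      ),
      economics = .default_economics()
    ),
    heterogeneous_effect = scenario_config(
      "heterogeneous_effect",
      sites = list(
        mk_site("colorectal", 150, 75, base, 0.6),
        mk_site("lung", 150, 45,
                list(prog_rate = 0.12, death_rate_pf = 0.03,
                     death_rate_pd = 0.13), 0.55),
        mk_site("pancreatic", 150, 30,
                list(prog_rate = 0.15, death_rate_pf = 0.05,
                     death_rate_pd = 0.18), 1.0)
      ),
      economics = .default_economics()
    ),
    small_n_site = scenario_config(
      "small_n_site",
      sites = list(
        mk_site("colorectal", 200, 75, base, 0.6),
        mk_site("lung", 200, 45, base, 0.6),
        mk_site("cholangiocarcinoma", 10, 12, base, 0.6)
      ),
      economics = .default_economics()
    )
  )
}

#' Generate a synthetic multi-site basket trial
#'
#' Draws coupled progression/death times per subject (see
#' [scenario_config()]), applies dropout and administrative censoring
#' (censoring time shared between a subject's OS and PFS records), and
#' emits one OS and one PFS record per subject. Deterministic given
#' `seed`.
#'
#' @param config A [scenario_config].
#' @param seed Integer RNG seed.
#' @return List with `ipd` (data frame: `subject_id`, `site`, `arm`,
#'   `endpoint`, `time`, `event`), `counts` (named biomarker-positive
#'   counts) and the echoed `config`.
#' @export
generate_basket_trial <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(as.integer(seed))
  rows <- list()
  for (s in config$sites) {
    for (arm in c("intervention", "comparator")) {
      a <- s$arms[[arm]]
      n <- s$n_per_arm
      t_prog <- stats::rexp(n, a$prog_rate)
      t_death_pf <- stats::rexp(n, a$death_rate_pf)
      t_death_pd <- stats::rexp(n, a$death_rate_pd)
      pfs_t <- pmin(t_prog, t_death_pf)
      os_t <- ifelse(t_death_pf <= t_prog, t_death_pf,
                     t_prog + t_death_pd)
      cens <- if (s$dropout_rate > 0) {
        pmin(stats::rexp(n, s$dropout_rate), s$admin_censor_months)
      } else {
        rep(s$admin_censor_months, n)
      }
      sid <- sprintf("%s_%s_%04d", s$site_id, arm, seq_len(n))
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = rep(sid, 2),
        site = s$site_id, arm = arm,
        endpoint = rep(c("PFS", "OS"), each = n),
        time = c(pmin(pfs_t, cens), pmin(os_t, cens)),
        event = as.integer(c(pfs_t <= cens, os_t <= cens)),
        stringsAsFactors = FALSE
      )
    }
  }
  ipd <- do.call(rbind, rows)
  rownames(ipd) <- NULL
  counts <- stats::setNames(
    vapply(config$sites, function(s) s$biomarker_positive_count,
           numeric(1)),
    vapply(config$sites, function(s) s$site_id, character(1)))
  list(ipd = ipd, counts = counts, config = config)
}

#' True marginal survival curves implied by a scenario arm
#'
#' Closed-form marginal OS and PFS of the three-clock coupling, used
#' as the ground truth in parameter-recovery checks.
#'
#' @param arm_rates List with `prog_rate`, `death_rate_pf`,
#'   `death_rate_pd`.
#' @param grid A [time_grid].
#' @return List with tabulated `os` and `pfs` vectors on the grid.
#' @export
true_site_curves <- function(arm_rates, grid) {
  hp <- arm_rates$prog_rate
  h1 <- arm_rates$death_rate_pf
  h2 <- arm_rates$death_rate_pd
  t <- grid$times
  pfs <- exp(-(hp + h1) * t)
  a <- hp + h1 - h2
  os <- if (abs(a) > 1e-12) {
    exp(-(hp + h1) * t) + hp * exp(-h2 * t) * (1 - exp(-a * t)) / a
  } else {
    exp(-(hp + h1) * t) + hp * t * exp(-h2 * t)
  }
  list(os = pmin(pmax(os, 0), 1), pfs = pfs)
}

# economics block (possibly site-overridden) -> arm_inputs
.arm_from_economics <- function(econ_block, os, pfs) {
  do.call(arm_inputs, c(list(os = os, pfs = pfs), econ_block))
}

#' Build a multi-site model from a generated (or real) basket trial
#'
#' Survival evidence for sites flagged `pooled` is constructed by
#' stacking their patient-level records across sites and fitting one
#' curve per arm and endpoint (curves are never averaged); sites
#' flagged `site_specific` are fitted from their own records only.
#' Shared fits carry a common `fit_id` so probabilistic sensitivity
#' analysis draws them jointly.
#'
#' @param trial Output of [generate_basket_trial()] (or a compatible
#'   list with `ipd`, `counts`, `config`).
#' @param family Parametric family fitted to every arm/endpoint
#'   (default exponential), or `"auto"` to pick the lowest-AIC family
#'   per curve.
#' @param evidence_levels Optional named override of each site's
#'   evidence level (`"pooled"` or `"site_specific"`).
#' @return A [psm_model].
#' @export
build_model_from_trial <- function(trial, family = "exponential",
                                   evidence_levels = NULL) {
  config <- trial$config
  ipd <- trial$ipd
  site_ids <- vapply(config$sites, function(s) s$site_id, character(1))
  levels <- stats::setNames(
    vapply(config$sites, function(s) s$evidence_level %||% "pooled",
           character(1)), site_ids)
  if (!is.null(evidence_levels)) {
    levels[names(evidence_levels)] <- unlist(evidence_levels)
  }

  fit_one <- function(sub, id) {
    f <- if (identical(family, "auto")) {
      ranked <- select_distribution(fit_all_families(sub))
      attr(ranked, "fits")[[1]]
    } else {
      fit_parametric(sub, family)
    }
    f$fit_id <- id
    f
  }

  pooled_ids <- site_ids[levels == "pooled"]
  pooled_fits <- list()
  if (length(pooled_ids)) {
    for (arm in c("intervention", "comparator")) {
      for (ep in c("OS", "PFS")) {
        sub <- ipd[ipd$site %in% pooled_ids & ipd$arm == arm &
                     ipd$endpoint == ep, ]
        pooled_fits[[paste(arm, ep, sep = ":")]] <-
          fit_one(sub, paste("pooled", arm, ep, sep = ":"))
      }
    }
  }

  sites <- list()
  for (s in config$sites) {
    id <- s$site_id
    getfit <- function(arm, ep) {
      if (levels[[id]] == "pooled") {
        pooled_fits[[paste(arm, ep, sep = ":")]]
      } else {
        sub <- ipd[ipd$site == id & ipd$arm == arm & ipd$endpoint == ep, ]
        fit_one(sub, paste("site", id, arm, ep, sep = ":"))
      }
    }
    econ_site <- s$economics %||% config$economics
    arms <- list()
    for (arm in c("intervention", "comparator")) {
      arms[[arm]] <- .arm_from_economics(econ_site[[arm]],
                                         os = getfit(arm, "OS"),
                                         pfs = getfit(arm, "PFS"))
    }
    sites[[id]] <- site_submodel(
      id, arms$intervention, arms$comparator,
      weight_source_count = s$biomarker_positive_count,
      evidence_level = levels[[id]],
      evidence_n = 2L * s$n_per_arm
    )
  }
  psm_model(sites, grid = config$grid, econ = config$econ,
            wtp = config$wtp)
}

#' Model built from a scenario's true parameters (no sampling noise)
#'
#' @param config A [scenario_config].
#' @return A [psm_model] whose arm curves are the closed-form marginal
#'   survival functions of the scenario, tabulated on its grid.
#' @export
true_model_from_config <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  sites <- list()
  for (s in config$sites) {
    econ_site <- s$economics %||% config$economics
    arms <- list()
    for (arm in c("intervention", "comparator")) {
      cv <- true_site_curves(s$arms[[arm]], config$grid)
      arms[[arm]] <- .arm_from_economics(econ_site[[arm]],
                                         os = cv$os, pfs = cv$pfs)
    }
    sites[[s$site_id]] <- site_submodel(
      s$site_id, arms$intervention, arms$comparator,
      weight_source_count = s$biomarker_positive_count,
      evidence_level = "site_specific",
      evidence_n = 0L
    )
  }
  psm_model(sites, grid = config$grid, econ = config$econ,
            wtp = config$wtp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
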