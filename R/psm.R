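#' Model time grid
#'
#' @param cycle_length Cycle length in months (default 1).
#' @param horizon Time horizon in months (default 480, i.e. lifetime for
#'   a typical late-stage oncology cohort).
#' @return A `time_grid`: list with `cycle_length`, `horizon`,
#'   `n_cycles` and the vector `times` of cycle boundaries
#'   (length `n_cycles + 1`, starting at 0).
#' @export
time_grid <- function(cycle_length = 1, horizon = 480) {
  stopifnot(cycle_length > 0, horizon > 0)
  n <- as.integer(ceiling(horizon / cycle_length))
  structure(list(cycle_length = cycle_length, horizon = horizon,
                 n_cycles = n,
                 times = seq(0, n * cycle_length, by = cycle_length)),
            class = "time_grid")
}

# Resolve a curve argument to a tabulated survival vector on the grid.
.tabulate_curve <- function(curve, grid) {
  n <- grid$n_cycles
  if (is.numeric(curve)) {
    if (length(curve) != n + 1) {
      stop("tabulated curve has length ", length(curve),
           " but the grid has ", n + 1, " points (mismatched grids?)",
           call. = FALSE)
    }
    s <- as.numeric(curve)
  } else if (is.list(curve) && !is.null(curve$family)) {
    s <- survival_at(curve, grid$times)
  } else {
    stop("curve must be a numeric vector on the grid or a parametric ",
         "curve specification", call. = FALSE)
  }
  if (any(s < -1e-9 | s > 1 + 1e-9)) {
    stop("survival values must lie in [0, 1]", call. = FALSE)
  }
  if (abs(s[1] - 1) > 1e-9) stop("survival at t = 0 must be 1", call. = FALSE)
  pmin(pmax(s, 0), 1)
}

#' State occupancy of the three-state partitioned survival model
#'
#' Occupancy is read directly off the two survivor curves:
#' progression-free `pf(t) = min(PFS(t), OS(t))`, progressed
#' `pd(t) = OS(t) - pf(t)`, dead `1 - OS(t)`. Because OS and PFS are
#' extrapolated independently the curves can cross; crossings are
#' repaired by the `min()` clip and counted in the `crossings`
#' attribute so they surface rather than pass silently.
#'
#' @param os_curve,pfs_curve Survival curves on `grid` (numeric vectors
#'   of length `n_cycles + 1` or parametric curve specifications).
#' @param grid A [time_grid].
#' @return A `state_occupancy` data frame with columns `time`, `pf`,
#'   `pd`, `dead` and attribute `crossings` (number of grid points where
#'   PFS exceeded OS).
#' @export
compute_occupancy <- function(os_curve, pfs_curve, grid) {
  stopifnot(inherits(grid, "time_grid"))
  os <- .tabulate_curve(os_curve, grid)
  pfs <- .tabulate_curve(pfs_curve, grid)
  crossings <- sum(pfs > os + 1e-12)
  if (crossings > 0) {
    warning(crossings, " grid point(s) with PFS > OS clipped to OS",
            call. = FALSE)
  }
  pf <- pmin(pfs, os)
  occ <- data.frame(time = grid$times, pf = pf, pd = os - pf,
                    dead = 1 - os)
  attr(occ, "crossings") <- crossings
  class(occ) <- c("state_occupancy", "data.frame")
  occ
}

#' Discounted sum of per-cycle values
#'
#' Discrete discounting at an annual rate with monthly exponent:
#' each cycle's value is multiplied by `(1 + rate)^(-t/12)` where `t`
#' is the cycle start (months) or the cycle midpoint when the
#' half-cycle correction is on.
#'
#' @param values Numeric vector, one value per cycle (length
#'   `grid$n_cycles`).
#' @param annual_rate Annual discount rate (proportion, `>= 0`).
#' @param grid A [time_grid].
#' @param half_cycle_correction Discount at cycle midpoints?
#' @return The discounted sum (scalar).
#' @export
discounted_sum <- function(values, annual_rate, grid,
                           half_cycle_correction = TRUE) {
  stopifnot(inherits(grid, "time_grid"), annual_rate >= 0,
            all(is.finite(values)))
  n <- grid$n_cycles
  if (length(values) != n) {
    stop("values must have one entry per cycle (", n, ")", call. = FALSE)
  }
  t_k <- grid$times[seq_len(n)]
  if (half_cycle_correction) t_k <- t_k + grid$cycle_length / 2
  sum(values * (1 + annual_rate)^(-t_k / 12))
}

#' Economic settings
#'
#' @param discount_rate_costs,discount_rate_effects Annual discount
#'   rates (proportions).
#' @param half_cycle_correction Apply half-cycle correction to
#'   discounting?
#' @return An `economic_params` list.
#' @export
economic_params <- function(discount_rate_costs = 0.03,
                            discount_rate_effects = 0.03,
                            half_cycle_correction = TRUE) {
  stopifnot(discount_rate_costs >= 0, discount_rate_effects >= 0)
  structure(list(discount_rate_costs = discount_rate_costs,
                 discount_rate_effects = discount_rate_effects,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "economic_params")
}

# Scalar arm-input fields that sensitivity analyses may target.
.arm_scalar_fields <- c("utility_pf", "utility_pd", "drug_cost_per_cycle",
                        "admin_cost_per_cycle", "disease_mgmt_cost_pf",
                        "disease_mgmt_cost_pd", "ae_cost_oneoff",
                        "eol_cost_oneoff")

#' Arm inputs for one treatment arm of one tumour site
#'
#' @param os,pfs Survival curves: parametric specifications
#'   (`list(family =, params =)`, a [parametric_curve] or
#'   [fitted_survival]) or numeric vectors tabulated on the model grid.
#' @param utility_pf,utility_pd Health-state utilities in `[0, 1]`.
#' @param drug_cost_per_cycle,admin_cost_per_cycle Treatment costs per
#'   cycle, accrued while progression-free and on treatment.
#' @param disease_mgmt_cost_pf,disease_mgmt_cost_pd Disease-management
#'   costs per cycle in each alive state.
#' @param ae_cost_oneoff One-off adverse-event management cost at model
#'   start.
#' @param eol_cost_oneoff One-off end-of-life cost applied to incident
#'   deaths.
#' @param max_treatment_cycles Stop drug/administration cost accrual
#'   after this many cycles; `NULL` (default) means treatment continues
#'   until progression.
#' @return An `arm_inputs` list.
#' @export
arm_inputs <- function(os, pfs, utility_pf = 0.75, utility_pd = 0.55,
                       drug_cost_per_cycle = 0, admin_cost_per_cycle = 0,
                       disease_mgmt_cost_pf = 0, disease_mgmt_cost_pd = 0,
                       ae_cost_oneoff = 0, eol_cost_oneoff = 0,
                       max_treatment_cycles = NULL) {
  x <- list(os = os, pfs = pfs, utility_pf = utility_pf,
            utility_pd = utility_pd,
            drug_cost_per_cycle = drug_cost_per_cycle,
            admin_cost_per_cycle = admin_cost_per_cycle,
            disease_mgmt_cost_pf = disease_mgmt_cost_pf,
            disease_mgmt_cost_pd = disease_mgmt_cost_pd,
            ae_cost_oneoff = ae_cost_oneoff,
            eol_cost_oneoff = eol_cost_oneoff,
            max_treatment_cycles = max_treatment_cycles)
  for (u in c("utility_pf", "utility_pd")) {
    if (x[[u]] < 0 || x[[u]] > 1) stop(u, " must lie in [0, 1]",
                                       call. = FALSE)
  }
  costs <- setdiff(.arm_scalar_fields, c("utility_pf", "utility_pd"))
  for (cc in costs) {
    if (x[[cc]] < 0) stop(cc, " must be non-negative", call. = FALSE)
  }
  structure(x, class = "arm_inputs")
}

#' Evaluate one arm of the partitioned survival model
#'
#' Accumulates discounted costs, life-years and QALYs over the model
#' horizon. Per-cycle state membership is the trapezoid average of the
#' occupancy at the cycle boundaries, so area-under-curve quantities
#' converge at second order in the cycle length. End-of-life costs
#' attach to incident deaths within the horizon only. If `background`
#' is supplied the OS curve is first floored at general-population
#' mortality (hazard-max) and PFS is capped at the adjusted OS.
#'
#' @param inputs An [arm_inputs] object.
#' @param grid A [time_grid].
#' @param econ An [economic_params] object.
#' @param background Optional list `(life_table, start_age, sex_mix)`
#'   for background-mortality adjustment of OS.
#' @return An `arm_result`: list with `total_cost`, `life_years`,
#'   `qalys` (life-years and QALYs in years), a `cost_breakdown` data
#'   frame, `time_in_state` (undiscounted years in each alive state)
#'   and the `crossings` count from occupancy.
#' @export
evaluate_arm <- function(inputs, grid, econ, background = NULL) {
  stopifnot(inherits(inputs, "arm_inputs"), inherits(grid, "time_grid"),
            inherits(econ, "economic_params"))
  os <- .tabulate_curve(inputs$os, grid)
  pfs <- .tabulate_curve(inputs$pfs, grid)
  if (!is.null(background)) {
    os <- apply_background_mortality(os, background$life_table,
                                     background$start_age,
                                     background$sex_mix, grid)
    pfs <- pmin(pfs, os)
  }
  occ <- suppressWarnings(compute_occupancy(os, pfs, grid))
  n <- grid$n_cycles
  cyc_months <- grid$cycle_length
  pf_bar <- (occ$pf[-(n + 1)] + occ$pf[-1]) / 2
  pd_bar <- (occ$pd[-(n + 1)] + occ$pd[-1]) / 2
  d_dead <- diff(occ$dead)

  hcc <- econ$half_cycle_correction
  r_c <- econ$discount_rate_costs
  r_e <- econ$discount_rate_effects

  on_treat <- rep(1, n)
  if (!is.null(inputs$max_treatment_cycles)) {
    on_treat[seq_len(n) > inputs$max_treatment_cycles] <- 0
  }

  drug <- discounted_sum(inputs$drug_cost_per_cycle * pf_bar * on_treat,
                         r_c, grid, hcc)
  admin <- discounted_sum(inputs$admin_cost_per_cycle * pf_bar * on_treat,
                          r_c, grid, hcc)
  mgmt <- discounted_sum(inputs$disease_mgmt_cost_pf * pf_bar +
                           inputs$disease_mgmt_cost_pd * pd_bar,
                         r_c, grid, hcc)
  ae <- inputs$ae_cost_oneoff # incurred at t = 0, no discounting
  eol <- discounted_sum(inputs$eol_cost_oneoff * d_dead, r_c, grid, hcc)

  ly <- discounted_sum((pf_bar + pd_bar) * cyc_months / 12, r_e, grid, hcc)
  qaly <- discounted_sum((inputs$utility_pf * pf_bar +
                            inputs$utility_pd * pd_bar) * cyc_months / 12,
                         r_e, grid, hcc)

  breakdown <- data.frame(
    category = c("drug", "administration", "disease_management",
                 "adverse_events", "end_of_life"),
    cost = c(drug, admin, mgmt, ae, eol)
  )
  structure(list(
    total_cost = sum(breakdown$cost),
    life_years = ly,
    qalys = qaly,
    cost_breakdown = breakdown,
    time_in_state = c(pf = sum(pf_bar) * cyc_months / 12,
                      pd = sum(pd_bar) * cyc_months / 12),
    crossings = attr(occ, "crossings")
  ), class = "arm_result")
}

#' Incremental cost-effectiveness of intervention versus comparator
#'
#' The ICER is only reported when it is defined: an intervention that
#' gains health at no extra cost is `dominant`, one that loses health
#' at no saving is `dominated`, and a zero health difference leaves the
#' ratio undefined (`zero_effect`). Net monetary benefit
#' `NMB = wtp * dE - dC` is always reported.
#'
#' @param intervention,comparator `arm_result` objects evaluated on the
#'   same grid and economic settings.
#' @param wtp Willingness to pay per QALY.
#' @return An `incremental_result`: list with `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer` (`NA` unless defined),
#'   `icer_status` in `{dominant, dominated, icer_defined, zero_effect}`
#'   and `nmb`.
#' @export
incremental <- function(intervention, comparator, wtp = 100000) {
  stopifnot(inherits(intervention, "arm_result"),
            inherits(comparator, "arm_result"))
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$qalys - comparator$qalys
  dly <- intervention$life_years - comparator$life_years
  if (de == 0) {
    status <- "zero_effect"; icer <- NA_real_
  } else if (de > 0 && dc <= 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (de < 0 && dc >= 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "icer_defined"; icer <- dc / de
  }
  structure(list(delta_cost = dc, delta_qaly = de, delta_ly = dly,
                 icer = icer, icer_status = status,
                 nmb = wtp * de - dc, wtp = wtp),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental result: dC = %.2f, dQALY = %.4f\n",
              x$delta_cost, x$delta_qaly))
  if (x$icer_status == "icer_defined") {
    cat(sprintf("  ICER = %.0f per QALY", x$icer))
  } else {
    cat("  ", x$icer_status, sep = "")
  }
  cat(sprintf("  (NMB at wtp %.0f: %.0f)\n", x$wtp, x$nmb))
  invisible(x)
}
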