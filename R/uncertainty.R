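#' Specification of one uncertain parameter
#'
#' @param name Unique parameter label.
#' @param target Path into the model: `"<arm>.<field>"` with arm one of
#'   `intervention`, `comparator`, `both` and field one of the scalar
#'   arm-input fields (utilities and per-cycle / one-off costs).
#' @param distribution One of `normal`, `lognormal`, `beta`, `gamma`,
#'   `fixed`. Utilities must use `beta` (or `fixed`) so draws stay in
#'   `[0, 1]`; costs use `gamma`, `lognormal` or `normal` (negative
#'   normal draws are truncated at 0 and counted).
#' @param args Named hyperparameters: `mean`/`sd` (normal),
#'   `meanlog`/`sdlog` (lognormal), `shape1`/`shape2` (beta),
#'   `shape`/`rate` (gamma), `value` (fixed).
#' @param scope `"shared"` (one draw per iteration written to every
#'   site — common assumptions vary jointly) or `"site_specific"`
#'   (independent draw for the named site).
#' @param site_id Required iff `scope = "site_specific"`.
#' @param dsa_low,dsa_high Bounds for deterministic one-way analysis.
#' @return A `parameter_spec` list.
#' @export
parameter_spec <- function(name, target,
                           distribution = c("normal", "lognormal", "beta",
                                            "gamma", "fixed"),
                           args = list(),
                           scope = c("shared", "site_specific"),
                           site_id = NULL, dsa_low = NA_real_,
                           dsa_high = NA_real_) {
  distribution <- match.arg(distribution)
  scope <- match.arg(scope)
  parts <- strsplit(target, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 ||
      !parts[1] %in% c("intervention", "comparator", "both") ||
      !parts[2] %in% .arm_scalar_fields) {
    stop("unresolvable target '", target, "'; expected <arm>.<field> ",
         "with arm in {intervention, comparator, both} and field in {",
         paste(.arm_scalar_fields, collapse = ", "), "}", call. = FALSE)
  }
  if (scope == "site_specific" && is.null(site_id)) {
    stop("site_id is required when scope = 'site_specific'", call. = FALSE)
  }
  is_utility <- startsWith(parts[2], "utility")
  if (is_utility && !distribution %in% c("beta", "fixed")) {
    stop("utility parameter '", name, "' must use a beta (or fixed) ",
         "distribution to stay in [0, 1]", call. = FALSE)
  }
  if (!is_utility && distribution == "beta") {
    stop("cost parameter '", name, "' cannot use a beta distribution",
         call. = FALSE)
  }
  need <- switch(distribution,
                 normal = c("mean", "sd"), lognormal = c("meanlog", "sdlog"),
                 beta = c("shape1", "shape2"), gamma = c("shape", "rate"),
                 fixed = "value")
  if (!all(need %in% names(args))) {
    stop("distribution '", distribution, "' needs hyperparameters: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  pos <- setdiff(need, c("mean", "meanlog", "value"))
  if (any(unlist(args[pos]) <= 0)) {
    stop("invalid hyperparameters for '", name, "': ",
         paste(pos, collapse = ", "), " must be positive", call. = FALSE)
  }
  if (!is.na(dsa_low) && !is.na(dsa_high) && dsa_low > dsa_high) {
    stop("dsa_low must not exceed dsa_high", call. = FALSE)
  }
  structure(list(name = name, arm = parts[1], field = parts[2],
                 target = target, distribution = distribution, args = args,
                 scope = scope, site_id = site_id,
                 dsa_low = dsa_low, dsa_high = dsa_high),
            class = "parameter_spec")
}

.draw_param <- function(spec) {
  a <- spec$args
  x <- switch(spec$distribution,
    normal = stats::rnorm(1, a$mean, a$sd),
    lognormal = stats::rlnorm(1, a$meanlog, a$sdlog),
    beta = stats::rbeta(1, a$shape1, a$shape2),
    gamma = stats::rgamma(1, shape = a$shape, rate = a$rate),
    fixed = a$value)
  if (!startsWith(spec$field, "utility") && x < 0) x <- 0
  x
}

.dsa_base_value <- function(spec) {
  a <- spec$args
  switch(spec$distribution,
    normal = a$mean,
    lognormal = exp(a$meanlog + a$sdlog^2 / 2),
    beta = a$shape1 / (a$shape1 + a$shape2),
    gamma = a$shape / a$rate,
    fixed = a$value)
}

# write one sampled value into the model
.apply_param <- function(model, spec, value, site_id = NULL) {
  sites <- if (is.null(site_id)) names(model$sites) else site_id
  arms <- if (spec$arm == "both") c("intervention", "comparator") else spec$arm
  for (id in sites) {
    for (arm in arms) {
      model$sites[[id]][[arm]][[spec$field]] <- value
    }
  }
  model
}

.check_specs <- function(model, specs) {
  if (inherits(specs, "parameter_spec")) specs <- list(specs)
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate parameter names", call. = FALSE)
  for (s in specs) {
    if (!inherits(s, "parameter_spec")) {
      stop("specs must be parameter_spec objects", call. = FALSE)
    }
    if (s$scope == "site_specific" && !s$site_id %in% names(model$sites)) {
      stop("parameter '", s$name, "' targets unknown site '", s$site_id,
           "'", call. = FALSE)
    }
  }
  specs
}

# natural-scale parameters from the transformed estimation scale
# (positive-constrained components are log-transformed during fitting)
.natural_from_transformed <- function(family, pt) {
  positive <- switch(family,
    exponential = 1L, weibull = c(1L, 2L), gompertz = 2L,
    log_normal = 2L, log_logistic = c(1L, 2L), generalized_gamma = 2L)
  p <- pt
  p[positive] <- exp(pt[positive])
  p
}

# collect the distinct fitted survival curves of a model, keyed by
# fit_id when present so pooled sites share one draw
.collect_fits <- function(model) {
  out <- list()
  counter <- 0
  for (id in names(model$sites)) {
    for (arm in c("intervention", "comparator")) {
      for (ep in c("os", "pfs")) {
        cv <- model$sites[[id]][[arm]][[ep]]
        if (inherits(cv, "fitted_survival") && !is.null(cv$vcov_t)) {
          key <- cv$fit_id
          if (is.null(key)) {
            counter <- counter + 1
            key <- paste("anon", id, arm, ep, sep = ":")
          }
          if (is.null(out[[key]])) {
            out[[key]] <- list(fit = cv, slots = list())
          }
          out[[key]]$slots <- c(out[[key]]$slots,
                                list(c(id, arm, ep)))
        }
      }
    }
  }
  out
}

#' Probabilistic sensitivity analysis over the multi-site model
#'
#' Per iteration every `shared` parameter is drawn once and written to
#' all sites (common assumptions vary jointly across tumour sites),
#' each `site_specific` parameter is drawn independently, survival
#' parameters are optionally drawn from the multivariate-normal
#' sampling distribution of their fits (one draw per distinct fit, so
#' pooled sites move together), and the full model — all sites plus
#' weighted aggregation — is re-evaluated.
#'
#' @param model A [psm_model].
#' @param specs List of [parameter_spec] objects.
#' @param n_iterations Number of Monte-Carlo iterations.
#' @param seed RNG seed; results are reproducible given the seed.
#' @param survival_uncertainty Also sample fitted survival parameters?
#'   (Requires arm curves to be `fitted_survival` objects.)
#' @return A `psa_result`: `samples` data frame (`iteration`, `site` —
#'   including `"aggregate"` —, `delta_cost`, `delta_qaly`),
#'   `param_draws` (`iteration`, `parameter`, `site`, `value`),
#'   `convergence` (running mean of aggregate NMB), `mean_*` PSA means,
#'   `n_rejected` (non-finite survival redraws), `seed`, `wtp`.
#' @export
run_psa <- function(model, specs, n_iterations, seed = 1L,
                    survival_uncertainty = FALSE) {
  stopifnot(inherits(model, "psm_model"), n_iterations >= 1)
  specs <- .check_specs(model, specs)
  fits <- if (survival_uncertainty) .collect_fits(model) else list()
  set.seed(seed)
  site_ids <- names(model$sites)
  samples <- vector("list", n_iterations)
  draws <- vector("list", n_iterations)
  n_rejected <- 0L
  for (it in seq_len(n_iterations)) {
    m <- model
    drec <- list()
    for (s in specs) {
      if (s$scope == "shared") {
        v <- .draw_param(s)
        m <- .apply_param(m, s, v)
        drec[[length(drec) + 1]] <-
          data.frame(parameter = s$name, site = site_ids, value = v)
      } else {
        v <- .draw_param(s)
        m <- .apply_param(m, s, v, site_id = s$site_id)
        drec[[length(drec) + 1]] <-
          data.frame(parameter = s$name, site = s$site_id, value = v)
      }
    }
    for (key in names(fits)) {
      f <- fits[[key]]$fit
      for (try in 1:25) {
        pt <- MASS::mvrnorm(1, f$params_t, f$vcov_t)
        p <- .natural_from_transformed(f$family, pt)
        ok <- !inherits(tryCatch(.check_params(f$family, p),
                                 error = function(e) e), "error")
        if (ok) break
        n_rejected <- n_rejected + 1L
      }
      if (!ok) {
        stop("could not draw valid survival parameters for fit '", key,
             "'", call. = FALSE)
      }
      newcv <- f
      newcv$params <- p
      for (slot in fits[[key]]$slots) {
        m$sites[[slot[1]]][[slot[2]]][[slot[3]]] <- newcv
      }
    }
    res <- run_model(m)
    samples[[it]] <- rbind(
      data.frame(iteration = it, site = res$per_site$site,
                 delta_cost = res$per_site$delta_cost,
                 delta_qaly = res$per_site$delta_qaly),
      data.frame(iteration = it, site = "aggregate",
                 delta_cost = res$delta_cost_agg,
                 delta_qaly = res$delta_qaly_agg)
    )
    if (length(drec)) {
      dd <- do.call(rbind, drec)
      dd$iteration <- it
      draws[[it]] <- dd
    }
  }
  samples <- do.call(rbind, samples)
  if (any(!is.finite(samples$delta_cost)) ||
      any(!is.finite(samples$delta_qaly))) {
    stop("PSA produced non-finite samples", call. = FALSE)
  }
  agg <- samples[samples$site == "aggregate", ]
  nmb <- model$wtp * agg$delta_qaly - agg$delta_cost
  structure(list(
    n_iterations = n_iterations, seed = seed, wtp = model$wtp,
    samples = samples,
    param_draws = if (length(specs)) do.call(rbind, draws) else NULL,
    convergence = data.frame(iteration = seq_len(n_iterations),
                             running_mean_nmb = cumsum(nmb) /
                               seq_len(n_iterations)),
    mean_delta_cost = mean(agg$delta_cost),
    mean_delta_qaly = mean(agg$delta_qaly),
    n_rejected = n_rejected
  ), class = "psa_result")
}

#' Build a PSA result from externally supplied incremental samples
#'
#' Useful for analytic checks and for importing samples produced
#' elsewhere; the samples are treated as aggregate-level draws.
#'
#' @param delta_cost,delta_qaly Equal-length numeric vectors of
#'   per-iteration incremental cost and QALY.
#' @param wtp Willingness to pay used for convergence diagnostics.
#' @return A `psa_result`.
#' @export
psa_from_samples <- function(delta_cost, delta_qaly, wtp = 100000) {
  stopifnot(length(delta_cost) == length(delta_qaly),
            all(is.finite(delta_cost)), all(is.finite(delta_qaly)))
  n <- length(delta_cost)
  nmb <- wtp * delta_qaly - delta_cost
  structure(list(
    n_iterations = n, seed = NA_integer_, wtp = wtp,
    samples = data.frame(iteration = seq_len(n), site = "aggregate",
                         delta_cost = delta_cost, delta_qaly = delta_qaly),
    param_draws = NULL,
    convergence = data.frame(iteration = seq_len(n),
                             running_mean_nmb = cumsum(nmb) / seq_len(n)),
    mean_delta_cost = mean(delta_cost),
    mean_delta_qaly = mean(delta_qaly),
    n_rejected = 0L
  ), class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value the probability of
#' cost-effectiveness is the fraction of PSA iterations with strictly
#' positive net monetary benefit (ties count as not cost-effective),
#' reported for the aggregate and for every site present in the
#' samples.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Non-empty vector of willingness-to-pay values.
#' @return A `ceac_curve` data frame: `wtp`, `probability`, `level`.
#' @export
ceac <- function(psa, wtp_grid) {
  stopifnot(inherits(psa, "psa_result"))
  if (length(wtp_grid) == 0) stop("wtp grid is empty", call. = FALSE)
  out <- list()
  for (lvl in unique(psa$samples$site)) {
    sub <- psa$samples[psa$samples$site == lvl, ]
    p <- vapply(wtp_grid, function(l) {
      mean(l * sub$delta_qaly - sub$delta_cost > 0)
    }, numeric(1))
    out[[lvl]] <- data.frame(wtp = wtp_grid, probability = p, level = lvl,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ceac_curve", "data.frame")
  res
}

#' Deterministic one-way sensitivity analysis (tornado)
#'
#' Each parameter is set in turn to its low and high bound (shared
#' parameters are applied to all sites simultaneously; site-specific
#' ones to their site only), the aggregate model is re-evaluated, and
#' the parameter is restored. Entries are sorted by descending range of
#' aggregate net monetary benefit.
#'
#' @param model A [psm_model].
#' @param specs List of [parameter_spec] objects; each must carry
#'   `dsa_low` and `dsa_high`.
#' @param wtp Willingness to pay per QALY.
#' @return A `tornado` data frame: `parameter`, `scope`, `site`, `low`,
#'   `high`, `nmb_low`, `nmb_high`, `icer_low`, `icer_high`,
#'   `nmb_range`; attribute `base` holds the base-case aggregate.
#' @export
dsa <- function(model, specs, wtp = model$wtp) {
  stopifnot(inherits(model, "psm_model"))
  specs <- .check_specs(model, specs)
  for (s in specs) {
    if (is.na(s$dsa_low) || is.na(s$dsa_high)) {
      stop("parameter '", s$name, "' lacks DSA bounds", call. = FALSE)
    }
  }
  model$wtp <- wtp
  base <- run_model(model)
  rows <- lapply(specs, function(s) {
    site <- if (s$scope == "shared") NULL else s$site_id
    lo <- run_model(.apply_param(model, s, s$dsa_low, site))
    hi <- run_model(.apply_param(model, s, s$dsa_high, site))
    data.frame(parameter = s$name, scope = s$scope,
               site = ifelse(is.null(site), "all", site),
               low = s$dsa_low, high = s$dsa_high,
               nmb_low = lo$nmb_agg, nmb_high = hi$nmb_agg,
               icer_low = lo$icer_agg, icer_high = hi$icer_agg,
               nmb_range = abs(hi$nmb_agg - lo$nmb_agg),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$nmb_range), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "base") <- base
  class(tab) <- c("tornado", "data.frame")
  tab
}
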