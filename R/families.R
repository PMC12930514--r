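#' Supported parametric survival families
#'
#' The six distributions routinely used for survival extrapolation in
#' health technology assessment. Parameters are on the natural scale and
#' follow the `flexsurv` conventions for each distribution.
#'
#' @return A data frame with columns `name`, `n_params` and a
#'   comma-separated `param_names` column.
#' @export
#' @examples
#' survival_families()
survival_families <- function() {
  data.frame(
    name = c("exponential", "weibull", "gompertz", "log_normal",
             "log_logistic", "generalized_gamma"),
    n_params = c(1L, 2L, 2L, 2L, 2L, 3L),
    param_names = c("rate", "shape,scale", "shape,rate", "meanlog,sdlog",
                    "shape,scale", "mu,sigma,Q"),
    stringsAsFactors = FALSE
  )
}

# flexsurv / stats distribution name for each family
.family_dist <- c(
  exponential = "exp", weibull = "weibull", gompertz = "gompertz",
  log_normal = "lnorm", log_logistic = "llogis",
  generalized_gamma = "gengamma"
)

.family_info <- function(family) {
  fams <- survival_families()
  i <- match(family, fams$name)
  if (is.na(i)) {
    stop("unknown parametric family '", family, "'; supported: ",
         paste(fams$name, collapse = ", "), call. = FALSE)
  }
  list(name = fams$name[i], n_params = fams$n_params[i],
       param_names = strsplit(fams$param_names[i], ",")[[1]],
       dist = .family_dist[[family]])
}

# Parameter-domain checks; positivity constraints differ by family.
# gompertz shape and gengamma mu/Q are unrestricted.
.check_params <- function(family, params) {
  info <- .family_info(family)
  params <- as.numeric(params)
  if (length(params) != info$n_params || any(!is.finite(params))) {
    stop("family '", family, "' needs ", info$n_params,
         " finite parameter(s) (", paste(info$param_names, collapse = ", "),
         "); got ", length(params), call. = FALSE)
  }
  positive <- switch(family,
    exponential = 1L, weibull = c(1L, 2L), gompertz = 2L,
    log_normal = 2L, log_logistic = c(1L, 2L), generalized_gamma = 2L)
  if (any(params[positive] <= 0)) {
    bad <- info$param_names[positive][params[positive] <= 0]
    stop("parameter-domain error for family '", family, "': ",
         paste(bad, collapse = ", "), " must be > 0", call. = FALSE)
  }
  params
}

#' Evaluate a parametric survivor function
#'
#' @param fit A [fitted_survival] object, or a list with elements
#'   `family` and `params` (natural scale).
#' @param t Vector of non-negative times (months).
#' @return `S(t)`, a vector of probabilities in `[0, 1]` with `S(0) = 1`.
#' @export
#' @examples
#' survival_at(list(family = "exponential", params = 0.5), c(0, 2))
survival_at <- function(fit, t) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  family <- fit$family
  params <- .check_params(family, fit$params)
  s <- switch(family,
    exponential = stats::pexp(t, rate = params[1], lower.tail = FALSE),
    weibull = stats::pweibull(t, shape = params[1], scale = params[2],
                              lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = params[1], rate = params[2],
                                   lower.tail = FALSE),
    log_normal = stats::plnorm(t, meanlog = params[1], sdlog = params[2],
                               lower.tail = FALSE),
    log_logistic = flexsurv::pllogis(t, shape = params[1], scale = params[2],
                                     lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = params[1],
                                            sigma = params[2], Q = params[3],
                                            lower.tail = FALSE)
  )
  pmin(pmax(s, 0), 1)
}

#' Evaluate a parametric hazard function
#'
#' @inheritParams survival_at
#' @return `h(t)`, a vector of non-negative hazard rates (per month).
#' @export
hazard_at <- function(fit, t) {
  stopifnot(is.numeric(t))
  family <- fit$family
  params <- .check_params(family, fit$params)
  h <- switch(family,
    exponential = rep(params[1], length(t)),
    weibull = flexsurv::hweibull(t, shape = params[1], scale = params[2]),
    gompertz = flexsurv::hgompertz(t, shape = params[1], rate = params[2]),
    log_normal = flexsurv::hlnorm(t, meanlog = params[1], sdlog = params[2]),
    log_logistic = flexsurv::hllogis(t, shape = params[1], scale = params[2]),
    generalized_gamma = flexsurv::hgengamma(t, mu = params[1],
                                            sigma = params[2], Q = params[3])
  )
  pmax(h, 0)
}

#' Draw event times from a parametric family
#'
#' @param n Number of draws.
#' @param family Family name (see [survival_families()]).
#' @param params Natural-scale parameter vector.
#' @return Vector of `n` non-negative times.
#' @export
rsurv <- function(n, family, params) {
  params <- .check_params(family, params)
  switch(family,
    exponential = stats::rexp(n, rate = params[1]),
    weibull = stats::rweibull(n, shape = params[1], scale = params[2]),
    gompertz = flexsurv::rgompertz(n, shape = params[1], rate = params[2]),
    log_normal = stats::rlnorm(n, meanlog = params[1], sdlog = params[2]),
    log_logistic = flexsurv::rllogis(n, shape = params[1], scale = params[2]),
    generalized_gamma = flexsurv::rgengamma(n, mu = params[1],
                                            sigma = params[2], Q = params[3])
  )
}

#' Construct a parametric curve specification
#'
#' A lightweight survival-curve handle (family plus natural-scale
#' parameters) usable wherever a fitted curve is expected, e.g. when a
#' model spec supplies extrapolation parameters directly rather than
#' patient-level data.
#'
#' @inheritParams rsurv
#' @return An object of class `parametric_curve`.
#' @export
parametric_curve <- function(family, params) {
  params <- .check_params(family, params)
  structure(list(family = family, params = params),
            class = "parametric_curve")
}
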