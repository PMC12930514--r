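#' Digitised Kaplan-Meier step coordinates
#'
#' Validates (and lightly repairs) the coordinates of a published KM
#' step function. A point at `(0, 1)` is prepended when missing, and
#' digitisation wobble that makes the curve locally increasing is
#' clipped to monotone non-increasing with a warning.
#'
#' @param time Step times (months, strictly increasing).
#' @param survival Survival probabilities at those times.
#' @return A `km_coordinates` data frame with columns `time`, `survival`.
#' @export
km_coordinates <- function(time, survival) {
  stopifnot(length(time) == length(survival), length(time) >= 1)
  o <- order(time)
  time <- as.numeric(time[o]); survival <- as.numeric(survival[o])
  if (any(duplicated(time))) stop("KM times must be strictly increasing",
                                  call. = FALSE)
  if (any(survival < -1e-9 | survival > 1 + 1e-9)) {
    stop("KM survival values must lie in [0, 1]", call. = FALSE)
  }
  if (time[1] > 0) { time <- c(0, time); survival <- c(1, survival) }
  if (time[1] == 0 && abs(survival[1] - 1) > 1e-9) {
    stop("KM curve must start at (0, 1)", call. = FALSE)
  }
  survival[1] <- 1
  mono <- cummin(survival)
  if (any(mono < survival - 1e-12)) {
    warning("non-monotone digitised survival values clipped to ",
            "non-increasing", call. = FALSE)
  }
  out <- data.frame(time = time, survival = pmin(pmax(mono, 0), 1))
  class(out) <- c("km_coordinates", "data.frame")
  out
}

#' Numbers-at-risk table
#'
#' @param time Times (months, increasing) at which numbers at risk are
#'   reported; the first entry should be 0 with the arm's sample size.
#' @param n_at_risk Non-negative, non-increasing integer counts.
#' @return A `risk_table` data frame.
#' @export
risk_table <- function(time, n_at_risk) {
  stopifnot(length(time) == length(n_at_risk))
  o <- order(time)
  time <- as.numeric(time[o]); n_at_risk <- as.integer(n_at_risk[o])
  if (any(duplicated(time))) stop("risk-table times must be increasing",
                                  call. = FALSE)
  if (any(n_at_risk < 0)) stop("n_at_risk must be non-negative",
                               call. = FALSE)
  if (any(diff(n_at_risk) > 0)) {
    stop("n_at_risk cannot increase over time", call. = FALSE)
  }
  out <- data.frame(time = time, n_at_risk = n_at_risk)
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Kaplan-Meier estimate from individual patient data
#'
#' Product-limit estimator (via [survival::survfit]); used as the
#' round-trip oracle for [reconstruct_ipd()].
#'
#' @param ipd Data frame with columns `time`, `event`.
#' @return A [km_coordinates] object stepping only at event times, with
#'   attributes `n` (subjects) and `n_events`.
#' @export
kaplan_meier <- function(ipd) {
  ipd <- validate_ipd(ipd)
  if (nrow(ipd) < 1) stop("ipd is empty", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd,
                          conf.type = "none")
  keep <- sf$n.event > 0
  km <- km_coordinates(c(0, sf$time[keep]), c(1, sf$surv[keep]))
  attr(km, "n") <- nrow(ipd)
  attr(km, "n_events") <- sum(ipd$event)
  km
}

#' Numbers at risk of an IPD collection at given times
#'
#' @param ipd Data frame with column `time`.
#' @param times Report times.
#' @return A [risk_table].
#' @export
risk_table_from_ipd <- function(ipd, times) {
  risk_table(times, vapply(times, function(t) sum(ipd$time >= t),
                           numeric(1)))
}

# Evaluate a KM step function at arbitrary times (right-continuous).
km_step_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  ifelse(idx == 0, 1, km$survival[pmax(idx, 1)])
}

#' Reconstruct pseudo individual patient data from a published KM curve
#'
#' Interval-by-interval reconstruction: within each numbers-at-risk
#' interval a candidate number of censorings is spread uniformly over
#' the interval and iteratively adjusted until the implied number at
#' risk at the start of the next interval matches the published risk
#' table; event counts at each step then follow from the published
#' survival drops. In the final interval the censoring rate is assumed
#' equal to the average over earlier intervals (spread uniformly)
#' unless `total_events` is given, in which case final-interval
#' censoring is calibrated so the global event count matches.
#'
#' @param km A [km_coordinates] object (or data frame with `time`,
#'   `survival`).
#' @param risk A [risk_table] (or data frame with `time`, `n_at_risk`)
#'   with at least two rows.
#' @param total_events Optional reported total number of events.
#' @return Pseudo-IPD data frame with columns `time`, `event`, plus
#'   attributes `n_events` and `n_censored`.
#' @export
reconstruct_ipd <- function(km, risk, total_events = NULL) {
  km <- km_coordinates(km$time, km$survival)
  risk <- risk_table(risk$time, risk$n_at_risk)
  if (nrow(risk) < 2) stop("risk table needs at least 2 rows", call. = FALSE)

  t_r <- risk$time; n_r <- as.numeric(risk$n_at_risk)
  n_int <- length(t_r)
  if (t_r[1] > km$time[1]) stop("risk table must start at or before time 0",
                                call. = FALSE)

  # insert the risk-table times as explicit (drop-free) step points so
  # every risk interval starts exactly on a step index
  extra <- setdiff(t_r, km$time)
  t_s <- sort(c(km$time, extra))
  S <- km_step_at(km, t_s)
  K <- length(t_s)

  # KM indices covered by each risk interval [t_r[i], t_r[i+1])
  lower <- match(t_r, t_s)
  upper <- c(lower[-1] - 1L, K)

  n_cen_int <- numeric(n_int)
  cen <- d <- numeric(K)
  n_hat <- numeric(K + 1); n_hat[1] <- n_r[1]
  km_hat <- rep(1, K)
  last_i <- rep(1L, n_int)

  spread_censor <- function(i, count, end_idx) {
    # spread `count` censor times uniformly over the interval and bin
    # them into the step sub-intervals [t_s[k], t_s[k+1]), k = lower[i]
    # .. end_idx - 1
    m <- end_idx - lower[i]
    counts <- numeric(max(m, 0))
    if (count > 0 && m >= 1) {
      span_lo <- t_s[lower[i]]
      span_hi <- t_s[end_idx]
      cen_t <- span_lo + seq_len(count) * (span_hi - span_lo) / (count + 1)
      counts <- graphics::hist(cen_t, breaks = t_s[lower[i]:end_idx],
                               plot = FALSE)$counts
    }
    counts
  }

  recount <- function(i, end_idx) {
    # recompute events / at-risk across interval i given current `cen`
    n_hat[lower[i]] <<- n_r[i]
    last <- last_i[i]
    for (k in lower[i]:end_idx) {
      if (i == 1 && k == 1) {
        d[k] <<- 0; km_hat[k] <<- 1
      } else {
        d[k] <<- if (km_hat[last] > 0 && n_hat[k] > 0) {
          round(n_hat[k] * (1 - S[k] / km_hat[last]))
        } else 0
        d[k] <<- max(min(d[k], n_hat[k]), 0)
        km_hat[k] <<- km_hat[last] * (1 - d[k] / max(n_hat[k], 1))
      }
      n_hat[k + 1] <<- n_hat[k] - d[k] - cen[k]
      if (n_hat[k + 1] < 0) {
        cen[k] <<- n_hat[k] - d[k]
        n_hat[k + 1] <<- 0
      }
      if (d[k] != 0) last <- k
    }
    last
  }

  for (i in seq_len(max(n_int - 1L, 0L))) {
    guess <- round(n_r[i] * S[lower[i + 1]] /
                     max(S[lower[i]], 1e-12) - n_r[i + 1])
    n_cen_int[i] <- max(guess, 0)
    iter <- 0
    last <- last_i[i]
    repeat {
      iter <- iter + 1
      if (iter > 1000) {
        stop("reconstruction failed to converge in risk interval ", i,
             " [", t_r[i], ", ", t_r[i + 1], ")", call. = FALSE)
      }
      if (n_cen_int[i] <= 0) {
        n_cen_int[i] <- 0
        cen[lower[i]:upper[i]] <- 0
      } else {
        cen[lower[i]:upper[i]] <- spread_censor(i, n_cen_int[i], lower[i + 1])
      }
      last <- recount(i, upper[i])
      gap <- n_hat[lower[i + 1]] - n_r[i + 1]
      if (gap == 0 || (gap < 0 && n_cen_int[i] <= 0)) break
      n_cen_int[i] <- n_cen_int[i] + gap
    }
    if (n_hat[lower[i + 1]] < n_r[i + 1]) {
      # published risk number unattainable given the curve; proceed with
      # the implied number (common with rounded digitisation)
      n_r[i + 1] <- n_hat[lower[i + 1]]
    }
    last_i[i + 1] <- last
  }

  # final interval: average censoring rate of earlier intervals
  i <- n_int
  if (n_int > 1) {
    elapsed <- t_s[upper[n_int - 1]] - t_s[1]
    rate <- if (elapsed > 0) sum(n_cen_int[seq_len(n_int - 1)]) / elapsed else 0
    n_cen_int[i] <- min(round(rate * (t_s[K] - t_s[lower[i]])), n_r[i])
  }
  n_cen_int[i] <- max(n_cen_int[i], 0)
  cen[lower[i]:K] <- 0
  if (n_cen_int[i] > 0 && K > lower[i]) {
    cen[lower[i]:(K - 1)] <- spread_censor(i, n_cen_int[i], K)
  }
  recount(i, upper[i])

  if (!is.null(total_events)) {
    sum_before <- if (n_int > 1) sum(d[seq_len(upper[n_int - 1])]) else 0
    if (n_int > 1 && sum_before >= total_events) {
      d[lower[i]:K] <- 0
      cen[lower[i]:K] <- 0
      n_hat[(lower[i] + 1):(K + 1)] <- n_r[i]
    } else {
      iter <- 0
      best <- NULL
      repeat {
        iter <- iter + 1
        sumd <- sum(d[seq_len(K)])
        if (is.null(best) || abs(sumd - total_events) < best$gap) {
          best <- list(gap = abs(sumd - total_events), d = d, cen = cen,
                       n_hat = n_hat)
        }
        if (sumd == total_events ||
            (sumd < total_events && n_cen_int[i] <= 0) || iter > 200) break
        n_cen_int[i] <- max(n_cen_int[i] + (sumd - total_events), 0)
        cen[lower[i]:K] <- 0
        if (n_cen_int[i] > 0 && K > lower[i]) {
          cen[lower[i]:(K - 1)] <- spread_censor(i, n_cen_int[i], K)
        }
        recount(i, K)
      }
      d <- best$d; cen <- best$cen; n_hat <- best$n_hat
    }
  }

  # assemble pseudo-IPD
  times <- events <- numeric(0)
  for (k in seq_len(K)) {
    if (d[k] > 0) {
      times <- c(times, rep(t_s[k], d[k]))
      events <- c(events, rep(1, d[k]))
    }
    if (cen[k] > 0) {
      hi <- if (k < K) t_s[k + 1] else t_s[K]
      ct <- t_s[k] + seq_len(cen[k]) * (hi - t_s[k]) / (cen[k] + 1)
      times <- c(times, ct)
      events <- c(events, rep(0, cen[k]))
    }
  }
  left <- n_hat[K + 1]
  if (left > 0) {
    times <- c(times, rep(max(t_s[K], t_r[n_int]), left))
    events <- c(events, rep(0, left))
  }
  out <- data.frame(time = times, event = as.integer(events))
  out <- out[order(out$time, -out$event), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) != risk$n_at_risk[1]) {
    # conservation check; should not trigger for feasible inputs
    stop("reconstruction produced ", nrow(out), " subjects but the risk ",
         "table starts at ", risk$n_at_risk[1], call. = FALSE)
  }
  attr(out, "n_events") <- sum(out$event)
  attr(out, "n_censored") <- sum(1 - out$event)
  out
}
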