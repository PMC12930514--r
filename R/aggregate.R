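#' Normalise epidemiological site counts into weights
#'
#' Weights reflect each tumour site's relative contribution to the
#' overall biomarker-positive population (or, alternatively, to trial
#' enrolment; record the choice of source in the model metadata).
#'
#' @param counts Named non-negative counts, one per site.
#' @return A `weight_set`: named numeric vector summing to 1.
#' @export
#' @examples
#' normalize_weights(c(A = 30, B = 45, C = 75))
normalize_weights <- function(counts) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by site_id", call. = FALSE)
  }
  counts <- as.numeric(counts) |> stats::setNames(names(counts))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("at least one site count must be positive",
                       call. = FALSE)
  structure(counts / total, class = "weight_set")
}

#' One tumour site's submodel
#'
#' @param site_id Site identifier.
#' @param intervention,comparator [arm_inputs] for the two arms.
#' @param weight_source_count Biomarker-positive count driving this
#'   site's weight.
#' @param evidence_level `"pooled"` (survival evidence borrowed from the
#'   pooled biomarker-positive population) or `"site_specific"`.
#' @param evidence_n Number of subjects contributing site-specific
#'   survival evidence (drives re-analysis triggers).
#' @return A `site_submodel` list.
#' @export
site_submodel <- function(site_id, intervention, comparator,
                          weight_source_count,
                          evidence_level = c("pooled", "site_specific"),
                          evidence_n = 0L) {
  evidence_level <- match.arg(evidence_level)
  stopifnot(inherits(intervention, "arm_inputs"),
            inherits(comparator, "arm_inputs"),
            weight_source_count >= 0, evidence_n >= 0)
  structure(list(site_id = as.character(site_id),
                 intervention = intervention, comparator = comparator,
                 weight_source_count = weight_source_count,
                 evidence_level = evidence_level,
                 evidence_n = as.integer(evidence_n)),
            class = "site_submodel")
}

#' Multi-site partitioned survival model
#'
#' Container holding the site submodels together with the structural
#' settings that are deliberately shared across all sites (time grid,
#' discounting, willingness to pay, background-mortality convention) —
#' sites may differ in evidence and parameters but never in structure.
#'
#' @param sites List of [site_submodel] objects (unique `site_id`s).
#' @param grid A [time_grid].
#' @param econ An [economic_params].
#' @param wtp Willingness to pay per QALY.
#' @param background Optional background-mortality settings (list with
#'   `life_table`, `start_age`, `sex_mix`), applied to OS in every arm.
#' @param weights Optional [normalize_weights] result; defaults to
#'   weights from the sites' `weight_source_count`s.
#' @param weight_source Label recorded in outputs (e.g.
#'   `"biomarker_positive_count"` or `"trial_enrolment"`).
#' @return A `psm_model` with an empty version log.
#' @export
psm_model <- function(sites, grid = time_grid(), econ = economic_params(),
                      wtp = 100000, background = NULL, weights = NULL,
                      weight_source = "biomarker_positive_count") {
  if (inherits(sites, "site_submodel")) sites <- list(sites)
  ids <- vapply(sites, function(s) s$site_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate site_id: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  names(sites) <- ids
  if (is.null(weights)) {
    weights <- normalize_weights(
      stats::setNames(vapply(sites, function(s) s$weight_source_count,
                             numeric(1)), ids))
  }
  if (!setequal(names(weights), ids)) {
    stop("weights must cover exactly the model's sites", call. = FALSE)
  }
  structure(list(sites = sites, grid = grid, econ = econ, wtp = wtp,
                 background = background,
                 weights = weights, weight_source = weight_source,
                 versions = list()),
            class = "psm_model")
}

#' Evaluate every site and aggregate by weights
#'
#' Runs each site's two arms through the partitioned survival engine,
#' forms per-site incremental results, and combines them. The weighted
#' sums of incremental costs and QALYs are computed first and the
#' aggregated ICER is derived from those sums; site-level ICERs are
#' never averaged, because ratios cannot be meaningfully averaged.
#'
#' @param model A [psm_model].
#' @param record_version Append the result to the model's version log?
#' @return An `aggregated_result` (see [aggregate_sites()]) with an
#'   extra `arm_results` element; if `record_version = TRUE` the
#'   returned object carries the updated model in attribute `model`.
#' @export
run_model <- function(model, record_version = FALSE) {
  stopifnot(inherits(model, "psm_model"))
  per_site <- list()
  arm_results <- list()
  for (s in model$sites) {
    iv <- evaluate_arm(s$intervention, model$grid, model$econ,
                       model$background)
    cp <- evaluate_arm(s$comparator, model$grid, model$econ,
                       model$background)
    per_site[[s$site_id]] <- incremental(iv, cp, model$wtp)
    arm_results[[s$site_id]] <- list(intervention = iv, comparator = cp)
  }
  agg <- aggregate_sites(per_site, model$weights, model$wtp)
  agg$arm_results <- arm_results
  agg$weight_source <- model$weight_source
  if (record_version) {
    model <- .append_version(model, agg)
    attr(agg, "model") <- model
  }
  agg
}

#' Weighted aggregation of per-site incremental results
#'
#' @param per_site Named list of [incremental] results keyed by site.
#' @param weights A `weight_set` over the same sites.
#' @param wtp Willingness to pay per QALY.
#' @return An `aggregated_result`: `delta_cost_agg`, `delta_qaly_agg`,
#'   `icer_agg` (`NA` unless defined), `icer_status`, `nmb_agg`, and a
#'   `per_site` data frame (site, weight, delta_cost, delta_qaly, icer,
#'   icer_status, nmb).
#' @export
aggregate_sites <- function(per_site, weights, wtp = 100000) {
  ids <- names(per_site)
  missing_w <- setdiff(ids, names(weights))
  missing_s <- setdiff(names(weights), ids)
  if (length(missing_w) || length(missing_s)) {
    stop("site keys of results and weights differ; missing: ",
         paste(c(missing_w, missing_s), collapse = ", "), call. = FALSE)
  }
  w <- as.numeric(weights[ids])
  dc <- vapply(per_site, function(r) r$delta_cost, numeric(1))
  de <- vapply(per_site, function(r) r$delta_qaly, numeric(1))
  dc_agg <- sum(w * dc)
  de_agg <- sum(w * de)
  # classification of the aggregate mirrors the per-site rule
  if (de_agg == 0) {
    status <- "zero_effect"; icer <- NA_real_
  } else if (de_agg > 0 && dc_agg <= 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (de_agg < 0 && dc_agg >= 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "icer_defined"; icer <- dc_agg / de_agg
  }
  tab <- data.frame(
    site = ids, weight = w, delta_cost = dc, delta_qaly = de,
    icer = vapply(per_site, function(r) ifelse(is.na(r$icer), NA_real_,
                                               r$icer), numeric(1)),
    icer_status = vapply(per_site, function(r) r$icer_status, character(1)),
    nmb = wtp * de - dc,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(delta_cost_agg = dc_agg, delta_qaly_agg = de_agg,
                 icer_agg = icer, icer_status = status,
                 nmb_agg = wtp * de_agg - dc_agg, wtp = wtp,
                 per_site = tab, incrementals = per_site),
            class = "aggregated_result")
}

#' @export
print.aggregated_result <- function(x, ...) {
  cat("Aggregated cost-effectiveness across", nrow(x$per_site), "site(s)\n")
  print(x$per_site[, c("site", "weight", "delta_cost", "delta_qaly",
                       "icer", "icer_status")], digits = 5)
  cat(sprintf("Weighted: dC = %.2f, dQALY = %.4f; ", x$delta_cost_agg,
              x$delta_qaly_agg))
  if (x$icer_status == "icer_defined") {
    cat(sprintf("aggregated ICER = %.0f per QALY\n", x$icer_agg))
  } else {
    cat("aggregate is", x$icer_status, "\n")
  }
  invisible(x)
}

# --- versioning ------------------------------------------------------

.model_snapshot <- function(model) {
  model$versions <- NULL
  model
}

.append_version <- function(model, results) {
  vid <- length(model$versions) + 1L
  results$arm_results <- NULL
  v <- structure(list(
    version_id = vid,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    snapshot = .model_snapshot(model),
    evidence_registry = vapply(model$sites, function(s) s$evidence_n,
                               integer(1)),
    results = results
  ), class = "model_version")
  model$versions <- c(model$versions, list(v))
  model
}

#' Break out a tumour site into its own dedicated submodel
#'
#' Switches the named site from pooled to site-specific evidence,
#' replacing its arm inputs with the supplied site-specific ones. All
#' other sites and every structural setting (grid, discounting,
#' conventions) are untouched, and a new model version is appended to
#' the version log.
#'
#' @param model A [psm_model].
#' @param site_id Site to break out.
#' @param site_specific_inputs List with elements `intervention` and
#'   `comparator` ([arm_inputs]), and optionally `evidence_n`.
#' @return The updated `psm_model` (new version recorded, holding the
#'   re-computed results).
#' @export
breakout <- function(model, site_id, site_specific_inputs) {
  stopifnot(inherits(model, "psm_model"))
  if (!site_id %in% names(model$sites)) {
    stop("unknown site '", site_id, "'; model has: ",
         paste(names(model$sites), collapse = ", "), call. = FALSE)
  }
  need <- c("intervention", "comparator")
  missing <- setdiff(need, names(site_specific_inputs))
  if (length(missing)) {
    stop("site-specific inputs incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (a in need) {
    if (!inherits(site_specific_inputs[[a]], "arm_inputs")) {
      stop("site_specific_inputs$", a, " must be an arm_inputs object",
           call. = FALSE)
    }
  }
  if (length(model$versions) == 0) {
    model <- .append_version(model, run_model(model))
  }
  s <- model$sites[[site_id]]
  s$evidence_level <- "site_specific"
  s$intervention <- site_specific_inputs$intervention
  s$comparator <- site_specific_inputs$comparator
  if (!is.null(site_specific_inputs$evidence_n)) {
    s$evidence_n <- as.integer(site_specific_inputs$evidence_n)
  }
  model$sites[[site_id]] <- s
  .append_version(model, run_model(model))
}

#' Sites due for re-analysis under a sample-size trigger
#'
#' A pre-specified trigger: a site is due when its accumulated
#' site-specific evidence has grown by at least `min_new_n` subjects
#' since the last recorded model version. Pure function; the model is
#' not modified.
#'
#' @param model A [psm_model].
#' @param updates Named integer vector: current evidence `n` per site.
#' @param thresholds List with `min_new_n` (positive integer; the
#'   default 50 is a placeholder — no evidence-based threshold exists
#'   and it should be set per decision problem).
#' @return Character vector of site ids due for re-analysis.
#' @export
check_reanalysis_triggers <- function(model, updates,
                                      thresholds = list(min_new_n = 50L)) {
  stopifnot(inherits(model, "psm_model"))
  if (is.null(thresholds$min_new_n) || thresholds$min_new_n <= 0) {
    stop("thresholds$min_new_n must be positive", call. = FALSE)
  }
  if (any(updates < 0)) stop("evidence counts cannot be negative",
                             call. = FALSE)
  base <- if (length(model$versions)) {
    utils::tail(model$versions, 1)[[1]]$evidence_registry
  } else {
    vapply(model$sites, function(s) s$evidence_n, integer(1))
  }
  due <- character(0)
  for (id in names(updates)) {
    if (!id %in% names(base)) {
      stop("unknown site '", id, "' in updates", call. = FALSE)
    }
    if (updates[[id]] - base[[id]] >= thresholds$min_new_n) {
      due <- c(due, id)
    }
  }
  due
}

#' Compare two model versions
#'
#' Reports how incremental evidence altered the cost-effectiveness:
#' per-site and aggregate deltas of incremental cost, incremental QALY
#' and ICER, plus the list of site-level input fields that changed.
#'
#' @param v1,v2 `model_version` objects, `v1` older than `v2`.
#' @return A `version_diff`: list with `aggregate` (named deltas),
#'   `per_site` data frame and `changed_fields` character vector.
#' @export
diff_versions <- function(v1, v2) {
  stopifnot(inherits(v1, "model_version"), inherits(v2, "model_version"))
  if (v1$version_id == v2$version_id) {
    stop("cannot diff a version against itself", call. = FALSE)
  }
  if (v1$version_id > v2$version_id) { tmp <- v1; v1 <- v2; v2 <- tmp }
  t1 <- v1$results$per_site; t2 <- v2$results$per_site
  ids <- union(t1$site, t2$site)
  m1 <- t1[match(ids, t1$site), ]; m2 <- t2[match(ids, t2$site), ]
  per_site <- data.frame(
    site = ids,
    d_delta_cost = m2$delta_cost - m1$delta_cost,
    d_delta_qaly = m2$delta_qaly - m1$delta_qaly,
    d_icer = m2$icer - m1$icer,
    stringsAsFactors = FALSE
  )
  changed <- character(0)
  for (id in intersect(names(v1$snapshot$sites), names(v2$snapshot$sites))) {
    s1 <- v1$snapshot$sites[[id]]; s2 <- v2$snapshot$sites[[id]]
    for (f in names(s1)) {
      if (!identical(s1[[f]], s2[[f]])) {
        changed <- c(changed, paste0("sites.", id, ".", f))
      }
    }
  }
  structure(list(
    from = v1$version_id, to = v2$version_id,
    aggregate = c(
      d_delta_cost = v2$results$delta_cost_agg - v1$results$delta_cost_agg,
      d_delta_qaly = v2$results$delta_qaly_agg - v1$results$delta_qaly_agg,
      d_icer = v2$results$icer_agg - v1$results$icer_agg
    ),
    per_site = per_site,
    changed_fields = changed
  ), class = "version_diff")
}
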