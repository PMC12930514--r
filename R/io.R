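#' Read / write individual patient data CSV
#'
#' Standard columns: `site`, `arm`, `endpoint` (`OS`/`PFS`), `time`
#' (months), `event` (0/1). `time` and `event` are required; the
#' identifying columns are optional for single-curve files.
#'
#' @param path CSV path.
#' @return Data frame of IPD records.
#' @export
read_ipd <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ipd(df, require_cols = c("time", "event"))
}

#' @rdname read_ipd
#' @param ipd IPD data frame to write.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(ipd, path, row.names = FALSE)
  invisible(path)
}

#' Read digitised Kaplan-Meier coordinates (CSV: `time`, `survival`)
#' @param path CSV path.
#' @return A [km_coordinates] object.
#' @export
read_km_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  km_coordinates(df$time, df$survival)
}

#' Read a numbers-at-risk table (CSV: `time`, `n_at_risk`)
#' @param path CSV path.
#' @return A [risk_table] object.
#' @export
read_risk_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  risk_table(df$time, df$n_at_risk)
}

# canonical serialisation + md5, used for spec hashes and the version
# log's per-record checksums
.canonical_json <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null", force = TRUE))
}

.md5_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

#' Hash of a model-spec document
#' @param spec A model-spec list (see [load_spec()]).
#' @return Character md5 digest of the canonical serialisation.
#' @export
spec_hash <- function(spec) .md5_string(.canonical_json(spec))

# ---- model spec documents ------------------------------------------

.global_defaults <- list(
  currency = "EUR", time_unit = "months", cycle_length = 1,
  horizon = 480, discount_rate_costs = 0.03, discount_rate_effects = 0.03,
  half_cycle_correction = TRUE, wtp = 1e5, seed = 1L,
  weight_source = "biomarker_positive_count", family = "exponential"
)

.arm_economic_defaults <- list(
  utility_pf = 0.75, utility_pd = 0.55, drug_cost_per_cycle = 0,
  admin_cost_per_cycle = 0, disease_mgmt_cost_pf = 0,
  disease_mgmt_cost_pd = 0, ae_cost_oneoff = 0, eol_cost_oneoff = 0
)

#' Load and validate a model-spec document
#'
#' The spec is a single human-readable structured document (YAML, or
#' JSON interchangeably) with a `global` block (grid, discounting,
#' willingness to pay, currency and time units, seed), a `sites` list
#' — adding a tumour site to the model is appending one block — and an
#' optional `parameters` list for sensitivity analysis. Missing global
#' and economic fields are filled with defaults, each logged via
#' `message()`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` spec file.
#' @return A validated `model_spec` list with attribute `base_dir`.
#' @export
load_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  spec <- validate_spec(spec)
  attr(spec, "base_dir") <- dirname(normalizePath(path))
  spec
}

#' @rdname load_spec
#' @param spec A model-spec list (possibly partial).
#' @export
validate_spec <- function(spec) {
  if (is.null(spec$sites) || length(spec$sites) == 0) {
    stop("spec must contain at least one site (field path: sites)",
         call. = FALSE)
  }
  spec$global <- spec$global %||% list()
  for (f in names(.global_defaults)) {
    if (is.null(spec$global[[f]])) {
      spec$global[[f]] <- .global_defaults[[f]]
      message("spec default applied: global.", f, " = ",
              format(.global_defaults[[f]]))
    }
  }
  ids <- vapply(spec$sites, function(s) as.character(s$site_id %||% ""),
                character(1))
  if (any(!nzchar(ids))) {
    stop("every site needs a site_id (field path: sites[].site_id)",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate site_id '", ids[duplicated(ids)][1], "'",
         call. = FALSE)
  }
  for (i in seq_along(spec$sites)) {
    s <- spec$sites[[i]]
    if (is.null(s$weight_source_count)) {
      stop("sites.", ids[i], ".weight_source_count is required",
           call. = FALSE)
    }
    s$evidence_level <- s$evidence_level %||% "pooled"
    s$evidence_n <- s$evidence_n %||% 0L
    for (arm in c("intervention", "comparator")) {
      a <- s[[arm]]
      if (is.null(a)) {
        stop("sites.", ids[i], ".", arm, " block is required",
             call. = FALSE)
      }
      for (ep in c("os", "pfs")) {
        cv <- a[[ep]]
        ok <- !is.null(cv) &&
          (!is.null(cv$family) && !is.null(cv$params) ||
             isTRUE(cv$from_ipd) || !is.null(cv$ipd))
        if (!ok) {
          stop("sites.", ids[i], ".", arm, ".", ep,
               " must give {family, params}, {from_ipd: true} or ",
               "{ipd: <csv>}", call. = FALSE)
        }
      }
      for (f in names(.arm_economic_defaults)) {
        if (is.null(a[[f]])) {
          a[[f]] <- .arm_economic_defaults[[f]]
          message("spec default applied: sites.", ids[i], ".", arm, ".",
                  f, " = ", .arm_economic_defaults[[f]])
        }
      }
      s[[arm]] <- a
    }
    spec$sites[[i]] <- s
  }
  spec$parameters <- spec$parameters %||% list()
  class(spec) <- c("model_spec", "list")
  spec
}

#' Save a model-spec document (YAML or JSON by extension)
#' @param spec A model-spec list.
#' @param path Output path.
#' @export
save_spec <- function(spec, path) {
  attr(spec, "base_dir") <- NULL
  spec <- unclass(spec)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(spec, path)
  }
  invisible(path)
}

# resolve one arm's curve spec into a curve object, fitting IPD slices
# where referenced
.resolve_curve <- function(cv, site_id, arm, ep, global_ipd, base_dir,
                           family, pooled_cache, pooled_ids) {
  if (!is.null(cv$family) && !is.null(cv$params)) {
    return(parametric_curve(cv$family, as.numeric(unlist(cv$params))))
  }
  fam <- cv$family %||% family
  if (!is.null(cv$ipd)) {
    path <- file.path(base_dir, cv$ipd)
    return(fit_parametric(read_ipd(path), fam))
  }
  # from_ipd: slice the global IPD file
  if (is.null(global_ipd)) {
    stop("sites.", site_id, ".", arm, ".", ep, " requests from_ipd but ",
         "global.ipd_file is not set", call. = FALSE)
  }
  epu <- toupper(ep)
  pooled <- site_id %in% pooled_ids
  key <- if (pooled) paste("pooled", arm, epu, sep = ":")
         else paste("site", site_id, arm, epu, sep = ":")
  if (!is.null(pooled_cache$fits[[key]])) return(pooled_cache$fits[[key]])
  sel <- global_ipd$arm == arm & global_ipd$endpoint == epu &
    (if (pooled) global_ipd$site %in% pooled_ids
     else global_ipd$site == site_id)
  f <- fit_parametric(global_ipd[sel, ], fam)
  f$fit_id <- key
  pooled_cache$fits[[key]] <- f
  f
}

#' Build a runnable model from a spec document
#'
#' @param spec A `model_spec` (from [load_spec()] / [validate_spec()]).
#' @param base_dir Directory against which file references resolve.
#' @return A [psm_model].
#' @export
model_from_spec <- function(spec, base_dir = attr(spec, "base_dir") %||%
                              ".") {
  g <- spec$global
  grid <- time_grid(g$cycle_length, g$horizon)
  econ <- economic_params(g$discount_rate_costs, g$discount_rate_effects,
                          g$half_cycle_correction)
  global_ipd <- if (!is.null(g$ipd_file)) {
    read_ipd(file.path(base_dir, g$ipd_file))
  }
  background <- if (!is.null(spec$background)) {
    list(life_table = read_life_table(file.path(base_dir,
                                                spec$background$life_table)),
         start_age = spec$background$start_age,
         sex_mix = unlist(spec$background$sex_mix))
  }
  pooled_ids <- vapply(spec$sites, function(s) s$site_id, character(1))[
    vapply(spec$sites, function(s) identical(s$evidence_level, "pooled"),
           logical(1))]
  cache <- new.env()
  cache$fits <- list()
  sites <- lapply(spec$sites, function(s) {
    arms <- lapply(c(intervention = "intervention",
                     comparator = "comparator"), function(arm) {
      a <- s[[arm]]
      os <- .resolve_curve(a$os, s$site_id, arm, "os", global_ipd,
                           base_dir, g$family, cache, pooled_ids)
      pfs <- .resolve_curve(a$pfs, s$site_id, arm, "pfs", global_ipd,
                            base_dir, g$family, cache, pooled_ids)
      do.call(arm_inputs, c(list(os = os, pfs = pfs),
                            a[names(.arm_economic_defaults)]))
    })
    site_submodel(s$site_id, arms$intervention, arms$comparator,
                  weight_source_count = s$weight_source_count,
                  evidence_level = s$evidence_level,
                  evidence_n = s$evidence_n)
  })
  psm_model(sites, grid = grid, econ = econ, wtp = g$wtp,
            background = background, weight_source = g$weight_source)
}

#' Parameter specs declared in a model-spec document
#' @param spec A `model_spec`.
#' @return List of [parameter_spec] objects.
#' @export
spec_parameters <- function(spec) {
  lapply(spec$parameters, function(p) {
    parameter_spec(p$name, p$target, p$distribution, p$args,
                   p$scope %||% "shared", p$site_id,
                   p$dsa_low %||% NA_real_, p$dsa_high %||% NA_real_)
  })
}

# ---- version log persistence ---------------------------------------

.version_record <- function(v) {
  list(
    version_id = v$version_id,
    timestamp = v$timestamp,
    evidence_registry = as.list(v$evidence_registry),
    results = list(
      delta_cost_agg = v$results$delta_cost_agg,
      delta_qaly_agg = v$results$delta_qaly_agg,
      icer_agg = v$results$icer_agg,
      icer_status = v$results$icer_status,
      per_site = v$results$per_site
    )
  )
}

#' Persist a model's version log as append-only JSON-lines
#'
#' Each line is one model version with a per-record md5 checksum;
#' [read_version_log()] verifies the checksums so silent corruption of
#' the audit trail is detected.
#'
#' @param model A [psm_model] with recorded versions.
#' @param path Output `.jsonl` path.
#' @param append Append to an existing log rather than rewrite.
#' @export
write_version_log <- function(model, path, append = FALSE) {
  lines <- vapply(model$versions, function(v) {
    rec <- .version_record(v)
    body <- .canonical_json(rec)
    rec$checksum <- .md5_string(body)
    .canonical_json(rec)
  }, character(1))
  if (append && file.exists(path)) {
    cat(lines, file = path, sep = "\n", append = TRUE)
    cat("\n", file = path, append = TRUE)
  } else {
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_version_log
#' @return `read_version_log()`: list of version records (parsed JSON).
#' @export
read_version_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(seq_along(lines), function(i) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    stored <- rec$checksum
    rec$checksum <- NULL
    body <- .canonical_json(rec)
    if (!identical(.md5_string(body), stored)) {
      stop("version log corrupted at line ", i, " (checksum mismatch)",
           call. = FALSE)
    }
    rec
  })
}
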