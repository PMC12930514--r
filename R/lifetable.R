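#' Construct a general-population life table
#'
#' @param age Integer ages in years (contiguous within each sex).
#' @param sex Sex labels (e.g. `"female"`, `"male"`).
#' @param qx Annual probability of death in `[0, 1]`.
#' @return A `life_table` data frame.
#' @export
life_table <- function(age, sex, qx) {
  lt <- data.frame(age = as.integer(age), sex = as.character(sex),
                   qx = as.numeric(qx), stringsAsFactors = FALSE)
  if (any(lt$qx < 0 | lt$qx > 1 | !is.finite(lt$qx))) {
    stop("life-table qx must lie in [0, 1]", call. = FALSE)
  }
  for (s in unique(lt$sex)) {
    a <- sort(lt$age[lt$sex == s])
    if (any(diff(a) != 1L)) {
      stop("life-table ages must be contiguous for sex '", s, "'",
           call. = FALSE)
    }
  }
  class(lt) <- c("life_table", "data.frame")
  lt
}

#' Read a life table from CSV
#'
#' Expected columns: `age`, `sex`, `qx`.
#'
#' @param path Path to the CSV file.
#' @return A `life_table` data frame.
#' @export
read_life_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age", "sex", "qx")
  if (!all(need %in% names(df))) {
    stop("life-table CSV must have columns age, sex, qx", call. = FALSE)
  }
  life_table(df$age, df$sex, df$qx)
}

# Cohort-average monthly background hazard at an integer attained age.
# Annual probabilities become monthly hazards via h = -ln(1 - qx) / 12;
# the sex mix collapses the per-sex hazards into one cohort hazard
# (the model is cohort-level and carries no individual sex).
.population_monthly_hazard <- function(lt, ages, sex_mix) {
  sexes <- names(sex_mix)
  if (is.null(sexes) || abs(sum(sex_mix) - 1) > 1e-8) {
    stop("sex_mix must be a named vector of proportions summing to 1",
         call. = FALSE)
  }
  h <- numeric(length(ages))
  for (s in sexes) {
    sub <- lt[lt$sex == s, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop("life table has no rows for sex '", s, "'", call. = FALSE)
    }
    i <- match(ages, sub$age)
    if (anyNA(i)) {
      stop("life table does not cover age(s) ",
           paste(sort(unique(ages[is.na(i)])), collapse = ", "),
           " for sex '", s, "'", call. = FALSE)
    }
    q <- pmin(sub$qx[i], 1 - 1e-12)
    h <- h + sex_mix[[s]] * (-log(1 - q) / 12)
  }
  h
}

#' Adjust a survival curve for background mortality
#'
#' Enforces consistency with general-population life expectancy by the
#' hazard-max convention: in every cycle the applied hazard is the
#' larger of the disease-model hazard and the cohort-average
#' general-population hazard at the attained age. The adjusted curve is
#' therefore pointwise no higher than the unadjusted curve and never
#' exceeds the general-population survivor curve from the cohort's
#' starting age. The operation is idempotent.
#'
#' @param curve A tabulated survival vector on `grid` (length
#'   `n_cycles + 1`, starting at 1), or a parametric curve /
#'   `fitted_survival` which is tabulated first.
#' @param lt A [life_table].
#' @param start_age Cohort age in years at model start.
#' @param sex_mix Named proportions, e.g. `c(female = 0.5, male = 0.5)`.
#' @param grid A [time_grid].
#' @return Numeric survival vector on the grid with attribute
#'   `convention = "hazard_max"`.
#' @export
apply_background_mortality <- function(curve, lt, start_age, sex_mix,
                                       grid) {
  stopifnot(inherits(grid, "time_grid"))
  if (!inherits(lt, "life_table")) stop("lt must be a life_table",
                                        call. = FALSE)
  s <- .tabulate_curve(curve, grid)
  times <- grid$times
  n <- grid$n_cycles
  # attained integer age at the start of each cycle
  ages <- as.integer(floor(start_age + times[seq_len(n)] / 12))
  max_age <- max(lt$age)
  if (any(ages > max_age)) {
    stop("horizon extends beyond life-table coverage: missing ages ",
         paste(range(ages[ages > max_age]), collapse = "-"),
         " (table ends at ", max_age, ")", call. = FALSE)
  }
  h_pop <- .population_monthly_hazard(lt, ages, sex_mix) * grid$cycle_length
  # per-cycle cumulative model hazard; 0/0 at an exhausted curve -> Inf
  ratio <- ifelse(s[-1] > 0 | s[-(n + 1)] > 0,
                  s[-1] / pmax(s[-(n + 1)], .Machine$double.xmin), 0)
  h_mod <- -log(pmax(ratio, 0))
  h_adj <- pmax(h_mod, h_pop)
  out <- c(1, exp(-cumsum(h_adj)))
  out[!is.finite(out)] <- 0
  attr(out, "convention") <- "hazard_max"
  out
}

# General-population survivor curve from start_age on a grid (used in
# tests to bound the adjusted curve).
population_survival <- function(lt, start_age, sex_mix, grid) {
  n <- grid$n_cycles
  ages <- as.integer(floor(start_age + grid$times[seq_len(n)] / 12))
  h <- .population_monthly_hazard(lt, ages, sex_mix) * grid$cycle_length
  c(1, exp(-cumsum(h)))
}
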