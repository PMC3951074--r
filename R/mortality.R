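#' Constant annual disease hazard from 5-year survival
#'
#' The trial evidence gives only a 5-year overall survival probability per
#' risk group; within the first five model cycles deaths are assumed to
#' follow a constant annual probability `q` solving `(1 - q)^5 = os5`.
#'
#' @param os5 5-year overall survival probability, in (0, 1].
#' @return The annual death probability.
#' @examples
#' disease_hazard_from_os5(0.85)   # about 0.032
#' @export
disease_hazard_from_os5 <- function(os5) {
  if (!is.numeric(os5) || any(os5 <= 0) || any(os5 > 1))
    stop("os5 must lie in (0, 1]")
  1 - os5^(1 / 5)
}

#' Validate a life table
#'
#' @param lt A data frame with columns `age` and `qx`.
#' @param min_max_age Smallest admissible final age (the model horizon).
#' @return `lt` with class `life_table`, invisibly on success.
#' @export
validate_life_table <- function(lt, min_max_age = 100) {
  if (!all(c("age", "qx") %in% names(lt)))
    stop("life table must have columns 'age' and 'qx'")
  if (nrow(lt) == 0L || lt$age[1] != 0L)
    stop("life table must start at age 0")
  gaps <- which(diff(lt$age) != 1L)
  if (length(gaps))
    stop("life table has a gap after age ", lt$age[gaps[1]])
  if (any(!is.finite(lt$qx)) || any(lt$qx < 0) || any(lt$qx > 1))
    stop("life-table qx values must lie in [0, 1]")
  if (max(lt$age) < min_max_age)
    stop("life table must extend to age ", min_max_age,
         " (ends at ", max(lt$age), ")")
  class(lt) <- unique(c("life_table", class(lt)))
  invisible(lt)
}

#' Load a life table from delimited text
#'
#' Reads a two-column `age,qx` file (header required) giving the annual
#' all-cause probability of death at each single year of age, validates
#' contiguity and probability bounds, and optionally clamps the terminal
#' age's probability to 1 so the last tabulated age is absorbing.
#'
#' @param path Path to the CSV file.
#' @param clamp_terminal If `TRUE`, force `qx = 1` at the final age.
#' @param min_max_age Smallest admissible final age.
#' @return A `life_table` data frame with columns `age` and `qx`.
#' @export
load_life_table <- function(path, clamp_terminal = FALSE, min_max_age = 100) {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  lt <- validate_life_table(lt, min_max_age = min_max_age)
  if (clamp_terminal) lt$qx[nrow(lt)] <- 1
  lt
}

#' Build the cohort's mortality schedule
#'
#' Combines the disease-driven hazard of the first five post-treatment
#' years (calibrated to each risk group's 5-year survival, treated as
#' all-cause over that period) with background all-cause mortality from a
#' life table from year six onward, when disease-specific excess mortality
#' is taken to be zero (survival plateau).
#'
#' @param params A `cea_params` object.
#' @param life_table A `life_table` data frame.
#' @return An object of class `mortality_schedule`.
#' @seealso [annual_death_prob()]
#' @export
mortality_schedule <- function(params, life_table) {
  validate_life_table(life_table, min_max_age = params$horizon_age)
  sched <- list(
    qd = c(average = disease_hazard_from_os5(params$avg_risk$os5),
           high    = disease_hazard_from_os5(params$high_risk$os5)),
    life_q = stats::setNames(life_table$qx, life_table$age),
    max_age = max(life_table$age),
    start_age = params$start_age
  )
  class(sched) <- "mortality_schedule"
  sched
}

#' Annual death probability at a model cycle
#'
#' For years 1-5 after treatment returns the risk group's constant disease
#' hazard; from year 6 onward returns the life-table probability at the
#' attained age.
#'
#' @param sched A `mortality_schedule`.
#' @param age Attained age in years (`start_age + t`).
#' @param t Years since treatment (cycle index, `>= 1`).
#' @param risk_group `"average"` or `"high"`.
#' @return The annual probability of death applied during cycle `t`.
#' @export
annual_death_prob <- function(sched, age, t, risk_group = c("average", "high")) {
  risk_group <- match.arg(risk_group)
  if (any(t < 1)) stop("t must be >= 1 (first transition ends cycle 1)")
  death_prob_vector(sched, risk_group, t, sched$start_age + t)
}

# vectorised workhorse: death probability for cycles tt at attained ages
death_prob_vector <- function(sched, risk_group, tt, ages = sched$start_age + tt) {
  out <- rep(sched$qd[[risk_group]], length(tt))
  late <- tt >= 6
  if (any(late)) {
    if (any(ages[late] > sched$max_age))
      stop("attained age ", max(ages[late]), " beyond life-table end (",
           sched$max_age, ")")
    out[late] <- unname(sched$life_q[as.character(ages[late])])
  }
  out
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat("Mortality schedule\n")
  cat(sprintf("  Disease hazard years 1-5: average %.5f, high %.5f\n",
              x$qd["average"], x$qd["high"]))
  cat(sprintf("  Background life table: ages 0-%d, q(%d) = %.5f\n",
              x$max_age, x$max_age, x$life_q[as.character(x$max_age)]))
  invisible(x)
}

#' Period life expectancy from a life table
#'
#' Standard abridged computation with deaths spread uniformly within the
#' year of age (a(x) = 0.5); survival beyond the final tabulated age is
#' truncated.
#'
#' @param lt A `life_table`.
#' @param age Age from which remaining life expectancy is computed.
#' @return Expected remaining years of life.
#' @export
life_expectancy <- function(lt, age = 0) {
  q <- lt$qx[lt$age >= age]
  if (!length(q)) stop("age beyond life-table end")
  S <- cumprod(1 - q)           # survival to the end of each year
  Sprev <- c(1, S[-length(S)])  # survival to the start of each year
  sum((Sprev + S) / 2)
}
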