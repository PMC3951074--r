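#' Generate a Gompertz-Makeham life table
#'
#' Synthesizes a single-year complete life table from the Gompertz-Makeham
#' mortality law, under which the hazard at age `a` is
#' `makeham + gompertz_scale * exp(gompertz_rate * a)`: an age-independent
#' background term plus an exponentially increasing senescent term.  The
#' annual death probability is `q(a) = 1 - exp(-hazard(a))`.
#'
#' The defaults are calibrated to a modern low-mortality population with a
#' period life expectancy at birth of about 82 years (both sexes combined,
#' contemporary-Japan ballpark).  The resulting table stands in for an
#' official complete life table in the model's background mortality; it is
#' an approximation, not official vital statistics.
#'
#' @param makeham Age-independent annual hazard component (>= 0).
#' @param gompertz_scale Senescent hazard at age 0 (>= 0).
#' @param gompertz_rate Exponential increase of the senescent hazard per
#'   year of age (>= 0).
#' @param max_age Final tabulated age.
#' @param clamp_terminal If `TRUE`, force `qx = 1` at `max_age`.
#' @return A `life_table` data frame with columns `age` and `qx`.
#' @examples
#' lt <- generate_life_table()
#' life_expectancy(lt)   # about 82
#' @export
generate_life_table <- function(makeham = 2e-4,
                                gompertz_scale = 1.5e-5,
                                gompertz_rate = 0.1,
                                max_age = 100,
                                clamp_terminal = FALSE) {
  if (makeham < 0 || gompertz_scale < 0 || gompertz_rate < 0)
    stop("Gompertz-Makeham parameters must be non-negative")
  age <- 0:max_age
  hazard <- makeham + gompertz_scale * exp(gompertz_rate * age)
  qx <- pmin(1, 1 - exp(-hazard))
  lt <- data.frame(age = age, qx = qx)
  if (clamp_terminal) lt$qx[nrow(lt)] <- 1
  validate_life_table(lt, min_max_age = max_age)
}

#' The bundled synthetic life table
#'
#' Loads the synthetic background-mortality table shipped with the package
#' (`extdata/lifetable_synthetic_jp.csv`).  The file is the output of
#' [generate_life_table()] at its default parameters, committed verbatim so
#' that results are bit-stable across installations; a test asserts that
#' regeneration reproduces it.
#'
#' @return A `life_table` data frame covering ages 0-100.
#' @export
synthetic_lifetable <- function() {
  path <- system.file("extdata", "lifetable_synthetic_jp.csv",
                      package = "protonCEA", mustWork = TRUE)
  load_life_table(path)
}

#' Write a life table as CSV
#'
#' @param lt A `life_table`.
#' @param path Destination path; `qx` is written at 17 significant digits
#'   so read-back reproduces the doubles exactly.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  out <- data.frame(age = lt$age, qx = sprintf("%.17g", lt$qx))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Deterministic toy fixtures for testing and teaching
#'
#' Returns small, fully specified `(params, life_table)` bundles with
#' closed-form expected behaviour:
#' \describe{
#'   \item{`null_risk`}{default parameters with all hearing-loss risks set
#'     to 0 - the arms differ only in the radiation course cost, so the
#'     QALY difference is exactly 0 and the ICER is undefined.}
#'   \item{`certain_death_y5`}{5-year survival near 0 in both groups - the
#'     cohort is essentially extinct by year 5.}
#'   \item{`flat_mortality`}{constant annual death probability 0.02 at all
#'     ages and in years 1-5 (`os5 = 0.98^5`), no hearing loss, utility 1 -
#'     discounted life-years equal the geometric series
#'     `sum_t (0.98/1.03)^t`.}
#'   \item{`base_case`}{[default_params()] with the bundled synthetic life
#'     table.}
#' }
#'
#' @param name One of `"null_risk"`, `"certain_death_y5"`,
#'   `"flat_mortality"`, `"base_case"`.
#' @return A list with elements `name`, `params` and `life_table`.
#' @export
generate_toy_fixture <- function(name) {
  known <- c("null_risk", "certain_death_y5", "flat_mortality", "base_case")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    stop("unknown fixture name; expected one of: ",
         paste(known, collapse = ", "))
  p <- default_params()
  lt <- switch(
    name,
    base_case = synthetic_lifetable(),
    flat_mortality = {
      p$avg_risk$os5 <- 0.98^5
      p$high_risk$os5 <- 0.98^5
      p$avg_risk$hl_risk_xrt <- 0; p$avg_risk$hl_risk_pt <- 0
      p$high_risk$hl_risk_xrt <- 0; p$high_risk$hl_risk_pt <- 0
      p$utilities <- lapply(p$utilities,
                            function(u) list(u_no_hl = 1, u_hl = 1))
      p$ranges <- list()
      data.frame(age = 0:100, qx = 0.02)
    },
    null_risk = {
      p$avg_risk$hl_risk_xrt <- 0; p$avg_risk$hl_risk_pt <- 0
      p$high_risk$hl_risk_xrt <- 0; p$high_risk$hl_risk_pt <- 0
      p$ranges <- p$ranges[!grepl("^hl_risk", names(p$ranges))]
      synthetic_lifetable()
    },
    certain_death_y5 = {
      p$avg_risk$os5 <- 1e-10
      p$high_risk$os5 <- 1e-10
      p$ranges <- p$ranges[!grepl("^os5", names(p$ranges))]
      synthetic_lifetable()
    })
  lt <- validate_life_table(lt)
  list(name = name, params = validate_params(p), life_table = lt)
}
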