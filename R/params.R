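#' Default model parameters
#'
#' Returns the complete base-case parameter set of the cost-utility model:
#' 5-year overall survival and Grade 3-4 hearing-loss risks per risk group
#' and treatment arm, the cohort's risk-group split, mean cochlear doses,
#' utility weights for the three preference-based indexes (EQ-5D, HUI3,
#' SF-6D, all measured after hearing-aid provision), unit costs from the
#' payer perspective, economic settings (3% annual discount rate, a
#' willingness-to-pay threshold of $46,729/QALY), and the triangular
#' uncertainty ranges used by the sensitivity analyses.
#'
#' Survivors without hearing loss carry a utility weight of 1 by default;
#' `u_no_hl` is configurable because population norms below 1 are a
#' defensible alternative.
#'
#' @return An object of class `cea_params`: a named list with components
#'   `avg_risk`, `high_risk` (each with `os5`, `hl_risk_xrt`, `hl_risk_pt`,
#'   `dose_xrt_gy`, `dose_pt_gy`), `p_high_risk`, `start_age`,
#'   `horizon_age`, `onset_start_year`, `onset_plateau_year`, `utilities`,
#'   `costs`, `econ` and `ranges`.
#' @seealso [load_params()], [save_params()], [validate_params()]
#' @examples
#' p <- default_params()
#' p$high_risk$hl_risk_pt
#' p$costs$c_hearing_aid
#' @export
default_params <- function() {
  p <- list(
    avg_risk = list(
      os5         = 0.85,
      hl_risk_xrt = 0.3900,
      hl_risk_pt  = 0.1555,
      dose_xrt_gy = 46.4,
      dose_pt_gy  = 29.3
    ),
    high_risk = list(
      os5         = 0.70,
      hl_risk_xrt = 0.4711,
      hl_risk_pt  = 0.2653,
      dose_xrt_gy = 50.0,
      dose_pt_gy  = 39.6
    ),
    p_high_risk        = 0.30,
    start_age          = 6,
    horizon_age        = 100,
    onset_start_year   = 1,
    onset_plateau_year = 3,
    utilities = list(
      "EQ-5D" = list(u_no_hl = 1.0, u_hl = 0.807),
      "HUI3"  = list(u_no_hl = 1.0, u_hl = 0.644),
      "SF-6D" = list(u_no_hl = 1.0, u_hl = 0.792)
    ),
    costs = list(
      c_xrt_course   = 3082.20,
      c_pt_course    = 26943.90,
      c_hearing_test = 65.4,
      c_fitting_test = 121.5,
      c_hearing_aid  = 2086.9,
      aid_lifetime   = 5
    ),
    econ = list(
      discount_rate     = 0.03,
      wtp               = 46729,
      jpy_per_usd       = 107.0,
      # span used for the one-way sensitivity analysis of the discount rate
      discount_sa_range = c(0, 0.07)
    ),
    ranges = list(
      os5_avg          = list(low = 0.75,   high = 0.94),
      os5_high         = list(low = 0.54,   high = 0.84),
      hl_risk_xrt_avg  = list(low = 0.3699, high = 0.4100),
      hl_risk_xrt_high = list(low = 0.4455, high = 0.4967),
      hl_risk_pt_avg   = list(low = 0.0497, high = 0.2612),
      hl_risk_pt_high  = list(low = 0.1836, high = 0.3471),
      p_high_risk      = list(low = 0.25,   high = 0.35),
      u_hl_eq5d        = list(low = 0.784,  high = 0.830),
      u_hl_hui3        = list(low = 0.626,  high = 0.663),
      u_hl_sf6d        = list(low = 0.779,  high = 0.804),
      c_xrt_course     = list(low = 2311.7,  high = 3852.8),
      c_pt_course      = list(low = 20207.9, high = 33679.9),
      c_hearing_aid    = list(low = 1565.2,  high = 2608.6),
      # no published interval: +/- 25% around the base value
      c_hearing_test   = list(low = 65.4 * 0.75,  high = 65.4 * 1.25),
      c_fitting_test   = list(low = 121.5 * 0.75, high = 121.5 * 1.25)
    )
  )
  class(p) <- c("cea_params", "list")
  p
}

#' Utility index names recognised by the model
#' @return Character vector `c("EQ-5D", "HUI3", "SF-6D")`.
#' @export
utility_indexes <- function() c("EQ-5D", "HUI3", "SF-6D")

# Accessors tying each named triangular range to its location in the
# parameter list.  Used by the tornado and probabilistic sensitivity
# analyses; `mode` of every triangular distribution is the current base
# value retrieved through `get`.
range_accessors <- function() {
  list(
    os5_avg = list(
      get = function(p) p$avg_risk$os5,
      set = function(p, v) { p$avg_risk$os5 <- v; p }),
    os5_high = list(
      get = function(p) p$high_risk$os5,
      set = function(p, v) { p$high_risk$os5 <- v; p }),
    hl_risk_xrt_avg = list(
      get = function(p) p$avg_risk$hl_risk_xrt,
      set = function(p, v) { p$avg_risk$hl_risk_xrt <- v; p }),
    hl_risk_xrt_high = list(
      get = function(p) p$high_risk$hl_risk_xrt,
      set = function(p, v) { p$high_risk$hl_risk_xrt <- v; p }),
    hl_risk_pt_avg = list(
      get = function(p) p$avg_risk$hl_risk_pt,
      set = function(p, v) { p$avg_risk$hl_risk_pt <- v; p }),
    hl_risk_pt_high = list(
      get = function(p) p$high_risk$hl_risk_pt,
      set = function(p, v) { p$high_risk$hl_risk_pt <- v; p }),
    p_high_risk = list(
      get = function(p) p$p_high_risk,
      set = function(p, v) { p$p_high_risk <- v; p }),
    u_hl_eq5d = list(
      get = function(p) p$utilities[["EQ-5D"]]$u_hl,
      set = function(p, v) { p$utilities[["EQ-5D"]]$u_hl <- v; p }),
    u_hl_hui3 = list(
      get = function(p) p$utilities[["HUI3"]]$u_hl,
      set = function(p, v) { p$utilities[["HUI3"]]$u_hl <- v; p }),
    u_hl_sf6d = list(
      get = function(p) p$utilities[["SF-6D"]]$u_hl,
      set = function(p, v) { p$utilities[["SF-6D"]]$u_hl <- v; p }),
    c_xrt_course = list(
      get = function(p) p$costs$c_xrt_course,
      set = function(p, v) { p$costs$c_xrt_course <- v; p }),
    c_pt_course = list(
      get = function(p) p$costs$c_pt_course,
      set = function(p, v) { p$costs$c_pt_course <- v; p }),
    c_hearing_aid = list(
      get = function(p) p$costs$c_hearing_aid,
      set = function(p, v) { p$costs$c_hearing_aid <- v; p }),
    c_hearing_test = list(
      get = function(p) p$costs$c_hearing_test,
      set = function(p, v) { p$costs$c_hearing_test <- v; p }),
    c_fitting_test = list(
      get = function(p) p$costs$c_fitting_test,
      set = function(p, v) { p$costs$c_fitting_test <- v; p })
  )
}

# map from utility index name to its u_hl range name
index_range_name <- function(index) {
  switch(index,
         "EQ-5D" = "u_hl_eq5d",
         "HUI3"  = "u_hl_hui3",
         "SF-6D" = "u_hl_sf6d",
         stop("unknown utility index: ", index))
}

fail_key <- function(key, msg) {
  stop("invalid parameter '", key, "': ", msg, call. = FALSE)
}

check_prob <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    fail_key(key, "must be a probability in [0, 1]")
}

check_nonneg <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    fail_key(key, "must be a non-negative number")
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of a `cea_params` object: probabilities
#' in \[0, 1\], non-negative doses and costs, start age before the horizon,
#' hearing-loss onset window ordered, utility weights ordered
#' `0 <= u_hl <= u_no_hl <= 1`, a proton hearing-loss risk below the X-ray
#' risk whenever the proton cochlear dose is lower, and every ranged
#' parameter's base value inside its `[low, high]` interval.  Errors name
#' the offending key.
#'
#' @param p A `cea_params` object.
#' @return `p`, invisibly, if all checks pass.
#' @export
validate_params <- function(p) {
  for (g in c("avg_risk", "high_risk")) {
    rg <- p[[g]]
    for (f in c("os5", "hl_risk_xrt", "hl_risk_pt"))
      check_prob(rg[[f]], paste(g, f, sep = "."))
    for (f in c("dose_xrt_gy", "dose_pt_gy"))
      check_nonneg(rg[[f]], paste(g, f, sep = "."))
    if (rg$dose_pt_gy < rg$dose_xrt_gy && rg$hl_risk_pt > rg$hl_risk_xrt)
      fail_key(paste(g, "hl_risk_pt", sep = "."),
               "must not exceed hl_risk_xrt when the proton dose is lower")
  }
  check_prob(p$p_high_risk, "p_high_risk")
  if (!(p$start_age < p$horizon_age))
    fail_key("start_age", "must be below horizon_age")
  if (p$onset_start_year < 0 || p$onset_plateau_year < p$onset_start_year)
    fail_key("onset_start_year", "onset window must satisfy 0 <= start <= plateau")
  for (ix in names(p$utilities)) {
    u <- p$utilities[[ix]]
    check_prob(u$u_no_hl, paste0("utilities.", ix, ".u_no_hl"))
    check_prob(u$u_hl, paste0("utilities.", ix, ".u_hl"))
    if (u$u_hl > u$u_no_hl)
      fail_key(paste0("utilities.", ix, ".u_hl"), "must not exceed u_no_hl")
  }
  for (f in names(p$costs)) check_nonneg(p$costs[[f]], paste0("costs.", f))
  if (p$costs$aid_lifetime < 1)
    fail_key("costs.aid_lifetime", "must be at least 1 year")
  check_nonneg(p$econ$discount_rate, "econ.discount_rate")
  if (!is.numeric(p$econ$wtp) || p$econ$wtp <= 0)
    fail_key("econ.wtp", "must be positive")
  acc <- range_accessors()
  for (nm in names(p$ranges)) {
    r <- p$ranges[[nm]]
    key <- paste0("ranges.", nm)
    if (is.null(acc[[nm]]))
      fail_key(key, "does not correspond to a known parameter")
    if (!is.numeric(r$low) || !is.numeric(r$high) || r$low > r$high)
      fail_key(key, "must satisfy low <= high")
    base <- acc[[nm]]$get(p)
    if (base < r$low || base > r$high)
      fail_key(key, sprintf("base value %g lies outside [%g, %g]",
                            base, r$low, r$high))
  }
  invisible(p)
}

# Recursive merge of a configuration list into the default structure.
# Unknown keys are an error (they are almost always typos and would
# silently leave the default in place).
merge_config <- function(base, cfg, path = character()) {
  for (nm in names(cfg)) {
    here <- paste(c(path, nm), collapse = ".")
    if (!nm %in% names(base))
      stop("unknown configuration key '", here, "'", call. = FALSE)
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(cfg[[nm]]))
        stop("configuration key '", here, "' must be a mapping", call. = FALSE)
      base[[nm]] <- merge_config(base[[nm]], cfg[[nm]], c(path, nm))
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a YAML file whose keys mirror the structure of [default_params()]
#' (e.g. `avg_risk: {os5: 0.85}`, `costs: {c_hearing_aid: 2086.9}`).  Keys
#' that are absent fall back to the shipped defaults; unknown keys raise an
#' error naming the key, and the merged set is validated before being
#' returned.  An empty file yields the defaults unchanged.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `cea_params` object.
#' @seealso [save_params()], [default_params()]
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  p <- default_params()
  if (!is.null(cfg)) {
    if (!is.list(cfg)) stop("configuration must be a YAML mapping")
    p <- merge_config(unclass(p), cfg)
    class(p) <- c("cea_params", "list")
  }
  validate_params(p)
  p
}

#' Save model parameters to a YAML configuration file
#'
#' Writes the full parameter set as YAML at high numeric precision so that
#' [load_params()] reads back an identical object.
#'
#' @param p A `cea_params` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_params <- function(p, path) {
  validate_params(p)
  txt <- yaml::as.yaml(unclass(p), precision = 17L)
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) stop("cannot write configuration file: ", path)
  invisible(path)
}

#' Dump a parameter set as normalized JSON
#'
#' Provenance helper: emits the resolved parameter set as pretty-printed
#' JSON, written alongside every analysis output so a run can be audited.
#'
#' @param p A `cea_params` object.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
params_to_json <- function(p, path) {
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.cea_params <- function(x, ...) {
  cat("Cost-utility model parameters\n")
  cat(sprintf("  Cohort: start age %d, horizon age %d, %.0f%% high-risk\n",
              x$start_age, x$horizon_age, 100 * x$p_high_risk))
  cat(sprintf("  5-year OS: average %.2f, high %.2f\n",
              x$avg_risk$os5, x$high_risk$os5))
  cat(sprintf("  Grade 3-4 hearing-loss risk (XRT): %.4f / %.4f\n",
              x$avg_risk$hl_risk_xrt, x$high_risk$hl_risk_xrt))
  cat(sprintf("  Grade 3-4 hearing-loss risk (PT):  %.4f / %.4f\n",
              x$avg_risk$hl_risk_pt, x$high_risk$hl_risk_pt))
  us <- vapply(x$utilities, function(u) u$u_hl, 0)
  cat("  Utility with hearing loss (aided): ",
      paste(sprintf("%s %.3f", names(us), us), collapse = ", "), "\n", sep = "")
  cat(sprintf("  Costs: XRT $%.2f, PT $%.2f, aid $%.1f (replaced every %d y)\n",
              x$costs$c_xrt_course, x$costs$c_pt_course,
              x$costs$c_hearing_aid, x$costs$aid_lifetime))
  cat(sprintf("  Discount %.0f%%, WTP $%s/QALY\n",
              100 * x$econ$discount_rate,
              format(x$econ$wtp, big.mark = ",")))
  invisible(x)
}
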