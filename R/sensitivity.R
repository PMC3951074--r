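#' Draw from a triangular distribution
#'
#' Inverse-CDF sampling from `Triangular(low, mode, high)`, the
#' distribution used for every uncertain parameter in the probabilistic
#' sensitivity analysis.  Degenerate ranges (`low == high`) return the
#' mode with probability 1.
#'
#' @param n Number of draws.
#' @param low,mode,high Distribution parameters, `low <= mode <= high`.
#' @return Numeric vector of `n` draws, all inside `[low, high]`.
#' @export
sample_triangular <- function(n, low, mode, high) {
  if (low > mode || mode > high)
    stop("triangular distribution needs low <= mode <= high")
  u <- stats::runif(n)
  w <- high - low
  if (w == 0) return(rep(mode, n))
  fc <- (mode - low) / w
  ifelse(u < fc,
         low + sqrt(u * w * (mode - low)),
         high - sqrt((1 - u) * w * (high - mode)))
}

# parameters varied in the tornado diagram, in addition to the discount
# rate (whose one-way span lives in econ$discount_sa_range)
tornado_param_names <- function(utility_index) {
  c("os5_avg", "os5_high",
    "hl_risk_xrt_avg", "hl_risk_xrt_high",
    "hl_risk_pt_avg", "hl_risk_pt_high",
    "p_high_risk", index_range_name(utility_index),
    "c_xrt_course", "c_pt_course", "c_hearing_aid")
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the ICER with each uncertain parameter set to the low and
#' high end of its range while all others stay at base: both 5-year
#' survivals, the four hearing-loss risks, the high-risk share, the
#' index's utility weight, both radiation course costs, the hearing-aid
#' price, and the discount rate (varied over 0-7%).  Entries are sorted
#' by descending ICER spread.
#'
#' @param params A `cea_params` object.
#' @param life_table A `life_table`.
#' @param utility_index Utility index whose ICER is analysed.
#' @return A `cea_tornado` data frame with columns `parameter`, `low`,
#'   `high`, `icer_at_low`, `icer_at_high`, `spread`; the base-case ICER
#'   is attached as attribute `base_icer`.
#' @export
one_way <- function(params, life_table,
                    utility_index = c("EQ-5D", "HUI3", "SF-6D")) {
  utility_index <- match.arg(utility_index)
  validate_params(params)
  acc <- range_accessors()
  base <- compute_ce(params, life_table, utility_index)
  icer_for <- function(p) compute_ce(p, life_table, utility_index)$icer
  rows <- lapply(tornado_param_names(utility_index), function(nm) {
    r <- params$ranges[[nm]]
    if (is.null(r)) stop("no range defined for parameter '", nm, "'")
    data.frame(parameter = nm, low = r$low, high = r$high,
               icer_at_low = icer_for(acc[[nm]]$set(params, r$low)),
               icer_at_high = icer_for(acc[[nm]]$set(params, r$high)))
  })
  dr <- params$econ$discount_sa_range
  disc_at <- function(r0) {
    p <- params; p$econ$discount_rate <- r0
    icer_for(p)
  }
  rows <- c(rows, list(data.frame(parameter = "discount_rate",
                                  low = dr[1], high = dr[2],
                                  icer_at_low = disc_at(dr[1]),
                                  icer_at_high = disc_at(dr[2]))))
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$icer
  attr(out, "utility_index") <- utility_index
  class(out) <- c("cea_tornado", "data.frame")
  out
}

#' Plot a tornado diagram
#'
#' @param x A `cea_tornado` object.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.cea_tornado <- function(x, ...) {
  n <- nrow(x)
  ord <- rev(seq_len(n))   # widest bar on top
  lo <- pmin(x$icer_at_low, x$icer_at_high)
  hi <- pmax(x$icer_at_low, x$icer_at_high)
  graphics::plot(NULL, xlim = range(lo, hi, attr(x, "base_icer")),
                 ylim = c(0.5, n + 0.5), yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "",
                 main = sprintf("One-way sensitivity (%s)",
                                attr(x, "utility_index")))
  graphics::rect(lo[ord], seq_len(n) - 0.35, hi[ord], seq_len(n) + 0.35,
                 col = "steelblue")
  graphics::abline(v = attr(x, "base_icer"), lty = 2)
  graphics::axis(2, at = seq_len(n), labels = x$parameter[ord], las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: all ranged
#' parameters (survival, hearing-loss risks, risk-group share, the three
#' utility weights, and the five cost items) are drawn jointly and
#' independently from their triangular distributions, and the full model
#' is re-evaluated for every draw.  By default the discount rate is drawn
#' as well, Triangular(0, 0.03, 0.07) over its studied span: the
#' acceptability probabilities only spread to their expected levels when
#' discounting uncertainty is propagated with everything else, so "all
#' variables fluctuating simultaneously" is taken to include it (set
#' `vary_discount = FALSE` to hold it at base).  Draws in which
#' a proton hearing-loss risk exceeds the corresponding X-ray risk are
#' retained as drawn (the parameters are sampled independently) and
#' flagged in the output.
#'
#' A single seed controls the whole sample; identical seeds give
#' bitwise-identical results.
#'
#' @param params A `cea_params` object.
#' @param life_table A `life_table`.
#' @param n Number of Monte Carlo draws (default 10,000).
#' @param seed Integer seed.
#' @param indices Utility indexes to evaluate per draw.
#' @param vary_discount Also draw the discount rate (default `TRUE`).
#' @return An object of class `cea_psa`: list with `draws` (one row per
#'   draw: the sampled parameter values and a `risk_order_flag`),
#'   `results` (one row per draw and index: `delta_cost`, `delta_qaly`),
#'   `base` (base-case `ce_result` per index), `n`, `seed`, `indices`.
#' @export
run_psa <- function(params, life_table, n = 10000, seed = 1L,
                    indices = utility_indexes(), vary_discount = TRUE) {
  if (n < 1) stop("n must be >= 1")
  indices <- match.arg(indices, utility_indexes(), several.ok = TRUE)
  validate_params(params)
  acc <- range_accessors()
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)

  rng_names <- names(params$ranges)
  draws <- as.data.frame(lapply(rng_names, function(nm) {
    r <- params$ranges[[nm]]
    sample_triangular(n, r$low, acc[[nm]]$get(params), r$high)
  }))
  names(draws) <- rng_names
  if (vary_discount) {
    dr <- params$econ$discount_sa_range
    draws$discount_rate <- sample_triangular(n, dr[1],
                                             params$econ$discount_rate, dr[2])
  }
  draws$risk_order_flag <-
    (draws$hl_risk_pt_avg > draws$hl_risk_xrt_avg) |
    (draws$hl_risk_pt_high > draws$hl_risk_xrt_high)

  life_q <- stats::setNames(life_table$qx, life_table$age)
  base_mort <- mortality_schedule(params, life_table)

  dc <- numeric(n)
  dq <- matrix(0, n, length(indices), dimnames = list(NULL, indices))
  for (i in seq_len(n)) {
    p <- params
    for (nm in rng_names) p <- acc[[nm]]$set(p, draws[[nm]][i])
    if (vary_discount) p$econ$discount_rate <- draws$discount_rate[i]
    mort <- base_mort
    mort$qd <- c(average = disease_hazard_from_os5(p$avg_risk$os5),
                 high    = disease_hazard_from_os5(p$high_risk$os5))
    eng <- ce_engine(p, mort)
    dc[i] <- unname(eng$cost[["PT"]] - eng$cost[["XRT"]])
    for (ix in indices) {
      u <- p$utilities[[ix]]
      dq[i, ix] <- engine_qalys(eng, "PT", u) - engine_qalys(eng, "XRT", u)
    }
  }

  results <- do.call(rbind, lapply(indices, function(ix)
    data.frame(draw = seq_len(n), index = ix, delta_cost = dc,
               delta_qaly = dq[, ix])))
  rownames(results) <- NULL
  base <- stats::setNames(
    lapply(indices, function(ix) compute_ce(params, life_table, ix)), indices)
  structure(list(draws = cbind(draw = seq_len(n), draws), results = results,
                 base = base, n = n, seed = seed, indices = indices),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws, seed %d\n",
              x$n, x$seed))
  for (ix in x$indices) {
    r <- x$results[x$results$index == ix, ]
    cat(sprintf("  %-6s mean dCost $%.0f, mean dQALY %.3f\n",
                ix, mean(r$delta_cost), mean(r$delta_qaly)))
  }
  nf <- sum(x$draws$risk_order_flag)
  cat(sprintf("  %d draw%s with proton risk above X-ray risk (flagged)\n",
              nf, if (nf == 1) "" else "s"))
  invisible(x)
}

#' Long-format PSA sample table
#'
#' @param x A `cea_psa` object.
#' @param ... Unused.
#' @return One row per draw and utility index: the drawn parameter
#'   values, the flag, and the incremental outcomes.
#' @export
as.data.frame.cea_psa <- function(x, ...) {
  merge(x$results, x$draws, by = "draw", sort = FALSE)
}

#' Plot PSA draws on the cost-effectiveness plane
#'
#' @param x A `cea_psa` object.
#' @param wtp Threshold line slope.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cea_psa <- function(x, wtp = 46729, ...) {
  cols <- stats::setNames(seq_along(x$indices) + 1, x$indices)
  graphics::plot(x$results$delta_qaly, x$results$delta_cost,
                 col = grDevices::adjustcolor(cols[x$results$index], 0.25),
                 pch = 16, cex = 0.4,
                 xlab = "Incremental QALYs (PT - XRT)",
                 ylab = "Incremental cost (USD)",
                 main = "PSA scatter, cost-effectiveness plane", ...)
  graphics::abline(0, wtp, lty = 2)
  graphics::legend("topleft", legend = x$indices, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value on a grid, the fraction of PSA draws
#' whose net monetary benefit `wtp * delta_qaly - delta_cost` is strictly
#' positive, per utility index and for all indexes pooled with equal
#' weight (scope `"integrated"`).
#'
#' @param samples A `cea_psa` object.
#' @param wtp Willingness-to-pay grid (default $0-150,000/QALY in $1,000
#'   steps).
#' @param threshold WTP value guaranteed to appear in the grid; appended
#'   if missing (default the $46,729/QALY decision threshold).
#' @return A `cea_ceac` data frame with columns `scope`, `wtp`,
#'   `p_cost_effective`.
#' @export
ceac <- function(samples, wtp = seq(0, 150000, by = 1000), threshold = 46729) {
  if (!inherits(samples, "cea_psa")) stop("samples must be a cea_psa object")
  if (nrow(samples$results) == 0L) stop("empty sample list")
  wtp <- sort(unique(c(wtp, threshold)))
  scopes <- c(samples$indices,
              if (length(samples$indices) > 1) "integrated")
  rows <- lapply(scopes, function(sc) {
    r <- if (sc == "integrated") samples$results
         else samples$results[samples$results$index == sc, ]
    p <- vapply(wtp, function(w)
      mean(w * r$delta_qaly - r$delta_cost > 0), 0)
    data.frame(scope = sc, wtp = wtp, p_cost_effective = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cea_ceac", "data.frame")
  out
}

#' Acceptability probability at one threshold
#'
#' @param curve A `cea_ceac` object.
#' @param scope Scope name (an index or `"integrated"`).
#' @param wtp Threshold; must be on the curve's grid.
#' @return The probability of cost-effectiveness at `wtp`.
#' @export
ceac_at <- function(curve, scope, wtp = 46729) {
  hit <- curve$scope == scope & curve$wtp == wtp
  if (!any(hit)) stop("wtp ", wtp, " not on the grid for scope ", scope)
  curve$p_cost_effective[hit][1]
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x A `cea_ceac` object.
#' @param threshold Vertical reference line (default $46,729/QALY).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.cea_ceac <- function(x, threshold = 46729, ...) {
  scopes <- unique(x$scope)
  graphics::plot(NULL, xlim = range(x$wtp), ylim = c(0, 1),
                 xlab = "Willingness to pay (USD/QALY)",
                 ylab = "P(proton therapy cost-effective)",
                 main = "Cost-effectiveness acceptability curves")
  for (i in seq_along(scopes)) {
    sub <- x[x$scope == scopes[i], ]
    graphics::lines(sub$wtp, sub$p_cost_effective, col = i + 1, lwd = 2,
                    lty = if (scopes[i] == "integrated") 1 else 2)
  }
  graphics::abline(v = threshold, lty = 3)
  graphics::legend("bottomright", legend = scopes,
                   col = seq_along(scopes) + 1, lwd = 2, bty = "n")
  invisible(x)
}
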