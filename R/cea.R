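#' Fit the full cost-utility model
#'
#' The package's central function: evaluates the lifetime Markov cohort
#' model for both treatment arms and returns the cost-effectiveness
#' comparison under each requested utility index, together with the mixed
#' state traces.  Methods for `print`, `summary`, `plot`, `simulate`
#' (probabilistic sensitivity analysis) and `as.data.frame` are provided.
#'
#' @param params A `cea_params` object (default [default_params()]).
#' @param life_table A `life_table` (default the bundled synthetic table).
#' @param indices Utility indexes to evaluate.
#' @return An object of class `cea`: list with `results` (named list of
#'   `ce_result`), `traces` (mixed `state_trace` per arm), `params`,
#'   `life_table`.
#' @examples
#' fit <- cea()
#' fit
#' summary(fit)
#' @export
cea <- function(params = default_params(),
                life_table = synthetic_lifetable(),
                indices = utility_indexes()) {
  indices <- match.arg(indices, utility_indexes(), several.ok = TRUE)
  validate_params(params)
  mort <- mortality_schedule(params, life_table)
  eng <- ce_engine(params, mort)
  results <- lapply(indices, function(ix) {
    u <- params$utilities[[ix]]
    qx <- engine_qalys(eng, "XRT", u)
    qp <- engine_qalys(eng, "PT", u)
    dq <- qp - qx
    dc <- unname(eng$cost[["PT"]] - eng$cost[["XRT"]])
    structure(list(cost_xrt = unname(eng$cost[["XRT"]]),
                   cost_pt = unname(eng$cost[["PT"]]),
                   qaly_xrt = qx, qaly_pt = qp,
                   delta_cost = dc, delta_qaly = dq,
                   icer = if (dq != 0) dc / dq else NA_real_,
                   icer_defined = dq != 0,
                   utility_index = ix),
              class = "ce_result")
  })
  names(results) <- indices
  structure(list(results = results, traces = eng$traces, params = params,
                 life_table = life_table),
            class = "cea")
}

#' Tabulate a fitted cost-utility model
#'
#' @param x A `cea` object.
#' @param ... Unused.
#' @return Data frame with one row per utility index and arm: `index`,
#'   `arm`, `cost`, `qaly`, `delta_cost`, `delta_qaly`, `icer` (the
#'   incremental columns are repeated on both rows of an index).
#' @export
as.data.frame.cea <- function(x, ...) {
  rows <- lapply(x$results, function(r)
    data.frame(index = r$utility_index,
               arm = c("PT", "XRT"),
               cost = c(r$cost_pt, r$cost_xrt),
               qaly = c(r$qaly_pt, r$qaly_xrt),
               delta_cost = r$delta_cost,
               delta_qaly = r$delta_qaly,
               icer = r$icer))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cea <- function(x, ...) {
  cat("Markov cohort cost-utility analysis: proton vs X-ray radiotherapy\n")
  cat(sprintf("  cohort age %d-%d, discount %.0f%%\n\n",
              x$params$start_age, x$params$horizon_age,
              100 * x$params$econ$discount_rate))
  df <- as.data.frame(x)
  df$cost <- sprintf("$%.2f", df$cost)
  df$qaly <- sprintf("%.2f", df$qaly)
  df$delta_cost <- sprintf("%.0f", df$delta_cost)
  df$delta_qaly <- sprintf("%.2f", df$delta_qaly)
  df$icer <- ifelse(is.na(df$icer), "undefined", sprintf("%.0f", df$icer))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cea <- function(object, wtp = object$params$econ$wtp, ...) {
  out <- list(table = as.data.frame(object), wtp = wtp,
              nmb = vapply(object$results, net_monetary_benefit, 0,
                           wtp = wtp),
              undiscounted_le = sum(1 - object$traces$XRT$p_dead[-1]))
  class(out) <- "summary.cea"
  out
}

#' @export
print.summary.cea <- function(x, ...) {
  df <- x$table
  df$cost <- round(df$cost, 2); df$qaly <- round(df$qaly, 3)
  df$delta_cost <- round(df$delta_cost, 2)
  df$delta_qaly <- round(df$delta_qaly, 3); df$icer <- round(df$icer)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("\nNet monetary benefit at WTP $%s/QALY:\n",
              format(x$wtp, big.mark = ",")))
  for (ix in names(x$nmb))
    cat(sprintf("  %-6s $%.0f (%s)\n", ix, x$nmb[[ix]],
                if (x$nmb[[ix]] > 0) "cost-effective" else "not cost-effective"))
  cat(sprintf("Undiscounted expected life years after treatment: %.1f\n",
              x$undiscounted_le))
  invisible(x)
}

#' Plot a fitted cost-utility model
#'
#' Draws the incremental cost-effectiveness plane: one point per utility
#' index at (QALY gain, extra cost), with the willingness-to-pay threshold
#' as a dashed line through the origin.
#'
#' @param x A `cea` object.
#' @param wtp Willingness-to-pay threshold drawn as a line.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cea <- function(x, wtp = x$params$econ$wtp, ...) {
  dq <- vapply(x$results, `[[`, 0, "delta_qaly")
  dc <- vapply(x$results, `[[`, 0, "delta_cost")
  graphics::plot(dq, dc, pch = 19, col = seq_along(dq) + 1,
                 xlim = range(0, dq * 1.15), ylim = range(0, dc * 1.15),
                 xlab = "Incremental QALYs (PT - XRT)",
                 ylab = "Incremental cost (USD)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(0, wtp, lty = 2)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::text(dq, dc, names(x$results), pos = 3, cex = 0.8)
  invisible(x)
}

#' Probabilistic sensitivity analysis as a simulation method
#'
#' `simulate()` on a fitted model delegates to [run_psa()], drawing all
#' ranged parameters from their triangular distributions.
#'
#' @param object A `cea` object.
#' @param nsim Number of Monte Carlo draws.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Passed to [run_psa()].
#' @return A `cea_psa` object.
#' @export
simulate.cea <- function(object, nsim = 10000, seed = 1L, ...) {
  run_psa(object$params, object$life_table, n = nsim, seed = seed, ...)
}
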