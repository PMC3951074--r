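#' Present-value discount factor
#'
#' @param t Time in years (vectorised, `>= 0`).
#' @param r Annual discount rate (`>= 0`); the base case uses 3%.
#' @return `(1 + r)^(-t)`.
#' @export
discount_factor <- function(t, r) {
  if (any(t < 0)) stop("t must be >= 0")
  if (r < 0) stop("r must be >= 0")
  (1 + r)^(-t)
}

#' Discounted quality-adjusted life years of a trace
#'
#' Accrues, at the end of every cycle `t >= 1`, the utility-weighted alive
#' occupancy `p_no_hl * u_no_hl + p_hl * u_hl`, discounted to present
#' value.  Cycle 0 (the treatment year start) carries no reward; there is
#' no half-cycle correction.
#'
#' @param trace A `state_trace`.
#' @param u A utility pair: list with `u_no_hl` and `u_hl`.
#' @param r Annual discount rate.
#' @return Discounted QALYs.
#' @export
discounted_qalys <- function(trace, u, r) {
  tt <- trace$t[trace$t >= 1]
  rows <- trace$t >= 1
  sum(discount_factor(tt, r) *
        (trace$p_no_hl[rows] * u$u_no_hl + trace$p_hl[rows] * u$u_hl))
}

#' Discounted lifetime costs of a trace
#'
#' Payer-perspective direct medical costs: the radiation course at `t = 0`
#' (undiscounted), and for each cohort of incident hearing-loss cases a
#' hearing test, a hearing-aid fitting test and a hearing aid at the onset
#' cycle, an annual hearing test in each of the following two years (paid
#' by members still alive), and a replacement hearing aid every
#' `aid_lifetime` years after onset for as long as members are alive.
#' Survival scaling of the deferred payments uses the trace's alive mass,
#' which is valid because mortality is state independent.
#'
#' @param trace A single-group `state_trace`.
#' @param onset_by_cycle Mass of new hearing-loss cases per cycle, aligned
#'   with `trace$t` (see [onset_mass()]).
#' @param costs The `costs` component of a `cea_params` object.
#' @param arm `"XRT"` or `"PT"` (selects the radiation course price).
#' @param r Annual discount rate.
#' @return Discounted cost in USD.
#' @export
discounted_costs <- function(trace, onset_by_cycle, costs,
                             arm = c("XRT", "PT"), r) {
  arm <- match.arg(arm)
  upfront <- if (arm == "XRT") costs$c_xrt_course else costs$c_pt_course
  n <- nrow(trace) - 1L               # last cycle index
  alive <- 1 - trace$p_dead           # indexed by t = 0..n at position t+1
  disc <- discount_factor(trace$t, r)
  total <- upfront
  for (s in which(onset_by_cycle > 0) - 1L) {
    m <- onset_by_cycle[s + 1L]
    # incidence fraction of the initial cohort; deferred payments are paid
    # by the members of this onset cohort still alive at the payment cycle
    frac <- if (alive[s + 1L] > 0) m / alive[s + 1L] else 0
    total <- total +
      (costs$c_hearing_test + costs$c_fitting_test + costs$c_hearing_aid) *
      m * disc[s + 1L]
    for (k in (s + 1):(s + 2)) {
      if (k <= n)
        total <- total + costs$c_hearing_test * frac * alive[k + 1L] * disc[k + 1L]
    }
    k <- s + costs$aid_lifetime
    while (k <= n) {
      total <- total + costs$c_hearing_aid * frac * alive[k + 1L] * disc[k + 1L]
      k <- k + costs$aid_lifetime
    }
  }
  total
}

# run both arms of the model once and price everything that does not
# depend on the utility index; shared by compute_ce() and run_psa()
ce_engine <- function(params, mort, r = params$econ$discount_rate) {
  w <- c(average = 1 - params$p_high_risk, high = params$p_high_risk)
  groups <- c("average", "high")
  out <- list(qaly_parts = list(), cost = c(XRT = 0, PT = 0), w = w)
  tt <- NULL
  for (arm in c("XRT", "PT")) {
    field <- if (arm == "XRT") "hl_risk_xrt" else "hl_risk_pt"
    arm_cost <- 0
    parts <- list()
    for (g in groups) {
      rg <- if (g == "average") params$avg_risk else params$high_risk
      sp <- arm_spec(arm, g, hl_lifetime_risk = rg[[field]], os5 = rg$os5)
      tr <- run_cohort(sp, mort, params)
      om <- onset_mass(tr)
      arm_cost <- arm_cost + w[[g]] *
        discounted_costs(tr, om, params$costs, arm, r)
      parts[[g]] <- tr
    }
    out$cost[[arm]] <- arm_cost
    out$qaly_parts[[arm]] <- parts
  }
  out$traces <- lapply(out$qaly_parts, function(parts)
    mix_cohorts(unname(parts[groups]), unname(w[groups])))
  out$discount <- r
  out
}

# discounted QALYs for one arm of an engine result under one utility pair
engine_qalys <- function(eng, arm, u, r = eng$discount) {
  parts <- eng$qaly_parts[[arm]]
  sum(vapply(names(parts), function(g)
    eng$w[[g]] * discounted_qalys(parts[[g]], u, r), 0))
}

#' Base-case cost-effectiveness result for one utility index
#'
#' Runs both treatment arms (each a 70/30 mix of the average- and
#' high-risk groups), accrues discounted costs and QALYs, and returns the
#' incremental comparison of proton beam therapy against X-ray
#' radiotherapy.  The ICER is computed from unrounded differences; when
#' the QALY difference is zero it is flagged undefined.
#'
#' @param params A `cea_params` object.
#' @param life_table A `life_table` for background mortality.
#' @param utility_index One of `"EQ-5D"`, `"HUI3"`, `"SF-6D"`.
#' @return An object of class `ce_result`: list with `cost_xrt`,
#'   `cost_pt`, `qaly_xrt`, `qaly_pt`, `delta_cost`, `delta_qaly`, `icer`,
#'   `icer_defined` and `utility_index`.
#' @examples
#' res <- compute_ce(default_params(), synthetic_lifetable(), "EQ-5D")
#' res$icer
#' @export
compute_ce <- function(params, life_table,
                       utility_index = c("EQ-5D", "HUI3", "SF-6D")) {
  utility_index <- match.arg(utility_index)
  validate_params(params)
  mort <- mortality_schedule(params, life_table)
  eng <- ce_engine(params, mort)
  u <- params$utilities[[utility_index]]
  qx <- engine_qalys(eng, "XRT", u)
  qp <- engine_qalys(eng, "PT", u)
  dq <- qp - qx
  dc <- unname(eng$cost[["PT"]] - eng$cost[["XRT"]])
  res <- list(cost_xrt = unname(eng$cost[["XRT"]]),
              cost_pt = unname(eng$cost[["PT"]]),
              qaly_xrt = qx, qaly_pt = qp,
              delta_cost = dc, delta_qaly = dq,
              icer = if (dq != 0) dc / dq else NA_real_,
              icer_defined = dq != 0,
              utility_index = utility_index)
  class(res) <- "ce_result"
  res
}

#' Net monetary benefit of the proton arm
#'
#' `wtp * delta_qaly - delta_cost`; positive values mean proton therapy is
#' cost-effective at that willingness-to-pay threshold.
#'
#' @param res A `ce_result`.
#' @param wtp Willingness to pay in USD per QALY.
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(res, wtp) {
  wtp * res$delta_qaly - res$delta_cost
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness result (%s)\n", x$utility_index))
  cat(sprintf("  proton:  cost $%10.2f  QALY %7.3f\n", x$cost_pt, x$qaly_pt))
  cat(sprintf("  X-ray:   cost $%10.2f  QALY %7.3f\n", x$cost_xrt, x$qaly_xrt))
  cat(sprintf("  delta:   cost $%10.2f  QALY %7.3f\n", x$delta_cost,
              x$delta_qaly))
  if (x$icer_defined) {
    cat(sprintf("  ICER: $%.0f per QALY gained\n", x$icer))
  } else {
    cat("  ICER undefined (zero QALY difference); dominance applies\n")
  }
  invisible(x)
}
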