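#' Cumulative hearing-loss incidence schedule
#'
#' Cumulative incidence of Grade 3-4 hearing loss among survivors as a
#' function of years since treatment: zero before `onset_start`, rising in
#' equal cumulative increments over cycles `onset_start` to
#' `onset_plateau`, and equal to the lifetime risk from the plateau onward
#' (hearing loss appears one year after treatment and plateaus from the
#' third year in the default configuration).
#'
#' @param t Cycle index (years since treatment), vectorised, `>= 0`.
#' @param lifetime_risk Lifetime Grade 3-4 hearing-loss risk in \[0, 1\].
#' @param onset_start First cycle with incident cases.
#' @param onset_plateau Cycle at which cumulative incidence reaches the
#'   lifetime risk.
#' @return Cumulative incidence among survivors at each `t`.
#' @export
cumulative_onset <- function(t, lifetime_risk, onset_start = 1,
                             onset_plateau = 3) {
  if (any(t < 0)) stop("t must be >= 0")
  if (lifetime_risk < 0 || lifetime_risk > 1)
    stop("lifetime_risk must lie in [0, 1]")
  width <- onset_plateau - onset_start + 1
  lifetime_risk * pmin(pmax(t - onset_start + 1, 0) / width, 1)
}

#' Per-cycle conditional hearing-loss conversion probability
#'
#' The conditional probability that a surviving, so-far-unaffected cohort
#' member converts to the hearing-loss state during cycle `t`, chosen so
#' that cumulative incidence among survivors follows
#' [cumulative_onset()]: equal cumulative increments between `onset_start`
#' and `onset_plateau`, then no further conversions.
#'
#' @inheritParams cumulative_onset
#' @return Conditional conversion probability at each `t`.
#' @examples
#' # 0.39 lifetime risk over the default window: cumulative 0.13/0.26/0.39
#' onset_fraction(1:4, 0.39)
#' @export
onset_fraction <- function(t, lifetime_risk, onset_start = 1,
                           onset_plateau = 3) {
  cum  <- cumulative_onset(t, lifetime_risk, onset_start, onset_plateau)
  prev <- cumulative_onset(pmax(t - 1, 0), lifetime_risk, onset_start,
                           onset_plateau)
  ifelse(prev >= 1, 0, (cum - prev) / (1 - prev))
}

#' Arm/risk-group specification for a cohort run
#'
#' @param arm `"XRT"` or `"PT"`.
#' @param risk_group `"average"` or `"high"`.
#' @param hl_lifetime_risk Lifetime Grade 3-4 hearing-loss risk.
#' @param os5 5-year overall survival.
#' @return An `arm_spec` list.
#' @export
arm_spec <- function(arm = c("XRT", "PT"), risk_group = c("average", "high"),
                     hl_lifetime_risk, os5) {
  arm <- match.arg(arm)
  risk_group <- match.arg(risk_group)
  if (hl_lifetime_risk < 0 || hl_lifetime_risk > 1)
    stop("hl_lifetime_risk must lie in [0, 1]")
  structure(list(arm = arm, risk_group = risk_group,
                 hl_lifetime_risk = hl_lifetime_risk, os5 = os5),
            class = "arm_spec")
}

# internal constructor for a state trace data frame
new_state_trace <- function(t, age, p_no_hl, p_hl, p_dead) {
  tr <- data.frame(t = t, age = age, p_no_hl = p_no_hl, p_hl = p_hl,
                   p_dead = p_dead)
  class(tr) <- c("state_trace", "data.frame")
  tr
}

#' Run the three-state cohort model for one arm and risk group
#'
#' Annual-cycle Markov cohort model over the states alive-without-hearing-
#' loss, alive-with-hearing-loss and dead, from the treatment age to the
#' model horizon.  Each cycle applies the annual death probability (state
#' independent: hearing loss does not alter survival) and then converts a
#' fraction of the surviving unaffected members to the hearing-loss state
#' per [onset_fraction()].  Death is absorbing.  Because mortality is
#' state independent the recursion telescopes to the closed form
#' `p_alive(t) = prod(1 - q)` and `p_hl(t) = p_alive(t) * cum(t)`, which is
#' what is computed (a test verifies equality with the explicit
#' transition-matrix recursion).
#'
#' @param spec An [arm_spec()].
#' @param mort A [mortality_schedule()].
#' @param params A `cea_params` object (supplies ages and onset window).
#' @return A `state_trace` data frame with columns `t`, `age`, `p_no_hl`,
#'   `p_hl`, `p_dead`; row `t = 0` is `(1, 0, 0)`.
#' @export
run_cohort <- function(spec, mort, params) {
  n <- params$horizon_age - params$start_age
  tt <- seq_len(n)
  q <- death_prob_vector(mort, spec$risk_group, tt)
  S <- cumprod(1 - q)
  cum <- cumulative_onset(tt, spec$hl_lifetime_risk,
                          params$onset_start_year, params$onset_plateau_year)
  new_state_trace(t = c(0L, tt), age = params$start_age + c(0L, tt),
                  p_no_hl = c(1, S * (1 - cum)),
                  p_hl = c(0, S * cum),
                  p_dead = c(0, 1 - S))
}

#' Mix state traces across risk groups
#'
#' Cycle-wise convex combination of traces, used to blend the average-risk
#' (70%) and high-risk (30%) groups into one arm-level cohort.
#'
#' @param traces List of `state_trace` objects of equal length.
#' @param weights Non-negative weights summing to 1.
#' @return The mixed `state_trace`.
#' @export
mix_cohorts <- function(traces, weights) {
  if (length(traces) != length(weights))
    stop("need one weight per trace")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  nr <- vapply(traces, nrow, 0L)
  if (length(unique(nr)) != 1L) stop("traces have mismatched lengths")
  out <- traces[[1]]
  for (col in c("p_no_hl", "p_hl", "p_dead")) {
    acc <- 0
    for (i in seq_along(traces)) acc <- acc + weights[i] * traces[[i]][[col]]
    out[[col]] <- acc
  }
  out
}

#' Per-cycle mass of new hearing-loss cases
#'
#' Mass (as a fraction of the initial cohort) entering the hearing-loss
#' state at each cycle, recovered from a single-group trace under
#' state-independent mortality.
#'
#' @param trace A `state_trace` for one risk group.
#' @return Numeric vector aligned with `trace$t`; zero at `t = 0`.
#' @export
onset_mass <- function(trace) {
  alive <- 1 - trace$p_dead
  prev_alive <- c(1, alive[-length(alive)])
  prev_hl <- c(0, trace$p_hl[-length(alive)])
  surv_ratio <- ifelse(prev_alive > 0, alive / prev_alive, 0)
  m <- trace$p_hl - prev_hl * surv_ratio
  # suppress floating-point residue at cycles with no true incidence
  m[m < 1e-13] <- 0
  m
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("State trace: %d annual cycles, ages %d-%d\n",
              nrow(x) - 1L, min(x$age), max(x$age)))
  cat(sprintf("  final occupancy: no-HL %.4f, HL %.4f, dead %.4f\n",
              x$p_no_hl[nrow(x)], x$p_hl[nrow(x)], x$p_dead[nrow(x)]))
  print.data.frame(utils::head(x, 4))
  if (nrow(x) > 4L) cat("  ... (", nrow(x) - 4L, " more cycles)\n", sep = "")
  invisible(x)
}
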