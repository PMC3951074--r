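test_that("the onset schedule climbs in equal cumulative increments to the lifetime risk", {
  expect_equal(onset_fraction(0:20, 0), rep(0, 21))
  # direct recursion oracle: apply the conditional probabilities and check
  # the cumulative incidence they generate
  h <- onset_fraction(1:6, 0.39, 1, 3)
  not_yet <- 1; cum <- numeric(6)
  for (t in 1:6) {
    cum[t] <- (if (t == 1) 0 else cum[t - 1]) + not_yet * h[t]
    not_yet <- not_yet * (1 - h[t])
  }
  expect_equal(cum, c(0.13, 0.26, 0.39, 0.39, 0.39, 0.39), tolerance = 1e-12)
  expect_equal(cumulative_onset(0:5, 0.39), c(0, 0.13, 0.26, 0.39, 0.39, 0.39),
               tolerance = 1e-12)
  # step window: all risk converts in one cycle
  expect_equal(onset_fraction(1, 0.5, 1, 1), 0.5)
  expect_equal(onset_fraction(2, 0.5, 1, 1), 0)
  # full lifetime risk is an absorbing edge case, not a division by zero
  expect_equal(cumulative_onset(3, 1, 1, 3), 1)
  expect_true(all(is.finite(onset_fraction(1:5, 1, 1, 3))))
  expect_error(onset_fraction(-1, 0.3), ">= 0")
  expect_error(cumulative_onset(1, 1.3), "\\[0, 1\\]")
})

test_that("the cohort engine matches an explicit transition-matrix recursion", {
  # 3 cycles, constant death probability 0.1, lifetime risk 0.3 over window (1,3)
  p <- default_params()
  p$start_age <- 6; p$horizon_age <- 9
  lt <- validate_life_table(data.frame(age = 0:100, qx = 0.1))
  p$avg_risk$os5 <- 0.9^5        # constant 0.1 hazard in years 1-5 too
  p$ranges <- list()
  sp <- arm_spec("XRT", "average", hl_lifetime_risk = 0.3, os5 = p$avg_risk$os5)
  tr <- run_cohort(sp, mortality_schedule(p, lt), p)
  oracle <- hand_recursion(q = rep(0.1, 3), h = onset_fraction(1:3, 0.3, 1, 3))
  expect_equal(tr$p_no_hl, oracle[, "p_no_hl"], tolerance = 1e-12)
  expect_equal(tr$p_hl, oracle[, "p_hl"], tolerance = 1e-12)
  expect_equal(tr$p_dead, oracle[, "p_dead"], tolerance = 1e-12)
})

test_that("traces conserve mass, absorb deaths, and hit the plateau prevalence among survivors", {
  p <- default_params()
  mort <- mortality_schedule(p, synthetic_lifetable())
  for (arm in c("XRT", "PT")) for (g in c("average", "high")) {
    rg <- if (g == "average") p$avg_risk else p$high_risk
    risk <- if (arm == "XRT") rg$hl_risk_xrt else rg$hl_risk_pt
    tr <- run_cohort(arm_spec(arm, g, risk, rg$os5), mort, p)
    expect_equal(nrow(tr), 95)
    expect_equal(tr$age, 6:100)
    expect_true(all(abs(tr$p_no_hl + tr$p_hl + tr$p_dead - 1) < 1e-12))
    expect_true(all(tr$p_no_hl >= 0 & tr$p_hl >= 0 & tr$p_dead >= 0))
    expect_true(all(diff(tr$p_dead) >= -1e-15))
    expect_equal(tr$p_hl[tr$t == 0], 0)
    # among survivors, prevalence equals the lifetime risk from the plateau on
    surv_prev <- tr$p_hl / (1 - tr$p_dead)
    expect_equal(surv_prev[tr$t >= 3], rep(risk, sum(tr$t >= 3)),
                 tolerance = 1e-9)
  }
})

test_that("null dynamics and arm dominance hold", {
  p <- default_params()
  p$avg_risk$os5 <- 1; p$high_risk$os5 <- 1
  p$ranges$os5_avg <- NULL; p$ranges$os5_high <- NULL
  mort0 <- mortality_schedule(p, zero_life_table())
  tr <- run_cohort(arm_spec("XRT", "average", 0, 1), mort0, p)
  expect_equal(tr$p_no_hl, rep(1, 95))

  # equal mortality: proton hearing-loss occupancy never exceeds X-ray's
  pd <- default_params()
  mort <- mortality_schedule(pd, synthetic_lifetable())
  for (g in c("average", "high")) {
    rg <- if (g == "average") pd$avg_risk else pd$high_risk
    tx <- run_cohort(arm_spec("XRT", g, rg$hl_risk_xrt, rg$os5), mort, pd)
    tp <- run_cohort(arm_spec("PT", g, rg$hl_risk_pt, rg$os5), mort, pd)
    expect_true(all(tp$p_hl <= tx$p_hl + 1e-15))
  }
})

test_that("cohort mixing is a cycle-wise convex combination", {
  p <- default_params()
  mort <- mortality_schedule(p, synthetic_lifetable())
  t1 <- run_cohort(arm_spec("XRT", "average", 0.39, 0.85), mort, p)
  t2 <- run_cohort(arm_spec("XRT", "high", 0.4711, 0.70), mort, p)
  m <- mix_cohorts(list(t1, t2), c(0.7, 0.3))
  expect_equal(m$p_dead, 0.7 * t1$p_dead + 0.3 * t2$p_dead, tolerance = 1e-15)
  expect_true(all(abs(m$p_no_hl + m$p_hl + m$p_dead - 1) < 1e-12))
  expect_equal(mix_cohorts(list(t1, t2), c(1, 0)), t1)
  expect_equal(mix_cohorts(list(t1, t1), c(0.5, 0.5)), t1)
  short <- t1[1:10, ]
  expect_error(mix_cohorts(list(t1, short), c(0.5, 0.5)), "mismatched")
  expect_error(mix_cohorts(list(t1, t2), c(0.5, 0.6)), "sum to 1")
})

test_that("onset mass recovers per-cycle incident cases from a trace", {
  p <- default_params()
  mort <- mortality_schedule(p, synthetic_lifetable())
  tr <- run_cohort(arm_spec("XRT", "average", 0.39, 0.85), mort, p)
  om <- onset_mass(tr)
  expect_equal(sum(om > 0), 3)              # incident cases only in years 1-3
  alive <- 1 - tr$p_dead
  expect_equal(om[2:4], alive[2:4] * diff(cumulative_onset(0:3, 0.39)),
               tolerance = 1e-12)
  expect_equal(sum(om[tr$t > 3]), 0)
})
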