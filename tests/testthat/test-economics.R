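test_that("discounting follows the present-value definition", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(10, 0.05), 1.05^-10)
  expect_error(discount_factor(-1, 0.03), ">= 0")
  expect_error(discount_factor(1, -0.01), ">= 0")
})

test_that("QALY accrual sums utility-weighted occupancy at cycle ends", {
  # 3-cycle toy trace with constant occupancy (0.9, 0.1, 0), u = (1, 0.5), r = 0
  tr <- make_trace(0:3, c(1, rep(0.9, 3)), c(0, rep(0.1, 3)), c(0, rep(0, 3)))
  expect_equal(discounted_qalys(tr, list(u_no_hl = 1, u_hl = 0.5), 0), 2.85)
  # full survival, utility 1, no discounting: one QALY per cycle
  n <- 94
  full <- make_trace(0:n, rep(1, n + 1), rep(0, n + 1), rep(0, n + 1))
  expect_equal(discounted_qalys(full, list(u_no_hl = 1, u_hl = 1), 0), 94)
  # QALYs strictly decrease as the discount rate rises
  q <- sapply(c(0, 0.03, 0.05, 0.07), function(r)
    discounted_qalys(full, list(u_no_hl = 1, u_hl = 1), r))
  expect_true(all(diff(q) < 0))
})

test_that("discounted life-years under flat mortality equal the geometric series", {
  fx <- generate_toy_fixture("flat_mortality")
  res <- compute_ce(fx$params, fx$life_table, "EQ-5D")
  closed_form <- sum((0.98 / 1.03)^(1:94))
  expect_equal(res$qaly_xrt, closed_form, tolerance = 1e-9)
  expect_equal(res$qaly_pt, closed_form, tolerance = 1e-9)
})

test_that("hearing costs enumerate tests, fitting and aid replacements per onset cohort", {
  p <- default_params()
  costs <- p$costs
  # single onset cohort of mass 1 at t = 1, no deaths, horizon 11 cycles,
  # r = 0, aid replaced every 5 years: purchases at t = 1, 6, 11
  n <- 11
  tr <- make_trace(0:n, c(1, rep(0, n)), c(0, rep(1, n)), rep(0, n + 1))
  onset <- c(0, 1, rep(0, n - 1))
  got <- discounted_costs(tr, onset, costs, "XRT", 0)
  oracle <- costs$c_xrt_course + 3 * costs$c_hearing_test +
    costs$c_fitting_test + 3 * costs$c_hearing_aid
  expect_equal(got, oracle, tolerance = 1e-12)
  # the proton arm differs only in the course price
  expect_equal(discounted_costs(tr, onset, costs, "PT", 0) - got,
               costs$c_pt_course - costs$c_xrt_course, tolerance = 1e-12)
  expect_error(discounted_costs(tr, onset, costs, "IMRT", 0))
})

test_that("a cohort with no hearing loss costs exactly the radiation course", {
  fx <- generate_toy_fixture("null_risk")
  res <- compute_ce(fx$params, fx$life_table, "EQ-5D")
  expect_equal(res$cost_xrt, 3082.20)
  expect_equal(res$cost_pt, 26943.90)
  expect_equal(res$delta_cost, 26943.90 - 3082.20)
  expect_equal(res$delta_qaly, 0)
  expect_false(res$icer_defined)
  expect_true(is.na(res$icer))
})

test_that("incremental results are internally consistent and sit in the expected quadrant", {
  p <- default_params()
  lt <- synthetic_lifetable()
  for (ix in utility_indexes()) {
    res <- compute_ce(p, lt, ix)
    expect_equal(res$delta_cost, res$cost_pt - res$cost_xrt, tolerance = 1e-12)
    expect_equal(res$delta_qaly, res$qaly_pt - res$qaly_xrt, tolerance = 1e-12)
    expect_equal(res$icer * res$delta_qaly, res$delta_cost, tolerance = 1e-9)
    # more QALYs at more cost: the upper-right quadrant
    expect_gt(res$qaly_pt, res$qaly_xrt)
    expect_gt(res$cost_pt, res$cost_xrt)
    # break-even identity of the net monetary benefit
    expect_equal(net_monetary_benefit(res, res$icer), 0, tolerance = 1e-9)
    expect_equal(net_monetary_benefit(res, 0), -res$delta_cost)
    expect_gt(net_monetary_benefit(res, p$econ$wtp), 0)
  }
})

test_that("the fitted model object exposes the analysis through standard methods", {
  fit <- cea()
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 6)
  expect_setequal(unique(df$index), utility_indexes())
  expect_identical(fit$results[["HUI3"]]$utility_index, "HUI3")
  expect_equal(fit$results[["EQ-5D"]]$icer,
               compute_ce(fit$params, fit$life_table, "EQ-5D")$icer)
  expect_output(print(fit), "ICER|icer")
  s <- summary(fit)
  expect_s3_class(s, "summary.cea")
  expect_true(all(s$nmb > 0))
  expect_output(print(s), "Net monetary benefit")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
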