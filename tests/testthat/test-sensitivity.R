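test_that("triangular sampling honours its support, mode and mean", {
  set.seed(11)
  expect_equal(sample_triangular(5, 2, 2, 2), rep(2, 5))
  # 5-year OS range for the average-risk group
  x <- sample_triangular(5000, 0.75, 0.85, 0.94)
  expect_true(all(x >= 0.75 & x <= 0.94))
  # closed-form mean (a+b+c)/3 within 3 standard errors
  y <- sample_triangular(1e5, 0, 1, 2)
  se <- sqrt(1 / 6) / sqrt(1e5)
  expect_lt(abs(mean(y) - 1), 3 * se)
  # one-sided triangles stay inside their support
  z <- sample_triangular(1000, 0, 0, 1)
  expect_true(all(z >= 0 & z <= 1))
  expect_error(sample_triangular(10, 1, 0.5, 2), "low <= mode <= high")
})

test_that("the tornado ranks parameters by ICER spread with coherent endpoints", {
  p <- default_params()
  lt <- synthetic_lifetable()
  tor <- one_way(p, lt, "EQ-5D")
  expect_true(all(diff(tor$spread) <= 1e-9))
  expect_equal(tor$spread, abs(tor$icer_at_high - tor$icer_at_low))
  # discounting shrinks far-future QALY gains faster than the cost gap
  disc <- tor[tor$parameter == "discount_rate", ]
  expect_lt(disc$icer_at_low, disc$icer_at_high)
  base_icer <- attr(tor, "base_icer")
  expect_equal(base_icer, compute_ce(p, lt, "EQ-5D")$icer)
  # endpoint ICERs bracket the base case for every varied parameter here
  expect_true(all(pmin(tor$icer_at_low, tor$icer_at_high) <= base_icer + 1e-6))
  expect_true(all(pmax(tor$icer_at_low, tor$icer_at_high) >= base_icer - 1e-6))
  # a zero-width range produces zero spread
  p2 <- p
  p2$ranges$c_hearing_aid <- list(low = p$costs$c_hearing_aid,
                                  high = p$costs$c_hearing_aid)
  tor2 <- one_way(p2, lt, "EQ-5D")
  expect_equal(tor2$spread[tor2$parameter == "c_hearing_aid"], 0)
})

test_that("PSA draws stay in their ranges, are seed-reproducible, and collapse to base when degenerate", {
  p <- default_params()
  lt <- synthetic_lifetable()
  a <- run_psa(p, lt, n = 50, seed = 123)
  b <- run_psa(p, lt, n = 50, seed = 123)
  expect_identical(a$draws, b$draws)
  expect_identical(a$results, b$results)
  c2 <- run_psa(p, lt, n = 50, seed = 124)
  expect_false(identical(a$draws, c2$draws))
  for (nm in names(p$ranges)) {
    r <- p$ranges[[nm]]
    expect_true(all(a$draws[[nm]] >= r$low & a$draws[[nm]] <= r$high))
  }
  expect_true(all(a$draws$discount_rate >= 0 & a$draws$discount_rate <= 0.07))

  pd <- degenerate_ranges(p)
  one <- run_psa(pd, lt, n = 1, seed = 5, vary_discount = FALSE)
  base <- compute_ce(p, lt, "EQ-5D")
  row <- one$results[one$results$index == "EQ-5D", ]
  expect_equal(row$delta_cost, base$delta_cost, tolerance = 1e-12)
  expect_equal(row$delta_qaly, base$delta_qaly, tolerance = 1e-12)
})

test_that("PSA outcomes centre near the base case for the near-symmetric ranges", {
  p <- default_params()
  lt <- synthetic_lifetable()
  psa <- run_psa(p, lt, n = 2000, seed = 99, indices = "EQ-5D",
                 vary_discount = FALSE)
  base <- compute_ce(p, lt, "EQ-5D")
  r <- psa$results
  expect_lt(abs(mean(r$delta_qaly) - base$delta_qaly), 0.1)
  expect_true(is.logical(psa$draws$risk_order_flag))
})

test_that("acceptability curves are probabilities, monotone for QALY-gaining samples, and pick out thresholds", {
  p <- default_params()
  lt <- synthetic_lifetable()
  psa <- run_psa(p, lt, n = 300, seed = 7)
  cv <- ceac(psa)
  expect_setequal(unique(cv$scope), c(utility_indexes(), "integrated"))
  expect_true(all(cv$p_cost_effective >= 0 & cv$p_cost_effective <= 1))
  expect_true(46729 %in% cv$wtp)
  if (min(psa$results$delta_qaly) >= 0) {
    for (sc in unique(cv$scope)) {
      sub <- cv[cv$scope == sc, ]
      expect_true(all(diff(sub$p_cost_effective[order(sub$wtp)]) >= -1e-12))
    }
  }
  # at zero willingness to pay nothing costing extra is acceptable
  expect_equal(ceac_at(cv, "integrated", 0), 0)
  # integrated scope pools the three per-index sample sets equally
  at_thr <- sapply(utility_indexes(), function(ix) ceac_at(cv, ix))
  expect_equal(ceac_at(cv, "integrated"), mean(at_thr), tolerance = 1e-12)
  expect_error(ceac_at(cv, "EQ-5D", 46730), "not on the grid")
  psa$results <- psa$results[0, ]
  expect_error(ceac(psa), "empty")
})
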