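test_that("negative binomial moment fit reproduces the source moments", {
  # closed-form method of moments: r = m^2/(v - m), p = m/v
  fit <- fit_negative_binomial(2.446, 2.358)
  expect_false(fit$fallback_poisson)
  expect_equal(fit$r, 2.446^2 / (2.358^2 - 2.446), tolerance = 1e-12)
  expect_equal(fit$r, 1.921, tolerance = 1e-3)
  expect_equal(fit$p, 0.440, tolerance = 1e-3)
  # implied mean and variance match the inputs exactly
  expect_equal(fit$r * (1 - fit$p) / fit$p, 2.446, tolerance = 1e-9)
  expect_equal(fit$r * (1 - fit$p) / fit$p^2, 2.358^2, tolerance = 1e-9)

  fit2 <- fit_negative_binomial(13.161, 5.990)
  expect_equal(fit2$r * (1 - fit2$p) / fit2$p^2, 35.8801, tolerance = 1e-9)

  # variance <= mean degenerates to Poisson
  expect_true(fit_negative_binomial(4.0, 2.0)$fallback_poisson)
  expect_error(fit_negative_binomial(0, 1), "positive")
})

test_that("daily arrival sampling matches the fitted moments", {
  set.seed(11)
  fit <- fit_negative_binomial(2.446, 2.358)
  x <- sample_daily_arrivals(fit, 2e5)
  expect_true(all(x >= 0))
  expect_equal(mean(x), 2.446, tolerance = 0.01)
  expect_equal(var(x), 5.560, tolerance = 0.02)
  # fallback Poisson with negligible rate is almost surely all zero
  tiny <- fit_negative_binomial(1e-9, 0)
  expect_true(all(sample_daily_arrivals(tiny, 1e4) == 0L))
})

test_that("lognormal moment fit is exact on the natural scale", {
  spec <- duration_spec(5.050, 2.350, 3, 11, "days")
  fit <- fit_truncated_lognormal(spec)
  expect_equal(fit$mu_log, 1.5214, tolerance = 1e-3)
  expect_equal(fit$sigma_log, 0.4428, tolerance = 1e-3)

  # analytic round trip: untruncated moments of the fit equal the spec's,
  # for every non-degenerate duration in the packaged configuration
  for (s in all_duration_specs(default_config())) {
    if (s$sd == 0) next
    m <- epflowsim:::lognormal_moments(fit_truncated_lognormal(s))
    expect_equal(unname(m["mean"]), s$mean, tolerance = 1e-9)
    expect_equal(unname(m["sd"]), s$sd, tolerance = 1e-9)
  }

  # degenerate specs collapse to constants
  cfit <- fit_truncated_lognormal(duration_spec(3, 0, 3, 3, "days"))
  expect_equal(cfit$sigma_log, 0)
  expect_equal(sample_truncated(cfit, 5), rep(3, 5))
})

test_that("sampled durations always respect their truncation bounds", {
  set.seed(22)
  for (s in all_duration_specs(default_config())) {
    x <- sample_truncated(fit_truncated_lognormal(s), 2000L)
    expect_true(all(x >= s$min & x <= s$max),
                info = sprintf("bounds [%g, %g]", s$min, s$max))
  }
  # an interval with negligible mass is refused rather than looping
  bad <- fit_truncated_lognormal(duration_spec(5.05, 2.35, 3, 11, "days"))
  bad$lower <- 1e5
  bad$upper <- 1e5 + 1
  expect_error(sample_truncated(bad, 1), "negligible")
})

test_that("integer-day sampling rounds half up and clamps to integer bounds", {
  expect_equal(epflowsim:::round_half_up(c(5.5, 5.49, 2.5, -0.4)), c(6, 5, 3, 0))
  set.seed(33)
  # SVT pre-op allows zero days: integer draws stay within {0, 1, 2}
  svt <- fit_truncated_lognormal(duration_spec(1.250, 0.550, 0, 2, "days"))
  x <- sample_integer_days(svt, 5e4)
  expect_true(all(x %in% 0:2))
  expect_equal(sample_integer_days(fit_truncated_lognormal(
    duration_spec(3, 0, 3, 3, "days")), 3), rep(3L, 3))
})

test_that("pre-op conditioning caps the draw at the realized length of stay", {
  set.seed(44)
  pa <- fit_truncated_lognormal(duration_spec(2.000, 2.151, 1, 8, "days"))
  draws <- replicate(2000L, sample_preop_given_los(pa, 3L))
  expect_true(all(draws %in% 1:3))
  # constant pre-op specs: exact values, zero post-op allowed at the boundary
  one <- fit_truncated_lognormal(duration_spec(1, 0, 1, 1, "days"))
  expect_identical(sample_preop_given_los(one, 5L), 1L)
  two <- fit_truncated_lognormal(duration_spec(2, 0, 2, 2, "days"))
  expect_identical(sample_preop_given_los(two, 2L), 2L)
  expect_error(sample_preop_given_los(two, 1L), "feasible")
})

test_that("procedure-class and physician draws follow their probabilities", {
  set.seed(55)
  cfg <- default_config()
  idx <- draw_procedure_class(cfg$procedure_classes, 1e5)
  freq <- tabulate(idx, nbins = 11L) / 1e5
  expect_equal(freq[1L], 18.4 / 100.1, tolerance = 0.005)
  props <- vapply(cfg$procedure_classes, `[[`, 0, "proportion")
  expect_true(all(abs(freq - props) < 0.005))
  expect_equal(draw_procedure_class(cfg$procedure_classes[1L], 5), rep(1L, 5))

  # two equal classes: a chi-square test should not reject fairness
  half <- replicate(2, procedure_class("X", 0.5, const_spec(60, "minutes"),
                                       const_spec(5, "minutes"), const_spec(3, "days"),
                                       const_spec(1, "days")), simplify = FALSE)
  counts <- tabulate(draw_procedure_class(half, 1e5), nbins = 2L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)

  mon <- weekday_allocation("Mon", 0.727, 0.273)
  s <- assign_physician("Mon", mon, 2e4)
  expect_equal(mean(s == 1L), 0.727, tolerance = 0.01)
  sure <- weekday_allocation("Wed", 1, 0)
  expect_true(all(assign_physician("Wed", sure, 100) == 1L))
  expect_error(assign_physician("Tue", mon), "allocation is for")
})

test_that("sampling is reproducible under a fixed seed", {
  fit <- fit_truncated_lognormal(duration_spec(5.05, 2.35, 3, 11, "days"))
  set.seed(99)
  a <- sample_truncated(fit, 100)
  set.seed(99)
  b <- sample_truncated(fit, 100)
  expect_identical(a, b)
})
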