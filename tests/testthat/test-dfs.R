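test_that("loading-rate estimation recovers a linear ramp", {
  # 10 pN over 1 ms at 1e4 nm/s: extension 0..10 nm doubles as the clock
  ext <- seq(0, 10, length.out = 101)
  force <- seq(0, 10, length.out = 101)
  rate <- estimate_loading_rate(ext, force, list(pulling_speed = 1e4))
  expect_equal(rate, 1e4, tolerance = 1e-9)
  expect_equal(
    estimate_loading_rate(ext, rep(5, 101), list(pulling_speed = 1e4)), 0
  )
  expect_error(
    estimate_loading_rate(ext, force, list()),
    "pulling_speed"
  )
  expect_error(
    estimate_loading_rate(ext[1:5], force[1:5], list(pulling_speed = 1e4)),
    "fewer than 10"
  )
})

test_that("marker loading rates agree with the series-stiffness oracle", {
  sim <- simulate_curve(single_marker_construct(), noiseless_config(),
    seed = 41
  )
  ev <- analyze_curve(sim$curve,
    criteria = selection_criteria(min_marker_peaks = 1)
  )
  marker <- ev[1, ]
  cfg <- simulation_config()
  oracle <- effective_loading_rate(
    marker$rupture_force_pN, marker$lc_nm,
    cfg$pulling_speed, cfg$cantilever_stiffness
  )
  expect_lt(abs(marker$loading_rate_pN_s - oracle) / oracle, 0.15)
})

test_that("log-spaced binning places rates in the expected bins", {
  d <- tibble::tibble(
    force = c(60, 70, 80),
    loading_rate = c(1e3, 1e4, 1e5)
  )
  binned <- bin_by_loading_rate(d, n_bins = 5, range = c(1e3, 3e5))
  expect_equal(binned$bin, c(1L, 3L, 5L))
  edges <- attr(binned, "edges")
  expect_equal(edges[1], 1e3)
  expect_equal(edges[6], 3e5)
  expect_equal(diff(log(edges)), rep(log(300) / 5, 5))
  # geometric bin centres
  expect_equal(binned$bin_center, sqrt(edges[-1] * edges[-6])[binned$bin])

  out <- bin_by_loading_rate(
    tibble::tibble(force = 50, loading_rate = 5e3),
    n_bins = 5
  )
  expect_equal(attr(out, "n_excluded"), 0L)
  expect_error(
    bin_by_loading_rate(
      tibble::tibble(force = 50, loading_rate = 10),
      n_bins = 5
    ),
    "outside"
  )
})

test_that("modal force estimation is sensible across sample sizes", {
  set.seed(3)
  sym <- rnorm(500, mean = 80, sd = 10)
  expect_equal(as.numeric(modal_force(sym)), mean(sym), tolerance = 3)
  expect_warning(m <- modal_force(c(1, 2, 3, 4)), "fewer than 5")
  expect_true(is.na(m))
  small <- rnorm(10, 60, 5)
  expect_true(is.finite(modal_force(small))) # histogram fallback
})

test_that("Bell-Evans fits on exact modal forces are a closed-form round trip", {
  kp <- kinetic_parameters(25, 0.2)
  r <- exp(seq(log(1e3), log(3e5), length.out = 5))
  fit <- fit_bell_evans(most_probable_force(r, kp), r)
  expect_equal(fit$k_off, 25, tolerance = 1e-6)
  expect_equal(fit$delta_x, 0.2, tolerance = 1e-9)
  expect_equal(fit$slope, 4.114 / 0.2, tolerance = 1e-9)
  expect_error(fit_bell_evans(c(50, 60), r[1:2]), "at least 3")
  expect_error(
    fit_bell_evans(c(90, 70, 50, 30, 10), r),
    "non-positive slope"
  )
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "k_off"], 25, tolerance = 1e-6)
  expect_true(all(c("n_bins", "r.squared") %in% names(glance(fit))))
})

test_that("rescaling all loading rates shifts only the off-rate, as predicted", {
  kp <- kinetic_parameters(25, 0.2)
  r <- exp(seq(log(1e3), log(3e5), length.out = 5))
  f <- most_probable_force(r, kp)
  fit1 <- fit_bell_evans(f, r)
  fit2 <- fit_bell_evans(f, r * 7)
  expect_equal(fit2$delta_x, fit1$delta_x, tolerance = 1e-9)
  expect_equal(fit2$k_off, fit1$k_off * 7, tolerance = 1e-6)
})

test_that("stochastic DFS recovery returns the generating parameters", {
  set.seed(61)
  rec <- dfs_recovery(kinetic_parameters(25, 0.2), n_per_bin = 300)
  # module-level sanity at a loose tolerance; the protocol-level check at
  # the published tolerance lives in the acceptance suite
  expect_gt(rec$fit$k_off, 25 / 1.5)
  expect_lt(rec$fit$k_off, 25 * 1.5)
  expect_lt(abs(rec$fit$delta_x - 0.2) / 0.2, 0.2)
  expect_equal(nrow(rec$modal), 5L)
  expect_equal(nrow(rec$dataset), 1500L)
})
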