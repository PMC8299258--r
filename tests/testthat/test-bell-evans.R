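test_that("bell_rate has the exponential force dependence", {
  kp <- kinetic_parameters(25, 0.2)
  expect_equal(bell_rate(0, kp), 25)
  # one thermal-energy unit of work gives exactly a factor e
  expect_equal(bell_rate(4.114 / 0.2, kp), 25 * exp(1), tolerance = 1e-12)
  expect_equal(bell_rate(100, kp), 25 * exp(100 * 0.2 / 4.114),
    tolerance = 1e-12
  )
  expect_equal(bell_rate(100, kp), 3230.28, tolerance = 1e-4)
  f <- seq(0, 200, by = 10)
  expect_true(all(diff(bell_rate(f, kp)) > 0))
  expect_true(all(bell_rate(f, kp) >= 25))
  expect_error(bell_rate(-1, kp), "non-negative")
})

test_that("most_probable_force is log-linear in the loading rate", {
  kp <- kinetic_parameters(25, 0.2)
  # argument of the logarithm equals 1 exactly at r = k_off kT / dx
  expect_equal(most_probable_force(25 * 4.114 / 0.2, kp), 0)
  expect_equal(
    most_probable_force(1e4, kp),
    (4.114 / 0.2) * log(1e4 * 0.2 / (25 * 4.114)),
    tolerance = 1e-12
  )
  expect_equal(most_probable_force(1e4, kp), 61.05, tolerance = 1e-3)
  # slope identity F*(10 r) - F*(r) = (kT/dx) ln 10
  r <- 10^seq(3.2, 5.2, length.out = 7)
  expect_equal(
    most_probable_force(10 * r, kp) - most_probable_force(r, kp),
    rep((4.114 / 0.2) * log(10), length(r)),
    tolerance = 1e-9
  )
  # clipped at zero below the crossover rate
  expect_identical(most_probable_force(1, kp), 0)
  expect_error(most_probable_force(0, kp), "positive")
})

test_that("sample_rupture_force is reproducible and matches the survival law", {
  kp <- kinetic_parameters(25, 0.2)
  set.seed(7)
  a <- sample_rupture_force(100, 1e4, kp)
  set.seed(7)
  b <- sample_rupture_force(100, 1e4, kp)
  expect_identical(a, b)

  set.seed(8)
  f <- sample_rupture_force(2e4, 1e4, kp)
  expect_true(all(f >= 0))
  # Kolmogorov-Smirnov distance against the closed-form CDF
  cdf <- function(q) 1 - rupture_force_survival(q, 1e4, kp)
  ks <- suppressWarnings(stats::ks.test(f, cdf))
  expect_lt(unname(ks$statistic), 0.02)
  # empirical mode near the analytic most probable force
  expect_equal(as.numeric(modal_force(f)), most_probable_force(1e4, kp),
    tolerance = 0.05
  )
})

test_that("kinetic_parameters validates its inputs", {
  expect_error(kinetic_parameters(-1, 0.2))
  expect_error(kinetic_parameters(25, 0))
})
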