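test_that("wlc_force reproduces the Marko-Siggia interpolation", {
  p <- wlc_parameters(0.4, 4.114)
  # direct evaluation of (kT/p) * (1/(4(1-t)^2) - 1/4 + t)
  expect_identical(wlc_force(0, 30, p), 0)
  expect_equal(wlc_force(15, 30, p), (4.114 / 0.4) * (0.25 / 0.25^2 / 4 + 0.25),
    tolerance = 1e-12
  )
  expect_equal(wlc_force(15, 30, p), 12.85625, tolerance = 1e-6)
  # near full extension the force diverges; frozen from direct evaluation
  expect_equal(wlc_force(29.7, 30, p),
    (4.114 / 0.4) * (0.25 / (1 - 0.99)^2 - 0.25 + 0.99),
    tolerance = 1e-10
  )
  expect_gt(wlc_force(29.7, 30, p), 2e4)
})

test_that("wlc_force is strictly increasing in extension and in 1/Lc", {
  p <- wlc_parameters()
  set.seed(101)
  for (i in 1:25) {
    lc <- runif(1, 10, 200)
    x <- sort(runif(8, 0, 0.88 * lc))
    f <- wlc_force(x, lc, p)
    expect_true(all(diff(f) > 0))
    # shrinking the contour length at fixed extension raises the force
    expect_true(all(wlc_force(x, lc * 0.9, p) > f))
  }
})

test_that("wlc_force rejects invalid domains", {
  expect_error(wlc_force(30, 30), "strictly less")
  expect_error(wlc_force(35, 30), "strictly less")
  expect_error(wlc_force(-1, 30), "non-negative")
  expect_error(wlc_force(5, -2), "positive")
})

test_that("wlc_extension inverts wlc_force to high accuracy", {
  p <- wlc_parameters()
  expect_identical(wlc_extension(0, 30, p), 0)
  expect_equal(wlc_extension(12.85625, 30, p), 15, tolerance = 1e-6)
  expect_error(wlc_extension(-5, 30), "non-negative")

  set.seed(202)
  f <- runif(1000, 0, 500)
  lc <- runif(1000, 5, 300)
  x <- wlc_extension(f, lc, p)
  expect_true(all(x >= 0 & x < lc))
  expect_lt(max(abs(wlc_force(x, lc, p) - f)), 1e-6)

  # independent bisection oracle on a subsample
  for (i in seq(1, 1000, by = 97)) {
    oracle <- uniroot(
      function(z) wlc_force(z, lc[i], p) - f[i],
      c(0, lc[i] * (1 - 1e-12)),
      tol = 1e-12
    )$root
    expect_equal(x[i], oracle, tolerance = 1e-6)
  }
})

test_that("contour_increment reproduces the published segment arithmetic", {
  expect_equal(contour_increment(34, 1.3), 10.94, tolerance = 1e-12)
  expect_equal(contour_increment(25, 1.2), 7.8, tolerance = 1e-12)
  expect_identical(contour_increment(0, 0), 0)
  expect_warning(contour_increment(2, 5), "shorter")
})

test_that("contour_increment is linear in its arguments", {
  set.seed(303)
  for (i in 1:20) {
    a <- sample(5:40, 1)
    b <- sample(5:40, 1)
    d1 <- runif(1, 0, 2)
    d2 <- runif(1, 0, 2)
    expect_equal(
      contour_increment(a + b, d1 + d2),
      contour_increment(a, d1) + contour_increment(b, d2),
      tolerance = 1e-12
    )
  }
})

test_that("the shipped segment table is self-consistent and round-trips", {
  tab <- mt3_segment_table()
  expect_true(validate_segment_table(tab))
  expect_equal(
    tab$theoretical_dlc_nm,
    0.36 * tab$n_aa - tab$folded_distance_nm
  )
  # printed values: full alpha 10.94 ("10.9"), beta 7.8, sub-segments 3.6/7.5
  expect_equal(
    tab$theoretical_dlc_nm[tab$label == "alpha(Cys34-Cys67)"], 10.94
  )
  expect_equal(tab$theoretical_dlc_nm[tab$label == "beta(Cys6-Cys30)"], 7.8)
  expect_equal(
    tab$theoretical_dlc_nm[tab$label == "alpha(Cys34-Cys45)"], 3.6
  )
  expect_equal(
    tab$theoretical_dlc_nm[tab$label == "alpha(Cys45-Cys67)"], 7.5
  )

  f <- withr::local_tempfile(fileext = ".tsv")
  write_segment_table(tab, f)
  back <- read_segment_table(f)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-9)

  # tampered file: stored increment inconsistent with the identity
  lines <- readLines(f)
  lines[2] <- sub("10.94", "12.5", lines[2], fixed = TRUE)
  writeLines(lines, f)
  expect_error(read_segment_table(f), "inconsistent")
})

test_that("segment table constructor rejects impossible segments", {
  expect_error(
    suppressWarnings(segment_table("bad", 2, 5)),
    "positive"
  )
})
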