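test_that("smoothing preserves structure and suppresses noise", {
  expect_equal(smooth_force(rep(5, 50), 11), rep(5, 50))
  ramp <- seq(0, 49)
  sm <- smooth_force(ramp, 11)
  expect_equal(sm[6:44], ramp[6:44]) # interior of a linear ramp unchanged
  set.seed(1)
  noise <- rnorm(5000, sd = 8)
  expect_lt(sd(smooth_force(noise, 11)), 4)
  expect_error(smooth_force(rnorm(5), 11), "longer")
  expect_error(smooth_force(rnorm(50), 4))
})

test_that("peak detection handles flat, empty and offset curves", {
  flat <- tibble::tibble(extension = seq(0, 50, by = 0.1), force = 0)
  expect_equal(nrow(detect_peaks(flat)), 0L)
  expect_error(detect_peaks(flat[0, ]), "empty")

  sim <- simulate_curve(polyprotein_construct("Zn-aMT"), noiseless_config(),
    seed = 4
  )
  pk <- detect_peaks(sim$curve)
  shifted <- sim$curve
  shifted$force <- shifted$force + 37.5
  attr(shifted, "metadata") <- attr(sim$curve, "metadata")
  pk2 <- detect_peaks(shifted)
  expect_equal(pk2$peak_index, pk$peak_index)
  expect_equal(pk2$rupture_force, pk$rupture_force, tolerance = 1e-9)
})

test_that("a noiseless marker cassette yields one peak per event", {
  # force a one-step target so the expected peak count is deterministic
  mx <- alpha_mixture(
    p_one_step = 1,
    pathway_probs = c(P1 = 0, P2 = 0, P3 = 0, P4 = 0)
  )
  cons <- polyprotein_construct("Zn-aMT")
  cons[["Zn-aMT"]] <- mt_alpha_domain("Zn", mixture = mx)
  found <- FALSE
  for (seed in 1:20) {
    sim <- simulate_curve(cons, noiseless_config(), seed = seed)
    if (nrow(sim$truth) == 7L && all(sim$truth$force_true > 25)) {
      found <- TRUE
      break
    }
  }
  expect_true(found)
  pk <- detect_peaks(sim$curve)
  expect_equal(nrow(pk), 8L) # 6 markers + 1 one-step cluster + detachment
})

test_that("branch WLC fits recover the contour length", {
  p <- wlc_parameters()
  x <- seq(5, 27, by = 0.05)
  y <- wlc_force(x, 30, p)
  fit <- fit_branch_wlc(x, y, p)
  expect_equal(fit$contour_length, 30, tolerance = 0.01)
  expect_lt(fit$residual_rms, 1e-3)

  set.seed(31)
  err <- replicate(30, {
    idx <- sort(sample(length(x), 300))
    fit <- fit_branch_wlc(x[idx], y[idx] + rnorm(300, sd = 8), p)
    fit$contour_length
  })
  expect_lt(max(abs(err - 30) / 30), 0.02) # within 2 percent with noise

  expect_error(
    fit_branch_wlc(x[1:5], y[1:5], p),
    "fewer than 10 points"
  )
})

test_that("co-fitting the persistence length stays near the truth", {
  p <- wlc_parameters(0.4)
  x <- seq(2, 27, by = 0.02)
  y <- wlc_force(x, 30, p)
  fit <- fit_branch_wlc(x, y, wlc_parameters(0.6), fit_persistence = TRUE)
  expect_equal(fit$contour_length, 30, tolerance = 0.2)
  expect_equal(fit$persistence_length, 0.4, tolerance = 0.05)
})

test_that("contour-length increments difference consecutive fits", {
  expect_equal(compute_dlc(c(50, 68)), 18)
  expect_equal(compute_dlc(c(50, 61.6)), 11.6)
  expect_identical(compute_dlc(60), numeric(0))
})

test_that("single-molecule selection applies the marker fingerprint", {
  mk_events <- function(n_marker, n_target) {
    tibble::tibble(
      curve_id = "c",
      peak_index = seq_len(n_marker + n_target + 1L),
      rupture_force_pN = 150,
      lc_nm = 50, fit_rms_pN = 1,
      dlc_nm = c(rep(18, n_marker), rep(11.2, n_target), NA),
      loading_rate_pN_s = 1e4,
      attribution = c(
        rep("marker", n_marker), rep("target", n_target),
        "detachment"
      ),
      accepted = NA
    )
  }
  sel <- select_single_molecule(mk_events(6, 1))
  expect_true(sel$accepted)
  expect_equal(sel$target_dlc, 11.2)
  sel2 <- select_single_molecule(mk_events(2, 1))
  expect_false(sel2$accepted)
  expect_length(sel2$target_dlc, 0)
})

test_that("noiseless pipeline round trip recovers the ground truth", {
  cons <- polyprotein_construct("Zn-aMT")
  cfg <- noiseless_config()
  n_checked <- 0
  n_clean <- 0
  for (seed in 101:130) {
    sim <- simulate_curve(cons, cfg, seed = seed)
    pred <- predict_observed_events(sim$truth)
    if (pred$ambiguous) next
    n_clean <- n_clean + 1
    ev <- analyze_curve(sim$curve)
    non_detach <- ev[ev$attribution != "detachment", ]
    ext_peaks <- sim$curve$extension[non_detach$peak_index]
    # one detected peak per predicted visible rupture, none elsewhere
    expect_equal(length(ext_peaks), nrow(pred$events))
    expect_lt(max(abs(ext_peaks - pred$events$extension)), 0.5)
    expect_lt(max(abs(non_detach$dlc_nm - pred$events$dlc)), 0.1)
    n_checked <- n_checked + nrow(pred$events)
  }
  expect_gt(n_clean, 10)
  expect_gt(n_checked, 70)
})

test_that("marker and target attributions never overlap", {
  ds <- simulate_dataset(polyprotein_construct("Zn-aMT"), 10, master_seed = 3)
  ev <- analyze_dataset(ds$curves)
  expect_true(all(ev$attribution %in%
    c("marker", "target", "detachment", "artifact")))
  counts <- table(ev$curve_id, ev$attribution)[, "detachment"]
  expect_true(all(counts == 1L))
})
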