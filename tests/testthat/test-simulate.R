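test_that("scenario draws follow the mixture probabilities", {
  mx <- alpha_mixture()
  set.seed(11)
  sc <- choose_unfolding_scenario(mx, 2e4)
  n <- nrow(sc)
  freq <- table(factor(sc$scenario,
    levels = c("one_step", "P1", "P2", "P3", "P4")
  )) / n
  probs <- c(one_step = 0.51, P1 = 0.16, P2 = 0.12, P3 = 0.10, P4 = 0.11)
  for (lab in names(probs)) {
    se <- sqrt(probs[lab] * (1 - probs[lab]) / n)
    expect_lt(abs(freq[[lab]] - probs[[lab]]), 3 * se)
  }
  two <- sc[sc$scenario != "one_step", ]
  se_dir <- sqrt(0.55 * 0.45 / nrow(two))
  expect_lt(abs(mean(two$direction == "C") - 0.55), 3 * se_dir)
  # two-step draws release the pathway pair in direction order
  pw <- default_pathways()
  i <- match(two$scenario, pw$id)
  expect_equal(
    two$dlc_first,
    ifelse(two$direction == "C", pw$dlc_large[i], pw$dlc_small[i])
  )
})

test_that("degenerate and invalid mixtures are handled", {
  only_one <- alpha_mixture(
    p_one_step = 1,
    pathway_probs = c(P1 = 0, P2 = 0, P3 = 0, P4 = 0)
  )
  set.seed(1)
  expect_true(all(choose_unfolding_scenario(only_one, 500)$scenario ==
    "one_step"))
  expect_error(
    alpha_mixture(p_one_step = 0.6),
    "must equal 1"
  )
  set.seed(5)
  a <- choose_unfolding_scenario(alpha_mixture(), 50)
  set.seed(5)
  b <- choose_unfolding_scenario(alpha_mixture(), 50)
  expect_identical(a, b)
})

test_that("a single noiseless marker gives one rupture and a clean 18 nm", {
  sim <- simulate_curve(single_marker_construct(), noiseless_config(),
    seed = 21
  )
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$dlc_true, 18)
  peaks <- detect_peaks(sim$curve)
  expect_equal(nrow(peaks), 2L) # unfolding + detachment
  expect_true(peaks$is_detachment[2])
  ev <- analyze_curve(sim$curve,
    criteria = selection_criteria(min_marker_peaks = 1)
  )
  expect_equal(ev$dlc_nm[1], 18, tolerance = 0.1)
})

test_that("simulated curves are deterministic given the seed", {
  cons <- polyprotein_construct("Zn-aMT")
  s1 <- simulate_curve(cons, seed = 33)
  s2 <- simulate_curve(cons, seed = 33)
  expect_identical(s1$curve$force, s2$curve$force)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_curve(cons, seed = 34)
  expect_false(identical(s1$curve$force, s3$curve$force))
})

test_that("force rises within branches and drops only at ruptures", {
  sim <- simulate_curve(polyprotein_construct("Zn-aMT"), noiseless_config(),
    seed = 55
  )
  f <- sim$curve$force
  drops <- which(diff(f) < -1)
  # one drop per ground-truth event plus the final detachment
  expect_equal(length(drops), nrow(sim$truth) + 1L)
})

test_that("apo constructs show only marker events", {
  sim <- simulate_curve(polyprotein_construct("Apo-aMT"), noiseless_config(),
    seed = 77
  )
  expect_true(all(grepl("GB1", sim$truth$domain)))
  ev <- analyze_curve(sim$curve)
  sel <- select_single_molecule(ev)
  expect_true(sel$accepted)
  expect_length(sel$target_dlc, 0)
})

test_that("two-step events conserve the one-step contour length", {
  cons <- polyprotein_construct("Zn-aMT")
  ds <- simulate_dataset(cons, 40, master_seed = 5)
  mt <- ds$truth[ds$truth$domain == "Zn-aMT", ]
  per_curve <- tapply(mt$dlc_true, mt$curve_id, sum)
  two_step <- tapply(mt$scenario, mt$curve_id, function(s) s[1] != "one_step")
  # every molecule releases the full cluster increment, one- or two-step,
  # up to the pair-table rounding of at most 0.5 nm
  expect_true(all(abs(per_curve - 11.3) <= 0.5))
  expect_true(any(two_step))
  n_events <- tapply(mt$step, mt$curve_id, length)
  expect_true(all(n_events[two_step] == 2L))
  expect_true(all(n_events[!two_step] == 1L))
})

test_that("mean rupture force increases with pulling speed", {
  speeds <- c(1500, 6000, 24000)
  mean_force <- vapply(speeds, function(v) {
    cfg <- simulation_config(pulling_speed = v, force_noise_sd = 0)
    ds <- simulate_dataset(single_marker_construct(), 60,
      master_seed = 9, config = cfg
    )
    mean(ds$truth$force_true)
  }, numeric(1))
  expect_true(all(diff(mean_force) > 0))
})

test_that("datasets are reproducible and round-trip through TSV files", {
  cons <- single_marker_construct()
  d1 <- simulate_dataset(cons, 3, master_seed = 12)
  d2 <- simulate_dataset(cons, 3, master_seed = 12)
  expect_identical(d1$truth, d2$truth)
  expect_identical(
    lapply(d1$curves, `[[`, "force"),
    lapply(d2$curves, `[[`, "force")
  )
  expect_error(simulate_dataset(cons, 0), "at least 1")

  dir <- withr::local_tempdir()
  manifest <- simulate_dataset(cons, 3, master_seed = 12, dir = dir)
  expect_true(all(file.exists(manifest$curve_file)))
  expect_true(all(file.exists(manifest$truth_file)))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_curve_tsv(manifest$curve_file[1])
  expect_equal(back$force, d1$curves[[1]]$force, tolerance = 1e-7)
  meta <- attr(back, "metadata")
  expect_equal(meta$curve_id, "curve_0001")
  expect_equal(meta$pulling_speed, simulation_config()$pulling_speed)
  # byte-identical rewrite with the same master seed
  dir2 <- withr::local_tempdir()
  simulate_dataset(cons, 3, master_seed = 12, dir = dir2)
  expect_identical(
    readLines(manifest$curve_file[1]),
    readLines(file.path(dir2, "curve_0001.tsv"))
  )
})
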