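test_that("worked-example events classify to the Cys45 pathway", {
  pw <- default_pathways()
  # small-first: N-terminal segment released before the C-terminal one
  a <- classify_event(c(3.6, 7.0), pw)
  expect_equal(a$label, "P2")
  expect_equal(a$anchor, "Cys45")
  expect_equal(a$direction, "N")
  # same pathway observed in reverse order unfolds from the C terminus
  b <- classify_event(c(7.3, 3.7), pw)
  expect_equal(b$label, "P2")
  expect_equal(b$direction, "C")
  # a single ~11 nm increment is a one-step rupture of the whole cluster
  d <- classify_event(11.3, pw)
  expect_equal(d$label, "one_step")
  expect_true(is.na(d$direction))
  expect_error(classify_event(numeric(0), pw), "empty")
})

test_that("out-of-window and multi-step events are bucketed, not forced", {
  pw <- default_pathways()
  expect_equal(classify_event(6.1, pw)$label, "unassigned")
  expect_equal(classify_event(c(9, 9), pw)$label, "unassigned") # bad sum
  expect_equal(classify_event(c(5, 5), pw)$label, "unassigned") # far pair
  expect_equal(classify_event(c(3, 4, 4), pw)$label, "multi_step")
})

test_that("exact distance ties break toward the lower pathway id", {
  # two artificial pathways symmetric about the test pair
  pw <- pathway_set(
    id = c("P1", "P2"), anchor = c("a", "b"),
    dlc_small = c(4.0, 5.0), dlc_large = c(7.0, 6.0),
    one_step_dlc = 11
  )
  res <- classify_event(c(4.5, 6.5), pw, pair_tolerance = 1)
  expect_equal(res$label, "P1")
  expect_true(res$tie)
})

test_that("direction flips under pair reversal and respects resolution", {
  expect_equal(assign_direction(c(4.1, 7.2), c(4.1, 7.2)), "N")
  expect_equal(assign_direction(c(4.1, 7.2), c(7.2, 4.1)), "C")
  expect_true(is.na(assign_direction(c(5, 5), c(5, 5))))
  expect_true(is.na(assign_direction(c(5.0, 5.1), c(5.1, 5.0),
    resolution = 0.2
  )))
  set.seed(17)
  pw <- default_pathways()
  for (k in 1:30) {
    i <- sample(4, 1)
    pair <- c(pw$dlc_small[i], pw$dlc_large[i])
    obs <- pair + rnorm(2, sd = 0.15)
    fwd <- classify_event(obs, pw)
    rev <- classify_event(rev(obs), pw)
    expect_equal(fwd$label, rev$label)
    if (!is.na(fwd$direction) && !is.na(rev$direction)) {
      expect_true(fwd$direction != rev$direction)
    }
  }
})

test_that("noise-free pathway recovery is perfect and noise only confuses neighbours", {
  pw <- default_pathways()
  # exact pairs classify to themselves in both directions
  for (i in 1:4) {
    pair <- c(pw$dlc_small[i], pw$dlc_large[i])
    expect_equal(classify_event(pair, pw)$label, pw$id[i])
    expect_equal(classify_event(rev(pair), pw)$label, pw$id[i])
    expect_equal(classify_event(pair, pw)$direction, "N")
    expect_equal(classify_event(rev(pair), pw)$direction, "C")
  }
  neighbours <- list(
    P1 = c("P1", "P2", "unassigned"),
    P2 = c("P1", "P2", "P3", "unassigned"),
    P3 = c("P2", "P3", "P4", "unassigned"),
    P4 = c("P3", "P4", "unassigned")
  )
  set.seed(23)
  for (rep in 1:200) {
    i <- sample(4, 1)
    obs <- c(pw$dlc_small[i], pw$dlc_large[i]) + rnorm(2, sd = 0.5)
    lab <- classify_event(obs, pw)$label
    expect_true(lab %in% neighbours[[pw$id[i]]])
  }
})

test_that("tabulation reports counts, frequencies and histograms", {
  asg <- tibble::tibble(
    curve_id = sprintf("c%d", 1:4),
    n_steps = c(1L, 1L, 2L, 2L),
    dlc_first = c(11.2, 11.4, 5.1, 6.2),
    dlc_second = c(NA, NA, 6.2, 5.3),
    label = c("one_step", "one_step", "P1", "P1"),
    anchor = c(NA, NA, "Cys49(51)", "Cys49(51)"),
    direction = c(NA, NA, "N", "C"),
    match_distance = c(NA, NA, 0.1, 0.2),
    tie = FALSE
  )
  st <- tabulate_pathways(asg)
  expect_equal(st$n_assigned, 4L)
  expect_equal(
    st$by_label$frequency[st$by_label$label == "one_step"], 0.5
  )
  expect_equal(sum(st$by_label$frequency, na.rm = TRUE), 1)
  expect_equal(sum(st$histogram_two_step$count), 4L)
  expect_equal(sum(st$histogram_one_step$count), 2L)
  expect_equal(st$direction$frequency, c(0.5, 0.5))

  only_one <- asg[1:2, ]
  st2 <- tabulate_pathways(only_one)
  expect_equal(nrow(st2$histogram_two_step), 0L)
  expect_equal(nrow(st2$direction), 0L)
  expect_error(tabulate_pathways(asg[0, ]), "no assignments")

  g <- glance(st)
  expect_equal(g$one_step_fraction, 0.5)
  expect_equal(g$c_terminal_fraction, 0.5)
  expect_equal(tidy(st), st$by_label)
})

test_that("default pathway construction checks the pair-sum invariant", {
  pw <- default_pathways()
  expect_equal(nrow(pw), 4L)
  expect_equal(pw$dlc_small, c(5.2, 4.1, 3.2, 2.4))
  expect_equal(pw$dlc_large, c(6.1, 7.2, 8.1, 9.3))
  expect_true(all(abs(pw$dlc_small + pw$dlc_large - 11.3) <= 1))
  # theoretical alternative for the Cys45 anchor from the segment table
  pw2 <- default_pathways(theoretical_anchors = "Cys45")
  expect_equal(pw2$dlc_small[pw2$id == "P2"], 3.6)
  expect_equal(pw2$dlc_large[pw2$id == "P2"], 7.5)
  expect_error(default_pathways(mt3_segment_table()[0, ]), "empty")
  expect_error(
    pathway_set("P1", "a", 3, 5, one_step_dlc = 11),
    "do not sum"
  )
})

test_that("classify_events aggregates per curve and feeds tabulation", {
  ds <- simulate_dataset(polyprotein_construct("Zn-aMT"), 30, master_seed = 19)
  ev <- analyze_dataset(ds$curves)
  asg <- classify_events(ev)
  expect_true(all(asg$label %in%
    c("one_step", "P1", "P2", "P3", "P4", "unassigned", "multi_step")))
  # two-step assignments carry a direction unless ambiguous; one-step never
  expect_true(all(is.na(asg$direction[asg$label == "one_step"])))
  st <- tabulate_pathways(asg)
  expect_equal(st$n_total, nrow(asg))
  freq <- st$by_label$frequency
  expect_equal(sum(freq, na.rm = TRUE), 1)
})
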