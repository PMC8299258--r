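#' Instrument and protocol settings for the pulling simulator
#'
#' Constant-velocity pulling protocol parameters. The defaults emulate a
#' typical polyprotein AFM experiment: 6000 nm/s pulling speed, a 40 pN/nm
#' cantilever, Gaussian force noise of 8 pN standard deviation, and one
#' recorded point per 0.025 nm of piezo travel. The fast pulling speed is
#' deliberate: with the fast cluster-rupture kinetics of the
#' metallothionein alpha domain (k_off = 25 1/s), slower ramps let most
#' clusters rupture in the low-force region where no peak can be detected,
#' and place two-step intermediates below the instrument length
#' resolution; at 6000 nm/s cluster ruptures load to ~100 pN and both
#' sub-steps of two-step events are resolvable. The tether length is the
#' contour length of unstructured linkers and tags in series with the
#' folded construct; together with the folded end-to-end extensions of the
#' domains it sets the initial contour length of the stretched chain.
#' Pulling stops when the force reaches `detachment_force`, modelling
#' tip--molecule detachment as a fixed high-force rupture.
#'
#' @param pulling_speed Cantilever base velocity, nm/s (> 0).
#' @param cantilever_stiffness Cantilever spring constant, pN/nm (> 0).
#' @param force_noise_sd Gaussian measurement noise on force, pN (>= 0).
#' @param sampling_interval Piezo travel between recorded points, nm (> 0).
#' @param tether_length Contour length of linkers/tags, nm (>= 0).
#' @param detachment_force Force at which the tether detaches, pN.
#' @param wlc [wlc_parameters()] of the unfolded chain.
#' @return An object of class `simulation_config`.
#' @examples
#' simulation_config()
#' @export
simulation_config <- function(pulling_speed = 6000,
                              cantilever_stiffness = 40,
                              force_noise_sd = 8,
                              sampling_interval = 0.025,
                              tether_length = 5,
                              detachment_force = 300,
                              wlc = wlc_parameters()) {
  if (!is.numeric(pulling_speed) || pulling_speed <= 0) {
    stop("`pulling_speed` must be positive", call. = FALSE)
  }
  stopifnot(
    cantilever_stiffness > 0, force_noise_sd >= 0,
    sampling_interval > 0, tether_length >= 0, detachment_force > 0,
    inherits(wlc, "wlc_parameters")
  )
  structure(
    list(
      pulling_speed = pulling_speed,
      cantilever_stiffness = cantilever_stiffness,
      force_noise_sd = force_noise_sd,
      sampling_interval = sampling_interval,
      tether_length = tether_length,
      detachment_force = detachment_force,
      wlc = wlc
    ),
    class = "simulation_config"
  )
}

# Solve the force balance x + F(x)/kc = z for a vector of piezo positions z
# at fixed contour length (safeguarded Newton; F convex and increasing).
solve_branch <- function(z, lc, kc, wlc) {
  x <- pmin(z, lc * (1 - 1e-4)) * 0.95
  for (i in seq_len(100L)) {
    t <- x / lc
    f <- (wlc$thermal_energy / wlc$persistence_length) *
      (0.25 / (1 - t)^2 - 0.25 + t)
    g <- x + f / kc - z
    if (max(abs(g)) < 1e-9) break
    df <- (wlc$thermal_energy / wlc$persistence_length / lc) *
      (0.5 / (1 - t)^3 + 1)
    x_new <- x - g / (1 + df / kc)
    bad_hi <- x_new >= lc
    x_new[bad_hi] <- (x[bad_hi] + lc) / 2
    bad_lo <- x_new < 0
    x_new[bad_lo] <- x[bad_lo] / 2
    x <- x_new
  }
  t <- x / lc
  list(
    extension = x,
    force = (wlc$thermal_energy / wlc$persistence_length) *
      (0.25 / (1 - t)^2 - 0.25 + t)
  )
}

#' Simulate one constant-velocity pulling curve
#'
#' Kinetic Monte-Carlo simulation of stretching a polyprotein at constant
#' cantilever velocity. At every piezo position the quasi-static force
#' follows from the worm-like chain of the current total contour length in
#' series with the cantilever spring. Every intact unit accumulates rupture
#' hazard `k(F) dt` according to its Bell--Evans kinetics; a unit ruptures
#' when its accumulated hazard crosses an exponentially distributed
#' threshold, adding its contour-length increment to the chain and dropping
#' the force. Metal-cluster domains first draw an unfolding scenario
#' ([choose_unfolding_scenario()]): one-step events release the full
#' increment at once, two-step events release the two pathway increments in
#' direction order, the second stage governed by the mixture's intermediate
#' kinetics. After the last rupture the tether detaches at the configured
#' detachment force (recorded, but not a ground-truth unfolding event).
#' Gaussian measurement noise is added to the recorded force only; the
#' rupture dynamics see the noise-free force.
#'
#' @param construct List of [domain_spec()]s (at least one), e.g. from
#'   [polyprotein_construct()].
#' @param config A [simulation_config()].
#' @param seed Integer seed; the curve is fully reproducible given
#'   (construct, config, seed).
#' @param curve_id Identifier stored in the curve metadata.
#' @return A list with elements `curve` (a `fx_curve` tibble with columns
#'   `extension` and `force` and a metadata attribute) and `truth` (tibble
#'   of ground-truth rupture events: `event`, `domain`, `scenario`,
#'   `anchor`, `direction`, `step`, `dlc_true`, `force_true`,
#'   `extension_true`, `loading_rate_true`).
#' @examples
#' sim <- simulate_curve(polyprotein_construct("Zn-aMT"),
#'   simulation_config(force_noise_sd = 0),
#'   seed = 1
#' )
#' sim$truth
#' @export
simulate_curve <- function(construct, config = simulation_config(), seed = 1,
                           curve_id = paste0("curve_", seed)) {
  stopifnot(is.list(construct), length(construct) >= 1L)
  if (inherits(construct, "domain_spec")) construct <- list(construct)
  lapply(construct, function(d) stopifnot(inherits(d, "domain_spec")))
  stopifnot(inherits(config, "simulation_config"))
  set.seed(as.integer(seed))

  kc <- config$cantilever_stiffness
  wlc <- config$wlc
  kt <- wlc$thermal_energy
  dz <- config$sampling_interval
  dt <- dz / config$pulling_speed

  # --- draw scenarios for mixture domains, build the stage queue ----------
  units <- list() # each: name, scenario info, stages (list of dlc+kinetic)
  for (d in construct) {
    if (is.null(d$kinetic)) next # never unfolds (apo): no stages
    if (!is.null(d$dlc)) {
      units[[length(units) + 1L]] <- list(
        name = d$name, scenario = "fixed", anchor = NA_character_,
        direction = NA_character_,
        stages = list(list(dlc = d$dlc, kinetic = d$kinetic))
      )
    } else {
      sc <- choose_unfolding_scenario(d$mixture, 1)
      ik <- d$mixture$intermediate_kinetic
      if (is.null(ik)) ik <- d$kinetic
      stages <- if (sc$scenario == "one_step") {
        list(list(dlc = sc$dlc_first, kinetic = d$kinetic))
      } else {
        list(
          list(dlc = sc$dlc_first, kinetic = d$kinetic),
          list(dlc = sc$dlc_second, kinetic = ik)
        )
      }
      units[[length(units) + 1L]] <- list(
        name = d$name, scenario = sc$scenario, anchor = sc$anchor,
        direction = sc$direction, stages = stages
      )
    }
  }

  l0 <- config$tether_length +
    sum(vapply(construct, `[[`, numeric(1), "folded_extension"))
  if (l0 <= 0) stop("initial contour length must be positive", call. = FALSE)
  total_dlc <- sum(vapply(
    units,
    function(u) sum(vapply(u$stages, `[[`, numeric(1), "dlc")), numeric(1)
  ))
  lc_final <- l0 + total_dlc
  x_det <- wlc_extension(config$detachment_force, lc_final, wlc)
  # leave room for the zero-force tail recorded after detachment
  z_max <- x_det + config$detachment_force / kc + 2.5
  z <- seq(0, z_max, by = dz)
  n <- length(z)

  # exponential rupture thresholds; stage-2 thresholds drawn at activation
  active <- lapply(units, function(u) {
    list(
      unit = u, stage = 1L, hazard = 0,
      threshold = stats::rexp(1)
    )
  })

  extension <- numeric(n)
  force <- numeric(n)
  events <- list()
  i0 <- 1L
  lc <- l0
  n_points <- n

  while (TRUE) {
    idx <- i0:n
    br <- solve_branch(z[idx], lc, kc, wlc)
    # first index at which each active unit ruptures
    m <- length(idx)
    rupture_at <- rep.int(NA_integer_, length(active))
    cums <- vector("list", length(active))
    for (a in seq_along(active)) {
      st <- active[[a]]
      k <- bell_rate(br$force, st$unit$stages[[st$stage]]$kinetic, kt)
      cum <- st$hazard + cumsum(k * dt)
      cums[[a]] <- cum
      hit <- which(cum >= st$threshold)
      if (length(hit)) rupture_at[a] <- hit[1L]
    }
    detach_at <- which(br$force >= config$detachment_force)
    detach_at <- if (length(detach_at)) detach_at[1L] else m
    first <- suppressWarnings(min(rupture_at, na.rm = TRUE))

    if (is.finite(first) && first < detach_at) {
      j <- first
      who <- which(rupture_at == first)[1L]
      g <- i0 + j - 1L
      extension[i0:g] <- br$extension[seq_len(j)]
      force[i0:g] <- br$force[seq_len(j)]
      st <- active[[who]]
      stage <- st$unit$stages[[st$stage]]
      k_wlc <- wlc_stiffness(br$extension[j], lc, wlc)
      events[[length(events) + 1L]] <- tibble::tibble(
        domain = st$unit$name, scenario = st$unit$scenario,
        anchor = st$unit$anchor, direction = st$unit$direction,
        step = st$stage, dlc_true = stage$dlc,
        force_true = br$force[j], extension_true = br$extension[j],
        loading_rate_true = config$pulling_speed /
          (1 / k_wlc + 1 / kc)
      )
      # survivors keep their accumulated hazard
      for (a in seq_along(active)) {
        if (a != who) active[[a]]$hazard <- cums[[a]][j]
      }
      if (st$stage < length(st$unit$stages)) {
        active[[who]]$stage <- st$stage + 1L
        active[[who]]$hazard <- 0
        active[[who]]$threshold <- stats::rexp(1)
      } else {
        active[[who]] <- NULL
      }
      lc <- lc + stage$dlc
      i0 <- g + 1L
      if (i0 > n) {
        n_points <- n
        break
      }
    } else {
      # detachment: record branch up to the detachment point, then a short
      # zero-force tail
      j <- detach_at
      g <- i0 + j - 1L
      extension[i0:g] <- br$extension[seq_len(j)]
      force[i0:g] <- br$force[seq_len(j)]
      tail_n <- min(round(2 / dz), n - g)
      if (tail_n > 0) {
        tail_idx <- (g + 1L):(g + tail_n)
        extension[tail_idx] <- br$extension[j] +
          (z[tail_idx] - z[g]) # tip relaxes; separation follows the piezo
        force[tail_idx] <- 0
      }
      n_points <- g + tail_n
      break
    }
  }

  extension <- extension[seq_len(n_points)]
  force <- force[seq_len(n_points)]
  if (config$force_noise_sd > 0) {
    force <- force + stats::rnorm(n_points, 0, config$force_noise_sd)
  }

  truth <- if (length(events)) {
    dplyr::bind_rows(events) |>
      dplyr::mutate(event = dplyr::row_number(), .before = 1)
  } else {
    tibble::tibble(
      event = integer(), domain = character(), scenario = character(),
      anchor = character(), direction = character(), step = integer(),
      dlc_true = numeric(), force_true = numeric(),
      extension_true = numeric(), loading_rate_true = numeric()
    )
  }

  curve <- tibble::tibble(extension = extension, force = force)
  attr(curve, "metadata") <- list(
    curve_id = curve_id, seed = as.integer(seed),
    pulling_speed = config$pulling_speed,
    cantilever_stiffness = config$cantilever_stiffness,
    force_noise_sd = config$force_noise_sd,
    sampling_interval = config$sampling_interval,
    tether_length = config$tether_length,
    detachment_force = config$detachment_force,
    persistence_length = wlc$persistence_length,
    thermal_energy = wlc$thermal_energy,
    construct = paste(vapply(construct, `[[`, character(1), "name"),
      collapse = ","
    )
  )
  class(curve) <- c("fx_curve", class(curve))
  list(curve = curve, truth = truth)
}

#' Simulate a dataset of pulling curves
#'
#' Repeats [simulate_curve()] with per-curve seeds derived deterministically
#' from a master seed. With `dir = NULL` the curves and ground truth are
#' returned in memory; otherwise each curve is written as a TSV file with a
#' JSON ground-truth sidecar plus a JSON manifest listing files and seeds,
#' and the file list is returned.
#'
#' @param construct List of [domain_spec()]s.
#' @param n_curves Number of curves (>= 1).
#' @param master_seed Integer master seed.
#' @param config A [simulation_config()].
#' @param dir Output directory, or `NULL` to keep everything in memory.
#' @return With `dir = NULL`: a list with `curves` (list of `fx_curve`),
#'   `truth` (one tibble with a `curve_id` column) and `manifest` (tibble of
#'   curve ids and seeds). Otherwise the manifest tibble with file paths,
#'   invisibly.
#' @examples
#' ds <- simulate_dataset(polyprotein_construct("marker-only", n_markers = 1),
#'   n_curves = 2, master_seed = 7
#' )
#' ds$manifest
#' @export
simulate_dataset <- function(construct, n_curves, master_seed = 1,
                             config = simulation_config(), dir = NULL) {
  if (!is.numeric(n_curves) || n_curves < 1) {
    stop("`n_curves` must be at least 1", call. = FALSE)
  }
  n_curves <- as.integer(n_curves)
  seeds <- (as.integer(master_seed) + 7919L * seq_len(n_curves)) %% 2147483647L
  ids <- sprintf("curve_%04d", seq_len(n_curves))
  sims <- lapply(seq_len(n_curves), function(i) {
    simulate_curve(construct, config, seed = seeds[i], curve_id = ids[i])
  })
  truth <- dplyr::bind_rows(lapply(seq_len(n_curves), function(i) {
    tr <- sims[[i]]$truth
    if (nrow(tr)) dplyr::mutate(tr, curve_id = ids[i], .before = 1) else tr
  }))
  manifest <- tibble::tibble(
    curve_id = ids, seed = seeds,
    master_seed = as.integer(master_seed)
  )
  if (is.null(dir)) {
    return(list(
      curves = lapply(sims, `[[`, "curve"),
      truth = truth, manifest = manifest
    ))
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", dir, call. = FALSE)
  }
  manifest$curve_file <- file.path(dir, paste0(ids, ".tsv"))
  manifest$truth_file <- file.path(dir, paste0(ids, "_truth.json"))
  for (i in seq_len(n_curves)) {
    write_curve_tsv(sims[[i]]$curve, manifest$curve_file[i])
    jsonlite::write_json(sims[[i]]$truth, manifest$truth_file[i],
      auto_unbox = FALSE, digits = NA
    )
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = FALSE, digits = NA
  )
  invisible(manifest)
}
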