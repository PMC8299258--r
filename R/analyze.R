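#' Selection criteria for single-molecule curves
#'
#' Thresholds implementing the marker-fingerprint selection that certifies
#' a single-molecule tether: a curve is accepted when at least
#' `min_marker_peaks` detected peaks have a contour-length increment inside
#' `marker_dlc_window` and a rupture force of at least `marker_force_min`.
#' The remaining thresholds control peak detection: peaks below
#' `min_peak_force` are ignored, and a rupture is called when the smoothed
#' force falls `drop_threshold` below its running maximum. `force_floor`
#' sets the minimal force of points used in WLC branch fits, and
#' `smooth_window` the moving-average width (points) used for detection
#' only.
#'
#' @param min_marker_peaks Minimal number of marker-like peaks for
#'   acceptance.
#' @param marker_dlc_window Length-2 increment window (nm) identifying
#'   marker peaks.
#' @param marker_force_min Minimal rupture force (pN) of a marker peak.
#'   With several markers in series the weakest-link effect places the
#'   first marker ruptures well below the single-domain most probable
#'   force, so this gate sits below the marker force distribution and the
#'   increment window does the identification.
#' @param min_peak_force Minimal peak force (pN) for any detected peak.
#' @param drop_threshold Force drop (pN) below the running maximum that
#'   calls a rupture.
#' @param force_floor Minimal force (pN) of points entering branch fits.
#' @param smooth_window Odd moving-average window (points) for detection.
#' @param max_dlc Increments above this (nm) are discarded as mis-fits.
#' @return An object of class `selection_criteria`.
#' @examples
#' selection_criteria()
#' @export
selection_criteria <- function(min_marker_peaks = 3,
                               marker_dlc_window = c(16, 20),
                               marker_force_min = 50,
                               min_peak_force = 20,
                               drop_threshold = 15,
                               force_floor = 10,
                               smooth_window = 11,
                               max_dlc = 25) {
  stopifnot(
    min_marker_peaks >= 0,
    length(marker_dlc_window) == 2L,
    marker_dlc_window[1] < marker_dlc_window[2],
    marker_force_min >= 0, min_peak_force >= 0, drop_threshold > 0,
    force_floor >= 0, smooth_window >= 3, smooth_window %% 2 == 1,
    max_dlc > 0
  )
  structure(
    list(
      min_marker_peaks = min_marker_peaks,
      marker_dlc_window = marker_dlc_window,
      marker_force_min = marker_force_min,
      min_peak_force = min_peak_force,
      drop_threshold = drop_threshold,
      force_floor = force_floor,
      smooth_window = smooth_window,
      max_dlc = max_dlc
    ),
    class = "selection_criteria"
  )
}

#' Moving-average smoothing
#'
#' Centred moving average used to stabilise peak detection against
#' measurement noise; never applied to the data entering WLC fits. Edge
#' points are averaged over the available part of the window.
#'
#' @param x Numeric series.
#' @param window Odd window length in points, >= 3 and at most
#'   `length(x)`.
#' @return Smoothed series of the same length.
#' @export
smooth_force <- function(x, window = 11) {
  stopifnot(is.numeric(x), window >= 3, window %% 2 == 1)
  if (window > length(x)) {
    stop("`window` longer than the series", call. = FALSE)
  }
  n <- length(x)
  half <- (window - 1L) / 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Force baseline. The zero-force reference is taken from the detached tail
# at the end of the retraction (the usual AFM convention): unlike the start
# of the curve, which is already under entropic load, the tail carries no
# force. Falls back to the low-extension region when no tail is present.
curve_baseline <- function(curve, window_nm = 1.5) {
  tail_sel <- curve$extension >= max(curve$extension) - window_nm
  if (sum(tail_sel) >= 5L) {
    return(stats::median(curve$force[tail_sel]))
  }
  sel <- curve$extension <= min(curve$extension) + window_nm
  if (sum(sel) < 3L) sel <- seq_len(min(10L, nrow(curve)))
  stats::median(curve$force[sel])
}

#' Detect rupture peaks in a sawtooth force-extension curve
#'
#' Baseline-corrects the force (median of the initial low-extension
#' region), smooths it for detection, and scans for rupture peaks: a peak
#' is called at the running force maximum once the smoothed force has
#' fallen `drop_threshold` below it; the detector re-arms after the force
#' has risen half a threshold above the following valley. Peaks weaker than
#' `min_peak_force` are discarded. The final peak is flagged as the
#' detachment of the tether.
#'
#' @param curve A `fx_curve` tibble (columns `extension`, `force`).
#' @param criteria A [selection_criteria()].
#' @return A tibble with one row per peak: `peak_index` (refined on the
#'   raw trace), `start_index` (beginning of the rising branch),
#'   `rupture_force` (baseline-corrected raw force at the peak, pN),
#'   `is_detachment`. The applied baseline is stored in attribute
#'   `baseline`.
#' @export
detect_peaks <- function(curve, criteria = selection_criteria()) {
  stopifnot(is.data.frame(curve), all(c("extension", "force") %in%
    names(curve)))
  if (nrow(curve) == 0L) {
    stop("empty curve", call. = FALSE)
  }
  baseline <- curve_baseline(curve)
  n_curve <- nrow(curve)
  w <- min(
    criteria$smooth_window,
    if (n_curve %% 2 == 1) n_curve else n_curve - 1L
  )
  if (w < 3L) {
    stop("curve too short for peak detection", call. = FALSE)
  }
  f <- smooth_force(curve$force - baseline, w)
  n <- length(f)
  thr <- criteria$drop_threshold
  peaks <- integer()
  starts <- integer()
  cand <- 1L
  branch_start <- 1L
  valley <- 1L
  falling <- FALSE
  for (i in 2:n) {
    if (!falling) {
      if (f[i] >= f[cand]) {
        cand <- i
      } else if (f[cand] - f[i] >= thr) {
        peaks <- c(peaks, cand)
        starts <- c(starts, branch_start)
        falling <- TRUE
        valley <- i
      }
    } else {
      if (f[i] < f[valley]) {
        valley <- i
      } else if (f[i] - f[valley] >= thr / 2) {
        falling <- FALSE
        cand <- i
        branch_start <- valley
      }
    }
  }
  keep <- f[peaks] >= criteria$min_peak_force
  peaks <- peaks[keep]
  starts <- starts[keep]
  # refine each peak on the raw trace: the smoothed maximum sits up to half
  # a window early and is biased low by the averaged post-rupture points
  raw <- curve$force - baseline
  half <- (w - 1L) %/% 2L
  for (k in seq_along(peaks)) {
    lo <- max(starts[k], peaks[k] - half)
    hi <- min(n, peaks[k] + half)
    peaks[k] <- lo - 1L + which.max(raw[lo:hi])
  }
  out <- tibble::tibble(
    peak_index = peaks,
    start_index = starts,
    rupture_force = raw[peaks],
    is_detachment = seq_along(peaks) == length(peaks)
  )
  attr(out, "baseline") <- baseline
  out
}

#' Fit a worm-like chain to one rising branch
#'
#' Least-squares estimate of the contour length of the stretched tether
#' from the points of a rising branch with (baseline-corrected) force above
#' `force_floor`. The persistence length is fixed by default (contour
#' length is poorly identifiable jointly with persistence length on short
#' branches) but can be co-fitted with `fit_persistence = TRUE`.
#'
#' @param extension,force Branch data (nm, pN), already baseline-corrected.
#' @param wlc [wlc_parameters()]; supplies the fixed persistence length and
#'   thermal energy.
#' @param force_floor Minimal force of points used in the fit, pN.
#' @param fit_persistence Also fit the persistence length.
#' @return A list: `contour_length` (nm), `persistence_length` (nm),
#'   `residual_rms` (pN), `n_points`.
#' @export
fit_branch_wlc <- function(extension, force, wlc = wlc_parameters(),
                           force_floor = 10, fit_persistence = FALSE) {
  keep <- force >= force_floor
  if (sum(keep) < 10L) {
    stop("branch has fewer than 10 points above the force floor",
      call. = FALSE
    )
  }
  x <- extension[keep]
  y <- force[keep]
  x_max <- max(x)
  rss_lc <- function(lc, p) {
    params <- wlc_parameters(p, wlc$thermal_energy)
    sum((wlc_force(x, lc, params) - y)^2)
  }
  if (!fit_persistence) {
    opt <- stats::optimize(rss_lc,
      interval = c(x_max + 1e-3, x_max + 100),
      p = wlc$persistence_length, tol = 1e-6
    )
    lc <- opt$minimum
    p <- wlc$persistence_length
    rss <- opt$objective
  } else {
    obj <- function(par) rss_lc(x_max + exp(par[1]), exp(par[2]))
    opt <- stats::optim(
      c(log(0.1 * x_max + 1), log(wlc$persistence_length)),
      obj
    )
    lc <- x_max + exp(opt$par[1])
    p <- exp(opt$par[2])
    rss <- opt$value
  }
  list(
    contour_length = lc, persistence_length = p,
    residual_rms = sqrt(rss / length(y)), n_points = length(y)
  )
}

#' Contour-length increments from consecutive branch fits
#'
#' `compute_dlc(lc)[i] = lc[i + 1] - lc[i]`: the contour length released by
#' the i-th rupture. `NA` fits propagate to the adjacent increments.
#'
#' @param lc Ordered fitted contour lengths, nm (length >= 1).
#' @return Numeric vector of length `length(lc) - 1` (empty for a single
#'   branch).
#' @examples
#' compute_dlc(c(50, 68)) # 18
#' @export
compute_dlc <- function(lc) {
  stopifnot(is.numeric(lc))
  if (length(lc) < 2L) {
    return(numeric(0))
  }
  diff(lc)
}

#' Analyse one force-extension curve
#'
#' The per-curve pipeline: baseline correction, peak detection
#' ([detect_peaks()]), WLC fit of every rising branch
#' ([fit_branch_wlc()]), contour-length increments ([compute_dlc()]),
#' per-peak loading-rate estimates, and attribution of each peak as
#' `marker` (increment inside the marker window at marker-level force),
#' `detachment` (final peak), `artifact` (negative or implausibly large
#' increment, or failed fit) or `target`.
#'
#' @param curve A `fx_curve` tibble.
#' @param criteria A [selection_criteria()].
#' @param wlc [wlc_parameters()] used in branch fits.
#' @param fit_persistence Co-fit the persistence length per branch.
#' @return An events tibble with one row per detected peak: `curve_id`,
#'   `peak_index`, `rupture_force_pN`, `lc_nm`, `fit_rms_pN`, `dlc_nm`,
#'   `loading_rate_pN_s`, `attribution`, `accepted`.
#' @export
analyze_curve <- function(curve, criteria = selection_criteria(),
                          wlc = wlc_parameters(), fit_persistence = FALSE) {
  meta <- attr(curve, "metadata")
  curve_id <- if (!is.null(meta$curve_id)) {
    as.character(meta$curve_id)
  } else {
    "curve"
  }
  peaks <- detect_peaks(curve, criteria)
  baseline <- attr(peaks, "baseline")
  n_pk <- nrow(peaks)
  empty <- tibble::tibble(
    curve_id = character(), peak_index = integer(),
    rupture_force_pN = numeric(), lc_nm = numeric(), fit_rms_pN = numeric(),
    dlc_nm = numeric(), loading_rate_pN_s = numeric(),
    attribution = character(), accepted = logical()
  )
  if (n_pk == 0L) {
    return(empty)
  }
  force_c <- curve$force - baseline
  lc <- rep(NA_real_, n_pk)
  rms <- rep(NA_real_, n_pk)
  rate <- rep(NA_real_, n_pk)
  rupture_force <- peaks$rupture_force
  for (i in seq_len(n_pk)) {
    idx <- peaks$start_index[i]:peaks$peak_index[i]
    fit <- tryCatch(
      fit_branch_wlc(curve$extension[idx], force_c[idx],
        wlc = wlc,
        force_floor = criteria$force_floor,
        fit_persistence = fit_persistence
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      lc[i] <- fit$contour_length
      rms[i] <- fit$residual_rms
      # noise-free rupture-force estimate: the fitted WLC evaluated at the
      # peak extension
      p_fit <- wlc_parameters(fit$persistence_length, wlc$thermal_energy)
      x_pk <- min(
        curve$extension[peaks$peak_index[i]],
        fit$contour_length * (1 - 1e-6)
      )
      rupture_force[i] <- wlc_force(x_pk, fit$contour_length, p_fit)
    }
    rate[i] <- tryCatch(
      estimate_loading_rate(curve$extension[idx], force_c[idx], meta),
      error = function(e) NA_real_
    )
  }
  dlc <- c(compute_dlc(lc), NA_real_)
  attribution <- rep("target", n_pk)
  attribution[n_pk] <- "detachment"
  is_marker <- !is.na(dlc) &
    dlc >= criteria$marker_dlc_window[1] &
    dlc <= criteria$marker_dlc_window[2] &
    rupture_force >= criteria$marker_force_min
  attribution[is_marker & attribution != "detachment"] <- "marker"
  bad <- seq_len(n_pk) < n_pk &
    (is.na(lc) | is.na(dlc) | dlc <= 0 | dlc > criteria$max_dlc)
  attribution[bad & attribution == "target"] <- "artifact"
  accepted <- sum(attribution == "marker") >= criteria$min_marker_peaks
  tibble::tibble(
    curve_id = curve_id,
    peak_index = peaks$peak_index,
    rupture_force_pN = rupture_force,
    lc_nm = lc, fit_rms_pN = rms, dlc_nm = dlc,
    loading_rate_pN_s = rate,
    attribution = attribution,
    accepted = accepted
  )
}

#' Analyse a dataset of curves
#'
#' Runs [analyze_curve()] over a list of curves (or a dataset directory
#' written by [simulate_dataset()]) and binds the per-peak events into one
#' table.
#'
#' @param curves List of `fx_curve` tibbles, or a directory path.
#' @param ... Passed to [analyze_curve()].
#' @return Combined events tibble.
#' @export
analyze_dataset <- function(curves, ...) {
  if (is.character(curves) && length(curves) == 1L) {
    curves <- read_curve_dataset(curves)
  }
  stopifnot(is.list(curves), length(curves) >= 1L)
  dplyr::bind_rows(lapply(curves, analyze_curve, ...))
}

#' Single-molecule selection of an analysed curve
#'
#' Applies the marker-fingerprint acceptance rule to the events of one
#' curve: accept when at least `min_marker_peaks` marker-attributed peaks
#' are present, and return the increments attributed to the target domain.
#' Rejection is a normal outcome, as is acceptance with an empty target
#' list (e.g. apo constructs, which show only marker peaks).
#'
#' @param events Events tibble of a single curve (from [analyze_curve()]).
#' @param criteria A [selection_criteria()].
#' @return A list: `accepted` (logical), `n_markers`, `target_dlc`
#'   (increments, temporal order), `target_events` (tibble).
#' @export
select_single_molecule <- function(events, criteria = selection_criteria()) {
  stopifnot(all(c("attribution", "dlc_nm", "peak_index") %in% names(events)))
  n_markers <- sum(events$attribution == "marker")
  accepted <- n_markers >= criteria$min_marker_peaks
  target <- events |>
    dplyr::filter(.data$attribution == "target") |>
    dplyr::arrange(.data$peak_index)
  list(
    accepted = accepted,
    n_markers = n_markers,
    target_dlc = if (accepted) target$dlc_nm else numeric(0),
    target_events = if (accepted) target else target[0, ]
  )
}
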