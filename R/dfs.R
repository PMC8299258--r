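#' Estimate the loading rate of one rupture event
#'
#' Slope of force versus time over the terminal part of a rising branch.
#' Time is reconstructed from the cantilever base position
#' `z = extension + force / stiffness` travelled at the constant pulling
#' speed; when the stiffness is missing from the metadata the extension
#' alone is used (which overestimates the rate by the ratio of tether to
#' effective stiffness).
#'
#' @param extension,force Branch data (nm, pN), baseline-corrected,
#'   temporal order.
#' @param metadata Curve metadata list; must contain `pulling_speed`
#'   (nm/s), optionally `cantilever_stiffness` (pN/nm).
#' @param fraction Terminal fraction of the branch used for the slope.
#' @return Loading rate in pN/s (0 for a flat branch).
#' @export
estimate_loading_rate <- function(extension, force, metadata,
                                  fraction = 0.2) {
  if (is.null(metadata$pulling_speed)) {
    stop("metadata lacks `pulling_speed`", call. = FALSE)
  }
  n <- length(force)
  if (n < 10L) {
    stop("branch has fewer than 10 points", call. = FALSE)
  }
  z <- if (!is.null(metadata$cantilever_stiffness)) {
    extension + force / metadata$cantilever_stiffness
  } else {
    extension
  }
  time <- z / metadata$pulling_speed
  tail_idx <- max(1L, ceiling(n * (1 - fraction))):n
  if (length(tail_idx) < 3L) tail_idx <- max(1L, n - 4L):n
  t_tail <- time[tail_idx]
  f_tail <- force[tail_idx]
  if (stats::sd(t_tail) == 0) {
    return(0)
  }
  slope <- stats::cov(t_tail, f_tail) / stats::var(t_tail)
  max(slope, 0)
}

#' Bin rupture events by loading rate
#'
#' Splits a dynamic-force-spectroscopy dataset into logarithmically spaced
#' loading-rate bins. Events outside the range are excluded (their count is
#' reported as attribute `n_excluded`). Bin centres are the geometric means
#' of the bin edges, matching the log-linear Bell--Evans model.
#'
#' @param data Tibble with columns `force` (pN) and `loading_rate` (pN/s).
#' @param n_bins Number of bins.
#' @param range Length-2 loading-rate range in pN/s.
#' @return The input tibble restricted to the range, with added columns
#'   `bin` (integer) and `bin_center` (pN/s); attributes `edges` and
#'   `n_excluded`.
#' @examples
#' d <- tibble::tibble(force = c(50, 60, 80), loading_rate = c(1e3, 1e4, 1e5))
#' bin_by_loading_rate(d)
#' @export
bin_by_loading_rate <- function(data, n_bins = 5, range = c(1e3, 3e5)) {
  stopifnot(
    all(c("force", "loading_rate") %in% names(data)),
    n_bins >= 1, length(range) == 2L, range[1] > 0, range[2] > range[1]
  )
  if (nrow(data) == 0L) {
    stop("empty dataset", call. = FALSE)
  }
  if (any(data$force <= 0, na.rm = TRUE)) {
    stop("rupture forces must be positive", call. = FALSE)
  }
  edges <- exp(seq(log(range[1]), log(range[2]), length.out = n_bins + 1))
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  inside <- !is.na(data$loading_rate) &
    data$loading_rate >= range[1] & data$loading_rate <= range[2]
  n_excluded <- sum(!inside)
  if (!any(inside)) {
    stop("all events fall outside the loading-rate range", call. = FALSE)
  }
  out <- data[inside, , drop = FALSE]
  bin <- findInterval(out$loading_rate, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), n_bins)
  out$bin <- bin
  out$bin_center <- centers[bin]
  attr(out, "edges") <- edges
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Most probable force of a sample of rupture forces
#'
#' Mode of a Gaussian kernel density estimate over the forces. The
#' bandwidth is Silverman's normal-reference value rescaled from the
#' n^(-1/5) density-estimation rate to the n^(-1/7) rate that is optimal
#' for mode estimation (a multiplicative factor n^(2/35)); the wider
#' kernel trades a small, nearly location-independent bias for a
#' substantially less variable mode, which matters because the
#' dynamic-force-spectroscopy fit extrapolates the per-bin modes to zero
#' force. Below `min_kde` events the mode of a histogram is used instead;
#' below 5 events the estimate is dropped (`NA`) with a warning.
#'
#' @param forces Numeric vector of rupture forces, pN.
#' @param min_kde Minimal sample size for the kernel density estimate.
#' @return Most probable force in pN (`NA_real_` when dropped). The KDE
#'   bandwidth is attached as attribute `bandwidth` when used.
#' @examples
#' set.seed(1)
#' modal_force(rnorm(200, 60, 10))
#' @export
modal_force <- function(forces, min_kde = 20) {
  forces <- forces[is.finite(forces)]
  n <- length(forces)
  if (n < 5L) {
    warning("fewer than 5 events: most probable force dropped",
      call. = FALSE
    )
    return(NA_real_)
  }
  if (n < min_kde) {
    h <- graphics::hist(forces, breaks = "Sturges", plot = FALSE)
    return(h$mids[which.max(h$counts)])
  }
  bw <- stats::bw.nrd0(forces) * n^(2 / 35)
  d <- stats::density(forces, bw = bw)
  out <- d$x[which.max(d$y)]
  attr(out, "bandwidth") <- d$bw
  out
}

#' Fit the Bell--Evans model to most probable forces
#'
#' Linear regression of the most probable rupture force on the natural
#' logarithm of the loading rate,
#' \deqn{F^\ast = \frac{kT}{\Delta x} \ln r + \frac{kT}{\Delta x}
#'   \ln\frac{\Delta x}{k_\mathrm{off} kT},}
#' from which `delta_x = kT / slope` and
#' `k_off = exp(-intercept/slope) / slope` (rates in pN/s). Standard errors
#' are propagated from the regression coefficients by the delta method;
#' because the error on `k_off` is multiplicative, its geometric standard
#' error is reported as well.
#'
#' @param forces Most probable forces per bin, pN (>= 3 finite values).
#' @param rates Corresponding loading rates (bin centres), pN/s.
#' @param thermal_energy Thermal energy kT, pN nm.
#' @param weights Optional regression weights (e.g. per-bin counts).
#' @return An object of class `bell_evans_fit`: a list with `k_off`,
#'   `delta_x`, `k_off_se`, `k_off_geometric_se`, `delta_x_se`, `slope`,
#'   `intercept` (with SEs), `n_bins`, `thermal_energy`, `data`, and the
#'   underlying `lm` fit.
#' @examples
#' kp <- kinetic_parameters(25, 0.2)
#' r <- 10^seq(3, 5.5, length.out = 5)
#' fit <- fit_bell_evans(most_probable_force(r, kp), r)
#' fit$k_off
#' @export
fit_bell_evans <- function(forces, rates, thermal_energy = 4.114,
                           weights = NULL) {
  keep <- is.finite(forces) & is.finite(rates) & rates > 0
  forces <- forces[keep]
  rates <- rates[keep]
  if (!is.null(weights)) weights <- weights[keep]
  if (length(forces) < 3L) {
    stop("Bell-Evans fit needs at least 3 (force, rate) points",
      call. = FALSE
    )
  }
  df <- data.frame(force = forces, log_rate = log(rates))
  fit <- stats::lm(force ~ log_rate, data = df, weights = weights)
  s <- stats::coef(fit)[["log_rate"]]
  a <- stats::coef(fit)[["(Intercept)"]]
  if (!is.finite(s) || s <= 0) {
    stop("non-positive slope: forces do not increase with loading rate; ",
      "no kinetic parameters recovered",
      call. = FALSE
    )
  }
  # vcov warns on an exactly collinear (perfect) fit; that case is fine here
  vc <- suppressWarnings(stats::vcov(fit))
  var_a <- vc[1, 1]
  var_s <- vc[2, 2]
  cov_as <- vc[1, 2]
  delta_x <- thermal_energy / s
  delta_x_se <- thermal_energy / s^2 * sqrt(var_s)
  k_off <- exp(-a / s) / s
  # gradient of log(k_off) = -a/s - log(s) w.r.t. (a, s)
  d_log_da <- -1 / s
  d_log_ds <- a / s^2 - 1 / s
  var_log_koff <- d_log_da^2 * var_a + d_log_ds^2 * var_s +
    2 * d_log_da * d_log_ds * cov_as
  se_log_koff <- sqrt(pmax(var_log_koff, 0))
  structure(
    list(
      k_off = k_off,
      delta_x = delta_x,
      k_off_se = k_off * se_log_koff,
      k_off_geometric_se = exp(se_log_koff),
      delta_x_se = delta_x_se,
      slope = s, slope_se = sqrt(var_s),
      intercept = a, intercept_se = sqrt(var_a),
      n_bins = length(forces),
      thermal_energy = thermal_energy,
      data = tibble::tibble(
        loading_rate = rates, modal_force = forces,
        fitted = stats::fitted(fit)
      ),
      lm = fit
    ),
    class = "bell_evans_fit"
  )
}

#' @export
print.bell_evans_fit <- function(x, ...) {
  cat("Bell-Evans fit (", x$n_bins, " loading-rate bins)\n", sep = "")
  cat(sprintf(
    "  k_off   = %.4g 1/s (geometric SE factor %.3g)\n",
    x$k_off, x$k_off_geometric_se
  ))
  cat(sprintf("  delta_x = %.4g nm (SE %.2g)\n", x$delta_x, x$delta_x_se))
  cat(sprintf(
    "  slope kT/delta_x = %.4g pN per e-fold of loading rate\n",
    x$slope
  ))
  invisible(x)
}

#' Run a dynamic-force-spectroscopy recovery experiment
#'
#' Convenience driver for the standard DFS protocol: sample `n_per_bin`
#' rupture forces at each of `n_bins` log-spaced loading rates (the
#' geometric bin centres of `range`), estimate the most probable force per
#' bin ([modal_force()]), and fit the Bell--Evans line
#' ([fit_bell_evans()]).
#'
#' @param params True [kinetic_parameters()] used to generate the forces.
#' @param n_per_bin Events per loading-rate bin.
#' @param n_bins Number of bins.
#' @param range Loading-rate range, pN/s.
#' @param thermal_energy Thermal energy kT, pN nm.
#' @return A list: `fit` (a `bell_evans_fit`), `dataset` (tibble of all
#'   sampled events), `modal` (tibble of per-bin modal forces).
#' @examples
#' set.seed(1)
#' rec <- dfs_recovery(kinetic_parameters(25, 0.2), n_per_bin = 100)
#' rec$fit$k_off
#' @export
dfs_recovery <- function(params, n_per_bin = 300, n_bins = 5,
                         range = c(1e3, 3e5), thermal_energy = 4.114) {
  stopifnot(inherits(params, "kinetic_parameters"))
  edges <- exp(seq(log(range[1]), log(range[2]), length.out = n_bins + 1))
  centers <- sqrt(edges[-1] * edges[-length(edges)])
  dataset <- purrr::map_dfr(centers, function(r) {
    tibble::tibble(
      loading_rate = r,
      force = sample_rupture_force(n_per_bin, r, params, thermal_energy)
    )
  })
  modal <- dataset |>
    dplyr::group_by(.data$loading_rate) |>
    dplyr::summarise(
      modal_force = as.numeric(modal_force(.data$force)),
      n = dplyr::n(), .groups = "drop"
    )
  fit <- fit_bell_evans(modal$modal_force, modal$loading_rate,
    thermal_energy = thermal_energy
  )
  list(fit = fit, dataset = dataset, modal = modal)
}

#' Write a Bell--Evans fit report
#'
#' Writes the fitted parameters as JSON and the per-bin table as TSV.
#'
#' @param fit A `bell_evans_fit`.
#' @param path Output path for the JSON report; the bin table is written
#'   next to it with suffix `_bins.tsv`.
#' @return `path`, invisibly.
#' @export
write_bell_evans_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bell_evans_fit"))
  jsonlite::write_json(
    list(
      k_off = fit$k_off, delta_x = fit$delta_x,
      k_off_se = fit$k_off_se,
      k_off_geometric_se = fit$k_off_geometric_se,
      delta_x_se = fit$delta_x_se,
      slope = fit$slope, intercept = fit$intercept,
      n_bins = fit$n_bins, thermal_energy = fit$thermal_energy
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  bins_path <- sub("\\.json$", "_bins.tsv", path)
  if (identical(bins_path, path)) bins_path <- paste0(path, "_bins.tsv")
  utils::write.table(as.data.frame(fit$data), bins_path,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
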