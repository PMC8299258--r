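#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a force-extension curve
#'
#' Sawtooth force-extension trace, optionally overlaid with the worm-like
#' chain fits of detected branches.
#'
#' @param object A `fx_curve` tibble.
#' @param events Optional events tibble from [analyze_curve()]; fitted
#'   branches are drawn as dashed WLC curves and peaks marked.
#' @param wlc [wlc_parameters()] used for the overlays.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fx_curve <- function(object, events = NULL,
                              wlc = wlc_parameters(), ...) {
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$extension, y = .data$force)
  ) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey30") +
    ggplot2::labs(x = "Extension (nm)", y = "Force (pN)")
  if (!is.null(events) && nrow(events) > 0) {
    fits <- events |>
      dplyr::filter(is.finite(.data$lc_nm)) |>
      dplyr::rowwise() |>
      dplyr::group_map(function(row, key) {
        x <- seq(0, row$lc_nm * 0.98, length.out = 120)
        tibble::tibble(
          peak_index = row$peak_index,
          extension = x,
          force = wlc_force(x, row$lc_nm, wlc)
        )
      }) |>
      dplyr::bind_rows()
    fits <- dplyr::filter(fits, .data$force <= max(object$force))
    p <- p +
      ggplot2::geom_line(
        data = fits,
        ggplot2::aes(group = .data$peak_index),
        linetype = "dashed", colour = "firebrick", linewidth = 0.3
      ) +
      ggplot2::geom_point(
        data = dplyr::mutate(events,
          extension = object$extension[.data$peak_index],
          force = .data$rupture_force_pN
        ),
        ggplot2::aes(colour = .data$attribution), size = 1.6
      )
  }
  p
}

#' Histogram of contour-length increments
#'
#' Contour-length-increment histogram of an events table, split by peak
#' attribution (markers around 18 nm, target-domain events below).
#'
#' @param events Events tibble from [analyze_dataset()].
#' @param binwidth Bin width in nm.
#' @return A ggplot object.
#' @export
plot_dlc_histogram <- function(events, binwidth = 0.4) {
  data <- dplyr::filter(
    events, is.finite(.data$dlc_nm),
    .data$attribution %in% c("marker", "target")
  )
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$dlc_nm,
    fill = .data$attribution
  )) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
      colour = "grey20", linewidth = 0.1) +
    ggplot2::labs(
      x = expression(Delta * L[c] ~ "(nm)"),
      y = "Count", fill = NULL
    )
}

#' Plot pathway statistics
#'
#' Bar chart of pathway frequencies with the N/C direction split of
#' two-step events.
#'
#' @param object A `pathway_statistics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_statistics <- function(object, ...) {
  data <- object$by_label |>
    dplyr::filter(.data$label %in% c("one_step", "P1", "P2", "P3", "P4"))
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$label,
    y = .data$frequency
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Frequency among assigned events")
}

#' Plot a Bell--Evans dynamic force spectrum
#'
#' Most probable force versus loading rate (log axis) with the fitted
#' Bell--Evans line and, as a sensitivity envelope, hypothetical fits with
#' the off-rate multiplied and divided by `envelope_factor` at the fitted
#' `delta_x`.
#'
#' @param object A `bell_evans_fit`.
#' @param events Optional tibble with columns `loading_rate` and `force` of
#'   the underlying rupture events (drawn as grey points).
#' @param envelope_factor Multiplicative k_off factor of the dashed
#'   envelope.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bell_evans_fit <- function(object, events = NULL,
                                    envelope_factor = 3, ...) {
  rng <- range(object$data$loading_rate)
  grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = 50))
  kt <- object$thermal_energy
  line_for <- function(k_off) {
    params <- kinetic_parameters(k_off, object$delta_x)
    tibble::tibble(
      loading_rate = grid,
      force = most_probable_force(grid, params, kt),
      k_off = k_off
    )
  }
  fit_line <- line_for(object$k_off)
  env <- dplyr::bind_rows(
    line_for(object$k_off * envelope_factor),
    line_for(object$k_off / envelope_factor)
  )
  p <- ggplot2::ggplot(mapping = ggplot2::aes(
    x = .data$loading_rate,
    y = .data$force
  ))
  if (!is.null(events)) {
    p <- p + ggplot2::geom_point(
      data = events, colour = "grey70",
      size = 0.5, alpha = 0.5
    )
  }
  p +
    ggplot2::geom_line(data = env, ggplot2::aes(group = .data$k_off),
      linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line(data = fit_line, colour = "black") +
    ggplot2::geom_point(
      data = dplyr::rename(object$data, force = "modal_force"),
      shape = 18, size = 3
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Loading rate (pN/s)", y = "Force (pN)")
}
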