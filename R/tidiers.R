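#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Bell--Evans fit
#'
#' @param x A `bell_evans_fit` from [fit_bell_evans()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`k_off`, `delta_x`,
#'   `slope`, `intercept`): `term`, `estimate`, `std.error`.
#' @export
tidy.bell_evans_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_off", "delta_x", "slope", "intercept"),
    estimate = c(x$k_off, x$delta_x, x$slope, x$intercept),
    std.error = c(x$k_off_se, x$delta_x_se, x$slope_se, x$intercept_se)
  )
}

#' Glance at a Bell--Evans fit
#'
#' @param x A `bell_evans_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_bins`, `r.squared`, `sigma`,
#'   `k_off_geometric_se`.
#' @export
glance.bell_evans_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$lm))
  tibble::tibble(
    n_bins = x$n_bins,
    r.squared = s$r.squared,
    sigma = s$sigma,
    k_off_geometric_se = x$k_off_geometric_se
  )
}

#' Tidy pathway statistics
#'
#' @param x A `pathway_statistics` object from [tabulate_pathways()].
#' @param ... Unused.
#' @return The per-label tibble of counts and frequencies.
#' @export
tidy.pathway_statistics <- function(x, ...) {
  x$by_label
}

#' Glance at pathway statistics
#'
#' @param x A `pathway_statistics` object.
#' @param ... Unused.
#' @return A one-row tibble: totals, one-step fraction among assigned
#'   events, and C-terminal fraction among direction-resolved two-step
#'   events.
#' @export
glance.pathway_statistics <- function(x, ...) {
  one <- x$by_label$frequency[x$by_label$label == "one_step"]
  c_frac <- x$direction$frequency[x$direction$direction == "C"]
  tibble::tibble(
    n_total = x$n_total,
    n_assigned = x$n_assigned,
    one_step_fraction = if (length(one)) one else NA_real_,
    c_terminal_fraction = if (length(c_frac)) c_frac else NA_real_
  )
}
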