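#' Worm-like chain parameters
#'
#' Bundle of the two physical constants entering the Marko--Siggia worm-like
#' chain (WLC) interpolation: the persistence length `p` (nm) and the thermal
#' energy `kT` (pN nm). The defaults (`p = 0.4` nm, `kT = 4.114` pN nm, i.e.
#' 298 K) are typical values for polyprotein stretching experiments; the
#' persistence length of an unfolded polypeptide is not a universal constant,
#' so both are configurable everywhere they are used.
#'
#' @param persistence_length Persistence length in nm. Must be positive.
#' @param thermal_energy Thermal energy kT in pN nm. Must be positive.
#' @return An object of class `wlc_parameters` (a named list).
#' @examples
#' wlc_parameters()
#' wlc_parameters(persistence_length = 0.36)
#' @export
wlc_parameters <- function(persistence_length = 0.4, thermal_energy = 4.114) {
  stopifnot(
    is.numeric(persistence_length), length(persistence_length) == 1L,
    is.finite(persistence_length), persistence_length > 0,
    is.numeric(thermal_energy), length(thermal_energy) == 1L,
    is.finite(thermal_energy), thermal_energy > 0
  )
  structure(
    list(
      persistence_length = persistence_length,
      thermal_energy = thermal_energy
    ),
    class = "wlc_parameters"
  )
}

#' @export
print.wlc_parameters <- function(x, ...) {
  cat(
    "WLC parameters: p =", x$persistence_length, "nm, kT =",
    x$thermal_energy, "pN nm\n"
  )
  invisible(x)
}

#' Worm-like chain entropic force
#'
#' Marko--Siggia interpolation for the force of a WLC polymer held at a given
#' end-to-end extension:
#' \deqn{F(x) = \frac{kT}{p}\left[\frac{1}{4(1 - x/L_c)^2} - \frac14 +
#'   \frac{x}{L_c}\right]}
#' The force is zero at zero extension, strictly increasing, and diverges as
#' the extension approaches the contour length. Vectorised over `extension`
#' and `contour_length`.
#'
#' @param extension End-to-end extension in nm; must satisfy
#'   `0 <= extension < contour_length`.
#' @param contour_length Contour length in nm; must be positive.
#' @param params A [wlc_parameters()] object.
#' @return Force in pN (same length as the recycled inputs).
#' @seealso [wlc_extension()] for the numerical inverse, [wlc_stiffness()]
#'   for the derivative dF/dx.
#' @examples
#' wlc_force(15, 30)           # half extension
#' wlc_force(c(5, 15, 25), 30) # monotone increasing
#' @export
wlc_force <- function(extension, contour_length, params = wlc_parameters()) {
  stopifnot(is.numeric(extension), is.numeric(contour_length))
  if (any(!is.finite(contour_length)) || any(contour_length <= 0)) {
    stop("`contour_length` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(extension)) || any(extension < 0)) {
    stop("`extension` must be non-negative and finite", call. = FALSE)
  }
  if (any(extension >= contour_length)) {
    stop("`extension` must be strictly less than `contour_length`",
      call. = FALSE
    )
  }
  t <- extension / contour_length
  (params$thermal_energy / params$persistence_length) *
    (0.25 / (1 - t)^2 - 0.25 + t)
}

#' Worm-like chain stiffness dF/dx
#'
#' Derivative of the Marko--Siggia force with respect to extension, used for
#' the series-spring compliance of polymer plus cantilever and for effective
#' loading-rate estimates.
#'
#' @inheritParams wlc_force
#' @return Stiffness in pN/nm.
#' @export
wlc_stiffness <- function(extension, contour_length, params = wlc_parameters()) {
  t <- extension / contour_length
  (params$thermal_energy / params$persistence_length / contour_length) *
    (0.5 / (1 - t)^3 + 1)
}

#' Invert the worm-like chain: extension at a given force
#'
#' Numerical inverse of [wlc_force()] by safeguarded Newton iteration. The
#' returned extension satisfies `wlc_force(x) == force` to within `tol` (in
#' pN). Vectorised over `force` and `contour_length`.
#'
#' @param force Force in pN; must be non-negative.
#' @param contour_length Contour length in nm.
#' @param params A [wlc_parameters()] object.
#' @param tol Convergence tolerance on the force residual, in pN.
#' @return Extension in nm, in `[0, contour_length)`.
#' @examples
#' x <- wlc_extension(50, 30)
#' wlc_force(x, 30) # 50
#' @export
wlc_extension <- function(force, contour_length, params = wlc_parameters(),
                          tol = 1e-9) {
  stopifnot(is.numeric(force), is.numeric(contour_length))
  if (any(!is.finite(force)) || any(force < 0)) {
    stop("`force` must be non-negative and finite", call. = FALSE)
  }
  if (any(contour_length <= 0)) {
    stop("`contour_length` must be positive", call. = FALSE)
  }
  n <- max(length(force), length(contour_length))
  force <- rep_len(force, n)
  lc <- rep_len(contour_length, n)
  # dimensionless force and fractional extension
  f <- force * params$persistence_length / params$thermal_energy
  t <- pmin(f / (1 + f), 0.999) # crude but monotone starting point
  for (i in seq_len(60L)) {
    g <- 0.25 / (1 - t)^2 - 0.25 + t - f
    if (all(abs(g) < tol * params$persistence_length /
      params$thermal_energy)) {
      break
    }
    dg <- 0.5 / (1 - t)^3 + 1
    t_new <- t - g / dg
    # keep iterates inside (0, 1)
    t_new[t_new <= 0] <- t[t_new <= 0] / 2
    too_big <- t_new >= 1
    t_new[too_big] <- (t[too_big] + 1) / 2
    t <- t_new
  }
  t * lc
}

#' Contour-length increment released by an unfolding event
#'
#' The contour-length gain when a folded segment of `n_aa` amino acids held at
#' a folded end-to-end distance `folded_distance` unfolds completely:
#' `residue_length * n_aa - folded_distance`. With the canonical
#' 0.36 nm per residue this is the standard AFM-SMFS identity used to map a
#' measured \eqn{\Delta L_c} onto a protein segment; e.g. a 34-residue
#' segment whose anchoring cysteines sit 1.3 nm apart in the folded
#' structure yields 0.36*34 - 1.3 = 10.94 nm (quoted as 10.9 nm).
#'
#' @param n_aa Number of amino acids in the segment (non-negative).
#' @param folded_distance Distance between the segment ends in the folded
#'   structure, nm (non-negative).
#' @param residue_length Contour length per residue, nm/aa; default 0.36.
#' @return Contour-length increment in nm. A warning is issued when a
#'   non-empty segment yields a non-positive increment (folded distance
#'   longer than the stretched segment).
#' @examples
#' contour_increment(34, 1.3) # 10.94, the alpha-domain one-step increment
#' contour_increment(25, 1.2) # 7.8, the beta-domain increment
#' @export
contour_increment <- function(n_aa, folded_distance, residue_length = 0.36) {
  stopifnot(
    is.numeric(n_aa), all(n_aa >= 0),
    is.numeric(folded_distance), all(folded_distance >= 0),
    is.numeric(residue_length), all(residue_length > 0)
  )
  dlc <- residue_length * n_aa - folded_distance
  if (any(dlc <= 0 & n_aa > 0)) {
    warning("segment shorter than its folded end-to-end distance: ",
      "non-positive contour-length increment",
      call. = FALSE
    )
  }
  dlc
}
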