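#' Bell--Evans kinetic parameters
#'
#' A (k_off, delta_x) pair describing force-activated bond rupture: `k_off`
#' is the spontaneous (zero-force) dissociation rate in 1/s and `delta_x`
#' the distance from the bound state to the dissociation transition state
#' along the pulling coordinate, in nm.
#'
#' @param k_off Zero-force off-rate, 1/s (> 0).
#' @param delta_x Distance to the transition state, nm (> 0).
#' @return An object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(k_off = 25, delta_x = 0.20)
#' @export
kinetic_parameters <- function(k_off, delta_x) {
  stopifnot(
    is.numeric(k_off), length(k_off) == 1L, is.finite(k_off), k_off > 0,
    is.numeric(delta_x), length(delta_x) == 1L, is.finite(delta_x),
    delta_x > 0
  )
  structure(list(k_off = k_off, delta_x = delta_x),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Bell-Evans kinetics: k_off =", x$k_off, "1/s, delta_x =",
    x$delta_x, "nm\n")
  invisible(x)
}

#' Force-dependent rupture rate (Bell model)
#'
#' \deqn{k(F) = k_\mathrm{off} \exp(F \Delta x / kT)}
#' Mechanical force tilts the energy landscape and lowers the dissociation
#' barrier, accelerating rupture exponentially.
#'
#' @param force Applied force in pN (non-negative); vectorised.
#' @param params A [kinetic_parameters()] object.
#' @param thermal_energy Thermal energy kT in pN nm.
#' @return Rupture rate in 1/s.
#' @examples
#' bell_rate(0, kinetic_parameters(25, 0.2))   # k_off
#' bell_rate(100, kinetic_parameters(25, 0.2)) # strongly accelerated
#' @export
bell_rate <- function(force, params, thermal_energy = 4.114) {
  stopifnot(inherits(params, "kinetic_parameters"), is.numeric(force))
  if (any(force < 0)) {
    stop("`force` must be non-negative", call. = FALSE)
  }
  params$k_off * exp(force * params$delta_x / thermal_energy)
}

#' Most probable rupture force at a constant loading rate
#'
#' For a constant loading rate r the Bell--Evans rupture-force distribution
#' peaks at
#' \deqn{F^\ast = \frac{kT}{\Delta x}
#'   \ln\!\frac{r\,\Delta x}{k_\mathrm{off}\,kT},}
#' i.e. the most probable force grows linearly with the logarithm of the
#' loading rate with slope kT/delta_x. At very low loading rates the
#' logarithm turns negative; physical forces are non-negative, so the value
#' is clipped at zero (the linear dynamic-force-spectroscopy fit never
#' operates in that regime).
#'
#' @param loading_rate Loading rate in pN/s (> 0); vectorised.
#' @inheritParams bell_rate
#' @return Most probable rupture force in pN.
#' @examples
#' most_probable_force(1e4, kinetic_parameters(25, 0.2))
#' @export
most_probable_force <- function(loading_rate, params, thermal_energy = 4.114) {
  stopifnot(inherits(params, "kinetic_parameters"), is.numeric(loading_rate))
  if (any(loading_rate <= 0)) {
    stop("`loading_rate` must be positive", call. = FALSE)
  }
  f <- (thermal_energy / params$delta_x) *
    log(loading_rate * params$delta_x / (params$k_off * thermal_energy))
  pmax(f, 0)
}

#' Analytic survival function of the Bell--Evans rupture force
#'
#' Probability that a bond loaded at constant rate r survives to force F:
#' \deqn{S(F) = \exp\!\left[-\frac{k_\mathrm{off} kT}{r\,\Delta x}
#'   \left(e^{F\Delta x/kT} - 1\right)\right]}
#' Used as the closed-form reference distribution for the sampler.
#'
#' @param force Force in pN (non-negative); vectorised.
#' @param loading_rate Loading rate in pN/s (> 0).
#' @inheritParams bell_rate
#' @return Survival probability in (0, 1].
#' @export
rupture_force_survival <- function(force, loading_rate, params,
                                   thermal_energy = 4.114) {
  stopifnot(inherits(params, "kinetic_parameters"))
  phi <- params$k_off * thermal_energy / (loading_rate * params$delta_x)
  exp(-phi * (exp(force * params$delta_x / thermal_energy) - 1))
}

#' Sample rupture forces from the Bell--Evans distribution
#'
#' Draws rupture forces for a bond loaded at constant rate r by inverting the
#' closed-form survival function (inverse-CDF sampling):
#' \deqn{F = \frac{kT}{\Delta x}\log\!\left(1 -
#'   \frac{r\,\Delta x}{k_\mathrm{off} kT}\,\log U\right), \quad
#'   U \sim \mathrm{Unif}(0,1).}
#' Sampling uses R's global RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @param n Number of samples.
#' @param loading_rate Loading rate in pN/s (> 0).
#' @inheritParams bell_rate
#' @return Numeric vector of `n` rupture forces in pN.
#' @examples
#' set.seed(1)
#' f <- sample_rupture_force(1000, 1e4, kinetic_parameters(25, 0.2))
#' mean(f)
#' @export
sample_rupture_force <- function(n, loading_rate, params,
                                 thermal_energy = 4.114) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (!is.numeric(loading_rate) || any(loading_rate <= 0)) {
    stop("`loading_rate` must be positive", call. = FALSE)
  }
  u <- stats::runif(n)
  phi <- params$k_off * thermal_energy / (loading_rate * params$delta_x)
  (thermal_energy / params$delta_x) * log1p(-log(u) / phi)
}
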