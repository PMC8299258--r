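#' Unfolding-scenario mixture for a metal-cluster domain
#'
#' Generative model for how a cluster-bearing domain unfolds in one pulling
#' cycle. With probability `p_one_step` the whole cluster ruptures at once,
#' releasing `one_step_dlc` of contour length; otherwise the event is
#' two-step through one of the pathways in `pathways` (probabilities
#' `pathway_probs`, unconditional, so that
#' `p_one_step + sum(pathway_probs) == 1`), releasing the pathway's two
#' increments in an order set by the unfolding direction: C-terminal-first
#' (large increment first) with probability `p_c_first`, N-terminal-first
#' otherwise.
#'
#' The default numbers are the observed Zn-alpha-domain statistics: one-step
#' 51\%, P1..P4 16/12/10/11\%, C-terminal-first 55\%.
#'
#' For domains whose pathways cannot be resolved (the beta domain), set
#' `unresolved_split = TRUE` and omit `pathways`: two-step events then split
#' `one_step_dlc` at a uniformly drawn point — an explicitly illustrative
#' model, not an inferred pathway structure.
#'
#' @param p_one_step Probability of a one-step rupture.
#' @param pathway_probs Named numeric vector of unconditional pathway
#'   probabilities (names must match `pathways$id`); empty when
#'   `unresolved_split`.
#' @param p_c_first Probability that a two-step event unfolds
#'   C-terminal-first.
#' @param pathways A [pathway_set()] supplying the increment pairs, or
#'   `NULL` with `unresolved_split`.
#' @param one_step_dlc One-step contour-length increment, nm. Defaults to
#'   the pathway-set value.
#' @param intermediate_kinetic [kinetic_parameters()] governing the second
#'   rupture of a two-step event, or `NULL` to reuse the domain kinetics
#'   (the observed pathways have similar frequencies, suggesting similar
#'   bond strengths).
#' @param unresolved_split Draw the two-step split point uniformly instead
#'   of from pathways.
#' @return An object of class `pathway_mixture`.
#' @examples
#' alpha_mixture()
#' @export
pathway_mixture <- function(p_one_step, pathway_probs = numeric(),
                            p_c_first = 0.5, pathways = NULL,
                            one_step_dlc = NULL,
                            intermediate_kinetic = NULL,
                            unresolved_split = FALSE) {
  stopifnot(
    p_one_step >= 0, p_one_step <= 1,
    p_c_first >= 0, p_c_first <= 1
  )
  if (unresolved_split) {
    if (length(pathway_probs) > 0L || !is.null(pathways)) {
      stop("`unresolved_split` mixtures take no pathway structure",
        call. = FALSE
      )
    }
    if (is.null(one_step_dlc) || one_step_dlc <= 0) {
      stop("`one_step_dlc` required for an unresolved-split mixture",
        call. = FALSE
      )
    }
  } else {
    if (is.null(pathways) || !inherits(pathways, "pathway_set")) {
      stop("`pathways` must be a pathway_set", call. = FALSE)
    }
    if (is.null(one_step_dlc)) one_step_dlc <- attr(pathways, "one_step_dlc")
    if (!setequal(names(pathway_probs), pathways$id)) {
      stop("`pathway_probs` names must match the pathway ids", call. = FALSE)
    }
    pathway_probs <- pathway_probs[pathways$id]
    if (any(pathway_probs < 0)) {
      stop("pathway probabilities must be non-negative", call. = FALSE)
    }
    total <- p_one_step + sum(pathway_probs)
    if (abs(total - 1) > 1e-9) {
      stop("p_one_step + sum(pathway_probs) must equal 1 (got ", total, ")",
        call. = FALSE
      )
    }
    pair_sums <- pathways$dlc_small + pathways$dlc_large
    if (any(abs(pair_sums - one_step_dlc) > 1)) {
      stop("pathway pair sums inconsistent with `one_step_dlc`",
        call. = FALSE
      )
    }
  }
  if (!is.null(intermediate_kinetic)) {
    stopifnot(inherits(intermediate_kinetic, "kinetic_parameters"))
  }
  structure(
    list(
      p_one_step = p_one_step,
      pathway_probs = pathway_probs,
      p_c_first = p_c_first,
      pathways = pathways,
      one_step_dlc = one_step_dlc,
      intermediate_kinetic = intermediate_kinetic,
      unresolved_split = unresolved_split
    ),
    class = "pathway_mixture"
  )
}

#' @rdname pathway_mixture
#' @export
alpha_mixture <- function(p_one_step = 0.51,
                          pathway_probs = c(
                            P1 = 0.16, P2 = 0.12,
                            P3 = 0.10, P4 = 0.11
                          ),
                          p_c_first = 0.55,
                          pathways = default_pathways(),
                          intermediate_kinetic = NULL) {
  pathway_mixture(p_one_step, pathway_probs, p_c_first, pathways,
    intermediate_kinetic = intermediate_kinetic
  )
}

#' @rdname pathway_mixture
#' @param ... Passed on to `pathway_mixture()`.
#' @export
beta_mixture <- function(p_one_step = 0.5, p_c_first = 0.5, ...) {
  pathway_mixture(p_one_step,
    p_c_first = p_c_first,
    one_step_dlc = contour_increment(25, 1.2),
    unresolved_split = TRUE, ...
  )
}

#' Draw unfolding scenarios from a mixture
#'
#' Categorical sampling of the per-molecule unfolding scenario: one-step, or
#' a (pathway, direction) combination for two-step events. Uses R's global
#' RNG, so draws are reproducible under `set.seed()`.
#'
#' @param mixture A [pathway_mixture()].
#' @param n Number of scenarios to draw.
#' @return A tibble with columns `scenario` (`"one_step"`, a pathway id, or
#'   `"two_step"` for unresolved splits), `anchor`, `direction` (`"N"`,
#'   `"C"`, or `NA` for one-step), `dlc_first`, `dlc_second` (NA for
#'   one-step).
#' @examples
#' set.seed(1)
#' choose_unfolding_scenario(alpha_mixture(), 5)
#' @export
choose_unfolding_scenario <- function(mixture, n = 1) {
  stopifnot(inherits(mixture, "pathway_mixture"), n >= 1)
  if (mixture$unresolved_split) {
    one <- stats::runif(n) < mixture$p_one_step
    direction <- ifelse(stats::runif(n) < mixture$p_c_first, "C", "N")
    # illustrative uniform split of the full increment
    small <- stats::runif(n, 1, mixture$one_step_dlc / 2)
    large <- mixture$one_step_dlc - small
    first <- ifelse(direction == "C", large, small)
    second <- ifelse(direction == "C", small, large)
    return(tibble::tibble(
      scenario = ifelse(one, "one_step", "two_step"),
      anchor = NA_character_,
      direction = ifelse(one, NA_character_, direction),
      dlc_first = ifelse(one, mixture$one_step_dlc, first),
      dlc_second = ifelse(one, NA_real_, second)
    ))
  }
  labels <- c("one_step", mixture$pathways$id)
  probs <- c(mixture$p_one_step, as.numeric(mixture$pathway_probs))
  scenario <- sample(labels, n, replace = TRUE, prob = probs)
  direction <- ifelse(stats::runif(n) < mixture$p_c_first, "C", "N")
  i <- match(scenario, mixture$pathways$id)
  one <- is.na(i)
  direction[one] <- NA_character_
  small <- mixture$pathways$dlc_small[i]
  large <- mixture$pathways$dlc_large[i]
  tibble::tibble(
    scenario = scenario,
    anchor = ifelse(one, NA_character_, mixture$pathways$anchor[i]),
    direction = direction,
    dlc_first = ifelse(one, mixture$one_step_dlc,
      ifelse(direction == "C", large, small)
    ),
    dlc_second = ifelse(one, NA_real_,
      ifelse(direction == "C", small, large)
    )
  )
}

#' Domain specifications for the pulling simulator
#'
#' A domain spec describes one unit of a polyprotein: its name, rupture
#' kinetics, the contour length it releases on unfolding (a fixed increment
#' for marker domains, a [pathway_mixture()] for metal-cluster domains, or
#' nothing for domains that never unfold, e.g. apo forms whose cluster is
#' absent and which contribute no force peak), and the end-to-end distance
#' it contributes to the tether while folded.
#'
#' `marker_domain()` builds a GB1-like fingerprint domain (18 nm increment,
#' rupture near 180 pN at typical instrument settings — see
#' [calibrate_marker_kinetics()]). `mt_alpha_domain()` and
#' `mt_beta_domain()` build metallothionein cluster domains;
#' `rd_domain()` a rubredoxin-like single-metal-site control with a fixed
#' increment (its site ruptures in one step). Zero-force off-rates are
#' 25 1/s (Zn) and 10 1/s (Cd) for the alpha domain and 0.5 1/s (Zn) /
#' 1.6 1/s (Cd) for rubredoxin; transition-state distances default to
#' 0.20 nm (cluster) and 0.15 nm (rubredoxin).
#'
#' @param name Domain name.
#' @param kinetic A [kinetic_parameters()] object, or `NULL` for a domain
#'   that never unfolds.
#' @param dlc Fixed contour-length increment in nm (exclusive with
#'   `mixture`).
#' @param mixture A [pathway_mixture()] (exclusive with `dlc`).
#' @param folded_extension End-to-end distance contributed while folded, nm.
#' @return An object of class `domain_spec`.
#' @examples
#' marker_domain()
#' mt_alpha_domain("Zn")
#' @export
domain_spec <- function(name, kinetic = NULL, dlc = NULL, mixture = NULL,
                        folded_extension = 2) {
  if (!is.null(dlc) && !is.null(mixture)) {
    stop("give either a fixed `dlc` or a `mixture`, not both", call. = FALSE)
  }
  if (!is.null(dlc) && (!is.numeric(dlc) || dlc <= 0)) {
    stop("`dlc` must be a positive length in nm", call. = FALSE)
  }
  if (!is.null(mixture)) stopifnot(inherits(mixture, "pathway_mixture"))
  if (!is.null(kinetic)) stopifnot(inherits(kinetic, "kinetic_parameters"))
  if (is.null(kinetic) && (!is.null(dlc) || !is.null(mixture))) {
    stop("an unfoldable domain needs `kinetic` parameters", call. = FALSE)
  }
  stopifnot(is.numeric(folded_extension), folded_extension >= 0)
  structure(
    list(
      name = name, kinetic = kinetic, dlc = dlc, mixture = mixture,
      folded_extension = folded_extension
    ),
    class = "domain_spec"
  )
}

#' @rdname domain_spec
#' @export
marker_domain <- function(kinetic = calibrate_marker_kinetics(),
                          dlc = 18, folded_extension = 2.5,
                          name = "GB1") {
  domain_spec(name, kinetic, dlc = dlc, folded_extension = folded_extension)
}

#' @rdname domain_spec
#' @param metal `"Zn"` or `"Cd"`; selects the default off-rate.
#' @param apo Build the apo (cluster-free) form, which produces no force
#'   peak.
#' @export
mt_alpha_domain <- function(metal = c("Zn", "Cd"), apo = FALSE,
                            mixture = NULL, kinetic = NULL,
                            folded_extension = 1.5) {
  metal <- match.arg(metal)
  name <- paste0(if (apo) "Apo-a" else paste0(metal, "-a"), "MT")
  if (apo) {
    return(domain_spec(name, folded_extension = folded_extension))
  }
  if (is.null(kinetic)) {
    kinetic <- kinetic_parameters(
      k_off = switch(metal, Zn = 25, Cd = 10),
      delta_x = 0.20
    )
  }
  if (is.null(mixture)) mixture <- alpha_mixture()
  domain_spec(name, kinetic,
    mixture = mixture,
    folded_extension = folded_extension
  )
}

#' @rdname domain_spec
#' @export
mt_beta_domain <- function(metal = c("Zn", "Cd"), apo = FALSE,
                           mixture = NULL, kinetic = NULL,
                           folded_extension = 1.5) {
  metal <- match.arg(metal)
  name <- paste0(if (apo) "Apo-b" else paste0(metal, "-b"), "MT")
  if (apo) {
    return(domain_spec(name, folded_extension = folded_extension))
  }
  if (is.null(kinetic)) {
    # beta-domain kinetics are not separately characterised; reuse the
    # cluster-rupture defaults of the alpha domain
    kinetic <- kinetic_parameters(
      k_off = switch(metal, Zn = 25, Cd = 10),
      delta_x = 0.20
    )
  }
  if (is.null(mixture)) mixture <- beta_mixture()
  domain_spec(name, kinetic,
    mixture = mixture,
    folded_extension = folded_extension
  )
}

#' @rdname domain_spec
#' @export
rd_domain <- function(metal = c("Zn", "Cd"), dlc = 13,
                      folded_extension = 2) {
  metal <- match.arg(metal)
  kinetic <- kinetic_parameters(
    k_off = switch(metal, Zn = 0.5, Cd = 1.6),
    delta_x = 0.15
  )
  domain_spec(paste0(metal, "-Rd"), kinetic,
    dlc = dlc,
    folded_extension = folded_extension
  )
}

#' Calibrate marker-domain kinetics to a target rupture force
#'
#' Published marker fingerprints are characterised by their typical rupture
#' force rather than by (k_off, delta_x). This helper inverts the
#' most-probable-force relation at the effective loading rate of the
#' instrument, `r = k_eff * v` with
#' `k_eff = (1/k_wlc + 1/k_cantilever)^-1` evaluated at the target force
#' and a representative contour length, and returns the `k_off` that puts
#' the most probable rupture force at `target_force` for the supplied
#' `delta_x`.
#'
#' @param target_force Desired most probable rupture force, pN.
#' @param delta_x Transition-state distance, nm. The default 0.25 nm
#'   puts the companion zero-force off-rate at ~0.04 1/s, typical of
#'   mechanically stable marker folds.
#' @param pulling_speed Cantilever velocity, nm/s.
#' @param cantilever_stiffness Cantilever spring constant, pN/nm.
#' @param contour_length Representative tether contour length at rupture,
#'   nm.
#' @param wlc [wlc_parameters()] of the unfolded chain.
#' @return A [kinetic_parameters()] object.
#' @examples
#' calibrate_marker_kinetics()
#' @export
calibrate_marker_kinetics <- function(target_force = 180, delta_x = 0.25,
                                      pulling_speed = 6000,
                                      cantilever_stiffness = 40,
                                      contour_length = 80,
                                      wlc = wlc_parameters()) {
  r <- effective_loading_rate(
    target_force, contour_length, pulling_speed,
    cantilever_stiffness, wlc
  )
  kt <- wlc$thermal_energy
  k_off <- (r * delta_x / kt) * exp(-target_force * delta_x / kt)
  kinetic_parameters(k_off = k_off, delta_x = delta_x)
}

#' Effective loading rate of polymer in series with the cantilever
#'
#' The force on the molecule grows at `k_eff * v`, where the effective
#' stiffness combines the worm-like-chain stiffness of the stretched tether
#' at the current force with the cantilever spring in series.
#'
#' @param force Force at which to evaluate the tether stiffness, pN.
#' @param contour_length Tether contour length, nm.
#' @param pulling_speed Cantilever velocity, nm/s.
#' @param cantilever_stiffness Cantilever spring constant, pN/nm.
#' @param wlc [wlc_parameters()].
#' @return Loading rate in pN/s.
#' @export
effective_loading_rate <- function(force, contour_length, pulling_speed,
                                   cantilever_stiffness,
                                   wlc = wlc_parameters()) {
  x <- wlc_extension(force, contour_length, wlc)
  k_wlc <- wlc_stiffness(x, contour_length, wlc)
  k_eff <- 1 / (1 / k_wlc + 1 / cantilever_stiffness)
  k_eff * pulling_speed
}

#' Standard polyprotein constructs
#'
#' Builds the domain list of the standard constructs used in
#' metallothionein pulling experiments: the target domain(s) sandwiched
#' between two cassettes of three GB1 marker domains
#' ((GB1)3-X-(GB1)3), plus apo controls and a rubredoxin-like
#' single-site control.
#'
#' @param type Construct name.
#' @param n_markers Total number of marker domains (split evenly around the
#'   target).
#' @param marker A [domain_spec()] used for every marker position.
#' @return A list of [domain_spec()]s.
#' @examples
#' names(polyprotein_construct("Zn-aMT"))
#' @export
polyprotein_construct <- function(type = c(
                                    "Zn-MT", "Cd-MT", "Zn-aMT", "Cd-aMT",
                                    "Zn-bMT", "Apo-MT", "Apo-aMT", "Apo-bMT",
                                    "Zn-Rd", "Cd-Rd", "marker-only"
                                  ),
                                  n_markers = 6,
                                  marker = marker_domain()) {
  type <- match.arg(type)
  target <- switch(type,
    "Zn-MT" = list(mt_beta_domain("Zn"), mt_alpha_domain("Zn")),
    "Cd-MT" = list(mt_beta_domain("Cd"), mt_alpha_domain("Cd")),
    "Zn-aMT" = list(mt_alpha_domain("Zn")),
    "Cd-aMT" = list(mt_alpha_domain("Cd")),
    "Zn-bMT" = list(mt_beta_domain("Zn")),
    "Apo-MT" = list(mt_beta_domain(apo = TRUE), mt_alpha_domain(apo = TRUE)),
    "Apo-aMT" = list(mt_alpha_domain(apo = TRUE)),
    "Apo-bMT" = list(mt_beta_domain(apo = TRUE)),
    "Zn-Rd" = list(rd_domain("Zn")),
    "Cd-Rd" = list(rd_domain("Cd")),
    "marker-only" = list()
  )
  n_left <- ceiling(n_markers / 2)
  n_right <- n_markers - n_left
  mk <- function(n, side) {
    lapply(seq_len(n), function(i) {
      d <- marker
      d$name <- paste0(d$name, "_", side, i)
      d
    })
  }
  construct <- c(mk(n_left, "N"), target, mk(n_right, "C"))
  names(construct) <- vapply(construct, `[[`, character(1), "name")
  construct
}
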