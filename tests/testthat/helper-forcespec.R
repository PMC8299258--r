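# Shared fixtures for the test suite: small constructs and configs built in
# code so simulations stay fast and deterministic.

single_marker_construct <- function() {
  polyprotein_construct("marker-only", n_markers = 1)
}

noiseless_config <- function(...) {
  simulation_config(force_noise_sd = 0, ...)
}

# Pure two-step alpha mixture (pathway probabilities renormalised)
two_step_alpha_mixture <- function(p_c_first = 0.55) {
  alpha_mixture(
    p_one_step = 0,
    pathway_probs = c(P1 = 0.16, P2 = 0.12, P3 = 0.10, P4 = 0.11) / 0.49,
    p_c_first = p_c_first
  )
}

# Predicted force drop when a rupture releases `dlc` of contour length at
# the recorded force and extension (cantilever relaxation ignored, so this
# slightly overestimates the real drop).
rupture_drop_size <- function(force, extension, dlc, p = wlc_parameters()) {
  t_frac <- wlc_extension(force, 1, p) # fractional extension at this force
  lc <- extension / t_frac
  force - wlc_force(extension, lc + dlc, p)
}

# Observation-model oracle for the noiseless round trip. A true rupture is
# visible when its force is above the detection floor, its force drop is
# above the drop threshold, and it is at least the instrument length
# resolution away from the previous visible rupture. The increment of an
# invisible rupture rolls into the preceding visible peak (or into the
# initial branch when no visible peak precedes it). Curves with events in
# the grey zone of any threshold are flagged ambiguous and skipped by the
# strict tests.
predict_observed_events <- function(truth, min_force = 25, min_drop = 20,
                                    min_separation = 1) {
  truth <- truth[order(truth$extension_true), , drop = FALSE]
  n <- nrow(truth)
  drop <- rupture_drop_size(
    truth$force_true, truth$extension_true, truth$dlc_true
  )
  visible <- logical(n)
  sep <- numeric(n)
  last_vis <- -Inf
  for (k in seq_len(n)) {
    sep[k] <- truth$extension_true[k] - last_vis
    visible[k] <- truth$force_true[k] >= min_force &&
      drop[k] >= min_drop && sep[k] >= min_separation
    if (visible[k]) last_vis <- truth$extension_true[k]
  }
  ambiguous <- any(
    (truth$force_true > 18 & truth$force_true < 30) |
      (drop > 12 & drop < 22) |
      (sep > 0.5 & sep < 1.5)
  )
  idx <- which(visible)
  dlc <- vapply(seq_along(idx), function(j) {
    upto <- if (j < length(idx)) idx[j + 1] - 1L else n
    sum(truth$dlc_true[idx[j]:upto])
  }, numeric(1))
  list(
    events = tibble::tibble(
      extension = truth$extension_true[idx],
      force = truth$force_true[idx],
      dlc = dlc
    ),
    ambiguous = ambiguous
  )
}
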