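#' Run the full simulate-analyse-classify pipeline
#'
#' End-to-end driver: simulate `n_curves` pulling curves of a construct,
#' analyse them blind (peak detection, WLC fits, increments, fingerprint
#' selection), classify the accepted target-domain events into unfolding
#' pathways, tabulate the pathway statistics, and — when the observed
#' loading rates span at least three bins — fit the Bell--Evans model to
#' the target-domain rupture events. All stages are deterministic given
#' `seed`. With `out_dir` set, the resolved configuration, events table,
#' pathway statistics and manifest are written as text files (TSV/JSON)
#' stamped with the package version, seed and a configuration hash.
#'
#' @param construct Construct name (see [polyprotein_construct()]) or a
#'   list of [domain_spec()]s.
#' @param n_curves Number of curves to simulate.
#' @param seed Master seed.
#' @param config A [simulation_config()].
#' @param criteria A [selection_criteria()].
#' @param pathways A [pathway_set()] used for classification.
#' @param dfs Attempt a Bell--Evans fit on the target events.
#' @param out_dir Optional output directory.
#' @return An object of class `forcespec_report`: a list with `counts`,
#'   `events`, `assignments`, `statistics`, `dfs_fit` (or `NULL`),
#'   `manifest` and `config`.
#' @examples
#' \donttest{
#' rep <- run_pipeline("Zn-aMT", n_curves = 20, seed = 1)
#' rep$counts
#' }
#' @export
run_pipeline <- function(construct = "Zn-aMT", n_curves = 100, seed = 1,
                         config = simulation_config(),
                         criteria = selection_criteria(),
                         pathways = default_pathways(),
                         dfs = FALSE, out_dir = NULL) {
  if (is.character(construct)) {
    construct_name <- construct
    construct <- polyprotein_construct(construct)
  } else {
    construct_name <- "custom"
  }
  ds <- simulate_dataset(construct, n_curves, master_seed = seed,
    config = config
  )
  events <- analyze_dataset(ds$curves, criteria = criteria, wlc = config$wlc)
  assignments <- classify_events(events, pathways = pathways)
  statistics <- if (nrow(assignments)) {
    tabulate_pathways(assignments)
  } else {
    NULL
  }
  dfs_fit <- NULL
  if (dfs) {
    target <- dplyr::filter(
      events, .data$accepted,
      .data$attribution == "target",
      is.finite(.data$loading_rate_pN_s), .data$loading_rate_pN_s > 0
    )
    if (nrow(target) >= 30L) {
      dfs_fit <- tryCatch(
        {
          d <- tibble::tibble(
            force = target$rupture_force_pN,
            loading_rate = target$loading_rate_pN_s
          )
          rng <- range(d$loading_rate)
          binned <- bin_by_loading_rate(d,
            n_bins = 5,
            range = c(rng[1] * 0.99, rng[2] * 1.01)
          )
          modal <- binned |>
            dplyr::group_by(.data$bin, .data$bin_center) |>
            dplyr::summarise(
              modal_force = as.numeric(modal_force(.data$force)),
              .groups = "drop"
            )
          fit_bell_evans(modal$modal_force, modal$bin_center,
            thermal_energy = config$wlc$thermal_energy
          )
        },
        error = function(e) NULL
      )
    }
  }
  counts <- tibble::tibble(
    n_curves = n_curves,
    n_accepted_curves = length(unique(events$curve_id[events$accepted])),
    n_peaks = nrow(events),
    n_target_events = sum(events$attribution == "target" & events$accepted),
    n_classified = nrow(assignments),
    n_assigned = if (is.null(statistics)) 0L else statistics$n_assigned
  )
  resolved <- list(
    package_version = as.character(utils::packageVersion("forcespec")),
    construct = construct_name,
    n_curves = n_curves,
    master_seed = as.integer(seed),
    config = config[setdiff(names(config), "wlc")],
    persistence_length = config$wlc$persistence_length,
    thermal_energy = config$wlc$thermal_energy,
    criteria = unclass(criteria),
    pathways = as.data.frame(pathways)
  )
  resolved$config_hash <- sprintf(
    "%08x",
    sum(utf8ToInt(jsonlite::toJSON(resolved, auto_unbox = TRUE)) *
      seq_along(utf8ToInt(jsonlite::toJSON(resolved, auto_unbox = TRUE)))) %%
      .Machine$integer.max
  )
  report <- structure(
    list(
      counts = counts, events = events, assignments = assignments,
      statistics = statistics, dfs_fit = dfs_fit,
      manifest = ds$manifest, config = resolved
    ),
    class = "forcespec_report"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
      auto_unbox = TRUE, digits = NA
    )
    utils::write.table(as.data.frame(events),
      file.path(out_dir, "events.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    if (!is.null(statistics)) {
      write_pathway_statistics(
        statistics,
        file.path(out_dir, "pathway_statistics.tsv")
      )
    }
    if (!is.null(dfs_fit)) {
      write_bell_evans_fit(dfs_fit, file.path(out_dir, "bell_evans_fit.json"))
    }
    jsonlite::write_json(ds$manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = FALSE, digits = NA
    )
  }
  report
}

#' @export
print.forcespec_report <- function(x, ...) {
  cat("forcespec pipeline report\n")
  cat("  construct:", x$config$construct, " seed:", x$config$master_seed,
    "\n")
  print(x$counts)
  if (!is.null(x$statistics)) {
    cat("\n")
    print(x$statistics)
  }
  if (!is.null(x$dfs_fit)) {
    cat("\n")
    print(x$dfs_fit)
  }
  invisible(x)
}
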