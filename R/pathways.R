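#' Define two-step unfolding pathways
#'
#' A pathway set describes the possible two-step rupture routes of a
#' metal-cluster-bearing domain. Each pathway corresponds to one anchoring
#' cysteine that remains bound to the cluster in the unfolding intermediate
#' and is characterised by an ordered pair of contour-length increments
#' `(dlc_small, dlc_large)` whose sum matches the one-step increment of the
#' whole domain. Pairs are stored sorted (`dlc_small < dlc_large`) so that a
#' pathway is direction-agnostic: the same pathway observed small-first
#' corresponds to N-terminal-first unfolding, large-first to
#' C-terminal-first (the larger sub-segment lies C-terminal of every
#' anchoring cysteine in the alpha domain).
#'
#' @param id Character vector of pathway identifiers (e.g. `"P1"`).
#' @param anchor Anchoring-cysteine labels.
#' @param dlc_small,dlc_large Small and large member of each increment pair,
#'   nm; must satisfy `dlc_small < dlc_large`.
#' @param one_step_dlc One-step (whole-domain) contour-length increment, nm.
#' @param sum_tolerance Allowed deviation of `dlc_small + dlc_large` from
#'   `one_step_dlc`, nm.
#' @return A tibble of class `pathway_set` with attribute `one_step_dlc`.
#' @examples
#' default_pathways()
#' @export
pathway_set <- function(id, anchor, dlc_small, dlc_large, one_step_dlc,
                        sum_tolerance = 1) {
  stopifnot(
    length(id) == length(anchor),
    length(id) == length(dlc_small),
    length(id) == length(dlc_large),
    is.numeric(one_step_dlc), one_step_dlc > 0
  )
  if (length(id) == 0L) {
    stop("pathway set must contain at least one pathway", call. = FALSE)
  }
  if (any(dlc_small <= 0) || any(dlc_large <= 0)) {
    stop("contour-length increments must be positive", call. = FALSE)
  }
  if (any(dlc_small >= dlc_large)) {
    stop("`dlc_small` must be strictly less than `dlc_large`", call. = FALSE)
  }
  bad <- abs(dlc_small + dlc_large - one_step_dlc) > sum_tolerance
  if (any(bad)) {
    stop(
      "pathway pair(s) ", paste(id[bad], collapse = ", "),
      " do not sum to the one-step increment within ", sum_tolerance, " nm",
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    id = as.character(id),
    anchor = as.character(anchor),
    dlc_small = as.numeric(dlc_small),
    dlc_large = as.numeric(dlc_large)
  )
  attr(out, "one_step_dlc") <- one_step_dlc
  class(out) <- c("pathway_set", class(out))
  out
}

#' Default alpha-domain pathway set
#'
#' The four two-step rupture pathways of the metallothionein alpha-domain
#' M4S11 cluster, one per resolvable anchoring cysteine, with increment
#' pairs set to the measured averages:
#' P1 = (5.2, 6.1) nm anchored at Cys49(51), P2 = (4.1, 7.2) at Cys45,
#' P3 = (3.2, 8.1) at Cys42, P4 = (2.4, 9.3) at Cys37(38); one-step
#' increment 11.3 nm. For anchors listed in `theoretical_anchors` the
#' measured pair is replaced by the theoretical pair computed from the
#' segment table (available for Cys45: 3.6 + 7.5 nm).
#'
#' @param segments A [segment_table()] providing theoretical sub-segment
#'   increments; default [mt3_segment_table()].
#' @param theoretical_anchors Character vector of anchor labels whose pairs
#'   should be taken from the segment table instead of the measured
#'   averages.
#' @param sum_tolerance Passed to [pathway_set()].
#' @return A [pathway_set()].
#' @examples
#' default_pathways()
#' default_pathways(theoretical_anchors = "Cys45")
#' @export
default_pathways <- function(segments = mt3_segment_table(),
                             theoretical_anchors = character(),
                             sum_tolerance = 1) {
  if (nrow(segments) == 0L) {
    stop("empty segment table", call. = FALSE)
  }
  validate_segment_table(segments)
  id <- c("P1", "P2", "P3", "P4")
  anchor <- c("Cys49(51)", "Cys45", "Cys42", "Cys37(38)")
  small <- c(5.2, 4.1, 3.2, 2.4)
  large <- c(6.1, 7.2, 8.1, 9.3)
  for (a in theoretical_anchors) {
    cys <- sub("\\(.*$", "", a)
    n_lab <- paste0("alpha(Cys34-", cys, ")")
    c_lab <- paste0("alpha(", cys, "-Cys67)")
    hit_n <- match(n_lab, segments$label)
    hit_c <- match(c_lab, segments$label)
    if (is.na(hit_n) || is.na(hit_c)) {
      stop("segment table has no sub-segment pair for anchor ", a,
        call. = FALSE
      )
    }
    i <- match(a, anchor)
    if (is.na(i)) stop("unknown anchor ", a, call. = FALSE)
    pair <- sort(c(
      segments$theoretical_dlc_nm[hit_n],
      segments$theoretical_dlc_nm[hit_c]
    ))
    small[i] <- pair[1]
    large[i] <- pair[2]
  }
  pathway_set(id, anchor, small, large,
    one_step_dlc = 11.3,
    sum_tolerance = sum_tolerance
  )
}

#' Assign the unfolding direction of a two-step event
#'
#' The two sub-segments released in a two-step rupture have unequal
#' contour-length increments, and the larger one always lies on the
#' C-terminal side of the anchoring cysteine. The direction therefore
#' follows from the observed order: if the first-observed increment matches
#' the large member of the pathway pair, unfolding started from the
#' C-terminus; if it matches the small member, from the N-terminus. When the
#' two pair members differ by less than `resolution` the direction is
#' unresolvable and `NA` is returned.
#'
#' @param pair Sorted numeric pair `(small, large)` of the assigned pathway.
#' @param observed The two observed increments in temporal order, nm.
#' @param resolution Minimal pair separation (nm) required to call a
#'   direction.
#' @return `"N"`, `"C"`, or `NA_character_`.
#' @examples
#' assign_direction(c(4.1, 7.2), c(3.6, 7.0)) # "N": small released first
#' assign_direction(c(4.1, 7.2), c(7.3, 3.7)) # "C": large released first
#' @export
assign_direction <- function(pair, observed, resolution = 0.2) {
  stopifnot(length(pair) == 2L, length(observed) == 2L)
  pair <- sort(pair)
  if (abs(pair[2] - pair[1]) < resolution) {
    return(NA_character_)
  }
  if (abs(observed[1] - observed[2]) < .Machine$double.eps^0.5) {
    return(NA_character_)
  }
  if (abs(observed[1] - pair[2]) < abs(observed[1] - pair[1])) "C" else "N"
}

#' Classify one unfolding event into a pathway
#'
#' Takes the ordered contour-length increments attributed to the target
#' domain in one curve and labels the event:
#' \itemize{
#'   \item a single increment inside `one_step_window` is a one-step
#'     rupture of the whole cluster;
#'   \item two increments whose sum lies within `sum_tolerance` of the
#'     pathway-set one-step increment are matched, as a sorted pair, to the
#'     nearest pathway by Euclidean distance; the match is accepted when the
#'     distance is at most `pair_tolerance`, and the direction is inferred
#'     from the observed order via [assign_direction()];
#'   \item anything else (including events with more than two increments,
#'     which occur in well under 1\% of experimental curves) is
#'     `"unassigned"` or `"multi_step"`.
#' }
#' Distance ties between pathways are broken toward the lower pathway id
#' for determinism and flagged in the `tie` column.
#'
#' @param dlc Numeric vector of increments in temporal order, nm (length
#'   >= 1).
#' @param pathways A [pathway_set()].
#' @param one_step_window Length-2 numeric window (nm) accepted as a
#'   one-step rupture.
#' @param pair_tolerance Maximal pair distance (nm) for a pathway match;
#'   the default 0.7 nm is about half the three-amino-acid (~1 nm)
#'   length resolution of AFM-SMFS.
#' @param sum_tolerance Allowed deviation of the pair sum from the one-step
#'   increment, nm.
#' @param direction_resolution Passed to [assign_direction()].
#' @return A one-row tibble with columns `label`, `anchor`, `direction`,
#'   `match_distance`, `tie`, `n_steps`.
#' @examples
#' classify_event(c(3.6, 7.0), default_pathways()) # P2, N-first
#' classify_event(11.3, default_pathways())        # one-step
#' @export
classify_event <- function(dlc, pathways = default_pathways(),
                           one_step_window = c(10, 13),
                           pair_tolerance = 0.7,
                           sum_tolerance = 1,
                           direction_resolution = 0.2) {
  stopifnot(inherits(pathways, "pathway_set"))
  if (length(dlc) == 0L) {
    stop("empty increment list: nothing to classify", call. = FALSE)
  }
  res <- tibble::tibble(
    label = "unassigned", anchor = NA_character_,
    direction = NA_character_, match_distance = NA_real_,
    tie = FALSE, n_steps = length(dlc)
  )
  if (length(dlc) == 1L) {
    if (dlc >= one_step_window[1] && dlc <= one_step_window[2]) {
      res$label <- "one_step"
    }
    return(res)
  }
  if (length(dlc) > 2L) {
    res$label <- "multi_step"
    return(res)
  }
  one_step_dlc <- attr(pathways, "one_step_dlc")
  if (abs(sum(dlc) - one_step_dlc) > sum_tolerance) {
    return(res)
  }
  pair <- sort(dlc)
  d <- sqrt((pair[1] - pathways$dlc_small)^2 +
    (pair[2] - pathways$dlc_large)^2)
  best <- min(d)
  if (best > pair_tolerance) {
    return(res)
  }
  hits <- which(abs(d - best) < 1e-9)
  res$tie <- length(hits) > 1L
  i <- hits[1L] # ties break toward the lower pathway id
  res$label <- pathways$id[i]
  res$anchor <- pathways$anchor[i]
  res$match_distance <- best
  res$direction <- assign_direction(
    c(pathways$dlc_small[i], pathways$dlc_large[i]), dlc,
    resolution = direction_resolution
  )
  res
}

#' Classify all accepted events of an analysed dataset
#'
#' Applies [classify_event()] to the target-domain increments of each
#' accepted curve in an events table produced by [analyze_dataset()] (or
#' any tibble with columns `curve_id`, `attribution`, `dlc_nm`,
#' `accepted`).
#'
#' @param events Events tibble; one row per detected peak.
#' @param pathways A [pathway_set()].
#' @param ... Passed to [classify_event()].
#' @return A tibble with one row per accepted curve that carries at least
#'   one target-domain increment: `curve_id`, `n_steps`, `dlc_first`,
#'   `dlc_second`, `label`, `anchor`, `direction`, `match_distance`, `tie`.
#' @export
classify_events <- function(events, pathways = default_pathways(), ...) {
  stopifnot(all(c("curve_id", "attribution", "dlc_nm") %in% names(events)))
  if ("accepted" %in% names(events)) {
    events <- dplyr::filter(events, .data$accepted)
  }
  target <- dplyr::filter(events, .data$attribution == "target")
  if (nrow(target) == 0L) {
    return(tibble::tibble(
      curve_id = character(), n_steps = integer(),
      dlc_first = numeric(), dlc_second = numeric(),
      label = character(), anchor = character(),
      direction = character(), match_distance = numeric(), tie = logical()
    ))
  }
  target |>
    dplyr::arrange(.data$curve_id, .data$peak_index) |>
    dplyr::group_by(.data$curve_id) |>
    dplyr::group_modify(function(g, key) {
      cls <- classify_event(g$dlc_nm, pathways = pathways, ...)
      tibble::tibble(
        n_steps = nrow(g),
        dlc_first = g$dlc_nm[1],
        dlc_second = if (nrow(g) >= 2L) g$dlc_nm[2] else NA_real_,
        label = cls$label, anchor = cls$anchor,
        direction = cls$direction,
        match_distance = cls$match_distance, tie = cls$tie
      )
    }) |>
    dplyr::ungroup()
}

#' Tabulate pathway statistics
#'
#' Aggregates a table of per-event pathway assignments into the summary
#' reported for cluster-rupture experiments: counts and frequencies per
#' pathway label (frequencies over assigned events, i.e. one-step plus
#' P1..P4), the N/C direction split among assigned two-step events, and
#' histograms of the observed increments (two-step increments at 0.4 nm
#' bins, one-step at 1 nm bins, both configurable).
#'
#' @param assignments Tibble from [classify_events()].
#' @param two_step_bin,one_step_bin Histogram bin widths in nm.
#' @return An object of class `pathway_statistics`: a list with tibbles
#'   `by_label`, `by_label_direction`, `direction`, `histogram_two_step`,
#'   `histogram_one_step`, and counts `n_total`, `n_assigned`.
#' @export
tabulate_pathways <- function(assignments, two_step_bin = 0.4,
                              one_step_bin = 1) {
  if (nrow(assignments) == 0L) {
    stop("no assignments to tabulate", call. = FALSE)
  }
  assigned_labels <- c("one_step", "P1", "P2", "P3", "P4")
  n_assigned <- sum(assignments$label %in% assigned_labels)
  by_label <- assignments |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::mutate(
      frequency = ifelse(.data$label %in% assigned_labels,
        .data$n / n_assigned, NA_real_
      )
    )
  by_label_direction <- assignments |>
    dplyr::filter(.data$label %in% c("P1", "P2", "P3", "P4")) |>
    dplyr::count(.data$label, .data$direction, name = "n")
  two_step <- dplyr::filter(
    assignments,
    .data$label %in% c("P1", "P2", "P3", "P4")
  )
  direction <- two_step |>
    dplyr::filter(!is.na(.data$direction)) |>
    dplyr::count(.data$direction, name = "n") |>
    dplyr::mutate(frequency = .data$n / sum(.data$n))
  hist_tbl <- function(x, width) {
    if (length(x) == 0L) {
      return(tibble::tibble(bin_left = numeric(), count = integer()))
    }
    left <- floor(min(x) / width) * width
    breaks <- seq(left, max(x) + width, by = width)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    tibble::tibble(bin_left = h$breaks[-length(h$breaks)], count = h$counts)
  }
  two_vals <- c(two_step$dlc_first, two_step$dlc_second)
  one_vals <- assignments$dlc_first[assignments$label == "one_step"]
  structure(
    list(
      by_label = by_label,
      by_label_direction = by_label_direction,
      direction = direction,
      histogram_two_step = hist_tbl(two_vals[!is.na(two_vals)], two_step_bin),
      histogram_one_step = hist_tbl(one_vals, one_step_bin),
      n_total = nrow(assignments),
      n_assigned = n_assigned
    ),
    class = "pathway_statistics"
  )
}

#' @export
print.pathway_statistics <- function(x, ...) {
  cat(
    "Pathway statistics:", x$n_total, "events,", x$n_assigned,
    "assigned\n\n"
  )
  print(x$by_label)
  if (nrow(x$direction) > 0L) {
    cat("\nDirection split among two-step events:\n")
    print(x$direction)
  }
  invisible(x)
}

#' Write pathway statistics as TSV
#'
#' Writes the per-label summary (and, alongside it, the two-step increment
#' histogram) in tab-separated form.
#'
#' @param stats A `pathway_statistics` object.
#' @param path Output path for the summary table; the histogram is written
#'   next to it with suffix `_histogram.tsv`.
#' @return `path`, invisibly.
#' @export
write_pathway_statistics <- function(stats, path) {
  stopifnot(inherits(stats, "pathway_statistics"))
  utils::write.table(as.data.frame(stats$by_label), path,
    sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  hist_path <- sub("\\.tsv$", "_histogram.tsv", path)
  if (identical(hist_path, path)) hist_path <- paste0(path, "_histogram.tsv")
  utils::write.table(as.data.frame(stats$histogram_two_step), hist_path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
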