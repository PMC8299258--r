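#' Read and write force-extension curves as TSV
#'
#' Curves are stored as two-column tab-separated text (`extension_nm`,
#' `force_pN`) preceded by `#`-prefixed metadata lines of the form
#' `# key: value`. All metadata written by the simulator (pulling speed,
#' cantilever stiffness, seed, construct, ...) are restored on reading;
#' numeric-looking values are converted back to numbers.
#'
#' @param curve A `fx_curve` tibble (as produced by [simulate_curve()]).
#' @param path File path.
#' @return `write_curve_tsv()` returns `path` invisibly;
#'   `read_curve_tsv()` returns a `fx_curve` tibble with a `metadata`
#'   attribute.
#' @examples
#' sim <- simulate_curve(polyprotein_construct("marker-only", n_markers = 1),
#'   seed = 1
#' )
#' f <- tempfile(fileext = ".tsv")
#' write_curve_tsv(sim$curve, f)
#' curve <- read_curve_tsv(f)
#' @export
write_curve_tsv <- function(curve, path) {
  stopifnot(is.data.frame(curve), all(c("extension", "force") %in%
    names(curve)))
  meta <- attr(curve, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, format(meta[[key]], digits = 15)),
      con = con
    )
  }
  writeLines("extension_nm\tforce_pN", con = con)
  writeLines(
    paste(
      format(curve$extension, digits = 10, trim = TRUE, scientific = FALSE),
      format(curve$force, digits = 10, trim = TRUE, scientific = FALSE),
      sep = "\t"
    ),
    con = con
  )
  invisible(path)
}

#' @rdname write_curve_tsv
#' @export
read_curve_tsv <- function(path) {
  if (!file.exists(path)) {
    stop("curve file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) {
    stop("malformed curve file (no data rows): ", path, call. = FALSE)
  }
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("extension_nm", "force_pN"))) {
    stop("malformed curve file header in ", path,
      " (line ", which(!grepl("^#", lines))[1], ")",
      call. = FALSE
    )
  }
  parts <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("malformed curve row in ", path, " (data line ", bad[1], ")",
      call. = FALSE
    )
  }
  mat <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(mat)) {
    stop("non-numeric values in curve file ", path, call. = FALSE)
  }
  curve <- tibble::tibble(extension = mat[, 1], force = mat[, 2])
  if (is.unsorted(curve$extension)) {
    curve <- dplyr::arrange(curve, .data$extension)
  }
  attr(curve, "metadata") <- meta
  class(curve) <- c("fx_curve", class(curve))
  curve
}

#' Read a simulated dataset directory
#'
#' Loads every curve listed in a dataset `manifest.json` written by
#' [simulate_dataset()] (ground-truth sidecars are not read: analysis is
#' blind to the truth).
#'
#' @param dir Directory containing `manifest.json` and curve TSV files.
#' @return A list of `fx_curve` tibbles, named by curve id.
#' @export
read_curve_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  files <- if (file.exists(manifest_path)) {
    m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    m$curve_file
  } else {
    list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  }
  if (length(files) == 0L) {
    stop("no curves found in ", dir, call. = FALSE)
  }
  curves <- lapply(files, read_curve_tsv)
  names(curves) <- vapply(
    curves,
    function(cv) {
      id <- attr(cv, "metadata")$curve_id
      if (is.null(id)) NA_character_ else as.character(id)
    },
    character(1)
  )
  curves
}
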