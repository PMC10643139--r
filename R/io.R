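#' Read a BED file of peak intervals
#'
#' Reads 3+ column tab-separated BED (0-based, half-open), skipping `track`,
#' `browser` and `#` lines, validating coordinates line by line, and returning
#' intervals sorted by (reference, start).
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `reference`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble::tibble(reference = character(), start = numeric(), end = numeric()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("line %d: BED needs at least 3 tab-separated fields.", idx[which(nf < 3L)[1]]))
  }
  ref <- vapply(fields, `[[`, character(1), 1L)
  start_chr <- vapply(fields, `[[`, character(1), 2L)
  end_chr <- vapply(fields, `[[`, character(1), 3L)
  start <- suppressWarnings(as.numeric(start_chr))
  end <- suppressWarnings(as.numeric(end_chr))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) {
    abort(sprintf("line %d: non-integer BED coordinates ('%s', '%s').",
                  idx[which(bad)[1]], start_chr[which(bad)[1]], end_chr[which(bad)[1]]))
  }
  bad <- start >= end | start < 0
  if (any(bad)) {
    abort(sprintf("line %d: BED interval must satisfy 0 <= start < end (got %s, %s).",
                  idx[which(bad)[1]], start[which(bad)[1]], end[which(bad)[1]]))
  }
  out <- tibble::tibble(reference = ref, start = start, end = end)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, character(1), 4L)
  if (all(nf >= 5L)) out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
  dplyr::arrange(out, .data$reference, .data$start, .data$end)
}

#' Write peak intervals as BED
#'
#' @param peaks A tibble with `reference`, `start`, `end` and optional `name`,
#'   `score` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  cols <- list(peaks$reference,
               format(peaks$start, scientific = FALSE, trim = TRUE),
               format(peaks$end, scientific = FALSE, trim = TRUE))
  if ("name" %in% names(peaks)) {
    cols <- c(cols, list(peaks$name))
    if ("score" %in% names(peaks)) cols <- c(cols, list(format(peaks$score, trim = TRUE)))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph file onto a fixed-bin track
#'
#' Intervals are validated (4 tab-separated columns, integer 0-based half-open
#' coordinates, no overlaps after sorting) and resampled to `bin`-width bins by
#' length-weighted averaging; uncovered positions count as zero.
#'
#' @param path Path to a bedGraph file.
#' @param seqlength Reference length in bases.
#' @param bin Target bin width in bases.
#' @param reference Expected reference name; records on other references are an
#'   error.
#' @return An `ssx_track`.
#' @export
read_bedgraph <- function(path, seqlength, bin, reference = "chrT") {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  n_bins <- ceiling(seqlength / bin)
  if (length(idx) == 0L) {
    return(signal_track(numeric(n_bins), bin = bin, reference = reference,
                        seqlength = seqlength))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    abort(sprintf("line %d: bedGraph needs exactly 4 tab-separated fields.",
                  idx[which(nf != 4L)[1]]))
  }
  ref <- vapply(fields, `[[`, character(1), 1L)
  if (any(ref != reference)) {
    abort(sprintf("line %d: unexpected reference '%s' (track is on '%s').",
                  idx[which(ref != reference)[1]], ref[ref != reference][1], reference))
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  bad <- is.na(start) | is.na(end) | is.na(value) | start != floor(start) |
    end != floor(end) | start < 0 | start >= end
  if (any(bad)) abort(sprintf("line %d: malformed bedGraph record.", idx[which(bad)[1]]))
  ord <- order(start)
  start <- start[ord]; end <- end[ord]; value <- value[ord]
  if (any(start[-1] < end[-length(end)])) {
    abort("bedGraph intervals overlap after sorting; overlapping coverage is not supported.")
  }
  if (any(end > seqlength)) abort("bedGraph interval extends past the reference end.")
  # Per-bin length-weighted mean: accumulate interval mass into overlapped bins.
  vals <- numeric(n_bins)
  first_bin <- floor(start / bin)
  last_bin <- floor((end - 1) / bin)
  for (i in seq_along(start)) {
    b <- first_bin[i]:last_bin[i]
    lo <- pmax(start[i], b * bin)
    hi <- pmin(end[i], (b + 1) * bin)
    vals[b + 1L] <- vals[b + 1L] + (hi - lo) * value[i]
  }
  widths <- pmin(seq_len(n_bins) * bin, seqlength) - (seq_len(n_bins) - 1) * bin
  signal_track(vals / widths, bin = bin, reference = reference, seqlength = seqlength)
}

#' Write a track as bedGraph
#'
#' Adjacent bins with equal values are merged into single records; values are
#' written with 6 significant digits, which makes repeated writes of the same
#' track byte-identical.
#'
#' @param track An `ssx_track`.
#' @param path Output path.
#' @param drop_zero Omit zero-valued records (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, drop_zero = TRUE) {
  stopifnot(inherits(track, "ssx_track"))
  v <- signif(track$values, 6)
  r <- rle(v)
  n <- length(r$values)
  ends_bin <- cumsum(r$lengths)
  starts <- c(0, ends_bin[-n]) * track$bin
  ends <- pmin(ends_bin * track$bin, track$seqlength)
  keep <- if (drop_zero) r$values != 0 else rep(TRUE, n)
  writeLines(sprintf("%s\t%s\t%s\t%.6g", track$reference,
                     format(starts[keep], scientific = FALSE, trim = TRUE),
                     format(ends[keep], scientific = FALSE, trim = TRUE),
                     r$values[keep]),
             path)
  invisible(path)
}

#' Read a spike-in count summary table
#'
#' Expects a tab-separated file with columns `sample_id`, `role` (`IP` or
#' `input`), `condition`, `group`, `primary_unique_reads`, `spike_unique_reads`.
#'
#' @param path Path to the TSV.
#' @return A validated tibble of per-sample unique-read counts.
#' @export
read_spikein_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_spikein_samples(x)
  x
}

validate_spikein_samples <- function(samples) {
  need <- c("sample_id", "role", "condition", "group",
            "primary_unique_reads", "spike_unique_reads")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0L) {
    abort(paste0("sample table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(samples$role %in% c("IP", "input"))) {
    abort("`role` must be 'IP' or 'input'.")
  }
  counts <- c(samples$primary_unique_reads, samples$spike_unique_reads)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("read counts must be nonnegative integers.")
  }
  if (anyDuplicated(samples$sample_id)) abort("duplicate sample_id values.")
  invisible(samples)
}

#' Write a tibble as a deterministic TSV
#'
#' Columns are written in their current order; doubles are formatted with 6
#' significant digits so identical objects yield byte-identical files.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(x, path) {
  y <- dplyr::mutate(as.data.frame(x), dplyr::across(
    dplyr::where(is.double), ~ sprintf("%.6g", .x)))
  readr::write_tsv(y, path, progress = FALSE)
  invisible(path)
}

#' Read / write a multi-channel image as multi-page TIFF
#'
#' One TIFF page per channel, 16-bit. Channel roles are never guessed from
#' metadata: `channels` maps role names to page indices.
#'
#' @param image A named list of equally sized numeric matrices (one per
#'   channel), values in `[0, 65535]`.
#' @param path TIFF path.
#' @param channels Named integer vector mapping channel roles to pages, e.g.
#'   `c(dapi = 1, egfp = 2, marker = 3)`.
#' @return For the writer, `path` invisibly; for the reader, a named list of
#'   numeric matrices keyed by role.
#' @export
write_image_tiff <- function(image, path) {
  pages <- lapply(image, function(ch) {
    if (any(ch < 0) || any(ch > 65535)) abort("channel intensities must lie in [0, 65535].")
    ch / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, channels) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (max(channels) > length(pages)) {
    abort(sprintf("channel map asks for page %d but the TIFF has %d pages.",
                  max(channels), length(pages)))
  }
  out <- lapply(channels, function(i) round(pages[[i]] * 65535))
  names(out) <- names(channels)
  out
}
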