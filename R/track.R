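#' Fixed-bin coverage track
#'
#' A `ssx_track` holds coverage values in fixed-width bins over a single named
#' reference sequence, the in-memory form of a bedGraph file. Bin `i` covers
#' bases `[(i-1)*bin, i*bin)` in 0-based coordinates; the last bin may be
#' truncated by the reference end.
#'
#' @param values Numeric vector of nonnegative bin values, one per bin.
#' @param bin Bin width in bases (positive integer).
#' @param reference Reference sequence name.
#' @param seqlength Reference length in bases; defaults to `length(values) * bin`.
#' @param provenance One of `"raw"`, `"scaled"`, `"downsampled"`,
#'   `"normalized"` — records what has been done to the values.
#'
#' @return An object of class `ssx_track`.
#' @export
#' @examples
#' tr <- signal_track(c(0, 2, 4, 2), bin = 50)
#' track_total(tr)
signal_track <- function(values, bin, reference = "chrT",
                         seqlength = NULL, provenance = "raw") {
  if (!is.numeric(values) || anyNA(values)) abort("`values` must be numeric without NA.")
  if (any(values < 0)) abort("track values must be nonnegative.")
  bin <- as.integer(bin)
  if (is.na(bin) || bin <= 0L) abort("`bin` must be a positive integer.")
  seqlength <- if (is.null(seqlength)) length(values) * bin else as.numeric(seqlength)
  n_expected <- ceiling(seqlength / bin)
  if (length(values) != n_expected) {
    abort(sprintf("track has %d bins but reference of length %s with %d-bp bins needs %d.",
                  length(values), format(seqlength, scientific = FALSE), bin, n_expected))
  }
  provenance <- match.arg(provenance, c("raw", "scaled", "downsampled", "normalized"))
  structure(
    list(reference = reference, seqlength = seqlength, bin = bin,
         values = as.numeric(values), provenance = provenance),
    class = "ssx_track"
  )
}

#' @export
print.ssx_track <- function(x, ...) {
  cat(sprintf("<ssx_track> %s:0-%s, %d bins of %d bp [%s], total signal %.6g\n",
              x$reference, format(x$seqlength, scientific = FALSE),
              length(x$values), x$bin, x$provenance, sum(x$values)))
  invisible(x)
}

#' @method tidy ssx_track
#' @export
#' @rdname signal_track
#' @param x,... An `ssx_track` and ignored extra arguments (tidy method).
tidy.ssx_track <- function(x, ...) {
  n <- length(x$values)
  tibble::tibble(
    reference = x$reference,
    start = (seq_len(n) - 1) * x$bin,
    end = pmin(seq_len(n) * x$bin, x$seqlength),
    value = x$values
  )
}

#' Total signal in a track
#' @param track An `ssx_track`.
#' @return Sum of all bin values.
#' @export
track_total <- function(track) {
  stopifnot(inherits(track, "ssx_track"))
  sum(track$values)
}

# Cumulative per-base signal mass up to base x (vectorized, 0-based).
# The per-base value within bin i is values[i]; x is clamped to [0, seqlength].
track_mass_upto <- function(track, x) {
  x <- pmin(pmax(x, 0), track$seqlength)
  csum <- c(0, cumsum(track$values)) * track$bin
  k <- pmin(floor(x / track$bin), length(track$values) - 1L)
  csum[k + 1L] + (x - k * track$bin) * track$values[k + 1L]
}

# Mean per-base value over 0-based half-open windows [starts, ends), with
# positions outside the reference contributing zero (zero padding).
track_window_mean <- function(track, starts, ends) {
  if (any(ends <= starts)) abort("window ends must exceed starts.")
  (track_mass_upto(track, ends) - track_mass_upto(track, starts)) / (ends - starts)
}

#' Re-bin a track into coarser summary bins
#'
#' Values are combined by length-weighted averaging of the per-base signal, the
#' same convention used when resampling bedGraph intervals onto a fixed grid.
#'
#' @param track An `ssx_track`.
#' @param bin New bin width in bases, at least the current width.
#' @return An `ssx_track` with the new bin width.
#' @export
rebin_track <- function(track, bin) {
  stopifnot(inherits(track, "ssx_track"))
  bin <- as.integer(bin)
  if (bin < track$bin) abort("summary bin must be >= the track bin.")
  n <- ceiling(track$seqlength / bin)
  starts <- (seq_len(n) - 1) * bin
  ends <- pmin(seq_len(n) * bin, track$seqlength)
  signal_track(track_window_mean(track, starts, ends), bin = bin,
               reference = track$reference, seqlength = track$seqlength,
               provenance = track$provenance)
}

#' Depth-normalize a track to signal per million reads
#'
#' Divides every bin by the library size (in reads) and multiplies by 1e6.
#' Fraction-based spike-in scaling factors ([cutandrun_scaling()]) are applied
#' to depth-normalized coverage; see the package vignette.
#'
#' @param track An `ssx_track` of raw counts.
#' @param total_reads Library size used as denominator; defaults to the track
#'   total.
#' @return A depth-normalized `ssx_track` (provenance `"normalized"`).
#' @export
normalize_track <- function(track, total_reads = track_total(track)) {
  stopifnot(inherits(track, "ssx_track"))
  if (total_reads <= 0) abort("`total_reads` must be positive.")
  out <- track
  out$values <- track$values / total_reads * 1e6
  out$provenance <- "normalized"
  out
}
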