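#' Midpoint of a peak interval
#'
#' @param start,end 0-based half-open interval bounds (vectorized).
#' @return `floor((start + end) / 2)`, 0-based.
#' @export
#' @examples
#' region_midpoint(100, 200)
region_midpoint <- function(start, end) {
  if (any(start >= end)) abort("intervals must satisfy start < end.")
  floor((start + end) / 2)
}

#' Peak-centered signal matrix
#'
#' Builds the regions-by-bins matrix behind reference-point heatmaps and
#' metaprofiles: each row covers a window of `±flank` bases around the peak
#' midpoint split into `bin`-bp cells, each cell holding the mean per-base
#' track value over its span. Window parts outside the reference contribute
#' zero and the affected rows are flagged.
#'
#' @param track An `ssx_track`.
#' @param peaks Tibble with `reference`, `start`, `end` and optionally `name`.
#' @param flank Half-window in bases (default 10000).
#' @param bin Cell width in bases (default 50); must divide `flank`.
#' @return An object of class `ssx_matrix`: list with `values` (regions x
#'   bins), `region_id`, `midpoint`, `flank`, `bin`, `edge_padded` (logical per
#'   row).
#' @export
signal_matrix <- function(track, peaks, flank = 10000, bin = 50) {
  stopifnot(inherits(track, "ssx_track"))
  if (flank %% bin != 0) abort("`flank` must be divisible by `bin`.")
  if (nrow(peaks) == 0L) abort("empty peak set.")
  off_ref <- peaks$reference != track$reference
  if (any(off_ref)) {
    warn(sprintf("%d peak(s) on references absent from the track were dropped.",
                 sum(off_ref)))
    peaks <- peaks[!off_ref, , drop = FALSE]
    if (nrow(peaks) == 0L) abort("no peaks left on the track's reference.")
  }
  region_id <- if ("name" %in% names(peaks)) peaks$name else {
    sprintf("%s:%s-%s", peaks$reference,
            format(peaks$start, scientific = FALSE, trim = TRUE),
            format(peaks$end, scientific = FALSE, trim = TRUE))
  }
  mid <- region_midpoint(peaks$start, peaks$end)
  n_bins <- 2L * flank / bin
  offsets <- (seq_len(n_bins) - 1L) * bin - flank
  starts <- outer(mid, offsets, `+`)
  vals <- matrix(track_window_mean(track, as.vector(starts), as.vector(starts) + bin),
                 nrow = nrow(peaks), ncol = n_bins)
  rownames(vals) <- region_id
  structure(
    list(values = vals, region_id = region_id, midpoint = mid,
         flank = flank, bin = bin,
         edge_padded = (mid - flank < 0) | (mid + flank > track$seqlength)),
    class = "ssx_matrix"
  )
}

#' @export
print.ssx_matrix <- function(x, ...) {
  cat(sprintf("<ssx_matrix> %d regions x %d bins (±%d bp, %d-bp bins), %d edge-padded row(s)\n",
              nrow(x$values), ncol(x$values), x$flank, x$bin, sum(x$edge_padded)))
  invisible(x)
}

#' @method tidy ssx_matrix
#' @export
tidy.ssx_matrix <- function(x, ...) {
  tibble::tibble(
    region_id = rep(x$region_id, times = ncol(x$values)),
    offset = rep((seq_len(ncol(x$values)) - 1L) * x$bin - x$flank, each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Rank matrix rows by increasing mean signal
#'
#' Stable ordering by ascending row mean, ties broken by region id; the
#' convention used to order heatmap rows.
#'
#' @param matrix An `ssx_matrix`.
#' @return Integer permutation of row indices.
#' @export
rank_rows <- function(matrix) {
  stopifnot(inherits(matrix, "ssx_matrix"))
  if (nrow(matrix$values) == 0L) abort("empty matrix.")
  order(rowMeans(matrix$values), matrix$region_id, method = "radix")
}

#' Per-region signal scores
#'
#' One score per peak: the mean per-base track value over the region body
#' (start to end), the quantity summarized in per-condition score
#' distributions.
#'
#' @inheritParams signal_matrix
#' @return A tibble with `region_id` and `score`.
#' @export
region_scores <- function(track, peaks) {
  stopifnot(inherits(track, "ssx_track"))
  if (nrow(peaks) == 0L) abort("empty peak set.")
  off_ref <- peaks$reference != track$reference
  if (any(off_ref)) {
    warn(sprintf("%d peak(s) on references absent from the track were dropped.",
                 sum(off_ref)))
    peaks <- peaks[!off_ref, , drop = FALSE]
  }
  region_id <- if ("name" %in% names(peaks)) peaks$name else {
    sprintf("%s:%s-%s", peaks$reference,
            format(peaks$start, scientific = FALSE, trim = TRUE),
            format(peaks$end, scientific = FALSE, trim = TRUE))
  }
  tibble::tibble(region_id = region_id,
                 score = track_window_mean(track, peaks$start, peaks$end))
}

#' Per-region log2 ratio of two score sets
#'
#' `log2((a + pseudocount) / (b + pseudocount))`, region by region. The
#' pseudocount bounds ratios at empty regions; its default of 1 is on the
#' binned-count scale.
#'
#' @param a,b Score tibbles from [region_scores()] over the same regions.
#' @param pseudocount Positive stabilizer added to both scores.
#' @return A tibble with `region_id` and `log2_ratio`.
#' @export
log2_ratio <- function(a, b, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  if (nrow(a) != nrow(b) || !all(a$region_id == b$region_id)) {
    abort("score sets cover different regions; align them before taking ratios.")
  }
  tibble::tibble(region_id = a$region_id,
                 log2_ratio = log2((a$score + pseudocount) / (b$score + pseudocount)))
}

#' K-means clustering of per-region ratios
#'
#' Lloyd's algorithm (via [stats::kmeans()]) started from k-means++ style
#' seeds drawn with the supplied seed; the best of `restarts` runs by total
#' within-cluster sum of squares is kept, so results are deterministic given
#' the seed. Used to split per-region log2 ratios into depleted and retained
#' populations.
#'
#' @param ratios A tibble with `region_id` and one or more numeric score
#'   columns (e.g. `log2_ratio` values from several samples).
#' @param k Number of clusters, `1 <= k <=` number of regions.
#' @param seed Integer seed.
#' @param restarts Number of independent seedings (default 10).
#' @return An object of class `ssx_kmeans`: list with `assignments` (tibble of
#'   `region_id`, `cluster`), `centroids` (k x p matrix), `tot_withinss`, `k`,
#'   `seed`.
#' @export
kmeans_cluster <- function(ratios, k = 2, seed = 1, restarts = 10) {
  x <- as.matrix(dplyr::select(ratios, dplyr::where(is.numeric)))
  n <- nrow(x)
  if (k < 1) abort("`k` must be at least 1.")
  if (k > n) abort(sprintf("k = %d exceeds the number of regions (%d).", k, n))
  if (anyNA(x) || any(!is.finite(x))) abort("ratio values must be finite.")
  if (k == 1L) {
    center <- matrix(colMeans(x), nrow = 1)
    return(structure(
      list(assignments = tibble::tibble(region_id = ratios$region_id,
                                        cluster = rep(1L, n)),
           centroids = center,
           tot_withinss = sum(sweep(x, 2, center[1, ])^2),
           k = 1L, seed = seed),
      class = "ssx_kmeans"
    ))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100L, algorithm = "Lloyd")
      )
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  structure(
    list(assignments = tibble::tibble(region_id = ratios$region_id,
                                      cluster = unname(best$cluster)),
         centroids = unname(best$centers),
         tot_withinss = best$tot.withinss,
         k = k, seed = seed),
    class = "ssx_kmeans"
  )
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2))
    }
  }
  x[idx, , drop = FALSE] + 0  # copy; jitter-free deterministic start
}

#' @export
print.ssx_kmeans <- function(x, ...) {
  cat(sprintf("<ssx_kmeans> k = %d, n = %d regions, total within-SS = %.6g\n",
              x$k, nrow(x$assignments), x$tot_withinss))
  invisible(x)
}

#' @method tidy ssx_kmeans
#' @export
tidy.ssx_kmeans <- function(x, ...) x$assignments

#' @method glance ssx_kmeans
#' @export
glance.ssx_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = nrow(x$assignments),
                 tot_withinss = x$tot_withinss, seed = x$seed)
}

#' Pairwise Spearman correlation of tracks
#'
#' Tracks are summarized into `summary_bin`-wide bins (length-weighted means)
#' and rank-correlated pairwise with average ranks for ties, giving the
#' symmetric matrix behind track-correlation heatmaps.
#'
#' @param tracks Named list of `ssx_track`s on the same reference space.
#' @param summary_bin Summary bin width in bases (default 10000); must be at
#'   least each track's own bin.
#' @return Symmetric correlation matrix with unit diagonal; columns for
#'   constant tracks (undefined rank correlation) are `NA` with a warning.
#' @export
spearman_matrix <- function(tracks, summary_bin = 10000) {
  if (length(tracks) < 2L) abort("need at least two tracks.")
  if (is.null(names(tracks))) names(tracks) <- paste0("track", seq_along(tracks))
  sl <- unique(vapply(tracks, function(t) t$seqlength, numeric(1)))
  if (length(sl) != 1L) abort("tracks cover different reference lengths.")
  binned <- vapply(tracks, function(t) rebin_track(t, summary_bin)$values,
                   numeric(ceiling(sl / summary_bin)))
  constant <- apply(binned, 2L, function(v) diff(range(v)) == 0)
  if (any(constant)) {
    warn(sprintf("track(s) %s are constant; their rank correlation is undefined (NA).",
                 paste(names(tracks)[constant], collapse = ", ")))
  }
  m <- suppressWarnings(cor(binned, method = "spearman"))
  m[constant, ] <- NA_real_
  m[, constant] <- NA_real_
  diag(m) <- 1
  m
}
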