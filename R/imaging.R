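#' Li minimum cross-entropy threshold
#'
#' Selects the intensity threshold minimizing the Li & Lee minimum
#' cross-entropy criterion between background (values `<= t`) and foreground
#' (values `> t`). The default solver evaluates the criterion exactly at every
#' distinct intensity via cumulative sums, so the returned value is the global
#' minimizer; `method = "iterative"` runs the classical fixed-point iteration,
#' which converges to the same value on well-separated histograms.
#'
#' @param image Numeric matrix of nonnegative intensities (e.g. the DAPI
#'   channel).
#' @param method `"exact"` (scan over all distinct values, default) or
#'   `"iterative"`.
#' @param tol Convergence tolerance for the iterative method.
#' @return The threshold value; foreground is `image > threshold`.
#' @export
li_threshold <- function(image, method = c("exact", "iterative"), tol = 1e-6) {
  method <- match.arg(method)
  v <- as.vector(image)
  if (anyNA(v) || any(v < 0)) abort("image intensities must be nonnegative and non-missing.")
  vals <- sort(unique(v))
  if (length(vals) < 2L) abort("degenerate image: no threshold.")
  if (method == "exact") {
    cnt <- tabulate(match(v, vals), nbins = length(vals))
    cum_n <- cumsum(cnt)
    cum_s <- cumsum(vals * cnt)
    i <- seq_len(length(vals) - 1L)          # background = vals[1..i]
    a_b <- cum_s[i]
    a_f <- cum_s[length(vals)] - a_b
    mu_b <- a_b / cum_n[i]
    mu_f <- a_f / (cum_n[length(vals)] - cum_n[i])
    term <- function(a, mu) ifelse(a > 0, a * log(mu), 0)
    crit <- -(term(a_b, mu_b) + term(a_f, mu_f))
    vals[i[which.min(crit)]]
  } else {
    t_cur <- mean(v)
    for (iter in seq_len(200L)) {
      bg <- v[v <= t_cur]
      fg <- v[v > t_cur]
      if (length(fg) == 0L || length(bg) == 0L) break
      m_b <- max(mean(bg), .Machine$double.xmin)
      m_f <- mean(fg)
      t_new <- if (abs(log(m_b) - log(m_f)) < 1e-300) t_cur else {
        (m_b - m_f) / (log(m_b) - log(m_f))
      }
      if (abs(t_new - t_cur) < tol) {
        t_cur <- t_new
        break
      }
      t_cur <- t_new
    }
    t_cur
  }
}

# 8- or 4-connected component labelling of a logical mask by multi-source
# breadth-first flood fill; labels are assigned in column-major order of each
# component's first pixel and are contiguous 1..n.
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix.")
  if (!connectivity %in% c(4, 8)) abort("`connectivity` must be 4 or 8.")
  nr <- nrow(mask); nc <- ncol(mask)
  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8) {
    dr <- c(dr, -1L, -1L, 1L, 1L)
    dc <- c(dc, -1L, 1L, -1L, 1L)
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (p in which(mask)) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    lab[p] <- cur
    frontier <- p
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% nr) + 1L
      cc <- ((frontier - 1L) %/% nr) + 1L
      nb_r <- rep(r, times = length(dr)) + rep(dr, each = length(r))
      nb_c <- rep(cc, times = length(dc)) + rep(dc, each = length(cc))
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      cand <- unique((nb_c[ok] - 1L) * nr + nb_r[ok])
      cand <- cand[mask[cand] & lab[cand] == 0L]
      lab[cand] <- cur
      frontier <- cand
    }
  }
  lab
}

#' Segment nuclei from a thresholded DAPI channel
#'
#' 8-connected components of the supra-threshold mask; components smaller than
#' `min_area` pixels are removed and labels renumbered contiguously.
#'
#' @param dapi DAPI channel matrix.
#' @param threshold Intensity threshold (typically from [li_threshold()]).
#' @param min_area Minimum component area in pixels (default 50).
#' @param connectivity Pixel connectivity, 8 (default) or 4.
#' @return An integer label matrix (0 = background) with attribute `n_labels`.
#' @export
segment_nuclei <- function(dapi, threshold = li_threshold(dapi), min_area = 50,
                           connectivity = 8) {
  mask <- dapi > threshold
  lab <- label_components(mask, connectivity = connectivity)
  if (max(lab) == 0L) {
    warn("no nuclei found above the threshold.")
    attr(lab, "n_labels") <- 0L
    return(lab)
  }
  areas <- tabulate(lab, nbins = max(lab))
  keep <- which(areas >= min_area)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab != 0L
  out[nz] <- remap[lab[nz]]
  if (length(keep) == 0L) warn("all components were below `min_area`.")
  attr(out, "n_labels") <- length(keep)
  out
}

#' Per-nucleus channel statistics
#'
#' Computes the mean intensity of every channel within each labelled nucleus,
#' then normalizes each channel mean by that nucleus's DAPI mean (DAPI itself
#' normalizes to 1). Nuclei with nonpositive DAPI mean are dropped with a
#' warning.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param image Named list of channel matrices; must contain `dapi`.
#' @return A tibble with one row per nucleus: `label`, `area`,
#'   `<channel>_mean` and `<channel>_norm` columns.
#' @export
measure_nuclei <- function(labels, image) {
  if (is.null(image$dapi)) abort("`image` must contain a 'dapi' channel.")
  shapes <- vapply(image, function(ch) paste(dim(ch), collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L || !identical(dim(image[[1]]), dim(labels))) {
    abort("all channels and the label map must share one shape.")
  }
  n <- max(labels)
  if (n == 0L) {
    return(tibble::tibble(label = integer(), area = integer()))
  }
  idx <- labels != 0L
  lv <- labels[idx]
  area <- tabulate(lv, nbins = n)
  means <- lapply(image, function(ch) {
    as.vector(rowsum(ch[idx], lv, reorder = TRUE)) / area
  })
  out <- tibble::tibble(label = seq_len(n), area = area)
  for (nm in names(means)) out[[paste0(nm, "_mean")]] <- means[[nm]]
  bad <- out$dapi_mean <= 0
  if (any(bad)) {
    warn(sprintf("%d nucleus(ei) with nonpositive DAPI mean dropped.", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  for (nm in names(means)) {
    out[[paste0(nm, "_norm")]] <- out[[paste0(nm, "_mean")]] / out$dapi_mean
  }
  out
}

#' Classify nuclei as eGFP-high or eGFP-low
#'
#' High if DAPI-normalized eGFP exceeds `cutoff`, low otherwise; values equal
#' to the cutoff are assigned low (documented tie rule).
#'
#' @param records Nucleus tibble from [measure_nuclei()] with an `egfp_norm`
#'   column.
#' @param cutoff Normalized-eGFP cutoff (default 1).
#' @return `records` with an added `egfp_class` column (`"high"`/`"low"`).
#' @export
classify_by_egfp <- function(records, cutoff = 1.0) {
  if (!"egfp_norm" %in% names(records)) abort("records lack a normalized eGFP column.")
  dplyr::mutate(records,
                egfp_class = ifelse(.data$egfp_norm > cutoff, "high", "low"))
}

#' High/low eGFP marker-intensity ratio
#'
#' The summary statistic of eGFP-reporter imaging: the mean DAPI-normalized
#' marker intensity of eGFP-high nuclei divided by that of eGFP-low nuclei.
#'
#' @param records Classified nucleus tibble ([classify_by_egfp()]).
#' @param marker Marker channel name (default `"marker"`); its
#'   `<marker>_norm` column is used.
#' @return An object of class `ssx_ratio` with fields `marker`, `n_high`,
#'   `n_low`, `mean_high`, `mean_low`, `ratio`.
#' @export
high_low_ratio <- function(records, marker = "marker") {
  col <- paste0(marker, "_norm")
  if (!col %in% names(records)) abort(sprintf("records lack column '%s'.", col))
  if (!"egfp_class" %in% names(records)) abort("records are not classified; run classify_by_egfp().")
  hi <- records[[col]][records$egfp_class == "high"]
  lo <- records[[col]][records$egfp_class == "low"]
  if (length(hi) == 0L || length(lo) == 0L) {
    abort("undefined ratio: need at least one nucleus in each eGFP class.")
  }
  structure(
    list(marker = marker, n_high = length(hi), n_low = length(lo),
         mean_high = mean(hi), mean_low = mean(lo),
         ratio = mean(hi) / mean(lo)),
    class = "ssx_ratio"
  )
}

#' @export
print.ssx_ratio <- function(x, ...) {
  cat(sprintf("<ssx_ratio> %s high/low = %.4g (n_high = %d, n_low = %d)\n",
              x$marker, x$ratio, x$n_high, x$n_low))
  invisible(x)
}

#' @method tidy ssx_ratio
#' @export
tidy.ssx_ratio <- function(x, ...) {
  tibble::tibble(egfp_class = c("high", "low"),
                 n = c(x$n_high, x$n_low),
                 mean_norm_intensity = c(x$mean_high, x$mean_low))
}

#' @method glance ssx_ratio
#' @export
glance.ssx_ratio <- function(x, ...) {
  tibble::tibble(marker = x$marker, ratio = x$ratio,
                 n_high = x$n_high, n_low = x$n_low)
}

#' Per-nucleus marker/DAPI intensity ratio
#'
#' The tissue-section statistic: each nucleus's mean marker intensity divided
#' by its mean DAPI intensity.
#'
#' @param records Nucleus tibble from [measure_nuclei()].
#' @param marker Marker channel name (default `"marker"`).
#' @return A tibble with `label` and `ratio`, plus attribute `mean_ratio` (the
#'   group mean).
#' @export
dapi_ratio_per_nucleus <- function(records, marker = "marker") {
  col <- paste0(marker, "_mean")
  if (!col %in% names(records)) abort(sprintf("records lack column '%s'.", col))
  out <- tibble::tibble(label = records$label,
                        ratio = records[[col]] / records$dapi_mean)
  attr(out, "mean_ratio") <- mean(out$ratio)
  out
}

#' Detect foci in a single channel
#'
#' Connected components above an intensity quantile, kept when their area lies
#' within bounds; an automated stand-in for manual focus selection.
#'
#' @param image Channel matrix.
#' @param intensity_quantile Threshold quantile of all pixel intensities
#'   (default 0.99).
#' @param min_area,max_area Area bounds in pixels.
#' @return A focus tibble with `x`, `y` (pixel centroids, 1-based), `r`
#'   (equivalent radius) and `area`; may be empty.
#' @export
detect_foci <- function(image, intensity_quantile = 0.99, min_area = 4,
                        max_area = Inf) {
  thr <- quantile(as.vector(image), intensity_quantile, names = FALSE)
  lab <- label_components(image > thr, connectivity = 8)
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(x = numeric(), y = numeric(), r = numeric(),
                          area = integer()))
  }
  idx <- which(lab != 0L)
  lv <- lab[idx]
  rr <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(lv, nbins = n)
  out <- tibble::tibble(
    x = as.vector(rowsum(as.numeric(cc), lv)) / area,
    y = as.vector(rowsum(as.numeric(rr), lv)) / area,
    r = sqrt(area / pi),
    area = area
  )
  dplyr::filter(out, .data$area >= min_area, .data$area <= max_area)
}

#' Percentage of query foci overlapping an anchor focus
#'
#' A query focus counts as overlapping when its centroid lies within an anchor
#' focus mask dilated by `match_radius`, i.e. within `anchor r + match_radius`
#' of an anchor centroid. This operationalizes visual co-occurrence scoring of
#' marker foci against tether foci.
#'
#' @param query,anchor Focus tibbles (`x`, `y`, `r`) in the same image frame.
#' @param match_radius Dilation radius in pixels; defaults to the mean anchor
#'   radius.
#' @return An object of class `ssx_overlap` with fields `pct`, `n_matched`,
#'   `n_query`, `match_radius`.
#' @export
foci_overlap_pct <- function(query, anchor, match_radius = NULL) {
  if (nrow(query) == 0L) abort("no foci to score.")
  if (is.null(match_radius)) match_radius <- mean(anchor$r)
  if (nrow(anchor) == 0L) {
    matched <- rep(FALSE, nrow(query))
  } else {
    d <- outer(query$x, anchor$x, `-`)^2 + outer(query$y, anchor$y, `-`)^2
    lim <- matrix(rep(anchor$r + match_radius, each = nrow(query)),
                  nrow = nrow(query))
    matched <- rowSums(sqrt(d) <= lim) > 0
  }
  structure(
    list(pct = 100 * mean(matched), n_matched = sum(matched),
         n_query = nrow(query), match_radius = match_radius),
    class = "ssx_overlap"
  )
}

#' @export
print.ssx_overlap <- function(x, ...) {
  cat(sprintf("<ssx_overlap> %.1f%% (%d / %d query foci within anchor + %.3g px)\n",
              x$pct, x$n_matched, x$n_query, x$match_radius))
  invisible(x)
}

#' @method glance ssx_overlap
#' @export
glance.ssx_overlap <- function(x, ...) {
  tibble::tibble(pct = x$pct, n_matched = x$n_matched, n_query = x$n_query,
                 match_radius = x$match_radius)
}

#' Mean DAB nuclear optical density
#'
#' Per-pixel optical density `log10(I0 / max(I, 1))` on a single-channel
#' brightfield proxy, averaged within each segmented nucleus; the cohort value
#' is the mean over nuclei.
#'
#' @param dab DAB channel matrix (brightfield intensities).
#' @param labels Integer label matrix of segmented nuclei.
#' @param I0 White reference intensity (default: image maximum).
#' @return A list with `nuclei` (tibble `label`, `mean_od`) and `mean_od`
#'   (cohort average).
#' @export
dab_mean_od <- function(dab, labels, I0 = max(dab)) {
  if (I0 <= 0) abort("`I0` must be positive.")
  n <- max(labels)
  if (n == 0L) abort("label map contains no nuclei.")
  od <- log10(I0 / pmax(dab, 1))
  idx <- labels != 0L
  lv <- labels[idx]
  per <- as.vector(rowsum(od[idx], lv)) / tabulate(lv, nbins = n)
  list(nuclei = tibble::tibble(label = seq_len(n), mean_od = per),
       mean_od = mean(per))
}
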