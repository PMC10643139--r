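#' Spike-in read fraction of a sample
#'
#' The fraction of uniquely aligned reads attributed to the exogenous spike-in
#' genome, `N_x = spike / (primary + spike)`. Multi-mapping reads never enter
#' these counts.
#'
#' @param primary_unique_reads,spike_unique_reads Nonnegative unique-read
#'   counts for the primary and spike-in genomes (vectorized).
#' @return Spike-in fraction(s) in `[0, 1]`.
#' @export
#' @examples
#' spikein_fraction(98, 2)
spikein_fraction <- function(primary_unique_reads, spike_unique_reads) {
  total <- primary_unique_reads + spike_unique_reads
  if (any(primary_unique_reads < 0) || any(spike_unique_reads < 0)) {
    abort("read counts must be nonnegative.")
  }
  if (any(total <= 0)) abort("no aligned reads: primary + spike counts are zero.")
  spike_unique_reads / total
}

#' Fraction-based spike-in scaling factors (CUT&RUN scheme)
#'
#' Per-sample factors `N_min / N_x`, where `N_x` is the sample's spike-in read
#' fraction and `N_min` the smallest fraction in its group. The `N_min` sample
#' gets factor exactly 1; all factors lie in (0, 1]. Because `N_x` is a
#' fraction, these factors correct spike-in composition, not sequencing depth:
#' apply them to depth-normalized coverage ([normalize_track()]), after which
#' the spike-in-attributed signal (fraction times scaled per-million depth) is
#' equal across samples.
#'
#' @param samples Tibble of samples with at least `sample_id`,
#'   `primary_unique_reads`, `spike_unique_reads`; an optional `group` column
#'   computes factors per group (default: one group).
#' @return A tibble (class `ssx_factors`) with one row per sample: `sample_id`,
#'   `group`, `spike_fraction`, `factor`, `reference_sample_id`, and attribute
#'   `scheme = "cutandrun"`.
#' @export
#' @examples
#' s <- tibble::tibble(sample_id = c("A", "B"),
#'                     primary_unique_reads = c(980, 960),
#'                     spike_unique_reads = c(20, 40))
#' cutandrun_scaling(s)
cutandrun_scaling <- function(samples) {
  if (nrow(samples) < 1L) abort("need at least one sample.")
  if (!"group" %in% names(samples)) samples$group <- "all"
  zero <- samples$spike_unique_reads <= 0
  if (any(zero)) {
    abort(sprintf("sample '%s' has zero spike-in reads; its scaling factor is undefined.",
                  samples$sample_id[which(zero)[1]]))
  }
  out <- samples |>
    dplyr::mutate(spike_fraction = spikein_fraction(.data$primary_unique_reads,
                                                    .data$spike_unique_reads)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      factor = min(.data$spike_fraction) / .data$spike_fraction,
      reference_sample_id = .data$sample_id[which.min(.data$spike_fraction)]
    ) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "group", "spike_fraction", "factor",
                  "reference_sample_id")
  new_factor_set(out, scheme = "cutandrun")
}

#' Alpha-normalized downsampling factors (calibrated ChIP scheme)
#'
#' For each IP sample paired by (group, condition) with an input sample, the
#' raw factor is
#' `1 / N(IP spike) * N(input spike) / N(input primary)`,
#' and a per-group coefficient `alpha` rescales raw factors so the largest
#' final factor equals exactly 1. Unlike the fraction-based scheme, the
#' `1/N(IP spike)` count term also corrects sequencing depth, so these factors
#' apply directly to raw counts (read downsampling / binomial thinning).
#'
#' @param samples Tibble with `sample_id`, `role` (`IP`/`input`), `condition`,
#'   `group`, `primary_unique_reads`, `spike_unique_reads`.
#' @return A tibble (class `ssx_factors`) with one row per IP sample:
#'   `sample_id`, `group`, `condition`, `input_sample_id`, `factor`, `alpha`,
#'   `reference_sample_id` (the factor-1 sample), attribute `scheme = "cchip"`.
#' @export
cchip_downsampling <- function(samples) {
  validate_spikein_samples(samples)
  ips <- dplyr::filter(samples, .data$role == "IP")
  inputs <- dplyr::filter(samples, .data$role == "input")
  if (nrow(ips) == 0L) abort("no IP samples.")
  paired <- dplyr::left_join(
    ips, inputs,
    by = c("group", "condition"), suffix = c("", "_input"),
    relationship = "many-to-many"
  )
  dup <- paired |> dplyr::count(.data$sample_id) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(sprintf("IP sample '%s' matches more than one input in its (group, condition).",
                  dup$sample_id[1]))
  }
  unmatched <- is.na(paired$sample_id_input)
  if (any(unmatched)) {
    abort(sprintf("IP sample '%s' has no matching input in its (group, condition).",
                  paired$sample_id[which(unmatched)[1]]))
  }
  if (any(paired$spike_unique_reads <= 0)) {
    abort(sprintf("IP sample '%s' has zero spike-in reads.",
                  paired$sample_id[which(paired$spike_unique_reads <= 0)[1]]))
  }
  if (any(paired$spike_unique_reads_input <= 0) || any(paired$primary_unique_reads_input <= 0)) {
    abort("input samples need positive primary and spike-in counts.")
  }
  out <- paired |>
    dplyr::mutate(raw_factor = (1 / .data$spike_unique_reads) *
                    .data$spike_unique_reads_input / .data$primary_unique_reads_input) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      alpha = 1 / max(.data$raw_factor),
      # dividing by the maximum (rather than multiplying by alpha) makes the
      # reference factor exactly 1 in floating point
      factor = .data$raw_factor / max(.data$raw_factor),
      reference_sample_id = .data$sample_id[which.max(.data$raw_factor)]
    ) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "group", "condition",
                  input_sample_id = "sample_id_input",
                  "factor", "alpha", "reference_sample_id")
  new_factor_set(out, scheme = "cchip")
}

new_factor_set <- function(x, scheme) {
  stopifnot(all(x$factor > 0), all(x$factor <= 1 + 1e-12))
  x$factor <- pmin(x$factor, 1)
  attr(x, "scheme") <- scheme
  class(x) <- c("ssx_factors", class(x))
  x
}

#' @method glance ssx_factors
#' @export
glance.ssx_factors <- function(x, ...) {
  tibble::tibble(
    scheme = attr(x, "scheme"),
    n_samples = nrow(x),
    n_groups = dplyr::n_distinct(x$group),
    min_factor = min(x$factor),
    max_factor = max(x$factor)
  )
}

#' Multiply a track (or counts) by a scaling factor
#'
#' @param track An `ssx_track` or a numeric vector.
#' @param factor A positive scaling factor.
#' @return The scaled object; tracks get provenance `"scaled"`.
#' @export
apply_factor <- function(track, factor) {
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0) {
    abort("`factor` must be a single positive number.")
  }
  if (inherits(track, "ssx_track")) {
    track$values <- track$values * factor
    track$provenance <- "scaled"
    track
  } else if (is.numeric(track)) {
    track * factor
  } else {
    abort("`track` must be an ssx_track or numeric.")
  }
}

#' Binomial thinning of integer counts
#'
#' Seeded read downsampling at the count level: each of the `n` counts in a bin
#' is kept independently with probability `factor`, so the expected total is
#' `factor` times the original total. This mirrors read-level downsampling for
#' count summaries.
#'
#' @param x An `ssx_track` of integer counts, or an integer vector.
#' @param factor Keep probability in (0, 1].
#' @param seed Integer seed.
#' @return The thinned object, same type as `x`; tracks get provenance
#'   `"downsampled"`.
#' @export
downsample_counts <- function(x, factor, seed) {
  if (length(factor) != 1L || factor <= 0 || factor > 1) {
    abort("`factor` must lie in (0, 1].")
  }
  vals <- if (inherits(x, "ssx_track")) x$values else x
  if (any(vals != floor(vals))) {
    abort("binomial thinning requires integer counts.")
  }
  thinned <- if (factor == 1) {
    vals
  } else {
    with_seed(seed, rbinom(length(vals), size = as.integer(vals), prob = factor))
  }
  if (inherits(x, "ssx_track")) {
    x$values <- as.numeric(thinned)
    x$provenance <- "downsampled"
    x
  } else {
    thinned
  }
}
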