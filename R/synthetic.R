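#' Simulate a spike-in calibrated chromatin profiling experiment
#'
#' Generates count summaries, binned IP coverage tracks and a peak set for two
#' conditions (`A` = control, `B` = perturbed) with known ground truth,
#' emulating the design of a spike-in calibrated comparison: the true spike-in
#' material per cell is constant across conditions, condition-B signal at
#' "depleted" peaks is globally scaled by `retention_factor` before depth
#' resampling, and a confounded sequencing depth (`depth_confound`) makes
#' naive library-size normalization mask the loss.
#'
#' Reads are not synthesized as sequences; the generator draws spike-in read
#' counts from a binomial over the sample depth and distributes primary reads
#' over bins multinomially, matching the count-level inputs of the calibration
#' formulas.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param genome_length Toy reference length in bases (single reference
#'   `"chrT"`).
#' @param bin Track bin width in bases.
#' @param n_peaks Number of non-overlapping peaks.
#' @param peak_width Two-element range of peak widths in bases.
#' @param depth Condition-A sequencing depth in reads; condition B gets
#'   `depth * depth_confound`.
#' @param depth_confound Multiplicative depth difference for condition B.
#' @param spike_prop True spike-in material as a proportion of condition-A
#'   primary IP material (constant per cell across conditions).
#' @param retention_factor Fraction of condition-A signal retained at depleted
#'   peaks in condition B, in (0, 1].
#' @param depleted_fraction Fraction of peaks in the depleted population, in
#'   `[0, 1]`; the rest retain full signal.
#' @param peak_mass_frac Fraction of IP material located in peaks (the rest is
#'   uniform background).
#' @param out_dir Optional directory; when given, writes `counts.tsv`,
#'   `peaks.bed`, one bedGraph per IP sample and `truth.tsv`.
#' @return A list with `samples` (per-sample unique-read counts), `tracks`
#'   (named list of raw-count `ssx_track`s for the IP samples), `peaks`
#'   (tibble with `depleted` flag withheld; see `truth`), and `truth` (the
#'   generating parameters and per-peak depleted flags; for tests only).
#' @export
sim_spikein_experiment <- function(seed,
                                   genome_length = 5e7,
                                   bin = 50,
                                   n_peaks = 10000,
                                   peak_width = c(500, 2000),
                                   depth = 2e6,
                                   depth_confound = 2,
                                   spike_prop = 0.05,
                                   retention_factor = 0.3,
                                   depleted_fraction = 1.0,
                                   peak_mass_frac = 0.9,
                                   out_dir = NULL) {
  if (depth <= 0) abort("`depth` must be positive.")
  if (n_peaks <= 0) abort("`n_peaks` must be a positive integer.")
  if (retention_factor <= 0 || retention_factor > 1) {
    abort("`retention_factor` must lie in (0, 1].")
  }
  if (depleted_fraction < 0 || depleted_fraction > 1) {
    abort("`depleted_fraction` must lie in [0, 1].")
  }
  slot <- genome_length / n_peaks
  if (slot < peak_width[2] + 2 * bin) {
    abort("genome too short for `n_peaks` non-overlapping peaks of this width.")
  }
  with_seed(seed, {
    widths <- round(runif(n_peaks, peak_width[1], peak_width[2]))
    starts <- round((seq_len(n_peaks) - 1) * slot +
                      runif(n_peaks) * (slot - widths - bin))
    peaks <- tibble::tibble(
      reference = "chrT", start = starts, end = starts + widths,
      name = sprintf("peak_%05d", seq_len(n_peaks))
    )
    depleted <- rep(FALSE, n_peaks)
    depleted[sample.int(n_peaks, round(depleted_fraction * n_peaks))] <- TRUE

    amp <- rgamma(n_peaks, shape = 3, rate = 1)          # per-base enrichment
    peak_mass_a <- sum(amp * widths)
    bg_per_base <- peak_mass_a * (1 - peak_mass_frac) / peak_mass_frac / genome_length

    n_bins <- ceiling(genome_length / bin)
    bin_mass <- function(scaled_amp) {
      m <- rep(bg_per_base * bin, n_bins)
      first_b <- floor(starts / bin)
      last_b <- floor((starts + widths - 1) / bin)
      for (i in seq_len(n_peaks)) {
        b <- first_b[i]:last_b[i]
        lo <- pmax(starts[i], b * bin)
        hi <- pmin(starts[i] + widths[i], (b + 1) * bin)
        m[b + 1L] <- m[b + 1L] + (hi - lo) * scaled_amp[i]
      }
      m
    }
    amp_b <- ifelse(depleted, amp * retention_factor, amp)
    mass <- list(A = bin_mass(amp), B = bin_mass(amp_b))
    spike_mass <- spike_prop * sum(mass$A)

    depths <- c(A = depth, B = depth * depth_confound)
    samples <- list()
    tracks <- list()
    for (cond in c("A", "B")) {
      m <- mass[[cond]]
      d <- round(depths[[cond]])
      sp_frac <- spike_mass / (sum(m) + spike_mass)
      sp_ip <- rbinom(1L, d, sp_frac)
      primary_ip <- d - sp_ip
      counts <- as.numeric(rmultinom(1L, primary_ip, prob = m))
      tracks[[paste0(cond, "_IP")]] <- signal_track(
        counts, bin = bin, reference = "chrT", seqlength = genome_length
      )
      # Input: uniform genomic material, same spike material per cell.
      in_frac <- spike_prop / (1 + spike_prop)
      sp_in <- rbinom(1L, d, in_frac)
      samples[[paste0(cond, "_IP")]] <- tibble::tibble(
        sample_id = paste0(cond, "_IP"), role = "IP", condition = cond,
        group = "g1", primary_unique_reads = primary_ip, spike_unique_reads = sp_ip
      )
      samples[[paste0(cond, "_input")]] <- tibble::tibble(
        sample_id = paste0(cond, "_input"), role = "input", condition = cond,
        group = "g1", primary_unique_reads = d - sp_in, spike_unique_reads = sp_in
      )
    }
    samples <- dplyr::bind_rows(samples)
    truth <- list(
      scenario = "spikein_experiment", seed = seed,
      retention_factor = retention_factor, depleted_fraction = depleted_fraction,
      depth_confound = depth_confound, spike_prop = spike_prop,
      depleted = depleted
    )
    out <- list(samples = samples, tracks = tracks, peaks = peaks, truth = truth)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_table_tsv(samples, file.path(out_dir, "counts.tsv"))
      write_bed(peaks, file.path(out_dir, "peaks.bed"))
      for (nm in names(tracks)) {
        write_bedgraph(tracks[[nm]], file.path(out_dir, paste0(nm, ".bedgraph")))
      }
      write_table_tsv(
        tibble::tibble(peak = peaks$name, depleted = depleted),
        file.path(out_dir, "truth_peaks.tsv")
      )
      write_table_tsv(
        tibble::tibble(
          parameter = c("retention_factor", "depleted_fraction", "depth_confound",
                        "spike_prop", "seed"),
          value = c(retention_factor, depleted_fraction, depth_confound,
                    spike_prop, seed)
        ),
        file.path(out_dir, "truth.tsv")
      )
    }
    out
  })
}

# Place n non-overlapping disks of radii r in a w x h field by rejection
# sampling; `gap` background pixels are kept between disks.
place_disks <- function(n, r, w, h, gap = 2, max_tries = 50000L) {
  cx <- numeric(0); cy <- numeric(0); rr <- numeric(0)
  tries <- 0L
  while (length(cx) < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort(sprintf("could only place %d of %d non-overlapping nuclei after %d tries.",
                    length(cx), n, max_tries))
    }
    ri <- r[length(cx) + 1L]
    x <- runif(1, ri + 1, w - ri)
    y <- runif(1, ri + 1, h - ri)
    if (length(cx) == 0L || all((cx - x)^2 + (cy - y)^2 > (rr + ri + gap)^2)) {
      cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, ri)
    }
  }
  tibble::tibble(cx = cx, cy = cy, r = rr)
}

# Paint per-nucleus disk levels onto a background matrix (rows = y, cols = x).
paint_disks <- function(width, height, disks, levels, background) {
  img <- matrix(background, nrow = height, ncol = width)
  for (i in seq_len(nrow(disks))) {
    r <- disks$r[i]
    xs <- max(1L, floor(disks$cx[i] - r)):min(width, ceiling(disks$cx[i] + r))
    ys <- max(1L, floor(disks$cy[i] - r)):min(height, ceiling(disks$cy[i] + r))
    dx <- outer(rep(1, length(ys)), xs - disks$cx[i])
    dy <- outer(ys - disks$cy[i], rep(1, length(xs)))
    inside <- dx^2 + dy^2 <= r^2
    sub <- img[ys, xs, drop = FALSE]
    sub[inside] <- levels[i]
    img[ys, xs] <- sub
  }
  img
}

#' Simulate a multi-channel nuclei image with known per-nucleus truth
#'
#' Non-overlapping disk nuclei on a uniform background, three channels (DAPI,
#' eGFP, marker). A designated "high" subset expresses eGFP above the DAPI
#' level (normalized eGFP > 1), the rest below; the marker channel responds to
#' eGFP class with a known `marker_fold`. Per-pixel Gaussian noise has
#' standard deviation `noise_sd_frac` times the local signal.
#'
#' @param seed Integer seed.
#' @param width,height Image size in pixels.
#' @param n_nuclei Number of nuclei (0 gives a valid blank image).
#' @param radius_range Two-element nucleus radius range, pixels.
#' @param dapi_mean Mean per-nucleus DAPI intensity (16-bit scale).
#' @param dapi_cv Between-nucleus coefficient of variation of DAPI level.
#' @param high_fraction Fraction of nuclei in the eGFP-high class.
#' @param egfp_high_norm,egfp_low_norm True DAPI-normalized eGFP levels of the
#'   two classes (must straddle 1).
#' @param marker_base_norm True DAPI-normalized marker level of low nuclei.
#' @param marker_fold Marker response in eGFP-high nuclei.
#' @param noise_sd_frac Per-pixel noise SD as a fraction of local signal.
#' @param background Background intensity.
#' @param out_dir Optional directory; writes `image.tiff` (multi-page: DAPI,
#'   eGFP, marker) and `truth_nuclei.tsv`.
#' @return A list with `image` (named list of matrices `dapi`, `egfp`,
#'   `marker`), `truth` (per-nucleus tibble) and `params`.
#' @export
sim_nuclei_image <- function(seed,
                             width = 384, height = 384,
                             n_nuclei = 200,
                             radius_range = c(5, 8),
                             dapi_mean = 3000, dapi_cv = 0.1,
                             high_fraction = 0.5,
                             egfp_high_norm = 3, egfp_low_norm = 0.2,
                             marker_base_norm = 0.8,
                             marker_fold = 2,
                             noise_sd_frac = 0.05,
                             background = 100,
                             out_dir = NULL) {
  if (n_nuclei < 0) abort("`n_nuclei` must be nonnegative.")
  with_seed(seed, {
    if (n_nuclei == 0L) {
      blank <- matrix(background, nrow = height, ncol = width)
      image <- list(dapi = blank, egfp = blank, marker = blank)
      truth <- tibble::tibble(nucleus = integer(), cx = numeric(), cy = numeric(),
                              r = numeric(), egfp_class = character(),
                              dapi_level = numeric(), egfp_level = numeric(),
                              marker_level = numeric())
    } else {
      radii <- runif(n_nuclei, radius_range[1], radius_range[2])
      disks <- place_disks(n_nuclei, radii, width, height)
      n_high <- round(high_fraction * n_nuclei)
      cls <- rep("low", n_nuclei)
      cls[sample.int(n_nuclei, n_high)] <- "high"
      dapi_level <- dapi_mean * pmax(1 + rnorm(n_nuclei, sd = dapi_cv), 0.2)
      egfp_level <- dapi_level * ifelse(cls == "high", egfp_high_norm, egfp_low_norm)
      marker_level <- dapi_level * marker_base_norm *
        ifelse(cls == "high", marker_fold, 1)
      image <- list(
        dapi = paint_disks(width, height, disks, dapi_level, background),
        egfp = paint_disks(width, height, disks, egfp_level, background),
        marker = paint_disks(width, height, disks, marker_level, background)
      )
      truth <- tibble::tibble(nucleus = seq_len(n_nuclei), cx = disks$cx,
                              cy = disks$cy, r = disks$r, egfp_class = cls,
                              dapi_level = dapi_level, egfp_level = egfp_level,
                              marker_level = marker_level)
    }
    if (noise_sd_frac > 0) {
      image <- lapply(image, function(ch) {
        noisy <- ch + rnorm(length(ch), sd = noise_sd_frac * ch)
        matrix(pmin(pmax(round(noisy), 0), 65535), nrow = nrow(ch))
      })
    } else {
      image <- lapply(image, function(ch) round(ch))
    }
    params <- list(scenario = "nuclei_image", seed = seed, n_nuclei = n_nuclei,
                   marker_fold = marker_fold, high_fraction = high_fraction,
                   noise_sd_frac = noise_sd_frac)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_image_tiff(image, file.path(out_dir, "image.tiff"))
      write_table_tsv(truth, file.path(out_dir, "truth_nuclei.tsv"))
    }
    list(image = image, truth = truth, params = params)
  })
}

#' Simulate a two-channel foci field with known co-localization
#'
#' `n_anchor` anchor (tether) foci are placed without overlap; each anchor
#' independently yields one query-channel focus that either co-occurs with the
#' anchor (probability `overlap_prob`, placed within `jitter` pixels of the
#' anchor center) or is displaced to a position guaranteed not to overlap any
#' anchor. Optional extra background query foci can be added. The overlap
#' fraction of the query set is therefore an unbiased binomial estimate of
#' `overlap_prob`.
#'
#' @param seed Integer seed.
#' @param n_anchor Number of anchor foci.
#' @param overlap_prob Co-occurrence probability in `[0, 1]`.
#' @param field Two-element field size `(width, height)` in pixels.
#' @param focus_radius Focus radius in pixels (both channels).
#' @param jitter Maximum displacement of a co-occurring focus from its anchor
#'   center, pixels (keep `<= focus_radius` so co-occurring foci always match).
#' @param n_background Extra non-co-occurring query foci (default 0).
#' @param out_dir Optional directory; writes `anchor_foci.tsv`,
#'   `query_foci.tsv`, `truth_foci.tsv`.
#' @return A list with `anchor` and `query` focus tibbles (`x`, `y`, `r`),
#'   `truth` (per-anchor partner flag) and `params`.
#' @export
sim_foci_field <- function(seed,
                           n_anchor = 500,
                           overlap_prob = 0.6,
                           field = c(1024, 1024),
                           focus_radius = 4,
                           jitter = 2,
                           n_background = 0,
                           out_dir = NULL) {
  if (overlap_prob < 0 || overlap_prob > 1) abort("`overlap_prob` must lie in [0, 1].")
  w <- field[1]; h <- field[2]
  with_seed(seed, {
    anchors <- place_disks(n_anchor, rep(focus_radius, n_anchor), w, h,
                           gap = 2 * focus_radius + 2)
    anchor <- tibble::tibble(x = anchors$cx, y = anchors$cy,
                             r = rep(focus_radius, n_anchor))
    has_partner <- runif(n_anchor) < overlap_prob
    # Co-occurring query foci: jittered copies of their anchors.
    theta <- runif(n_anchor, 0, 2 * pi)
    rad <- jitter * sqrt(runif(n_anchor))
    qx <- anchor$x + rad * cos(theta)
    qy <- anchor$y + rad * sin(theta)
    # Displaced query foci: rejection-sampled outside every dilated anchor.
    n_disp <- sum(!has_partner) + n_background
    exclusion <- 3 * focus_radius + 1
    dx <- numeric(0); dy <- numeric(0)
    while (length(dx) < n_disp) {
      m <- max(2L * (n_disp - length(dx)), 16L)
      px <- runif(m, focus_radius + 1, w - focus_radius)
      py <- runif(m, focus_radius + 1, h - focus_radius)
      mind2 <- apply(outer(px, anchor$x, `-`)^2 + outer(py, anchor$y, `-`)^2, 1, min)
      ok <- mind2 > exclusion^2
      dx <- c(dx, px[ok]); dy <- c(dy, py[ok])
    }
    dx <- dx[seq_len(n_disp)]; dy <- dy[seq_len(n_disp)]
    disp_for_anchor <- seq_len(sum(!has_partner))
    qx[!has_partner] <- dx[disp_for_anchor]
    qy[!has_partner] <- dy[disp_for_anchor]
    query <- tibble::tibble(
      x = c(qx, tail(dx, n_background)),
      y = c(qy, tail(dy, n_background)),
      r = focus_radius
    )
    truth <- tibble::tibble(anchor = seq_len(n_anchor), has_partner = has_partner)
    params <- list(scenario = "foci_field", seed = seed, n_anchor = n_anchor,
                   overlap_prob = overlap_prob, focus_radius = focus_radius,
                   jitter = jitter, n_background = n_background)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_table_tsv(anchor, file.path(out_dir, "anchor_foci.tsv"))
      write_table_tsv(query, file.path(out_dir, "query_foci.tsv"))
      write_table_tsv(truth, file.path(out_dir, "truth_foci.tsv"))
    }
    list(anchor = anchor, query = query, truth = truth, params = params)
  })
}

#' Render a focus set as an intensity image
#'
#' Paints each focus as a bright disk on a dark background; useful for testing
#' image-based focus detection against a known focus table.
#'
#' @param foci Focus tibble (`x`, `y`, `r`).
#' @param width,height Image size in pixels.
#' @param intensity Disk intensity; background is 0.
#' @return A numeric matrix.
#' @export
render_foci <- function(foci, width, height, intensity = 10000) {
  disks <- tibble::tibble(cx = foci$x, cy = foci$y, r = foci$r)
  paint_disks(width, height, disks, rep(intensity, nrow(foci)), background = 0)
}

#' Simulate a NanoBRET plate for one condition
#'
#' Two `+ligand` and two `-ligand` wells whose donor/acceptor emissions are
#' consistent with a known true milliBRET value above the no-acceptor
#' baseline: `+ligand` BU is `baseline_bu + true_mbu/1000`, `-ligand` BU is
#' `baseline_bu`, with multiplicative noise on each emission.
#'
#' @param seed Integer seed.
#' @param true_mbu True ligand-dependent signal in milliBRET units.
#' @param baseline_bu Raw BRET ratio of the no-acceptor control wells.
#' @param donor_scale Mean donor emission in counts.
#' @param noise_cv Multiplicative noise CV on each emission.
#' @param condition Condition label.
#' @param replicates Technical replicates per arm (default 2).
#' @param out_dir Optional directory; writes `plate.csv` and `truth.tsv`.
#' @return A list with `wells` (tibble: `condition`, `ligand`, `replicate`,
#'   `donor`, `acceptor`) and `truth`.
#' @export
sim_bret_plate <- function(seed, true_mbu = 30, baseline_bu = 0.02,
                           donor_scale = 1e5, noise_cv = 0.02,
                           condition = "condition", replicates = 2,
                           out_dir = NULL) {
  if (donor_scale <= 0) abort("`donor_scale` must be positive.")
  if (baseline_bu < 0 || true_mbu < 0) abort("negative emissions are not allowed.")
  with_seed(seed, {
    arms <- tibble::tibble(
      ligand = rep(c("plus", "minus"), each = replicates),
      replicate = rep(seq_len(replicates), 2),
      bu = rep(c(baseline_bu + true_mbu / 1000, baseline_bu), each = replicates)
    )
    donor <- donor_scale * (1 + rnorm(nrow(arms), sd = noise_cv))
    acceptor <- arms$bu * donor_scale * (1 + rnorm(nrow(arms), sd = noise_cv))
    if (any(donor <= 0) || any(acceptor < 0)) {
      abort("noise produced negative emissions; lower `noise_cv`.")
    }
    wells <- tibble::tibble(condition = condition, ligand = arms$ligand,
                            replicate = arms$replicate, donor = donor,
                            acceptor = acceptor)
    truth <- list(scenario = "bret_plate", seed = seed, true_mbu = true_mbu,
                  baseline_bu = baseline_bu, noise_cv = noise_cv)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      readr::write_csv(wells, file.path(out_dir, "plate.csv"), progress = FALSE)
      write_table_tsv(tibble::tibble(parameter = c("true_mbu", "baseline_bu", "seed"),
                                     value = c(true_mbu, baseline_bu, seed)),
                      file.path(out_dir, "truth.tsv"))
    }
    list(wells = wells, truth = truth)
  })
}

#' Simulate a salt-extraction band-intensity profile
#'
#' Per-fraction band intensities proportional to known fraction weights, with
#' multiplicative noise.
#'
#' @param seed Integer seed.
#' @param fraction_weights Weights over the fractions (80/150/300/500 mM NaCl
#'   and the final chromatin fraction), summing to 1 within 1e-6.
#' @param total_intensity Total band intensity.
#' @param noise_cv Multiplicative noise CV per band.
#' @param out_dir Optional directory; writes `salt_profile.tsv` and
#'   `truth.tsv`.
#' @return A list with `intensities` (tibble: `fraction`, `intensity`) and
#'   `truth`.
#' @export
sim_salt_profile <- function(seed,
                             fraction_weights = c(0.10, 0.15, 0.15, 0.10, 0.50),
                             total_intensity = 1e4,
                             noise_cv = 0.05,
                             out_dir = NULL) {
  if (abs(sum(fraction_weights) - 1) > 1e-6) {
    abort("`fraction_weights` must sum to 1 within 1e-6.")
  }
  if (any(fraction_weights < 0)) abort("`fraction_weights` must be nonnegative.")
  labels <- if (length(fraction_weights) == 5L) {
    c("80mM", "150mM", "300mM", "500mM", "chromatin")
  } else {
    paste0("fraction_", seq_along(fraction_weights))
  }
  with_seed(seed, {
    intensity <- pmax(total_intensity * fraction_weights *
                        (1 + rnorm(length(fraction_weights), sd = noise_cv)), 0)
    out <- list(
      intensities = tibble::tibble(fraction = labels, intensity = intensity),
      truth = list(scenario = "salt_profile", seed = seed,
                   fraction_weights = fraction_weights, noise_cv = noise_cv)
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_table_tsv(out$intensities, file.path(out_dir, "salt_profile.tsv"))
      write_table_tsv(tibble::tibble(fraction = labels, weight = fraction_weights),
                      file.path(out_dir, "truth.tsv"))
    }
    out
  })
}
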