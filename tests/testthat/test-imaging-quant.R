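disk_image <- function(w, h, centers, r, fg = 200, bg = 10) {
  disks <- tibble::tibble(cx = centers[, 1], cy = centers[, 2], r = r)
  render <- ssxquant::render_foci(tibble::tibble(x = disks$cx, y = disks$cy, r = disks$r),
                                  w, h, intensity = fg - bg)
  render + bg
}

test_that("Li threshold separates a two-valued image and matches the scan oracle", {
  img <- disk_image(64, 64, cbind(c(16, 48), c(20, 44)), r = 7, fg = 200, bg = 10)
  thr <- li_threshold(img)
  expect_gte(thr, 10)
  expect_lt(thr, 200)
  # induced mask recovers exactly the ground-truth disks
  expect_identical(img > thr, img == 200)
  expect_equal(thr, oracle_li_scan(as.vector(img)))
  expect_error(li_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("Li threshold equals the exhaustive minimizer on random mixed images", {
  withr::with_seed(101, {
    for (i in 1:25) {
      bimodal <- i %% 2 == 0
      v <- if (bimodal) {
        c(rnorm(3000, 40, 8), rnorm(1096, 180, 25))
      } else {
        rgamma(4096, shape = 2, scale = 30)
      }
      img <- matrix(pmax(round(v), 0), 64, 64)
      expect_equal(li_threshold(img), oracle_li_scan(as.vector(img)))
    }
  })
})

test_that("Li threshold scales with the image and the iteration agrees when separable", {
  img <- disk_image(48, 48, cbind(24, 24), r = 10, fg = 3000, bg = 100)
  thr <- li_threshold(img)
  expect_equal(li_threshold(img * 3), 3 * thr)
  it <- li_threshold(img, method = "iterative")
  # same induced segmentation on a well-separated image
  expect_identical(img > thr, img > it)
})

test_that("segmentation labels 8-connected components and honors min_area", {
  img <- disk_image(80, 80, cbind(c(20, 60, 40), c(20, 20, 60)), r = c(8, 8, 3),
                    fg = 100, bg = 0)
  lab <- segment_nuclei(img, threshold = 50, min_area = 1)
  expect_identical(attr(lab, "n_labels"), 3L)
  areas <- tabulate(lab[lab > 0])
  expect_equal(sort(areas), sort(oracle_label_areas(img > 50)))
  # the r = 3 disk (~29 px) is filtered at min_area = 50
  lab2 <- segment_nuclei(img, threshold = 50, min_area = 50)
  expect_identical(attr(lab2, "n_labels"), 2L)
  expect_identical(sort(unique(as.vector(lab2))), c(0L, 1L, 2L))
  expect_warning(blank <- segment_nuclei(matrix(0, 10, 10), threshold = 1),
                 "no nuclei")
  expect_identical(attr(blank, "n_labels"), 0L)
})

test_that("labelling agrees with an independent graph-components oracle on random blobs", {
  withr::with_seed(113, {
    for (i in 1:5) {
      mask <- matrix(runif(64 * 64) < 0.35, 64, 64)
      lab <- segment_nuclei(mask + 0, threshold = 0.5, min_area = 1)
      got <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
      expect_equal(got, oracle_label_areas(mask, connectivity = 8))
    }
  })
})

test_that("per-nucleus means match a pixel loop and normalize to DAPI", {
  withr::with_seed(127, {
    dapi <- matrix(runif(32 * 32, 50, 150), 32, 32)
    marker <- matrix(runif(32 * 32, 0, 80), 32, 32)
  })
  mask <- disk_image(32, 32, cbind(c(9, 24), c(9, 24)), r = 5, fg = 1, bg = 0) > 0.5
  lab <- segment_nuclei(mask + 0, threshold = 0.5, min_area = 1)
  rec <- measure_nuclei(lab, list(dapi = dapi, marker = marker))
  for (l in rec$label) {
    px <- lab == l
    expect_equal(rec$dapi_mean[rec$label == l], mean(dapi[px]))
    expect_equal(rec$marker_mean[rec$label == l], mean(marker[px]))
  }
  expect_equal(rec$dapi_norm, rep(1, nrow(rec)))
  expect_equal(rec$marker_norm, rec$marker_mean / rec$dapi_mean)
  # uniform channel: every mean is that value
  rec2 <- measure_nuclei(lab, list(dapi = matrix(100, 32, 32),
                                   marker = matrix(50, 32, 32)))
  expect_true(all(rec2$dapi_mean == 100))
  expect_equal(rec2$marker_norm, rep(0.5, nrow(rec2)))
})

test_that("eGFP classification uses the documented tie rule", {
  rec <- tibble::tibble(label = 1:3, egfp_norm = c(1.5, 0.2, 1.0))
  cls <- classify_by_egfp(rec)
  expect_identical(cls$egfp_class, c("high", "low", "low"))
})

test_that("high/low ratio needs both classes and is rescaling-invariant", {
  rec <- tibble::tibble(
    label = 1:8,
    dapi_mean = rep(100, 8),
    marker_norm = c(2, 2.2, 1.8, 2.0, 1.0, 1.1, 0.9, 1.0),
    egfp_norm = c(rep(2, 4), rep(0.3, 4))
  ) |> classify_by_egfp()
  r <- high_low_ratio(rec)
  expect_equal(r$ratio, mean(c(2, 2.2, 1.8, 2.0)) / mean(c(1.0, 1.1, 0.9, 1.0)))
  expect_equal(r$n_high, 4)
  # identical distributions -> ratio 1
  same <- dplyr::mutate(rec, marker_norm = 1.3)
  expect_equal(high_low_ratio(same)$ratio, 1)
  # all-high input is an error
  expect_error(high_low_ratio(dplyr::mutate(rec, egfp_norm = 2) |> classify_by_egfp()),
               "undefined ratio")
  # permuting nuclei changes nothing
  r2 <- high_low_ratio(rec[sample(8), ])
  expect_equal(r2$ratio, r$ratio)
})

test_that("DAPI normalization cancels uniform rescaling of channels", {
  sim <- sim_nuclei_image(seed = 31, n_nuclei = 40, width = 256, height = 256,
                          noise_sd_frac = 0.02)
  lab <- segment_nuclei(sim$image$dapi)
  rec <- classify_by_egfp(measure_nuclei(lab, sim$image))
  r0 <- high_low_ratio(rec)$ratio
  # marker channel gain cancels in the high/low ratio of class means
  img_g <- sim$image; img_g$marker <- img_g$marker * 1.7
  rg <- high_low_ratio(classify_by_egfp(measure_nuclei(lab, img_g)))$ratio
  expect_equal(rg, r0, tolerance = 1e-12)
  # joint gain on all channels cancels entirely
  img_j <- lapply(sim$image, function(ch) ch * 2.4)
  rj <- high_low_ratio(classify_by_egfp(measure_nuclei(lab, img_j)))$ratio
  expect_equal(rj, r0, tolerance = 1e-12)
})

test_that("per-nucleus marker/DAPI ratios hit closed forms", {
  mask <- disk_image(32, 32, cbind(c(9, 24), c(9, 24)), r = 5, fg = 1, bg = 0) > 0.5
  lab <- segment_nuclei(mask + 0, threshold = 0.5, min_area = 1)
  dapi <- matrix(80, 32, 32)
  rec1 <- measure_nuclei(lab, list(dapi = dapi, marker = dapi))
  expect_equal(dapi_ratio_per_nucleus(rec1)$ratio, rep(1, 2))
  rec2 <- measure_nuclei(lab, list(dapi = dapi, marker = dapi * 2))
  dr <- dapi_ratio_per_nucleus(rec2)
  expect_equal(dr$ratio, rep(2, 2))
  expect_equal(attr(dr, "mean_ratio"), 2)
  withr::with_seed(131, marker <- matrix(runif(32 * 32, 10, 90), 32, 32))
  rec3 <- measure_nuclei(lab, list(dapi = dapi, marker = marker))
  want <- vapply(rec3$label, function(l) mean(marker[lab == l]) / 80, numeric(1))
  expect_equal(dapi_ratio_per_nucleus(rec3)$ratio, want)
})

test_that("focus detection finds bright disks and ignores blank fields", {
  foci <- tibble::tibble(x = c(20, 50), y = c(30, 12), r = 4)
  img <- render_foci(foci, 64, 64)
  det <- detect_foci(img, intensity_quantile = 0.9, min_area = 5)
  expect_equal(nrow(det), 2L)
  expect_equal(sort(det$x), sort(foci$x), tolerance = 1)
  expect_equal(sort(det$y), sort(foci$y), tolerance = 1)
  expect_equal(nrow(detect_foci(matrix(0, 32, 32), intensity_quantile = 0.999)), 0L)
})

test_that("foci overlap scoring is exact on aligned/displaced sets and monotone in radius", {
  anchor <- tibble::tibble(x = c(10, 30, 50), y = c(10, 30, 50), r = 3)
  expect_equal(foci_overlap_pct(anchor, anchor)$pct, 100)
  far <- dplyr::mutate(anchor, x = x + 25)
  expect_equal(foci_overlap_pct(far, anchor, match_radius = 3)$pct, 0)
  expect_error(foci_overlap_pct(anchor[0, ], anchor), "no foci")
  # monotone nondecreasing in match radius
  withr::with_seed(137, query <- tibble::tibble(x = runif(50, 0, 64),
                                                y = runif(50, 0, 64), r = 2))
  pcts <- vapply(c(0, 2, 5, 10, 20), function(mr)
    foci_overlap_pct(query, anchor, match_radius = mr)$pct, numeric(1))
  expect_true(all(diff(pcts) >= 0))
})

test_that("DAB optical density follows the log10 definition", {
  mask <- disk_image(32, 32, cbind(c(9, 24), c(9, 24)), r = 5, fg = 1, bg = 0) > 0.5
  lab <- segment_nuclei(mask + 0, threshold = 0.5, min_area = 1)
  white <- matrix(1000, 32, 32)
  res0 <- dab_mean_od(white, lab, I0 = 1000)
  expect_equal(res0$mean_od, 0)
  res1 <- dab_mean_od(white / 10, lab, I0 = 1000)
  expect_equal(res1$mean_od, 1)
  # synthetic nuclei with assigned ODs recover within quantization error
  target_od <- c(0.3, 0.8)
  img <- matrix(1000, 32, 32)
  img[lab == 1] <- round(1000 * 10^(-target_od[1]))
  img[lab == 2] <- round(1000 * 10^(-target_od[2]))
  res2 <- dab_mean_od(img, lab, I0 = 1000)
  expect_equal(res2$nuclei$mean_od, target_od, tolerance = 0.02)
  expect_error(dab_mean_od(white, matrix(0L, 32, 32)), "no nuclei")
})
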