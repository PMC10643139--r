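test_that("region midpoint is the floor of the interval center", {
  expect_equal(region_midpoint(100, 200), 150)
  expect_equal(region_midpoint(0, 1), 0)
  expect_equal(region_midpoint(7, 10), 8)
  expect_error(region_midpoint(10, 10), "start < end")
})

test_that("signal matrix reproduces closed forms on constant and delta tracks", {
  const <- signal_track(rep(3, 100), bin = 10)
  peaks <- tibble::tibble(reference = "chrT", start = c(300, 500), end = c(340, 560))
  m <- signal_matrix(const, peaks, flank = 100, bin = 10)
  expect_equal(dim(m$values), c(2L, 20L))
  expect_true(all(m$values == 3))
  # single nonzero track bin exactly at a midpoint lights exactly one column
  vals <- rep(0, 100); vals[33] <- 7   # bases 320-329
  delta <- signal_track(vals, bin = 10)
  md <- signal_matrix(delta, peaks[1, ], flank = 100, bin = 10)  # midpoint 320
  nonzero <- which(md$values[1, ] != 0)
  expect_identical(nonzero, 11L)       # first bin right of the midpoint
  expect_equal(unname(md$values[1, 11]), 7)
})

test_that("signal matrix equals the per-position brute-force oracle", {
  tr <- make_test_track(n = 200, bin = 10, seed = 7)
  withr::with_seed(8, {
    start <- sort(sample(0:1900, 20))
    peaks <- tibble::tibble(reference = "chrT", start = start,
                            end = start + sample(20:80, 20, replace = TRUE))
  })
  m <- signal_matrix(tr, peaks, flank = 200, bin = 25)
  expect_equal(unname(m$values), oracle_signal_matrix(tr, peaks, 200, 25),
               tolerance = 1e-9)
  # permutation invariance of row contents
  perm <- sample(20)
  m2 <- signal_matrix(tr, peaks[perm, ], flank = 200, bin = 25)
  expect_equal(unname(m2$values), unname(m$values[perm, ]))
})

test_that("edge windows are zero padded and flagged", {
  tr <- signal_track(rep(2, 10), bin = 10)  # reference of 100 bases
  peaks <- tibble::tibble(reference = "chrT", start = 0, end = 10)  # midpoint 5
  m <- signal_matrix(tr, peaks, flank = 50, bin = 10)
  expect_true(m$edge_padded[1])
  # leftmost cell covers [-45, -35): fully outside, so 0
  expect_equal(unname(m$values[1, 1]), 0)
  # cell straddling position 0 ([-5, 5)) averages 0-padding with value 2
  expect_equal(unname(m$values[1, 5]), 1)
  expect_warning(
    signal_matrix(tr, tibble::tibble(reference = c("chrT", "chrX"),
                                     start = c(40, 1), end = c(60, 9)),
                  flank = 20, bin = 10),
    "dropped")
})

test_that("row ranking is stable and ascending by mean", {
  m <- structure(list(values = rbind(a = rep(5, 4), b = rep(1, 4), c = rep(3, 4)),
                      region_id = c("a", "b", "c"), midpoint = 1:3,
                      flank = 20, bin = 10, edge_padded = rep(FALSE, 3)),
                 class = "ssx_matrix")
  expect_identical(rank_rows(m), c(2L, 3L, 1L))
  m$values <- rbind(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4))
  expect_identical(rank_rows(m), 1:3)  # ties keep region-id order
  tr <- make_test_track(n = 100, bin = 10, seed = 13)
  withr::with_seed(14, {
    start <- sort(sample(0:900, 15)); peaks <- tibble::tibble(
      reference = "chrT", start = start, end = start + 40)
  })
  mm <- signal_matrix(tr, peaks, flank = 50, bin = 10)
  ord <- rank_rows(mm)
  expect_equal(ord, order(rowMeans(mm$values), mm$region_id))
})

test_that("region scores equal the per-base mean over the peak body", {
  const <- signal_track(rep(4.5, 50), bin = 10)
  peaks <- tibble::tibble(reference = "chrT", start = c(10, 200), end = c(60, 260))
  expect_equal(region_scores(const, peaks)$score, c(4.5, 4.5))
  # value v inside the peak, zero outside
  vals <- rep(0, 50); vals[2:6] <- 8   # bases 10-59
  inpk <- signal_track(vals, bin = 10)
  expect_equal(region_scores(inpk, peaks[1, ])$score, 8)
  tr <- make_test_track(n = 120, bin = 10, seed = 17)
  withr::with_seed(18, {
    start <- sort(sample(0:1000, 12)); pk <- tibble::tibble(
      reference = "chrT", start = start, end = start + sample(5:95, 12, replace = TRUE))
  })
  got <- region_scores(tr, pk)$score
  want <- vapply(seq_len(12), function(i) oracle_window_mean(tr, pk$start[i], pk$end[i]),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("log2 ratios follow the pseudocounted formula", {
  a <- tibble::tibble(region_id = c("r1", "r2"), score = c(4, 10))
  expect_equal(log2_ratio(a, a)$log2_ratio, c(0, 0))
  b <- tibble::tibble(region_id = c("r1", "r2"), score = c(2, 5))
  expect_equal(log2_ratio(a, b, pseudocount = 1e-9)$log2_ratio, c(1, 1),
               tolerance = 1e-6)
  withr::with_seed(19, {
    x <- tibble::tibble(region_id = paste0("r", 1:30), score = runif(30, 0, 50))
    y <- tibble::tibble(region_id = paste0("r", 1:30), score = runif(30, 0, 50))
  })
  expect_equal(log2_ratio(x, y, pseudocount = 0.5)$log2_ratio,
               log2((x$score + 0.5) / (y$score + 0.5)))
  expect_error(log2_ratio(a, b[1, ]), "different regions")
})

test_that("k-means clustering is exact on separable data and optimal at small n", {
  one <- kmeans_cluster(tibble::tibble(region_id = letters[1:5],
                                       log2_ratio = c(1, 2, 3, 4, 5)), k = 1)
  expect_equal(as.vector(one$centroids), 3)
  # two point masses
  two <- kmeans_cluster(tibble::tibble(
    region_id = paste0("r", 1:10),
    log2_ratio = rep(c(-3, 0), each = 5)), k = 2, seed = 2)
  expect_equal(sort(as.vector(two$centroids)), c(-3, 0))
  expect_equal(dplyr::n_distinct(two$assignments$cluster[1:5]), 1L)
  expect_equal(dplyr::n_distinct(two$assignments$cluster[6:10]), 1L)
  # n = 8: objective equals the exhaustive-partition minimum
  withr::with_seed(23, x <- round(rnorm(8), 2))
  fit <- kmeans_cluster(tibble::tibble(region_id = paste0("r", 1:8),
                                       log2_ratio = x),
                        k = 2, seed = 3, restarts = 20)
  expect_equal(fit$tot_withinss, oracle_best_partition_ss(x), tolerance = 1e-9)
  expect_error(kmeans_cluster(tibble::tibble(region_id = "a", log2_ratio = 1), k = 2),
               "exceeds")
  # determinism
  fit2 <- kmeans_cluster(tibble::tibble(region_id = paste0("r", 1:8),
                                        log2_ratio = x),
                         k = 2, seed = 3, restarts = 20)
  expect_identical(fit$assignments, fit2$assignments)
})

test_that("spearman matrix matches rank-then-pearson and flags constant tracks", {
  withr::with_seed(29, {
    a <- signal_track(runif(100, 0, 10), bin = 10)
    b <- signal_track(runif(100, 0, 10), bin = 10)
  })
  m <- spearman_matrix(list(a = a, b = b), summary_bin = 20)
  expect_equal(m["a", "a"], 1)
  expect_true(isSymmetric(m))
  ra <- rebin_track(a, 20)$values
  rb <- rebin_track(b, 20)$values
  expect_equal(m["a", "b"], cor(rank(ra), rank(rb)), tolerance = 1e-12)
  # strictly decreasing transform gives -1
  inv <- signal_track(max(a$values) + 1 - a$values, bin = 10)
  m2 <- spearman_matrix(list(a = a, inv = inv), summary_bin = 10)
  expect_equal(m2["a", "inv"], -1)
  flat <- signal_track(rep(2, 100), bin = 10)
  expect_warning(m3 <- spearman_matrix(list(a = a, flat = flat), summary_bin = 20),
                 "constant")
  expect_true(is.na(m3["a", "flat"]))
})

test_that("scaling a track scales matrices and scores but not orderings", {
  tr <- make_test_track(n = 150, bin = 10, seed = 37)
  withr::with_seed(38, {
    start <- sort(sample(0:1300, 10))
    peaks <- tibble::tibble(reference = "chrT", start = start, end = start + 50)
  })
  sc <- apply_factor(tr, 2.5)
  m1 <- signal_matrix(tr, peaks, flank = 100, bin = 20)
  m2 <- signal_matrix(sc, peaks, flank = 100, bin = 20)
  expect_equal(m2$values, m1$values * 2.5)
  expect_identical(rank_rows(m2), rank_rows(m1))
  s1 <- region_scores(tr, peaks); s2 <- region_scores(sc, peaks)
  expect_equal(s2$score, s1$score * 2.5)
})
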