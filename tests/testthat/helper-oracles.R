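# Independent brute-force oracles used across the suite. These deliberately
# take the naive route (per-base / per-pixel loops, exhaustive enumeration)
# so they share no code with the implementation they check.

# Per-base expansion of a fixed-bin track: value of each single base.
oracle_per_base <- function(track) {
  rep(track$values, each = track$bin)[seq_len(track$seqlength)]
}

# Mean per-base value over [start, end), zero outside the reference.
oracle_window_mean <- function(track, start, end) {
  pb <- oracle_per_base(track)
  pos <- seq(start, end - 1)
  vals <- numeric(length(pos))
  inb <- pos >= 0 & pos < track$seqlength
  vals[inb] <- pb[pos[inb] + 1]
  mean(vals)
}

# Full signal matrix by looping over rows and columns.
oracle_signal_matrix <- function(track, peaks, flank, bin) {
  mids <- floor((peaks$start + peaks$end) / 2)
  n_bins <- 2 * flank / bin
  out <- matrix(NA_real_, nrow(peaks), n_bins)
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(n_bins)) {
      s <- mids[i] - flank + (j - 1) * bin
      out[i, j] <- oracle_window_mean(track, s, s + bin)
    }
  }
  out
}

# Exhaustive k=2 partition minimum of within-cluster sum of squares.
oracle_best_partition_ss <- function(x) {
  n <- length(x)
  best <- Inf
  for (code in 0:(2^n - 1)) {
    grp <- as.logical(bitwAnd(rep(code, n), 2^(seq_len(n) - 1)))
    if (all(grp) || all(!grp)) next
    ss <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    if (ss < best) best <- ss
  }
  best
}

# Minimum-cross-entropy threshold by a slow loop over every candidate.
oracle_li_scan <- function(v) {
  cand <- sort(unique(v))
  cand <- cand[-length(cand)]
  crit <- vapply(cand, function(t) {
    bg <- v[v <= t]; fg <- v[v > t]
    tb <- if (sum(bg) > 0) sum(bg) * log(mean(bg)) else 0
    tf <- if (sum(fg) > 0) sum(fg) * log(mean(fg)) else 0
    -(tb + tf)
  }, numeric(1))
  cand[which.min(crit)]
}

# Connected-component labelling via igraph over the pixel adjacency graph.
oracle_label_areas <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(integer(0))
  pos <- match(idx, idx)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, 1, 0, 0, -1, -1, 1, 1), dc = c(0, 0, -1, 1, -1, 1, -1, 1))
  } else {
    cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  }
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    nb_r <- r + offs[k, 1]; nb_c <- cc + offs[k, 2]
    ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= nc
    nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
    hit <- !is.na(match(nb, idx))
    edges <- rbind(edges, cbind(pos[ok][hit], match(nb[hit], idx)))
  }
  if (is.null(edges)) return(rep(1L, length(idx)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  sort(as.integer(table(comp$membership)), decreasing = TRUE)
}

# Exact rational arithmetic for the alpha-normalized downsampling factors:
# factor_i = (I_i * S_ref * P_ref) / (S_i * P_i * I_ref) where ref maximizes
# the raw factor; with counts small enough the products are exact in doubles.
oracle_cchip_factors <- function(spike_ip, spike_input, primary_input) {
  raw_num <- as.numeric(spike_input)
  raw_den <- as.numeric(spike_ip) * as.numeric(primary_input)
  # compare raw_i = num_i/den_i by cross-multiplication (exact)
  ref <- 1
  for (i in seq_along(raw_num)) {
    if (raw_num[i] * raw_den[ref] > raw_num[ref] * raw_den[i]) ref <- i
  }
  (raw_num * raw_den[ref]) / (raw_den * raw_num[ref])
}

expect_track_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$values, b$values, tolerance = tol)
  expect_identical(a$bin, b$bin)
  expect_identical(a$seqlength, b$seqlength)
}

# Small deterministic track with irregular values.
make_test_track <- function(n = 40, bin = 10, seed = 99) {
  withr::with_seed(seed, signal_track(round(runif(n, 0, 20), 2), bin = bin))
}
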