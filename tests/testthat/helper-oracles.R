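# Independent oracles and shared fixtures for the test suite.

# Exhaustive maximum bipartite matching by recursion; the independent
# oracle for the greedy DSB pairing (feasible for clusters of <= 8 SSBs).
max_matching_oracle <- function(bp, strand, max_sep = 10) {
  a <- bp[strand == 0]
  b <- bp[strand == 1]
  if (!length(a) || !length(b)) return(0L)
  rec <- function(i, used) {
    if (i > length(a)) return(0L)
    best <- rec(i + 1, used)
    for (j in seq_along(b)) {
      if (!used[j] && abs(a[i] - b[j]) <= max_sep) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1, rep(FALSE, length(b)))
}

# Monte Carlo rejection estimate of the hollow-cylinder sector volume:
# sample uniformly in the bounding cylinder (radius r_max, height h) and
# count the fraction falling in the sector. Returns estimate and MC SE.
mc_sector_volume <- function(aperture_deg, r_max, r_min, height, n = 2e5) {
  r <- sqrt(stats::runif(n, 0, r_max^2))
  ang <- stats::runif(n, -180, 180)
  inside <- r >= r_min & ang >= -aperture_deg / 2 & ang < aperture_deg / 2
  v_box <- pi * r_max^2 * height
  p <- mean(inside)
  list(value = v_box * p, se = v_box * sqrt(p * (1 - p) / n))
}

# Random target addresses for a model, deliberately covering the index
# extremes (fragment/level ends, loop seam base pairs, both strands).
random_addresses <- function(model, n) {
  roi <- model$roi
  nbp <- model$params$bp_per_nucleosome
  edge_bp <- c(0, model$per_loop - 1, model$per_loop, nbp - 1)
  data.frame(
    fragment = sample(c(0, roi$n_fragments - 1, sample(0:(roi$n_fragments - 1), n - 2, TRUE))),
    level = sample(c(0, roi$levels_per_fragment - 1, sample(0:(roi$levels_per_fragment - 1), n - 2, TRUE))),
    nucleosome = sample(0:(roi$nucleosomes_per_level - 1), n, TRUE),
    bp = sample(c(edge_bp, sample(0:(nbp - 1), n - 4, TRUE))),
    strand = sample(0:1, n, TRUE)
  )
}

# interior-point fractions mixing bulk and near-boundary positions
boundary_fracs <- function(n, eps = 1e-7) {
  f <- stats::runif(n)
  k <- sample(n, max(2, n %/% 10))
  f[k] <- sample(c(eps, 1 - eps), length(k), TRUE)
  f
}

roundtrip_ok <- function(model, ad, r_frac, ang_frac, s_frac) {
  pt <- target_placement(model, ad$fragment, ad$level, ad$nucleosome,
                         ad$bp, ad$strand, r_frac, ang_frac, s_frac)
  loc <- locate_events(model, pt$x_nm, pt$y_nm, pt$z_nm)
  loc$hit & loc$fragment == ad$fragment & loc$level == ad$level &
    loc$nucleosome == ad$nucleosome & loc$bp == ad$bp &
    loc$strand == ad$strand
}
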