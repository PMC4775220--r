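test_that("LoG kernel matches the closed form of a Gaussian second derivative", {
  k <- log_kernel(1)
  w <- k$weights
  expect_equal(k$radius, 4)
  ## centering shifts every weight by the (tiny) truncation mean; the
  ## closed form g''(0) = -g(0)/sigma^2 holds up to that shift
  expect_equal(unname(w["0"]), -1 / sqrt(2 * pi), tolerance = 1e-3)
  expect_lt(abs(w["1"]), 1e-3)                 # zero of (x^2 - sigma^2)
  expect_equal(unname(w), unname(rev(w)))      # even function
  expect_lt(abs(sum(w)), 1e-15)                # exact zero sum

  k300 <- log_kernel(300)
  expect_equal(k300$radius, 1200)
  expect_lt(abs(sum(k300$weights)), 1e-18)
  expect_lt(abs(k300$weights["300"]), abs(k300$weights["0"]) * 1e-2)
})

test_that("convolution equals the brute-force double loop", {
  set.seed(10)
  for (sigma in c(4, 9)) {
    k <- log_kernel(sigma)
    for (rep in 1:5) {
      v <- rpois(300 + 8 * sigma, lambda = 5) + runif(300 + 8 * sigma)
      expect_lt(max(abs(convolve_coverage(v, k) - brute_convolve(v, k))),
                1e-9)
    }
  }
})

test_that("convolution identities: constant track, impulse, short track", {
  k <- log_kernel(5)
  ## zero-sum kernel: constant tracks respond zero away from the
  ## zero-padded edges
  resp_const <- convolve_coverage(rep(7.3, 200), k)
  interior <- (k$radius + 1):(200 - k$radius)
  expect_lt(max(abs(resp_const[interior])), 1e-9)

  imp <- numeric(200); imp[100] <- 1
  resp <- convolve_coverage(imp, k)
  expect_equal(resp[(100 - k$radius):(100 + k$radius)],
               unname(rev(k$weights)))

  expect_error(convolve_coverage(numeric(30), k), "must exceed")
})

test_that("an analytic Gaussian bump yields one peak at its center", {
  x <- 0:19999
  cov <- 50 * exp(-(x - 5000)^2 / (2 * 300^2))
  k <- log_kernel(300)
  resp <- convolve_coverage(cov, k)
  expect_equal(which.min(resp) - 1, 5000, tolerance = 1e-9)

  pk <- call_peaks(resp, cov, min_coverage = 5)
  expect_equal(nrow(pk), 1)
  expect_lte(abs(pk$summit - 5000), 10)

  cov2 <- 50 * exp(-(x - 4000)^2 / (2 * 300^2)) +
    50 * exp(-(x - 14000)^2 / (2 * 300^2))
  pk2 <- call_peaks(convolve_coverage(cov2, k), cov2, min_coverage = 5)
  expect_equal(nrow(pk2), 2)
  expect_lte(abs(pk2$summit[1] - 4000), 10)
  expect_lte(abs(pk2$summit[2] - 14000), 10)
})

test_that("flat coverage produces no peaks", {
  k <- log_kernel(50)
  flat <- rep(20, 5000)
  expect_equal(nrow(call_peaks(convolve_coverage(flat, k), flat)), 0)
})

test_that("peak calls are invariant to constant background shifts", {
  gm <- make_genome_model(8, 150000, seed = 14)
  st <- plant_sites(gm, 4, seed = 14)
  fr <- simulate_fragments(gm, st, seed = 14)
  cov <- pool_coverage(lapply(fr[1:2], build_coverage,
                              model = gm))[["chr1"]]$values
  k <- log_kernel(300)
  base <- call_peaks(convolve_coverage(cov, k), cov,
                     edge_exclude = k$radius)
  expect_gt(nrow(base), 0)
  for (const in c(1, 13, 250)) {
    shifted <- call_peaks(convolve_coverage(cov + const, k), cov + const,
                          min_coverage = 5, edge_exclude = k$radius)
    expect_equal(shifted[, c("start", "end", "summit", "score")],
                 base[, c("start", "end", "summit", "score")])
  }
})

test_that("scaling coverage scales responses and preserves adaptive calls", {
  gm <- make_genome_model(8, 150000, seed = 15)
  st <- plant_sites(gm, 4, seed = 15)
  fr <- simulate_fragments(gm, st, seed = 15)
  cov <- pool_coverage(lapply(fr[1:2], build_coverage,
                              model = gm))[["chr1"]]$values
  k <- log_kernel(300)
  r1 <- convolve_coverage(cov, k)
  c_scale <- 3.7
  r2 <- convolve_coverage(cov * c_scale, k)
  expect_equal(r2, r1 * c_scale, tolerance = 1e-12)
  p1 <- call_peaks(r1, cov, min_coverage = 0)
  p2 <- call_peaks(r2, cov * c_scale, min_coverage = 0)
  expect_equal(p2[, c("start", "end", "summit")],
               p1[, c("start", "end", "summit")])
  expect_equal(p2$score, p1$score * c_scale, tolerance = 1e-12)
})

test_that("merge_gap joins close runs and min_width drops slivers", {
  ## hand-built response: two dips 30 nt apart, plus one isolated
  ## narrow dip
  resp <- numeric(2000)
  resp[301:400] <- -1
  resp[431:530] <- -1
  resp[1001:1020] <- -1
  cov <- rep(10, 2000); cov[1] <- 12   # non-degenerate track
  pk <- call_peaks(resp, cov, min_score = 0.5, min_coverage = 0,
                   min_width = 50, merge_gap = 50)
  expect_equal(nrow(pk), 1)                 # dips merged, sliver dropped
  expect_equal(pk$start, 300)
  expect_equal(pk$end, 530)
  ## with merging off, the two wide dips stay separate
  pk2 <- call_peaks(resp, cov, min_score = 0.5, min_coverage = 0,
                    min_width = 50, merge_gap = 1)
  expect_equal(nrow(pk2), 2)
  ## summit ties break leftmost
  expect_equal(pk2$summit[1], 300)
})

test_that("planted sites are recovered with high recall and precision", {
  recalls <- precisions <- numeric(2)
  for (i in 1:2) {
    gm <- make_genome_model(40, 600000, seed = i)
    st <- plant_sites(gm, 20, seed = i)
    fr <- simulate_fragments(gm, st, seed = i)
    tracks <- pool_coverage(lapply(fr[1:2], build_coverage, model = gm))
    pk <- detect_peaks(tracks, bandwidth = 300)
    ev <- match_peaks_to_sites(pk, st, min_reciprocal = 0.5)
    recalls[i] <- ev$recall
    precisions[i] <- ev$precision
  }
  expect_true(all(recalls >= 0.9))
  expect_true(all(precisions >= 0.9))
})
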