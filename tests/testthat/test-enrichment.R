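make_peaks <- function(start, end, chrom = "chr1") {
  pk <- data.frame(chrom = chrom, start = start, end = end,
                   summit = floor((start + end) / 2),
                   peak_id = sprintf("p%02d", seq_along(start)))
  class(pk) <- c("rip_peaks", "data.frame")
  pk
}

make_fs <- function(frags, sample_id = "s1", condition = "RIP") {
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = 1L, fragments = frags,
                 library_size = nrow(frags)),
            class = "fragment_set")
}

test_that("midpoint counting assigns each fragment to at most one peak", {
  fr <- data.frame(chrom = "chr1", start = 100, end = 300)  # midpoint 200
  inside <- make_peaks(150, 250)
  outside <- make_peaks(250, 400)
  expect_equal(as.integer(count_in_peaks(inside, list(make_fs(fr)))$counts),
               1L)
  expect_equal(as.integer(count_in_peaks(outside, list(make_fs(fr)))$counts),
               0L)

  ## conservation: 10 fragments inside one peak, 2 samples
  fr10 <- data.frame(chrom = "chr1", start = rep(100, 10), end = rep(300, 10))
  pcm <- count_in_peaks(make_peaks(150, 250),
                        list(make_fs(fr10, "a", "RIP"),
                             make_fs(fr10, "b", "control")))
  expect_equal(unname(colSums(pcm$counts)), c(10, 10))

  expect_error(count_in_peaks(make_peaks(c(100, 150), c(200, 260)),
                              list(make_fs(fr))),
               "overlap")

  ## any-overlap mode can double-count across adjacent peaks
  pk2 <- make_peaks(c(100, 200), c(200, 400))
  pcm2 <- count_in_peaks(pk2, list(make_fs(fr)), mode = "overlap")
  expect_equal(as.integer(pcm2$counts), c(1L, 1L))
})

test_that("column sums never exceed library sizes and tile counts conserve", {
  gm <- make_genome_model(10, 200000, seed = 20)
  fr <- simulate_fragments(gm, plant_sites(gm, 0), seed = 20)
  tiles <- make_peaks(seq(0, 199000, by = 1000), seq(1000, 200000, by = 1000))
  pcm <- count_in_peaks(tiles, fr)
  libs <- vapply(fr, `[[`, 0, "library_size")
  expect_true(all(colSums(pcm$counts) <= libs))
  ## the tiles cover every midpoint, so equality holds
  expect_equal(unname(colSums(pcm$counts)), unname(libs))
})

test_that("size factors reproduce the median-of-ratios definition", {
  expect_equal(size_factors(matrix(c(5, 5, 5, 5, 5, 5), ncol = 2)), c(1, 1))

  m <- matrix(c(2, 6, 10, 4, 12, 20), ncol = 2)
  expect_equal(round(size_factors(m), 4), c(0.7071, 1.4142))

  ## doubling one column doubles its factor relative to every other
  ## sample (the estimator is anchored to row geometric means, so the
  ## absolute factors all shift by the compensating 2^(1/m))
  set.seed(4)
  r <- matrix(rpois(300, 60) + 1, ncol = 3)
  s0 <- size_factors(r)
  r2 <- r; r2[, 2] <- r2[, 2] * 2
  s1 <- size_factors(r2)
  expect_equal(s1[2] / s1[1], 2 * s0[2] / s0[1])
  expect_equal(s1[2] / s1[3], 2 * s0[2] / s0[3])
  expect_equal(s1[1] / s1[3], s0[1] / s0[3])
  expect_equal(s1[2], s0[2] * 2^(2 / 3))

  expect_error(size_factors(matrix(c(0, 1, 1, 0), ncol = 2)),
               "no peak has positive counts")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  m <- matrix(rnbinom(400, mu = 80, size = 5) + 1, ncol = 4)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("dispersion estimation has the stated limits", {
  cond <- c("RIP", "RIP", "control", "control")
  ## constant counts: zero raw dispersion
  cst <- matrix(50, nrow = 5, ncol = 4)
  d <- estimate_dispersion(cst, rep(1, 4), cond)
  expect_equal(d$alpha_raw, rep(0, 5))

  ## Poisson counts at high mean: median dispersion -> 0
  set.seed(8)
  pois <- matrix(rpois(4 * 2000, 300), ncol = 4)
  dp <- estimate_dispersion(pois, size_factors(pois), cond)
  expect_lt(median(dp$alpha), 0.02)

  ## NB alpha = 0.2 at high mean: median recovered within [0.1, 0.3]
  nb <- matrix(rnbinom(4 * 2000, mu = 300, size = 5), ncol = 4)
  dn <- estimate_dispersion(nb, size_factors(nb), cond)
  expect_gt(median(dn$alpha), 0.1)
  expect_lt(median(dn$alpha), 0.3)

  expect_error(estimate_dispersion(cst[, 1:3], rep(1, 3),
                                   c("RIP", "RIP", "control")),
               "at least 2 replicates")
})

test_that("the exact test matches its conditional distribution", {
  ## balanced counts, equal size factors: the observed split is modal
  expect_equal(nb_exact_test(c(5, 5), c(5, 5), c(1, 1), c(1, 1), 0.1), 1)

  ## Poisson limit, 1 vs 1, observed (0, 10): conditional Binomial(10, 1/2)
  expect_equal(nb_exact_test(0, 10, 1, 1, 0), 2 / 1024)

  ## condition swap symmetry
  set.seed(9)
  for (i in 1:20) {
    ka <- rpois(2, 40); kb <- rpois(2, 60)
    sa <- runif(2, 0.5, 2); sb <- runif(2, 0.5, 2)
    al <- runif(1, 0, 0.4)
    expect_equal(nb_exact_test(ka, kb, sa, sb, al),
                 nb_exact_test(kb, ka, sb, sa, al))
  }

  ## zero total
  expect_equal(nb_exact_test(c(0, 0), c(0, 0), c(1, 1), c(1, 1), 0.1), 1)

  ## p-values live in (0, 1]
  p <- replicate(50, {
    ka <- rpois(2, 20); kb <- rpois(2, 20)
    nb_exact_test(ka, kb, c(1, 1.2), c(0.9, 1), 0.2)
  })
  expect_true(all(p > 0 & p <= 1))
})

test_that("enumeration p-values equal an independent brute-force oracle", {
  configs <- list(
    list(sa = 1, sb = 1, alpha = 0),
    list(sa = c(1, 1), sb = c(1, 1), alpha = 0.15),
    list(sa = c(0.8, 1.1), sb = c(1.3, 0.9), alpha = 0.3))
  for (cfg in configs) {
    for (K in c(1, 2, 5, 10, 25)) {
      for (a in 0:K) {
        ka <- c(a, rep(0, length(cfg$sa) - 1))
        kb <- c(K - a, rep(0, length(cfg$sb) - 1))
        expect_equal(nb_exact_test(ka, kb, cfg$sa, cfg$sb, cfg$alpha),
                     brute_nb_exact_p(ka, kb, cfg$sa, cfg$sb, cfg$alpha),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("BH adjustment reproduces the step-up worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.03), 0.03)
})

test_that("significance gating is strict and direction-aware", {
  res <- data.frame(
    peak_id = c("a", "b", "c", "d"),
    fdr = c(0.01, 0.049, 0.05, 0.2),
    direction = c("control_up", "RIP_up", "RIP_up", "RIP_up"))
  kept <- significant_peaks(res, 0.05)
  expect_equal(kept$peak_id, "b")
  expect_equal(nrow(significant_peaks(res[0, ], 0.05)), 0)
})

test_that("rip_enrichment flags planted enrichment and not background", {
  gm <- make_genome_model(12, 220000, seed = 23)
  st <- plant_sites(gm, 4, enrichment = 8, seed = 23)
  fr <- simulate_fragments(gm, st, seed = 23)
  tracks <- pool_coverage(lapply(fr[1:2], build_coverage, model = gm))
  pk <- detect_peaks(tracks)
  pcm <- count_in_peaks(pk, fr)
  res <- rip_enrichment(pcm, sf = background_size_factors(pk, fr, gm))
  expect_s3_class(res, "rip_enrichment")
  ev <- match_peaks_to_sites(pk, st)
  expect_true(all(res$significant[ev$peak_matched]))
  expect_true(all(res$direction[ev$peak_matched] == "RIP_up"))
})
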