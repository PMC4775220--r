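# Independent oracles and tiny fixtures shared across the suite.

# Three-exon transcript used for region classification checks:
# exons [0,100), [200,300), [400,500); CDS genomic span [50,450).
tiny_transcript <- function(cds = c(50, 450)) {
  list(transcript_id = "tx_tiny",
       exons = data.frame(start = c(0, 200, 400), end = c(100, 300, 500)),
       cds = cds)
}

# Minimal genome model wrapper for coverage tests (no genes needed).
bare_model <- function(chrom_length, chrom = "chr1") {
  structure(list(chromosomes = stats::setNames(chrom_length, chrom),
                 genes = list()),
            class = "genome_model")
}

# Brute-force convolution oracle: literal double loop over
# response[p] = sum_x w[x] * values[p + x], zero-padded.
brute_convolve <- function(values, kernel) {
  n <- length(values)
  r <- kernel$radius
  w <- unname(kernel$weights)
  out <- numeric(n)
  for (p in seq_len(n)) {
    acc <- 0
    for (j in seq_along(w)) {
      x <- j - r - 1L
      q <- p + x
      if (q >= 1L && q <= n) acc <- acc + w[j] * values[q]
    }
    out[p] <- acc
  }
  out
}

# Independent NB conditional exact test: hand-coded log-pmf via lgamma
# (no dnbinom/dpois), explicit normalisation and tail summation.
brute_nb_exact_p <- function(k_a, k_b, sf_a, sf_b, alpha) {
  K <- sum(k_a) + sum(k_b)
  if (K == 0) return(1)
  S_a <- sum(sf_a); S_b <- sum(sf_b)
  mu <- K / (S_a + S_b)
  lpmf <- function(x, m, size) {
    if (is.infinite(size))  # Poisson limit
      return(x * log(m) - m - lgamma(x + 1))
    lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
      size * log(size / (size + m)) + x * log(m / (size + m))
  }
  size_a <- if (alpha > 0) S_a^2 / (alpha * sum(sf_a^2)) else Inf
  size_b <- if (alpha > 0) S_b^2 / (alpha * sum(sf_b^2)) else Inf
  a <- 0:K
  lp <- lpmf(a, mu * S_a, size_a) + lpmf(K - a, mu * S_b, size_b)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[sum(k_a) + 1L]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Numerical-integration oracle for the splicing Bayes factor.
numeric_bayes_factor <- function(i1, e1, i2, e2) {
  marg <- function(i, e)
    stats::integrate(function(p) p^i * (1 - p)^e, 0, 1,
                     rel.tol = 1e-12, abs.tol = 0)$value
  marg(i1, e1) * marg(i2, e2) / marg(i1 + i2, e1 + e2)
}

# Region segments of a transcript recomputed independently of
# transcript_regions(), by scanning positions with classify_position.
scan_classes <- function(tx, strand) {
  span <- c(tx$exons$start[1], tx$exons$end[nrow(tx$exons)])
  vapply(seq(span[1], span[2] - 1), classify_position, character(1),
         tx = tx, strand = strand)
}
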