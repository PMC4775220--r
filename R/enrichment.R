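#' Count fragments per peak per sample
#'
#' A fragment is assigned to the peak containing its midpoint
#' (`floor((start + end) / 2)`), so each fragment is counted at most
#' once; `mode = "overlap"` instead counts any overlap (a fragment can
#' then hit two adjacent peaks). Peaks must be disjoint.
#'
#' @param peaks `rip_peaks` with a `peak_id` column.
#' @param fragment_sets list of `fragment_set`s.
#' @param mode `"midpoint"` (default) or `"overlap"`.
#' @return object of class `peak_count_matrix`: list with `counts`
#'   (integer matrix, peaks x samples), `peaks`, `samples` (data frame
#'   `sample_id`, `condition`, `library_size`).
#' @export
count_in_peaks <- function(peaks, fragment_sets,
                           mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  if (nrow(peaks) > 0) {
    gr <- granges_from_intervals(peaks$chrom, peaks$start, peaks$end)
    if (length(GenomicRanges::findOverlaps(gr, drop.self = TRUE)) > 0)
      stop("peaks overlap; count_in_peaks requires disjoint peaks",
           call. = FALSE)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  counts <- vapply(fragment_sets, function(fs) {
    fr <- fs$fragments
    if (nrow(peaks) == 0) return(integer(0))
    if (nrow(fr) == 0) return(integer(nrow(peaks)))
    qgr <- if (mode == "midpoint") {
      mid <- floor((fr$start + fr$end) / 2)
      granges_from_intervals(fr$chrom, mid, mid + 1)
    } else {
      granges_from_intervals(fr$chrom, fr$start, fr$end)
    }
    GenomicRanges::countOverlaps(gr, qgr)
  }, integer(nrow(peaks)))
  counts <- matrix(as.integer(counts), nrow = nrow(peaks),
                   dimnames = list(peaks$peak_id,
                                   vapply(fragment_sets, `[[`, "",
                                          "sample_id")))
  samples <- data.frame(
    sample_id = vapply(fragment_sets, `[[`, "", "sample_id"),
    condition = vapply(fragment_sets, `[[`, "", "condition"),
    library_size = vapply(fragment_sets, function(f)
      as.numeric(f$library_size), numeric(1)))
  structure(list(counts = counts, peaks = peaks, samples = samples),
            class = "peak_count_matrix")
}

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over peaks of
#' `counts[i, j] / geometric_mean_i`, taken over peaks whose counts are
#' positive in every sample (positive geometric mean). Corrects for
#' library-size differences before the count test.
#'
#' @param counts integer matrix, peaks x samples.
#' @return numeric vector of size factors, one per sample.
#' @examples
#' size_factors(matrix(c(2, 6, 10, 4, 12, 20), ncol = 2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)
  if (!any(usable))
    stop("no peak has positive counts in every sample; cannot estimate size factors",
         call. = FALSE)
  apply(counts, 2, function(col)
    exp(stats::median(log(col[usable]) - log_geo[usable])))
}

#' Size factors from background windows
#'
#' Binding-site count matrices are a poor basis for library-size
#' normalisation when most detected peaks are genuinely enriched: the
#' median ratio then absorbs the enrichment itself. This helper applies
#' the same median-of-ratios estimator to counts in background windows
#' — tiles over the gene spans that do not touch any detected peak —
#' where the two conditions are expected to agree.
#'
#' @param peaks `rip_peaks` to exclude.
#' @param fragment_sets list of `fragment_set`s.
#' @param model a `genome_model` (tiling is over its gene spans).
#' @param window background window width in nt.
#' @return numeric size factors, one per sample (named).
#' @export
background_size_factors <- function(peaks, fragment_sets, model,
                                    window = 1000) {
  spans <- gene_spans(model)
  tiles <- do.call(rbind, lapply(seq_len(nrow(spans)), function(i) {
    cuts <- seq(spans$start[i], spans$end[i], by = window)
    if (length(cuts) < 2) return(NULL)
    data.frame(chrom = spans$chrom[i], start = cuts[-length(cuts)],
               end = cuts[-1])
  }))
  if (nrow(peaks) > 0) {
    tg <- granges_from_intervals(tiles$chrom, tiles$start, tiles$end)
    pg <- granges_from_intervals(peaks$chrom, peaks$start, peaks$end)
    tiles <- tiles[!IRanges::overlapsAny(tg, pg), , drop = FALSE]
  }
  counts <- vapply(fragment_sets, function(fs) {
    fr <- fs$fragments
    if (nrow(fr) == 0) return(integer(nrow(tiles)))
    mid <- floor((fr$start + fr$end) / 2)
    GenomicRanges::countOverlaps(
      granges_from_intervals(tiles$chrom, tiles$start, tiles$end),
      granges_from_intervals(fr$chrom, mid, mid + 1))
  }, integer(nrow(tiles)))
  sf <- size_factors(counts)
  stats::setNames(sf, vapply(fragment_sets, `[[`, "", "sample_id"))
}

#' Per-peak negative-binomial dispersion
#'
#' Method-of-moments dispersion from size-factor-normalised counts:
#' within each condition the sample variance is computed, the variances
#' are pooled, and `alpha_i = max(0, (v - m) / m^2)` with `m` the
#' overall normalised mean. A hyperbolic mean-dispersion trend
#' `alpha(m) = a0 + a1 / m` is fitted by least squares across peaks with
#' positive raw dispersion, and each peak gets the conservative maximum
#' of its own estimate and the trend value — with only two replicates
#' per condition the per-peak moment estimate alone is far too noisy.
#'
#' @param counts integer matrix, peaks x samples.
#' @param sf size factors (from [size_factors()]).
#' @param conditions character vector, one condition label per sample.
#' @return list with `alpha` (final per-peak dispersion), `alpha_raw`,
#'   `mu` (normalised mean), `trend` (coefficients a0, a1).
#' @export
estimate_dispersion <- function(counts, sf, conditions) {
  counts <- as.matrix(counts)
  tab <- table(conditions)
  if (any(tab < 2))
    stop("each condition needs at least 2 replicates to estimate dispersion",
         call. = FALSE)
  q <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(q)
  cond_levels <- unique(conditions)
  vars <- sapply(cond_levels, function(cc)
    apply(q[, conditions == cc, drop = FALSE], 1, stats::var))
  v <- rowMeans(vars)
  alpha_raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)

  fit_ok <- alpha_raw > 0 & mu > 0
  trend <- c(a0 = 0, a1 = 0)
  if (sum(fit_ok) >= 2) {
    fit <- stats::lm(a ~ im, data = data.frame(a = alpha_raw[fit_ok],
                                               im = 1 / mu[fit_ok]))
    trend <- c(a0 = unname(stats::coef(fit)[1]),
               a1 = unname(stats::coef(fit)[2]))
  }
  alpha_trend <- pmax(0, trend["a0"] + trend["a1"] / pmax(mu, 1e-8))
  alpha <- pmax(alpha_raw, alpha_trend)
  list(alpha = unname(alpha), alpha_raw = unname(alpha_raw), mu = unname(mu),
       trend = trend)
}

#' Negative-binomial conditional exact test
#'
#' Tests whether a peak's total count splits between the two conditions
#' as expected under a common concentration. Conditional on the total
#' `K`, each split `(a, K - a)` gets probability proportional to the
#' product of the two conditions' negative-binomial likelihoods, with
#' per-condition means implied by the size factors and variances from
#' the dispersion `alpha` (the sum of NB replicates is
#' moment-matched to a single NB). The two-sided p-value sums the
#' probabilities of all splits no more likely than the observed one.
#' With `alpha = 0` the NB reduces to Poisson and the conditional
#' distribution is binomial.
#'
#' @param k_a,k_b observed counts per replicate in conditions A and B.
#' @param sf_a,sf_b matching size factors.
#' @param alpha NB dispersion shared by both conditions.
#' @return two-sided p-value in (0, 1]; `K = 0` returns 1 by
#'   convention.
#' @export
nb_exact_test <- function(k_a, k_b, sf_a, sf_b, alpha = 0) {
  K <- sum(k_a) + sum(k_b)
  if (K == 0) return(1)
  probs <- nb_split_probs(K, sf_a, sf_b, alpha)
  obs <- probs[sum(k_a) + 1L]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

## Normalised probabilities of all splits (a, K - a), a = 0..K.
nb_split_probs <- function(K, sf_a, sf_b, alpha) {
  S_a <- sum(sf_a); S_b <- sum(sf_b)
  mu_hat <- K / (S_a + S_b)
  a <- 0:K
  if (alpha > 0) {
    ## moment-matched NB for the sum of replicate counts: the mean is
    ## mu_hat * S and the excess variance alpha * mu_hat^2 * sum(s^2),
    ## so the effective size parameter is S^2 / (alpha * sum(s^2))
    size_a <- S_a^2 / (alpha * sum(sf_a^2))
    size_b <- S_b^2 / (alpha * sum(sf_b^2))
    lp <- stats::dnbinom(a, size = size_a, mu = mu_hat * S_a, log = TRUE) +
      stats::dnbinom(K - a, size = size_b, mu = mu_hat * S_b, log = TRUE)
  } else {
    lp <- stats::dpois(a, mu_hat * S_a, log = TRUE) +
      stats::dpois(K - a, mu_hat * S_b, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (capped at 1, monotone in the ranked
#' p-values); thin wrapper over [stats::p.adjust()].
#'
#' @param p p-values in (0, 1].
#' @return adjusted values (FDR).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Differential enrichment of RIP over control
#'
#' Runs the full count test for every peak: size factors, dispersion
#' estimation, the NB conditional exact test, BH adjustment, and the
#' significance gate `fdr < threshold` with RIP-direction enrichment.
#'
#' @param pcm a `peak_count_matrix` from [count_in_peaks()].
#' @param fdr_threshold significance gate (strict `<`).
#' @param sf size factors; default is median-of-ratios on the peak
#'   matrix itself, appropriate when most peaks are not differential.
#'   When most peaks are expected to be true binding sites, pass
#'   [background_size_factors()] instead (the pipeline does).
#' @return data frame of class `rip_enrichment`, one row per peak:
#'   `peak_id`, `base_mean_rip`, `base_mean_control`, `log2_fold_change`
#'   (RIP over control, 0.5 pseudocount), `alpha`, `p_value`, `fdr`,
#'   `direction` (`"RIP_up"`/`"control_up"`), `significant`. Size
#'   factors are attached as `attr(, "size_factors")`.
#' @export
rip_enrichment <- function(pcm, fdr_threshold = 0.05, sf = NULL) {
  stopifnot(inherits(pcm, "peak_count_matrix"))
  counts <- pcm$counts
  conditions <- pcm$samples$condition
  if (!setequal(unique(conditions), c("RIP", "control")))
    stop("conditions must be exactly 'RIP' and 'control'", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, conditions)
  is_rip <- conditions == "RIP"
  q <- sweep(counts, 2, sf, "/")
  bm_rip <- rowMeans(q[, is_rip, drop = FALSE])
  bm_ctl <- rowMeans(q[, !is_rip, drop = FALSE])

  p <- vapply(seq_len(nrow(counts)), function(i)
    nb_exact_test(counts[i, is_rip], counts[i, !is_rip],
                  sf[is_rip], sf[!is_rip], disp$alpha[i]),
    numeric(1))
  fdr <- bh_adjust(p)
  direction <- ifelse(bm_rip > bm_ctl, "RIP_up", "control_up")
  out <- data.frame(
    peak_id = rownames(counts),
    base_mean_rip = bm_rip,
    base_mean_control = bm_ctl,
    log2_fold_change = log2((bm_rip + 0.5) / (bm_ctl + 0.5)),
    alpha = disp$alpha,
    p_value = p,
    fdr = fdr,
    direction = direction,
    significant = fdr < fdr_threshold & direction == "RIP_up",
    row.names = NULL)
  attr(out, "size_factors") <- sf
  attr(out, "fdr_threshold") <- fdr_threshold
  class(out) <- c("rip_enrichment", "data.frame")
  out
}

#' Filter to significant peaks
#'
#' Keeps exactly the peaks with `fdr < fdr_threshold` and RIP-direction
#' enrichment (more reads in the RIP samples).
#'
#' @param results an `rip_enrichment` data frame.
#' @param fdr_threshold significance gate (strict `<`).
#' @return the filtered rows.
#' @export
significant_peaks <- function(results, fdr_threshold = 0.05) {
  out <- results[results$fdr < fdr_threshold &
                   results$direction == "RIP_up", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.rip_enrichment <- function(x, ...) {
  cat(sprintf("rip_enrichment: %d peaks, %d significant (FDR < %g, RIP up)\n",
              nrow(x), sum(x$significant), attr(x, "fdr_threshold")))
  cat("size factors:",
      paste(sprintf("%s=%.3f", names(attr(x, "size_factors")),
                    attr(x, "size_factors")), collapse = ", "), "\n")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' @export
summary.rip_enrichment <- function(object, ...) {
  cat(sprintf("peaks tested:       %d\n", nrow(object)))
  cat(sprintf("significant (RIP):  %d\n", sum(object$significant)))
  cat(sprintf("median dispersion:  %.4f\n", stats::median(object$alpha)))
  cat(sprintf("median |log2 FC|:   %.3f\n",
              stats::median(abs(object$log2_fold_change))))
  invisible(object)
}
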