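#' Beta posterior for percent spliced in (PSI)
#'
#' Junction-level estimate of the inclusion fraction. Raw inclusion and
#' exclusion read counts are first divided by the number of junctions
#' supporting each isoform (a skipped exon has two inclusion junctions
#' but one exclusion junction), so isoform length does not bias the
#' estimate. With a Beta prior the normalised counts give a conjugate
#' Beta posterior.
#'
#' @param inclusion,exclusion raw junction read counts (>= 0).
#' @param n_inc_junc,n_exc_junc junctions supporting each isoform.
#' @param prior Beta prior parameters (default uniform).
#' @return object of class `psi_posterior`: list with `alpha`, `beta`,
#'   `mean` (the PSI point estimate), `ci` (95% equal-tailed credible
#'   interval).
#' @examples
#' psi_posterior(8, 4, n_inc_junc = 2, n_exc_junc = 1)
#' @export
psi_posterior <- function(inclusion, exclusion, n_inc_junc = 2,
                          n_exc_junc = 1, prior = c(1, 1)) {
  if (inclusion < 0 || exclusion < 0)
    stop("junction counts must be nonnegative", call. = FALSE)
  a <- prior[1] + inclusion / n_inc_junc
  b <- prior[2] + exclusion / n_exc_junc
  structure(list(alpha = a, beta = b, mean = a / (a + b),
                 ci = stats::qbeta(c(0.025, 0.975), a, b)),
            class = "psi_posterior")
}

#' @export
print.psi_posterior <- function(x, ...) {
  cat(sprintf("PSI = %.3f  [%.3f, %.3f]  (Beta(%.2f, %.2f))\n",
              x$mean, x$ci[1], x$ci[2], x$alpha, x$beta))
  invisible(x)
}

#' Bayes factor for a PSI difference between two conditions
#'
#' Compares two binomial models for the (junction-normalised,
#' half-up-rounded) inclusion/exclusion counts of the two conditions:
#' under M0 both conditions share one inclusion fraction with a
#' Uniform(0,1) prior; under M1 each condition has its own independent
#' Uniform(0,1) fraction. Both marginal likelihoods have closed forms
#' in Beta functions, and `BF = m1 / m0`. Values above 1 favour a PSI
#' difference; the conventional reporting threshold is BF > 2.
#'
#' @param i1,e1 condition-1 effective inclusion/exclusion counts.
#' @param i2,e2 condition-2 effective counts.
#' @return the Bayes factor (positive scalar).
#' @examples
#' bayes_factor(1, 0, 0, 1)  # 1.5
#' bayes_factor(1, 0, 1, 0)  # 0.75
#' @export
bayes_factor <- function(i1, e1, i2, e2) {
  if (any(c(i1, e1, i2, e2) < 0))
    stop("counts must be nonnegative", call. = FALSE)
  i1 <- round_half_up(i1); e1 <- round_half_up(e1)
  i2 <- round_half_up(i2); e2 <- round_half_up(e2)
  log_m0 <- lbeta(i1 + i2 + 1, e1 + e2 + 1)
  log_m1 <- lbeta(i1 + 1, e1 + 1) + lbeta(i2 + 1, e2 + 1)
  exp(log_m1 - log_m0)
}

#' Score a table of splice events
#'
#' Computes per-condition PSI posteriors and the Bayes factor for SE
#' (skipped exon) and RI (retained intron) events; other event types
#' (MXE, A5SS, A3SS, AFE, ALE, T3UTR) are passed through with their
#' counts and `NA` scores, flagged in `scored`.
#'
#' @param events data frame with columns `event_id`, `type`, `i1`, `e1`,
#'   `i2`, `e2` (inclusion/exclusion junction reads per condition).
#' @param bf_threshold Bayes-factor threshold for the `changed` flag.
#' @return the input with `psi1`, `psi2`, `bayes_factor`, `scored`,
#'   `changed` columns appended.
#' @export
score_splice_events <- function(events, bf_threshold = 2) {
  known <- c("SE", "RI", "MXE", "A5SS", "A3SS", "AFE", "ALE", "T3UTR")
  if (!all(events$type %in% known))
    stop("unknown splice event type(s): ",
         paste(setdiff(events$type, known), collapse = ", "), call. = FALSE)
  ## junction multiplicities for the modelled types: SE inclusion spans
  ## two junctions vs one exclusion junction; RI retention reads out
  ## over the two intron boundaries vs one spliced exon-exon junction
  juncs <- list(SE = c(2, 1), RI = c(2, 1))
  n <- nrow(events)
  psi1 <- psi2 <- bf <- rep(NA_real_, n)
  scored <- events$type %in% names(juncs)
  for (i in which(scored)) {
    j <- juncs[[events$type[i]]]
    p1 <- psi_posterior(events$i1[i], events$e1[i], j[1], j[2])
    p2 <- psi_posterior(events$i2[i], events$e2[i], j[1], j[2])
    psi1[i] <- p1$mean; psi2[i] <- p2$mean
    bf[i] <- bayes_factor(events$i1[i] / j[1], events$e1[i] / j[2],
                          events$i2[i] / j[1], events$e2[i] / j[2])
  }
  events$psi1 <- psi1
  events$psi2 <- psi2
  events$bayes_factor <- bf
  events$scored <- scored
  events$changed <- !is.na(bf) & bf > bf_threshold
  events
}

#' Read and write splice-event tables
#'
#' TSV with columns `event_id`, `type`, `i1`, `e1`, `i2`, `e2` and,
#' after scoring, `psi1`, `psi2`, `bayes_factor`, `scored`, `changed`.
#'
#' @param path TSV path.
#' @param events splice-event data frame.
#' @return `read_splice_events` returns the data frame.
#' @export
read_splice_events <- function(path) {
  utils::read.delim(path, colClasses = c(event_id = "character",
                                         type = "character"))
}

#' @rdname read_splice_events
#' @export
write_splice_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Relative expression by the delta-delta-Ct method
#'
#' qPCR relative quantification of a target in sample 1 versus sample 2
#' against a reference gene:
#' `2^-((Ct_target_s1 - Ct_ref_s1) - (Ct_target_s2 - Ct_ref_s2))`.
#'
#' @param ct_target_s1,ct_ref_s1 target and reference Ct in sample 1.
#' @param ct_target_s2,ct_ref_s2 target and reference Ct in sample 2.
#' @return relative expression of sample 1 versus sample 2.
#' @examples
#' delta_delta_ct(20, 18, 22, 18)  # 4
#' @export
delta_delta_ct <- function(ct_target_s1, ct_ref_s1, ct_target_s2,
                           ct_ref_s2) {
  cts <- c(ct_target_s1, ct_ref_s1, ct_target_s2, ct_ref_s2)
  if (any(!is.finite(cts)))
    stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_s1 - ct_ref_s1) - (ct_target_s2 - ct_ref_s2)
  2^(-ddct)
}

#' Isoform ratio with replicate spread
#'
#' Per-replicate ratio of two isoforms' relative expressions, reported
#' as mean and sample standard deviation over at least three
#' independent replicates.
#'
#' @param rel_a,rel_b relative expressions of isoforms a and b, one
#'   value per replicate.
#' @return list with `ratios`, `mean`, `sd`, `n`.
#' @export
isoform_ratio <- function(rel_a, rel_b) {
  if (length(rel_a) != length(rel_b))
    stop("isoform replicate vectors must have equal length", call. = FALSE)
  if (length(rel_a) < 3)
    stop("isoform ratios require at least 3 replicates", call. = FALSE)
  if (any(rel_b == 0))
    stop("denominator isoform has zero relative expression", call. = FALSE)
  r <- rel_a / rel_b
  list(ratios = r, mean = mean(r), sd = stats::sd(r), n = length(r))
}
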