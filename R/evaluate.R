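#' Match called peaks to planted truth by reciprocal overlap
#'
#' A peak recovers a planted site when their overlap covers at least
#' `min_reciprocal` of BOTH intervals. Recall is the fraction of sites
#' recovered; precision the fraction of peaks matching a site.
#'
#' @param peaks `rip_peaks` (or any data frame with `chrom`, `start`,
#'   `end`).
#' @param sites `planted_sites` truth.
#' @param min_reciprocal minimum reciprocal overlap fraction.
#' @return list with `recall`, `precision`, `site_recovered` (logical
#'   per site), `peak_matched` (logical per peak), and `pairs`
#'   (data frame of matched peak/site indices).
#' @export
match_peaks_to_sites <- function(peaks, sites, min_reciprocal = 0.5) {
  if (nrow(sites) == 0 || nrow(peaks) == 0) {
    return(list(recall = if (nrow(sites) == 0) NA_real_ else 0,
                precision = if (nrow(peaks) == 0) NA_real_ else 0,
                site_recovered = logical(nrow(sites)),
                peak_matched = logical(nrow(peaks)),
                pairs = data.frame(peak = integer(0), site = integer(0))))
  }
  pg <- granges_from_intervals(peaks$chrom, peaks$start, peaks$end)
  sg <- granges_from_intervals(sites$chrom, sites$start, sites$end)
  hits <- GenomicRanges::findOverlaps(pg, sg)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(pg)[qh], IRanges::ranges(sg)[sh]))
  keep <- ov >= min_reciprocal * (peaks$end - peaks$start)[qh] &
    ov >= min_reciprocal * (sites$end - sites$start)[sh]
  pairs <- data.frame(peak = qh[keep], site = sh[keep])
  list(recall = length(unique(pairs$site)) / nrow(sites),
       precision = length(unique(pairs$peak)) / nrow(peaks),
       site_recovered = seq_len(nrow(sites)) %in% pairs$site,
       peak_matched = seq_len(nrow(peaks)) %in% pairs$peak,
       pairs = pairs)
}
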