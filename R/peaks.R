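#' Laplacian-of-Gaussian kernel
#'
#' Second derivative of a Gaussian density with standard deviation
#' `sigma` (the bandwidth), evaluated at integer offsets on
#' `[-radius, radius]` with `radius = radius_multiplier * sigma`, then
#' mean-centered so the weights sum to zero exactly. The zero sum makes
#' the filter blind to constant background; a bump of width about
#' `2 * sigma` produces a strongly negative response at its center.
#'
#' @param sigma bandwidth in nt (> 0); 300 for RIP-seq-scale peaks.
#' @param radius_multiplier truncation half-width in units of sigma.
#' @return object of class `log_kernel`: list with `sigma`, `radius`,
#'   `weights` (names give the offsets `-radius:radius`).
#' @examples
#' k <- log_kernel(300)
#' sum(k$weights)   # 0 by construction
#' @export
log_kernel <- function(sigma, radius_multiplier = 4) {
  stop_if_not_scalar_number(sigma, "sigma")
  if (sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  radius <- as.integer(ceiling(radius_multiplier * sigma))
  x <- seq.int(-radius, radius)
  w <- stats::dnorm(x, 0, sigma) * (x^2 - sigma^2) / sigma^4
  w <- w - mean(w)
  structure(list(sigma = sigma, radius = radius,
                 weights = stats::setNames(w, x)),
            class = "log_kernel")
}

#' Convolve a coverage track with a kernel
#'
#' Computes `response[p] = sum_x w[x] * values[p + x]`, with positions
#' beyond the track treated as zero coverage. Direct summation (no FFT),
#' so the result matches a brute-force double loop to rounding error.
#'
#' @param track a `coverage_track` (or bare numeric vector).
#' @param kernel a `log_kernel`.
#' @return numeric response vector, same length as the track.
#' @export
convolve_coverage <- function(track, kernel) {
  values <- if (inherits(track, "coverage_track")) track$values else track
  r <- kernel$radius
  if (length(values) <= 2L * r)
    stop(sprintf("track length %d must exceed kernel support %d",
                 length(values), 2L * r), call. = FALSE)
  padded <- c(numeric(r), values, numeric(r))
  ## stats::filter computes sum_j f[j] * x[i - (j - (k+1)/2)], i.e. a
  ## correlation with the reversed filter: pass the reversed weights to
  ## realise sum_x w[x] * values[p + x].
  resp <- stats::filter(padded, rev(unname(kernel$weights)), sides = 2)
  as.numeric(resp[(r + 1):(r + length(values))])
}

#' Call peaks from a LoG response
#'
#' A candidate peak is a maximal run of negative response (its
#' boundaries are the flanking zero crossings). Runs separated by less
#' than `merge_gap` nt are merged. A candidate is kept when it contains
#' a position with score `-response >= min_score`, its mean coverage is
#' at least `min_coverage`, and it is at least `min_width` nt wide. The
#' summit is the position of the most negative response (leftmost on
#' ties) and the peak score is `-response` there.
#'
#' `min_score = NULL` sets the threshold adaptively to
#' `mad_k * mad(response)` over the positions with nonzero response,
#' which tracks the noise level of the data-bearing part of the track
#' instead of requiring a depth-specific constant: stretches with no
#' fragments within the kernel radius respond exactly zero and carry no
#' noise information, so they are excluded from the scale estimate.
#' Response magnitudes below `1e-9` of the maximum are treated as zero
#' (numerical zero of the zero-sum kernel), so a constant track yields
#' no peaks and adding a constant to the coverage changes no call.
#'
#' @param response numeric response vector (from [convolve_coverage()]).
#' @param coverage matching `coverage_track` or numeric vector.
#' @param chrom chromosome name stamped on the peaks.
#' @param min_score minimum summit score, or `NULL` for adaptive.
#' @param mad_k multiplier for the adaptive threshold.
#' @param min_coverage minimum mean raw depth over the peak.
#' @param min_width minimum peak width in nt.
#' @param merge_gap merge negative runs closer than this many nt.
#' @param edge_exclude drop candidate runs touching the first or last
#'   `edge_exclude` positions of the track, where the response reflects
#'   the zero padding rather than data; [detect_peaks()] sets this to
#'   the kernel radius.
#' @return data frame of class `rip_peaks`: `chrom`, `start`, `end`
#'   (0-based half-open), `summit`, `score`, `mean_coverage`, sorted by
#'   `(chrom, start)`.
#' @export
call_peaks <- function(response, coverage, chrom = "chr1",
                       min_score = NULL, mad_k = 4, min_coverage = 5,
                       min_width = 50, merge_gap = 50, edge_exclude = 0) {
  values <- if (inherits(coverage, "coverage_track")) coverage$values
            else coverage
  stopifnot(length(response) == length(values))
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), summit = numeric(0),
                      score = numeric(0), mean_coverage = numeric(0))
  class(empty) <- c("rip_peaks", "data.frame")

  ## a structureless track only produces zero-sum rounding residue
  if (diff(range(values)) == 0) return(empty)
  tol <- 1e-9 * max(abs(response))
  response[abs(response) <= tol] <- 0
  if (is.null(min_score)) {
    noise <- response[response != 0]
    if (length(noise) == 0) return(empty)
    min_score <- mad_k * stats::mad(noise)
  }

  neg <- response < 0
  if (!any(neg)) return(empty)

  r <- rle(neg)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths        # 0-based starts
  starts <- run_start[r$values]
  ends <- run_end[r$values]

  ## merge runs whose gap is below merge_gap
  if (length(starts) > 1) {
    keep_s <- starts[1]; ms <- numeric(0); me <- numeric(0)
    cur_s <- starts[1]; cur_e <- ends[1]
    for (i in seq_along(starts)[-1]) {
      if (starts[i] - cur_e < merge_gap) {
        cur_e <- ends[i]
      } else {
        ms <- c(ms, cur_s); me <- c(me, cur_e)
        cur_s <- starts[i]; cur_e <- ends[i]
      }
    }
    ms <- c(ms, cur_s); me <- c(me, cur_e)
    starts <- ms; ends <- me
  }

  if (edge_exclude > 0) {
    keep <- starts >= edge_exclude &
      ends <= length(response) - edge_exclude
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0) return(empty)
  }

  rows <- lapply(seq_along(starts), function(i) {
    idx <- (starts[i] + 1):ends[i]            # 1-based positions in run
    score_max <- -min(response[idx])
    if (score_max < min_score) return(NULL)
    if (ends[i] - starts[i] < min_width) return(NULL)
    mc <- mean(values[idx])
    if (mc < min_coverage) return(NULL)
    summit <- idx[which.min(response[idx])] - 1  # 0-based, leftmost tie
    data.frame(chrom = chrom, start = starts[i], end = ends[i],
               summit = summit, score = score_max, mean_coverage = mc)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  class(out) <- c("rip_peaks", "data.frame")
  out
}

#' Detect peaks on a set of coverage tracks
#'
#' Convenience wrapper: builds the LoG kernel once and runs
#' [convolve_coverage()] + [call_peaks()] per chromosome, concatenating
#' the results with stable peak ids.
#'
#' @param tracks named list of `coverage_track`s (one per chromosome).
#' @param bandwidth LoG sigma in nt.
#' @param ... passed to [call_peaks()].
#' @return `rip_peaks` data frame with a `peak_id` column.
#' @export
detect_peaks <- function(tracks, bandwidth = 300, ...) {
  kernel <- log_kernel(bandwidth)
  pieces <- lapply(names(tracks), function(ch) {
    resp <- convolve_coverage(tracks[[ch]], kernel)
    call_peaks(resp, tracks[[ch]], chrom = ch,
               edge_exclude = kernel$radius, ...)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 0)
    out$peak_id <- sprintf("peak_%05d", seq_len(nrow(out)))
  else out$peak_id <- character(0)
  class(out) <- c("rip_peaks", "data.frame")
  out
}

#' Write peaks as BED6 and TSV
#'
#' BED scores are the summit scores rescaled to 0-1000 (max score maps
#' to 1000); the TSV keeps the full fields.
#'
#' @param peaks an `rip_peaks` data frame with `peak_id`.
#' @param bed_path,tsv_path output paths (either may be `NULL`).
#' @export
write_peaks <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    if (nrow(peaks) == 0) {
      file.create(bed_path)
    } else {
      s <- peaks$score
      bed_score <- as.integer(round(1000 * s / max(s)))
      gr <- granges_from_intervals(peaks$chrom, peaks$start, peaks$end,
                                   name = peaks$peak_id, score = bed_score)
      rtracklayer::export(gr, bed_path, format = "bed")
    }
  }
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(peaks), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
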