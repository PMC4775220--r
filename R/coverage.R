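#' Build per-base coverage tracks from a fragment set
#'
#' Depth at position p counts the fragments whose half-open interval
#' `[start, end)` contains p. One dense track per chromosome.
#'
#' @param fs a `fragment_set`, or a plain data frame with `chrom`,
#'   `start`, `end`.
#' @param model a `genome_model` supplying chromosome lengths.
#' @param library_size library size recorded on the tracks; defaults to
#'   the number of fragments.
#' @return named list (by chromosome) of `coverage_track` objects with
#'   fields `chrom`, `values` (numeric vector, one entry per base),
#'   `scale` (`"raw"`) and `library_size`.
#' @examples
#' gm <- make_genome_model(1, 20000, seed = 1)
#' fs <- simulate_fragments(gm, plant_sites(gm, 0), seed = 1)[[1]]
#' cov <- build_coverage(fs, gm)
#' cov[[1]]
#' @export
build_coverage <- function(fs, model, library_size = NULL) {
  fr <- if (inherits(fs, "fragment_set")) fs$fragments else fs
  if (is.null(library_size))
    library_size <- if (inherits(fs, "fragment_set")) fs$library_size
                    else nrow(fr)
  tracks <- list()
  for (ch in names(model$chromosomes)) {
    clen <- as.integer(model$chromosomes[[ch]])
    f <- fr[fr$chrom == ch, , drop = FALSE]
    bad <- which(f$start < 0 | f$end > clen | f$end <= f$start)
    if (length(bad) > 0)
      stop(sprintf("fragment [%d, %d) out of bounds on %s (length %d)",
                   as.integer(f$start[bad[1]]), as.integer(f$end[bad[1]]),
                   ch, clen), call. = FALSE)
    ## difference-array trick: +1 at starts, -1 at ends, cumsum
    d <- numeric(clen + 1L)
    if (nrow(f) > 0) {
      add <- tabulate(f$start + 1L, nbins = clen + 1L)
      sub <- tabulate(f$end + 1L, nbins = clen + 1L)
      d <- add - sub
    }
    values <- cumsum(d)[seq_len(clen)]
    tracks[[ch]] <- structure(
      list(chrom = ch, values = values, scale = "raw",
           library_size = library_size),
      class = "coverage_track")
  }
  unknown <- setdiff(unique(fr$chrom), names(model$chromosomes))
  if (length(unknown) > 0)
    stop(sprintf("fragments on unknown chromosome(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  tracks
}

#' Pool coverage tracks
#'
#' Sums raw tracks base-wise (e.g. RIP replicates before peak
#' detection); library sizes add.
#'
#' @param track_lists list of per-chromosome track lists, all raw scale.
#' @return a pooled per-chromosome track list.
#' @export
pool_coverage <- function(track_lists) {
  stopifnot(length(track_lists) >= 1)
  out <- track_lists[[1]]
  if (length(track_lists) == 1) return(out)
  for (tl in track_lists[-1]) {
    for (ch in names(out)) {
      stopifnot(identical(out[[ch]]$scale, tl[[ch]]$scale))
      out[[ch]]$values <- out[[ch]]$values + tl[[ch]]$values
      out[[ch]]$library_size <- out[[ch]]$library_size + tl[[ch]]$library_size
    }
  }
  out
}

#' Reads-per-million normalisation
#'
#' Scales a raw track to RPM: `values * 1e6 / library_size`.
#'
#' @param track a raw-scale `coverage_track`.
#' @return the RPM-scaled track.
#' @export
rpm_normalize <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (!identical(track$scale, "raw"))
    stop("track is already RPM-scaled", call. = FALSE)
  if (is.null(track$library_size) || track$library_size == 0)
    stop("cannot RPM-normalize a track with library_size 0", call. = FALSE)
  track$values <- track$values * 1e6 / track$library_size
  track$scale <- "RPM"
  track
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track %s: %d nt, scale=%s, library_size=%s, mean depth %.3g\n",
    x$chrom, length(x$values), x$scale, format(x$library_size),
    mean(x$values)))
  invisible(x)
}
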