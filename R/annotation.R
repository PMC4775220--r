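#' Region class of a genomic position within a transcript
#'
#' Strand-aware classification: exonic sequence upstream of the CDS (in
#' transcript orientation) is 5'UTR, within the CDS genomic span it is
#' CDS, downstream is 3'UTR, and non-exonic positions inside the
#' transcript span are intron. On the minus strand the 5'UTR therefore
#' sits at higher genomic coordinates. Exonic positions of transcripts
#' without a CDS are `exon_noncoding`.
#'
#' @param position 0-based genomic position; must lie within the
#'   transcript span.
#' @param tx transcript record (`exons`, optional `cds`).
#' @param strand `"+"` or `"-"`.
#' @return one of `"utr5"`, `"cds"`, `"utr3"`, `"intron"`,
#'   `"exon_noncoding"`.
#' @export
classify_position <- function(position, tx, strand) {
  ex <- tx$exons
  span_lo <- ex$start[1]; span_hi <- ex$end[nrow(ex)]
  if (position < span_lo || position >= span_hi)
    stop(sprintf("position %d outside transcript span [%d, %d)",
                 as.integer(position), as.integer(span_lo),
                 as.integer(span_hi)), call. = FALSE)
  exonic <- any(position >= ex$start & position < ex$end)
  if (!exonic) return("intron")
  if (is.null(tx$cds)) return("exon_noncoding")
  cs <- tx$cds[1]; ce <- tx$cds[2]
  if (position >= cs && position < ce) return("cds")
  low <- position < cs
  if (strand == "+") {
    if (low) "utr5" else "utr3"
  } else {
    if (low) "utr3" else "utr5"
  }
}

#' Annotate peaks with gene and region class
#'
#' Each peak is classified by its summit position. Among the
#' transcripts whose span covers the summit, the winner is chosen by
#' region-class precedence (default 3'UTR > 5'UTR > CDS > intron, with
#' noncoding exons last), then by longest transcript span, then by
#' lexicographic transcript id; a summit covered by no transcript is
#' `intergenic`.
#'
#' @param peaks `rip_peaks` with `summit` and `peak_id` columns.
#' @param model a `genome_model`.
#' @param precedence class precedence, highest first.
#' @return data frame of class `annotated_peaks`: the peak columns plus
#'   `gene_id`, `transcript_id`, `region_class`.
#' @export
annotate_peaks <- function(peaks, model,
                           precedence = c("utr3", "utr5", "cds", "intron",
                                          "exon_noncoding")) {
  tx_tab <- transcript_table(model)
  n <- nrow(peaks)
  gene_id <- rep("intergenic", n)
  transcript_id <- rep(NA_character_, n)
  region_class <- rep("intergenic", n)

  if (n > 0 && nrow(tx_tab) > 0) {
    summit_gr <- granges_from_intervals(peaks$chrom, peaks$summit,
                                        peaks$summit + 1)
    tx_gr <- granges_from_intervals(tx_tab$chrom, tx_tab$start, tx_tab$end)
    hits <- GenomicRanges::findOverlaps(summit_gr, tx_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      cand <- sh[qh == i]
      cls <- vapply(cand, function(j)
        classify_position(peaks$summit[i],
                          tx_tab$tx[[j]], tx_tab$strand[j]),
        character(1))
      rank <- match(cls, precedence)
      rank[is.na(rank)] <- length(precedence) + 1L
      span <- tx_tab$end[cand] - tx_tab$start[cand]
      ord <- order(rank, -span, tx_tab$transcript_id[cand])
      best <- cand[ord[1]]
      gene_id[i] <- tx_tab$gene_id[best]
      transcript_id[i] <- tx_tab$transcript_id[best]
      region_class[i] <- cls[ord[1]]
    }
  }
  out <- as.data.frame(peaks)
  out$gene_id <- gene_id
  out$transcript_id <- transcript_id
  out$region_class <- region_class
  class(out) <- c("annotated_peaks", "data.frame")
  out
}

transcript_table <- function(model) {
  rows <- list()
  for (g in model$genes) {
    for (tx in g$transcripts) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = min(tx$exons$start), end = max(tx$exons$end),
        strand = g$strand, gene_id = g$gene_id,
        transcript_id = tx$transcript_id)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  ## keep the transcript records themselves for position classification
  out$tx <- unlist(lapply(model$genes, function(g) g$transcripts),
                   recursive = FALSE)
  out
}

#' Region-class distribution of annotated peaks
#'
#' Fractions over the four coding-transcript classes (5'UTR, CDS,
#' intron, 3'UTR); intergenic and noncoding-exon peaks are excluded
#' from the denominator and reported separately via the counts
#' attribute.
#'
#' @param annotated an `annotated_peaks` data frame.
#' @return named numeric vector of fractions summing to 1 over the
#'   classes present; `attr(, "counts")` holds raw counts of all
#'   classes including `intergenic`/`exon_noncoding`.
#' @export
region_distribution <- function(annotated) {
  if (nrow(annotated) == 0)
    stop("cannot compute a region distribution from zero peaks",
         call. = FALSE)
  counts <- table(annotated$region_class)
  four <- c("utr5", "cds", "intron", "utr3")
  in_four <- annotated$region_class %in% four
  if (!any(in_four))
    stop("no peaks in the four coding region classes", call. = FALSE)
  frac_tab <- table(factor(annotated$region_class[in_four], levels = four))
  fractions <- as.numeric(frac_tab) / sum(frac_tab)
  names(fractions) <- four
  attr(fractions, "counts") <- counts
  fractions
}

#' Distinct genes bound by peaks
#'
#' @param annotated an `annotated_peaks` data frame.
#' @return sorted, deduplicated character vector of gene ids, excluding
#'   `intergenic`.
#' @export
gene_list <- function(annotated) {
  sort(unique(annotated$gene_id[annotated$gene_id != "intergenic"]))
}

#' Write annotated peaks as TSV and BED
#'
#' The BED name field carries `peak_id|gene_id|region_class`.
#'
#' @param annotated an `annotated_peaks` data frame.
#' @param tsv_path,bed_path output paths (either may be `NULL`).
#' @export
write_annotated_peaks <- function(annotated, tsv_path = NULL,
                                  bed_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(as.data.frame(annotated), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    if (nrow(annotated) == 0) {
      file.create(bed_path)
    } else {
      gr <- granges_from_intervals(
        annotated$chrom, annotated$start, annotated$end,
        name = paste(annotated$peak_id, annotated$gene_id,
                     annotated$region_class, sep = "|"),
        score = 0L)
      rtracklayer::export(gr, bed_path, format = "bed")
    }
  }
  invisible(NULL)
}
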