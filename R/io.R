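## All ripcall coordinates are 0-based, half-open (BED convention).
## GRanges are 1-based, closed; conversion happens only here.

granges_from_intervals <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(chrom,
                         IRanges::IRanges(start = start + 1, end = end), ...)
}

intervals_from_granges <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr))
}

#' Write and read genome models as GTF
#'
#' The gene model is serialised as GTF `exon` and `CDS` features with
#' `gene_id`/`transcript_id` attributes, alongside a two-column
#' chromosome-sizes file (chromosome name, length) since GTF carries no
#' sequence lengths.
#'
#' @param model a `genome_model`.
#' @param gtf_path output GTF path.
#' @param chrom_sizes_path output chromosome-sizes path.
#' @return `write_genome_model` returns the paths invisibly;
#'   `read_genome_model` returns a `genome_model`.
#' @export
write_genome_model <- function(model, gtf_path, chrom_sizes_path) {
  rows <- list()
  for (g in model$genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = ex$start, end = ex$end, strand = g$strand,
        type = "exon", gene_id = g$gene_id, transcript_id = tx$transcript_id)
      if (!is.null(tx$cds)) {
        cs <- pmax(ex$start, tx$cds[1]); ce <- pmin(ex$end, tx$cds[2])
        keep <- ce > cs
        if (any(keep))
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = g$chrom, start = cs[keep], end = ce[keep],
            strand = g$strand, type = "CDS", gene_id = g$gene_id,
            transcript_id = tx$transcript_id)
      }
    }
  }
  tab <- do.call(rbind, rows)
  gr <- granges_from_intervals(tab$chrom, tab$start, tab$end,
                               strand = tab$strand, type = tab$type,
                               gene_id = tab$gene_id,
                               transcript_id = tab$transcript_id)
  suppressWarnings(rtracklayer::export(gr, gtf_path, format = "gtf"))
  utils::write.table(
    data.frame(chrom = names(model$chromosomes),
               length = as.integer(model$chromosomes)),
    chrom_sizes_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(c(gtf = gtf_path, chrom_sizes = chrom_sizes_path))
}

#' @rdname write_genome_model
#' @export
read_genome_model <- function(gtf_path, chrom_sizes_path) {
  sizes <- utils::read.table(chrom_sizes_path, sep = "\t",
                             col.names = c("chrom", "length"))
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  tab <- intervals_from_granges(gr)
  tab$strand <- as.character(GenomicRanges::strand(gr))
  tab$type <- as.character(gr$type)
  tab$gene_id <- gr$gene_id
  tab$transcript_id <- gr$transcript_id
  tab <- tab[tab$type %in% c("exon", "CDS"), , drop = FALSE]

  genes <- list()
  for (gid in unique(tab$gene_id)) {
    gt <- tab[tab$gene_id == gid, , drop = FALSE]
    txs <- list()
    for (tid in unique(gt$transcript_id)) {
      tt <- gt[gt$transcript_id == tid, , drop = FALSE]
      ex <- tt[tt$type == "exon", c("start", "end")]
      ex <- ex[order(ex$start), , drop = FALSE]
      rownames(ex) <- NULL
      cds_rows <- tt[tt$type == "CDS", , drop = FALSE]
      cds <- if (nrow(cds_rows) > 0)
        c(min(cds_rows$start), max(cds_rows$end)) else NULL
      txs[[length(txs) + 1L]] <- list(transcript_id = tid, exons = ex,
                                      cds = cds)
    }
    genes[[length(genes) + 1L]] <- list(
      gene_id = gid, chrom = gt$chrom[1], strand = gt$strand[1],
      transcripts = txs)
  }
  model <- structure(
    list(chromosomes = stats::setNames(as.numeric(sizes$length),
                                       sizes$chrom),
         genes = genes),
    class = "genome_model")
  validate_genome_model(model)
  model
}

#' Write and read fragment sets as BED6
#'
#' One BED file per sample; the name field numbers the fragments and the
#' score field is 0.
#'
#' @param fs a `fragment_set`.
#' @param path BED path.
#' @param sample_id,condition,replicate sample metadata to attach when
#'   reading (BED does not carry them).
#' @return `read_fragments_bed` returns a `fragment_set`.
#' @export
write_fragments_bed <- function(fs, path) {
  fr <- fs$fragments
  if (nrow(fr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- granges_from_intervals(fr$chrom, fr$start, fr$end,
                               name = sprintf("%s_frag_%d", fs$sample_id,
                                              seq_len(nrow(fr))),
                               score = 0L)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_fragments_bed
#' @export
read_fragments_bed <- function(path, sample_id, condition, replicate = 1L) {
  if (file.size(path) == 0) {
    fr <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0))
  } else {
    fr <- intervals_from_granges(rtracklayer::import(path, format = "bed"))
  }
  structure(list(sample_id = sample_id, condition = condition,
                 replicate = as.integer(replicate), fragments = fr,
                 library_size = nrow(fr)),
            class = "fragment_set")
}

#' Write and read planted sites as BED
#'
#' The enrichment factor goes in the BED score column and the region
#' class in the name field.
#'
#' @param sites a `planted_sites` data frame.
#' @param path BED path.
#' @return `read_sites_bed` returns a `planted_sites` data frame
#'   (without `gene_id`, which BED does not carry).
#' @export
write_sites_bed <- function(sites, path) {
  if (nrow(sites) == 0) {
    file.create(path)
    return(invisible(path))
  }
  gr <- granges_from_intervals(sites$chrom, sites$start, sites$end,
                               name = sprintf("site_%d_%s",
                                              seq_len(nrow(sites)),
                                              sites$class),
                               score = sites$enrichment)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_sites_bed
#' @export
read_sites_bed <- function(path) {
  if (file.size(path) == 0) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), class = character(0),
                      enrichment = numeric(0))
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    out <- intervals_from_granges(gr)
    out$class <- sub("^site_[0-9]+_", "", gr$name)
    out$enrichment <- gr$score
  }
  class(out) <- c("planted_sites", "data.frame")
  out
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal depth become 4-column bedGraph records (0-based,
#' half-open); zero runs are omitted.
#'
#' @param tracks a `coverage_track`, or a list of them (one record block
#'   per chromosome).
#' @param path output path.
#' @export
write_bedgraph <- function(tracks, path) {
  if (inherits(tracks, "coverage_track")) tracks <- list(tracks)
  pieces <- lapply(tracks, function(track) {
    r <- rle(track$values)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    data.frame(chrom = track$chrom, start = starts[keep],
               end = ends[keep], score = r$values[keep])
  })
  df <- do.call(rbind, pieces)
  gr <- granges_from_intervals(df$chrom, df$start, df$end, score = df$score)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
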