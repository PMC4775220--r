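#' Construct a toy genome model
#'
#' Generates a single-chromosome genome populated with `n_genes` disjoint
#' protein-coding genes. Every gene carries one transcript with 2-4 exons
#' (so introns always exist), a coding region, and nonempty UTRs; the
#' 3'UTR is drawn large enough to host binding sites of a few hundred
#' nucleotides, mimicking the long 3'UTRs where RNA-binding proteins are
#' typically found. All coordinates are 0-based, half-open.
#'
#' @param n_genes number of genes to place (>= 1).
#' @param chrom_length chromosome length in nucleotides.
#' @param seed integer seed; identical arguments and seed give an
#'   identical model.
#' @param chrom chromosome name.
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (named vector of lengths) and `genes` (list of gene records, each
#'   with `gene_id`, `chrom`, `strand` and a list of `transcripts`).
#' @examples
#' gm <- make_genome_model(n_genes = 3, chrom_length = 60000, seed = 1)
#' gm
#' @export
make_genome_model <- function(n_genes, chrom_length, seed, chrom = "chr1") {
  stop_if_not_scalar_number(n_genes, "n_genes")
  stop_if_not_scalar_number(chrom_length, "chrom_length")
  if (n_genes < 1) stop("'n_genes' must be >= 1", call. = FALSE)

  with_seed(substream_seed(seed, "genome"), {
    structures <- lapply(seq_len(n_genes), function(i) random_gene_structure())
    lens <- vapply(structures, function(s) s$length, numeric(1))

    edge_margin <- 500
    min_gap <- 200
    slack <- chrom_length - sum(lens) - 2 * edge_margin -
      (n_genes - 1) * min_gap
    if (slack < 0)
      stop(sprintf(
        "cannot place %d disjoint genes (total span %d nt) on a %d nt chromosome",
        n_genes, as.integer(sum(lens)), as.integer(chrom_length)),
        call. = FALSE)

    ## distribute the leftover space as random inter-gene gaps
    extra <- as.vector(stats::rmultinom(1, size = as.integer(slack),
                                        prob = rep(1, n_genes)))
    starts <- edge_margin + cumsum(extra) +
      c(0, cumsum(lens[-n_genes] + min_gap))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    genes <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      genes[[i]] <- build_gene(
        gene_id = sprintf("gene_%03d", i), chrom = chrom,
        strand = strands[i], origin = starts[i], structure = structures[[i]])
    }
    model <- structure(
      list(chromosomes = stats::setNames(as.numeric(chrom_length), chrom),
           genes = genes),
      class = "genome_model")
    validate_genome_model(model)
    model
  })
}

## Draw exon/intron/UTR lengths in transcript (5'->3') order. UTRs,
## introns and internal (fully coding) exons are all drawn >= 600 nt so
## every region class offers segments that can host a binding site of a
## few hundred nucleotides, while the largest possible gene (~8.9 kb)
## still fits a 10 kb chromosome.
random_gene_structure <- function() {
  n_exons <- sample(2:4, 1)
  utr5 <- sample(600:900, 1)
  cds_first <- sample(200:400, 1)
  cds_last <- sample(200:400, 1)
  utr3 <- sample(800:1200, 1)
  internal <- if (n_exons > 2) sample(700:900, n_exons - 2, replace = TRUE)
              else integer(0)
  exon_lens <- c(utr5 + cds_first, internal, cds_last + utr3)
  intron_lens <- sample(800:1400, n_exons - 1, replace = TRUE)
  list(n_exons = n_exons, exon_lens = exon_lens, intron_lens = intron_lens,
       utr5 = utr5, utr3 = utr3,
       length = sum(exon_lens) + sum(intron_lens))
}

build_gene <- function(gene_id, chrom, strand, origin, structure) {
  ## lay exons in transcript order, then flip to genomic order on '-'
  n <- structure$n_exons
  exon_lens <- structure$exon_lens
  intron_lens <- structure$intron_lens
  if (strand == "-") {
    exon_lens <- rev(exon_lens)
    intron_lens <- rev(intron_lens)
  }
  starts <- origin + c(0, cumsum(exon_lens[-n] + intron_lens))
  ends <- starts + exon_lens
  span <- c(origin, ends[n])
  if (strand == "+") {
    cds <- c(span[1] + structure$utr5, span[2] - structure$utr3)
  } else {
    cds <- c(span[1] + structure$utr3, span[2] - structure$utr5)
  }
  tx <- list(transcript_id = paste0(gene_id, ".1"),
             exons = data.frame(start = starts, end = ends),
             cds = cds)
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       transcripts = list(tx))
}

#' Validate a genome model
#'
#' Checks the structural invariants: transcripts lie within chromosome
#' bounds, exons are disjoint and sorted, the CDS (when present) is
#' contained in the exonic span, and transcripts of a gene share its
#' chromosome and strand. Called by the constructors; useful after
#' reading a model from disk.
#'
#' @param model a `genome_model`.
#' @return the model, invisibly; errors on violation.
#' @export
validate_genome_model <- function(model) {
  stopifnot(inherits(model, "genome_model"))
  for (g in model$genes) {
    if (length(g$transcripts) < 1)
      stop(sprintf("gene %s has no transcripts", g$gene_id), call. = FALSE)
    if (!g$chrom %in% names(model$chromosomes))
      stop(sprintf("gene %s on unknown chromosome %s", g$gene_id, g$chrom),
           call. = FALSE)
    clen <- model$chromosomes[[g$chrom]]
    for (tx in g$transcripts) {
      ex <- tx$exons
      if (any(ex$end <= ex$start))
        stop(sprintf("transcript %s has an empty exon", tx$transcript_id),
             call. = FALSE)
      if (is.unsorted(ex$start, strictly = TRUE) ||
          any(ex$start[-1] < ex$end[-nrow(ex)]))
        stop(sprintf("transcript %s exons not disjoint/sorted",
                     tx$transcript_id), call. = FALSE)
      if (ex$start[1] < 0 || ex$end[nrow(ex)] > clen)
        stop(sprintf("transcript %s outside chromosome bounds",
                     tx$transcript_id), call. = FALSE)
      if (!is.null(tx$cds)) {
        if (tx$cds[1] < ex$start[1] || tx$cds[2] > ex$end[nrow(ex)] ||
            tx$cds[1] >= tx$cds[2])
          stop(sprintf("transcript %s CDS outside exonic span",
                       tx$transcript_id), call. = FALSE)
      }
    }
  }
  invisible(model)
}

#' Region classes of a transcript
#'
#' Partitions the genomic span of a transcript into labelled segments:
#' `utr5`, `cds`, `utr3` (strand-aware; on the minus strand the 5'UTR sits
#' at higher genomic coordinates), `intron` between exons, and
#' `exon_noncoding` for exonic sequence of transcripts without a CDS.
#'
#' @param tx a transcript record (`exons` data frame and optional `cds`).
#' @param strand `"+"` or `"-"`.
#' @return data frame with columns `start`, `end`, `class`; the segments
#'   are sorted, disjoint, and cover the span exactly once.
#' @export
transcript_regions <- function(tx, strand) {
  ex <- tx$exons
  n <- nrow(ex)
  segs <- list()
  add <- function(start, end, class) {
    if (end > start)
      segs[[length(segs) + 1L]] <<- data.frame(start = start, end = end,
                                               class = class)
  }
  for (i in seq_len(n)) {
    if (is.null(tx$cds)) {
      add(ex$start[i], ex$end[i], "exon_noncoding")
    } else {
      cs <- tx$cds[1]; ce <- tx$cds[2]
      low_class <- if (strand == "+") "utr5" else "utr3"
      high_class <- if (strand == "+") "utr3" else "utr5"
      add(ex$start[i], min(ex$end[i], cs), low_class)
      add(max(ex$start[i], cs), min(ex$end[i], ce), "cds")
      add(max(ex$start[i], ce), ex$end[i], high_class)
    }
    if (i < n) add(ex$end[i], ex$start[i + 1], "intron")
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' @export
print.genome_model <- function(x, ...) {
  n_tx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("genome_model: %d chromosome(s), %d gene(s), %d transcript(s)\n",
              length(x$chromosomes), length(x$genes), n_tx))
  for (ch in names(x$chromosomes))
    cat(sprintf("  %s: %s nt\n", ch, format(x$chromosomes[[ch]],
                                            big.mark = ",")))
  invisible(x)
}

## Flat table of region segments across the model, one row per segment,
## with gene/transcript/strand bookkeeping. Used by the site planter.
model_region_segments <- function(model) {
  out <- lapply(model$genes, function(g) {
    do.call(rbind, lapply(g$transcripts, function(tx) {
      segs <- transcript_regions(tx, g$strand)
      segs$chrom <- g$chrom
      segs$gene_id <- g$gene_id
      segs$transcript_id <- tx$transcript_id
      segs$strand <- g$strand
      segs
    }))
  })
  do.call(rbind, out)
}

## Genomic span (start, end) per gene, as a data.frame.
gene_spans <- function(model) {
  do.call(rbind, lapply(model$genes, function(g) {
    ex <- g$transcripts[[1]]$exons
    lo <- min(vapply(g$transcripts, function(tx) min(tx$exons$start),
                     numeric(1)))
    hi <- max(vapply(g$transcripts, function(tx) max(tx$exons$end),
                     numeric(1)))
    data.frame(chrom = g$chrom, start = lo, end = hi, gene_id = g$gene_id)
  }))
}
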