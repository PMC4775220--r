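test_that("positions classify by region, strand-aware", {
  tx <- tiny_transcript()
  expect_equal(classify_position(150, tx, "+"), "intron")
  expect_equal(classify_position(470, tx, "+"), "utr3")
  expect_equal(classify_position(20, tx, "+"), "utr5")
  expect_equal(classify_position(50, tx, "+"), "cds")
  expect_equal(classify_position(449, tx, "+"), "cds")
  expect_equal(classify_position(450, tx, "+"), "utr3")
  ## minus strand: the 5'UTR moves to the high-coordinate end
  expect_equal(classify_position(20, tx, "-"), "utr3")
  expect_equal(classify_position(470, tx, "-"), "utr5")
  expect_equal(classify_position(150, tx, "-"), "intron")
  expect_error(classify_position(600, tx, "+"), "outside transcript span")
  ## transcripts without a CDS are noncoding exons
  nc <- tiny_transcript(cds = NULL)
  expect_equal(classify_position(20, nc, "+"), "exon_noncoding")
  expect_equal(classify_position(150, nc, "+"), "intron")
})

test_that("classification partitions every generated transcript span", {
  for (seed in c(31, 32)) {
    gm <- make_genome_model(4, 80000, seed = seed)
    for (g in gm$genes) {
      for (tx in g$transcripts) {
        segs <- transcript_regions(tx, g$strand)
        cls <- scan_classes(tx, g$strand)
        ## position-wise scan agrees with the segment partition
        seg_cls <- rep(segs$class, segs$end - segs$start)
        expect_equal(cls, seg_cls)
      }
    }
  }
})

test_that("flipping the strand swaps UTR labels position-wise", {
  tx <- tiny_transcript()
  swap <- c(utr5 = "utr3", utr3 = "utr5", cds = "cds", intron = "intron")
  for (p in seq(0, 499, by = 7)) {
    plus <- classify_position(p, tx, "+")
    minus <- classify_position(p, tx, "-")
    expect_equal(unname(swap[plus]), minus)
  }
})

make_site_peak <- function(summit, id = "pk1") {
  pk <- data.frame(chrom = "chr1", start = summit - 50, end = summit + 50,
                   summit = summit, score = 1, mean_coverage = 10,
                   peak_id = id)
  class(pk) <- c("rip_peaks", "data.frame")
  pk
}

two_tx_model <- function() {
  ## gene A: single transcript whose sole intron covers 1000-2000
  txA <- list(transcript_id = "A.1",
              exons = data.frame(start = c(500, 2000), end = c(1000, 2500)),
              cds = c(600, 2400))
  ## gene B overlaps that intron with a 3'UTR exon
  txB <- list(transcript_id = "B.1",
              exons = data.frame(start = c(900, 1400), end = c(1100, 1800)),
              cds = c(950, 1500))
  structure(list(
    chromosomes = c(chr1 = 10000),
    genes = list(
      list(gene_id = "geneA", chrom = "chr1", strand = "+",
           transcripts = list(txA)),
      list(gene_id = "geneB", chrom = "chr1", strand = "+",
           transcripts = list(txB)))),
    class = "genome_model")
}

test_that("summits are annotated with precedence, ties and intergenic", {
  m <- two_tx_model()
  ## summit 1600: intron of A.1, 3'UTR of B.1 -> 3'UTR wins by precedence
  ann <- annotate_peaks(make_site_peak(1600), m)
  expect_equal(ann$gene_id, "geneB")
  expect_equal(ann$region_class, "utr3")
  ## custom precedence can prefer the intron call
  ann2 <- annotate_peaks(make_site_peak(1600), m,
                         precedence = c("intron", "utr3", "utr5", "cds",
                                        "exon_noncoding"))
  expect_equal(ann2$gene_id, "geneA")
  expect_equal(ann2$region_class, "intron")
  ## summit in gene A's intron only
  ann3 <- annotate_peaks(make_site_peak(1900), m)
  expect_equal(ann3$region_class, "intron")
  expect_equal(ann3$gene_id, "geneA")
  ## gene desert
  ann4 <- annotate_peaks(make_site_peak(5000), m)
  expect_equal(ann4$gene_id, "intergenic")
  expect_equal(ann4$region_class, "intergenic")
})

test_that("region distribution and gene lists summarise annotations", {
  ann <- data.frame(region_class = c("intron", "intron", "utr3"),
                    gene_id = c("g1", "g1", "g2"))
  class(ann) <- c("annotated_peaks", "data.frame")
  d <- region_distribution(ann)
  expect_equal(unname(d["intron"]), 2 / 3)
  expect_equal(unname(d["utr3"]), 1 / 3)
  expect_equal(sum(d), 1)
  expect_equal(gene_list(ann), c("g1", "g2"))

  empty <- ann[0, ]
  class(empty) <- c("annotated_peaks", "data.frame")
  expect_error(region_distribution(empty), "zero peaks")
  expect_length(gene_list(empty), 0)

  ## intergenic and noncoding peaks leave the four-class fractions
  mixed <- data.frame(
    region_class = c("intron", "utr3", "intergenic", "exon_noncoding"),
    gene_id = c("g1", "g2", "intergenic", "g3"))
  class(mixed) <- c("annotated_peaks", "data.frame")
  dm <- region_distribution(mixed)
  expect_equal(sum(dm), 1)
  expect_equal(unname(dm["intron"]), 0.5)
  expect_equal(unname(attr(dm, "counts")["intergenic"]), 1,
               ignore_attr = TRUE)
})
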