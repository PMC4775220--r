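# ripcall

Binding-site discovery for RIP-seq (RNA immunoprecipitation
sequencing) experiments, for analysts who have aligned fragment
intervals from an antibody pulldown plus an IgG control and want the
protein's binding sites on RNA: where they are, whether they are
enriched over background, and which transcript region they fall in.

The pipeline is:

1. **Coverage** — per-base fragment depth per sample, with optional
   reads-per-million scaling.
2. **Peak detection** — convolution of pooled RIP coverage with the
   second derivative of a Gaussian (Laplacian of Gaussian, bandwidth
   σ = 300 nt). Enrichment bumps of width ≈ 2σ give strongly negative
   responses; peaks are negative-response runs bounded by zero
   crossings, thresholded adaptively at 4 robust noise SDs.
3. **Differential enrichment** — fragments counted per peak by
   midpoint; median-of-ratios size factors
   `s_j = median_i ( k_ij / (Π_v k_iv)^{1/m} )`; per-peak
   negative-binomial dispersion (method of moments with a conservative
   mean–dispersion trend, `Var = μ + αμ²`); a conditional exact test
   on each peak's total count split between RIP and control; and
   Benjamini–Hochberg FDR. A binding site is a peak with
   **FDR < 0.05 and more (normalised) reads in RIP**.
4. **Annotation** — each site is labelled by the transcript region at
   its summit: 5'UTR, CDS, intron or 3'UTR, strand-aware.
5. **Splicing helpers** — beta-binomial percent-spliced-in with
   junction-count normalisation, Ψ ~ Beta(1 + I/2, 1 + E) for a
   skipped exon, a closed-form Bayes factor
   `BF = B(i₁+1,e₁+1)·B(i₂+1,e₂+1)/B(i₁+i₂+1,e₁+e₂+1)` for a Ψ
   difference between conditions, and ΔΔCt isoform ratios
   (`2^-ΔΔCt` against a reference gene).

A synthetic-data module generates toy genomes, gene models and
fragment sets with planted enriched sites, so the whole pipeline is
testable — and demonstrable — without any external data.

## Worked example

Simulate the default experiment (2 RIP + 2 IgG replicates, 40 genes
on 600 kb, 20 planted sites at 8× enrichment, mean fragment length
200 nt) and run the full pipeline:

```r
library(ripcall)

res <- run_pipeline(list(seed = 1), outdir = "ripcall_out")
res
#> ripcall pipeline run
#>   outdir:            ripcall_out
#>   peaks detected:    20
#>   significant peaks: 20 (FDR < 0.05, RIP up)
#>   region fractions:  utr5=0.00 cds=0.00 intron=0.50 utr3=0.50
#>   bound genes:       19
```

All 20 planted sites are detected, none besides them, and every one
passes the FDR gate in the RIP direction:

```r
truth <- read_sites_bed(file.path("ripcall_out", "truth.bed"))
ev <- match_peaks_to_sites(res$peaks, truth, min_reciprocal = 0.5)
c(recall = ev$recall, precision = ev$precision)
#> recall precision
#>   1.00      1.00

head(res$enrichment[, c("peak_id", "base_mean_rip", "base_mean_control",
                        "log2_fold_change", "fdr")], 3)
#>      peak_id base_mean_rip base_mean_control log2_fold_change          fdr
#> 1 peak_00001      244.8225          33.93784         2.832613 2.275817e-09
#> 2 peak_00002      271.5410          36.86884         2.863916 2.074007e-07
#> 3 peak_00003      225.4449          35.86613         2.635304 6.275984e-09
```

The base means are size-factor-normalised fragment counts per
condition; the log2 fold changes near `log2(8) ≈ 3` reflect the
planted 8× enrichment (slightly shrunk by the pseudocount and the
fragments that fall outside the site core). The run directory holds
the full bundle: GTF gene model, per-sample fragment BEDs, pooled
coverage bedGraph, peak BED/TSV, enrichment table, annotated sites,
region distribution, and a manifest with parameters and checksums.

Splicing quantities work the same way from counts:

```r
psi_posterior(8, 4, n_inc_junc = 2, n_exc_junc = 1)
#> PSI = 0.500  [0.212, 0.788]  (Beta(5.00, 5.00))
delta_delta_ct(20, 18, 22, 18)   # target 2 cycles earlier in sample 1
#> [1] 4
```

A thin command-line front end wraps the same functions
(`inst/scripts/ripcall.R`): subcommands `simulate`, `coverage`,
`callpeaks`, `diff`, `annotate`, `psi` and `run`.

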