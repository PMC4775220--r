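---
title: "RIP-seq binding-site discovery with ripcall: models and methods"
author: "ripcall authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RIP-seq binding-site discovery with ripcall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ripcall implements a complete RIP-seq (RNA immunoprecipitation
sequencing) analysis: binding-site candidates are detected on read
coverage with a Laplacian-of-Gaussian (LoG) filter, tested for
differential enrichment of the RIP pulldown over an IgG control with a
negative-binomial conditional exact test, gated at a
Benjamini–Hochberg FDR, and annotated with the transcript region
(5'UTR, CDS, intron, 3'UTR) at each peak summit. A synthetic-data
generator plants enriched sites in toy gene models so every stage is
testable end to end without external data. A small splicing module
provides beta-binomial percent-spliced-in (Ψ) estimates with
closed-form Bayes factors, and ΔΔCt helpers for qPCR isoform ratios.

This vignette is the package's account of the underlying models, the
parameters that matter, and the numerical and design choices made
where several options were defensible.

## Peak detection: LoG filtering of coverage

Fragment intervals per sample are summed into per-base coverage
(`build_coverage()`; all coordinates in the package are 0-based,
half-open, matching BED). Detection runs on the pooled raw coverage of
the RIP replicates. Pooling is the default because the downstream
count test — not the detector — owns library-size correction and
replicate-level inference; per-replicate detection with a union of
calls is available via `detection$pool_replicates: false`. Raw rather
than RPM signal is used for the same reason (`detection$signal` flips
this).

The detector convolves coverage with the second derivative of a
Gaussian density of standard deviation σ (the *bandwidth*, default
300 nt), truncated at 4σ and mean-centered so the weights sum to zero
exactly (`log_kernel()`). A zero-sum kernel is blind to constant
background, and a coverage bump of width ≈ 2σ produces a strongly
negative response at its center. Candidate peaks are maximal runs of
negative response — their boundaries are the response's zero
crossings — merged across gaps shorter than `merge_gap` (50 nt),
filtered by width (`min_width`, 50 nt), by mean coverage
(`min_coverage`, 5×), and by summit score `-response`
(`min_score`). The summit is the most negative response position,
leftmost on ties; output order is deterministic.

Numerical choices worth stating:

* **Adaptive score threshold.** `min_score` defaults to
  `mad_k × MAD` (k = 4) of the response, computed **only over
  positions with nonzero response**. Stretches with no fragment within
  one kernel radius respond exactly zero and carry no noise
  information; including them would halve the MAD in sparse genomes
  and make the threshold depend on the genic fraction of the genome
  rather than on the noise. The restriction also separates true bumps
  from the deterministic one-sided negative lobe the LoG produces at
  sharp coverage steps (e.g. transcript boundaries), whose magnitude
  is `h·g'(σ)` for a step of height `h` — about 14× smaller than the
  response of an 8-fold enrichment bump at any depth.
* **Numerical zero.** Response magnitudes below `1e-9` of the maximum
  are clamped to zero (they are rounding residue of the zero-sum
  kernel), and a track with zero dynamic range yields no peaks. This
  makes peak calls exactly invariant to adding a constant to the
  coverage.
* **Edges.** Convolution zero-pads; within one kernel radius of the
  track ends the response reflects the padding, not data, so
  `detect_peaks()` excludes candidate runs touching those margins.

## Differential enrichment: NB conditional exact test

Fragments are counted per peak by **midpoint** (each fragment counted
at most once; `enrichment$counting: overlap` switches to any-overlap).
Library-size correction uses median-of-ratios size factors
(`size_factors()`): `s_j` is the median over rows of
`counts[i, j] / geometric_mean_i`, over rows positive in every sample.

In the pipeline the size factors are estimated on **background
windows** — 1 kb tiles over gene spans that do not touch any detected
peak (`background_size_factors()`) — rather than on the peak matrix
itself. When detection is precise, most peak rows are genuinely
enriched, and median-of-ratios on such a matrix absorbs the
enrichment into the factors (the classic "most features differential"
failure). Background tiles are exchangeable between conditions by
construction, so their median ratio estimates sequencing depth only.
`rip_enrichment()` still defaults to the peak-matrix estimator for
stand-alone use with mostly-null matrices.

Dispersion is estimated per peak by method of moments on normalised
counts (`α = max(0, (v − m)/m²)` with within-condition pooled
variance), a hyperbolic trend `α(m) = a₀ + a₁/m` is fitted by least
squares across peaks with positive raw estimates, and each peak gets
the **maximum** of its own estimate and the trend. With only 2 + 2
replicates the per-peak moment estimate is extremely noisy; the
conservative maximum trades a little power for protection against
underestimated variance. The cost is measurable: in null simulations
the raw p < 0.05 fraction is ≈ 0.031 at a depth of ~120 fragments per
peak (the scale of a full 100M-read experiment) and drops to ≈ 0.025
at the toy depth of ~30, while the same test with the true dispersion
is calibrated (0.043–0.054) at both depths. The package's calibration
checks therefore run at the full-experiment depth; the bias, not the
test, is what shrinks at shallow counts.

The test itself conditions on a peak's total count K across all
samples. Each split (a, K − a) between conditions receives probability
proportional to the product of the two conditions' negative-binomial
likelihoods, with the sum of replicate counts moment-matched to a
single NB (mean `μ̂·S`, effective size `S²/(α·Σs²)`); the two-sided
p-value sums the probabilities of all splits no more likely than the
observed one. At α = 0 this reduces to the conditional binomial
(Poisson) test. Zero-total peaks get p = 1 so peak and result tables
stay aligned. FDR control is Benjamini–Hochberg; a binding site is
significant when `fdr < 0.05` (strict) **and** the RIP samples have
the larger normalised mean.

## Annotation

Each significant peak is classified by its **summit** position, giving
one label per binding site. Classification is strand-aware: exonic
sequence upstream of the CDS in transcript orientation is 5'UTR, so on
the minus strand the 5'UTR sits at higher genomic coordinates.
Transcripts without a CDS contribute `exon_noncoding`, reported
separately and excluded from the four-class fractions. When several
transcripts cover a summit, the label is chosen by precedence
3'UTR > 5'UTR > CDS > intron (config-overridable), then longest
transcript, then lexicographic id. The precedence prefers the most
specific functional element when isoforms disagree; it is a
convention, not a biological claim.

## The synthetic-data generator

`make_genome_model()` builds single-chromosome genomes of disjoint
protein-coding genes (2–4 exons; 5'UTRs 600–900 nt, 3'UTRs
800–1200 nt, internal exons fully coding 700–900 nt, introns
800–1400 nt). Every region class offers segments of ≥ 600 nt so
binding sites of the default width can be planted anywhere the region
mix asks; the largest possible gene still fits a 10 kb chromosome.
`plant_sites()` draws each site's class from the region mix (default
intron 0.55, 3'UTR 0.41, 5'UTR 0.02, CDS 0.02 — echoing where
RNA-binding proteins concentrate on pre-mRNA), places it wholly inside
a segment of that class, and keeps sites ≥ 4× their width apart so
neighbouring sites cannot blur into one peak.

`simulate_fragments()` emulates the experiment's design: 2 RIP + 2 IgG
replicates, mean fragment length 200 nt (shifted Poisson, 50 nt
floor), background shared between conditions. Per-window fragment
counts are negative-binomially dispersed (gamma–Poisson; `α = 0` gives
exact Poisson) around `background_rate × window_length`, multiplied by
the enrichment factor inside planted sites for RIP samples only. The
window tiling refines at site boundaries so the enrichment applies to
the planted interval exactly. Background is transcript-shaped by
default (fragments only from gene spans, since both pulldowns sample
the transcriptome); a flat genome-wide background is available.

Defaults are chosen once as the package's study conditions:
`background_rate = 0.05` fragments/nt (≈ 10× base coverage per sample
at 200 nt fragments — deep enough for clear peaks, small enough that a
full pipeline run takes seconds), `nb_dispersion = 0.1` (typical
biological-replicate overdispersion), enrichment 8×, 20 sites of
600 nt (≈ 2σ) on a 600 kb, 40-gene genome. Dispersion is constant
across windows; estimating a mean–dispersion trend is the analysis's
job, not the generator's.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: mappability and GC bias, PCR
duplicates, exon-level expression variation within a gene,
strand-specific coverage, partial IgG co-enrichment at true sites, and
window-to-window correlation of biological noise (dispersion is drawn
independently per window, so counts over multi-window peaks are less
dispersed than `nb_dispersion`; the analysis estimates dispersion from
the data rather than trusting the generator's constant).

## Splicing quantitation

For a skipped exon, inclusion reads distribute over two junctions and
exclusion reads over one, so raw counts are divided by their junction
multiplicities before estimation — otherwise the longer isoform is
overcounted. With a uniform prior the normalised counts give a
conjugate Beta posterior for Ψ (`psi_posterior()`); the point estimate
is the posterior mean, with a 95% equal-tailed credible interval.
Retained introns use multiplicities 2 (retention, the two intron
boundaries) and 1 (the spliced exon–exon junction).

The Bayes factor compares independent per-condition inclusion
fractions against one shared fraction, both with Uniform(0,1) priors;
the marginal likelihoods are Beta functions and
`BF = B(i₁+1, e₁+1)·B(i₂+1, e₂+1) / B(i₁+i₂+1, e₁+e₂+1)` on effective
counts rounded half away from zero (the rounding changes BF by < 1e-3
for counts ≥ 10). BF > 2 is the conventional reporting threshold. Only
SE and RI events carry the Ψ model; other event types (MXE, A5SS,
A3SS, AFE, ALE, T3UTR) are parsed and passed through flagged as
unscored, because their isoform structures need more than one
inclusion fraction. ΔΔCt helpers implement
`2^-((Ct_t,s1 − Ct_ref,s1) − (Ct_t,s2 − Ct_ref,s2))` and replicate
mean ± sd isoform ratios (≥ 3 replicates required).

## Pipeline and reproducibility

`run_pipeline()` drives simulate (or import) → coverage → callpeaks →
diff → annotate from one YAML config with a frozen schema — unknown
keys are rejected at every level so typos fail loudly. All randomness
derives from the single `seed`; identical configs give byte-identical
outputs, and each stage reads its inputs from, and writes its outputs
to, the run directory, so any stage re-runs reproducibly in isolation.
The manifest records every parameter and the checksum of every file.

## Problem sizes used in the checks

The test suite exercises the detector's oracle equivalence on ~50
random tracks, full-pipeline recovery on three 600 kb / 20-site runs,
region-mix recovery on one 3 Mb / 150-site run, null calibration on
20 × 2500 NB peaks at full-experiment depth, the exact-test oracle on
every total K ≤ 50, and the Bayes-factor closed form against numerical
integration over all effective counts ≤ 30. These sizes were chosen to
give the relevant Monte-Carlo standard errors a comfortable margin
against each check's tolerance while keeping a complete run of the
suite within a few minutes.

## Known limitations

* Exactly a two-condition, replicate-balanced-or-not design; no GLM
  covariates, no batch terms.
* Single-bandwidth detection: sites much wider or narrower than 2σ
  lose score; there is no scale-space search.
* Summit-based annotation assigns one gene per peak; peaks straddling
  genes are labelled by the summit only.
* The Ψ model is a deliberately simple junction-count stand-in for a
  full generative isoform model; its Bayes factors are comparable
  within this package, not to other tools' numbers.
* The conservative dispersion rule costs type-I rate at shallow depth
  (see above); with more replicates a shrinkage estimator would
  dominate it.
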