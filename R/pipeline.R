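#' Default pipeline configuration
#'
#' Returns the full configuration tree with every tunable of the
#' pipeline: LoG bandwidth 300 nt, the FDR gate at 0.05, and a
#' simulated design of 2 RIP + 2 IgG replicates with mean fragment
#' length 200 nt.
#'
#' @return nested named list; see the package vignette for the meaning
#'   and units of every field.
#' @export
default_config <- function() {
  list(
    seed = 42,
    outdir = "ripcall_out",
    simulate = list(
      n_genes = 40, chrom_length = 600000, n_sites = 20, width = 600,
      enrichment = 8,
      region_mix = list(intron = 0.55, utr3 = 0.41, utr5 = 0.02,
                        cds = 0.02),
      background_rate = 0.05, fragment_len_mean = 200, nb_dispersion = 0.1,
      n_rip = 2, n_control = 2, background = "transcript", window = 200),
    inputs = NULL,
    detection = list(
      bandwidth = 300, min_score = NULL, mad_k = 4, min_coverage = 5,
      min_width = 50, merge_gap = 50, signal = "raw",
      pool_replicates = TRUE),
    enrichment = list(fdr_threshold = 0.05, counting = "midpoint"),
    annotation = list(precedence = c("utr3", "utr5", "cds", "intron",
                                     "exon_noncoding"))
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), overlays it on
#' [default_config()], and rejects unknown keys at every level so typos
#' fail loudly instead of silently using a default.
#'
#' @param config path to a YAML file, or a (possibly partial) config
#'   list.
#' @return validated full configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path",
                             call. = FALSE)
  merge_checked(default_config(), config, path = "config")
}

merge_checked <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("unknown %s key(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        is.list(user[[k]])) {
      defaults[[k]] <- merge_checked(defaults[[k]], user[[k]],
                                     paste(path, k, sep = "$"))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Run the full RIP-seq pipeline
#'
#' Orchestrates simulate (or load) -> coverage -> peak detection ->
#' differential enrichment -> annotation from one configuration, with a
#' run log and a manifest of parameters and file checksums. Each stage
#' reads its inputs from, and writes its outputs to, `outdir`, so any
#' stage can be re-run in isolation and reproduces its files exactly.
#'
#' @param config YAML path or config list (see [default_config()]).
#' @param outdir output directory; overrides `config$outdir`.
#' @return object of class `rip_pipeline`: list with the key result
#'   objects (`peaks`, `enrichment`, `annotated`, `distribution`) and
#'   `files` (all output paths).
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- load_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  ## `simulate: false` in the config disables the default simulate block
  if (isFALSE(cfg$simulate)) cfg$simulate <- NULL
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a 'simulate' block or an 'inputs' block",
         call. = FALSE)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$outdir, "run.log")
  cat("ripcall pipeline\n", file = logf)

  ## an explicit inputs block takes precedence over the (default)
  ## simulate block
  if (!is.null(cfg$inputs)) {
    log_line(logf, "stage import")
    stage_import(cfg)
  } else {
    log_line(logf, "stage simulate")
    stage_simulate(cfg)
  }
  log_line(logf, "stage coverage")
  stage_coverage(cfg)
  log_line(logf, "stage callpeaks")
  stage_callpeaks(cfg)
  log_line(logf, "stage diff")
  stage_diff(cfg)
  log_line(logf, "stage annotate")
  res <- stage_annotate(cfg)

  files <- pipeline_files(cfg$outdir)
  manifest <- list(
    parameters = cfg,
    checksums = as.list(tools::md5sum(unlist(files[file.exists(unlist(files))]))))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  log_line(logf, "done")

  peaks <- utils::read.delim(files$peaks_tsv)
  enr <- utils::read.delim(files$enrichment_tsv)
  structure(list(config = cfg, peaks = peaks, enrichment = enr,
                 annotated = res$annotated, distribution = res$distribution,
                 files = c(files, manifest = file.path(cfg$outdir,
                                                       "manifest.yaml"))),
            class = "rip_pipeline")
}

log_line <- function(logf, msg) cat(msg, "\n", file = logf, append = TRUE,
                                    sep = "")

pipeline_files <- function(outdir) {
  p <- function(x) file.path(outdir, x)
  list(gtf = p("genome.gtf"), chrom_sizes = p("chrom.sizes"),
       truth = p("truth.bed"), samples = p("samples.tsv"),
       coverage = p("coverage_pooled.bedgraph"),
       peaks_bed = p("peaks.bed"), peaks_tsv = p("peaks.tsv"),
       enrichment_tsv = p("enrichment.tsv"),
       significant_bed = p("significant.bed"),
       annotated_tsv = p("annotated.tsv"), annotated_bed = p("annotated.bed"),
       distribution = p("region_distribution.tsv"))
}

#' Pipeline stages
#'
#' Individual stages of [run_pipeline()]. Each takes the validated
#' configuration (`load_config()` output with `outdir` set), reads its
#' inputs from files in `outdir`, and writes its outputs there, so a
#' stage re-run from the same on-disk inputs reproduces its files.
#'
#' @param cfg validated configuration list.
#' @return used for their file side effects; `stage_annotate` also
#'   returns the annotated peaks and region distribution.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  f <- pipeline_files(cfg$outdir)
  s <- cfg$simulate
  model <- make_genome_model(s$n_genes, s$chrom_length, seed = cfg$seed)
  sites <- plant_sites(model, s$n_sites,
                       region_mix = unlist(s$region_mix), width = s$width,
                       enrichment = s$enrichment, seed = cfg$seed)
  frags <- simulate_fragments(model, sites,
                              background_rate = s$background_rate,
                              fragment_len_mean = s$fragment_len_mean,
                              nb_dispersion = s$nb_dispersion,
                              n_rip = s$n_rip, n_control = s$n_control,
                              seed = cfg$seed,
                              background = s$background, window = s$window)
  write_genome_model(model, f$gtf, f$chrom_sizes)
  write_sites_bed(sites, f$truth)
  meta <- do.call(rbind, lapply(frags, function(fs) {
    path <- file.path(cfg$outdir, sprintf("fragments_%s.bed", fs$sample_id))
    write_fragments_bed(fs, path)
    data.frame(sample_id = fs$sample_id, condition = fs$condition,
               replicate = fs$replicate, path = basename(path))
  }))
  utils::write.table(meta, f$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

## Copy externally supplied inputs into the bundle layout.
stage_import <- function(cfg) {
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  f <- pipeline_files(cfg$outdir)
  inp <- cfg$inputs
  for (need in c("gtf", "chrom_sizes", "fragments"))
    if (is.null(inp[[need]]))
      stop(sprintf("inputs block is missing '%s'", need), call. = FALSE)
  file.copy(inp$gtf, f$gtf, overwrite = TRUE)
  file.copy(inp$chrom_sizes, f$chrom_sizes, overwrite = TRUE)
  meta <- do.call(rbind, lapply(inp$fragments, function(fr) {
    dest <- file.path(cfg$outdir,
                      sprintf("fragments_%s.bed", fr$sample_id))
    file.copy(fr$path, dest, overwrite = TRUE)
    data.frame(sample_id = fr$sample_id, condition = fr$condition,
               replicate = fr$replicate %||% 1L, path = basename(dest))
  }))
  utils::write.table(meta, f$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

read_bundle_samples <- function(cfg) {
  f <- pipeline_files(cfg$outdir)
  meta <- utils::read.delim(f$samples)
  model <- read_genome_model(f$gtf, f$chrom_sizes)
  frags <- lapply(seq_len(nrow(meta)), function(i)
    read_fragments_bed(file.path(cfg$outdir, meta$path[i]),
                       meta$sample_id[i], meta$condition[i],
                       meta$replicate[i]))
  list(model = model, meta = meta, frags = frags)
}

#' @rdname pipeline_stages
#' @export
stage_coverage <- function(cfg) {
  f <- pipeline_files(cfg$outdir)
  b <- read_bundle_samples(cfg)
  rip <- b$frags[vapply(b$frags, `[[`, "", "condition") == "RIP"]
  pooled <- pool_coverage(lapply(rip, build_coverage, model = b$model))
  if (identical(cfg$detection$signal, "rpm"))
    pooled <- lapply(pooled, rpm_normalize)
  write_bedgraph(pooled, f$coverage)
  invisible(NULL)
}

#' @rdname pipeline_stages
#' @export
stage_callpeaks <- function(cfg) {
  f <- pipeline_files(cfg$outdir)
  b <- read_bundle_samples(cfg)
  d <- cfg$detection
  rip <- b$frags[vapply(b$frags, `[[`, "", "condition") == "RIP"]
  det_sets <- if (isTRUE(d$pool_replicates)) list(rip) else
    lapply(rip, list)
  peak_sets <- lapply(det_sets, function(set) {
    tracks <- pool_coverage(lapply(set, build_coverage, model = b$model))
    if (identical(d$signal, "rpm")) tracks <- lapply(tracks, rpm_normalize)
    detect_peaks(tracks, bandwidth = d$bandwidth, min_score = d$min_score,
                 mad_k = d$mad_k, min_coverage = d$min_coverage,
                 min_width = d$min_width, merge_gap = d$merge_gap)
  })
  peaks <- if (length(peak_sets) == 1) peak_sets[[1]] else
    union_peak_sets(peak_sets)
  write_peaks(peaks, bed_path = f$peaks_bed, tsv_path = f$peaks_tsv)
  invisible(peaks)
}

## Union of per-replicate peak calls: overlapping calls are reduced to
## one interval; summit and score come from the strongest contributor.
union_peak_sets <- function(peak_sets) {
  all <- do.call(rbind, lapply(peak_sets, as.data.frame))
  if (nrow(all) == 0) {
    out <- all
    out$peak_id <- character(0)
    class(out) <- c("rip_peaks", "data.frame")
    return(out)
  }
  gr <- granges_from_intervals(all$chrom, all$start, all$end)
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(hits)
  rows <- lapply(seq_along(red), function(j) {
    members <- all[grp == j, , drop = FALSE]
    best <- members[which.max(members$score), ]
    data.frame(chrom = as.character(GenomicRanges::seqnames(red[j])),
               start = GenomicRanges::start(red[j]) - 1,
               end = GenomicRanges::end(red[j]),
               summit = best$summit, score = best$score,
               mean_coverage = stats::weighted.mean(
                 members$mean_coverage, members$end - members$start))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out$peak_id <- sprintf("peak_%05d", seq_len(nrow(out)))
  class(out) <- c("rip_peaks", "data.frame")
  out
}

#' @rdname pipeline_stages
#' @export
stage_diff <- function(cfg) {
  f <- pipeline_files(cfg$outdir)
  b <- read_bundle_samples(cfg)
  peaks <- read_peaks_tsv(f$peaks_tsv)
  pcm <- count_in_peaks(peaks, b$frags, mode = cfg$enrichment$counting)
  sf <- background_size_factors(peaks, b$frags, b$model)
  res <- rip_enrichment(pcm, fdr_threshold = cfg$enrichment$fdr_threshold,
                        sf = sf)
  out <- cbind(as.data.frame(peaks)[, c("peak_id", "chrom", "start", "end",
                                        "summit")],
               as.data.frame(res)[, -1])
  utils::write.table(out, f$enrichment_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sig <- out[out$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    file.create(f$significant_bed)
  } else {
    gr <- granges_from_intervals(sig$chrom, sig$start, sig$end,
                                 name = sig$peak_id, score = 0L)
    rtracklayer::export(gr, f$significant_bed, format = "bed")
  }
  invisible(res)
}

read_peaks_tsv <- function(path) {
  peaks <- utils::read.delim(path,
                             colClasses = c(chrom = "character"))
  class(peaks) <- c("rip_peaks", "data.frame")
  peaks
}

#' @rdname pipeline_stages
#' @export
stage_annotate <- function(cfg) {
  f <- pipeline_files(cfg$outdir)
  b <- read_bundle_samples(cfg)
  enr <- utils::read.delim(f$enrichment_tsv,
                           colClasses = c(chrom = "character"))
  sig <- enr[enr$significant, , drop = FALSE]
  class(sig) <- c("rip_peaks", "data.frame")
  ann <- annotate_peaks(sig, b$model,
                        precedence = cfg$annotation$precedence)
  write_annotated_peaks(ann, tsv_path = f$annotated_tsv,
                        bed_path = f$annotated_bed)
  dist <- if (nrow(ann) > 0 &&
                any(ann$region_class %in% c("utr5", "cds", "intron",
                                            "utr3"))) {
    region_distribution(ann)
  } else {
    stats::setNames(rep(NA_real_, 4), c("utr5", "cds", "intron", "utr3"))
  }
  utils::write.table(
    data.frame(region_class = names(dist), fraction = as.numeric(dist)),
    f$distribution, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(annotated = ann, distribution = dist))
}

#' @export
print.rip_pipeline <- function(x, ...) {
  cat("ripcall pipeline run\n")
  cat(sprintf("  outdir:            %s\n", x$config$outdir))
  cat(sprintf("  peaks detected:    %d\n", nrow(x$peaks)))
  cat(sprintf("  significant peaks: %d (FDR < %g, RIP up)\n",
              sum(x$enrichment$significant),
              x$config$enrichment$fdr_threshold))
  if (!all(is.na(x$distribution)))
    cat(sprintf("  region fractions:  %s\n",
                paste(sprintf("%s=%.2f", names(x$distribution),
                              x$distribution), collapse = " ")))
  cat(sprintf("  bound genes:       %d\n",
              length(gene_list(x$annotated))))
  invisible(x)
}
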