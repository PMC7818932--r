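log_info <- function(...) message("[repeatloop] ", sprintf(...))

#' Read a flat key-value run configuration
#'
#' YAML with flat keys. Recognised keys: `rloop_bed`, `rnaseh_bed` (optional),
#' `gro_beds` (scalar or list, optional), `genes`, `genes_format`, `repeats`,
#' `repeats_dialect`, `chrom_sizes`, `gaps_bed` (optional), `n_samples`,
#' `seed`, `max_rejection_attempts`, `exclude_gaps`, `level` (`class`,
#' `family` or `both`), `flank`, `min_overlap`, `controls`
#' (subset of `genome,sampling,gro`), `write_controls`.
#'
#' @param path YAML file
#' @return a named list of configuration values (class `RunConfig`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "RunConfig")
}

resolve_cfg <- function(cfg, overrides = list()) {
  defaults <- list(rnaseh_bed = NULL, gro_beds = NULL, gaps_bed = NULL,
                   genes_format = NULL, repeats_dialect = "ucsc_rmsk",
                   n_samples = 1000L, seed = 1L,
                   max_rejection_attempts = 1000L, exclude_gaps = TRUE,
                   level = "both", flank = 2000L, min_overlap = 1L,
                   controls = c("genome", "sampling", "gro"),
                   write_controls = FALSE)
  cfg <- utils::modifyList(defaults, as.list(cfg))
  utils::modifyList(cfg, overrides)  # flags win over the config file
}

#' Run the full enrichment analysis
#'
#' End-to-end orchestration: (1) read inputs, (2) optionally drop R-loop peaks
#' overlapping RNaseH-treated peaks, (3) merge GRO replicate peak sets,
#' (4) partition the genome, (5) build the requested controls, (6) compute
#' class- and/or family-level enrichment matrices, and (7) write the genomic
#' distribution, size summary and base-level Venn reports. Every stage logs
#' counts; output is a pure function of (inputs, config, seed).
#'
#' Output files in `out_dir`: `enrichment_class.tsv`, `enrichment_family.tsv`
#' (per requested level), `genomic_distribution.tsv`, `venn.tsv`,
#' `size_summary.tsv`, and optionally `controls/control-XXXX.bed`.
#'
#' @param cfg a [read_run_config()] result or a named list of the same keys
#' @param out_dir output directory
#' @param ... overrides of individual config keys (e.g. `seed = 7`,
#'   `n_samples = 200`)
#' @return invisibly, a list with the matrices and summaries.
#' @export
pipeline_run <- function(cfg, out_dir, ...) {
  cfg <- resolve_cfg(cfg, list(...))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  layout <- read_chrom_sizes(cfg$chrom_sizes)
  if (!is.null(cfg$gaps_bed)) {
    layout <- genome_layout(layout$lengths, gaps = read_bed(cfg$gaps_bed))
  }
  log_info("genome: %d chromosomes, %.0f bases", length(layout$lengths),
           genome_size(layout))
  rloops <- read_bed(cfg$rloop_bed, layout = layout, provenance = "rloop")
  log_info("R-loop peaks in: %d (%.0f bases)", length(rloops), total_bases(rloops))
  if (!is.null(cfg$rnaseh_bed)) {
    rnaseh <- read_bed(cfg$rnaseh_bed, layout = layout)
    rloops <- remove_overlapping_peaks(rloops, rnaseh,
                                       min_overlap_bases = cfg$min_overlap)
    log_info("after RNaseH-peak filter: %d peaks", length(rloops))
  }
  if (length(rloops) == 0) stop("no R-loop peaks left to analyse")
  gro <- NULL
  if (!is.null(cfg$gro_beds) && length(cfg$gro_beds)) {
    reps <- lapply(unlist(cfg$gro_beds), read_bed, layout = layout)
    gro <- merge_peaks(suppressWarnings(do.call(c, reps)))
    log_info("GRO transcribed regions: %d sample(s) merged to %d intervals (%.0f bases)",
             length(reps), length(gro), total_bases(gro))
  }
  models <- read_genes(cfg$genes, format = cfg$genes_format, layout = layout)
  catalog <- read_repeats(cfg$repeats, dialect = cfg$repeats_dialect,
                          layout = layout)
  log_info("annotations: %d genes, %d repeat elements",
           length(models$genes), length(catalog$elements))
  partition <- partition_genome(models, layout, flank = cfg$flank)
  log_info("partition built (flank %d)", cfg$flank)

  controls <- list()
  want <- unlist(strsplit(paste(cfg$controls, collapse = ","), ","))
  want <- trimws(want)
  if ("genome" %in% want) {
    controls$genome <- genome_control(layout, exclude_gaps = cfg$exclude_gaps)
  }
  if ("sampling" %in% want) {
    scfg <- sampling_config(n_samples = cfg$n_samples, seed = cfg$seed,
                            max_rejection_attempts = cfg$max_rejection_attempts,
                            exclude_gaps = cfg$exclude_gaps)
    log_info("sampling control: %d groups, seed %d", scfg$n_samples, scfg$seed)
    controls$sampling <- sample_matched_controls(rloops, partition, layout,
                                                 scfg,
                                                 min_overlap_bases = cfg$min_overlap)
  }
  if ("gro" %in% want && !is.null(gro)) controls$gro <- gro_control(gro)

  levels <- if (identical(cfg$level, "both")) c("class", "family") else cfg$level
  matrices <- list()
  for (lv in levels) {
    mat <- enrichment_matrix(rloops, catalog, level = lv, controls = controls)
    matrices[[lv]] <- mat
    write_enrichment_tsv(mat, file.path(out_dir, sprintf("enrichment_%s.tsv", lv)))
    log_info("enrichment_%s.tsv: %d rows", lv, nrow(mat))
  }

  dist <- genomic_distribution(rloops, partition,
                               min_overlap_bases = cfg$min_overlap)
  utils::write.table(data.frame(category = names(dist), fraction = unname(dist)),
                     file.path(out_dir, "genomic_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sizes <- width(rloops)
  size_summary <- data.frame(n_peaks = length(rloops),
                             median_length = stats::median(sizes),
                             mean_length = mean(sizes),
                             min_length = min(sizes), max_length = max(sizes),
                             total_bases = total_bases(rloops))
  utils::write.table(size_summary, file.path(out_dir, "size_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  venn <- NULL
  if (!is.null(gro)) {
    venn <- venn_bases(rloops, gro, gene_spans(models))
    vd <- data.frame(cell = c(names(venn$cells), "pct_rloop_in_transcribed"),
                     value = c(unname(venn$cells), venn$pct_rloop_in_transcribed))
    utils::write.table(vd, file.path(out_dir, "venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_info("R-loop bases in transcribed regions: %.1f%%",
             venn$pct_rloop_in_transcribed)
  }
  if (isTRUE(cfg$write_controls) && !is.null(controls$sampling)) {
    cdir <- file.path(out_dir, "controls")
    dir.create(cdir, showWarnings = FALSE)
    for (j in seq_along(controls$sampling)) {
      grj <- controls$sampling[[j]]
      mcols(grj)$name <- sprintf("%s_%d", names(controls$sampling)[j],
                                 seq_along(grj))
      write_bed(grj, file.path(cdir, paste0(names(controls$sampling)[j], ".bed")))
    }
  }
  invisible(list(matrices = matrices, distribution = dist,
                 size_summary = size_summary, venn = venn,
                 rloops = rloops, partition = partition, controls = controls))
}

#' Simulate a dataset from a flat config (CLI entry)
#'
#' Thin wrapper over [simulation_config()] + [simulate_dataset()]: accepts a
#' named list (or YAML path) of `simulation_config()` arguments, plus
#' `out_dir`.
#'
#' @param cfg named list or YAML path of [simulation_config()] arguments
#' @param out_dir output directory
#' @param ... overrides of individual keys
#' @return invisibly, the [simulate_dataset()] result.
#' @export
pipeline_simulate <- function(cfg = list(), out_dir, ...) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  cfg <- utils::modifyList(as.list(cfg), list(...))
  if (!is.null(cfg$chrom_lengths)) cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  if (!is.null(cfg$rloop_category_probs)) {
    cfg$rloop_category_probs <- unlist(cfg$rloop_category_probs)
  }
  if (!is.null(cfg$multipliers)) cfg$multipliers <- unlist(cfg$multipliers)
  sim_cfg <- do.call(simulation_config, cfg)
  log_info("simulating dataset (seed %d) into %s", sim_cfg$seed, out_dir)
  res <- simulate_dataset(sim_cfg, out_dir)
  log_info("wrote %d R-loop peaks, %d repeat elements, %d genes",
           length(res$rloops),
           if (is.null(res$genome$catalog)) 0L else length(res$genome$catalog$elements),
           if (is.null(res$genome$models)) 0L else length(res$genome$models$genes))
  invisible(res)
}
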