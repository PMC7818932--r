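#' Configuration for the matched sampling control
#'
#' @param n_samples number of control groups to draw (the published analysis
#'   uses 1000)
#' @param seed RNG seed; the same seed always reproduces the same control
#'   groups
#' @param max_rejection_attempts rejection-sampling rounds per interval before
#'   the category-segment fallback placement kicks in
#' @param exclude_gaps avoid assembly gap intervals when the layout carries a
#'   gap track
#' @return a `SamplingConfig` list.
#' @export
sampling_config <- function(n_samples = 1000L, seed = 1L,
                            max_rejection_attempts = 1000L,
                            exclude_gaps = TRUE) {
  stopifnot(n_samples >= 1, max_rejection_attempts >= 1)
  structure(list(n_samples = as.integer(n_samples), seed = as.integer(seed),
                 max_rejection_attempts = as.integer(max_rejection_attempts),
                 exclude_gaps = isTRUE(exclude_gaps)),
            class = "SamplingConfig")
}

#' Genome control: the whole assembly as one peak set
#'
#' Background for the "R-loops fall uniformly in the genome" hypothesis: one
#' interval per chromosome covering it fully, minus assembly gaps when the
#' layout carries them and `exclude_gaps` is set.
#'
#' @param layout a [genome_layout()]
#' @param exclude_gaps drop gap intervals from the control
#' @return a `GRanges` covering the (non-gap) genome.
#' @export
genome_control <- function(layout, exclude_gaps = TRUE) {
  stopifnot(inherits(layout, "GenomeLayout"))
  gr <- GRanges(names(layout$lengths), IRanges(1L, unname(layout$lengths)))
  if (exclude_gaps && !is.null(layout$gaps) && length(layout$gaps)) {
    gr <- subtract_peaks(gr, layout$gaps)
  }
  metadata(gr)$provenance <- "genome-control"
  gr
}

#' GRO control: merged transcribed regions
#'
#' Background for the "R-loops form where transcription happens" hypothesis:
#' the GRO-seq transcribed regions themselves, merged across replicates, used
#' directly as the control sequence set.
#'
#' @param gro_peaks transcribed-region `GRanges` (replicates already combined
#'   with [merge_peaks()], or any peak set — it is merged again here)
#' @return merged `GRanges`.
#' @export
gro_control <- function(gro_peaks) {
  if (length(gro_peaks) == 0) stop("GRO control requires a non-empty transcribed-region set")
  out <- merge_peaks(gro_peaks)
  metadata(out)$provenance <- "gro-control"
  out
}

#' Matched sampling control
#'
#' Draws `cfg$n_samples` control groups from the genome, each preserving the
#' template peak set exactly in (i) number of intervals, (ii) the multiset of
#' interval lengths and (iii) each interval's genomic-location category under
#' the same priority rule ([assign_peak_category()]) that classified the
#' template. Placement is rejection sampling: a chromosome is chosen with
#' probability proportional to its length, a start uniformly among positions
#' where the interval fits, and the draw is accepted when its assigned
#' category matches the template's (and, with `exclude_gaps`, it avoids gap
#' intervals). A template that is still unplaced after
#' `max_rejection_attempts` rounds falls back to a uniformly chosen segment of
#' its category with a uniform start inside the segment (the interval may run
#' past the segment); one warning reports the fallback count. Sampling is with
#' replacement: control intervals may overlap each other.
#'
#' @param rloops template peak set (`GRanges`)
#' @param partition a [partition_genome()] result
#' @param layout a [genome_layout()]
#' @param cfg a [sampling_config()]
#' @param min_overlap_bases overlap threshold used for category assignment
#' @return a [GenomicRanges::GRangesList] of length `n_samples`; element `j`
#'   is control group `j` with intervals parallel to the template peaks.
#' @export
sample_matched_controls <- function(rloops, partition, layout,
                                    cfg = sampling_config(),
                                    min_overlap_bases = 1L) {
  stopifnot(inherits(partition, "RegionPartition"),
            inherits(layout, "GenomeLayout"),
            inherits(cfg, "SamplingConfig"))
  if (length(rloops) == 0) stop("template peak set is empty")
  tmpl_len <- width(rloops)
  tmpl_cat <- assign_peak_category(rloops, partition, min_overlap_bases)
  if (anyNA(tmpl_cat)) stop("a template peak could not be assigned a category")
  # zero available bases for a required category is unrecoverable
  for (cat in unique(tmpl_cat)) {
    if (total_bases(partition$categories[[cat]]) == 0) {
      stop("category '", cat, "' has zero available bases in the partition")
    }
  }
  n_tmpl <- length(rloops)
  len <- rep(tmpl_len, times = cfg$n_samples)
  target_rank <- rep(match(tmpl_cat, partition$priority), times = cfg$n_samples)
  gaps <- if (cfg$exclude_gaps) layout$gaps else NULL
  all_gr <- withr::with_seed(cfg$seed, {
    place_matched(len, target_rank, partition, layout, gaps = gaps,
                  max_rounds = cfg$max_rejection_attempts,
                  min_overlap = min_overlap_bases,
                  fallback_label = "control interval")
  })
  grp <- factor(rep(seq_len(cfg$n_samples), each = n_tmpl),
                levels = seq_len(cfg$n_samples))
  out <- GenomicRanges::split(all_gr, grp)
  names(out) <- sprintf("control-%04d", seq_len(cfg$n_samples))
  out
}
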