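#' Configuration for the synthetic-data generator
#'
#' Defines a complete synthetic study: a genome layout, non-overlapping genes
#' with exon structure, a two-level repeat catalog, an R-loop peak set with
#' controllable length/location structure and planted per-unit enrichments,
#' and GRO-style transcribed regions. Defaults give a toy-scale dataset
#' (2 x 500 kb chromosomes, 100 genes, ~1500 repeat elements, 500 peaks) that
#' mimics the shape of published DRIP-seq summaries: right-skewed log-normal
#' peak lengths with a median of 600 nt, promoter-heavy placement with 10% of
#' peaks intergenic.
#'
#' @param seed RNG seed; stages derive their streams from it (genome: `seed`,
#'   R-loops: `seed + 1`, GRO: `seed + 2`)
#' @param chrom_lengths named vector of chromosome lengths
#' @param n_genes number of non-overlapping genes
#' @param gene_len_meanlog,gene_len_sdlog log-normal gene length parameters
#' @param exon_lambda Poisson rate; a gene gets `1 + rpois(exon_lambda)` exons
#' @param repeats data.frame with columns `class`, `family`, `count`,
#'   `len_meanlog`, `len_sdlog` describing the repeat catalog
#' @param repeat_placement optional named list: family -> named probability
#'   vector over partition categories; families absent from the list are
#'   placed uniformly in the genome
#' @param n_rloops number of R-loop peaks
#' @param rloop_len_median,rloop_len_sdlog log-normal peak length parameters
#'   (median = `exp(meanlog)`)
#' @param rloop_category_probs named probability vector over the five
#'   categories, the planted genomic-location distribution
#' @param multipliers named numeric vector of planted enrichment multipliers
#'   (> 0) per repeat unit; 1 = no planted effect (the null)
#' @param multiplier_level `"class"` or `"family"`, the level `multipliers`
#'   names refer to
#' @param gro_fraction fraction of genes treated as transcribed
#' @param gro_flank bases of strand-aware downstream extension of transcribed
#'   gene spans (run-on transcription past the gene end)
#' @param flank promoter/terminator flank used for placement (2000)
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 500000L, chr2 = 500000L),
                              n_genes = 100L,
                              gene_len_meanlog = log(4000), gene_len_sdlog = 0.5,
                              exon_lambda = 2,
                              repeats = default_repeat_spec(),
                              repeat_placement = NULL,
                              n_rloops = 500L,
                              rloop_len_median = 600, rloop_len_sdlog = 0.6,
                              rloop_category_probs = c(promoter2k = 0.45,
                                                       terminator2k = 0.15,
                                                       exon = 0.15,
                                                       intron = 0.15,
                                                       intergenic = 0.10),
                              multipliers = NULL,
                              multiplier_level = c("class", "family"),
                              gro_fraction = 0.7, gro_flank = 500L,
                              flank = 2000L) {
  multiplier_level <- match.arg(multiplier_level)
  stopifnot(all(rloop_category_probs >= 0),
            abs(sum(rloop_category_probs) - 1) < 1e-8,
            gro_fraction >= 0, gro_fraction <= 1,
            is.null(multipliers) || all(multipliers > 0))
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_genes = as.integer(n_genes),
                 gene_len_meanlog = gene_len_meanlog,
                 gene_len_sdlog = gene_len_sdlog, exon_lambda = exon_lambda,
                 repeats = repeats, repeat_placement = repeat_placement,
                 n_rloops = as.integer(n_rloops),
                 rloop_len_median = rloop_len_median,
                 rloop_len_sdlog = rloop_len_sdlog,
                 rloop_category_probs = rloop_category_probs,
                 multipliers = multipliers, multiplier_level = multiplier_level,
                 gro_fraction = gro_fraction, gro_flank = as.integer(gro_flank),
                 flank = as.integer(flank)),
            class = "SimulationConfig")
}

#' Default synthetic repeat catalog specification
#'
#' A small class -> family hierarchy echoing the RepeatMasker taxonomy
#' (LINE/SINE/LTR/DNA transposons, simple and low-complexity repeats,
#' satellites, RC, structural RNAs, retroposons), with counts and log-normal
#' element lengths giving roughly 1500 elements on the default 1 Mb genome.
#' @return data.frame with columns `class`, `family`, `count`, `len_meanlog`,
#'   `len_sdlog`.
#' @export
default_repeat_spec <- function() {
  data.frame(
    class = c("LINE", "LINE", "SINE", "SINE", "LTR", "LTR", "DNA", "DNA",
              "Simple_repeat", "Low_complexity", "Satellite", "Satellite",
              "RC", "rRNA", "snRNA", "Retroposon"),
    family = c("L1", "CR1", "Alu", "MIR", "Gypsy", "Copia", "TcMar-Tc1", "hAT",
               "Simple_repeat", "Low_complexity", "centr", "telo",
               "Helitron", "rRNA", "snRNA", "SVA"),
    count = c(150L, 80L, 200L, 100L, 120L, 80L, 80L, 70L,
              250L, 200L, 60L, 40L, 40L, 30L, 30L, 30L),
    len_meanlog = c(log(800), log(400), log(300), log(200), log(500), log(450),
                    log(300), log(250), log(120), log(150), log(600), log(400),
                    log(300), log(200), log(150), log(700)),
    len_sdlog = c(0.6, 0.5, 0.3, 0.3, 0.5, 0.5, 0.4, 0.4,
                  0.5, 0.5, 0.5, 0.5, 0.4, 0.4, 0.3, 0.5)
  )
}

# uniform draw of (chrom, start) such that an interval of length len fits;
# chromosome chosen proportional to length
draw_positions <- function(n, len, layout) {
  chrom_len <- unname(layout$lengths)
  ci <- sample.int(length(chrom_len), n, replace = TRUE, prob = chrom_len)
  room <- chrom_len[ci] - len + 1
  ok <- room >= 1
  start <- floor(stats::runif(n) * pmax(room, 1)) + 1
  list(ci = ci, start = ifelse(ok, start, NA), ok = ok)
}

# rejection placement into target categories (see place_matched)
place_by_category <- function(len, target, partition, layout,
                              accept_prob_fn = NULL, max_rounds = 500L) {
  place_matched(len, match(target, partition$priority), partition, layout,
                accept_prob_fn = accept_prob_fn, max_rounds = max_rounds)
}

#' Simulate a genome: layout, gene models and repeat catalog
#'
#' Places `n_genes` non-overlapping genes uniformly (length log-normal, random
#' strand, exon chains with first/last segments exonic), then places repeat
#' elements: uniformly in the genome by default, or — for families named in
#' `repeat_placement` — into partition categories drawn from the given
#' weights. Deterministic for a fixed `cfg$seed`.
#'
#' @param cfg a [simulation_config()]
#' @return list with `layout` ([genome_layout()]), `models` ([gene_models()]
#'   or `NULL` when `n_genes = 0`), `catalog` ([repeat_catalog()] or `NULL`
#'   when the repeat spec is empty) and `partition` (the five-category
#'   [partition_genome()] of the simulated genes).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  layout <- genome_layout(cfg$chrom_lengths)
  withr::with_seed(cfg$seed, {
    models <- simulate_genes(cfg, layout)
    partition <- partition_genome(
      if (is.null(models)) list() else models, layout, flank = cfg$flank)
    catalog <- simulate_repeats(cfg, layout, partition)
  })
  list(layout = layout, models = models, catalog = catalog,
       partition = partition)
}

simulate_genes <- function(cfg, layout) {
  if (cfg$n_genes == 0) return(NULL)
  glen <- pmax(200, round(stats::rlnorm(cfg$n_genes, cfg$gene_len_meanlog,
                                        cfg$gene_len_sdlog)))
  if (sum(glen) > genome_size(layout)) {
    stop("requested gene bases exceed the genome size")
  }
  placed <- GRanges()
  res <- vector("list", cfg$n_genes)
  pending <- order(glen, decreasing = TRUE)  # big genes first pack better
  rounds <- 0L
  pos_chr <- integer(cfg$n_genes); pos_start <- integer(cfg$n_genes)
  while (length(pending) && rounds < 2000L) {
    d <- draw_positions(length(pending), glen[pending], layout)
    idx <- which(d$ok)
    if (length(idx)) {
      cand <- GRanges(names(layout$lengths)[d$ci[idx]],
                      IRanges(d$start[idx], width = glen[pending][idx]))
      # reject overlap with already-placed genes and with earlier candidates
      # of this round
      clash <- IRanges::overlapsAny(cand, placed, ignore.strand = TRUE)
      self <- findOverlaps(cand, ignore.strand = TRUE, drop.self = TRUE)
      dup <- unique(queryHits(self)[queryHits(self) > subjectHits(self)])
      clash[dup] <- TRUE
      acc <- idx[!clash]
      if (length(acc)) {
        gi <- pending[acc]
        pos_chr[gi] <- d$ci[acc]
        pos_start[gi] <- d$start[acc]
        placed <- merge_peaks(suppressWarnings(c(
          placed, GRanges(names(layout$lengths)[d$ci[acc]],
                          IRanges(d$start[acc], width = glen[gi])))))
        pending <- pending[-acc]
      }
    }
    rounds <- rounds + 1L
  }
  if (length(pending)) stop("could not place all genes without overlap; ",
                            "reduce n_genes or gene lengths")
  g <- GRanges(names(layout$lengths)[pos_chr],
               IRanges(pos_start, width = glen),
               strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE))
  mcols(g)$gene_id <- sprintf("gene%04d", seq_len(cfg$n_genes))
  # exon chains: 2k-1 alternating segments inside the span, exons at the ends
  exon_list <- vector("list", cfg$n_genes)
  n_ex <- 1L + stats::rpois(cfg$n_genes, cfg$exon_lambda)
  for (i in seq_len(cfg$n_genes)) {
    w <- width(g)[i]
    k <- n_ex[i]
    if (w < 2L * k * 2L) k <- 1L  # too short to cut: single exon
    if (k == 1L) {
      exon_list[[i]] <- data.frame(s = start(g)[i], e = end(g)[i])
    } else {
      cuts <- sort(sample.int(w - 1L, 2L * (k - 1L)))
      bounds <- c(0L, cuts, w)
      seg_s <- start(g)[i] + bounds[-length(bounds)]
      seg_e <- start(g)[i] + bounds[-1] - 1L
      is_exon <- seq_along(seg_s) %% 2L == 1L
      exon_list[[i]] <- data.frame(s = seg_s[is_exon], e = seg_e[is_exon])
    }
  }
  nex <- vapply(exon_list, nrow, 0L)
  ex <- GRanges(rep(as.character(GenomeInfoDb::seqnames(g)), nex),
                IRanges(unlist(lapply(exon_list, `[[`, "s")),
                        unlist(lapply(exon_list, `[[`, "e"))))
  mcols(ex)$gene_id <- rep(mcols(g)$gene_id, nex)
  gene_models(g, ex)
}

simulate_repeats <- function(cfg, layout, partition) {
  spec <- cfg$repeats
  if (is.null(spec) || nrow(spec) == 0) return(NULL)
  parts <- vector("list", nrow(spec))
  for (r in seq_len(nrow(spec))) {
    n <- spec$count[r]
    if (n == 0) next
    len <- pmax(20, round(stats::rlnorm(n, spec$len_meanlog[r],
                                        spec$len_sdlog[r])))
    len <- pmin(len, min(layout$lengths))
    wts <- cfg$repeat_placement[[spec$family[r]]]
    if (is.null(wts)) {
      repeat {
        d <- draw_positions(n, len, layout)
        if (all(d$ok)) break
      }
      gr <- GRanges(names(layout$lengths)[d$ci], IRanges(d$start, width = len))
    } else {
      stopifnot(all(names(wts) %in% partition$priority))
      target <- sample(names(wts), n, replace = TRUE, prob = wts)
      gr <- place_by_category(len, target, partition, layout)
    }
    mcols(gr)$rep_name <- sprintf("%s-%d", spec$family[r], seq_len(n))
    mcols(gr)$rep_class <- spec$class[r]
    mcols(gr)$rep_family <- spec$family[r]
    parts[[r]] <- gr
  }
  parts <- parts[!vapply(parts, is.null, TRUE)]
  repeat_catalog(suppressWarnings(do.call(c, parts)))
}

#' Simulate R-loop peaks with planted enrichments
#'
#' Draws peak lengths from a log-normal with the configured median, draws each
#' peak's location category from the configured probabilities, and places the
#' peak by rejection sampling under exactly the rule the sampling control
#' uses: uniform in the genome, accepted when [assign_peak_category()] returns
#' the drawn category. Planted multipliers bias acceptance within the chosen
#' category — a candidate overlapping unit `k`'s elements is accepted with
#' relative weight `multipliers[k]` — so a multiplier of 1 reproduces the null
#' exactly and the emitted annotations remain internally consistent.
#'
#' @param cfg a [simulation_config()]
#' @param genome output of [simulate_genome()]
#' @return list with `peaks` (`GRanges`, provenance `"rloop"`) and
#'   `ground_truth` (the planted multipliers, level, category probabilities
#'   and length parameters).
#' @export
simulate_rloops <- function(cfg, genome) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  partition <- genome$partition
  mult <- cfg$multipliers
  accept_fn <- NULL
  if (!is.null(mult) && length(mult)) {
    if (is.null(genome$catalog)) stop("multipliers given but the genome has no repeats")
    units <- repeat_units(genome$catalog, cfg$multiplier_level)
    missing_units <- setdiff(names(mult), units)
    if (length(missing_units)) {
      stop("multiplier for repeat unit(s) with zero elements: ",
           paste(missing_units, collapse = ", "))
    }
    unit_grs <- lapply(names(mult), function(k)
      unit_ranges(genome$catalog, cfg$multiplier_level, k))
    w_cap <- prod(pmax(mult, 1))
    accept_fn <- function(cand) {
      w <- rep(1, length(cand))
      for (u in seq_along(mult)) {
        al <- align_seqlevels(cand, unit_grs[[u]])
        hit <- IRanges::overlapsAny(al$a, al$b, ignore.strand = TRUE)
        w[hit] <- w[hit] * mult[u]
      }
      w / w_cap
    }
  }
  withr::with_seed(cfg$seed + 1L, {
    len <- pmax(50, round(stats::rlnorm(cfg$n_rloops,
                                        log(cfg$rloop_len_median),
                                        cfg$rloop_len_sdlog)))
    len <- pmin(len, min(genome$layout$lengths))
    probs <- cfg$rloop_category_probs
    target <- sample(names(probs), cfg$n_rloops, replace = TRUE, prob = probs)
    peaks <- place_by_category(len, target, partition, genome$layout,
                               accept_prob_fn = accept_fn)
  })
  mcols(peaks)$name <- sprintf("rloop%04d", seq_along(peaks))
  peaks <- validate_peaks(peaks, genome$layout)
  metadata(peaks)$provenance <- "rloop"
  gt <- list(multipliers = as.list(if (is.null(mult)) stats::setNames(numeric(0), character(0)) else mult),
             multiplier_level = cfg$multiplier_level,
             category_probs = as.list(cfg$rloop_category_probs),
             rloop_len_median = cfg$rloop_len_median,
             rloop_len_sdlog = cfg$rloop_len_sdlog,
             n_rloops = cfg$n_rloops, seed = cfg$seed)
  list(peaks = sort_peaks(peaks), ground_truth = gt)
}

#' Simulate GRO-seq transcribed regions
#'
#' Marks a random `gro_fraction` of genes as transcribed, extends each
#' transcribed span downstream (strand-aware) by `gro_flank` bases, clips at
#' chromosome ends and merges.
#'
#' @param cfg a [simulation_config()]
#' @param genome output of [simulate_genome()]
#' @return list with `peaks` (merged `GRanges`, provenance `"gro"`; may be
#'   empty when `gro_fraction = 0`) and `transcribed_gene_ids`.
#' @export
simulate_gro <- function(cfg, genome) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (is.null(genome$models) || length(genome$models$genes) == 0) {
    return(list(peaks = GRanges(), transcribed_gene_ids = character()))
  }
  g <- genome$models$genes
  withr::with_seed(cfg$seed + 2L, {
    n_tx <- round(cfg$gro_fraction * length(g))
    sel <- sort(sample.int(length(g), n_tx))
  })
  tx <- g[sel]
  if (length(tx) && cfg$gro_flank > 0) {
    plus <- as.character(strand(tx)) != "-"
    e <- end(tx); s <- start(tx)
    chr <- as.character(GenomeInfoDb::seqnames(tx))
    e[plus] <- pmin(e[plus] + cfg$gro_flank,
                    unname(genome$layout$lengths[chr[plus]]))
    s[!plus] <- pmax(s[!plus] - cfg$gro_flank, 1L)
    tx <- GRanges(chr, IRanges(s, e))
  }
  peaks <- merge_peaks(tx)
  metadata(peaks)$provenance <- "gro"
  list(peaks = peaks,
       transcribed_gene_ids = mcols(g)$gene_id[sel])
}

#' Simulate a complete dataset and write it to disk
#'
#' Runs [simulate_genome()], [simulate_rloops()] and [simulate_gro()] and
#' writes `chrom.sizes`, `genes.gtf`, `repeats.tsv` (UCSC rmsk dialect),
#' `rloops.bed`, `gro.bed` and `ground_truth.json` into `dir`. Every file
#' round-trips through this package's own readers; byte-identical for a fixed
#' seed.
#'
#' @param cfg a [simulation_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, a list with the in-memory objects and the file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- simulate_genome(cfg)
  rl <- simulate_rloops(cfg, genome)
  gro <- simulate_gro(cfg, genome)
  paths <- list(chrom_sizes = file.path(dir, "chrom.sizes"),
                genes = file.path(dir, "genes.gtf"),
                repeats = file.path(dir, "repeats.tsv"),
                rloops = file.path(dir, "rloops.bed"),
                gro = file.path(dir, "gro.bed"),
                ground_truth = file.path(dir, "ground_truth.json"))
  write_chrom_sizes(genome$layout, paths$chrom_sizes)
  if (!is.null(genome$models)) write_gtf(genome$models, paths$genes)
  else writeLines(character(0), paths$genes)
  if (!is.null(genome$catalog)) write_rmsk_table(genome$catalog, paths$repeats)
  write_bed(rl$peaks, paths$rloops)
  write_bed(gro$peaks, paths$gro)
  gt <- rl$ground_truth
  gt$transcribed_gene_ids <- gro$transcribed_gene_ids
  gt$gro_fraction <- cfg$gro_fraction
  writeLines(jsonlite::toJSON(gt, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths$ground_truth)
  invisible(list(genome = genome, rloops = rl$peaks,
                 ground_truth = gt, gro = gro$peaks, paths = paths))
}
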