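#' Partition a genome into labeled region categories
#'
#' Assigns every base of the genome to exactly one category by a priority
#' rule. The default five-category scheme is
#' `promoter2k > terminator2k > exon > intron > intergenic`, where promoter2k
#' is the `flank` bases immediately upstream of a gene start (strand-aware),
#' terminator2k the `flank` bases downstream of the gene end, intron the gene
#' body minus exons, and intergenic the remainder. Flanks are clipped at
#' chromosome ends. A base claimed by several categories (e.g. an exon of one
#' gene inside the promoter flank of another) goes to the highest-priority
#' category. A three-category variant `promoter2k > gene > intergenic` (with
#' `gene` = merged gene spans) is available by passing that priority.
#'
#' @param models a [gene_models()] object (may contain zero genes, in which
#'   case the whole genome is intergenic)
#' @param layout a [genome_layout()]
#' @param flank flank size in bases for promoter/terminator (default 2000)
#' @param priority character vector of categories, highest priority first; the
#'   last entry must be `"intergenic"`. Recognised categories: `promoter2k`,
#'   `terminator2k`, `exon`, `intron`, `gene`, `intergenic`.
#' @return an object of class `RegionPartition` with fields `categories`
#'   (named list of disjoint merged `GRanges` covering the genome), `priority`,
#'   `flank`, `layout` and `combined` (one `GRanges` with a `category` column).
#' @export
partition_genome <- function(models, layout, flank = 2000L,
                             priority = c("promoter2k", "terminator2k",
                                          "exon", "intron", "intergenic")) {
  stopifnot(inherits(layout, "GenomeLayout"), flank >= 0)
  known <- c("promoter2k", "terminator2k", "exon", "intron", "gene", "intergenic")
  if (!all(priority %in% known)) {
    stop("unknown category: ", setdiff(priority, known)[1])
  }
  if (priority[length(priority)] != "intergenic") {
    stop("the lowest-priority category must be 'intergenic'")
  }
  genome_gr <- GRanges(names(layout$lengths),
                       IRanges(1L, unname(layout$lengths)))
  empty <- GRanges()
  if (inherits(models, "GeneModels") && length(models$genes) > 0) {
    g <- models$genes
    chr <- as.character(GenomeInfoDb::seqnames(g))
    plus <- as.character(strand(g)) != "-"
    # strand-aware flanks, clipped at chromosome ends rather than discarded
    flank_of <- function(upstream) {
      if (flank == 0) return(GRanges())
      left <- xor(upstream, !plus)   # + upstream and - downstream sit left
      s <- ifelse(left, start(g) - flank, end(g) + 1L)
      e <- ifelse(left, start(g) - 1L, end(g) + flank)
      s <- pmax(s, 1L)
      e <- pmin(e, unname(layout$lengths[chr]))
      keep <- s <= e
      merge_peaks(GRanges(chr[keep], IRanges(s[keep], e[keep])))
    }
    exon_gr <- merge_peaks(unlist(models$exons))
    span_gr <- merge_peaks(g)
    declared <- list(promoter2k = flank_of(upstream = TRUE),
                     terminator2k = flank_of(upstream = FALSE),
                     exon = exon_gr,
                     intron = subtract_peaks(span_gr, exon_gr),
                     gene = span_gr)
  } else {
    declared <- list(promoter2k = empty, terminator2k = empty, exon = empty,
                     intron = empty, gene = empty)
  }
  categories <- vector("list", length(priority))
  names(categories) <- priority
  taken <- GRanges()
  for (cat in priority) {
    if (cat == "intergenic") {
      cur <- subtract_peaks(genome_gr, taken)
    } else {
      cur <- subtract_peaks(declared[[cat]], taken)
    }
    categories[[cat]] <- cur
    taken <- merge_peaks(suppressWarnings(c(taken, cur)))
  }
  combined <- suppressWarnings(do.call(c, unname(Map(function(gr, cat) {
    if (length(gr)) mcols(gr)$category <- cat
    gr
  }, categories, names(categories)))))
  structure(list(categories = categories, priority = priority,
                 flank = as.integer(flank), layout = layout,
                 combined = combined),
            class = "RegionPartition")
}

#' @export
print.RegionPartition <- function(x, ...) {
  tot <- genome_size(x$layout)
  for (cat in x$priority) {
    b <- total_bases(x$categories[[cat]])
    cat(sprintf("  %-12s %12s bases (%.1f%%)\n", cat,
                format(b, big.mark = ","), 100 * b / tot))
  }
  invisible(x)
}

# The partition's segments tile each chromosome contiguously, so the
# categories overlapped by [s, e] are exactly the segments between
# findInterval(s) and findInterval(e); the assigned category is the best
# priority rank among them. This index answers that query on plain vectors,
# which keeps the rejection-sampling hot loops off the GRanges path.
build_category_index <- function(partition) {
  comb <- partition$combined
  chr <- as.character(GenomeInfoDb::seqnames(comb))
  rank <- match(mcols(comb)$category, partition$priority)
  idx <- list()
  for (cn in names(partition$layout$lengths)) {
    sel <- chr == cn
    o <- order(start(comb)[sel])
    idx[[cn]] <- list(starts = start(comb)[sel][o],
                      ends = end(comb)[sel][o],
                      rank = rank[sel][o])
  }
  attr(idx, "n_ranks") <- length(partition$priority)
  idx
}

# chr: character vector; s, e: 1-based closed coordinates within bounds.
# Returns the priority rank (integer) of the assigned category; NA where no
# category accumulates min_overlap bases (possible only for min_overlap > 1).
assign_rank_fast <- function(index, chr, s, e, min_overlap = 1L) {
  out <- rep(NA_integer_, length(s))
  n_ranks <- attr(index, "n_ranks")
  for (cn in unique(chr)) {
    sel <- which(chr == cn)
    st <- index[[cn]]$starts
    en <- index[[cn]]$ends
    rk <- index[[cn]]$rank
    i1 <- findInterval(s[sel], st)
    i2 <- findInterval(e[sel], st)
    if (min_overlap == 1L) {
      r <- rk[i1]
      k <- 1L
      repeat {
        more <- i1 + k <= i2
        if (!any(more)) break
        r[more] <- pmin(r[more], rk[i1[more] + k])
        k <- k + 1L
      }
      out[sel] <- r
    } else {
      acc <- matrix(0, nrow = length(sel), ncol = n_ranks)
      k <- 0L
      repeat {
        at <- which(i1 + k <= i2)
        if (!length(at)) break
        j <- i1[at] + k
        ov <- pmin(e[sel][at], en[j]) - pmax(s[sel][at], st[j]) + 1
        acc[cbind(at, rk[j])] <- acc[cbind(at, rk[j])] + ov
        k <- k + 1L
      }
      pass <- acc >= min_overlap
      r <- apply(pass, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
      out[sel] <- r
    }
  }
  out
}

# gap index: per chromosome the sorted (merged) gap starts/ends; an interval
# [s, e] hits a gap iff the last gap starting at or before e ends at or past s
build_gap_index <- function(gaps, layout) {
  if (is.null(gaps) || length(gaps) == 0) return(NULL)
  gch <- as.character(GenomeInfoDb::seqnames(gaps))
  idx <- lapply(stats::setNames(nm = names(layout$lengths)), function(cn) {
    sel <- gch == cn
    o <- order(start(gaps)[sel])
    list(starts = start(gaps)[sel][o], ends = end(gaps)[sel][o])
  })
  idx
}

gap_overlap_fast <- function(gap_index, chr, s, e) {
  hit <- logical(length(s))
  for (cn in unique(chr)) {
    gi <- gap_index[[cn]]
    if (is.null(gi) || length(gi$starts) == 0) next
    sel <- which(chr == cn)
    j <- findInterval(e[sel], gi$starts)
    hit[sel] <- j >= 1 & gi$ends[pmax(j, 1)] >= s[sel]
  }
  hit
}

# shared rejection-placement engine: draw (chromosome proportional to length,
# start uniform among fitting positions) until the assigned category rank
# matches target_rank, optionally avoiding gaps and thinning accepted draws
# with accept_prob_fn (planted enrichment); after max_rounds, fall back to a
# uniformly chosen segment of the target category. Caller seeds the RNG.
place_matched <- function(len, target_rank, partition, layout, gaps = NULL,
                          accept_prob_fn = NULL, max_rounds = 1000L,
                          min_overlap = 1L, fallback_label = "interval") {
  index <- build_category_index(partition)
  gap_index <- build_gap_index(gaps, layout)
  chrom_names <- names(layout$lengths)
  chrom_len <- as.numeric(unname(layout$lengths))
  n <- length(len)
  res_chr <- integer(n)
  res_start <- numeric(n)
  pending <- seq_len(n)
  rounds <- 0L
  while (length(pending) && rounds < max_rounds) {
    m <- length(pending)
    ci <- sample.int(length(chrom_len), m, replace = TRUE, prob = chrom_len)
    room <- chrom_len[ci] - len[pending] + 1
    s <- floor(stats::runif(m) * pmax(room, 1)) + 1
    e <- s + len[pending] - 1
    ok <- which(room >= 1)
    rounds <- rounds + 1L
    if (!length(ok)) next
    rk <- assign_rank_fast(index, chrom_names[ci[ok]], s[ok], e[ok], min_overlap)
    cand <- ok[!is.na(rk) & rk == target_rank[pending[ok]]]
    if (!is.null(gap_index) && length(cand)) {
      hit <- gap_overlap_fast(gap_index, chrom_names[ci[cand]], s[cand], e[cand])
      cand <- cand[!hit]
    }
    if (!is.null(accept_prob_fn) && length(cand)) {
      gr <- GRanges(chrom_names[ci[cand]], IRanges(s[cand], e[cand]))
      pr <- accept_prob_fn(gr)
      cand <- cand[stats::runif(length(cand)) < pr]
    }
    if (length(cand)) {
      gi <- pending[cand]
      res_chr[gi] <- ci[cand]
      res_start[gi] <- s[cand]
      pending <- pending[-cand]
    }
  }
  if (length(pending)) {
    warning(length(pending), " ", fallback_label,
            "(s) placed by category-segment fallback")
    for (i in pending) {
      cat_name <- partition$priority[target_rank[i]]
      seg <- partition$categories[[cat_name]]
      if (length(seg) == 0) stop("category '", cat_name, "' has no segments")
      j <- sample.int(length(seg), 1L)
      chr <- as.character(GenomeInfoDb::seqnames(seg))[j]
      st <- start(seg)[j] + floor(stats::runif(1) * width(seg)[j])
      st <- max(1, min(st, layout$lengths[[chr]] - len[i] + 1))
      res_chr[i] <- match(chr, chrom_names)
      res_start[i] <- st
    }
  }
  GRanges(chrom_names[res_chr], IRanges(res_start, width = len))
}

# vectorised category assignment; returns character (NA when no category
# reaches min_overlap_bases, only possible for min_overlap_bases > 1)
assign_category_batch <- function(gr, partition, min_overlap_bases = 1L) {
  stopifnot(inherits(partition, "RegionPartition"), min_overlap_bases >= 1)
  out <- rep(NA_character_, length(gr))
  if (length(gr) == 0) return(out)
  part <- partition$combined
  al <- align_seqlevels(gr, part)
  hits <- findOverlaps(al$a, al$b, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  q <- queryHits(hits); s <- subjectHits(hits)
  rank <- match(mcols(part)$category[s], partition$priority)
  if (min_overlap_bases == 1L) {
    ord <- order(q, rank)
    first <- !duplicated(q[ord])
    out[q[ord][first]] <- partition$priority[rank[ord][first]]
    return(out)
  }
  ov <- pmin(end(al$a)[q], end(al$b)[s]) - pmax(start(al$a)[q], start(al$b)[s]) + 1
  key <- paste(q, rank)
  agg <- rowsum(ov, key)
  kq <- as.integer(sub(" .*", "", rownames(agg)))
  kr <- as.integer(sub(".* ", "", rownames(agg)))
  pass <- agg[, 1] >= min_overlap_bases
  kq <- kq[pass]; kr <- kr[pass]
  ord <- order(kq, kr)
  first <- !duplicated(kq[ord])
  out[kq[ord][first]] <- partition$priority[kr[ord][first]]
  out
}

#' Assign a peak to a region category
#'
#' Returns the highest-priority category of the partition that the peak
#' overlaps by at least `min_overlap_bases` bases. With the default threshold
#' of 1 and a full partition, every in-bounds peak gets a category.
#'
#' @param peaks `GRanges` of one or more peaks
#' @param partition a [partition_genome()] result
#' @param min_overlap_bases minimum shared bases to count an overlap
#' @return character vector of categories, parallel to `peaks`.
#' @export
assign_peak_category <- function(peaks, partition, min_overlap_bases = 1L) {
  assign_category_batch(peaks, partition, min_overlap_bases)
}

#' Genomic distribution of a peak set
#'
#' Fraction of peaks (by count, one vote per peak via
#' [assign_peak_category()]) falling in each category of the partition.
#'
#' @inheritParams assign_peak_category
#' @return named numeric vector over the partition's categories, summing to 1.
#' @export
genomic_distribution <- function(peaks, partition, min_overlap_bases = 1L) {
  if (length(peaks) == 0) stop("cannot compute a distribution of zero peaks")
  cat <- assign_peak_category(peaks, partition, min_overlap_bases)
  tab <- table(factor(cat, levels = partition$priority))
  stats::setNames(as.numeric(tab) / length(peaks), partition$priority)
}

#' Base-level three-set Venn of R-loops, transcribed regions and genes
#'
#' Computes the seven exclusive cell sizes (in bases) of the three merged
#' sets, plus the percentage of R-loop bases covered by transcribed regions
#' (the headline co-transcriptionality number).
#'
#' @param rloops,transcribed,genes `GRanges` (each merged internally)
#' @return list with `cells` (named numeric vector of the 7 exclusive base
#'   counts: `rloop_only`, `transcribed_only`, `gene_only`,
#'   `rloop_transcribed`, `rloop_gene`, `transcribed_gene`, `all_three`) and
#'   `pct_rloop_in_transcribed` (`NA` when `rloops` is empty).
#' @export
venn_bases <- function(rloops, transcribed, genes) {
  r <- merge_peaks(rloops); t <- merge_peaks(transcribed); g <- merge_peaks(genes)
  rt <- intersect_bases(r, t)
  rg <- intersect_bases(r, g)
  tg <- intersect_bases(t, g)
  al <- align_seqlevels(r, t)
  rt_gr <- GenomicRanges::intersect(al$a, al$b, ignore.strand = TRUE)
  rtg <- intersect_bases(rt_gr, g)
  cells <- c(
    rloop_only = total_bases(r) - rt - rg + rtg,
    transcribed_only = total_bases(t) - rt - tg + rtg,
    gene_only = total_bases(g) - rg - tg + rtg,
    rloop_transcribed = rt - rtg,
    rloop_gene = rg - rtg,
    transcribed_gene = tg - rtg,
    all_three = rtg
  )
  pct <- if (total_bases(r) == 0) NA_real_ else 100 * rt / total_bases(r)
  list(cells = cells, pct_rloop_in_transcribed = pct)
}
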