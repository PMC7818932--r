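# Independent per-base oracles used to verify the interval algebra, the
# genome partition and the statistics. Everything here works on plain logical
# / integer vectors indexed by base position (1-based), deliberately avoiding
# the GRanges code paths under test.

suppressPackageStartupMessages({
  library(GenomicRanges)
})

# bind explicitly: seqnames lives in GenomeInfoDb and is not on the package's
# import list, so source-mode test loading does not see it otherwise
seqnames <- GenomeInfoDb::seqnames

# per-chromosome boolean occupancy vectors for a GRanges
bitmap_from_gr <- function(gr, lengths) {
  bm <- lapply(lengths, function(L) logical(L))
  if (length(gr)) {
    chr <- as.character(seqnames(gr))
    for (i in seq_along(gr)) {
      bm[[chr[i]]][start(gr)[i]:end(gr)[i]] <- TRUE
    }
  }
  bm
}

bitmap_count <- function(bm) sum(vapply(bm, sum, 0))

bitmap_and <- function(a, b) Map(`&`, a, b)
bitmap_andnot <- function(a, b) Map(function(x, y) x & !y, a, b)

# merged intervals reconstructed from a bitmap (runs of TRUE)
bitmap_to_df <- function(bm) {
  out <- lapply(names(bm), function(cn) {
    r <- rle(bm[[cn]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = cn, start = as.integer(starts[keep]),
               end = as.integer(ends[keep]))
  })
  res <- do.call(rbind, out)
  if (!is.null(res)) {
    res <- res[order(res$chrom, res$start), , drop = FALSE]
    rownames(res) <- NULL
  }
  res
}

gr_to_df <- function(gr) {
  if (length(gr) == 0) return(NULL)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = as.integer(start(gr)), end = as.integer(end(gr)))
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

expect_same_intervals <- function(gr, df_expected) {
  got <- gr_to_df(gr)
  if (is.null(df_expected)) {
    expect_true(is.null(got) || nrow(got) == 0)
  } else {
    rownames(got) <- rownames(df_expected) <- NULL
    expect_equal(got, df_expected[order(df_expected$chrom, df_expected$start), ,
                                  drop = FALSE],
                 ignore_attr = TRUE)
  }
}

# random peak set on a toy genome
random_peaks <- function(n, lengths, max_len = 2000, min_len = 1) {
  chr <- sample(names(lengths), n, replace = TRUE)
  len <- sample(seq(min_len, max_len), n, replace = TRUE)
  len <- pmin(len, lengths[chr])
  start0 <- floor(runif(n) * (lengths[chr] - len + 1))  # 0-based
  peak_set(chr, start0, start0 + len)
}

# brute-force per-base category rank scan, independent of partition_genome():
# claims each category's bases by direct coordinate arithmetic and takes the
# best priority rank per base
brute_partition_ranks <- function(models, lengths, flank = 2000,
                                  priority = c("promoter2k", "terminator2k",
                                               "exon", "intron", "intergenic")) {
  n_rank <- length(priority)
  ranks <- lapply(lengths, function(L) rep.int(n_rank, L))  # intergenic default
  claim <- function(cat, chrom, s, e) {
    r <- match(cat, priority)
    if (is.na(r)) return()
    s <- max(1, s); e <- min(lengths[[chrom]], e)
    if (s > e) return()
    seg <- ranks[[chrom]][s:e]
    ranks[[chrom]][s:e] <<- pmin(seg, r)
  }
  if (!is.null(models) && length(models$genes)) {
    g <- models$genes
    for (i in seq_along(g)) {
      chrom <- as.character(seqnames(g))[i]
      gs <- start(g)[i]; ge <- end(g)[i]
      plus <- as.character(strand(g))[i] != "-"
      if (plus) {
        claim("promoter2k", chrom, gs - flank, gs - 1)
        claim("terminator2k", chrom, ge + 1, ge + flank)
      } else {
        claim("promoter2k", chrom, ge + 1, ge + flank)
        claim("terminator2k", chrom, gs - flank, gs - 1)
      }
      ex <- models$exons[[i]]
      exonic <- logical(ge - gs + 1)
      for (j in seq_along(ex)) {
        exonic[(start(ex)[j]:end(ex)[j]) - gs + 1] <- TRUE
      }
      claim("gene", chrom, gs, ge)
      for (p in which(exonic)) claim("exon", chrom, gs + p - 1, gs + p - 1)
      for (p in which(!exonic)) claim("intron", chrom, gs + p - 1, gs + p - 1)
    }
  }
  ranks
}

# per-base rank vector of a computed RegionPartition
partition_ranks <- function(partition, lengths) {
  ranks <- lapply(lengths, function(L) rep.int(NA_integer_, L))
  for (cat in partition$priority) {
    r <- match(cat, partition$priority)
    gr <- partition$categories[[cat]]
    if (length(gr) == 0) next
    chr <- as.character(seqnames(gr))
    for (i in seq_along(gr)) {
      ranks[[chr[i]]][start(gr)[i]:end(gr)[i]] <- r
    }
  }
  ranks
}

# brute-force peak category: walk the priority order, first category sharing
# >= min_overlap bases with the peak wins
brute_peak_category <- function(peak_chrom, peak_s, peak_e, rank_vec, priority,
                                min_overlap = 1) {
  v <- rank_vec[[peak_chrom]][peak_s:peak_e]
  for (r in seq_along(priority)) {
    if (sum(v == r) >= min_overlap) return(priority[r])
  }
  NA_character_
}

# independent two-pass mean / sd
twopass_mean_sd <- function(x) {
  m <- sum(x) / length(x)
  v <- sum((x - m)^2) / (length(x) - 1)
  c(mean = m, sd = sqrt(v))
}

# small deterministic gene set for annotation tests
toy_gene_models <- function() {
  g <- GRanges(c("chrA", "chrA", "chrB"),
               IRanges(c(5001, 12001, 2001), c(8000, 15000, 6000)),
               strand = c("+", "-", "+"))
  mcols(g)$gene_id <- c("g1", "g2", "g3")
  ex <- GRanges(c("chrA", "chrA", "chrA", "chrB"),
                IRanges(c(5001, 7001, 12001, 2001), c(5500, 8000, 15000, 6000)))
  mcols(ex)$gene_id <- c("g1", "g1", "g2", "g3")
  suppressWarnings(gene_models(g, ex))
}

toy_layout <- function() genome_layout(c(chrA = 20000L, chrB = 10000L))
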