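test_that("rmsk table dialect parses, validates and round-trips", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("genoName\tgenoStart\tgenoEnd\trepName\trepClass\trepFamily",
               "chrT\t100\t160\t(AT)n\tSimple_repeat\tSimple_repeat"), f)
  cat <- read_repeats(f, "ucsc_rmsk")
  expect_equal(length(cat$elements), 1)
  expect_equal(start(cat$elements), 101)   # 0-based half-open converted
  expect_equal(end(cat$elements), 160)
  expect_equal(repeat_units(cat, "class"), "Simple_repeat")

  writeLines(c("genoName\tgenoStart\tgenoEnd\trepName\trepClass",
               "chrT\t100\t160\tx\tLINE"), f)
  expect_error(read_repeats(f, "ucsc_rmsk"), "repFamily")
  writeLines(c("genoName\tgenoStart\tgenoEnd\trepName\trepClass\trepFamily",
               "chrT\t160\t100\tx\tLINE\tL1"), f)
  expect_error(read_repeats(f, "ucsc_rmsk"), "line 2")

  # simulated catalog round-trip: per-unit peak sets identical
  sim <- simulate_genome(simulation_config(seed = 5, n_genes = 10L,
                                           chrom_lengths = c(chrT = 100000L)))
  f2 <- tempfile()
  write_rmsk_table(sim$catalog, f2)
  back <- read_repeats(f2, "ucsc_rmsk")
  for (k in repeat_units(sim$catalog, "family")) {
    expect_identical(gr_to_df(unit_ranges(back, "family", k)),
                     gr_to_df(unit_ranges(sim$catalog, "family", k)))
  }
})

test_that("RepeatMasker .out dialect converts 1-based closed coordinates", {
  f <- tempfile(fileext = ".out")
  writeLines(c("   SW  perc perc perc  query     position in query",
               "score  div. del. ins.  sequence  begin end (left)",
               "",
               "  463 1.3 0.6 1.7 chrT 101 160 (5000) + AT_rich Low_complexity 1 60 (0) 1",
               "  239 29.4 1.9 1.0 chrT 201 300 (4000) C MIR3 SINE/MIR 1 100 (0) 2"),
             f)
  cat <- read_repeats(f, "repeatmasker_out")
  expect_equal(length(cat$elements), 2)
  expect_equal(start(cat$elements), c(101, 201))  # internally [100,160) in BED terms
  expect_equal(end(cat$elements), c(160, 300))
  expect_setequal(repeat_units(cat, "class"), c("Low_complexity", "SINE"))
  # bare class means family = class
  lc <- cat$elements[mcols(cat$elements)$rep_class == "Low_complexity"]
  expect_equal(mcols(lc)$rep_family, "Low_complexity")
})

test_that("a family under two classes is rejected", {
  gr <- GRanges(c("c", "c"), IRanges(c(1, 10), c(5, 15)))
  mcols(gr)$rep_name <- c("a", "b")
  mcols(gr)$rep_class <- c("LINE", "SINE")
  mcols(gr)$rep_family <- c("L1", "L1")
  expect_error(repeat_catalog(gr), "more than one class")
})

test_that("GTF round-trips gene models; missing exons fall back to the span", {
  m <- toy_gene_models()
  f <- tempfile(fileext = ".gtf")
  write_gtf(m, f)
  back <- read_genes(f, "gtf")
  expect_identical(mcols(back$genes)$gene_id, mcols(m$genes)$gene_id)
  expect_identical(gr_to_df(back$genes), gr_to_df(m$genes))
  expect_identical(as.character(strand(back$genes)), as.character(strand(m$genes)))
  for (i in seq_along(m$genes)) {
    expect_identical(gr_to_df(back$exons[[i]]), gr_to_df(m$exons[[i]]))
  }

  # gene without exon records: exon = gene span
  g <- GRanges("chrA", IRanges(1001, 2000), strand = "+")
  mcols(g)$gene_id <- "solo"
  m2 <- gene_models(g)
  expect_same_intervals(m2$exons[[1]],
                        data.frame(chrom = "chrA", start = 1001, end = 2000))

  # orphan exons are skipped with a warning
  ex <- GRanges("chrA", IRanges(1100, 1200))
  mcols(ex)$gene_id <- "ghost"
  expect_warning(gene_models(g, ex), "without a parent gene")
})

test_that("exon structure implies introns", {
  g <- GRanges("chrA", IRanges(1001, 2000), strand = "+")
  mcols(g)$gene_id <- "g"
  ex <- GRanges(c("chrA", "chrA"), IRanges(c(1001, 1501), c(1200, 2000)))
  mcols(ex)$gene_id <- c("g", "g")
  m <- gene_models(g, ex)
  lay <- genome_layout(c(chrA = 10000L))
  part <- partition_genome(m, lay, flank = 100)
  expect_same_intervals(part$categories$intron,
                        data.frame(chrom = "chrA", start = 1201, end = 1500))
})

test_that("partition covers the genome disjointly and honours priority", {
  lay <- toy_layout()
  m <- toy_gene_models()
  part <- partition_genome(m, lay)
  total <- sum(vapply(part$categories, total_bases, 0))
  expect_equal(total, genome_size(lay))
  # pairwise disjoint
  cats <- names(part$categories)
  for (i in seq_along(cats)) {
    for (j in seq_along(cats)) {
      if (i < j) {
        expect_equal(intersect_bases(part$categories[[cats[i]]],
                                     part$categories[[cats[j]]]), 0)
      }
    }
  }
  # a base in both an exon (g1, + at 5001-8000) and the promoter flank of g2
  # (-, promoter 15001-17000 does not reach; instead use g2 terminator side):
  # g2 is minus-strand at 12001-15000, so its promoter2k is 15001-17000 and
  # its terminator2k is 10001-12000; base 7990 lies in g1 exon only.
  # Construct the documented collision directly: gene B starting right after
  # gene A's exon so promoter2k of B overlaps the exon of A.
  gA <- GRanges("chrA", IRanges(1001, 3000), strand = "+")
  gB <- GRanges("chrA", IRanges(4001, 6000), strand = "+")
  g2 <- c(gA, gB)
  mcols(g2)$gene_id <- c("A", "B")
  m2 <- gene_models(g2)  # single-exon genes: whole span exonic
  p2 <- partition_genome(m2, genome_layout(c(chrA = 10000L)), flank = 2000)
  # bases 2001-3000 are exon of A and within 2000 upstream of B: promoter wins
  expect_equal(assign_peak_category(GRanges("chrA", IRanges(2500, 2500)), p2),
               "promoter2k")
})

test_that("no genes means everything is intergenic", {
  lay <- toy_layout()
  part <- partition_genome(gene_models(GRanges(character(0),
                                               IRanges(integer(0), integer(0)),
                                               gene_id = character(0))[0]),
                           lay)
  expect_equal(total_bases(part$categories$intergenic), genome_size(lay))
  expect_equal(assign_peak_category(GRanges("chrB", IRanges(5, 50)), part),
               "intergenic")
})

test_that("the three-category priority variant works", {
  lay <- toy_layout()
  m <- toy_gene_models()
  part3 <- partition_genome(m, lay,
                            priority = c("promoter2k", "gene", "intergenic"))
  expect_setequal(names(part3$categories),
                  c("promoter2k", "gene", "intergenic"))
  expect_equal(sum(vapply(part3$categories, total_bases, 0)), genome_size(lay))
  # a peak inside a gene body is "gene" here
  expect_equal(assign_peak_category(GRanges("chrA", IRanges(6000, 6100)), part3),
               "gene")
})

test_that("peak category assignment matches a brute-force priority scan", {
  set.seed(21)
  lay <- toy_layout()
  m <- toy_gene_models()
  part <- partition_genome(m, lay)
  ranks <- partition_ranks(part, lay$lengths)
  peaks <- random_peaks(150, lay$lengths, max_len = 3000)
  got <- assign_peak_category(peaks, part)
  for (i in seq_along(peaks)) {
    expected <- brute_peak_category(as.character(seqnames(peaks))[i],
                                    start(peaks)[i], end(peaks)[i],
                                    ranks, part$priority)
    expect_identical(got[i], expected)
  }
  # higher threshold can produce NA or a different category
  got50 <- assign_peak_category(peaks, part, min_overlap_bases = 50)
  for (i in seq_along(peaks)) {
    expected <- brute_peak_category(as.character(seqnames(peaks))[i],
                                    start(peaks)[i], end(peaks)[i],
                                    ranks, part$priority, min_overlap = 50)
    expect_identical(got50[i], expected)
  }
})

test_that("genomic_distribution counts peaks, sums to one, ignores order", {
  lay <- toy_layout()
  m <- toy_gene_models()
  part <- partition_genome(m, lay)
  # all peaks inside the promoter flank of g1 (+ at 5001): 3001-5000
  p <- peak_set(rep("chrA", 3), c(3100, 3500, 4000), c(3200, 3600, 4100))
  d <- genomic_distribution(p, part)
  expect_equal(unname(d["promoter2k"]), 1)
  expect_equal(sum(d), 1, tolerance = 1e-12)

  set.seed(31)
  q <- random_peaks(100, lay$lengths, max_len = 1500)
  d1 <- genomic_distribution(q, part)
  d2 <- genomic_distribution(rev(q), part)
  expect_equal(d1, d2)
  expect_equal(sum(d1), 1, tolerance = 1e-12)
  expect_error(genomic_distribution(GRanges(), part), "zero peaks")
})

test_that("venn cells are exact on trivial and random triples", {
  r_in <- peak_set("chrA", 100, 200)
  t_sup <- peak_set("chrA", 50, 300)
  g_far <- peak_set("chrB", 0, 100)
  v <- venn_bases(r_in, t_sup, g_far)
  expect_equal(v$pct_rloop_in_transcribed, 100)
  expect_equal(unname(v$cells["rloop_transcribed"]), 100)
  expect_equal(unname(v$cells["rloop_only"]), 0)

  v2 <- venn_bases(peak_set("chrA", 0, 10), peak_set("chrA", 20, 30),
                   peak_set("chrA", 40, 50))
  expect_equal(unname(v2$cells[c("rloop_transcribed", "rloop_gene",
                                 "transcribed_gene", "all_three")]),
               rep(0, 4))
  expect_equal(v2$pct_rloop_in_transcribed, 0)

  expect_true(is.na(venn_bases(GRanges(), t_sup, g_far)$pct_rloop_in_transcribed))

  set.seed(41)
  lengths <- c(chrT = 60000L)
  for (i in 1:5) {
    r <- random_peaks(40, lengths); t <- random_peaks(40, lengths)
    g <- random_peaks(40, lengths)
    v <- venn_bases(r, t, g)
    bm_r <- bitmap_from_gr(r, lengths); bm_t <- bitmap_from_gr(t, lengths)
    bm_g <- bitmap_from_gr(g, lengths)
    expect_equal(unname(v$cells["all_three"]),
                 bitmap_count(bitmap_and(bitmap_and(bm_r, bm_t), bm_g)))
    expect_equal(sum(v$cells),
                 bitmap_count(Map(function(a, b, c) a | b | c,
                                  bm_r, bm_t, bm_g)))
    expect_true(all(v$cells >= 0))
  }
})
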