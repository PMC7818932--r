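make_catalog <- function(df) {
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  mcols(gr)$rep_name <- df$name
  mcols(gr)$rep_class <- df$class
  mcols(gr)$rep_family <- df$family
  repeat_catalog(gr)
}

test_that("repeat base percentage matches hand counts", {
  cat <- make_catalog(data.frame(
    chrom = c("c", "c"), start = c(101, 501), end = c(200, 530),
    name = c("s1", "k1"), class = c("Satellite", "LINE"),
    family = c("centr", "L1")))
  # peaks entirely inside Satellite
  p_in <- GRanges("c", IRanges(121, 180))
  expect_equal(repeat_base_percentage(p_in, cat, "class", "Satellite"), 100)
  # absent unit
  expect_equal(repeat_base_percentage(p_in, cat, "class", "SINE"), 0)
  # 2 peaks of 100 bp, unit covers 30 bp of one: 30/200 = 15%
  p2 <- GRanges(c("c", "c"), IRanges(c(501, 1001), c(600, 1100)))
  expect_equal(repeat_base_percentage(p2, cat, "class", "LINE"), 15)
  expect_error(repeat_base_percentage(GRanges(), cat, "class", "LINE"),
               "zero bases")
  # vectorised form agrees
  v <- repeat_base_percentages(p2, cat, "class")
  expect_equal(unname(v["LINE"]), 15)
  expect_equal(unname(v["Satellite"]), 0)
})

test_that("overlapping units each get full credit (no exclusive attribution)", {
  cat <- make_catalog(data.frame(
    chrom = c("c", "c"), start = c(101, 101), end = c(200, 200),
    name = c("a", "b"), class = c("LINE", "SINE"), family = c("L1", "Alu")))
  p <- GRanges("c", IRanges(101, 200))
  expect_equal(repeat_base_percentage(p, cat, "class", "LINE"), 100)
  expect_equal(repeat_base_percentage(p, cat, "class", "SINE"), 100)
})

test_that("ratio enrichment matches log10 closed form and flags degenerate input", {
  expect_equal(ratio_enrichment(10, 1)$statistic, 1, tolerance = 1e-12)
  expect_equal(ratio_enrichment(5, 5)$statistic, 0, tolerance = 1e-12)
  expect_equal(ratio_enrichment(2, 20)$statistic, -1, tolerance = 1e-12)
  r0 <- ratio_enrichment(0, 2)
  expect_true(is.na(r0$statistic))
  expect_equal(r0$na_flag, "absent_in_peaks")
  r1 <- ratio_enrichment(3, 0)
  expect_equal(r1$na_flag, "absent_in_control")
  # both zero: control absence wins
  expect_equal(ratio_enrichment(0, 0)$na_flag, "absent_in_control")
  # identity property over a grid
  for (x in c(0.01, 0.5, 7, 42, 100)) {
    expect_equal(ratio_enrichment(x, x)$statistic, 0, tolerance = 1e-12)
  }
})

test_that("z-score matches an independent two-pass computation to 1e-12", {
  set.seed(55)
  q <- runif(1000, 0, 30)
  z <- zscore_enrichment(12, q)
  ref <- twopass_mean_sd(q)
  expect_equal(z$statistic, (12 - ref["mean"]) / ref["sd"],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(z$na_flag, "none")
  # p equal to the mean gives zero
  expect_equal(zscore_enrichment(mean(q), q)$statistic, 0, tolerance = 1e-12)
  # zero variance flags
  zv <- zscore_enrichment(5, rep(3, 100))
  expect_true(is.na(zv$statistic))
  expect_equal(zv$na_flag, "zero_variance")
  # sample sd (n-1) is the divisor
  q3 <- c(1, 2, 3)
  expect_equal(zscore_enrichment(3, q3)$statistic, (3 - 2) / 1,
               tolerance = 1e-12)
  expect_error(zscore_enrichment(1, 5), "at least 2")
})

test_that("enrichment matrix has one row per unit per requested control", {
  cat <- make_catalog(data.frame(
    chrom = c("c", "c"), start = c(101, 1001), end = c(400, 1400),
    name = c("a", "b"), class = c("LINE", "SINE"), family = c("L1", "Alu")))
  lay <- genome_layout(c(c = 20000L))
  part <- partition_genome(list(), lay)
  rl <- peak_set("c", c(150, 2000, 5000), c(350, 2500, 5600))
  ctl_s <- sample_matched_controls(rl, part, lay,
                                   sampling_config(n_samples = 20, seed = 1))
  mat <- enrichment_matrix(rl, cat, "class",
                           controls = list(genome = genome_control(lay),
                                           gro = gro_control(peak_set("c", 0, 10000)),
                                           sampling = ctl_s))
  expect_equal(nrow(mat), 2 * 3)
  expect_setequal(unique(mat$control), c("genome", "gro", "sampling"))
  mat2 <- enrichment_matrix(rl, cat, "class",
                            controls = list(genome = genome_control(lay),
                                            gro = gro_control(peak_set("c", 0, 10000))))
  expect_equal(nrow(mat2), 2 * 2)
  expect_error(enrichment_matrix(rl, cat, "class", controls = list(bogus = rl)),
               "unknown control")
  # statistic present iff na_flag is none
  expect_identical(is.na(mat$statistic), mat$na_flag != "none")
  # TSV round trip keeps rows
  f <- tempfile(fileext = ".tsv")
  write_enrichment_tsv(mat, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(mat))
  expect_equal(back$statistic, mat$statistic, tolerance = 1e-6)
})

test_that("a planted enrichment is detected and monotone in the multiplier", {
  run_z <- function(mult, seed = 9) {
    cfg <- simulation_config(seed = seed, chrom_lengths = c(chrT = 200000L),
                             n_genes = 20L, n_rloops = 150L,
                             multipliers = c(LINE = mult),
                             multiplier_level = "class")
    g <- simulate_genome(cfg)
    rl <- suppressWarnings(simulate_rloops(cfg, g)$peaks)
    ctl <- sample_matched_controls(rl, g$partition, g$layout,
                                   sampling_config(n_samples = 60, seed = 101))
    mat <- enrichment_matrix(rl, g$catalog, "class",
                             controls = list(genome = genome_control(g$layout),
                                             sampling = ctl))
    list(z = mat$statistic[mat$unit == "LINE" & mat$control == "sampling"],
         ratio = mat$statistic[mat$unit == "LINE" & mat$control == "genome"])
  }
  strong <- run_z(4)
  expect_gt(strong$z, 2)
  expect_gt(strong$ratio, 0)
  weak <- run_z(1)
  expect_lt(abs(weak$z), 3)
})
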