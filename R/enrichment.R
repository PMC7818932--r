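#' Base percentage of one repeat unit in a peak set
#'
#' `100 * intersect_bases(merge(peaks), unit) / total_bases(merge(peaks))`:
#' the percentage of the peak set's bases lying inside the merged elements of
#' repeat unit `k`. Units are independent — a base inside elements of two
#' different classes counts toward both.
#'
#' @param peaks non-empty `GRanges`
#' @param catalog a [repeat_catalog()]
#' @param level `"class"` or `"family"`
#' @param k unit name
#' @return percentage in `[0, 100]`.
#' @export
repeat_base_percentage <- function(peaks, catalog, level = c("class", "family"), k) {
  level <- match.arg(level)
  tb <- total_bases(peaks)
  if (tb == 0) stop("peak set covers zero bases")
  100 * intersect_bases(peaks, unit_ranges(catalog, level, k)) / tb
}

#' Base percentages of all units of a level in a peak set
#'
#' Vectorised form of [repeat_base_percentage()] over every unit present in
#' the catalog at the chosen level.
#'
#' @inheritParams repeat_base_percentage
#' @return named numeric vector of percentages over units.
#' @export
repeat_base_percentages <- function(peaks, catalog, level = c("class", "family")) {
  level <- match.arg(level)
  m <- group_unit_percentages(GenomicRanges::GRangesList(p = peaks), catalog, level)
  stats::setNames(m[1, ], colnames(m))
}

# percentage matrix [groups x units] for a GRangesList of peak groups;
# each group is merged before counting, one findOverlaps per level
group_unit_percentages <- function(groups, catalog, level = c("class", "family")) {
  level <- match.arg(level)
  idx <- unit_ranges_all(catalog, level)
  red <- reduce(groups, ignore.strand = TRUE)
  totals <- as.numeric(sum(width(red)))
  if (any(totals == 0)) stop("a peak group covers zero bases")
  flat <- unlist(red, use.names = FALSE)
  gid <- rep(seq_along(red), lengths(red))
  q <- matrix(0, nrow = length(groups), ncol = length(idx$units),
              dimnames = list(names(groups), idx$units))
  if (length(idx$ranges) && length(flat)) {
    al <- align_seqlevels(flat, idx$ranges)
    hits <- findOverlaps(al$a, al$b, ignore.strand = TRUE)
    if (length(hits)) {
      qi <- queryHits(hits); si <- subjectHits(hits)
      ov <- pmin(end(al$a)[qi], end(al$b)[si]) -
        pmax(start(al$a)[qi], start(al$b)[si]) + 1
      ui <- match(mcols(idx$ranges)$unit[si], idx$units)
      key <- (gid[qi] - 1L) * length(idx$units) + ui
      agg <- rowsum(as.numeric(ov), key)
      kk <- as.integer(rownames(agg))
      gg <- (kk - 1L) %/% length(idx$units) + 1L
      uu <- (kk - 1L) %% length(idx$units) + 1L
      q[cbind(gg, uu)] <- agg[, 1]
    }
  }
  sweep(q, 1, totals, "/") * 100
}

#' Log10 ratio enrichment
#'
#' `log10(x / y)` of the observed (`x`) versus control (`y`) base percentage,
#' the statistic used with the genome and GRO controls. Degenerate inputs get
#' an NA flag instead of a value: `absent_in_peaks` when `x = 0`,
#' `absent_in_control` when `y = 0` (which wins when both are zero).
#'
#' @param x,y percentages in `[0, 100]` (vectorised, recycled)
#' @return data.frame with columns `statistic` (numeric, `NA` when flagged)
#'   and `na_flag` (`"none"`, `"absent_in_peaks"`, `"absent_in_control"`).
#' @examples
#' ratio_enrichment(10, 1)$statistic  # 1
#' @export
ratio_enrichment <- function(x, y) {
  stopifnot(all(x >= 0 & x <= 100), all(y >= 0 & y <= 100))
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  flag <- rep("none", n)
  flag[x == 0] <- "absent_in_peaks"
  flag[y == 0] <- "absent_in_control"   # takes precedence when both are zero
  stat <- ifelse(flag == "none", log10(x / y), NA_real_)
  data.frame(statistic = stat, na_flag = flag)
}

#' Z-score enrichment against a sampling null
#'
#' Standardises the observed percentage `p` against the control draws `q`:
#' `(p - mean(q)) / sd(q)` with the sample standard deviation (divisor n-1).
#' When the draws have zero variance the statistic is NA with flag
#' `zero_variance`.
#'
#' @param p observed percentage
#' @param q numeric vector of control percentages (length >= 2)
#' @return one-row data.frame with `statistic`, `na_flag`, `control_mean`,
#'   `control_sd`.
#' @export
zscore_enrichment <- function(p, q) {
  if (length(q) < 2) stop("the sampling null needs at least 2 draws")
  m <- mean(q)
  s <- stats::sd(q)
  if (s == 0) {
    data.frame(statistic = NA_real_, na_flag = "zero_variance",
               control_mean = m, control_sd = s)
  } else {
    data.frame(statistic = (p - m) / s, na_flag = "none",
               control_mean = m, control_sd = s)
  }
}

#' Enrichment matrix over repeat units and controls
#'
#' One row per (repeat unit, control) pair, mirroring the published heatmap
#' panels: the genome and GRO controls are scored with the log10 ratio, the
#' sampling control with the Z-score against its draw distribution. Positive
#' statistics mean overrepresented in the peaks, negative underrepresented.
#'
#' @param rloops observed peak set (`GRanges`)
#' @param catalog a [repeat_catalog()]
#' @param level `"class"` or `"family"`
#' @param controls named list with any of: `genome` (a `GRanges`), `gro` (a
#'   `GRanges`), `sampling` (a `GRangesList` from
#'   [sample_matched_controls()]). Controls omitted from the list are omitted
#'   from the matrix.
#' @return data.frame with columns `level`, `unit`, `control`, `observed_pct`,
#'   `control_summary` (the control percentage, or `mean=..;sd=..` for
#'   sampling), `statistic`, `na_flag`.
#' @export
enrichment_matrix <- function(rloops, catalog, level = c("class", "family"),
                              controls = list()) {
  level <- match.arg(level)
  units <- repeat_units(catalog, level)
  obs <- repeat_base_percentages(rloops, catalog, level)
  rows <- list()
  for (ctl in names(controls)) {
    if (ctl %in% c("genome", "gro")) {
      y <- repeat_base_percentages(controls[[ctl]], catalog, level)
      re <- ratio_enrichment(obs[units], y[units])
      rows[[ctl]] <- data.frame(level = level, unit = units, control = ctl,
                                observed_pct = unname(obs[units]),
                                control_summary = formatC(unname(y[units]),
                                                          digits = 6, format = "g"),
                                statistic = re$statistic, na_flag = re$na_flag)
    } else if (ctl == "sampling") {
      qm <- group_unit_percentages(controls[[ctl]], catalog, level)
      zz <- do.call(rbind, lapply(units, function(k) {
        zscore_enrichment(obs[[k]], qm[, k])
      }))
      rows[[ctl]] <- data.frame(level = level, unit = units, control = ctl,
                                observed_pct = unname(obs[units]),
                                control_summary = sprintf("mean=%.6g;sd=%.6g",
                                                          zz$control_mean,
                                                          zz$control_sd),
                                statistic = zz$statistic, na_flag = zz$na_flag)
    } else {
      stop("unknown control kind: ", ctl)
    }
  }
  out <- do.call(rbind, unname(rows))
  rownames(out) <- NULL
  out[order(out$unit, match(out$control, c("genome", "sampling", "gro"))), ,
      drop = FALSE]
}

#' Write an enrichment matrix as TSV
#' @param mat a data.frame from [enrichment_matrix()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(mat, path) {
  out <- mat
  out$na_flag[is.na(out$na_flag)] <- "none"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
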