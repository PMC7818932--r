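#' Construct a repeat catalog
#'
#' A repeat catalog holds RepeatMasker-style elements, each carrying a repeat
#' class, family and name, and provides merged per-unit peak sets at either
#' grouping level. Classes and families are the unit `k` over which enrichment
#' statistics are computed; a family belongs to exactly one class.
#'
#' @param elements `GRanges` with metadata columns `rep_name`, `rep_class`,
#'   `rep_family` (all non-empty strings).
#' @return an object of class `RepeatCatalog`.
#' @export
repeat_catalog <- function(elements) {
  stopifnot(methods::is(elements, "GRanges"))
  need <- c("rep_name", "rep_class", "rep_family")
  missing_cols <- setdiff(need, colnames(mcols(elements)))
  if (length(missing_cols)) {
    stop("repeat elements lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    v <- mcols(elements)[[col]]
    if (any(is.na(v)) || any(!nzchar(v))) stop("empty value in ", col)
  }
  fam2cls <- unique(data.frame(family = mcols(elements)$rep_family,
                               class = mcols(elements)$rep_class))
  if (anyDuplicated(fam2cls$family)) {
    dup <- fam2cls$family[duplicated(fam2cls$family)][1]
    stop("repeat family '", dup, "' appears under more than one class")
  }
  structure(list(elements = sort_peaks(elements)), class = "RepeatCatalog")
}

#' @export
print.RepeatCatalog <- function(x, ...) {
  cat(sprintf("RepeatCatalog: %d elements, %d classes, %d families\n",
              length(x$elements),
              length(repeat_units(x, "class")),
              length(repeat_units(x, "family"))))
  invisible(x)
}

#' Repeat units present in a catalog
#' @param catalog a [repeat_catalog()]
#' @param level `"class"` or `"family"`
#' @return sorted character vector of unit names.
#' @export
repeat_units <- function(catalog, level = c("class", "family")) {
  level <- match.arg(level)
  col <- if (level == "class") "rep_class" else "rep_family"
  sort(unique(mcols(catalog$elements)[[col]]))
}

#' Merged interval set of one repeat unit
#' @param catalog a [repeat_catalog()]
#' @param level `"class"` or `"family"`
#' @param k unit name
#' @return merged `GRanges` of the unit's elements (no internal overlaps);
#'   empty `GRanges` when the unit is absent.
#' @export
unit_ranges <- function(catalog, level = c("class", "family"), k) {
  level <- match.arg(level)
  col <- if (level == "class") "rep_class" else "rep_family"
  merge_peaks(catalog$elements[mcols(catalog$elements)[[col]] == k])
}

# one GRanges per level with a unit index, for vectorised overlap counting
unit_ranges_all <- function(catalog, level = c("class", "family")) {
  level <- match.arg(level)
  units <- repeat_units(catalog, level)
  col <- if (level == "class") "rep_class" else "rep_family"
  parts <- lapply(units, function(k) {
    gr <- merge_peaks(catalog$elements[mcols(catalog$elements)[[col]] == k])
    mcols(gr)$unit <- k
    gr
  })
  list(units = units, ranges = suppressWarnings(do.call(c, parts)))
}

#' Read repeat annotations
#'
#' Two dialects are supported. `ucsc_rmsk` is a tab-separated table with a
#' header naming (at least) `genoName`, `genoStart`, `genoEnd`, `repName`,
#' `repClass`, `repFamily`; coordinates are 0-based half-open as in the UCSC
#' rmsk track. `repeatmasker_out` is the native RepeatMasker `.out` layout:
#' three header lines followed by whitespace-separated records with 1-based
#' closed coordinates and a combined `class/family` column (a bare class means
#' family = class).
#'
#' @param path input file
#' @param dialect `"ucsc_rmsk"` or `"repeatmasker_out"`
#' @param layout optional [genome_layout()] for bounds checking
#' @return a [repeat_catalog()].
#' @export
read_repeats <- function(path, dialect = c("ucsc_rmsk", "repeatmasker_out"),
                         layout = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "ucsc_rmsk") read_rmsk_table(path, layout)
  else read_rmsk_out(path, layout)
}

read_rmsk_table <- function(path, layout = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE)
  need <- c("genoName", "genoStart", "genoEnd", "repName", "repClass", "repFamily")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- !is.finite(df$genoStart) | !is.finite(df$genoEnd) |
    df$genoStart < 0 | df$genoStart >= df$genoEnd
  if (any(bad)) {
    stop(sprintf("%s: line %d: inverted or empty repeat coordinates",
                 path, which(bad)[1] + 1L))
  }
  gr <- GRanges(df$genoName, IRanges(df$genoStart + 1, df$genoEnd))
  mcols(gr)$rep_name <- df$repName
  mcols(gr)$rep_class <- df$repClass
  mcols(gr)$rep_family <- df$repFamily
  gr <- validate_peaks(gr, layout)
  repeat_catalog(gr)
}

read_rmsk_out <- function(path, layout = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4) stop(path, ": truncated RepeatMasker .out file")
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(trimws(body), "[ \t]+")
  nf <- lengths(rows)
  if (any(nf < 11)) {
    stop(sprintf("%s: line %d: too few fields for a RepeatMasker record",
                 path, which(nf < 11)[1] + 3L))
  }
  chrom <- vapply(rows, `[[`, "", 5L)
  s <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 6L)))
  e <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 7L)))
  if (anyNA(s) || anyNA(e)) {
    stop(sprintf("%s: line %d: non-numeric coordinates",
                 path, which(is.na(s) | is.na(e))[1] + 3L))
  }
  if (any(s > e)) {
    stop(sprintf("%s: line %d: inverted repeat coordinates",
                 path, which(s > e)[1] + 3L))
  }
  rep_name <- vapply(rows, `[[`, "", 10L)
  clsfam <- vapply(rows, `[[`, "", 11L)
  pieces <- strsplit(clsfam, "/", fixed = TRUE)
  rep_class <- vapply(pieces, `[[`, "", 1L)
  rep_family <- vapply(pieces, function(p) if (length(p) >= 2) p[2] else p[1], "")
  gr <- GRanges(chrom, IRanges(s, e))  # .out is 1-based closed already
  mcols(gr)$rep_name <- rep_name
  mcols(gr)$rep_class <- rep_class
  mcols(gr)$rep_family <- rep_family
  gr <- validate_peaks(gr, layout)
  repeat_catalog(gr)
}

#' Write a catalog as a UCSC rmsk-dialect table
#'
#' Emits the six columns [read_repeats()] requires, 0-based half-open, so the
#' output round-trips through `read_repeats(dialect = "ucsc_rmsk")`.
#' @param catalog a [repeat_catalog()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_rmsk_table <- function(catalog, path) {
  el <- catalog$elements
  df <- data.frame(genoName = as.character(GenomeInfoDb::seqnames(el)),
                   genoStart = start(el) - 1L,
                   genoEnd = end(el),
                   repName = mcols(el)$rep_name,
                   repClass = mcols(el)$rep_class,
                   repFamily = mcols(el)$rep_family)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
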