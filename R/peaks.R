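#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps reduce
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- metadata metadata<-
#' @importFrom BiocGenerics start end width strand
NULL

#' Construct a peak set
#'
#' Peak sets are plain [GenomicRanges::GRanges] objects; this helper builds one
#' from vectors, attaches an optional provenance tag (kept in
#' `S4Vectors::metadata(x)$provenance`) and validates it against a layout.
#'
#' @param chrom,start,end vectors of chromosome, 0-based start and exclusive
#'   end (BED convention; converted to the 1-based closed GRanges convention).
#' @param name,strand optional per-interval label and strand (`+`, `-`, `*`).
#' @param provenance optional set-level tag (e.g. `"rloop"`, `"gro"`).
#' @param layout optional [genome_layout()]; when supplied, intervals are
#'   bounds-checked and the seqinfo is attached.
#' @return a `GRanges`, sorted within chromosomes.
#' @export
peak_set <- function(chrom, start, end, name = NULL, strand = NULL,
                     provenance = NULL, layout = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) stop("non-numeric coordinates")
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("empty or inverted interval (start >= end)")
  gr <- GRanges(chrom, IRanges(start + 1, end),
                strand = if (is.null(strand)) "*" else strand)
  if (!is.null(name)) mcols(gr)$name <- as.character(name)
  gr <- validate_peaks(gr, layout)
  if (!is.null(provenance)) metadata(gr)$provenance <- provenance
  sort_peaks(gr)
}

sort_peaks <- function(gr) {
  BiocGenerics::sort(gr, ignore.strand = TRUE)
}

validate_peaks <- function(gr, layout = NULL) {
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "GenomeLayout"))
    chr <- as.character(GenomeInfoDb::seqnames(gr))
    unknown <- !(chr %in% names(layout$lengths))
    if (any(unknown)) {
      stop("interval on chromosome absent from the genome layout: ",
           chr[unknown][1])
    }
    if (any(end(gr) > layout$lengths[chr])) {
      stop("interval extends past the end of its chromosome")
    }
    md <- metadata(gr)
    GenomeInfoDb::seqlevels(gr) <- names(layout$lengths)
    GenomeInfoDb::seqinfo(gr) <- layout_seqinfo(layout)
    metadata(gr) <- md
  }
  gr
}

# put two GRanges on a shared seqlevel set so set operations are legal
align_seqlevels <- function(a, b) {
  lev <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  suppressWarnings({
    GenomeInfoDb::seqlevels(a) <- lev
    GenomeInfoDb::seqlevels(b) <- lev
  })
  list(a = a, b = b)
}

#' Merge a peak set
#'
#' Collapses overlapping (and, for `min_gap > 0`, nearby) intervals on the same
#' chromosome into single intervals, as `bedtools merge` does. Strand and
#' per-interval names are dropped. With `min_gap = 0`, adjacent and overlapping
#' intervals are joined and base content is preserved exactly.
#'
#' @param peaks a `GRanges`
#' @param min_gap non-negative integer; intervals separated by at most this
#'   many bases are joined.
#' @return merged `GRanges`, sorted, no two intervals within `min_gap`.
#' @examples
#' p <- peak_set(c("chr1", "chr1"), c(0, 5), c(10, 15))
#' merge_peaks(p)  # chr1:[0,15) in BED terms
#' @export
merge_peaks <- function(peaks, min_gap = 0L) {
  stopifnot(methods::is(peaks, "GRanges"), min_gap >= 0)
  out <- reduce(GenomicRanges::granges(peaks), ignore.strand = TRUE,
                min.gapwidth = as.integer(min_gap) + 1L)
  BiocGenerics::strand(out) <- "*"
  sort_peaks(out)
}

#' Total bases covered by a peak set
#'
#' Counts each base once, i.e. the width sum of the merged set.
#' @param peaks a `GRanges`
#' @return numeric base count.
#' @export
total_bases <- function(peaks) {
  sum(as.numeric(width(merge_peaks(peaks))))
}

#' Bases covered by both of two peak sets
#'
#' Base-level intersection count (the `bedtools intersect` base total). Both
#' sets are merged internally first; the result is symmetric.
#' @param a,b `GRanges`
#' @return numeric base count.
#' @examples
#' a <- peak_set("chr1", 0, 10); b <- peak_set("chr1", 5, 15)
#' intersect_bases(a, b)  # 5
#' @export
intersect_bases <- function(a, b) {
  al <- align_seqlevels(merge_peaks(a), merge_peaks(b))
  sum(as.numeric(width(GenomicRanges::intersect(al$a, al$b, ignore.strand = TRUE))))
}

#' Base-level difference of two peak sets
#'
#' Returns the bases of `a` not covered by `b` (the `bedtools subtract`
#' semantics at base level); the result is merged.
#' @param a,b `GRanges`
#' @return `GRanges` covering `total_bases(a) - intersect_bases(a, b)` bases.
#' @export
subtract_peaks <- function(a, b) {
  al <- align_seqlevels(merge_peaks(a), merge_peaks(b))
  sort_peaks(GenomicRanges::setdiff(al$a, al$b, ignore.strand = TRUE))
}

#' Drop whole peaks that overlap another set
#'
#' Removes from `a` every interval whose overlap with the merged `b` totals at
#' least `min_overlap_bases` bases. The unit of removal is the interval, not
#' the base: surviving peaks keep their original coordinates, names and
#' strand. This is the IP-minus-RNaseH peak filter of a DRIP-seq pipeline.
#'
#' @param a peaks to filter (`GRanges`)
#' @param b peaks to filter against (`GRanges`)
#' @param min_overlap_bases positive integer; a peak is removed when its bases
#'   shared with `b` reach this count (default 1, i.e. any overlap).
#' @return the surviving subset of `a`, in sorted order.
#' @export
remove_overlapping_peaks <- function(a, b, min_overlap_bases = 1L) {
  stopifnot(min_overlap_bases >= 1)
  if (length(b) == 0) return(sort_peaks(a))
  bm <- merge_peaks(b)
  al <- align_seqlevels(a, bm)
  hits <- findOverlaps(al$a, al$b, ignore.strand = TRUE)
  ov <- pmin(end(al$a)[queryHits(hits)], end(al$b)[subjectHits(hits)]) -
    pmax(start(al$a)[queryHits(hits)], start(al$b)[subjectHits(hits)]) + 1L
  tot <- rep(0, length(al$a))
  if (length(hits)) {
    agg <- rowsum(ov, queryHits(hits))
    tot[as.integer(rownames(agg))] <- agg[, 1]
  }
  sort_peaks(al$a[tot < min_overlap_bases])
}

#' Read a BED3-BED6 file
#'
#' Tab-separated, 0-based half-open coordinates. Columns beyond the sixth are
#' ignored; `#`-comment, `track` and `browser` lines are skipped. Malformed
#' lines (non-integer coordinates, `start >= end`) raise an error naming the
#' line number; with a `layout`, intervals are bounds-checked.
#'
#' @param path BED file path
#' @param layout optional [genome_layout()] for validation
#' @param provenance optional provenance tag to attach
#' @return a `GRanges` (1-based closed internally), sorted.
#' @export
read_bed <- function(path, layout = NULL, provenance = NULL) {
  lines <- readLines(path, warn = FALSE)
  t <- trimws(lines, which = "right")
  skip <- !nzchar(t) | startsWith(t, "#") | startsWith(t, "track") |
    startsWith(t, "browser")
  lineno <- which(!skip)
  rows <- strsplit(t[!skip], "\t", fixed = TRUE)
  if (length(rows) == 0) {
    gr <- GRanges()
    if (!is.null(provenance)) metadata(gr)$provenance <- provenance
    return(validate_peaks(gr, layout))
  }
  nf <- lengths(rows)
  if (any(nf < 3)) {
    stop(sprintf("%s: line %d: BED needs at least 3 columns",
                 path, lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(rows, `[[`, "", 1L)
  s_raw <- vapply(rows, `[[`, "", 2L)
  e_raw <- vapply(rows, `[[`, "", 3L)
  s <- suppressWarnings(as.numeric(s_raw))
  e <- suppressWarnings(as.numeric(e_raw))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad)) {
    stop(sprintf("%s: line %d: non-integer coordinates '%s' '%s'",
                 path, lineno[which(bad)[1]], s_raw[which(bad)[1]],
                 e_raw[which(bad)[1]]))
  }
  if (any(s < 0)) {
    stop(sprintf("%s: line %d: negative start", path, lineno[which(s < 0)[1]]))
  }
  if (any(s >= e)) {
    stop(sprintf("%s: line %d: empty interval (start >= end)",
                 path, lineno[which(s >= e)[1]]))
  }
  name <- ifelse(nf >= 4, vapply(rows, function(r) r[min(4, length(r))], ""), NA)
  name[name %in% c(".", "")] <- NA
  str <- rep("*", length(rows))
  has6 <- nf >= 6
  if (any(has6)) {
    s6 <- vapply(rows[has6], `[[`, "", 6L)
    s6[!s6 %in% c("+", "-")] <- "*"
    str[has6] <- s6
  }
  gr <- GRanges(chrom, IRanges(s + 1, e), strand = str)
  if (any(nf >= 4)) mcols(gr)$name <- as.character(name)
  gr <- tryCatch(validate_peaks(gr, layout), error = function(err) {
    stop(path, ": ", conditionMessage(err))
  })
  if (!is.null(provenance)) metadata(gr)$provenance <- provenance
  sort_peaks(gr)
}

#' Write a peak set as BED
#'
#' Emits BED3 when the set carries neither names nor strand, otherwise BED6
#' (score column 0, missing names as `.`). Coordinates are converted back to
#' 0-based half-open. `read_bed(write_bed(x))` round-trips to an identical set.
#'
#' @param peaks a `GRanges`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  s <- start(peaks) - 1L
  e <- end(peaks)
  nm <- mcols(peaks)$name
  str <- as.character(strand(peaks))
  if (is.null(nm) && all(str == "*")) {
    writeLines(paste(chrom, s, e, sep = "\t"), path)
  } else {
    if (is.null(nm)) nm <- rep(NA_character_, length(peaks))
    nm <- ifelse(is.na(nm), ".", nm)
    str <- ifelse(str %in% c("+", "-"), str, ".")
    writeLines(paste(chrom, s, e, nm, 0L, str, sep = "\t"), path)
  }
  invisible(path)
}
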