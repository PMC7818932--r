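#' Genome layout: chromosome names, lengths and optional assembly gaps
#'
#' A `GenomeLayout` is the coordinate frame over which all peak sets, the
#' genome control and the sampling control are defined: an ordered set of
#' chromosomes with lengths, plus (optionally) assembly gap intervals (N-runs)
#' that sampling can be told to avoid.
#'
#' @param lengths named integer-ish vector of chromosome lengths in bases;
#'   names are the chromosome identifiers, which must be unique, and lengths
#'   must be strictly positive.
#' @param gaps optional [GenomicRanges::GRanges] of assembly gaps; every gap
#'   must lie within the bounds of its chromosome.
#' @return An object of class `GenomeLayout` with fields `lengths` (named
#'   integer vector) and `gaps` (`GRanges` or `NULL`).
#' @examples
#' layout <- genome_layout(c(chr1 = 100000, chr2 = 50000))
#' genome_size(layout)
#' @export
genome_layout <- function(lengths, gaps = NULL) {
  if (length(lengths) == 0) stop("a GenomeLayout needs at least one chromosome")
  nm <- names(lengths)
  if (is.null(nm) || any(!nzchar(nm))) stop("chromosome lengths must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome identifier: ", nm[duplicated(nm)][1])
  }
  len <- as.integer(round(as.numeric(lengths)))
  if (any(is.na(len)) || any(len <= 0)) {
    stop("chromosome lengths must be positive integers")
  }
  names(len) <- nm
  if (!is.null(gaps)) {
    stopifnot(methods::is(gaps, "GRanges"))
    bad <- !(as.character(GenomeInfoDb::seqnames(gaps)) %in% nm)
    if (any(bad)) stop("gap interval on unknown chromosome: ",
                       as.character(GenomeInfoDb::seqnames(gaps))[bad][1])
    hi <- len[as.character(GenomeInfoDb::seqnames(gaps))]
    if (any(BiocGenerics::start(gaps) < 1L) || any(BiocGenerics::end(gaps) > hi)) {
      stop("gap interval outside chromosome bounds")
    }
    gaps <- merge_peaks(gaps)
  }
  structure(list(lengths = len, gaps = gaps), class = "GenomeLayout")
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat(sprintf("GenomeLayout: %d chromosome(s), %s bases",
              length(x$lengths), format(sum(as.numeric(x$lengths)), big.mark = ",")))
  if (!is.null(x$gaps)) cat(sprintf(", %d gap interval(s)", length(x$gaps)))
  cat("\n")
  invisible(x)
}

#' Total genome size of a layout
#' @param layout a [genome_layout()]
#' @return numeric, total bases across chromosomes (gaps included).
#' @export
genome_size <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  sum(as.numeric(layout$lengths))
}

#' Seqinfo corresponding to a layout
#' @param layout a [genome_layout()]
#' @return a [GenomeInfoDb::Seqinfo] with the layout's chromosomes and lengths.
#' @export
layout_seqinfo <- function(layout) {
  stopifnot(inherits(layout, "GenomeLayout"))
  GenomeInfoDb::Seqinfo(seqnames = names(layout$lengths),
                        seqlengths = unname(layout$lengths))
}

#' Read a two-column chrom.sizes table
#'
#' @param path file with whitespace-delimited rows `name length`. Comment
#'   lines starting with `#` are skipped.
#' @return a [genome_layout()] with chromosomes in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) stop("no chromosome records in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop(sprintf("%s: line %d: expected two columns (name, length)",
                 path, lineno[which(nf < 2)[1]]))
  }
  nm <- vapply(fields, `[[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  if (anyNA(len)) {
    stop(sprintf("%s: line %d: non-numeric chromosome length",
                 path, lineno[which(is.na(len))[1]]))
  }
  if (any(len <= 0)) {
    stop(sprintf("%s: line %d: non-positive chromosome length",
                 path, lineno[which(len <= 0)[1]]))
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("%s: line %d: duplicate chromosome '%s'",
                 path, lineno[which(duplicated(nm))[1]], nm[duplicated(nm)][1]))
  }
  genome_layout(stats::setNames(len, nm))
}

#' Write a layout as a chrom.sizes table
#' @param layout a [genome_layout()]
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  stopifnot(inherits(layout, "GenomeLayout"))
  writeLines(paste(names(layout$lengths), layout$lengths, sep = "\t"), path)
  invisible(path)
}
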