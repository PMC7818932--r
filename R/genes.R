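#' Construct a set of gene models
#'
#' A gene model is a gene span with strand and the (merged, in-span) exon
#' intervals; introns are the in-gene remainder. Genes with unknown strand are
#' treated as `+` for promoter/terminator orientation, with a warning.
#'
#' @param genes `GRanges` with a `gene_id` metadata column (unique ids).
#' @param exons `GRanges` with a `gene_id` column linking each exon to a gene.
#'   Exons falling outside their gene's span are an error; genes without any
#'   exon record get a single exon equal to the gene span.
#' @return an object of class `GeneModels` with fields `genes` (`GRanges`) and
#'   `exons` (`GRangesList` parallel to `genes`).
#' @export
gene_models <- function(genes, exons = NULL) {
  stopifnot(methods::is(genes, "GRanges"))
  ids <- mcols(genes)$gene_id
  if (is.null(ids)) stop("genes need a gene_id column")
  if (anyDuplicated(ids)) stop("duplicate gene_id: ", ids[duplicated(ids)][1])
  unstranded <- as.character(strand(genes)) == "*"
  if (any(unstranded)) {
    warning(sum(unstranded), " gene(s) without strand treated as '+'")
    BiocGenerics::strand(genes)[unstranded] <- "+"
  }
  ord <- order(as.character(GenomeInfoDb::seqnames(genes)), start(genes))
  genes <- genes[ord]
  ids <- mcols(genes)$gene_id
  flat <- GRanges()
  gi <- integer(0)
  if (!is.null(exons) && length(exons)) {
    eid <- mcols(exons)$gene_id
    if (is.null(eid)) stop("exons need a gene_id column")
    orphan <- !(eid %in% ids)
    if (any(orphan)) {
      warning(sum(orphan), " exon(s) without a parent gene skipped")
      exons <- exons[!orphan]
      eid <- eid[!orphan]
    }
    ex <- GenomicRanges::granges(exons)
    BiocGenerics::strand(ex) <- "*"
    red <- reduce(GenomicRanges::split(ex, factor(eid, levels = ids)),
                  ignore.strand = TRUE)
    flat <- unlist(red, use.names = FALSE)
    gi <- rep(seq_along(ids), lengths(red))
    bad <- start(flat) < start(genes)[gi] | end(flat) > end(genes)[gi]
    if (any(bad)) stop("exon outside gene span for gene ", ids[gi[bad][1]])
  }
  no_exon <- setdiff(seq_along(ids), gi)
  if (length(no_exon)) {   # fallback: a single exon spanning the gene
    flat <- suppressWarnings(c(flat, GenomicRanges::granges(genes)[no_exon]))
    BiocGenerics::strand(flat) <- "*"
    gi <- c(gi, no_exon)
  }
  o <- order(gi, start(flat))
  exl <- GenomicRanges::split(flat[o], factor(gi[o], levels = seq_along(ids)))
  names(exl) <- ids
  structure(list(genes = genes, exons = exl), class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d genes, %d exons\n",
              length(x$genes), sum(lengths(x$exons))))
  invisible(x)
}

#' Read gene models from GTF or GFF3
#'
#' Uses `gene` and `exon` feature records; exons are linked to genes by
#' `gene_id` (GTF) or `Parent` (GFF3). Genes lacking exon records get a single
#' exon spanning the gene. Coordinates (1-based closed in both formats) are
#' used as-is.
#'
#' @param path annotation file
#' @param format `"gtf"` or `"gff3"` (default guessed from the extension)
#' @param layout optional [genome_layout()] for bounds checking
#' @return a [gene_models()] object.
#' @export
read_genes <- function(path, format = NULL, layout = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  }
  format <- match.arg(format, c("gtf", "gff3"))
  gr <- rtracklayer::import(path, format = format)
  type <- as.character(mcols(gr)$type)
  genes <- gr[type == "gene"]
  exons <- gr[type == "exon"]
  if (length(genes) == 0) stop(path, ": no gene records")
  if (format == "gtf") {
    gid <- mcols(genes)$gene_id
    eid <- mcols(exons)$gene_id
  } else {
    gid <- mcols(genes)$ID
    if (is.null(gid)) gid <- mcols(genes)$gene_id
    parent <- mcols(exons)$Parent
    eid <- if (length(exons)) vapply(as.list(parent), function(p) {
      if (length(p)) sub("^(gene|transcript):", "", p[1]) else NA_character_
    }, "") else character()
  }
  if (is.null(gid) || any(is.na(gid))) stop(path, ": gene records lack identifiers")
  g <- GenomicRanges::granges(genes)
  mcols(g)$gene_id <- as.character(gid)
  e <- GenomicRanges::granges(exons)
  if (length(e)) mcols(e)$gene_id <- as.character(eid)
  if (!is.null(layout)) {
    g <- validate_peaks(g, layout)
    e <- validate_peaks(e, layout)
  }
  gene_models(g, e)
}

#' Write gene models as GTF
#'
#' Emits one `gene` record and one `exon` record per exon, with `gene_id`
#' attributes, so the output round-trips through [read_genes()].
#' @param models a [gene_models()] object
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "GeneModels"))
  g <- models$genes
  ids <- mcols(g)$gene_id
  attr_of <- function(id) sprintf('gene_id "%s"; transcript_id "%s.t1";', id, id)
  gene_lines <- paste(as.character(GenomeInfoDb::seqnames(g)), "repeatloop",
                      "gene", start(g), end(g), ".",
                      as.character(strand(g)), ".", attr_of(ids), sep = "\t")
  ex <- unlist(models$exons)
  eid <- rep(ids, lengths(models$exons))
  exon_lines <- character(0)
  if (length(ex)) {
    estr <- as.character(strand(g))[rep(seq_along(g), lengths(models$exons))]
    exon_lines <- paste(as.character(GenomeInfoDb::seqnames(ex)), "repeatloop",
                        "exon", start(ex), end(ex), ".", estr, ".",
                        attr_of(eid), sep = "\t")
  }
  writeLines(c(gene_lines, exon_lines), path)
  invisible(path)
}

#' Merged gene spans of a set of models
#' @param models a [gene_models()] object
#' @return merged `GRanges` of gene spans (strand dropped).
#' @export
gene_spans <- function(models) {
  stopifnot(inherits(models, "GeneModels"))
  merge_peaks(models$genes)
}
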