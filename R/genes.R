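## Gene models are stored relationally: one row per transcript isoform,
## BED12-shaped. Exon coordinates are absolute (0-based half-open) list
## columns; the thick range delimits the CDS in exon space.

#' Construct a gene-model table
#'
#' One row per isoform. `locus_id` groups isoforms into loci; by
#' convention the isoform identifier is `<locus_id>.<suffix>` in BED name
#' fields, but any grouping works.
#'
#' @param locus_id,isoform_id character vectors.
#' @param chrom,start,end,strand isoform span coordinates.
#' @param exon_starts,exon_ends lists of numeric vectors, absolute
#'   coordinates, one entry per isoform.
#' @param thick_start,thick_end CDS extent (equal when noncoding).
#' @return a `data.frame` of class `gene_models`.
#' @export
gene_models <- function(locus_id, isoform_id, chrom, start, end,
                        strand = "+", exon_starts, exon_ends,
                        thick_start = start, thick_end = start) {
  df <- data.frame(locus_id = as.character(locus_id),
                   isoform_id = as.character(isoform_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = strand,
                   thick_start = as.numeric(thick_start),
                   thick_end = as.numeric(thick_end),
                   stringsAsFactors = FALSE)
  df$exon_starts <- unname(lapply(exon_starts, as.numeric))
  df$exon_ends <- unname(lapply(exon_ends, as.numeric))
  validate_gene_models(df)
  class(df) <- c("gene_models", "data.frame")
  df
}

validate_gene_models <- function(df) {
  validate_intervals(df)
  for (i in seq_len(nrow(df))) {
    es <- df$exon_starts[[i]]; ee <- df$exon_ends[[i]]
    if (length(es) == 0L || length(es) != length(ee))
      stop("isoform ", df$isoform_id[i], ": malformed exon lists")
    if (any(ee <= es)) stop("isoform ", df$isoform_id[i], ": empty exon")
    if (min(es) < df$start[i] || max(ee) > df$end[i])
      stop("isoform ", df$isoform_id[i], ": exons outside span")
    if (df$thick_end[i] > df$thick_start[i] &&
        (df$thick_start[i] < df$start[i] || df$thick_end[i] > df$end[i]))
      stop("isoform ", df$isoform_id[i], ": CDS outside span")
  }
  invisible(df)
}

#' Minimal span of a locus across all isoforms
#'
#' The locus extent used for region assignment runs from the left-most
#' start to the right-most end over every transcript isoform.
#'
#' @param genes a `gene_models` table.
#' @return data.frame with one row per locus: `locus_id`, `chrom`,
#'   `start`, `end`.
#' @export
locus_spans <- function(genes) {
  sp <- split(seq_len(nrow(genes)), genes$locus_id)
  out <- data.frame(
    locus_id = names(sp),
    chrom = vapply(sp, function(i) genes$chrom[i[1]], character(1)),
    start = vapply(sp, function(i) min(genes$start[i]), numeric(1)),
    end = vapply(sp, function(i) max(genes$end[i]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$locus_id), , drop = FALSE]
}

#' @rdname locus_spans
#' @param locus_id single locus identifier.
#' @export
locus_span <- function(genes, locus_id) {
  sel <- genes$locus_id == locus_id
  if (!any(sel)) stop("unknown locus: ", locus_id)
  list(chrom = genes$chrom[sel][1],
       start = min(genes$start[sel]), end = max(genes$end[sel]))
}

## all exons of all isoforms as a flat interval table
exon_intervals <- function(genes) {
  n <- vapply(genes$exon_starts, length, integer(1))
  data.frame(chrom = rep(genes$chrom, n),
             start = unlist(genes$exon_starts),
             end = unlist(genes$exon_ends),
             stringsAsFactors = FALSE)
}

#' Select the reference isoform of each locus
#'
#' One transcript isoform per locus, the first in alphabetical order of
#' the isoform identifier -- the same deterministic rule used for protein
#' lengths and CDS alignments.
#'
#' @param genes a `gene_models` table.
#' @return `gene_models` table with one row per locus.
#' @export
select_isoforms <- function(genes) {
  keep <- unlist(lapply(split(seq_len(nrow(genes)), genes$locus_id),
                        function(i) i[order(genes$isoform_id[i])][1]),
                 use.names = FALSE)
  out <- genes[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CDS intervals of an isoform
#'
#' Intersection of the isoform's exons with its thick (CDS) extent.
#'
#' @param genes a `gene_models` table.
#' @param isoform_id transcript identifier.
#' @return interval table of CDS pieces in genomic order.
#' @export
cds_intervals <- function(genes, isoform_id) {
  i <- match(isoform_id, genes$isoform_id)
  if (is.na(i)) stop("unknown isoform: ", isoform_id)
  es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
  s <- pmax(es, genes$thick_start[i]); e <- pmin(ee, genes$thick_end[i])
  keep <- e > s
  data.frame(chrom = genes$chrom[i], start = s[keep], end = e[keep],
             stringsAsFactors = FALSE)
}
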