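## Readers and writers for the plain-text formats the pipeline consumes:
## BED3/6 for regions and elements, BED12 for gene models, bedGraph for
## replication probes, TSV for label tables, aligned FASTA for per-gene
## codon alignments. Parsing is delegated to rtracklayer/Biostrings; the
## boundary converts to the package's 0-based half-open interval tables.

gr_to_df <- function(gr) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = as.numeric(GenomicRanges::end(gr)),
                   stringsAsFactors = FALSE)
  m <- S4Vectors::mcols(gr)
  if (!is.null(m$name)) df$name <- as.character(m$name)
  if (!is.null(m$score)) df$score <- as.numeric(m$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

df_to_gr <- function(df) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
  if ("name" %in% names(df)) gr$name <- df$name
  if ("score" %in% names(df)) gr$score <- df$score
  gr
}

#' Read/write BED interval files
#'
#' BED3/BED6 files; coordinates stay 0-based half-open.
#'
#' @param path file path.
#' @return `read_bed`: an interval table.
#' @export
read_bed <- function(path) {
  gr_to_df(rtracklayer::import(path, format = "BED"))
}

#' @rdname read_bed
#' @param df interval table to write.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  rtracklayer::export(df_to_gr(df), path, format = "BED")
  invisible(path)
}

#' Read/write gene models as BED12
#'
#' One BED12 line per transcript isoform; blocks are exons, the thick
#' range is the CDS. The locus identifier is recovered from the name field
#' by stripping the final `.suffix` (FlyBase style, `FBgn0000001.RA`).
#'
#' @param path file path.
#' @return `read_genes_bed12`: a `gene_models` table.
#' @export
read_genes_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$blocks)) stop(path, ": not a BED12 file (no blocks)")
  start0 <- GenomicRanges::start(gr) - 1
  bl <- gr$blocks
  n <- S4Vectors::elementNROWS(bl)
  ul <- unlist(bl, use.names = FALSE)
  abs_start <- rep(start0, n) + IRanges::start(ul) - 1
  abs_end <- rep(start0, n) + IRanges::end(ul)
  thick <- gr$thick
  gene_models(
    locus_id = sub("\\.[^.]*$", "", gr$name),
    isoform_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    exon_starts = S4Vectors::split(abs_start, rep(seq_along(gr), n)),
    exon_ends = S4Vectors::split(abs_end, rep(seq_along(gr), n)),
    thick_start = ifelse(IRanges::width(thick) == 0, start0,
                         GenomicRanges::start(thick) - 1),
    thick_end = ifelse(IRanges::width(thick) == 0, start0,
                       as.numeric(GenomicRanges::end(thick))))
}

#' @rdname read_genes_bed12
#' @param genes a `gene_models` table to write.
#' @export
write_genes_bed12 <- function(genes, path) {
  validate_gene_models(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$name <- genes$isoform_id
  gr$score <- 0L
  gr$thick <- IRanges::IRanges(
    ifelse(genes$thick_end > genes$thick_start, genes$thick_start + 1L,
           genes$start + 1L),
    ifelse(genes$thick_end > genes$thick_start, genes$thick_end,
           genes$start))
  gr$blocks <- IRanges::IRangesList(lapply(seq_len(nrow(genes)), function(i)
    IRanges::IRanges(genes$exon_starts[[i]] - genes$start[i] + 1L,
                     genes$exon_ends[[i]] - genes$start[i])))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read/write replication-probe tracks (bedGraph)
#'
#' Four-column chrom/start/end/score tracks of signed replication-timing
#' values (early > 0, late < 0 on the source scale).
#'
#' @param path file path.
#' @return `read_bedgraph`: interval table with a `score` column.
#' @export
read_bedgraph <- function(path) {
  gr_to_df(rtracklayer::import(path, format = "bedGraph"))
}

#' @rdname read_bedgraph
#' @param df interval table with `score`.
#' @export
write_bedgraph <- function(df, path) {
  validate_intervals(df)
  stopifnot("score" %in% names(df))
  rtracklayer::export(df_to_gr(df), path, format = "bedGraph")
  invisible(path)
}

#' Read/write locus label tables
#'
#' Tab-delimited, one row per locus: `locus_id`, `protein_length`, and 0/1
#' flag columns (`human_homolog`, `mosquito_homolog`, `virilis_homolog`,
#' `testis_specific`, `expression_known`, `est_support`) plus an
#' `ncrna_class` column (`none`, `miRNA`, `snoRNA`, `tRNA`, `lincRNA`).
#'
#' @param path file path.
#' @return `read_labels`: a data.frame.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  stopifnot("locus_id" %in% names(df))
  df
}

#' @rdname read_labels
#' @param df label table.
#' @export
write_labels <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write codon alignments (aligned FASTA)
#'
#' One record per species, all rows of equal length divisible by 3, frame
#' anchored at the first column. Alphabet `A C G T - N`.
#'
#' @param path FASTA file path.
#' @return `read_codon_alignment`: a `codon_alignment`.
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  codon_alignment(stats::setNames(as.character(ss), names(ss)))
}

#' @rdname read_codon_alignment
#' @param aln a `codon_alignment`.
#' @export
write_codon_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(aln$rows)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Construct a codon alignment
#'
#' @param rows named character vector of aligned sequences (names are
#'   taxa), uppercase `A C G T - N`, equal lengths divisible by 3.
#' @return object of class `codon_alignment` with elements `taxa`, `rows`.
#' @export
codon_alignment <- function(rows) {
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  if (w %% 3L != 0L) stop("alignment length not divisible by 3")
  if (any(grepl("[^ACGTN-]", rows))) stop("alignment has invalid characters")
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("alignment rows must be named by taxon")
  structure(list(taxa = names(rows), rows = rows, width = w),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment: %d taxa x %d columns (%d codons)>\n",
              length(x$taxa), x$width, x$width %/% 3L))
  invisible(x)
}
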