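## Coordinates are 0-based, half-open ([start, end)) everywhere in this
## package, the BED convention. 1-based containers (IRanges) are used only
## internally and converted at the boundary.

#' Construct an interval table
#'
#' An interval table is the package's lightweight coordinate currency: a
#' `data.frame` with columns `chrom`, `start`, `end` (0-based, half-open)
#' and optionally `name`, `score`, `strand`. Strand is carried through but
#' ignored by all interval algebra.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param ... further columns (`name`, `score`, `strand`), recycled.
#' @return a `data.frame` of intervals.
#' @export
intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end") %in% names(df)))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval end must exceed start")
  invisible(df)
}

## split an interval table into a per-chromosome IRangesList (1-based closed)
as_irl <- function(df) {
  ir <- IRanges::IRanges(start = df$start + 1L, end = df$end)
  S4Vectors::split(ir, factor(df$chrom, levels = sort(unique(df$chrom))))
}

irl_to_df <- function(irl) {
  ul <- unlist(irl, use.names = FALSE)
  n <- S4Vectors::elementNROWS(irl)
  data.frame(chrom = rep(names(irl), n),
             start = IRanges::start(ul) - 1,
             end = as.numeric(IRanges::end(ul)),
             stringsAsFactors = FALSE)
}

#' Region sets: merged, sorted collections of genomic intervals
#'
#' A `region_set` holds disjoint intervals sorted by (chrom, start).
#' Overlapping or abutting input intervals are merged on construction, so
#' coverage sums over a region set are always well defined. Interval names
#' (e.g. cytological region labels) are kept when present; names of merged
#' intervals are concatenated with `","`.
#'
#' @param df an interval table (see [intervals()]); a `name` column is
#'   retained as per-interval region identifiers.
#' @param name identifier for the whole set.
#' @return an object of class `region_set` with elements `name` and
#'   `intervals` (the merged interval table).
#' @export
region_set <- function(df, name = "regions") {
  if (inherits(df, "region_set")) return(df)
  validate_intervals(df)
  has_names <- "name" %in% names(df) && !anyNA(df$name)
  if (nrow(df) == 0L)
    return(structure(list(name = name, intervals = empty_intervals()),
                     class = "region_set"))
  irl <- as_irl(df)
  red <- IRanges::reduce(irl)
  out <- irl_to_df(red)
  if (has_names) {
    out$name <- NA_character_
    for (i in seq_len(nrow(out))) {
      hit <- df$chrom == out$chrom[i] & df$start < out$end[i] & df$end > out$start[i]
      out$name[i] <- paste(sort(unique(df$name[hit])), collapse = ",")
    }
  } else {
    out$name <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  }
  structure(list(name = name, intervals = out), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set '%s': %d intervals, %s bp on %d chromosome(s)>\n",
              x$name, nrow(x$intervals),
              format(total_width(x), big.mark = ","),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' @export
length.region_set <- function(x) nrow(x$intervals)

#' Total number of bases covered by a region set
#' @param rs a `region_set`.
#' @return numeric base count.
#' @export
total_width <- function(rs) {
  rs <- region_set(rs)
  sum(rs$intervals$end - rs$intervals$start)
}

#' Overlap length of two intervals
#'
#' Bases shared by two half-open intervals; 0 when the chromosomes differ
#' or the intervals merely abut.
#'
#' @param a,b single-row interval tables (or lists with `chrom`, `start`,
#'   `end`).
#' @return integer number of shared bases.
#' @export
overlap_length <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  max(0, min(a$end, b$end) - max(a$start, b$start))
}

#' Fraction of a span covered by a region set
#'
#' The per-gene assignment rule ("at least 50% of the genomic length
#' covered") is a threshold on this quantity. Coverage is summed across all
#' intervals of the (merged) set, so a span straddling two regions counts
#' its combined coverage.
#'
#' @param span a single interval (list or 1-row data.frame).
#' @param regions a `region_set` or interval table.
#' @return fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(span, regions) {
  len <- span$end - span$start
  if (length(len) != 1L || len <= 0) stop("span must have positive length")
  rs <- region_set(regions)
  iv <- rs$intervals[rs$intervals$chrom == span$chrom, , drop = FALSE]
  if (nrow(iv) == 0L) return(0)
  ov <- pmax(0, pmin(iv$end, span$end) - pmax(iv$start, span$start))
  sum(ov) / len
}

## vectorized coverage for many spans against one merged set
coverage_fractions <- function(spans, regions) {
  rs <- region_set(regions)
  vapply(seq_len(nrow(spans)), function(i)
    coverage_fraction(spans[i, ], rs), numeric(1))
}

#' Base-wise intersection of two region sets
#'
#' Exact base-level AND of two sets; associative and commutative, so it can
#' be folded over any number of tracks (as done when combining the four
#' pairwise conserved-element tracks).
#'
#' @param a,b `region_set`s or interval tables.
#' @param name name for the result.
#' @return a `region_set`.
#' @export
intersect_sets <- function(a, b, name = "intersection") {
  a <- region_set(a); b <- region_set(b)
  chroms <- intersect(a$intervals$chrom, b$intervals$chrom)
  if (length(chroms) == 0L)
    return(structure(list(name = name, intervals = empty_intervals()),
                     class = "region_set"))
  da <- a$intervals[a$intervals$chrom %in% chroms, ]
  db <- b$intervals[b$intervals$chrom %in% chroms, ]
  ia <- as_irl(da); ib <- as_irl(db)
  common <- intersect(names(ia), names(ib))
  res <- S4Vectors::mendoapply(IRanges::intersect, ia[common], ib[common])
  out <- irl_to_df(res)
  if (nrow(out) == 0L) out <- empty_intervals()
  region_set(out, name = name)
}

#' Base-wise difference of two region sets
#'
#' Bases of `a` not covered by `b`.
#' @inheritParams intersect_sets
#' @return a `region_set`.
#' @export
setdiff_sets <- function(a, b, name = "difference") {
  a <- region_set(a); b <- region_set(b)
  if (nrow(a$intervals) == 0L)
    return(structure(list(name = name, intervals = empty_intervals()),
                     class = "region_set"))
  if (nrow(b$intervals) == 0L) {
    out <- a; out$name <- name
    return(out)
  }
  chroms <- sort(unique(a$intervals$chrom))
  pieces <- lapply(chroms, function(ch) {
    ia <- IRanges::IRanges(a$intervals$start[a$intervals$chrom == ch] + 1L,
                           a$intervals$end[a$intervals$chrom == ch])
    bsel <- b$intervals$chrom == ch
    if (!any(bsel)) {
      ir <- ia
    } else {
      ib <- IRanges::IRanges(b$intervals$start[bsel] + 1L,
                             b$intervals$end[bsel])
      ir <- IRanges::setdiff(ia, ib)
    }
    if (length(ir) == 0L) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1,
               end = as.numeric(IRanges::end(ir)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0L) out <- empty_intervals()
  region_set(out, name = name)
}

#' Base-wise union of region sets
#' @param ... `region_set`s or interval tables.
#' @param name name for the result.
#' @return a `region_set`.
#' @export
union_sets <- function(..., name = "union") {
  dfs <- lapply(list(...), function(x) region_set(x)$intervals[, c("chrom", "start", "end")])
  region_set(do.call(rbind, dfs), name = name)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             name = character(), stringsAsFactors = FALSE)
}

#' Partition chromosomes into exonic, intronic and intergenic space
#'
#' Produces the three-way genomic annotation used for length-proportional
#' expected counts: exonic bases are the union of exons of all isoforms of
#' all gene models; intronic bases are locus spans minus exonic bases;
#' intergenic bases are everything else. A base covered by an exon of one
#' isoform and an intron of another is exonic (exon precedence). The three
#' sets are disjoint and their union is exactly the declared chromosomes.
#'
#' @param genes a gene-model table (one row per isoform; see
#'   [read_genes_bed12()]).
#' @param chromosomes interval table of full chromosome extents.
#' @return an object of class `annotation_partition`: list with
#'   `region_set`s `exonic`, `intronic`, `intergenic`.
#' @export
partition_annotation <- function(genes, chromosomes) {
  validate_intervals(chromosomes)
  chrom_rs <- region_set(chromosomes, "chromosomes")
  spans <- locus_spans(genes)
  bad <- vapply(seq_len(nrow(spans)), function(i)
    coverage_fraction(spans[i, ], chrom_rs) < 1, logical(1))
  if (any(bad))
    stop("loci outside declared chromosomes: ",
         paste(spans$locus_id[bad], collapse = ", "))
  exonic <- region_set(exon_intervals(genes), "exonic")
  span_rs <- region_set(spans[, c("chrom", "start", "end")], "spans")
  intronic <- setdiff_sets(span_rs, exonic, name = "intronic")
  intergenic <- setdiff_sets(chrom_rs, span_rs, name = "intergenic")
  structure(list(exonic = exonic, intronic = intronic,
                 intergenic = intergenic, chromosomes = chrom_rs),
            class = "annotation_partition")
}

#' @export
print.annotation_partition <- function(x, ...) {
  cat(sprintf(
    "<annotation_partition: exonic %s bp, intronic %s bp, intergenic %s bp>\n",
    format(total_width(x$exonic), big.mark = ","),
    format(total_width(x$intronic), big.mark = ","),
    format(total_width(x$intergenic), big.mark = ",")))
  invisible(x)
}
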