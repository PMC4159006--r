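## Protein-length summaries, rank-sum comparisons, and per-locus
## replication-timing score aggregation.

#' Summarize protein lengths with explicit exclusions
#'
#' Arithmetic mean, median and quartiles of amino-acid lengths, after
#' removing entries excluded by id (e.g. a single extreme outlier such as
#' a 22,971-aa protein); exclusions are recorded in the result.
#'
#' @param lengths numeric vector of amino-acid counts, named by locus id
#'   when exclusions are used.
#' @param exclude character vector of ids to drop.
#' @return object of class `length_summary`: list with `n`, `mean`,
#'   `median`, `q1`, `q3`, `excluded_ids`.
#' @export
summarize_lengths <- function(lengths, exclude = NULL) {
  excluded <- character(0)
  if (!is.null(exclude) && length(exclude) > 0L) {
    if (is.null(names(lengths)))
      stop("lengths must be named to use exclusions")
    excluded <- intersect(exclude, names(lengths))
    lengths <- lengths[!names(lengths) %in% exclude]
  }
  if (length(lengths) == 0L) stop("no lengths left after exclusion")
  q <- stats::quantile(lengths, c(0.25, 0.5, 0.75), names = FALSE)
  structure(list(n = length(lengths), mean = mean(lengths),
                 median = q[2], q1 = q[1], q3 = q[3],
                 excluded_ids = excluded),
            class = "length_summary")
}

#' @export
print.length_summary <- function(x, ...) {
  cat(sprintf("<length_summary: n = %d, mean = %.1f aa, median = %.1f aa%s>\n",
              x$n, x$mean, x$median,
              if (length(x$excluded_ids) > 0)
                paste0(", excluded: ", paste(x$excluded_ids, collapse = ","))
              else ""))
  invisible(x)
}

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Exact enumeration when both samples have at most 50 observations and
#' there are no ties; otherwise the tie-corrected normal approximation
#' (without continuity correction).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (Mann-Whitney W), `p`, and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) <= 50L && length(y) <= 50L
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = FALSE))
  list(statistic = unname(res$statistic), p = res$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Mean replication score of one locus
#'
#' Unweighted mean of the scores of all probes overlapping the locus span
#' by at least `min_overlap` bases; `NA` when no probe qualifies (such
#' loci are excluded from group statistics).
#'
#' @param span locus span (list or 1-row data.frame with `chrom`,
#'   `start`, `end`).
#' @param probes interval table with a `score` column.
#' @param min_overlap minimum probe-locus overlap in bases (default 5).
#' @param weighted if TRUE, weight probe scores by their overlap length
#'   instead of averaging them equally.
#' @return numeric score or `NA`.
#' @export
mean_replication_score <- function(span, probes, min_overlap = 5,
                                   weighted = FALSE) {
  sel <- probes$chrom == span$chrom
  ov <- pmin(probes$end[sel], span$end) - pmax(probes$start[sel], span$start)
  qual <- ov >= min_overlap
  if (!any(qual)) return(NA_real_)
  if (weighted)
    stats::weighted.mean(probes$score[sel][qual], ov[qual])
  else
    mean(probes$score[sel][qual])
}

#' Mean replication scores for every locus
#'
#' Vectorized [mean_replication_score()] over all loci of a gene-model
#' table, using an interval-overlap index.
#'
#' @param genes a `gene_models` table.
#' @param probes interval table with `score`.
#' @inheritParams mean_replication_score
#' @return data.frame: `locus_id`, `n_probes`, `score` (`NA` when no
#'   probe overlaps by at least `min_overlap` bases).
#' @export
locus_replication_scores <- function(genes, probes, min_overlap = 5,
                                     weighted = FALSE) {
  spans <- locus_spans(genes)
  out <- data.frame(locus_id = spans$locus_id, n_probes = 0L,
                    score = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(spans$chrom)) {
    si <- which(spans$chrom == ch)
    pi <- which(probes$chrom == ch)
    if (length(pi) == 0L) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(spans$start[si] + 1L, spans$end[si]),
      IRanges::IRanges(probes$start[pi] + 1L, probes$end[pi]),
      minoverlap = min_overlap)
    if (length(hits) == 0L) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    sc <- probes$score[pi][s]
    if (weighted) {
      w <- pmin(probes$end[pi][s], spans$end[si][q]) -
        pmax(probes$start[pi][s], spans$start[si][q])
      num <- tapply(sc * w, q, sum); den <- tapply(w, q, sum)
      idx <- as.integer(names(num))
      out$score[si[idx]] <- as.numeric(num / den)
    } else {
      m <- tapply(sc, q, mean)
      idx <- as.integer(names(m))
      out$score[si[idx]] <- as.numeric(m)
    }
    nt <- table(q)
    out$n_probes[si[as.integer(names(nt))]] <- as.integer(nt)
  }
  out
}

#' Replication-timing comparison between gene classes
#'
#' Splits loci by a binary label (e.g. "conserved in human"), optionally
#' dropping a chromosome (e.g. the X for male-derived cell lines, where
#' dosage compensation advances replication), and compares per-locus mean
#' replication scores between the classes with a rank-sum test. Loci
#' without a qualifying probe are not counted.
#'
#' @param genes a `gene_models` table.
#' @param probes interval table with `score`.
#' @param labels label table with the `label` column.
#' @param label name of the 0/1 label column.
#' @param exclude_chrom optional chromosome name to drop.
#' @param breaks histogram break points for the distribution tables
#'   (default 20 equal bins over the observed range).
#' @inheritParams mean_replication_score
#' @return list with `summary` (per-class n/mean/median), `test`
#'   (rank-sum result), `scores` (per-locus table with `class`), and
#'   `histogram` (per-class bin counts).
#' @export
replication_by_class <- function(genes, probes, labels, label,
                                 exclude_chrom = NULL, min_overlap = 5,
                                 breaks = 20) {
  stopifnot(label %in% names(labels))
  spans <- locus_spans(genes)
  keep_loci <- spans$locus_id
  if (!is.null(exclude_chrom))
    keep_loci <- spans$locus_id[!spans$chrom %in% exclude_chrom]
  sc <- locus_replication_scores(genes, probes, min_overlap = min_overlap)
  sc <- sc[sc$locus_id %in% keep_loci & !is.na(sc$score), , drop = FALSE]
  lab <- labels[[label]][match(sc$locus_id, labels$locus_id)]
  sc$class <- ifelse(lab == 1, label, paste0("no_", label))
  classes <- c(label, paste0("no_", label))
  if (any(!classes %in% sc$class))
    stop("no scored loci left in class: ",
         paste(setdiff(classes, sc$class), collapse = ", "))
  x <- sc$score[sc$class == classes[1]]
  y <- sc$score[sc$class == classes[2]]
  summary <- data.frame(
    class = classes, n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)), median = c(stats::median(x), stats::median(y)),
    stringsAsFactors = FALSE)
  brk <- if (length(breaks) == 1L)
    seq(min(sc$score), max(sc$score), length.out = breaks + 1L) else breaks
  hist_tab <- do.call(rbind, lapply(classes, function(cl) {
    h <- graphics::hist(sc$score[sc$class == cl], breaks = brk, plot = FALSE)
    data.frame(class = cl, bin_low = utils::head(h$breaks, -1),
               bin_high = h$breaks[-1], count = h$counts,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, test = wilcoxon_rank_sum(x, y),
       scores = sc, histogram = hist_tab)
}
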