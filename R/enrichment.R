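## Observed/expected enrichment machinery: two-cell goodness-of-fit
## chi-squared tests with length- or fraction-proportional expectations,
## the 2x2 Pearson test, and the census builders for gene classes,
## conserved elements and noncoding RNAs.

#' Two-cell goodness-of-fit chi-squared test
#'
#' Compares an observed count against a model expectation within a total:
#' `X^2 = (O-E)^2/E + ((T-O)-(T-E))^2/(T-E)`, df = 1, upper-tail p, no
#' continuity correction. This is the test behind every expected-count
#' comparison in the gene-class and element tables.
#'
#' @param observed observed count, `0 <= observed <= total`.
#' @param expected expected count under the null, `0 < expected < total`.
#' @param total total number of trials.
#' @param category label carried into the result row.
#' @return one-row data.frame: `category`, `observed`, `expected`,
#'   `obs_over_exp`, `exp_over_obs`, `chi2`, `p`.
#' @export
gof_chi_squared <- function(observed, expected, total, category = NA_character_) {
  if (observed < 0 || observed > total)
    stop("observed must lie in [0, total]")
  if (expected <= 0 || expected >= total)
    stop("degenerate null: expected must lie strictly inside (0, total)")
  chi2 <- (observed - expected)^2 / expected +
    ((total - observed) - (total - expected))^2 / (total - expected)
  data.frame(category = category,
             observed = observed, expected = expected,
             obs_over_exp = observed / expected,
             exp_over_obs = if (observed > 0) expected / observed else NA_real_,
             chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' `X^2 = n(ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`, df = 1, without Yates
#' continuity correction (the uncorrected statistic is the one that
#' matches published EST-support comparisons of this kind).
#'
#' @param a,b,c,d cell counts (row-wise).
#' @return list with `chi2` and `p`.
#' @export
pearson_chi2_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  n <- a + b + c + d
  m <- c(a + b, c + d, a + c, b + d)
  if (any(m == 0)) stop("2x2 table has a zero margin")
  chi2 <- n * (a * d - b * c)^2 / prod(m)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Gene-class enrichment inside regions
#'
#' For a binary gene label (e.g. "has a human homolog"), compares the
#' observed number of label-positive genes among region-assigned loci with
#' the expectation under the genome-wide label frequency: `expected =
#' (genome-wide fraction of label-positive loci) x (number of assigned
#' loci)`, tested with [gof_chi_squared()]. With `stratum` given, the
#' comparison is repeated inside each stratum (e.g. testis-specific
#' vs. other among expression-annotated genes), each stratum using its own
#' genome-wide fraction.
#'
#' @param assignments output of [assign_loci()].
#' @param labels label table (see [read_labels()]).
#' @param label name of the 0/1 label column to test.
#' @param stratum optional name of a 0/1 column to stratify on; strata
#'   rows are `all`, `<stratum>`, `other`. Loci with `NA` in the stratum
#'   column are dropped from the stratified rows.
#' @return data.frame of [gof_chi_squared()] rows, one per stratum.
#' @export
gene_class_enrichment <- function(assignments, labels, label,
                                  stratum = NULL) {
  stopifnot(label %in% names(labels))
  lab <- labels[match(assignments$locus_id, labels$locus_id), ]
  if (anyNA(lab$locus_id)) stop("labels missing for some loci")
  inside <- assignments$status == "region"
  one <- function(sel, name) {
    total <- sum(inside & sel)
    if (total == 0L) {
      warning("empty stratum: ", name)
      return(NULL)
    }
    frac <- mean(lab[[label]][sel] == 1)
    obs <- sum(inside & sel & lab[[label]] == 1)
    exp <- frac * total
    if (exp <= 0 || exp >= total) {
      warning("degenerate stratum: ", name)
      return(NULL)
    }
    gof_chi_squared(obs, exp, total, category = name)
  }
  rows <- list(one(rep(TRUE, nrow(lab)), "all"))
  if (!is.null(stratum)) {
    stopifnot(stratum %in% names(labels))
    ok <- !is.na(lab[[stratum]])
    rows <- c(rows, list(one(ok & lab[[stratum]] == 1, stratum),
                         one(ok & lab[[stratum]] == 0, "other")))
  }
  do.call(rbind, rows)
}

## which partition category contains each position (exon > intron > intergenic)
category_of_positions <- function(chrom, pos, partition) {
  cats <- c("exonic", "intronic", "intergenic")
  out <- rep(NA_character_, length(pos))
  for (cat in cats) {
    iv <- partition[[cat]]$intervals
    for (ch in unique(chrom)) {
      sel <- which(chrom == ch & is.na(out))
      if (length(sel) == 0L) next
      ivc <- iv[iv$chrom == ch, , drop = FALSE]
      if (nrow(ivc) == 0L) next
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(pos[sel] + 1L, pos[sel] + 1L),
        IRanges::IRanges(ivc$start + 1L, ivc$end))
      out[sel[hit]] <- cat
    }
  }
  out
}

in_regions <- function(chrom, pos, regions) {
  rs <- region_set(regions)
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    iv <- rs$intervals[rs$intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    out[sel] <- IRanges::overlapsAny(
      IRanges::IRanges(pos[sel] + 1L, pos[sel] + 1L),
      IRanges::IRanges(iv$start + 1L, iv$end))
  }
  out
}

#' Element enrichment inside regions with length-proportional expectations
#'
#' Elements are assigned to an annotation category (exonic / intronic /
#' intergenic) by the category containing their midpoint (default; an
#' any-overlap or 50%-overlap rule is available). Per category, the
#' genome-wide element density (per Mb) times the category's length
#' inside the regions gives the expected count; the observed count is
#' tested with [gof_chi_squared()] against the category's genome-wide
#' total.
#'
#' @param elements interval table of elements.
#' @param partition an `annotation_partition`.
#' @param regions a `region_set`.
#' @param rule how an element is placed inside/outside regions:
#'   `"midpoint"` (default, makes expectations exactly
#'   length-proportional), `"any"`, or `"half"`.
#' @return data.frame with one row per category: observed, expected,
#'   ratios, chi-squared p, and genome-wide `density_per_mb`.
#' @export
element_enrichment <- function(elements, partition, regions,
                               rule = c("midpoint", "any", "half")) {
  rule <- match.arg(rule)
  validate_intervals(elements)
  rs <- region_set(regions)
  mid <- floor((elements$start + elements$end) / 2)
  cat_of <- category_of_positions(elements$chrom, mid, partition)
  inside <- switch(rule,
    midpoint = in_regions(elements$chrom, mid, rs),
    any = coverage_fractions(elements, rs) > 0,
    half = coverage_fractions(elements, rs) >= 0.5)
  rows <- list()
  for (cat in c("exonic", "intronic", "intergenic")) {
    sel <- !is.na(cat_of) & cat_of == cat
    total <- sum(sel)
    len_all <- total_width(partition[[cat]])
    len_in <- total_width(intersect_sets(partition[[cat]], rs))
    if (len_in == 0 || total == 0) next
    density <- total / (len_all / 1e6)
    expected <- density * (len_in / 1e6)
    observed <- sum(sel & inside)
    if (expected <= 0 || expected >= total) next
    row <- gof_chi_squared(observed, expected, total, category = cat)
    row$density_per_mb <- density
    row$length_in_regions <- len_in
    rows[[cat]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Census of short noncoding RNAs and lincRNAs inside regions
#'
#' Short ncRNAs (miRNA, snoRNA, tRNA) are assigned one annotation
#' category by majority of their span (exon > intron > intergenic
#' precedence on ties); per class and category, the observed count inside
#' the regions is compared with `genome-wide class count in the category x
#' (category length inside regions / category length genome-wide)`.
#' lincRNAs instead use a fractional-overlap rule (`lincrna_min_cov` of
#' their length inside the regions) and are summarized by count, mean
#' occupied length inside vs. outside, and the fraction of intergenic
#' bases covered.
#'
#' @param ncrna interval table with a `class` column (`miRNA`, `snoRNA`,
#'   `tRNA`, `lincRNA`).
#' @param partition an `annotation_partition`.
#' @param regions a `region_set`.
#' @param lincrna_min_cov coverage fraction that places a lincRNA inside
#'   the regions (default 0.5).
#' @return list with `short` (per class x category observed/expected
#'   table) and `lincrna` (summary data.frame).
#' @export
ncrna_census <- function(ncrna, partition, regions, lincrna_min_cov = 0.5) {
  stopifnot("class" %in% names(ncrna))
  rs <- region_set(regions)
  short <- ncrna[ncrna$class != "lincRNA", , drop = FALSE]
  rows <- list()
  if (nrow(short) > 0L) {
    cat_of <- vapply(seq_len(nrow(short)), function(i) {
      iv <- short[i, ]
      covs <- c(exonic = coverage_fraction(iv, partition$exonic),
                intronic = coverage_fraction(iv, partition$intronic),
                intergenic = coverage_fraction(iv, partition$intergenic))
      names(covs)[which.max(covs)]   # ties resolved by listed precedence
    }, character(1))
    inside <- coverage_fractions(short, rs) >= 0.5
    for (cl in sort(unique(short$class))) {
      for (cat in c("exonic", "intronic", "intergenic")) {
        sel <- short$class == cl & cat_of == cat
        n_cat <- sum(sel)
        len_all <- total_width(partition[[cat]])
        len_in <- total_width(intersect_sets(partition[[cat]], rs))
        expected <- n_cat * len_in / len_all
        observed <- sum(sel & inside)
        rows[[paste(cl, cat)]] <- data.frame(
          class = cl, category = cat, n_genome = n_cat,
          observed = observed, expected = expected,
          exp_over_obs = if (observed > 0) expected / observed else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  short_tab <- do.call(rbind, rows)
  if (!is.null(short_tab)) rownames(short_tab) <- NULL

  linc <- ncrna[ncrna$class == "lincRNA", , drop = FALSE]
  linc_tab <- NULL
  if (nrow(linc) > 0L) {
    cov <- coverage_fractions(linc, rs)
    inside <- cov >= lincrna_min_cov
    len <- linc$end - linc$start
    ig_in <- total_width(intersect_sets(partition$intergenic, rs))
    linc_in_rs <- region_set(linc[, c("chrom", "start", "end")], "linc")
    covered_in <- total_width(intersect_sets(linc_in_rs, rs))
    linc_tab <- data.frame(
      n_total = nrow(linc),
      n_inside = sum(inside),
      frac_inside = mean(inside),
      mean_len_inside = if (any(inside)) mean(len[inside]) else NA_real_,
      mean_len_outside = if (any(!inside)) mean(len[!inside]) else NA_real_,
      frac_intergenic_covered = if (ig_in > 0) covered_in / ig_in else NA_real_)
  }
  list(short = short_tab, lincrna = linc_tab)
}

#' Replay printed observed/expected counts
#'
#' Recomputes goodness-of-fit statistics from a table of raw counts
#' (category, observed, expected, total), reproducing published
#' chi-squared p-values without any genome data.
#'
#' @param counts data.frame with columns `category`, `observed`,
#'   `expected`, `total`.
#' @return data.frame of [gof_chi_squared()] rows.
#' @export
replay_counts <- function(counts) {
  stopifnot(all(c("category", "observed", "expected", "total") %in%
                  names(counts)))
  out <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
    gof_chi_squared(counts$observed[i], counts$expected[i],
                    counts$total[i], category = counts$category[i])))
  rownames(out) <- NULL
  out
}
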