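## Orchestration: one call runs every analysis stage on an input bundle
## and writes the report tables; a separate replay path reproduces
## published summary statistics directly from printed counts.

#' Run the full region-characterization pipeline
#'
#' Executes, in order: locus-to-region assignment, adjacent-control
#' selection, gene-class enrichment (human and mosquito homologs,
#' stratified by testis specificity), conserved-element enrichment (the
#' UCE-like track, the scored track filtered at `phastcons_min_score`,
#' and the four-track intersection set), the ncRNA census, the
#' concatenated-alignment divergence comparison (when alignments are
#' present), protein-length summaries, and the replication-timing
#' comparison. Every stage is a pure function of the inputs and
#' thresholds, so a rerun writes byte-identical tables.
#'
#' @param bundle input data: a `synthetic_bundle` or the list returned by
#'   [read_bundle()].
#' @param out_dir optional directory for tab-delimited report tables and
#'   a run log.
#' @param coverage_threshold locus assignment threshold (default 0.5).
#' @param hcne_min_len minimum intersection-element length (default 50).
#' @param probe_min_overlap minimum probe overlap in bp (default 5).
#' @param lincrna_min_cov lincRNA inside-region coverage rule (default
#'   0.5).
#' @param phastcons_min_score score cutoff for the scored element track
#'   (default 600).
#' @param element_rule element in-region membership rule (see
#'   [element_enrichment()]).
#' @return list of result tables (invisibly writes them under `out_dir`).
#' @export
run_pipeline <- function(bundle, out_dir = NULL,
                         coverage_threshold = 0.5, hcne_min_len = 50,
                         probe_min_overlap = 5, lincrna_min_cov = 0.5,
                         phastcons_min_score = 600,
                         element_rule = "midpoint") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  chroms <- bundle$chromosomes
  regions <- region_set(bundle$regions, "UR")
  genes <- bundle$genes
  labels <- bundle$labels

  assignments <- stage("assign",
    assign_loci(genes, regions, threshold = coverage_threshold))
  controls <- stage("adjacent_controls",
    select_all_controls(assignments, genes, regions))
  partition <- stage("partition",
    partition_annotation(genes, chroms[, c("chrom", "start", "end")]))

  gene_class <- stage("gene_class_enrichment", {
    rows <- lapply(c("human_homolog", "mosquito_homolog"), function(lb)
      cbind(label = lb,
            gene_class_enrichment(assignments, labels, lb,
                                  stratum = "testis_specific")))
    do.call(rbind, rows)
  })

  elements <- stage("element_enrichment", {
    pc <- bundle$elements$phastcons
    pc <- pc[!is.na(pc$score) & pc$score > phastcons_min_score, ,
             drop = FALSE]
    hcne <- build_hcne_set(bundle$elements$hcne_tracks,
                           partition$exonic, min_len = hcne_min_len)
    rows <- list(
      cbind(track = "uce",
            element_enrichment(bundle$elements$uce, partition, regions,
                               rule = element_rule)),
      cbind(track = "phastcons",
            element_enrichment(pc, partition, regions,
                               rule = element_rule)),
      cbind(track = "hcne",
            element_enrichment(hcne$intervals, partition, regions,
                               rule = element_rule)))
    do.call(rbind, rows)
  })

  ncrna <- stage("ncrna_census",
    ncrna_census(bundle$ncrna, partition, regions,
                 lincrna_min_cov = lincrna_min_cov))

  divergence <- NULL
  if (!is.null(bundle$alignments)) {
    divergence <- stage("divergence", {
      ur_ids <- intersect(assignments$locus_id[assignments$status == "region"],
                          names(bundle$alignments))
      adj_ids <- intersect(
        unique(c(controls$locus_id,
                 assignments$locus_id[assignments$status == "outside"])),
        names(bundle$alignments))
      no_human <- labels$locus_id[labels$human_homolog == 0]
      with_human <- labels$locus_id[labels$human_homolog == 1]
      subsets <- list(no_human_homolog = no_human,
                      with_human_homolog = with_human)
      ## a subset empty in either group is reported as absent, not fatal
      keep <- vapply(subsets, function(ids)
        length(intersect(intersect(ur_ids, ids), names(bundle$alignments))) > 0 &&
        length(intersect(intersect(adj_ids, ids), names(bundle$alignments))) > 0,
        logical(1))
      concatenate_and_compare(
        bundle$alignments,
        groups = list(region = ur_ids, adjacent = adj_ids),
        subsets = subsets[keep])
    })
  }

  lengths <- stage("protein_lengths", {
    pl <- stats::setNames(labels$protein_length, labels$locus_id)
    grp <- list(region = assignments$locus_id[assignments$status == "region"],
                adjacent = controls$locus_id)
    rows <- lapply(names(grp), function(g) {
      ids <- intersect(grp[[g]], names(pl)[!is.na(pl)])
      if (length(ids) == 0L) return(NULL)
      s <- summarize_lengths(pl[ids])
      data.frame(group = g, n = s$n, mean = s$mean, median = s$median,
                 q1 = s$q1, q3 = s$q3, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  replication <- stage("replication",
    replication_by_class(genes, bundle$probes, labels, "human_homolog",
                         min_overlap = probe_min_overlap))

  results <- list(assignments = assignments, controls = controls,
                  gene_class = gene_class, elements = elements,
                  ncrna = ncrna, divergence = divergence,
                  lengths = lengths, replication = replication)
  if (!is.null(out_dir)) write_report(results, out_dir, list(
    coverage_threshold = coverage_threshold, hcne_min_len = hcne_min_len,
    probe_min_overlap = probe_min_overlap,
    lincrna_min_cov = lincrna_min_cov,
    phastcons_min_score = phastcons_min_score,
    element_rule = element_rule))
  invisible(results)
}

write_report <- function(results, out_dir, thresholds) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (is.null(df)) return()
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(results$assignments, "assignments.tsv")
  wt(results$controls, "adjacent_controls.tsv")
  wt(results$gene_class, "gene_class_enrichment.tsv")
  wt(results$elements, "element_enrichment.tsv")
  wt(results$ncrna$short, "ncrna_census.tsv")
  wt(results$ncrna$lincrna, "lincrna_summary.tsv")
  if (!is.null(results$divergence)) {
    wt(results$divergence$pairs, "divergence_pairs.tsv")
    wt(results$divergence$summary, "divergence_summary.tsv")
  }
  wt(results$lengths, "protein_lengths.tsv")
  wt(results$replication$summary, "replication_summary.tsv")
  wt(results$replication$histogram, "replication_histogram.tsv")
  n_assigned <- sum(results$assignments$status == "region")
  log_lines <- c(
    sprintf("package underrep %s",
            as.character(utils::packageVersion("underrep"))),
    sprintf("thresholds: %s",
            paste(names(thresholds), unlist(thresholds), sep = "=",
                  collapse = " ")),
    sprintf("loci assigned to regions: %d of %d", n_assigned,
            nrow(results$assignments)),
    sprintf("adjacent control genes: %d (assigned gene count %d; a deficit arises when a region's flanks run out of eligible genes)",
            nrow(results$controls), n_assigned))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Published count tables for the underreplicated regions
#'
#' The printed summary counts for the 60 underreplicated UR(B) regions of
#' the D. melanogaster genome, shipped as plain-text inputs for the
#' replay path: gene conservation counts (observed, expected, total per
#' stratum), the EST-support 2x2 table, and protein-length aggregates.
#'
#' @param which one of `"homologs"`, `"est"`, `"lengths"`.
#' @return a data.frame.
#' @export
published_ur_counts <- function(which = c("homologs", "est", "lengths")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("urb_", which, ".tsv"),
                   package = "underrep")
  if (f == "") stop("count table not found; is the package installed?")
  utils::read.delim(f, stringsAsFactors = FALSE)
}

#' Adjust a mean after removing one known value
#'
#' Bookkeeping identity `(n * mean - x) / (n - 1)`, used to reproduce
#' published protein-length averages after excluding a single extreme
#' protein from a printed (n, mean) pair.
#'
#' @param n sample size.
#' @param mean sample mean.
#' @param value the value removed.
#' @return the mean of the remaining `n - 1` values.
#' @export
adjust_mean_without <- function(n, mean, value) {
  if (n < 2) stop("need n >= 2")
  (n * mean - value) / (n - 1)
}

#' Replay published summary statistics from printed counts
#'
#' Recomputes, from the shipped count tables alone (no genome data): the
#' gene-conservation goodness-of-fit chi-squared p-values per stratum,
#' the EST-support Pearson 2x2 chi-square, the protein-length means after
#' excluding the single 22,971-aa protein, and the testis-specific gene
#' fraction.
#'
#' @return list with `homologs` (a [replay_counts()] table), `est`
#'   (`chi2`, `p`), `lengths` (means after exclusion), and
#'   `testis_fraction`.
#' @export
replay_published_tables <- function() {
  hom <- replay_counts(published_ur_counts("homologs"))
  est <- published_ur_counts("est")
  est_res <- pearson_chi2_2x2(est$with_est[1], est$without_est[1],
                              est$with_est[2], est$without_est[2])
  len <- published_ur_counts("lengths")
  get <- function(g, col) len[[col]][len$group == g]
  outlier <- get("ur_longest_protein", "mean")
  lengths <- data.frame(
    group = c("ur_all", "ur_human_homolog"),
    n = c(get("ur_all", "n"), get("ur_human_homolog", "n")),
    mean = c(get("ur_all", "mean"), get("ur_human_homolog", "mean")),
    mean_without_outlier = c(
      adjust_mean_without(get("ur_all", "n"), get("ur_all", "mean"),
                          outlier),
      adjust_mean_without(get("ur_human_homolog", "n"),
                          get("ur_human_homolog", "mean"), outlier)),
    stringsAsFactors = FALSE)
  hom_tab <- published_ur_counts("homologs")
  testis_n <- hom_tab$total[hom_tab$category == "human_testis_specific"]
  expr_n <- len$n[len$group == "ur_expression_annotated"]
  list(homologs = hom, est = est_res, lengths = lengths,
       testis_fraction = testis_n / expr_n)
}
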