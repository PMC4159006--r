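## Assignment of loci to underreplicated regions, matched adjacent-gene
## control selection, and conserved-element set construction.

#' Assign loci to a region set by fractional span coverage
#'
#' A locus belongs to the region set when at least `threshold` of its
#' genomic span (left-most start to right-most end over all isoforms) is
#' covered by the (merged) regions; coverage is summed across regions, so
#' a locus straddling two regions counts its combined coverage. Each
#' assigned locus is labelled with the region contributing the most
#' overlap.
#'
#' @param genes a `gene_models` table.
#' @param regions a `region_set` (or interval table) of target regions.
#' @param threshold minimum covered fraction, in (0, 1]; default 0.5
#'   ("at least 50%"), and the boundary case is assigned.
#' @return data.frame: `locus_id`, `status` (`"region"`/`"outside"`),
#'   `region` (name of best-overlapping region or `NA`), `coverage`.
#' @export
assign_loci <- function(genes, regions, threshold = 0.5) {
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  rs <- region_set(regions)
  spans <- locus_spans(genes)
  cov <- coverage_fractions(spans, rs)
  assigned <- cov >= threshold
  region <- rep(NA_character_, nrow(spans))
  iv <- rs$intervals
  for (i in which(assigned)) {
    sel <- iv$chrom == spans$chrom[i]
    ov <- pmax(0, pmin(iv$end[sel], spans$end[i]) -
                  pmax(iv$start[sel], spans$start[i]))
    region[i] <- iv$name[sel][which.max(ov)]
  }
  data.frame(locus_id = spans$locus_id,
             status = ifelse(assigned, "region", "outside"),
             region = region, coverage = cov,
             stringsAsFactors = FALSE)
}

#' Select matched adjacent-gene controls for one region
#'
#' For a region containing `n` assigned genes, selects the `n` nearest
#' eligible genes in the flanking sequence space: `ceiling(n/2)` upstream
#' (by span end, descending) and `floor(n/2)` downstream (by span start,
#' ascending). Eligible genes are not assigned to any region of the set
#' and overlap no region by even a single base. When one side runs out of
#' eligible genes the deficit is taken from the other side; if both sides
#' combined cannot supply `n` genes, an error names the region.
#'
#' @param region_name name of the region (as in the assignment table).
#' @param assignments output of [assign_loci()] for the same gene set.
#' @param genes the `gene_models` table.
#' @param regions the full `region_set` (for the overlap exclusion).
#' @param n number of controls; defaults to the region's assigned count.
#' @return data.frame like `assignments` with `status = "adjacent"`,
#'   `region = region_name`, plus a `side` column.
#' @export
select_adjacent_controls <- function(region_name, assignments, genes,
                                     regions, n = NULL) {
  rs <- region_set(regions)
  iv <- rs$intervals
  ri <- which(iv$name == region_name)
  if (length(ri) != 1L) stop("unknown region: ", region_name)
  if (is.null(n))
    n <- sum(assignments$status == "region" &
               assignments$region == region_name, na.rm = TRUE)
  if (n == 0L)
    return(data.frame(locus_id = character(), status = character(),
                      region = character(), coverage = numeric(),
                      side = character(), stringsAsFactors = FALSE))
  spans <- locus_spans(genes)
  spans <- spans[match(assignments$locus_id, spans$locus_id), ]
  unassigned <- assignments$status == "outside"
  no_overlap <- coverage_fractions(spans, rs) == 0
  eligible <- unassigned & no_overlap & spans$chrom == iv$chrom[ri]

  up <- which(eligible & spans$end <= iv$start[ri])
  up <- up[order(-spans$end[up], spans$locus_id[up])]
  down <- which(eligible & spans$start >= iv$end[ri])
  down <- down[order(spans$start[down], spans$locus_id[down])]

  n_up <- ceiling(n / 2); n_down <- n - n_up
  if (length(up) < n_up) { n_down <- n - length(up); n_up <- length(up) }
  if (length(down) < n_down) {
    n_up <- min(n - length(down), length(up)); n_down <- n - n_up
  }
  if (n_up + n_down < n || length(down) < n_down)
    stop("region ", region_name, ": only ", length(up) + length(down),
         " eligible adjacent genes for ", n, " assigned genes")
  take <- c(up[seq_len(n_up)], down[seq_len(n_down)])
  data.frame(locus_id = spans$locus_id[take],
             status = "adjacent", region = region_name,
             coverage = 0,
             side = rep(c("upstream", "downstream"), c(n_up, n_down)),
             stringsAsFactors = FALSE)
}

#' Select adjacent controls for every region
#'
#' Applies [select_adjacent_controls()] region by region, in coordinate
#' order, never reusing a gene already taken as a control for an earlier
#' region.
#'
#' @inheritParams select_adjacent_controls
#' @return combined control data.frame.
#' @export
select_all_controls <- function(assignments, genes, regions) {
  rs <- region_set(regions)
  iv <- rs$intervals
  counts <- table(assignments$region[assignments$status == "region"])
  out <- list()
  taken <- character()
  for (i in seq_len(nrow(iv))) {
    rn <- iv$name[i]
    n <- if (rn %in% names(counts)) counts[[rn]] else 0L
    if (n == 0L) next
    masked <- assignments
    masked$status[masked$locus_id %in% taken] <- "control_used"
    ctrl <- select_adjacent_controls(rn, masked, genes, rs, n = n)
    taken <- c(taken, ctrl$locus_id)
    out[[rn]] <- ctrl
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the filtered conserved-noncoding-element set
#'
#' Base-wise AND of four pairwise conservation tracks, then removal of
#' intervals shorter than `min_len` and of intervals overlapping exonic
#' space by one or more bases. The result is invariant under permutation
#' of the input tracks.
#'
#' @param tracks list of four `region_set`s (or interval tables).
#' @param exonic `region_set` of exonic bases.
#' @param min_len minimum element length in bases (default 50).
#' @return a `region_set` of surviving elements.
#' @export
build_hcne_set <- function(tracks, exonic, min_len = 50) {
  if (length(tracks) < 2L) stop("need at least two tracks to intersect")
  common <- Reduce(intersect_sets, lapply(tracks, region_set))
  iv <- common$intervals
  iv <- iv[iv$end - iv$start >= min_len, , drop = FALSE]
  if (nrow(iv) > 0L) {
    exon_rs <- region_set(exonic)
    ov <- vapply(seq_len(nrow(iv)), function(i)
      coverage_fraction(iv[i, ], exon_rs) > 0, logical(1))
    iv <- iv[!ov, , drop = FALSE]
  }
  if (nrow(iv) == 0L) iv <- empty_intervals()
  region_set(iv, name = "hcne")
}
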