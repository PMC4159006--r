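## Seeded synthetic-genome generator. Produces a multi-chromosome genome
## in which gene conservation probability, conserved-element density and
## replication score differ inside vs. outside a set of designated
## regions, plus per-gene multi-species codon alignments with a
## group-specific nonsynonymous rate -- and a manifest recording every
## planted truth, so each pipeline stage can be validated end to end.
## Identical seeds give byte-identical bundles.

#' Synthetic genome configuration
#'
#' Defaults emulate, at roughly one-fifth genome scale, the statistical
#' structure of the underreplicated regions of the D. melanogaster
#' genome: ~12% of the genome inside regions at about half the outside
#' gene density; conservation-label probabilities of 0.11 inside
#' vs. 0.43 outside (human) and 0.54 vs. 0.79 (mosquito); conserved
#' elements about 2x denser in intronic space inside regions; early
#' replication (score 1.4) for conserved vs. late (0.5) for nonconserved
#' genes; and a 1.4x higher nonsynonymous rate for region genes.
#'
#' @param seed integer; mandatory source of all randomness.
#' @param chromosomes named numeric vector of chromosome lengths (bp).
#' @param n_regions number of designated regions.
#' @param region_length_range min/max region length (bp).
#' @param n_loci number of protein-coding loci.
#' @param frac_loci_inside fraction of loci planted fully inside regions.
#' @param n_straddle loci planted across a region boundary with partial
#'   coverage (exercises the 50% rule); 0 by default.
#' @param region_margin gap (bp) kept free between regions and outside
#'   genes; straddling loci extend at most this far outside.
#' @param multi_isoform_prob fraction of loci given a second, shorter
#'   isoform (exercises span and isoform-selection rules).
#' @param gene_length long-tailed gene-span model: lognormal
#'   `meanlog`/`sdlog`, floor `min`, and probability `p_long` of a very
#'   long gene drawn uniformly from `long_range`.
#' @param label_probabilities per-flag Bernoulli probabilities, each
#'   `c(inside, outside)`.
#' @param est_support EST-evidence probability given presence/absence of
#'   a D. virilis homolog.
#' @param protein_length lognormal amino-acid length parameters for
#'   homolog vs. non-homolog genes.
#' @param element_densities per-Mb element densities `c(inside, outside)`
#'   per annotation category, with length models, for `uce`, `phastcons`
#'   (scored) and `hcne` core elements (plus decoy/short/exonic rates for
#'   the four pairwise tracks).
#' @param ncrna short ncRNA counts, their inside-density factors,
#'   category mixes, and lincRNA length model (kb, inside vs. outside).
#' @param replication probe tiling and score model: class means
#'   (conserved/nonconserved/intergenic), noise sd.
#' @param codon_model codon-alignment simulation: codons per gene,
#'   pairwise synonymous divergence `ds`, `dn_ds` ratio, the region-group
#'   nonsynonymous multiplier `region_dn_factor`, transition/transversion
#'   ratio `kappa`, taxa, masking rates, genes per group.
#' @param simulate_alignments generate per-gene codon alignments.
#' @return a `synthetic_genome_config` list.
#' @export
synthetic_genome_config <- function(
    seed,
    chromosomes = c(chrX = 5e6, chr2 = 7e6, chr3 = 8e6),
    n_regions = 12,
    region_length_range = c(120e3, 280e3),
    n_loci = 2200,
    frac_loci_inside = 0.068,
    n_straddle = 0,
    region_margin = 1000,
    multi_isoform_prob = 0,
    gene_length = list(meanlog = log(2200), sdlog = 1.1, min = 400,
                       p_long = 0.012, long_range = c(3e4, 6e4)),
    label_probabilities = list(
      human_homolog = c(inside = 0.11, outside = 0.43),
      mosquito_homolog = c(inside = 0.54, outside = 0.79),
      virilis_homolog = c(inside = 0.93, outside = 0.97),
      expression_known = c(inside = 0.90, outside = 0.90),
      testis_specific = c(inside = 0.35, outside = 0.13)),
    est_support = c(homolog = 0.90, no_homolog = 0.83),
    protein_length = list(homolog = c(meanlog = log(560), sdlog = 0.8),
                          no_homolog = c(meanlog = log(280), sdlog = 0.7)),
    element_densities = list(
      uce = list(densities = list(exonic = c(2, 2),
                                  intronic = c(24.3, 11.0),
                                  intergenic = c(30.6, 23.2)),
                 min_len = 100, len_geom_mean = 60),
      phastcons = list(densities = list(exonic = c(30, 30),
                                        intronic = c(189, 93),
                                        intergenic = c(233, 190)),
                       min_len = 20, len_geom_mean = 60,
                       score_min = 600, score_exp_mean = 150),
      hcne = list(densities = list(intronic = c(121, 49),
                                   intergenic = c(158, 105)),
                  min_len = 50, len_geom_mean = 40,
                  decoy_per_mb = 30, short_per_mb = 5, exonic_per_mb = 3,
                  max_flank = 30)),
    ncrna = list(
      counts = c(miRNA = 40, snoRNA = 40, tRNA = 60, lincRNA = 180),
      lengths = c(miRNA = 80, snoRNA = 120, tRNA = 75),
      category_mix = list(miRNA = c(exonic = 0.05, intronic = 0.45,
                                    intergenic = 0.50),
                          snoRNA = c(exonic = 0.03, intronic = 0.57,
                                     intergenic = 0.40),
                          tRNA = c(exonic = 0, intronic = 0.20,
                                   intergenic = 0.80)),
      short_inside_factor = c(miRNA = 0.2, snoRNA = 0.0, tRNA = 0.3),
      lincrna_len_kb = c(inside = 2.2, outside = 1.7),
      lincrna_sdlog = 0.5),
    replication = list(means = c(conserved = 1.4, nonconserved = 0.5,
                                 intergenic = 0),
                       sd = 1.0, probe_len = 300, probe_step = 1000),
    codon_model = list(n_codons = 150, ds = 0.3, dn_ds = 0.10,
                       region_dn_factor = 1.4, kappa = 2,
                       taxa = c("dmel", "dsim", "dyak", "dere",
                                "dana", "dpse", "dper", "dwil"),
                       gap_codon_prob = 0.01, n_codon_prob = 0.002,
                       n_genes_per_group = 60),
    simulate_alignments = TRUE) {
  if (missing(seed)) stop("a seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(all(unlist(lapply(label_probabilities, function(p)
    p >= 0 & p <= 1))),
    frac_loci_inside > 0, frac_loci_inside < 1,
    n_regions >= 1, n_loci >= 2)
  class(cfg) <- "synthetic_genome_config"
  cfg
}

## -- low-level placement helpers ------------------------------------------

## n points placed uniformly inside an interval set (weighted by width)
sample_positions <- function(space_df, n) {
  w <- space_df$end - space_df$start
  iv <- sample.int(nrow(space_df), n, replace = TRUE, prob = w)
  pos <- space_df$start[iv] + floor(stats::runif(n) * w[iv])
  data.frame(chrom = space_df$chrom[iv], pos = pos,
             iv_start = space_df$start[iv], iv_end = space_df$end[iv],
             stringsAsFactors = FALSE)
}

#' Place elements uniformly within an interval space
#'
#' Draws a Poisson number of elements at `density_per_mb` over the space
#' and places each uniformly (interval chosen proportional to its width),
#' clamping elements to fit their interval. With `avoid` given, elements
#' overlapping those intervals (or each other, when `disjoint = TRUE`)
#' are re-drawn.
#'
#' @param space interval table or `region_set` defining allowed bases.
#' @param density_per_mb expected elements per megabase of space.
#' @param min_len,len_geom_mean element length model: `min_len` plus a
#'   geometric tail with this mean.
#' @param avoid optional interval table of forbidden zones.
#' @param disjoint keep placed elements non-overlapping (default TRUE).
#' @param n override the Poisson draw with a fixed count.
#' @param fit_length when TRUE, each element is placed only in intervals
#'   at least as wide as its drawn length (no clamping), preserving the
#'   length distribution of long elements.
#' @return interval table of elements.
#' @export
place_elements <- function(space, density_per_mb, min_len = 1,
                           len_geom_mean = 50, avoid = NULL,
                           disjoint = TRUE, n = NULL, fit_length = FALSE) {
  space_df <- region_set(space)$intervals
  if (nrow(space_df) == 0L) return(empty_intervals()[, 1:3])
  mb <- sum(space_df$end - space_df$start) / 1e6
  if (is.null(n)) n <- stats::rpois(1, density_per_mb * mb)
  if (n == 0L) return(empty_intervals()[, 1:3])
  placed <- empty_intervals()[, 1:3]
  attempts <- 0L
  while (nrow(placed) < n && attempts < 50L) {
    attempts <- attempts + 1L
    need <- n - nrow(placed)
    len <- min_len + stats::rgeom(need, 1 / max(2, len_geom_mean))
    if (fit_length) {
      p <- do.call(rbind, lapply(len, function(l) {
        sp <- space_df[space_df$end - space_df$start >= l, , drop = FALSE]
        if (nrow(sp) == 0L) sp <- space_df   # nothing fits: clamp after all
        sample_positions(sp, 1L)
      }))
    } else {
      p <- sample_positions(space_df, need)
    }
    len <- pmin(len, p$iv_end - p$iv_start)
    start <- pmin(p$pos, p$iv_end - len)
    cand <- data.frame(chrom = p$chrom, start = start, end = start + len,
                       stringsAsFactors = FALSE)
    ok <- rep(TRUE, nrow(cand))
    if (!is.null(avoid) && nrow(avoid) > 0L)
      ok <- ok & !overlaps_any_df(cand, avoid)
    if (disjoint && nrow(placed) > 0L)
      ok <- ok & !overlaps_any_df(cand, placed)
    cand <- cand[ok, , drop = FALSE]
    if (disjoint && nrow(cand) > 1L) {
      keep <- !duplicated_overlaps(cand)
      cand <- cand[keep, , drop = FALSE]
    }
    placed <- rbind(placed, cand[seq_len(min(nrow(cand), need)), ,
                                 drop = FALSE])
  }
  placed <- placed[order(placed$chrom, placed$start), , drop = FALSE]
  rownames(placed) <- NULL
  placed
}

overlaps_any_df <- function(a, b) {
  out <- logical(nrow(a))
  for (ch in unique(a$chrom)) {
    ai <- which(a$chrom == ch); bi <- which(b$chrom == ch)
    if (length(bi) == 0L) next
    out[ai] <- IRanges::overlapsAny(
      IRanges::IRanges(a$start[ai] + 1L, a$end[ai]),
      IRanges::IRanges(b$start[bi] + 1L, b$end[bi]))
  }
  out
}

## marks rows overlapping an earlier row in the same table
duplicated_overlaps <- function(df) {
  out <- logical(nrow(df))
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    o <- i[order(df$start[i])]
    last_end <- -Inf
    for (k in o) {
      if (df$start[k] < last_end) out[k] <- TRUE
      else last_end <- df$end[k]
    }
  }
  out
}

## pack given gene lengths into an interval without overlap, via uniform
## spacings of the leftover room
pack_into_interval <- function(iv_start, iv_end, lengths) {
  n <- length(lengths)
  slack <- (iv_end - iv_start) - sum(lengths)
  stopifnot(slack >= 0)
  gaps <- floor(diff(c(0, sort(stats::runif(n)), 1)) * slack)
  lengths <- lengths[sample.int(n)]
  starts <- iv_start + utils::head(cumsum(c(0, lengths)), n) +
    cumsum(gaps[seq_len(n)])
  data.frame(start = starts, end = starts + lengths,
             len = lengths, stringsAsFactors = FALSE)
}

## -- main generator --------------------------------------------------------

#' Simulate a genome bundle with planted ground truth
#'
#' Generates regions, gene models with exon/CDS structure, per-locus
#' labels, conserved-element tracks (a UCE-like set, a scored set, and
#' four pairwise tracks whose AND-intersection is known), a replication
#' probe track, noncoding RNAs, and (optionally) per-gene codon
#' alignments for a region group and a control group. The returned
#' `manifest` is the single source of planted truth for every downstream
#' check. All randomness flows from `config$seed`; the same seed yields
#' an identical bundle.
#'
#' @param config a [synthetic_genome_config()].
#' @param out_dir optional directory; when given, the bundle is written
#'   with [write_bundle()].
#' @return object of class `synthetic_bundle`: list with `chromosomes`,
#'   `regions`, `genes`, `labels`, `elements` (`uce`, `phastcons`,
#'   `hcne_tracks`), `ncrna`, `probes`, `alignments`, `manifest`.
#' @export
simulate_genome <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_genome_config"))
  bundle <- withr::with_seed(config$seed, simulate_genome_impl(config))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

simulate_genome_impl <- function(cfg) {
  chroms <- data.frame(chrom = names(cfg$chromosomes), start = 0,
                       end = as.numeric(cfg$chromosomes),
                       stringsAsFactors = FALSE)

  ## regions: allocate per chromosome by length, place in equal slots
  n_per <- diff(round(cumsum(c(0, cfg$chromosomes)) /
                        sum(cfg$chromosomes) * cfg$n_regions))
  reg <- list()
  k <- 0L
  for (ci in seq_len(nrow(chroms))) {
    ni <- n_per[ci]
    if (ni == 0L) next
    slot <- (chroms$end[ci] - 2e5) / ni
    for (j in seq_len(ni)) {
      k <- k + 1L
      len <- round(stats::runif(1, cfg$region_length_range[1],
                                cfg$region_length_range[2]))
      len <- min(len, floor(slot * 0.8))
      lo <- 1e5 + (j - 1) * slot
      start <- round(stats::runif(1, lo, lo + slot - len))
      reg[[k]] <- data.frame(chrom = chroms$chrom[ci], start = start,
                             end = start + len,
                             name = sprintf("UR%02d", k),
                             stringsAsFactors = FALSE)
    }
  }
  regions_df <- do.call(rbind, reg)
  regions <- region_set(regions_df, "UR")

  ## locus compartments
  n_inside <- max(1L, round(cfg$n_loci * cfg$frac_loci_inside))
  n_straddle <- min(cfg$n_straddle, nrow(regions_df))
  n_outside <- cfg$n_loci - n_inside - n_straddle
  status <- c(rep("inside", n_inside), rep("outside", n_outside),
              rep("straddle", n_straddle))

  ## labels drawn per compartment (straddlers use outside probabilities)
  is_in <- status == "inside"
  lab <- data.frame(locus_id = sprintf("SG%05d", seq_len(cfg$n_loci)),
                    stringsAsFactors = FALSE)
  for (fl in names(cfg$label_probabilities)) {
    p <- cfg$label_probabilities[[fl]]
    lab[[fl]] <- as.integer(stats::runif(cfg$n_loci) <
                              ifelse(is_in, p["inside"], p["outside"]))
  }
  ## testis classification only exists for expression-annotated genes
  lab$testis_specific[lab$expression_known == 0] <- NA_integer_
  lab$est_support <- as.integer(
    stats::runif(cfg$n_loci) <
      ifelse(lab$virilis_homolog == 1, cfg$est_support["homolog"],
             cfg$est_support["no_homolog"]))
  lab$ncrna_class <- "none"

  ## protein lengths by conservation class
  pl_par <- ifelse(lab$human_homolog == 1, "homolog", "no_homolog")
  plen <- vapply(seq_len(cfg$n_loci), function(i) {
    par <- cfg$protein_length[[pl_par[i]]]
    max(50, round(stats::rlnorm(1, par["meanlog"], par["sdlog"])))
  }, numeric(1))
  lab$protein_length <- plen

  ## gene spans: long-tailed, never shorter than CDS + UTR + intron room
  gl <- cfg$gene_length
  span_len <- round(stats::rlnorm(cfg$n_loci, gl$meanlog, gl$sdlog))
  long <- stats::runif(cfg$n_loci) < gl$p_long
  span_len[long] <- round(stats::runif(sum(long), gl$long_range[1],
                                       gl$long_range[2]))
  cds_len <- 3 * (plen + 1)
  span_len <- pmax(span_len, gl$min, cds_len + 150 + 120)

  ## placement: inside loci packed into regions, outside loci into the
  ## complement minus a margin, straddlers across region left edges
  margin <- cfg$region_margin
  out_space <- setdiff_sets(
    region_set(chroms),
    region_set(data.frame(chrom = regions_df$chrom,
                          start = pmax(0, regions_df$start - margin),
                          end = pmin(
                            chroms$end[match(regions_df$chrom, chroms$chrom)],
                            regions_df$end + margin))))$intervals
  loci_pos <- vector("list", cfg$n_loci)
  straddle_truth <- NULL
  if (n_straddle > 0L) {
    rows <- list()
    for (j in seq_len(n_straddle)) {
      rg <- regions_df[j, ]
      covf <- stats::runif(1, 0.05, 0.95)
      i <- n_inside + n_outside + j
      len <- min(span_len[i], floor(0.9 * margin / (1 - covf)),
                 floor(0.9 * (rg$end - rg$start) / covf))
      len <- max(len, 30L)
      span_len[i] <- len
      ov <- round(covf * len)
      start <- rg$start - (len - ov)
      loci_pos[[i]] <- data.frame(chrom = rg$chrom, start = start,
                                  end = start + len)
      rows[[j]] <- data.frame(locus_id = lab$locus_id[i],
                              coverage = ov / len,
                              stringsAsFactors = FALSE)
    }
    straddle_truth <- do.call(rbind, rows)
  }
  place_compartment <- function(idx, space_df) {
    lens <- span_len[idx]
    caps <- (space_df$end - space_df$start) * 0.8
    assign <- integer(length(idx))
    used <- numeric(nrow(space_df))
    for (o in order(-lens)) {
      room <- caps - used - lens[o]
      cand <- which(room >= 0)
      if (length(cand) == 0L) stop("infeasible config: genes exceed space")
      pick <- cand[sample.int(length(cand), 1, prob = room[cand] + 1)]
      assign[o] <- pick
      used[pick] <- used[pick] + lens[o]
    }
    for (s in unique(assign)) {
      sel <- which(assign == s)
      packed <- pack_into_interval(space_df$start[s], space_df$end[s],
                                   lens[sel])
      reord <- order(packed$len)[rank(lens[sel], ties.method = "first")]
      for (q in seq_along(sel))
        loci_pos[[idx[sel[q]]]] <<- data.frame(
          chrom = space_df$chrom[s], start = packed$start[reord[q]],
          end = packed$end[reord[q]])
    }
  }
  ## region space available for inside genes, minus straddler intrusions
  in_space <- regions_df[, c("chrom", "start", "end")]
  if (n_straddle > 0L)
    for (j in seq_len(n_straddle)) {
      intr <- loci_pos[[n_inside + n_outside + j]]
      in_space$start[j] <- max(in_space$start[j], intr$end + 10)
    }
  place_compartment(which(status == "inside"), in_space)
  place_compartment(which(status == "outside"), out_space)
  pos <- do.call(rbind, loci_pos)
  pos$locus_id <- lab$locus_id

  ## exon/intron structure; CDS centred with 75-bp UTRs
  genes <- build_gene_structures(pos, cds_len, cfg$multi_isoform_prob)

  partition <- partition_annotation(genes, chroms)

  ## conserved elements
  spaces <- list()
  for (cat in c("exonic", "intronic", "intergenic")) {
    spaces[[cat]] <- list(
      inside = intersect_sets(partition[[cat]], regions),
      outside = setdiff_sets(partition[[cat]], regions))
  }
  make_track <- function(spec) {
    pieces <- list(); counts <- list()
    for (cat in names(spec$densities)) {
      for (side in c("inside", "outside")) {
        d <- spec$densities[[cat]][if (side == "inside") 1 else 2]
        el <- place_elements(spaces[[cat]][[side]], d,
                             min_len = spec$min_len,
                             len_geom_mean = spec$len_geom_mean)
        counts[[paste(cat, side)]] <- data.frame(
          category = cat, side = side, count = nrow(el),
          stringsAsFactors = FALSE)
        pieces[[paste(cat, side)]] <- el
      }
    }
    list(elements = do.call(rbind, pieces), counts = do.call(rbind, counts))
  }
  uce <- make_track(cfg$element_densities$uce)
  pc <- make_track(cfg$element_densities$phastcons)
  pc$elements$score <- round(cfg$element_densities$phastcons$score_min +
    stats::rexp(nrow(pc$elements),
                1 / cfg$element_densities$phastcons$score_exp_mean))
  hcne <- simulate_hcne_tracks(cfg$element_densities$hcne, spaces,
                               partition, chroms)

  ## noncoding RNAs
  nc <- simulate_ncrna(cfg$ncrna, spaces, regions, chroms)
  ncrna_ids <- nc$ncrna
  lab2 <- lab

  ## replication probes
  probes <- simulate_probes(cfg$replication, chroms, genes, lab)

  ## codon alignments for a region group and an outside control group
  alignments <- NULL; aln_truth <- NULL
  if (isTRUE(cfg$simulate_alignments)) {
    cm <- cfg$codon_model
    n_g <- cm$n_genes_per_group
    ur_ids <- lab$locus_id[status == "inside"][seq_len(min(n_g, n_inside))]
    out_ids <- lab$locus_id[status == "outside"][seq_len(min(n_g, n_outside))]
    sim_group <- function(ids, dn_mult) {
      lapply(stats::setNames(ids, ids), function(id)
        simulate_codon_alignment(cm$n_codons, taxa = cm$taxa, ds = cm$ds,
                                 dn_mult = dn_mult, kappa = cm$kappa,
                                 gap_codon_prob = cm$gap_codon_prob,
                                 n_codon_prob = cm$n_codon_prob))
    }
    sims <- c(sim_group(ur_ids, cm$dn_ds * cm$region_dn_factor),
              sim_group(out_ids, cm$dn_ds))
    alignments <- lapply(sims, function(s) s$alignment)
    aln_truth <- list(
      groups = list(region = ur_ids, adjacent = out_ids),
      events = lapply(sims, function(s) s$events),
      site_classes = lapply(sims, function(s) s$site_classes))
  }

  manifest <- list(
    config = cfg,
    regions = regions_df,
    loci = cbind(pos[, c("locus_id", "chrom", "start", "end")],
                 status = status,
                 lab[, setdiff(names(lab), "locus_id")]),
    straddle = straddle_truth,
    element_counts = rbind(cbind(type = "uce", uce$counts),
                           cbind(type = "phastcons", pc$counts)),
    hcne_truth = hcne$truth,
    ncrna_truth = nc$truth,
    replication = cfg$replication,
    alignment_truth = aln_truth)

  structure(list(chromosomes = chroms, regions = regions,
                 genes = genes, labels = lab2,
                 elements = list(uce = uce$elements,
                                 phastcons = pc$elements,
                                 hcne_tracks = hcne$tracks),
                 ncrna = ncrna_ids, probes = probes,
                 alignments = alignments, manifest = manifest),
            class = "synthetic_bundle")
}

build_gene_structures <- function(pos, cds_len, multi_isoform_prob) {
  n <- nrow(pos)
  rows <- vector("list", n)
  extra <- list()
  n_ex_draw <- pmin(1L + stats::rpois(n, 2), 8L)
  second <- stats::runif(n) < multi_isoform_prob
  for (i in seq_len(n)) {
    L <- pos$end[i] - pos$start[i]
    E <- cds_len[i] + 150
    k <- max(1L, min(n_ex_draw[i], (L - E) %/% 80L + 1L))
    ## split exon space into k pieces of >= 30 bp (uniform spacings)
    if (k > 1L) {
      cuts <- floor(diff(c(0, sort(stats::runif(k - 1)), 1)) * (E - 30L * k))
      exl <- 30L + cuts
      exl[k] <- E - sum(exl[-k])
    } else {
      E <- L    # a single exon must cover the whole span (BED12 blocks)
      exl <- E
    }
    intr_total <- L - E
    gaps <- if (k > 1L) {
      ## introns of >= 60 bp splitting the leftover span
      g_extra <- intr_total - 60L * (k - 1L)
      60L + utils::head(floor(diff(c(0, sort(stats::runif(k - 1)), 1)) *
                                g_extra), k - 1L)
    } else integer(0)
    es <- pos$start[i] + utils::head(cumsum(c(0, exl)), k) +
      cumsum(c(0, gaps))
    ee <- es + exl
    ee[k] <- pos$end[i]
    es[k] <- ee[k] - exl[k]
    ## CDS in exon space: skip 75 bp of 5' UTR
    exon_off <- cumsum(c(0, exl))[seq_len(k)]
    tpos <- function(off) {    # exon-space offset -> genomic
      j <- findInterval(off, exon_off)
      es[j] + (off - exon_off[j])
    }
    thick_s <- tpos(75)
    thick_e <- tpos(75 + cds_len[i] - 1) + 1
    rows[[i]] <- list(locus_id = pos$locus_id[i],
                      isoform_id = paste0(pos$locus_id[i], ".RA"),
                      chrom = pos$chrom[i], start = pos$start[i],
                      end = pos$end[i],
                      strand = if (i %% 2 == 0) "-" else "+",
                      es = es, ee = ee,
                      thick_s = thick_s, thick_e = thick_e)
    if (second[i] && k >= 2L) {
      extra[[length(extra) + 1L]] <- list(
        locus_id = pos$locus_id[i],
        isoform_id = paste0(pos$locus_id[i], ".RB"),
        chrom = pos$chrom[i], start = es[2], end = pos$end[i],
        strand = if (i %% 2 == 0) "-" else "+",
        es = es[-1], ee = ee[-1],
        thick_s = max(thick_s, es[2]), thick_e = thick_e)
    }
  }
  rows <- c(rows, extra)
  gene_models(
    locus_id = vapply(rows, `[[`, character(1), "locus_id"),
    isoform_id = vapply(rows, `[[`, character(1), "isoform_id"),
    chrom = vapply(rows, `[[`, character(1), "chrom"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    strand = vapply(rows, `[[`, character(1), "strand"),
    exon_starts = lapply(rows, `[[`, "es"),
    exon_ends = lapply(rows, `[[`, "ee"),
    thick_start = vapply(rows, `[[`, numeric(1), "thick_s"),
    thick_end = vapply(rows, `[[`, numeric(1), "thick_e"))
}

## four pairwise conservation tracks built around planted core elements:
## the AND-intersection of the tracks equals the cores exactly (per core
## one rotating track carries the exact extent, the rest random flanks;
## decoys are planted in at most three tracks, away from cores)
simulate_hcne_tracks <- function(spec, spaces, partition, chroms) {
  cores <- list(); meta <- list()
  for (cat in names(spec$densities)) {
    for (side in c("inside", "outside")) {
      d <- spec$densities[[cat]][if (side == "inside") 1 else 2]
      el <- place_elements(spaces[[cat]][[side]], d,
                           min_len = spec$min_len,
                           len_geom_mean = spec$len_geom_mean)
      if (nrow(el) > 0L)
        meta[[paste(cat, side)]] <- data.frame(
          category = cat, side = side, kind = "pass", count = nrow(el))
      cores[[paste(cat, side)]] <- el
    }
  }
  pass_cores <- do.call(rbind, cores)
  ## short cores (fail the length filter) and exon-overlapping cores
  short <- place_elements(
    union_sets(partition$intronic, partition$intergenic),
    spec$short_per_mb, min_len = 20, len_geom_mean = 10,
    avoid = pass_cores)
  short <- short[short$end - short$start < spec$min_len, , drop = FALSE]
  exonic <- place_elements(partition$exonic, spec$exonic_per_mb,
                           min_len = spec$min_len,
                           len_geom_mean = spec$len_geom_mean,
                           avoid = pass_cores)
  all_cores <- rbind(pass_cores, short, exonic)
  all_cores <- all_cores[order(all_cores$chrom, all_cores$start), ,
                         drop = FALSE]
  nc <- nrow(all_cores)
  buffer <- data.frame(chrom = all_cores$chrom,
                       start = pmax(0, all_cores$start - 200),
                       end = all_cores$end + 200)
  genome <- data.frame(chrom = chroms$chrom, start = 0, end = chroms$end)
  decoys <- place_elements(genome, spec$decoy_per_mb, min_len = 30,
                           len_geom_mean = 60, avoid = buffer)
  decoy_tracks <- lapply(seq_len(nrow(decoys)), function(i)
    sample.int(4L, sample.int(3L, 1)))
  exact_track <- (seq_len(nc) - 1L) %% 4L + 1L
  tracks <- lapply(1:4, function(t) {
    fl <- matrix(floor(stats::runif(nc * 2, 0, spec$max_flank + 1)),
                 ncol = 2)
    ex <- exact_track == t
    fl[ex, ] <- 0L
    tr <- data.frame(chrom = all_cores$chrom,
                     start = pmax(0, all_cores$start - fl[, 1]),
                     end = all_cores$end + fl[, 2],
                     stringsAsFactors = FALSE)
    dsel <- vapply(decoy_tracks, function(ts) t %in% ts, logical(1))
    region_set(rbind(tr, decoys[dsel, , drop = FALSE]),
               name = paste0("hcne_track", t))
  })
  truth <- list(
    n_pass = nrow(pass_cores), n_short = nrow(short),
    n_exonic = nrow(exonic),
    pass_cores = pass_cores,
    counts = do.call(rbind, meta))
  list(tracks = tracks, truth = truth)
}

simulate_ncrna <- function(spec, spaces, regions, chroms) {
  rows <- list(); truth <- list()
  id <- 0L
  region_frac <- total_width(regions) /
    sum(spaces$intergenic$inside$intervals$end -
          spaces$intergenic$inside$intervals$start,
        spaces$intergenic$outside$intervals$end -
          spaces$intergenic$outside$intervals$start,
        spaces$intronic$inside$intervals$end -
          spaces$intronic$inside$intervals$start,
        spaces$intronic$outside$intervals$end -
          spaces$intronic$outside$intervals$start,
        spaces$exonic$inside$intervals$end -
          spaces$exonic$inside$intervals$start,
        spaces$exonic$outside$intervals$end -
          spaces$exonic$outside$intervals$start)
  for (cl in c("miRNA", "snoRNA", "tRNA")) {
    n <- spec$counts[[cl]]
    mix <- spec$category_mix[[cl]]
    cats <- sample(names(mix), n, replace = TRUE, prob = mix)
    p_in <- region_frac * spec$short_inside_factor[[cl]]
    inside <- stats::runif(n) < p_in
    for (i in seq_len(n)) {
      sp <- spaces[[cats[i]]][[if (inside[i]) "inside" else "outside"]]
      if (nrow(sp$intervals) == 0L) { inside[i] <- FALSE
        sp <- spaces[[cats[i]]]$outside }
      el <- place_elements(sp, 0, n = 1, min_len = spec$lengths[[cl]],
                           len_geom_mean = 10)
      id <- id + 1L
      rows[[id]] <- cbind(el, name = sprintf("nc%04d", id), class = cl,
                          planted_inside = inside[i],
                          planted_category = cats[i])
    }
    truth[[cl]] <- data.frame(class = cl, n = n,
                              n_inside = sum(inside),
                              stringsAsFactors = FALSE)
  }
  ## lincRNAs: intergenic, longer inside regions than outside
  n_l <- spec$counts[["lincRNA"]]
  ig_in <- sum(spaces$intergenic$inside$intervals$end -
                 spaces$intergenic$inside$intervals$start)
  ig_all <- ig_in + sum(spaces$intergenic$outside$intervals$end -
                          spaces$intergenic$outside$intervals$start)
  n_in <- stats::rbinom(1, n_l, ig_in / ig_all)
  for (i in seq_len(n_l)) {
    inside <- i <= n_in
    mu <- spec$lincrna_len_kb[[if (inside) "inside" else "outside"]] * 1000
    len <- round(stats::rlnorm(1, log(mu) - spec$lincrna_sdlog^2 / 2,
                               spec$lincrna_sdlog))
    sp <- spaces$intergenic[[if (inside) "inside" else "outside"]]
    el <- place_elements(sp, 0, n = 1, min_len = len, len_geom_mean = 2,
                         fit_length = TRUE)
    id <- id + 1L
    rows[[id]] <- cbind(el, name = sprintf("nc%04d", id), class = "lincRNA",
                        planted_inside = inside,
                        planted_category = "intergenic")
  }
  truth$lincRNA <- data.frame(class = "lincRNA", n = n_l, n_inside = n_in,
                              stringsAsFactors = FALSE)
  nc <- do.call(rbind, rows)
  rownames(nc) <- NULL
  list(ncrna = nc, truth = do.call(rbind, truth))
}

simulate_probes <- function(spec, chroms, genes, labels) {
  spans <- locus_spans(genes)
  hum <- labels$human_homolog[match(spans$locus_id, labels$locus_id)] == 1
  cons <- region_set(spans[hum, c("chrom", "start", "end")], "conserved")
  noncons <- region_set(spans[!hum, c("chrom", "start", "end")], "noncons")
  rows <- list()
  ## class means are planted with the same >= 5 bp overlap rule the
  ## per-locus averaging uses, so recovered class means match the plant
  ov5 <- function(starts, chrom, rs) {
    iv <- rs$intervals[rs$intervals$chrom == chrom, , drop = FALSE]
    if (nrow(iv) == 0L) return(logical(length(starts)))
    IRanges::overlapsAny(
      IRanges::IRanges(starts + 1L, starts + spec$probe_len),
      IRanges::IRanges(iv$start + 1L, iv$end), minoverlap = 5L)
  }
  for (ci in seq_len(nrow(chroms))) {
    starts <- seq(0, chroms$end[ci] - spec$probe_len, by = spec$probe_step)
    mu <- rep(spec$means[["intergenic"]], length(starts))
    mu[ov5(starts, chroms$chrom[ci], noncons)] <- spec$means[["nonconserved"]]
    mu[ov5(starts, chroms$chrom[ci], cons)] <- spec$means[["conserved"]]
    rows[[ci]] <- data.frame(
      chrom = chroms$chrom[ci], start = starts,
      end = starts + spec$probe_len,
      score = round(stats::rnorm(length(starts), mu, spec$sd), 3),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

## -- codon-alignment simulator --------------------------------------------

codon_rate_table <- function(kappa, dn_mult) {
  meta <- codon_meta()
  aa <- meta$aa
  targets <- vector("list", 64); rates <- vector("list", 64)
  cls <- vector("list", 64); type <- vector("list", 64)
  total <- numeric(64)
  for (i in meta$sense) {
    cod <- strsplit(CODONS[i], "")[[1]]
    tg <- integer(0); rt <- numeric(0); cl <- integer(0); ty <- integer(0)
    for (p in 1:3) {
      for (b in setdiff(BASES, cod[p])) {
        mut <- cod; mut[p] <- b
        j <- match(paste(mut, collapse = ""), CODONS)
        if (aa[j] == "*") next          # proposals creating stops rejected
        ts <- is_transition(cod[p], b)
        w <- (if (ts) kappa else 1) / (kappa + 2)
        sel <- if (aa[j] == aa[i]) 1 else dn_mult
        tg <- c(tg, j); rt <- c(rt, w * sel)
        cl <- c(cl, match(meta$deg[i, p], c(0L, 2L, 4L)))
        ty <- c(ty, if (ts) 1L else 2L)
      }
    }
    targets[[i]] <- tg; rates[[i]] <- rt; cls[[i]] <- cl; type[[i]] <- ty
    total[i] <- sum(rt)
  }
  list(targets = targets, rates = rates, cls = cls, type = type,
       total = total)
}

evolve_branch <- function(cod, len, rt) {
  ev <- matrix(0, 3, 2, dimnames = list(c("L0", "L2", "L4"), c("ts", "tv")))
  if (len <= 0) return(list(codons = cod, events = ev))
  t <- stats::rexp(length(cod), rt$total[cod])
  for (i in which(t < len)) {
    ci <- cod[i]; ti <- t[i]
    repeat {
      k <- sample.int(length(rt$targets[[ci]]), 1, prob = rt$rates[[ci]])
      ev[rt$cls[[ci]][k], rt$type[[ci]][k]] <-
        ev[rt$cls[[ci]][k], rt$type[[ci]][k]] + 1
      ci <- rt$targets[[ci]][k]
      ti <- ti + stats::rexp(1, rt$total[ci])
      if (ti >= len) break
    }
    cod[i] <- ci
  }
  list(codons = cod, events = ev)
}

#' Simulate a codon alignment on a star phylogeny
#'
#' Evolves a random stop-free ancestral codon string independently along
#' the branches of a star tree. Substitution proposals are weighted by a
#' transition/transversion ratio `kappa`; synonymous changes proceed at a
#' rate calibrated so that the expected pairwise divergence at 4-fold
#' degenerate sites equals `ds`, nonsynonymous changes at `ds x dn_mult`;
#' proposals creating stop codons are rejected. Realized substitutions
#' are recorded per taxon, degeneracy class (of the changing position in
#' the source codon) and change type, as ground truth for distance
#' estimators.
#'
#' @param n_codons codons in the ancestral sequence.
#' @param taxa taxon names (star-tree tips).
#' @param ds expected pairwise substitutions per 4-fold site.
#' @param dn_mult nonsynonymous/synonymous rate ratio.
#' @param kappa transition/transversion rate ratio.
#' @param gap_codon_prob,n_codon_prob per-codon masking rates applied to
#'   all taxa but the first (whole codons replaced by `---` or `NNN`).
#' @return object of class `sim_codon_alignment`: list with `alignment`
#'   (a `codon_alignment`), `events` (per-taxon class x type counts),
#'   `site_classes` (ancestral `L0, L2, L4`), `ancestor`, `params`.
#' @export
simulate_codon_alignment <- function(n_codons, taxa = paste0("t", 1:8),
                                     ds = 0.3, dn_mult = 0.1, kappa = 2,
                                     gap_codon_prob = 0,
                                     n_codon_prob = 0) {
  stopifnot(n_codons >= 1, length(taxa) >= 2)
  meta <- codon_meta()
  rt <- codon_rate_table(kappa, dn_mult)
  anc <- sample(meta$sense, n_codons, replace = TRUE)
  L <- colSums(meta$nsites[anc, , drop = FALSE])
  events <- list(); rows <- character(length(taxa))
  for (ti in seq_along(taxa)) {
    br <- evolve_branch(anc, ds / 2, rt)
    events[[taxa[ti]]] <- br$events
    cods <- CODONS[br$codons]
    if (ti > 1L && (gap_codon_prob > 0 || n_codon_prob > 0)) {
      u <- stats::runif(n_codons)
      cods[u < gap_codon_prob] <- "---"
      cods[u >= gap_codon_prob & u < gap_codon_prob + n_codon_prob] <- "NNN"
    }
    rows[ti] <- paste(cods, collapse = "")
  }
  names(rows) <- taxa
  structure(list(alignment = codon_alignment(rows), events = events,
                 site_classes = L, ancestor = anc,
                 params = list(ds = ds, dn_mult = dn_mult, kappa = kappa)),
            class = "sim_codon_alignment")
}

#' Realized divergence of a simulated taxon pair
#'
#' Uncorrected per-site substitution counts from the simulator's event
#' log: the quantity a multiple-hit-corrected estimator should recover.
#' `d4` is total events per 4-fold site; `Ks` and `Ka` combine classes
#' with the same weights as the corresponding estimator formulas.
#'
#' @param sim a `sim_codon_alignment`.
#' @param t1,t2 taxon names.
#' @return list with `d4`, `Ks`, `Ka`.
#' @export
sim_realized_distance <- function(sim, t1, t2) {
  ev <- sim$events[[t1]] + sim$events[[t2]]
  L <- sim$site_classes
  list(d4 = sum(ev["L4", ]) / L[["L4"]],
       Ks = (ev["L2", "ts"] + ev["L4", "ts"]) / (L[["L2"]] + L[["L4"]]) +
         ev["L4", "tv"] / L[["L4"]],
       Ka = ev["L0", "ts"] / L[["L0"]] +
         (ev["L0", "tv"] + ev["L2", "tv"]) / (L[["L0"]] + L[["L2"]]))
}

## -- bundle I/O ------------------------------------------------------------

#' Write a synthetic bundle to disk
#'
#' Emits the full plain-text input bundle: `regions.bed`, `genes.bed`
#' (BED12), `labels.tsv`, `uce.bed`, `phastcons.bed`, four
#' `hcne_track*.bed`, `ncrna.bed` + `ncrna_classes.tsv`,
#' `probes.bedGraph`, per-gene FASTA alignments under `alignments/`, and
#' the planted-truth manifest (`manifest.json` plus TSV truth tables).
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  reg <- bundle$regions$intervals
  write_bed(reg, p("regions.bed"))
  write_genes_bed12(bundle$genes, p("genes.bed"))
  write_labels(bundle$labels, p("labels.tsv"))
  write_bed(bundle$elements$uce, p("uce.bed"))
  pc <- bundle$elements$phastcons
  pc$name <- sprintf("pc%05d", seq_len(nrow(pc)))
  write_bed(pc[, c("chrom", "start", "end", "name", "score")],
            p("phastcons.bed"))
  for (t in 1:4)
    write_bed(bundle$elements$hcne_tracks[[t]]$intervals[
      , c("chrom", "start", "end")],
      p(sprintf("hcne_track%d.bed", t)))
  write_bed(bundle$ncrna[, c("chrom", "start", "end", "name")],
            p("ncrna.bed"))
  utils::write.table(
    bundle$ncrna[, c("name", "class", "planted_inside", "planted_category")],
    p("ncrna_classes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_bedgraph(bundle$probes, p("probes.bedGraph"))
  utils::write.table(bundle$chromosomes, p("chromosomes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$alignments)) {
    dir.create(p("alignments"), showWarnings = FALSE)
    for (id in names(bundle$alignments))
      write_codon_alignment(bundle$alignments[[id]],
                            p("alignments", paste0(id, ".fa")))
  }
  man <- bundle$manifest
  utils::write.table(man$loci, p("truth_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(man$element_counts, p("truth_elements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- man[c("config", "hcne_truth", "ncrna_truth")]
  keep$hcne_truth$pass_cores <- NULL
  jsonlite::write_json(keep, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}

#' Read a synthetic bundle from disk
#'
#' @param dir directory written by [write_bundle()].
#' @return list with the same data slots as a `synthetic_bundle` (no
#'   manifest).
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  chroms <- utils::read.delim(p("chromosomes.tsv"),
                              stringsAsFactors = FALSE)
  nc <- read_bed(p("ncrna.bed"))
  cls <- utils::read.delim(p("ncrna_classes.tsv"), stringsAsFactors = FALSE)
  nc <- cbind(nc, cls[match(nc$name, cls$name),
                      setdiff(names(cls), "name"), drop = FALSE])
  aln <- NULL
  if (dir.exists(p("alignments"))) {
    files <- sort(list.files(p("alignments"), pattern = "\\.fa$"))
    aln <- lapply(stats::setNames(file.path(p("alignments"), files),
                                  sub("\\.fa$", "", files)),
                  read_codon_alignment)
  }
  list(chromosomes = chroms,
       regions = region_set(read_bed(p("regions.bed")), "UR"),
       genes = read_genes_bed12(p("genes.bed")),
       labels = read_labels(p("labels.tsv")),
       elements = list(
         uce = read_bed(p("uce.bed")),
         phastcons = read_bed(p("phastcons.bed")),
         hcne_tracks = lapply(1:4, function(t)
           region_set(read_bed(p(sprintf("hcne_track%d.bed", t))),
                      paste0("hcne_track", t)))),
       ncrna = nc, probes = read_bedgraph(p("probes.bedGraph")),
       alignments = aln)
}
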