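test_that("two-cell goodness of fit behaves at the null and boundaries", {
  r <- gof_chi_squared(50, 50, 200)
  expect_equal(r$chi2, 0)
  expect_equal(r$p, 1)
  expect_equal(r$obs_over_exp * r$exp_over_obs, 1)
  expect_error(gof_chi_squared(-1, 50, 200), "observed")
  expect_error(gof_chi_squared(10, 0, 200), "degenerate")
  expect_error(gof_chi_squared(10, 200, 200), "degenerate")
})

test_that("gof matches stats::chisq.test on random two-cell problems", {
  set.seed(314)
  for (rep in 1:1000) {
    total <- sample(20:2000, 1)
    expected <- runif(1, 1, total - 1)
    observed <- sample.int(total + 1, 1) - 1L
    r <- gof_chi_squared(observed, expected, total)
    ref <- suppressWarnings(
      stats::chisq.test(c(observed, total - observed),
                        p = c(expected / total, 1 - expected / total)))
    expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("pearson 2x2 matches the closed form and chisq.test", {
  expect_equal(pearson_chi2_2x2(10, 0, 0, 10)$chi2, 20)
  expect_equal(pearson_chi2_2x2(10, 20, 30, 60)$chi2, 0)  # proportional
  expect_error(pearson_chi2_2x2(0, 0, 5, 5), "zero margin")
  set.seed(159)
  for (rep in 1:1000) {
    x <- sample.int(80, 4)
    r <- pearson_chi2_2x2(x[1], x[2], x[3], x[4])
    ref <- suppressWarnings(
      stats::chisq.test(matrix(x, 2, byrow = TRUE), correct = FALSE))
    expect_equal(r$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(r$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("EST-support style tables need no continuity correction", {
  # uncorrected statistic ~3.84 on the published counts; the Yates-
  # corrected one would be ~3.0, so the uncorrected form is the match
  r <- pearson_chi2_2x2(53, 11, 786, 83)
  expect_equal(r$chi2, 3.84, tolerance = 0.01 / 3.84)
  yates <- suppressWarnings(stats::chisq.test(
    matrix(c(53, 11, 786, 83), 2, byrow = TRUE), correct = TRUE))
  expect_lt(unname(yates$statistic), 3.1)
})

test_that("gene-class enrichment recovers the planted conservation deficit", {
  b <- shared_default_bundle()
  asn <- assign_loci(b$genes, b$regions)
  res <- gene_class_enrichment(asn, b$labels, "human_homolog",
                               stratum = "testis_specific")
  all_row <- res[res$category == "all", ]
  # planted 0.11 inside vs 0.43 outside at ~6.8% of loci inside gives
  # exp/obs near 0.41/0.11 ~ 3.8; binomial noise on ~150 genes
  expect_gt(all_row$exp_over_obs, 2.8)
  expect_lt(all_row$exp_over_obs, 5.2)
  expect_lt(all_row$p, 1e-4)
  expect_equal(nrow(res), 3L)
})

test_that("gene-class enrichment is null when probabilities match", {
  cfg <- small_test_config(
    901, simulate_alignments = FALSE,
    label_probabilities = list(
      human_homolog = c(inside = 0.4, outside = 0.4),
      mosquito_homolog = c(inside = 0.7, outside = 0.7),
      virilis_homolog = c(inside = 0.95, outside = 0.95),
      expression_known = c(inside = 0.9, outside = 0.9),
      testis_specific = c(inside = 0.2, outside = 0.2)))
  b <- simulate_genome(cfg)
  asn <- assign_loci(b$genes, b$regions)
  res <- gene_class_enrichment(asn, b$labels, "human_homolog")
  expect_gt(res$exp_over_obs, 0.7)
  expect_lt(res$exp_over_obs, 1.4)
  expect_gt(res$p, 0.001)
})

test_that("element expectations are exactly length-proportional", {
  b <- shared_default_bundle()
  part <- partition_annotation(b$genes,
                               b$chromosomes[, c("chrom", "start", "end")])
  inside <- element_enrichment(b$elements$phastcons, part, b$regions)
  complement <- setdiff_sets(region_set(b$chromosomes), b$regions)
  outside <- element_enrichment(b$elements$phastcons, part, complement)
  for (cat in c("intronic", "intergenic")) {
    e_in <- inside$expected[inside$category == cat]
    e_out <- outside$expected[outside$category == cat]
    n_cat <- e_in / (inside$length_in_regions[inside$category == cat] /
                       1e6) / inside$density_per_mb[inside$category == cat]
    # expected mass over inside + outside equals the category total
    total <- inside$observed[inside$category == cat] +
      outside$observed[outside$category == cat]
    expect_equal(e_in + e_out, total, tolerance = 1e-9)
  }
})

test_that("uniformly placed elements show no enrichment", {
  b <- shared_default_bundle()
  part <- partition_annotation(b$genes,
                               b$chromosomes[, c("chrom", "start", "end")])
  set.seed(77)
  el <- place_elements(part$intronic, 120, min_len = 30, len_geom_mean = 40)
  res <- element_enrichment(el, part, b$regions)
  row <- res[res$category == "intronic", ]
  se <- sqrt(row$expected) / row$expected
  expect_lt(abs(row$obs_over_exp - 1), 4 * se)
})

test_that("planted intronic excess is recovered at the derived ratio", {
  b <- shared_default_bundle()
  part <- partition_annotation(b$genes,
                               b$chromosomes[, c("chrom", "start", "end")])
  res <- element_enrichment(b$elements$phastcons, part, b$regions)
  row <- res[res$category == "intronic", ]
  dens <- b$manifest$config$element_densities$phastcons$densities$intronic
  len_in <- row$length_in_regions
  len_all <- total_width(part$intronic)
  s <- len_in / len_all
  r <- dens[1] / dens[2]
  target <- r / (1 + (r - 1) * s)   # expected obs/exp under the plant
  se <- sqrt(1 / row$expected + 1 / row$observed)
  expect_lt(abs(row$obs_over_exp / target - 1), 4 * se)
})

test_that("midpoint, any-overlap and half rules order sensibly", {
  part <- partition_annotation(
    make_gene("gA", "c", list(c(10000, 11000))),
    intervals("c", 0, 1e5))
  regions <- region_set(intervals("c", 50000, 80000), "UR")
  # element straddling the region edge: midpoint outside, overlap inside
  el <- intervals("c", c(49990, 60000), c(50006, 60100))
  rs <- lapply(c("midpoint", "any", "half"), function(rule)
    element_enrichment(el, part, regions, rule = rule))
  obs <- vapply(rs, function(r)
    r$observed[r$category == "intergenic"], numeric(1))
  expect_equal(obs, c(1, 2, 1))   # midpoint: 1, any: 2, half: 1
})

test_that("ncRNA census recovers planted depletion and lincRNA contrast", {
  b <- shared_default_bundle()
  part <- partition_annotation(b$genes,
                               b$chromosomes[, c("chrom", "start", "end")])
  cen <- ncrna_census(b$ncrna, part, b$regions)
  sno <- cen$short[cen$short$class == "snoRNA", ]
  # snoRNAs planted entirely outside the regions
  expect_equal(sum(sno$observed), 0L)
  expect_gt(sum(sno$expected), 0)
  # majority-category call matches the planted category
  nc <- b$ncrna[b$ncrna$class != "lincRNA", ]
  linc <- cen$lincrna
  truth <- b$ncrna[b$ncrna$class == "lincRNA", ]
  expect_equal(linc$n_inside, sum(truth$planted_inside))
  expect_equal(linc$mean_len_inside,
               mean((truth$end - truth$start)[truth$planted_inside]))
  expect_equal(linc$mean_len_outside,
               mean((truth$end - truth$start)[!truth$planted_inside]))
  expect_lt(linc$frac_intergenic_covered, 0.2)
})

test_that("short ncRNAs placed uniformly match their expectations", {
  b <- shared_default_bundle()
  part <- partition_annotation(b$genes,
                               b$chromosomes[, c("chrom", "start", "end")])
  set.seed(4242)
  el <- place_elements(part$intergenic, 30, min_len = 80, len_geom_mean = 10)
  nc <- cbind(el, name = sprintf("u%03d", seq_len(nrow(el))),
              class = "tRNA")
  cen <- ncrna_census(nc, part, b$regions)
  row <- cen$short[cen$short$category == "intergenic", ]
  expect_lt(abs(row$observed - row$expected), 4 * sqrt(row$expected))
})

test_that("replay_counts reproduces chi-squared results from raw counts", {
  counts <- data.frame(category = c("a", "b"),
                       observed = c(104, 15),
                       expected = c(400.2, 27.9),
                       total = c(933, 298))
  out <- replay_counts(counts)
  expect_equal(out$chi2[1],
               (104 - 400.2)^2 / 400.2 + (296.2)^2 / (933 - 400.2))
  expect_equal(out$p, pchisq(out$chi2, 1, lower.tail = FALSE))
})

test_that("goodness-of-fit p-values are near-uniform under the null", {
  # fixed partition; elements re-placed uniformly each replicate
  set.seed(2718)
  part <- partition_annotation(
    random_genes(40, list(cU = 400000L), seed = 271),
    intervals("cU", 0, 4e5))
  regions <- region_set(intervals("cU", c(5e4, 2.5e5), c(9e4, 3.1e5)), "UR")
  ps <- replicate(300, {
    el <- place_elements(part$intergenic, 2500, min_len = 10,
                         len_geom_mean = 5, disjoint = FALSE)
    r <- element_enrichment(el, part, regions)
    r$p[r$category == "intergenic"]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
})
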