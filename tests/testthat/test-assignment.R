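make_span_gene <- function(id, chrom, start, end)
  make_gene(id, chrom, list(c(start, end)))

test_that("the 50% coverage rule assigns the boundary case", {
  genes <- bind_genes(
    make_span_gene("gHalf", "c", 100, 300),    # exactly half covered
    make_span_gene("gOut", "c", 5000, 5200),   # fully outside
    make_span_gene("gIn", "c", 210, 280))      # fully inside
  regions <- region_set(intervals("c", 200, 1000, name = "R1"), "UR")
  asn <- assign_loci(genes, regions)
  expect_equal(asn$status[asn$locus_id == "gHalf"], "region")
  expect_equal(asn$coverage[asn$locus_id == "gHalf"], 0.5)
  expect_equal(asn$status[asn$locus_id == "gOut"], "outside")
  expect_equal(asn$status[asn$locus_id == "gIn"], "region")
  expect_equal(asn$region[asn$status == "region"], c("R1", "R1"))
})

test_that("threshold extremes select any-overlap and containment", {
  genes <- bind_genes(
    make_span_gene("gTouch", "c", 190, 400),  # ~5% covered
    make_span_gene("gMost", "c", 210, 1100),  # ~89% covered
    make_span_gene("gFull", "c", 300, 900))   # contained
  regions <- region_set(intervals("c", 200, 1000), "UR")
  low <- assign_loci(genes, regions, threshold = 1e-9)
  expect_equal(sum(low$status == "region"), 3L)
  full <- assign_loci(genes, regions, threshold = 1)
  expect_equal(full$locus_id[full$status == "region"], "gFull")
  expect_error(assign_loci(genes, regions, threshold = 0), "threshold")
})

test_that("coverage is summed across regions for straddling loci", {
  genes <- make_span_gene("gTwo", "c", 900, 1300)
  # covered 100 bp by each of two regions: 50% combined
  regions <- region_set(intervals("c", c(600, 1200), c(1000, 1500)), "UR")
  asn <- assign_loci(genes, regions)
  expect_equal(asn$coverage, 0.5)
  expect_equal(asn$status, "region")
})

test_that("generator-planted inside loci are recovered exactly", {
  cfg <- small_test_config(811, n_loci = 200, frac_loci_inside = 0.6,
                           region_length_range = c(2e5, 3e5),
                           gene_length = list(meanlog = log(1500),
                                              sdlog = 0.8, min = 400,
                                              p_long = 0,
                                              long_range = c(3e4, 6e4)),
                           simulate_alignments = FALSE)
  b <- simulate_genome(cfg)
  truth <- b$manifest$loci
  expect_equal(sum(truth$status == "inside"), 120L)
  asn <- assign_loci(b$genes, b$regions)
  expect_setequal(asn$locus_id[asn$status == "region"],
                  truth$locus_id[truth$status == "inside"])
})

test_that("straddling loci are assigned by their realized coverage", {
  cfg <- small_test_config(812, n_straddle = 4, region_margin = 5e4,
                           simulate_alignments = FALSE)
  b <- simulate_genome(cfg)
  st <- b$manifest$straddle
  expect_equal(nrow(st), 4L)
  asn <- assign_loci(b$genes, b$regions)
  for (i in seq_len(nrow(st))) {
    row <- asn[asn$locus_id == st$locus_id[i], ]
    expect_equal(row$coverage, st$coverage[i], tolerance = 1e-9)
    expect_equal(row$status,
                 if (st$coverage[i] >= 0.5) "region" else "outside")
  }
})

controls_fixture <- function() {
  # region [2000, 3000); flanking genes at known distances
  genes <- bind_genes(
    make_span_gene("up1", "c", 1700, 1900),
    make_span_gene("up2", "c", 1400, 1600),
    make_span_gene("up3", "c", 1000, 1200),
    make_span_gene("in1", "c", 2100, 2300),
    make_span_gene("in2", "c", 2400, 2600),
    make_span_gene("in3", "c", 2650, 2800),
    make_span_gene("in4", "c", 2820, 2950),
    make_span_gene("down1", "c", 3100, 3300),
    make_span_gene("down2", "c", 3400, 3600),
    make_span_gene("down3", "c", 3700, 3900))
  regions <- region_set(intervals("c", 2000, 3000, name = "R1"), "UR")
  list(genes = genes, regions = regions,
       asn = assign_loci(genes, regions))
}

test_that("adjacent controls split half upstream, half downstream", {
  fx <- controls_fixture()
  ctrl <- select_adjacent_controls("R1", fx$asn, fx$genes, fx$regions)
  expect_equal(nrow(ctrl), 4L)
  expect_setequal(ctrl$locus_id[ctrl$side == "upstream"], c("up1", "up2"))
  expect_setequal(ctrl$locus_id[ctrl$side == "downstream"],
                  c("down1", "down2"))
})

test_that("odd control counts take the extra gene upstream", {
  fx <- controls_fixture()
  ctrl <- select_adjacent_controls("R1", fx$asn, fx$genes, fx$regions,
                                   n = 3)
  expect_equal(sum(ctrl$side == "upstream"), 2L)
  expect_equal(sum(ctrl$side == "downstream"), 1L)
  expect_equal(ctrl$locus_id[ctrl$side == "downstream"], "down1")
})

test_that("genes overlapping any region are skipped as controls", {
  genes <- bind_genes(
    make_span_gene("upTouch", "c", 1700, 2001),  # 1 bp into R1
    make_span_gene("up2", "c", 1400, 1600),
    make_span_gene("up3", "c", 1000, 1200),
    make_span_gene("in1", "c", 2100, 2300),
    make_span_gene("in2", "c", 2400, 2600),
    make_span_gene("downOther", "c", 3100, 3550),  # overlaps R2
    make_span_gene("down2", "c", 3600, 3800),
    make_span_gene("down3", "c", 3900, 4100))
  regions <- region_set(intervals("c", c(2000, 3500), c(3000, 3580),
                                  name = c("R1", "R2")), "UR")
  asn <- assign_loci(genes, regions)
  ctrl <- select_adjacent_controls("R1", asn, genes, regions)
  expect_false(any(c("upTouch", "downOther") %in% ctrl$locus_id))
  expect_setequal(ctrl$locus_id, c("up2", "down2"))  # n = 2 assigned
})

test_that("an exhausted flank borrows from the other side, then errors", {
  genes <- bind_genes(
    make_span_gene("up1", "c", 1700, 1900),
    make_span_gene("in1", "c", 2100, 2300),
    make_span_gene("in2", "c", 2400, 2600),
    make_span_gene("in3", "c", 2650, 2800),
    make_span_gene("down1", "c", 3100, 3300),
    make_span_gene("down2", "c", 3400, 3600))
  regions <- region_set(intervals("c", 2000, 3000, name = "R1"), "UR")
  asn <- assign_loci(genes, regions)
  ctrl <- select_adjacent_controls("R1", asn, genes, regions)
  expect_equal(nrow(ctrl), 3L)
  expect_equal(sum(ctrl$side == "downstream"), 2L)  # deficit moved down
  expect_error(
    select_adjacent_controls("R1", asn, genes, regions, n = 5),
    "R1")
})

test_that("control sets never intersect region assignments", {
  b <- shared_bundle()
  asn <- assign_loci(b$genes, b$regions)
  ctrl <- select_all_controls(asn, b$genes, b$regions)
  assigned <- asn$locus_id[asn$status == "region"]
  expect_length(intersect(ctrl$locus_id, assigned), 0L)
  expect_false(any(duplicated(ctrl$locus_id)))
  # controls overlap no region at all
  spans <- locus_spans(b$genes)
  spans <- spans[spans$locus_id %in% ctrl$locus_id, ]
  cov <- vapply(seq_len(nrow(spans)), function(i)
    coverage_fraction(spans[i, ], b$regions), numeric(1))
  expect_true(all(cov == 0))
})

test_that("build_hcne_set applies length and exon filters at the boundary", {
  exonic <- region_set(intervals("c", 5000, 6000), "exonic")
  mk_tracks <- function(core_start, core_end) lapply(1:4, function(t)
    region_set(intervals("c", core_start - (t %% 2), core_end + (t %% 3))))
  # 60-bp common core survives
  got <- build_hcne_set(mk_tracks(100, 160), exonic)
  expect_equal(length(got), 1L)
  # 49-bp core dropped
  got49 <- build_hcne_set(mk_tracks(100, 149), exonic)
  expect_equal(length(got49), 0L)
  # 50-bp core kept (boundary is >=)
  got50 <- build_hcne_set(mk_tracks(100, 150), exonic)
  expect_equal(length(got50), 1L)
  # core overlapping an exon by 1 bp dropped
  gotex <- build_hcne_set(mk_tracks(4940, 5001), exonic)
  expect_equal(length(gotex), 0L)
})

test_that("build_hcne_set is invariant under track permutation and
           recovers planted cores", {
  b <- shared_bundle()
  part <- partition_annotation(b$genes,
                               b$chromosomes[, c("chrom", "start", "end")])
  tracks <- b$elements$hcne_tracks
  got <- build_hcne_set(tracks, part$exonic)
  truth <- b$manifest$hcne_truth
  expect_equal(length(got), truth$n_pass)
  want <- truth$pass_cores[order(truth$pass_cores$chrom,
                                 truth$pass_cores$start), ]
  expect_equal(got$intervals$start, want$start)
  expect_equal(got$intervals$end, want$end)
  perm <- build_hcne_set(tracks[c(3, 1, 4, 2)], part$exonic)
  expect_identical(perm$intervals[, c("chrom", "start", "end")],
                   got$intervals[, c("chrom", "start", "end")])
})
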