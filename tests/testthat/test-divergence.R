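test_that("codon site classification matches the genetic-code oracle", {
  expect_equal(classify_codon_sites("GGA"), c(0L, 0L, 4L))
  expect_equal(classify_codon_sites("ATG"), c(0L, 0L, 0L))
  expect_equal(classify_codon_sites("AAA"), c(0L, 0L, 2L))
  expect_equal(classify_codon_sites("ATA"), c(0L, 0L, 2L))  # 3-fold Ile
  expect_error(classify_codon_sites("TAA"), "stop")
  expect_error(classify_codon_sites("AT-"), "not a codon")
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  for (cod in sense)
    expect_equal(classify_codon_sites(cod), oracle_degeneracy(cod),
                 label = cod)
})

test_that("difference counting handles clean single-hit codons", {
  z <- count_site_differences("GGAGGA", "GGAGGA")
  expect_equal(z$s4 + z$s2 + z$s0 + z$v4 + z$v2 + z$v0, 0)
  one <- count_site_differences("GGA", "GGG")  # 4-fold transition
  expect_equal(one$s4, 1)
  expect_equal(one$v4 + one$s2 + one$s0 + one$v2 + one$v0, 0)
  tv <- count_site_differences("GGA", "GGC")   # 4-fold transversion
  expect_equal(tv$v4, 1)
})

test_that("columns with gaps, N or stop codons are skipped entirely", {
  a <- "ATGGGA---NNNTGGGGA"
  b <- "ATGGGGAAAAAATGATGA"   # col4 TGA is a stop in b; cols 2 differ
  cnt <- count_site_differences(a, b)
  expect_equal(cnt$n_codons, 2L)  # only ATG/ATG and GGA/GGG columns used
  expect_equal(cnt$s4, 1)
  expect_error(count_site_differences("ATGC", "ATGC"), "frame")
})

test_that("pathway averaging equals the brute-force oracle", {
  set.seed(606)
  # single multi-hit pairs incl. the spec-style 30-codon, 3-change case
  for (rep in 1:30) {
    x <- random_codon_row(30)
    y <- mutate_row(x, 3)
    got <- count_site_differences(x, y)
    want <- oracle_pair_counts(x, y)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9,
                   label = paste("rep", rep, f))
  }
})

test_that("pbl distances match direct closed forms and the oracle", {
  z <- structure(list(L0 = 100, L2 = 50, L4 = 80, s0 = 0, s2 = 0, s4 = 0,
                      v0 = 0, v2 = 0, v4 = 0), class = "site_class_counts")
  d0 <- pbl_distance(z)
  expect_equal(c(d0$Ka, d0$Ks, d0$d4), c(0, 0, 0))
  z$s4 <- 10; z$L2 <- 0; z$L4 <- 100   # P4 = 0.1, Q4 = 0
  d <- pbl_distance(z)
  expect_equal(d$d4, 0.5 * log(1.25), tolerance = 1e-12)
  expect_equal(d$Ks, 0.5 * log(1.25), tolerance = 1e-12)
})

test_that("saturation and empty classes raise explicit errors", {
  sat <- structure(list(L0 = 10, L2 = 10, L4 = 10, s0 = 0, s2 = 0, s4 = 6,
                        v0 = 0, v2 = 0, v4 = 0), class = "site_class_counts")
  expect_error(pbl_distance(sat), "saturated.*4-fold")
  no4 <- structure(list(L0 = 10, L2 = 10, L4 = 0, s0 = 0, s2 = 0, s4 = 0,
                        v0 = 0, v2 = 0, v4 = 0), class = "site_class_counts")
  expect_error(pbl_distance(no4), "4-fold")
})

test_that("estimator equals oracle end to end on random pairs", {
  set.seed(1234)
  for (rep in 1:120) {
    n <- sample(10:100, 1)
    x <- random_codon_row(n)
    y <- mutate_row(x, rpois(1, n / 8))
    got <- count_site_differences(x, y)
    want <- oracle_pair_counts(x, y)
    for (f in setdiff(names(want), "n_codons"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9)
    d_want <- oracle_pbl(want)
    d_got <- tryCatch(pbl_distance(got), error = function(e) NULL)
    if (!is.null(d_got)) {
      expect_equal(d_got$Ka, d_want$Ka, tolerance = 1e-9)
      expect_equal(d_got$Ks, d_want$Ks, tolerance = 1e-9)
      expect_equal(d_got$d4, d_want$d4, tolerance = 1e-9)
    }
  }
})

test_that("small-divergence limit approaches per-site proportions", {
  set.seed(88)
  sim <- simulate_codon_alignment(20000, taxa = c("a", "b"), ds = 0.03,
                                  dn_mult = 0.3)
  cnt <- count_site_differences(sim$alignment, c("a", "b"))
  d <- pbl_distance(cnt)
  p4 <- (cnt$s4 + cnt$v4) / cnt$L4
  expect_lt(abs(d$d4 / p4 - 1), 0.05)
  pa <- cnt$s0 / cnt$L0 + (cnt$v0 + cnt$v2) / (cnt$L0 + cnt$L2)
  expect_lt(abs(d$Ka / pa - 1), 0.05)
})

test_that("distances increase monotonically with planted changes", {
  set.seed(55)
  x <- random_codon_row(2000)
  y <- x
  prev_ks <- -1; prev_ka <- -1
  for (step in 1:8) {
    y <- mutate_row(y, 40)
    d <- pbl_distance(count_site_differences(x, y))
    expect_gte(d$Ks, prev_ks - 1e-9)
    expect_gte(d$Ka, prev_ka - 1e-9)
    prev_ks <- d$Ks; prev_ka <- d$Ka
  }
})

test_that("simulated alignments recover planted Ks at modest scale", {
  set.seed(321)
  sim <- simulate_codon_alignment(8000, taxa = c("a", "b"), ds = 0.3,
                                  dn_mult = 0.1)
  d <- pbl_distance(count_site_differences(sim$alignment, c("a", "b")))
  r <- sim_realized_distance(sim, "a", "b")
  expect_lt(abs(d$Ks / r$Ks - 1), 0.05)
  expect_lt(abs(d$d4 / r$d4 - 1), 0.05)
})

test_that("pairwise_distances covers all taxon pairs", {
  set.seed(12)
  sim <- simulate_codon_alignment(300, taxa = paste0("t", 1:8), ds = 0.2)
  pd <- pairwise_distances(sim$alignment)
  expect_equal(nrow(pd), choose(8, 2))
  expect_true(all(pd$d4 >= 0))
})

test_that("concatenation is order-invariant and drops odd taxon sets", {
  set.seed(31)
  mk <- function() simulate_codon_alignment(40, taxa = c("a", "b", "c"),
                                            ds = 0.2)$alignment
  alns <- list(g2 = mk(), g1 = mk(), g3 = mk())
  c1 <- concatenate_alignments(alns)
  c2 <- concatenate_alignments(alns[c(3, 1, 2)])
  expect_identical(c1$rows, c2$rows)
  bad <- simulate_codon_alignment(40, taxa = c("a", "b"), ds = 0.2)$alignment
  expect_warning(c3 <- concatenate_alignments(c(alns, list(g0 = bad))),
                 "differing taxon sets")
  expect_identical(c3$rows, c1$rows)
  expect_error(concatenate_alignments(alns, ids = "missing"), "missing")
})

test_that("a gene shared by both groups gives ratio exactly 1", {
  set.seed(77)
  aln <- simulate_codon_alignment(200, taxa = c("a", "b", "c"),
                                  ds = 0.25)$alignment
  res <- concatenate_and_compare(list(gA = aln),
                                 groups = list(x = "gA", y = "gA"))
  expect_true(all(res$summary$mean_ratio == 1))
  expect_error(concatenate_and_compare(list(gA = aln),
                                       groups = list(x = "gA",
                                                     y = character(0))),
               "empty group")
})

test_that("a planted nonsynonymous contrast is recovered between groups", {
  set.seed(2024)
  taxa <- paste0("t", 1:8)
  mk <- function(n, pre, dn) lapply(
    stats::setNames(seq_len(n), sprintf("%s%02d", pre, seq_len(n))),
    function(i) simulate_codon_alignment(120, taxa = taxa, ds = 0.3,
                                         dn_mult = dn)$alignment)
  ur <- mk(15, "u", 0.14); adj <- mk(15, "a", 0.10)
  res <- concatenate_and_compare(c(ur, adj),
                                 groups = list(region = names(ur),
                                               adjacent = names(adj)))
  ka <- res$summary$mean_ratio[res$summary$metric == "Ka"]
  d4 <- res$summary$mean_ratio[res$summary$metric == "d4"]
  expect_gt(ka, 1.15); expect_lt(ka, 1.7)
  expect_gt(d4, 0.92); expect_lt(d4, 1.08)
})
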