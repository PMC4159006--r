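# Fixture builders shared across test files. Bundles are simulated once
# per run and memoized.

make_gene <- function(id, chrom, exons, cds = NULL, isoform = "RA",
                      strand = "+") {
  es <- vapply(exons, `[[`, numeric(1), 1)
  ee <- vapply(exons, `[[`, numeric(1), 2)
  gene_models(locus_id = id, isoform_id = paste0(id, ".", isoform),
              chrom = chrom, start = min(es), end = max(ee),
              strand = strand, exon_starts = list(es),
              exon_ends = list(ee),
              thick_start = if (is.null(cds)) min(es) else cds[1],
              thick_end = if (is.null(cds)) min(es) else cds[2])
}

bind_genes <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("gene_models", "data.frame")
  out
}

# random loci with 1-3 exons inside the declared chromosomes
random_genes <- function(n, chrom_lens, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gl <- list()
  for (i in seq_len(n)) {
    ch <- sample(names(chrom_lens), 1)
    L <- sample(200:2000, 1)
    start <- sample.int(chrom_lens[[ch]] - L, 1) - 1L
    k <- sample(1:3, 1)
    bounds <- sort(sample(seq(start, start + L), 2 * k))
    exons <- lapply(seq_len(k), function(j)
      c(bounds[2 * j - 1], bounds[2 * j]))
    exons <- Filter(function(e) e[2] > e[1], exons)
    if (length(exons) == 0L) exons <- list(c(start, start + L))
    exons[[1]][1] <- start
    exons[[length(exons)]][2] <- start + L
    gl[[i]] <- make_gene(sprintf("RG%04d", i), ch, exons)
  }
  do.call(bind_genes, gl)
}

small_test_config <- function(seed, ...) {
  base <- list(
    seed = seed,
    chromosomes = c(chr2 = 2e6, chr3 = 2e6),
    n_regions = 4,
    region_length_range = c(8e4, 1.5e5),
    n_loci = 300,
    codon_model = utils::modifyList(
      formals(synthetic_genome_config)$codon_model |> eval(),
      list(n_genes_per_group = 20, n_codons = 100)))
  do.call(synthetic_genome_config, utils::modifyList(base, list(...)))
}

.fixture_env <- new.env()

shared_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- simulate_genome(small_test_config(20240917))
  .fixture_env$bundle
}

# mid-sized bundle with default (study-condition) rates, no alignments
shared_default_bundle <- function() {
  if (is.null(.fixture_env$default_bundle))
    .fixture_env$default_bundle <- simulate_genome(
      synthetic_genome_config(seed = 20240918, simulate_alignments = FALSE))
  .fixture_env$default_bundle
}
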