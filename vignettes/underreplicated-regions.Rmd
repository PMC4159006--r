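---
title: "Characterizing underreplicated genomic regions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing underreplicated genomic regions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(underrep)
```

## The scientific problem

Polytene chromosomes of *Drosophila melanogaster* underreplicate a set of
late-replicating regions. Sixty such regions, with borders refined by
chromatin signatures (here called UR regions), cover roughly 12% of the
mappable genome. This package re-implements, as a tested pipeline, the
comparative-genomics characterization of these regions: which genes they
contain, how conserved those genes are across distant species, how fast
their proteins evolve relative to matched neighboring genes, how
conserved *noncoding* elements distribute with respect to the regions,
and how gene conservation relates to replication timing in cell
culture.

The package has two operating modes:

* **Replay** -- the published summary counts (gene totals, expected
  counts, 2x2 tables, length aggregates) are shipped as plain-text
  tables and every printed statistic is recomputed from them
  (`replay_published_tables()`). No genome data are needed.
* **Full pipeline** -- `run_pipeline()` executes every stage on a data
  bundle (BED regions, BED12 gene models, label tables, element tracks,
  a probe track, per-gene codon alignments). Real extracts can be
  supplied; the seeded generator `simulate_genome()` produces a complete
  bundle with planted ground truth for validation.

## Coordinate model and gene assignment

All coordinates are 0-based half-open (the BED convention); 1-based
containers appear only inside the IRanges-backed internals. Region sets
are merged on construction so coverage sums are well defined; strand is
carried but ignored by interval algebra.

A locus is assigned to the UR set when at least 50% of its genomic span
-- left-most start to right-most end over *all* transcript isoforms --
is covered by UR bases, summed across regions (a locus straddling two
regions counts its combined coverage; the boundary case "exactly 50%"
is assigned). For per-locus quantities that need one transcript (protein
length, CDS alignment) the first isoform in alphabetical order is used.

The annotation partition (exonic / intronic / intergenic) assigns every
base of the declared chromosomes to exactly one category with
exon-over-intron precedence: a base covered by an exon of one isoform
and an intron of another is exonic. The partition identity
`|exonic| + |intronic| + |intergenic| = genome length` is asserted on
every fixture, and both the partition and the interval intersection are
pinned against brute-force per-base classifiers in the test suite.

## Matched adjacent-gene controls

For each region with *n* assigned genes, the control set takes the
`ceiling(n/2)` nearest eligible genes upstream (by span end) and
`floor(n/2)` nearest downstream (by span start). Eligibility is strict:
a control must be unassigned *and* overlap no UR region by even one
base. Where one flank runs out, the deficit moves to the other flank;
when both are exhausted the stage fails naming the region. Two
deterministic tie-breaks are package decisions (the source material
says only "half upstream and half downstream"): an odd count places the
extra gene upstream, and distance ties resolve by gene identifier. The
run log reports control counts next to assigned counts, so flank
deficits (the published analysis itself pairs 891 controls with 933
region genes) are visible rather than silent.

## Enrichment with length-proportional expectations

Every observed/expected comparison uses the same two-cell df = 1
goodness-of-fit without continuity correction:

$$X^2 = \frac{(O-E)^2}{E} + \frac{((T-O)-(T-E))^2}{T-E}, \qquad
p = P(\chi^2_1 \ge X^2).$$

* **Gene classes** (e.g. "has a human homolog", stratified by testis
  specificity): `E` is the genome-wide label fraction times the number
  of assigned genes in the stratum.
* **Elements** (ultraconserved elements, high-scoring conserved
  segments, the four-track intersection set): per annotation category,
  `E` is the genome-wide per-Mb density of the category times the
  category's length inside the regions. Membership of an element in a
  region is decided by its midpoint by default; midpoint assignment is
  what makes the expected counts exactly length-proportional, and the
  `any-overlap` and `50%` alternatives are available behind an argument.
* **Short ncRNAs** are assigned a single category by majority of their
  span (exon > intron > intergenic precedence on ties); lincRNAs use a
  50%-of-length overlap rule and are summarized by count, mean occupied
  length inside vs. outside, and fraction of intergenic bases covered.

The 2x2 EST-support comparison uses the uncorrected Pearson chi-square
`n(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; on the published counts
(53/11 vs. 786/83) this gives 3.84 where the Yates-corrected statistic
would give about 3.0, which is the evidence that the published value was
computed without correction. No multiple-testing correction is applied
anywhere (none was applied in the source analysis); the report states
the number of tests performed.

Both chi-squared forms are property-tested against `stats::chisq.test`
on a thousand random tables, and the two-cell test's p-values are
checked for approximate uniformity under a uniformly planted null.

### A note on deep-tail p-values

The replayed gene-conservation tests reproduce printed values such as
1.7E-85 and 1.1E-59. Our tails come from `pchisq`, which is accurate in
this range; the published tails were computed in a spreadsheet whose
historical chi-squared tail routine is imprecise below ~1E-30. Three of
the six printed mantissas therefore differ from the accurate value by
1--3 units in the second digit (e.g. accurate 1.80E-62 vs. printed
2.1E-62). The acceptance tests assert exact 2-significant-figure
agreement where the accurate computation reproduces the print, and
agreement within 25% of the printed magnitude (a negligible band on a
23-order-of-magnitude spread) for the spreadsheet-limited cells.

## Pamilo--Bianchi--Li distances

The divergence stage estimates synonymous and nonsynonymous distances
from concatenated codon alignments by degeneracy class. Each codon
position is 4-fold degenerate if every substitution is synonymous,
0-fold if none is, 2-fold otherwise (3-fold isoleucine positions count
as 2-fold). For an aligned pair, with $P_i = s_i/L_i$ (transitions per
class-$i$ site) and $Q_i = v_i/L_i$ (transversions),

$$A_i = \tfrac12\ln\frac{1}{1-2P_i-Q_i} - \tfrac14\ln\frac{1}{1-2Q_i},
\qquad B_i = \tfrac12\ln\frac{1}{1-2Q_i},$$

$$K_s = \frac{L_2A_2 + L_4A_4}{L_2+L_4} + B_4, \qquad
K_a = A_0 + \frac{L_0B_0 + L_2B_2}{L_0+L_2}, \qquad d_4 = A_4 + B_4.$$

Counting conventions the formulas leave open are fixed as follows and
pinned by a brute-force oracle in the tests:

* Codon columns containing a gap, an `N`, or a stop codon in either row
  are dropped for that pair only (pairwise, not listwise, deletion --
  each pair uses its maximal clean column set).
* Site totals $L_i$ average the two rows' tallies; when the two codons
  class a differing position differently, the difference count is split
  half-and-half between the two classes.
* Codons differing at 2--3 positions are resolved by equal-weight
  averaging over all shortest substitution pathways that avoid stop
  codons (the classical counting convention); if every pathway passes
  through a stop, all pathways are used and a stop endpoint's
  unclassifiable site cedes its weight to the sense codon.
* Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) raises an explicit error
  naming the class, as does an alignment with no 4-fold sites.

Concatenation joins per-gene alignments in lexicographic gene-id order
(order provably does not affect the result; a shuffle test asserts it)
and requires a consistent taxon set, dropping deviating genes with a
warning. Group comparisons emit all pairwise distances per group plus
the mean between-group ratio per metric, overall and within label
subsets (e.g. genes without human homologs). Standard errors of PBL
distances are out of scope.

## Protein lengths and replication timing

Length summaries are plain means/medians/quartiles with explicit,
logged id-based exclusions; removing a single extreme value from a
printed $(n, \bar{x})$ pair uses the identity $(n\bar{x}-x)/(n-1)$.
Rank-sum comparisons use the two-sided Mann--Whitney test: exact
enumeration when both samples are tie-free with $\le 50$ observations,
otherwise the tie-corrected normal approximation (the two branches agree
within $|\Delta p| < 0.01$ at $n = 30$, asserted in the tests).

Per-locus replication scores average all probes overlapping the locus
span by at least 5 bp, unweighted (matching the "average for all
probes overlapping" convention); an overlap-weighted variant sits
behind a flag. The unweighted mean is deliberately *not* invariant to
splitting a probe in two -- the split probe votes twice -- while the
weighted variant is; both behaviors are tested. Loci with no qualifying
probe are excluded from group statistics, and a chromosome can be
excluded wholesale (the X for male-derived cell lines, where dosage
compensation advances replication). Whether per-locus averages should
use the span or merged exon space is unstated in the source; the span
is used, matching "probes overlapping every locus".

## The synthetic genome generator

`simulate_genome()` is first-class, tested code, not a fixture dump. It
emulates the statistical structure of the study system at roughly
one-fifth genome scale -- the sizes keep the full validation suite
fast while leaving every per-category count large enough to test
against:

* three chromosomes totalling 20 Mb; 12 regions of 120--280 kb
  (~12% of the genome, matching the real regions' share);
* 2,200 loci, ~6.8% planted fully inside regions (the regions' lower
  gene density), the rest fully outside, with an optional straddling
  class exercising the 50% boundary; long-tailed gene spans (lognormal
  plus an explicit very-long-gene tail to 30--60 kb);
* conservation labels at the published contrasts: human homolog 0.11
  inside vs. 0.43 outside, mosquito 0.54 vs. 0.79, testis-specific 0.35
  vs. 0.13 among expression-annotated genes; protein lengths lognormal
  with conserved genes longer;
* element tracks at the published per-Mb densities and inside/outside
  ratios (e.g. intronic high-score elements ~1.9-fold denser inside);
  the four pairwise conservation tracks are built around planted cores
  such that their AND-intersection equals the cores *exactly* (per core
  one rotating track carries the exact extent; decoys appear in at most
  three tracks and away from cores), giving exact ground truth for the
  intersection + length + exon filters;
* a tiled probe track whose class means (1.4 conserved / 0.5
  nonconserved) are planted with the same 5-bp-overlap rule the scorer
  uses, so the plant is recoverable rather than diluted by locus-edge
  probes;
* short ncRNAs with planted depletion inside regions (snoRNAs absent
  entirely) and intergenic lincRNAs drawn at 2.2 kb inside vs. 1.7 kb
  outside, placed only into intervals that fit the drawn length so the
  planted means survive placement;
* per-gene codon alignments on a star phylogeny of eight taxa.

The codon simulator evolves a stop-free ancestral sequence along each
branch with a per-site event process: proposal weights favor
transitions by $\kappa$, synonymous changes proceed at a rate
calibrated so expected pairwise divergence at 4-fold sites equals
`ds`, nonsynonymous changes at `ds * dn_mult`, and proposals creating
stops are rejected. Realized substitutions are logged per taxon, class
and type -- the single source of truth the estimator is tested against.
A star tree suffices because only pairwise distances are estimated, and
it makes expected pairwise divergence the simple sum of two branches.
The region gene group gets a 1.4x nonsynonymous multiplier.

The manifest records every planted truth (locus placements and labels,
per-category element counts, the exact surviving core set, ncRNA
placements, alignment event logs). Identical seeds give byte-identical
bundles, and written bundles round-trip through the readers without
loss.

What the generator does **not** emulate: real base composition, repeat
and transposon content, isoform complexity beyond a two-isoform test
mode, correlated placement of elements with specific long genes, or a
realistic phylogeny. Passing tests therefore demonstrate that the
*methods* recover planted structure of the published kind and effect
sizes -- not that any particular biological conclusion transfers to a
new genome.

## Numerical and design choices

* Merging at `region_set` construction also merges abutting intervals;
  coverage arithmetic is unaffected.
* Interval algebra, BED/bedGraph/FASTA parsing, chi-squared tails and
  the rank-sum test delegate to IRanges/GenomicRanges, rtracklayer,
  Biostrings and `stats`; the package's own contributions are the
  assignment/control/filter rules, the expected-count model, the PBL
  estimator, and the generator.
* The multi-hit pathway table is precomputed once per session for all
  ordered sense-codon pairs, making pair counting a vectorized table
  lookup (30,000 codons in well under a second after warm-up).
* Distance ties and ordering in control selection, concatenation order,
  and all generator draws are deterministic given the seed; pipeline
  reruns are byte-identical, which the tests assert.
* Problem sizes used by the validation suite: 1,000 random codon pairs
  of up to 100 codons against the pathway-enumeration oracle; 30,000
  codons for synonymous-rate recovery (within 5% of realized
  substitutions; observed ~0.7%); 40 genes x 250 codons per group for
  the 1.4x contrast; 500 replicates for null p-value uniformity; 50-60
  random loci on 100 kb genomes for per-base partition oracles. These
  are the package's validation scales, chosen so each check has
  adequate statistical resolution.

## Known limitations

* PBL variances/standard errors are not computed, so no per-pair
  significance is attached to distance differences.
* The expected-count model treats element placements as independent
  (Poisson); clustered real elements would be overdispersed and the
  chi-squared p-values correspondingly anti-conservative.
* Homology labels are inputs, never recomputed; alignment construction
  (MAF stitching) is upstream of this package.
* The retroposed-gene and GO-term analyses of the source study are out
  of scope (the former's expected-proportion basis is not
  reconstructible from the printed numbers).
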