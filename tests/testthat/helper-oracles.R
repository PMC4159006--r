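# Independent brute-force oracles used to pin the implementation.
# Everything here is deliberately naive and self-contained: a literal
# genetic-code table (not Biostrings), per-base bit masks (not IRanges),
# and recursive pathway enumeration.

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_is_stop <- function(codon) ORACLE_CODE[[codon]] == "*"

oracle_degeneracy <- function(codon) {
  b <- strsplit(codon, "")[[1]]
  vapply(1:3, function(p) {
    syn <- 0L
    for (alt in setdiff(c("A", "C", "G", "T"), b[p])) {
      mut <- b; mut[p] <- alt
      if (ORACLE_CODE[[paste(mut, collapse = "")]] == ORACLE_CODE[[codon]])
        syn <- syn + 1L
    }
    if (syn == 3L) 4L else if (syn == 0L) 0L else 2L
  }, integer(1))
}

oracle_is_ts <- function(a, b) {
  pur <- c("A", "G")
  (a %in% pur) == (b %in% pur)
}

# pathway-averaged difference counts for one codon pair; recursive
# enumeration of substitution orders, stop-free paths preferred
oracle_codon_pair <- function(c1, c2) {
  acc0 <- c(s0 = 0, s2 = 0, s4 = 0, v0 = 0, v2 = 0, v4 = 0)
  b1 <- strsplit(c1, "")[[1]]; b2 <- strsplit(c2, "")[[1]]
  dpos <- which(b1 != b2)
  if (length(dpos) == 0L) return(acc0)
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L)
      return(list(list(acc = acc0, clean = TRUE)))
    out <- list()
    for (p in remaining) {
      nxt <- cur; nxt[p] <- b2[p]
      cods <- c(paste(cur, collapse = ""), paste(nxt, collapse = ""))
      stops <- vapply(cods, oracle_is_stop, logical(1))
      cls <- unlist(lapply(cods[!stops], function(cd)
        oracle_degeneracy(cd)[p]))
      type <- if (oracle_is_ts(cur[p], b2[p])) "s" else "v"
      step <- acc0
      for (cl in cls)
        step[paste0(type, cl)] <- step[paste0(type, cl)] + 1 / length(cls)
      for (tail in walk(nxt, setdiff(remaining, p)))
        out[[length(out) + 1L]] <- list(acc = step + tail$acc,
                                        clean = !any(stops) && tail$clean)
    }
    out
  }
  paths <- walk(b1, dpos)
  clean <- Filter(function(p) p$clean, paths)
  use <- if (length(clean) > 0L) clean else paths
  Reduce(`+`, lapply(use, `[[`, "acc")) / length(use)
}

# full pair counting over two aligned rows, codon by codon
oracle_pair_counts <- function(x, y) {
  n <- nchar(x) %/% 3L
  L <- c(L0 = 0, L2 = 0, L4 = 0)
  sv <- c(s0 = 0, s2 = 0, s4 = 0, v0 = 0, v2 = 0, v4 = 0)
  for (i in seq_len(n)) {
    c1 <- substr(x, 3 * i - 2, 3 * i); c2 <- substr(y, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (oracle_is_stop(c1) || oracle_is_stop(c2)) next
    for (cd in c(c1, c2)) {
      d <- oracle_degeneracy(cd)
      for (p in 1:3) L[paste0("L", d[p])] <- L[paste0("L", d[p])] + 0.5
    }
    sv <- sv + oracle_codon_pair(c1, c2)
  }
  c(as.list(L), as.list(sv))
}

# direct closed-form PBL evaluation (independent typing of the formulas)
oracle_pbl <- function(cnt) {
  P <- c(cnt$s0 / cnt$L0, cnt$s2 / cnt$L2, cnt$s4 / cnt$L4)
  Q <- c(cnt$v0 / cnt$L0, cnt$v2 / cnt$L2, cnt$v4 / cnt$L4)
  P[is.nan(P)] <- 0; Q[is.nan(Q)] <- 0
  A <- 0.5 * log(1 / (1 - 2 * P - Q)) - 0.25 * log(1 / (1 - 2 * Q))
  B <- 0.5 * log(1 / (1 - 2 * Q))
  L <- c(cnt$L0, cnt$L2, cnt$L4)
  A[L == 0] <- 0; B[L == 0] <- 0
  list(Ka = A[1] + (L[1] * B[1] + L[2] * B[2]) / (L[1] + L[2]),
       Ks = (L[2] * A[2] + L[3] * A[3]) / (L[2] + L[3]) + B[3],
       d4 = A[3] + B[3])
}

# random sense-codon sequence and a mutated partner
random_codon_row <- function(n_codons) {
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

mutate_row <- function(row, n_changes) {
  b <- strsplit(row, "")[[1]]
  for (k in seq_len(n_changes)) {
    repeat {
      p <- sample.int(length(b), 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
      old <- b[p]; b[p] <- alt
      cod_i <- (p - 1) %/% 3 + 1
      cod <- paste(b[(3 * cod_i - 2):(3 * cod_i)], collapse = "")
      if (!oracle_is_stop(cod)) break
      b[p] <- old
    }
  }
  paste(b, collapse = "")
}

# --- per-base interval oracles -------------------------------------------

# logical coverage masks per chromosome for an interval table
oracle_mask <- function(df, chrom_lens) {
  masks <- lapply(chrom_lens, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    idx <- seq(df$start[i] + 1L, df$end[i])
    masks[[ch]][idx] <- TRUE
  }
  masks
}

mask_to_count <- function(masks) sum(vapply(masks, sum, numeric(1)))

# per-base annotation classifier: exon > intron > intergenic
oracle_partition_masks <- function(genes, chrom_lens) {
  spans <- locus_spans(genes)
  span_m <- oracle_mask(spans, chrom_lens)
  exon_m <- oracle_mask(exon_df_for_tests(genes), chrom_lens)
  lapply(names(chrom_lens), function(ch) {
    cls <- rep("intergenic", chrom_lens[[ch]])
    cls[span_m[[ch]]] <- "intronic"
    cls[exon_m[[ch]]] <- "exonic"
    cls
  }) |> stats::setNames(names(chrom_lens))
}

exon_df_for_tests <- function(genes) {
  n <- vapply(genes$exon_starts, length, integer(1))
  data.frame(chrom = rep(genes$chrom, n),
             start = unlist(genes$exon_starts),
             end = unlist(genes$exon_ends))
}

region_set_masks <- function(rs, chrom_lens) {
  df <- region_set(rs)$intervals
  oracle_mask(df[df$chrom %in% names(chrom_lens), , drop = FALSE],
              chrom_lens)
}
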