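## Pamilo-Bianchi-Li synonymous/nonsynonymous distances from codon
## alignments. Sites are classified by degeneracy (0-, 2-, 4-fold, with
## the 3-fold isoleucine positions counted as 2-fold), transitional and
## transversional differences are tallied per class with equal-weight
## averaging over shortest stop-free substitution pathways for multi-hit
## codons, and Kimura-type corrections per class give Ka, Ks and the
## 4-fold-site distance d4.

BASES <- c("A", "C", "G", "T")
CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))

.div_cache <- new.env(parent = emptyenv())

codon_meta <- function() {
  if (!is.null(.div_cache$meta)) return(.div_cache$meta)
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- unname(gc_tab[CODONS])
  sense <- which(aa != "*")
  deg <- matrix(NA_integer_, nrow = 64, ncol = 3)
  for (i in sense) {
    cod <- strsplit(CODONS[i], "")[[1]]
    for (p in 1:3) {
      alts <- setdiff(BASES, cod[p])
      syn <- sum(vapply(alts, function(b) {
        mut <- cod; mut[p] <- b
        unname(gc_tab[paste(mut, collapse = "")]) == aa[i]
      }, logical(1)))
      deg[i, p] <- if (syn == 3L) 4L else if (syn == 0L) 0L else 2L
    }
  }
  nsites <- matrix(0, nrow = 64, ncol = 3,
                   dimnames = list(NULL, c("L0", "L2", "L4")))
  for (i in sense)
    for (p in 1:3)
      nsites[i, paste0("L", deg[i, p])] <-
        nsites[i, paste0("L", deg[i, p])] + 1
  meta <- list(aa = aa, sense = sense, deg = deg, nsites = nsites)
  .div_cache$meta <- meta
  meta
}

is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

#' Degeneracy class of each codon position
#'
#' Under the universal genetic code: a position is 4-fold degenerate when
#' every substitution is synonymous, 0-fold when none is, and 2-fold
#' otherwise (the 3-fold isoleucine third positions count as 2-fold).
#'
#' @param codon a sense codon over `A C G T`.
#' @return integer vector of length 3 with values in `{0, 2, 4}`.
#' @export
classify_codon_sites <- function(codon) {
  meta <- codon_meta()
  i <- match(toupper(codon), CODONS)
  if (is.na(i)) stop("not a codon: ", codon)
  if (!(i %in% meta$sense)) stop("stop codon: ", codon)
  meta$deg[i, ]
}

## Pathway-averaged difference contributions for one ordered codon pair.
## Returns a 3x2 matrix (class 0/2/4 x transition/transversion).
pair_contribution <- function(i, j, meta) {
  ci <- strsplit(CODONS[i], "")[[1]]
  cj <- strsplit(CODONS[j], "")[[1]]
  dpos <- which(ci != cj)
  zero <- matrix(0, 3, 2, dimnames = list(c("0", "2", "4"), c("s", "v")))
  if (length(dpos) == 0L) return(zero)
  perms <- all_permutations(dpos)
  contribs <- list(); contribs_all <- list()
  for (ord in perms) {
    cur <- ci
    acc <- zero
    valid <- TRUE
    for (p in ord) {
      nxt <- cur; nxt[p] <- cj[p]
      cur_i <- match(paste(cur, collapse = ""), CODONS)
      nxt_i <- match(paste(nxt, collapse = ""), CODONS)
      cur_stop <- !(cur_i %in% meta$sense)
      nxt_stop <- !(nxt_i %in% meta$sense)
      if (nxt_stop || cur_stop) valid <- FALSE
      type <- if (is_transition(cur[p], cj[p])) "s" else "v"
      ## class of the changing site: split between the two codons' calls;
      ## a stop-codon endpoint (fallback pathways only) cannot be
      ## classified, so the sense side carries the full weight
      cl <- character(0)
      if (!cur_stop) cl <- c(cl, as.character(meta$deg[cur_i, p]))
      if (!nxt_stop) cl <- c(cl, as.character(meta$deg[nxt_i, p]))
      for (cc in cl) acc[cc, type] <- acc[cc, type] + 1 / length(cl)
      cur <- nxt
    }
    contribs_all[[length(contribs_all) + 1L]] <- acc
    if (valid) contribs[[length(contribs) + 1L]] <- acc
  }
  if (length(contribs) == 0L) contribs <- contribs_all
  Reduce(`+`, contribs) / length(contribs)
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (k in seq_along(x))
    for (rest in all_permutations(x[-k]))
      out[[length(out) + 1L]] <- c(x[k], rest)
  out
}

## 64*64 x 6 lookup of pathway-averaged (s0,s2,s4,v0,v2,v4); sense pairs only
pair_table <- function() {
  if (!is.null(.div_cache$pair_tab)) return(.div_cache$pair_tab)
  meta <- codon_meta()
  tab <- matrix(NA_real_, nrow = 64 * 64, ncol = 6,
                dimnames = list(NULL, c("s0", "s2", "s4", "v0", "v2", "v4")))
  for (i in meta$sense) {
    for (j in meta$sense) {
      if (i == j) {
        tab[(i - 1) * 64 + j, ] <- 0
      } else {
        m <- pair_contribution(i, j, meta)
        tab[(i - 1) * 64 + j, ] <- c(m[, "s"], m[, "v"])
      }
    }
  }
  .div_cache$pair_tab <- tab
  tab
}

row_to_codon_idx <- function(row) {
  w <- nchar(row)
  cods <- substring(row, seq(1L, w, 3L), seq(3L, w, 3L))
  match(cods, CODONS)   # NA for any codon containing gap or N
}

#' Site and difference counts for an aligned sequence pair
#'
#' Codon columns containing a gap, an `N`, or a stop codon in either row
#' are skipped entirely. Per-class site totals `L0, L2, L4` are the mean
#' of the two rows' tallies; nucleotide differences are recorded as
#' transitions (`s`) or transversions (`v`) at the class of the changing
#' position, split fractionally between the two codons' class calls when
#' they disagree, and averaged with equal weight over all shortest
#' stop-free substitution pathways for codons differing at more than one
#' position.
#'
#' @param x,y aligned sequences of equal length divisible by 3 (uppercase
#'   `A C G T - N`), or a `codon_alignment` plus two taxon names.
#' @return object of class `site_class_counts`: list with `L0, L2, L4,
#'   s0, s2, s4, v0, v2, v4, n_codons`.
#' @export
count_site_differences <- function(x, y) {
  if (inherits(x, "codon_alignment")) {
    stopifnot(length(y) == 2L)
    rows <- x$rows[y]; x <- rows[[1]]; y <- rows[[2]]
  }
  if (nchar(x) != nchar(y)) stop("rows differ in length")
  if (nchar(x) %% 3L != 0L) stop("frame violation: length not divisible by 3")
  meta <- codon_meta()
  ix <- row_to_codon_idx(toupper(x))
  iy <- row_to_codon_idx(toupper(y))
  ok <- !is.na(ix) & !is.na(iy) & ix %in% meta$sense & iy %in% meta$sense
  ix <- ix[ok]; iy <- iy[ok]
  L <- (colSums(meta$nsites[ix, , drop = FALSE]) +
          colSums(meta$nsites[iy, , drop = FALSE])) / 2
  d <- ix != iy
  if (any(d)) {
    tab <- pair_table()
    sv <- colSums(tab[(ix[d] - 1) * 64 + iy[d], , drop = FALSE])
  } else {
    sv <- c(s0 = 0, s2 = 0, s4 = 0, v0 = 0, v2 = 0, v4 = 0)
  }
  structure(c(as.list(L), as.list(sv), list(n_codons = length(ix))),
            class = "site_class_counts")
}

#' Pamilo-Bianchi-Li distance from site-class counts
#'
#' Per degeneracy class `i`, with `P_i = s_i/L_i` and `Q_i = v_i/L_i`,
#' the Kimura-type components are
#' `A_i = 1/2 log(1/(1 - 2P_i - Q_i)) - 1/4 log(1/(1 - 2Q_i))` and
#' `B_i = 1/2 log(1/(1 - 2Q_i))`. The synonymous distance is
#' `Ks = (L2 A2 + L4 A4)/(L2 + L4) + B4`, the nonsynonymous distance is
#' `Ka = A0 + (L0 B0 + L2 B2)/(L0 + L2)`, and the 4-fold-site distance is
#' `d4 = A4 + B4` (substitutions per site).
#'
#' @param counts a `site_class_counts` object.
#' @return object of class `pbl_distance`: list with per-class `P`, `Q`,
#'   `A`, `B` and `Ka`, `Ks`, `d4`.
#' @export
pbl_distance <- function(counts) {
  L <- c(counts$L0, counts$L2, counts$L4)
  s <- c(counts$s0, counts$s2, counts$s4)
  v <- c(counts$v0, counts$v2, counts$v4)
  cls <- c("0-fold", "2-fold", "4-fold")
  if (L[1] + L[2] <= 0 || L[2] + L[3] <= 0)
    stop("empty site classes: need L0+L2 > 0 and L2+L4 > 0")
  if (L[3] <= 0) stop("no 4-fold degenerate sites: d4/Ks undefined")
  P <- ifelse(L > 0, s / L, 0)
  Q <- ifelse(L > 0, v / L, 0)
  A <- B <- numeric(3)
  for (i in 1:3) {
    if (L[i] == 0) next
    a1 <- 1 - 2 * P[i] - Q[i]
    a2 <- 1 - 2 * Q[i]
    if (a1 <= 0 || a2 <= 0)
      stop("saturated divergence at ", cls[i], " sites")
    A[i] <- 0.5 * log(1 / a1) - 0.25 * log(1 / a2)
    B[i] <- 0.5 * log(1 / a2)
  }
  Ks <- (L[2] * A[2] + L[3] * A[3]) / (L[2] + L[3]) + B[3]
  Ka <- A[1] + (L[1] * B[1] + L[2] * B[2]) / (L[1] + L[2])
  structure(list(P = P, Q = Q, A = A, B = B, L = L,
                 Ka = Ka, Ks = Ks, d4 = A[3] + B[3]),
            class = "pbl_distance")
}

#' @export
print.pbl_distance <- function(x, ...) {
  cat(sprintf("<pbl_distance: Ka = %.4f, Ks = %.4f, d4 = %.4f>\n",
              x$Ka, x$Ks, x$d4))
  invisible(x)
}

#' All pairwise PBL distances of a codon alignment
#'
#' @param aln a `codon_alignment`.
#' @param warn_saturated emit `NA` rows with a warning for saturated
#'   pairs instead of failing (default TRUE).
#' @return data.frame: `taxon1`, `taxon2`, `Ka`, `Ks`, `d4`.
#' @export
pairwise_distances <- function(aln, warn_saturated = TRUE) {
  taxa <- aln$taxa
  combs <- utils::combn(taxa, 2)
  rows <- lapply(seq_len(ncol(combs)), function(k) {
    t1 <- combs[1, k]; t2 <- combs[2, k]
    d <- tryCatch(pbl_distance(count_site_differences(aln, c(t1, t2))),
                  error = function(e) {
                    if (!warn_saturated) stop(e)
                    warning(t1, "-", t2, ": ", conditionMessage(e),
                            call. = FALSE)
                    NULL
                  })
    data.frame(taxon1 = t1, taxon2 = t2,
               Ka = if (is.null(d)) NA_real_ else d$Ka,
               Ks = if (is.null(d)) NA_real_ else d$Ks,
               d4 = if (is.null(d)) NA_real_ else d$d4,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Concatenate per-gene codon alignments
#'
#' Joins alignments end to end in lexicographic gene-id order (the order
#' does not affect any distance). Genes whose taxon set differs from the
#' consensus (the most common taxon set) are dropped with a warning.
#'
#' @param alignments named list of `codon_alignment`s (names are gene
#'   ids).
#' @param ids optional subset of gene ids to include.
#' @return a single `codon_alignment`.
#' @export
concatenate_alignments <- function(alignments, ids = NULL) {
  if (is.null(names(alignments))) stop("alignments must be named by gene id")
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(alignments))
    if (length(missing) > 0L)
      stop("no alignment for: ", paste(missing, collapse = ", "))
    alignments <- alignments[ids]
  }
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  alignments <- alignments[order(names(alignments))]
  taxa_sets <- lapply(alignments, function(a) sort(a$taxa))
  keys <- vapply(taxa_sets, paste, character(1), collapse = "|")
  consensus <- names(sort(table(keys), decreasing = TRUE))[1]
  drop <- keys != consensus
  if (any(drop)) {
    warning("dropping genes with differing taxon sets: ",
            paste(names(alignments)[drop], collapse = ", "))
    alignments <- alignments[!drop]
  }
  taxa <- sort(alignments[[1]]$taxa)
  rows <- vapply(taxa, function(tx)
    paste(vapply(alignments, function(a) unname(a$rows[tx]), character(1)),
          collapse = ""), character(1))
  codon_alignment(rows)
}

#' Concatenated-alignment divergence comparison between gene groups
#'
#' For each gene group (e.g. region-assigned vs. adjacent controls), the
#' per-gene CDS alignments are concatenated into one contig and all
#' pairwise PBL distances are computed; the result pairs the two groups'
#' values per taxon pair for `d4`, `Ka` and `Ks`, optionally within gene
#' subsets (e.g. genes without human homologs), together with the mean
#' ratio between groups per metric.
#'
#' @param alignments named list of `codon_alignment`s (gene ids).
#' @param groups named list of two character vectors of gene ids.
#' @param subsets optional named list of gene-id vectors; each subset
#'   restricts both groups (`all` = no restriction is always included).
#' @return list with `pairs` (per taxon pair and subset, one column pair
#'   per metric) and `summary` (mean group1/group2 ratio per metric and
#'   subset).
#' @export
concatenate_and_compare <- function(alignments, groups, subsets = NULL) {
  if (length(groups) != 2L || is.null(names(groups)))
    stop("groups must be a named list of two gene-id vectors")
  g1 <- names(groups)[1]; g2 <- names(groups)[2]
  subsets <- c(list(all = NULL), subsets)
  pair_rows <- list(); summ_rows <- list()
  for (sn in names(subsets)) {
    ids1 <- groups[[1]]; ids2 <- groups[[2]]
    if (!is.null(subsets[[sn]])) {
      ids1 <- intersect(ids1, subsets[[sn]])
      ids2 <- intersect(ids2, subsets[[sn]])
    }
    ids1 <- intersect(ids1, names(alignments))
    ids2 <- intersect(ids2, names(alignments))
    if (length(ids1) == 0L || length(ids2) == 0L)
      stop("empty group in subset '", sn, "'")
    d1 <- pairwise_distances(concatenate_alignments(alignments, ids1))
    d2 <- pairwise_distances(concatenate_alignments(alignments, ids2))
    stopifnot(identical(d1$taxon1, d2$taxon1),
              identical(d1$taxon2, d2$taxon2))
    pr <- data.frame(subset = sn, taxon1 = d1$taxon1, taxon2 = d1$taxon2,
                     stringsAsFactors = FALSE)
    for (m in c("d4", "Ka", "Ks")) {
      pr[[paste0(m, "_", g1)]] <- d1[[m]]
      pr[[paste0(m, "_", g2)]] <- d2[[m]]
      summ_rows[[paste(sn, m)]] <- data.frame(
        subset = sn, metric = m,
        n_genes_1 = length(ids1), n_genes_2 = length(ids2),
        mean_ratio = mean(d1[[m]] / d2[[m]], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
    pair_rows[[sn]] <- pr
  }
  summary <- do.call(rbind, summ_rows)
  rownames(summary) <- NULL
  list(pairs = do.call(rbind, pair_rows), summary = summary)
}
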