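# Internal vectorised kernel shared by the genome scan and the permutation
# nulls. Works on flat per-marker vectors instead of the trios x markers x 3
# array so that a single pair evaluation costs a handful of vector ops on
# n-trio vectors. Equality with the array-based (modular) path is asserted in
# the test suite.

# Per-marker cache: for each marker, the usable-trio subset with parental and
# child dosages, Mendelian probability columns and their column sums.
.marker_cache <- function(gm, trios) {
  g <- gm$genotypes
  tt <- trios$trios
  use <- trios$usable
  nt <- nrow(tt)
  lapply(seq_len(n_markers(gm)), function(m) {
    u <- use[, m]
    fa <- g[tt$father[u], m]; mo <- g[tt$mother[u], m]; ch <- g[tt$child[u], m]
    P0 <- .MENDEL[3L * fa + mo + 1L, , drop = FALSE]
    list(u = u, pos = cumsum(u), n = sum(u), fa = fa, mo = mo, ch = ch,
         p1 = P0[, 1], p2 = P0[, 2], p3 = P0[, 3],
         es = c(sum(P0[, 1]), sum(P0[, 2]), sum(P0[, 3])))
  })
}

# Corrected, renormalized per-trio probability columns for one marker, given
# the (observed or pseudo) child dosages. Iterative proportional fitting to
# the fixed point where sample-wide expected genotype counts equal the
# observed ones (mirrors normalized_expected()). Returns list(p1, p2, p3).
.norm_probs <- function(cm, ch, tol = 1e-9, max_iter = 100) {
  obs <- tabulate(ch + 1L, 3L)
  p1 <- cm$p1; p2 <- cm$p2; p3 <- cm$p3
  es <- cm$es
  for (it in seq_len(max_iter)) {
    f1 <- if (es[1] > 0) obs[1] / es[1] else 1
    f2 <- if (es[2] > 0) obs[2] / es[2] else 1
    f3 <- if (es[3] > 0) obs[3] / es[3] else 1
    q1 <- p1 * f1; q2 <- p2 * f2; q3 <- p3 * f3
    tot <- q1 + q2 + q3
    p1 <- q1 / tot; p2 <- q2 / tot; p3 <- q3 / tot
    if (max(abs(c(f1, f2, f3) - 1)) < tol) break
    es <- c(sum(p1), sum(p2), sum(p3))
  }
  list(p1 = p1, p2 = p2, p3 = p3)
}

# Pair statistic from two markers' normalized probs and child dosages,
# restricted to the common (pair-usable) trios indexed by ia/ib into each
# marker's usable subset.
.pair_S <- function(npa, cha, ia, npb, chb, ib) {
  a1 <- npa$p1[ia]; a2 <- npa$p2[ia]; a3 <- npa$p3[ia]
  b1 <- npb$p1[ib]; b2 <- npb$p2[ib]; b3 <- npb$p3[ib]
  # column-major over cells (j = marker-a genotype, k = marker-b genotype)
  E <- c(sum(a1 * b1), sum(a2 * b1), sum(a3 * b1),
         sum(a1 * b2), sum(a2 * b2), sum(a3 * b2),
         sum(a1 * b3), sum(a2 * b3), sum(a3 * b3))
  O <- tabulate(3L * chb[ib] + cha[ia] + 1L, 9L)  # cell (j,k) at index 3k+j+1
  pos <- E > 0
  sum((O[pos] - E[pos])^2 / E[pos])
}

# Draw one pseudo-offspring dosage vector for a marker: one transmitted allele
# per parent, uniform over each heterozygous parent's two alleles.
.draw_pseudo <- function(fa, mo) {
  n <- length(fa)
  tf <- (fa == 2L) + (fa == 1L) * (stats::runif(n) < 0.5)
  tm <- (mo == 2L) + (mo == 1L) * (stats::runif(n) < 0.5)
  as.integer(tf + tm)
}

# Observed statistic plus B pseudo-control null statistics for one pair.
# The full pipeline (correction from the pseudo data included) is recomputed
# inside every permutation so observed and null statistics are exchangeable.
.pair_perm <- function(ca, cb, ia, ib, B) {
  obs <- .pair_S(.norm_probs(ca, ca$ch), ca$ch, ia,
                 .norm_probs(cb, cb$ch), cb$ch, ib)
  null_S <- numeric(B)
  for (r in seq_len(B)) {
    pca <- .draw_pseudo(ca$fa, ca$mo)
    pcb <- .draw_pseudo(cb$fa, cb$mo)
    null_S[r] <- .pair_S(.norm_probs(ca, pca), pca, ia,
                         .norm_probs(cb, pcb), pcb, ib)
  }
  list(observed_S = obs, null_S = null_S)
}

# Common-trio index vectors (into each marker's usable subset) for a pair.
.pair_index <- function(ca, cb) {
  common <- ca$u & cb$u
  list(ia = ca$pos[common], ib = cb$pos[common], n = sum(common))
}

# Deterministic per-pair seed below 2^31, derived from the global seed and the
# pair's marker ids so results do not depend on evaluation order.
.pair_seed <- function(seed, id_a, id_b) {
  h <- sum(utf8ToInt(paste(id_a, id_b, sep = "|")) *
             (31 ^ (seq_len(nchar(id_a) + nchar(id_b) + 1) %% 7)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Evaluate seed-dependent code without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Pair imbalance statistics for many marker pairs at once
#'
#' Computes the observed statistic (no permutations) for every requested
#' marker pair, by default all pairs of markers on different chromosomes.
#' This is the fast statistic-only ranking used, e.g., to locate a planted
#' incompatibility; calibrated significance requires [permutation_pvalue()]
#' or [trio_scan()].
#'
#' @param gm a [genotype_matrix()] object.
#' @param trios the [extract_trios()] result.
#' @param pairs optional 2-column integer matrix of marker index pairs; when
#'   `NULL`, all inter-chromosomal pairs are used.
#' @param min_trios pairs with fewer jointly usable trios are skipped.
#' @return data.frame with `marker_a`, `marker_b`, `chrom_a`, `chrom_b`,
#'   `n_pair`, `S`.
#' @export
all_pair_statistics <- function(gm, trios, pairs = NULL, min_trios = 20) {
  if (is.null(pairs)) pairs <- inter_chromosomal_pairs(gm$markers$chromosome)
  cache <- .marker_cache(gm, trios)
  nps <- lapply(cache, function(cm) .norm_probs(cm, cm$ch))
  n <- nrow(pairs)
  S <- rep(NA_real_, n); np <- integer(n)
  for (i in seq_len(n)) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    px <- .pair_index(cache[[a]], cache[[b]])
    np[i] <- px$n
    if (px$n < min_trios) next
    S[i] <- .pair_S(nps[[a]], cache[[a]]$ch, px$ia,
                    nps[[b]], cache[[b]]$ch, px$ib)
  }
  mk <- gm$markers
  out <- data.frame(marker_a = mk$marker_id[pairs[, 1]],
                    marker_b = mk$marker_id[pairs[, 2]],
                    chrom_a = mk$chromosome[pairs[, 1]],
                    chrom_b = mk$chromosome[pairs[, 2]],
                    n_pair = np, S = S, stringsAsFactors = FALSE)
  out[!is.na(out$S), , drop = FALSE]
}

# All index pairs (i < j) of markers on different chromosomes.
inter_chromosomal_pairs <- function(chrom) {
  n <- length(chrom)
  if (n < 2) return(matrix(integer(0), 0, 2))
  idx <- utils::combn(n, 2)
  keep <- chrom[idx[1, ]] != chrom[idx[2, ]]
  cbind(idx[1, keep], idx[2, keep])
}
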