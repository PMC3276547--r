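# Pseudo-control permutation nulls and multiplicity correction.

#' The four equally likely offspring genotypes of a parent pair
#'
#' Enumerates the 2 x 2 combinations of one transmitted allele per parent,
#' duplicates kept, so that a uniform draw over the four entries reproduces
#' the Mendelian offspring distribution.
#'
#' @param father,mother scalar dosages in \{0, 1, 2\}.
#' @return Integer vector of length 4 (a multiset of dosages).
#' @export
#' @examples
#' possible_offspring(1, 1)  # 0 1 1 2
possible_offspring <- function(father, mother) {
  stopifnot(length(father) == 1, length(mother) == 1,
            father %in% 0:2, mother %in% 0:2)
  tf <- if (father == 1) c(0L, 1L) else rep(as.integer(father / 2), 2)
  tm <- if (mother == 1) c(0L, 1L) else rep(as.integer(mother / 2), 2)
  as.integer(outer(tf, tm, `+`))
}

#' Sample one pseudo-offspring genome per trio
#'
#' For every trio and every usable marker, draws one of the four genotypes the
#' child could have inherited, uniformly and independently across markers and
#' trios. Entries where the trio is not usable are `NA`. Pseudo-offspring are
#' the exchangeable controls from which the permutation null is built.
#'
#' @param gm a [genotype_matrix()] object.
#' @param trios the [extract_trios()] result.
#' @param seed integer seed for reproducibility (`NULL` to use the current
#'   RNG state).
#' @return trios x markers integer matrix of pseudo dosages.
#' @export
sample_pseudo_offspring <- function(gm, trios, seed = NULL) {
  draw <- function() {
    g <- gm$genotypes
    tt <- trios$trios
    use <- trios$usable
    out <- matrix(NA_integer_, nrow(tt), ncol(use))
    for (m in seq_len(ncol(use))) {
      u <- use[, m]
      if (!any(u)) next
      out[u, m] <- .draw_pseudo(g[tt$father[u], m], g[tt$mother[u], m])
    }
    out
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Permutation p-value for one marker pair
#'
#' Recomputes the full statistic pipeline (Mendelian expectations, correction
#' factors, normalization, joint table, statistic) on `B` pseudo-offspring
#' draws, yielding a marker-pair-specific empirical null. The p-value is the
#' add-one smoothed exceedance fraction `(1 + #\{null >= observed\}) / (1 + B)`
#' (ties count against the observed score); `smooth = FALSE` gives the raw
#' fraction `#\{null >= observed\} / B`, which can be 0.
#'
#' @param gm a [genotype_matrix()] object.
#' @param trios the [extract_trios()] result.
#' @param pair length-2 vector of marker indices or ids.
#' @param B number of permutations (default 1000).
#' @param seed integer seed; an internal per-pair stream is derived from it,
#'   so results are independent of the order in which pairs are evaluated.
#' @param smooth use add-one smoothing (default `TRUE`).
#' @param min_trios minimum pair-usable trios, as in [joint_genotype_table()].
#' @return Object of class `"perm_result"`: list with `pair` (marker ids),
#'   `observed_S`, `null_S` (length `B`), `p_value`, `B`, `n_pair`, `seed`;
#'   or `NULL` if the pair was skipped.
#' @export
permutation_pvalue <- function(gm, trios, pair, B = 1000, seed = 1,
                               smooth = TRUE, min_trios = 20) {
  stopifnot(B >= 1)
  if (is.character(pair)) pair <- match(pair, gm$markers$marker_id)
  stopifnot(length(pair) == 2, !anyNA(pair))
  ids <- gm$markers$marker_id[pair]
  cache <- .marker_cache(gm, trios)
  ca <- cache[[pair[1]]]; cb <- cache[[pair[2]]]
  px <- .pair_index(ca, cb)
  if (px$n < min_trios) {
    message(sprintf("pair (%s, %s) skipped: only %d usable trios (< %d)",
                    ids[1], ids[2], px$n, min_trios))
    return(NULL)
  }
  pseed <- .pair_seed(seed, ids[1], ids[2])
  res <- .with_seed(pseed, .pair_perm(ca, cb, px$ia, px$ib, B))
  k <- sum(res$null_S >= res$observed_S)
  p <- if (smooth) (1 + k) / (1 + B) else k / B
  structure(list(pair = ids, observed_S = res$observed_S, null_S = res$null_S,
                 p_value = p, B = B, n_pair = px$n, seed = pseed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("pair (%s, %s): S = %.3f, permutation p = %.4g (B = %d, %d trios)\n",
              x$pair[1], x$pair[2], x$observed_S, x$p_value, x$B, x$n_pair))
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving with the
#' input vector.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values of the same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}
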