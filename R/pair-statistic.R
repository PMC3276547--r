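# Core of the method: expected offspring genotypes under Mendelian
# transmission, the per-marker segregation-distortion correction, and the
# chi-square style pair imbalance statistic S on 3x3 joint genotype tables.

# Mendelian offspring genotype probabilities for each ordered parental dosage
# pair, indexed by 3*father + mother + 1. Row (f,m) gives P(child = 0,1,2).
.MENDEL <- local({
  tbl <- matrix(0, 9, 3)
  transmit <- list(`0` = 0, `1` = c(0, 1), `2` = 1)  # transmissible minor counts
  for (f in 0:2) for (m in 0:2) {
    p <- numeric(3)
    for (tf in transmit[[as.character(f)]])
      for (tm in transmit[[as.character(m)]])
        p[tf + tm + 1] <- p[tf + tm + 1] +
          1 / (length(transmit[[as.character(f)]]) *
               length(transmit[[as.character(m)]]))
    tbl[3 * f + m + 1, ] <- p
  }
  tbl
})

#' Mendelian offspring genotype probabilities
#'
#' Probability of each offspring dosage (0, 1, 2 copies of the minor allele)
#' given the parents' dosages, under equal transmission chances of each
#' parental allele. Symmetric in the two parents.
#'
#' @param father,mother integer dosages in \{0, 1, 2\} (vectorised; equal
#'   length or length 1).
#' @return For scalar input, a probability 3-vector; for vector input an
#'   `n x 3` matrix with rows summing to 1.
#' @export
#' @examples
#' mendelian_offspring_probs(1, 1)  # 0.25 0.50 0.25
#' mendelian_offspring_probs(0, 2)  # 0 1 0
mendelian_offspring_probs <- function(father, mother) {
  if (anyNA(father) || anyNA(mother))
    stop("missing parental genotype: mask unusable trios before calling")
  stopifnot(all(father %in% 0:2), all(mother %in% 0:2))
  out <- .MENDEL[3L * father + mother + 1L, , drop = FALSE]
  if (length(father) == 1 && length(mother) == 1) drop(out) else out
}

#' Expected genotype field for a trio set
#'
#' For every usable (trio, marker) combination, the Mendelian probability
#' 3-vector of the child's genotype given its parents. Unusable entries are
#' `NA`.
#'
#' @param gm a [genotype_matrix()] object.
#' @param trios a [extract_trios()] result consistent with `gm`.
#' @return Object of class `"expected_field"`: list with `probs` (trios x
#'   markers x 3 array), `stage = "mendelian"`, and `usable` (copied mask).
#' @export
expected_field <- function(gm, trios) {
  g <- gm$genotypes
  nt <- n_trios(trios); nm <- n_markers(gm)
  probs <- array(NA_real_, c(nt, nm, 3))
  gf <- g[trios$trios$father, , drop = FALSE]
  gmo <- g[trios$trios$mother, , drop = FALSE]
  use <- trios$usable
  if (!any(use)) stop("expected_field: no usable trio-marker entries")
  idx <- which(use)
  p <- .MENDEL[3L * gf[idx] + gmo[idx] + 1L, , drop = FALSE]
  for (k in 1:3) {
    slice <- probs[, , k]
    slice[idx] <- p[, k]
    probs[, , k] <- slice
  }
  structure(list(probs = probs, stage = "mendelian", usable = use),
            class = "expected_field")
}

#' Per-marker segregation-distortion correction factors
#'
#' For each marker and genotype class, the ratio of the sample-wide observed
#' child genotype count to the sample-wide expected count (the sum of
#' Mendelian probabilities over usable trios). A 0/0 ratio is defined as 1
#' (no information, and the factor multiplies a zero anyway). A positive
#' observed count with zero expectation would indicate a Mendelian error that
#' escaped masking and raises an error.
#'
#' @param gm a [genotype_matrix()] object.
#' @param trios the [extract_trios()] result.
#' @param field a stage-`"mendelian"` [expected_field()].
#' @return markers x 3 numeric matrix of factors.
#' @export
correction_factors <- function(gm, trios, field) {
  stopifnot(inherits(field, "expected_field"), field$stage == "mendelian")
  gc_ <- gm$genotypes[trios$trios$child, , drop = FALSE]
  use <- trios$usable
  nm <- n_markers(gm)
  fac <- matrix(1, nm, 3)
  for (k in 1:3) {
    obs <- colSums((gc_ == (k - 1L)) & use, na.rm = TRUE)
    expd <- colSums(field$probs[, , k] * use, na.rm = TRUE)
    bad <- obs > 0 & expd == 0
    if (any(bad))
      stop("observed genotype with zero Mendelian expectation at marker(s): ",
           paste(gm$markers$marker_id[bad], collapse = ", "))
    ok <- expd > 0
    fac[ok, k] <- obs[ok] / expd[ok]
  }
  fac
}

#' Apply correction factors and renormalize
#'
#' Multiplies each usable trio's expected 3-vector elementwise by its marker's
#' correction factors and renormalizes the vector to sum to 1, yielding the
#' confounder-corrected expected genotype distribution per child per marker.
#'
#' @param field a stage-`"mendelian"` [expected_field()].
#' @param factors markers x 3 matrix from [correction_factors()].
#' @return A stage-`"normalized"` `expected_field`.
#' @export
correct_and_normalize <- function(field, factors) {
  stopifnot(inherits(field, "expected_field"), field$stage == "mendelian",
            all(is.finite(factors)), all(factors >= 0))
  probs <- field$probs
  nt <- dim(probs)[1]
  for (k in 1:3)
    probs[, , k] <- probs[, , k] * rep(factors[, k], each = nt)
  tot <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  if (any(tot[field$usable] == 0))
    stop("corrected expectation sums to zero for a usable entry; cannot renormalize")
  for (k in 1:3)
    probs[, , k] <- probs[, , k] / tot
  structure(list(probs = probs, stage = "normalized", usable = field$usable),
            class = "expected_field")
}

#' Distortion-corrected, normalized expected genotype field
#'
#' The standard pipeline step producing the expected genotype distributions
#' entering the joint tables. A single pass of [correction_factors()] plus
#' [correct_and_normalize()] matches the sample-wide expected genotype
#' frequencies to the observed ones only approximately: the per-trio
#' renormalization perturbs the column sums again whenever trios have
#' heterogeneous parental genotypes. This function therefore alternates the
#' two steps (iterative proportional fitting over the trios x genotypes
#' table, per marker) until the sample-wide expected frequencies equal the
#' observed frequencies to within `tol` — the fixed point the correction is
#' meant to achieve. Convergence is guaranteed because the observed genotype
#' assignment itself is a feasible table.
#'
#' @param gm a [genotype_matrix()] object.
#' @param trios the [extract_trios()] result.
#' @param tol convergence tolerance on the per-iteration scaling factors
#'   (stop once all are within `tol` of 1); with n trios the residual
#'   observed-minus-expected count mismatch is below `n * tol`. Default 1e-9.
#' @param max_iter iteration cap (default 100; a handful of iterations is
#'   typical).
#' @return A stage-`"normalized"` [expected_field()] with attribute
#'   `"factors"` holding the cumulative markers x 3 scaling factors.
#' @export
normalized_expected <- function(gm, trios, tol = 1e-9, max_iter = 100) {
  field <- expected_field(gm, trios)
  total <- matrix(1, n_markers(gm), 3)
  for (it in seq_len(max_iter)) {
    fac <- correction_factors(gm, trios, field)
    field <- correct_and_normalize(field, fac)
    total <- total * fac
    if (max(abs(fac - 1)) < tol) break
    field$stage <- "mendelian"  # re-enter the one-pass primitives
  }
  field$stage <- "normalized"
  attr(field, "factors") <- total
  field
}

#' Observed and expected 3x3 joint genotype table for a marker pair
#'
#' Counts, over trios usable at both markers, the observed child genotype
#' combinations, and accumulates the expected table as the per-trio outer
#' product of the two corrected marginal 3-vectors (independence of the two
#' loci is the null hypothesis).
#'
#' @param gm a [genotype_matrix()] object.
#' @param trios the [extract_trios()] result.
#' @param field a stage-`"normalized"` [expected_field()].
#' @param pair length-2 vector of marker indices (or marker ids).
#' @param min_trios minimum number of pair-usable trios; below it the pair is
#'   skipped (returns `NULL` with a message). Default 20.
#' @return Object of class `"joint_table"`: list with `observed`, `expected`
#'   (3x3 matrices), `n_pair`, `marker_a`, `marker_b`; or `NULL` if skipped.
#' @export
joint_genotype_table <- function(gm, trios, field, pair, min_trios = 20) {
  stopifnot(inherits(field, "expected_field"), field$stage == "normalized")
  if (is.character(pair)) pair <- match(pair, gm$markers$marker_id)
  stopifnot(length(pair) == 2, !anyNA(pair))
  a <- pair[1]; b <- pair[2]
  use <- trios$usable[, a] & trios$usable[, b]
  n_pair <- sum(use)
  if (n_pair < min_trios) {
    message(sprintf("pair (%s, %s) skipped: only %d usable trios (< %d)",
                    gm$markers$marker_id[a], gm$markers$marker_id[b],
                    n_pair, min_trios))
    return(NULL)
  }
  gc_ <- gm$genotypes[trios$trios$child, , drop = FALSE]
  ca <- gc_[use, a]; cb <- gc_[use, b]
  observed <- matrix(tabulate(3L * ca + cb + 1L, 9L), 3, 3, byrow = TRUE)
  pa <- field$probs[use, a, , drop = FALSE]; dim(pa) <- c(n_pair, 3)
  pb <- field$probs[use, b, , drop = FALSE]; dim(pb) <- c(n_pair, 3)
  expected <- crossprod(pa, pb)
  dimnames(observed) <- dimnames(expected) <- list(0:2, 0:2)
  structure(list(observed = observed, expected = expected, n_pair = n_pair,
                 marker_a = gm$markers$marker_id[a],
                 marker_b = gm$markers$marker_id[b]),
            class = "joint_table")
}

#' Pair imbalance statistic
#'
#' The chi-square style score for one marker pair: the sum over the nine
#' genotype combinations of squared observed-minus-expected differences
#' divided by the expected value. Cells with zero expectation (which, after
#' masking of Mendelian errors, force a zero observation) contribute 0.
#'
#' @param tab a [joint_genotype_table()] result.
#' @return Object of class `"imbalance_score"`: list with `statistic`,
#'   `n_pair`, `n_nonzero_cells`.
#' @export
imbalance_statistic <- function(tab) {
  stopifnot(inherits(tab, "joint_table"))
  O <- tab$observed; E <- tab$expected
  pos <- E > 0
  if (any(O[!pos] > 0))
    stop("observed count in a zero-expectation cell: Mendelian inconsistency upstream")
  S <- sum((O[pos] - E[pos])^2 / E[pos])
  structure(list(statistic = S, n_pair = tab$n_pair,
                 n_nonzero_cells = sum(pos)),
            class = "imbalance_score")
}

#' @export
print.imbalance_score <- function(x, ...) {
  cat(sprintf("pair imbalance statistic S = %.4f (%d trios, %d informative cells)\n",
              x$statistic, x$n_pair, x$n_nonzero_cells))
  invisible(x)
}

#' @export
print.joint_table <- function(x, ...) {
  cat(sprintf("joint genotype table for (%s, %s), %d trios\nobserved:\n",
              x$marker_a, x$marker_b, x$n_pair))
  print(x$observed)
  cat("expected:\n")
  print(round(x$expected, 3))
  invisible(x)
}
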