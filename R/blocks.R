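# LD-block partition and representative choice for the screening step.

#' Pairwise composite LD (r-squared) between two markers
#'
#' Squared Pearson correlation of the dosage vectors over individuals
#' non-missing at both markers. Phase is not assumed known, so this is the
#' composite (genotypic) LD measure.
#'
#' @param gm a [genotype_matrix()] object.
#' @param i,j marker indices or ids.
#' @param individuals optional subset of individual row indices over which to
#'   compute the correlation (e.g. parents only).
#' @return r-squared in \[0, 1\]; 0 with a warning when either marker has zero
#'   variance over the jointly called individuals.
#' @export
pairwise_r2 <- function(gm, i, j, individuals = NULL) {
  if (is.character(i)) i <- match(i, gm$markers$marker_id)
  if (is.character(j)) j <- match(j, gm$markers$marker_id)
  g <- gm$genotypes
  if (!is.null(individuals)) g <- g[individuals, , drop = FALSE]
  x <- g[, i]; y <- g[, j]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) {
    warning("fewer than 2 jointly called individuals; r2 undefined, returning 0")
    return(0)
  }
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero genotype variance; r2 undefined, returning 0")
    return(0)
  }
  stats::cor(x, y)^2
}

#' Partition each chromosome into LD blocks
#'
#' Greedy left-to-right chaining along the physical marker order: the current
#' block is extended while the adjacent-marker r-squared is at least
#' `r2_threshold`, otherwise a new block starts. Singleton blocks are allowed.
#' By default the correlation is computed on parental genotypes only (children
#' are correlated with their parents and would inflate LD estimates).
#'
#' @param gm a [genotype_matrix()] object (markers sorted by position).
#' @param r2_threshold adjacent-marker r-squared needed to stay in one block
#'   (default 0.8).
#' @param individuals optional row indices over which to compute r-squared;
#'   typically `parent_indices(trios)`. `NULL` uses everyone.
#' @return Object of class `"ld_blocks"`: data.frame with one row per block:
#'   `block_id`, `chromosome`, `start`, `end` (marker column indices into
#'   `gm`), `n_markers`, and `representative` (`NA` until
#'   [choose_representatives()] is applied).
#' @export
partition_ld_blocks <- function(gm, r2_threshold = 0.8, individuals = NULL) {
  mk <- gm$markers
  blocks <- list()
  for (chr in unique(mk$chromosome)) {
    idx <- which(mk$chromosome == chr)
    start <- idx[1]
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        r2 <- suppressWarnings(
          pairwise_r2(gm, idx[k], idx[k + 1], individuals))
        if (r2 < r2_threshold) {
          blocks[[length(blocks) + 1]] <- c(start, idx[k])
          start <- idx[k + 1]
        }
      }
    }
    blocks[[length(blocks) + 1]] <- c(start, idx[length(idx)])
  }
  out <- data.frame(block_id = paste0("B", seq_along(blocks)),
                    chromosome = mk$chromosome[vapply(blocks, `[`, 0L, 1)],
                    start = vapply(blocks, `[`, 0L, 1),
                    end = vapply(blocks, `[`, 0L, 2),
                    stringsAsFactors = FALSE)
  out$n_markers <- out$end - out$start + 1L
  out$representative <- NA_integer_
  class(out) <- c("ld_blocks", "data.frame")
  out
}

#' Choose one representative marker per LD block
#'
#' Within each block, the candidates are the markers attaining the block's
#' minimum number of missing calls; one is drawn uniformly at random.
#'
#' @param blocks a [partition_ld_blocks()] result.
#' @param gm the same [genotype_matrix()] object.
#' @param seed integer seed for the random choice.
#' @return `blocks` with the `representative` column filled (marker column
#'   indices into `gm`).
#' @export
choose_representatives <- function(blocks, gm, seed = 1) {
  miss <- colSums(is.na(gm$genotypes))
  .with_seed(seed, {
    for (r in seq_len(nrow(blocks))) {
      cand <- blocks$start[r]:blocks$end[r]
      cand <- cand[miss[cand] == min(miss[cand])]
      blocks$representative[r] <-
        if (length(cand) == 1) cand else sample(cand, 1)
    }
  })
  blocks
}

#' Row indices of individuals acting as parents in a trio set
#'
#' @param trios the [extract_trios()] result.
#' @return Sorted unique integer row indices.
#' @export
parent_indices <- function(trios) {
  sort(unique(c(trios$trios$father, trios$trios$mother)))
}
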