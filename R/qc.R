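# Quality-control filters applied before any pair testing.

#' Remove individuals with excess missingness
#'
#' @param gm a [genotype_matrix()] object.
#' @param max_missing maximum tolerated fraction of missing calls per
#'   individual; individuals strictly above it are dropped. Default 0.10.
#' @return Filtered `geno_matrix` (marker set unchanged).
#' @export
filter_individuals <- function(gm, max_missing = 0.10) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- rowMeans(is.na(gm$genotypes))
  keep <- frac <= max_missing
  if (!all(keep))
    message(sprintf("filter_individuals: removed %d of %d individuals (> %.0f%% missing)",
                    sum(!keep), length(keep), 100 * max_missing))
  subset_genotypes(gm, individuals = keep)
}

#' Remove markers with excess missingness, low MAF, or excluded chromosomes
#'
#' A marker survives when its missing-call fraction is at most `max_missing`,
#' its minor allele frequency (computed over non-missing calls) is at least
#' `min_maf`, and its chromosome is not excluded. No Hardy-Weinberg filter is
#' applied: departure from Hardy-Weinberg equilibrium is handled downstream by
#' the per-marker segregation-distortion correction, not by discarding markers.
#'
#' @param gm a [genotype_matrix()] object.
#' @param max_missing maximum missing fraction per marker (default 0.10).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @param exclude_chromosomes character vector of chromosomes to drop wholesale
#'   (e.g. `"X"` when its genotype quality is poor).
#' @return Filtered `geno_matrix` (individual set unchanged).
#' @export
filter_markers <- function(gm, max_missing = 0.10, min_maf = 0.05,
                           exclude_chromosomes = character()) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  frac <- colMeans(is.na(gm$genotypes))
  maf <- marker_maf(gm)
  maf[is.nan(maf)] <- 0
  keep <- frac <= max_missing & maf >= min_maf &
    !(gm$markers$chromosome %in% exclude_chromosomes)
  if (!all(keep))
    message(sprintf("filter_markers: removed %d of %d markers", sum(!keep),
                    length(keep)))
  subset_genotypes(gm, markers = keep)
}
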