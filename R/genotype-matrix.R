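#' Genotype matrix container
#'
#' Construct the package's central genotype container: an individuals x markers
#' integer matrix of minor-allele dosages (0 = homozygous major, 1 =
#' heterozygous, 2 = homozygous minor, `NA` = missing call) together with the
#' marker metadata.
#'
#' @param genotypes integer matrix, individuals in rows, markers in columns.
#'   Entries must be 0, 1, 2 or `NA`.
#' @param individual_ids character vector of unique individual identifiers,
#'   one per row. Defaults to the rownames of `genotypes`.
#' @param markers data.frame with one row per marker and columns `marker_id`,
#'   `chromosome`, `position` and optionally `allele_major`, `allele_minor`.
#'   Markers must be sorted by (chromosome, position); `genotype_matrix()`
#'   reorders both the metadata and the genotype columns if they are not.
#'
#' @return An object of class `"geno_matrix"`: a list with elements
#'   `genotypes`, `individual_ids` and `markers`.
#' @export
genotype_matrix <- function(genotypes, individual_ids = rownames(genotypes),
                            markers) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(individual_ids))
    individual_ids <- paste0("ind", seq_len(nrow(genotypes)))
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique")
  if (length(individual_ids) != nrow(genotypes))
    stop("length(individual_ids) != nrow(genotypes)")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  req <- c("marker_id", "chromosome", "position")
  if (!all(req %in% names(markers)))
    stop("markers must have columns: ", paste(req, collapse = ", "))
  if (nrow(markers) != ncol(genotypes))
    stop("nrow(markers) != ncol(genotypes)")
  if (!"allele_major" %in% names(markers)) markers$allele_major <- NA_character_
  if (!"allele_minor" %in% names(markers)) markers$allele_minor <- NA_character_
  markers$marker_id <- as.character(markers$marker_id)
  markers$chromosome <- as.character(markers$chromosome)
  markers$position <- as.integer(markers$position)
  if (any(markers$position < 0, na.rm = TRUE)) stop("negative marker position")
  if (anyDuplicated(markers$marker_id)) stop("marker ids must be unique")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  ord <- order(markers$chromosome, markers$position)
  if (!identical(ord, seq_len(nrow(markers)))) {
    markers <- markers[ord, , drop = FALSE]
    genotypes <- genotypes[, ord, drop = FALSE]
  }
  rownames(markers) <- NULL
  dimnames(genotypes) <- list(individual_ids, markers$marker_id)
  structure(list(genotypes = genotypes, individual_ids = individual_ids,
                 markers = markers),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  g <- x$genotypes
  cat(sprintf("geno_matrix: %d individuals x %d markers on %d chromosome(s)\n",
              nrow(g), ncol(g), length(unique(x$markers$chromosome))))
  miss <- mean(is.na(g))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$genotypes)

#' @rdname genotype_matrix
#' @param gm a `geno_matrix` object.
#' @export
n_individuals <- function(gm) nrow(gm$genotypes)

#' @rdname genotype_matrix
#' @export
n_markers <- function(gm) ncol(gm$genotypes)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()] object.
#' @param individuals,markers integer or logical index vectors (individuals by
#'   row, markers by column); `NULL` keeps everything.
#' @return A `geno_matrix` restricted to the selected rows/columns.
#' @export
subset_genotypes <- function(gm, individuals = NULL, markers = NULL) {
  if (is.null(individuals)) individuals <- seq_len(n_individuals(gm))
  if (is.null(markers)) markers <- seq_len(n_markers(gm))
  genotype_matrix(gm$genotypes[individuals, markers, drop = FALSE],
                  gm$individual_ids[individuals],
                  gm$markers[markers, , drop = FALSE])
}

#' Minor allele frequency per marker
#'
#' Frequency of the coded (dosage-counted) allele computed over non-missing
#' calls only, folded so the reported value is always the rarer allele's
#' frequency (`min(p, 1 - p)`).
#'
#' @param gm a [genotype_matrix()] object.
#' @param fold if `FALSE`, return the raw coded-allele frequency instead of
#'   folding at 0.5.
#' @return Numeric vector of length `n_markers(gm)`; `NaN` for markers with no
#'   non-missing calls.
#' @export
marker_maf <- function(gm, fold = TRUE) {
  g <- gm$genotypes
  n_called <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_called)
  if (fold) pmin(p, 1 - p) else p
}
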