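# Trio extraction and per-marker usability masks.

#' Extract genotyped parent-offspring trios
#'
#' A trio is a genotyped child whose father and mother are both present in the
#' genotype matrix. The per-marker usability mask is `TRUE` exactly where the
#' child and both parents have non-missing calls and the child's genotype is
#' Mendelian-consistent with the parents'; Mendelian-inconsistent calls
#' (almost certainly genotyping errors) are masked for that trio at that
#' marker only, so a single bad call can never force an expected probability
#' of zero onto an observed genotype.
#'
#' @param gm a [genotype_matrix()] object.
#' @param ped pedigree data.frame (`individual_id`, `father_id`, `mother_id`);
#'   rows whose ids cannot be resolved against `gm` are skipped with a warning.
#' @return An object of class `"trio_set"`: list with `trios` (data.frame of
#'   `child`, `father`, `mother` row indices into `gm` plus the three ids) and
#'   `usable` (trios x markers logical matrix).
#' @export
extract_trios <- function(gm, ped) {
  idx <- function(ids) match(ids, gm$individual_ids)
  ci <- idx(ped$individual_id); fi <- idx(ped$father_id); mi <- idx(ped$mother_id)
  listed <- !is.na(ped$father_id) & !is.na(ped$mother_id)
  unresolved <- listed & (is.na(ci) | is.na(fi) | is.na(mi))
  if (any(unresolved))
    warning(sprintf("extract_trios: skipped %d pedigree rows with ungenotyped members",
                    sum(unresolved)))
  keep <- listed & !unresolved
  if (!any(keep)) stop("no usable trios: no genotyped child has two genotyped parents")
  trios <- data.frame(child = ci[keep], father = fi[keep], mother = mi[keep],
                      child_id = ped$individual_id[keep],
                      father_id = ped$father_id[keep],
                      mother_id = ped$mother_id[keep],
                      stringsAsFactors = FALSE)
  g <- gm$genotypes
  gc_ <- g[trios$child, , drop = FALSE]
  gf <- g[trios$father, , drop = FALSE]
  gmo <- g[trios$mother, , drop = FALSE]
  usable <- !is.na(gc_) & !is.na(gf) & !is.na(gmo)
  consistent <- mendelian_consistent(gc_, gf, gmo)
  n_incons <- sum(usable & !consistent, na.rm = TRUE)
  if (n_incons > 0)
    message(sprintf("extract_trios: masked %d Mendelian-inconsistent trio-marker calls",
                    n_incons))
  usable <- usable & !is.na(consistent) & consistent
  if (!any(usable)) stop("no usable trios: all trio-marker calls are missing or inconsistent")
  structure(list(trios = trios, usable = usable), class = "trio_set")
}

#' @export
print.trio_set <- function(x, ...) {
  cat(sprintf("trio_set: %d trios x %d markers; %.1f%% trio-marker calls usable\n",
              nrow(x$trios), ncol(x$usable), 100 * mean(x$usable)))
  invisible(x)
}

#' Number of trios in a trio set
#'
#' @param trios a [extract_trios()] result.
#' @export
n_trios <- function(trios) nrow(trios$trios)

#' Mendelian consistency of child genotypes given parental genotypes
#'
#' A child dosage `c` is consistent with parental dosages `(f, m)` when it can
#' be written as the sum of one allele transmissible by each parent
#' (homozygotes transmit their only allele, heterozygotes either).
#'
#' @param child,father,mother integer dosages (vectors/matrices of equal
#'   shape, values 0/1/2 or `NA`).
#' @return Logical of the same shape; `NA` where any input is `NA`.
#' @export
mendelian_consistent <- function(child, father, mother) {
  lo <- (father == 2) + (mother == 2)        # minimum minor alleles a child can get
  hi <- (father >= 1) + (mother >= 1)        # maximum
  child >= lo & child <= hi
}
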