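# Congruence of interaction profiles: do two loci share more interaction
# partners than expected by chance? Loci bridging the same pair of redundant
# pathways should, which makes profile congruence a pathway-level signal on
# top of the individual pair calls.

#' Build interaction profiles from pair calls
#'
#' Converts a table of interaction calls into one partner set per locus
#' (symmetric adjacency: a call (a, b) puts b into a's profile and a into
#' b's). Loci are blocks or markers depending on the call level.
#'
#' @param calls data.frame with columns naming the two loci (defaults
#'   `block_a`/`block_b`, falling back to `marker_a`/`marker_b`) and a `p`
#'   column.
#' @param p_cutoff calls with `p` at or below this define an interaction
#'   (typically less stringent than the pair-level significance cutoff, since
#'   whole profiles are compared).
#' @param universe character vector of all tested loci (needed even when they
#'   have no partners); defaults to the loci appearing in `calls`.
#' @return Object of class `"interaction_profiles"`: named list of character
#'   partner sets, with the universe as an attribute.
#' @export
build_profiles <- function(calls, p_cutoff = 0.05, universe = NULL) {
  nm <- if ("block_a" %in% names(calls) &&
            !all(is.na(calls$block_a))) c("block_a", "block_b")
        else c("marker_a", "marker_b")
  la <- as.character(calls[[nm[1]]]); lb <- as.character(calls[[nm[2]]])
  if (is.null(universe)) universe <- sort(unique(c(la, lb)))
  universe <- as.character(universe)
  hit <- !is.na(calls$p) & calls$p <= p_cutoff
  profiles <- stats::setNames(
    lapply(universe, function(x) character(0)), universe)
  for (i in which(hit)) {
    a <- la[i]; b <- lb[i]
    if (a == b) next
    profiles[[a]] <- union(profiles[[a]], b)
    profiles[[b]] <- union(profiles[[b]], a)
  }
  structure(profiles, universe = universe, class = "interaction_profiles")
}

#' Congruence score of two loci
#'
#' Hypergeometric upper-tail test for the overlap of two loci's interaction
#' partner sets, reported as `-log10(p)`. The two focal loci (and any direct
#' interaction between them) are removed from the universe and from each
#' other's partner sets first, so a shared direct edge cannot inflate the
#' congruence of its own endpoints.
#'
#' @param profiles an [build_profiles()] result.
#' @param a,b locus ids.
#' @return Object of class `"congruence_score"`: list with `loci`,
#'   `n_partners_a`, `n_partners_b`, `shared`, `p_value`, `score`.
#' @export
congruence_score <- function(profiles, a, b) {
  universe <- attr(profiles, "universe")
  if (length(universe) == 0) stop("empty locus universe")
  stopifnot(a %in% universe, b %in% universe, a != b)
  pa <- setdiff(profiles[[a]], c(a, b))
  pb <- setdiff(profiles[[b]], c(a, b))
  N <- length(setdiff(universe, c(a, b)))
  shared <- length(intersect(pa, pb))
  # P(X >= shared), X ~ Hypergeom(draws |pa| from N with |pb| successes)
  p <- stats::phyper(shared - 1, length(pb), N - length(pb), length(pa),
                     lower.tail = FALSE)
  structure(list(loci = c(a, b), n_partners_a = length(pa),
                 n_partners_b = length(pb), shared = shared,
                 p_value = p, score = -log10(p)),
            class = "congruence_score")
}

#' @export
print.congruence_score <- function(x, ...) {
  cat(sprintf("congruence(%s, %s): %d shared of (%d, %d) partners, score = %.3f\n",
              x$loci[1], x$loci[2], x$shared, x$n_partners_a, x$n_partners_b,
              x$score))
  invisible(x)
}

#' Congruence scores for all locus pairs
#'
#' @param profiles an [build_profiles()] result.
#' @param min_partners only score pairs where both loci have at least this
#'   many partners (default 1; loci without interactions carry no profile
#'   information).
#' @return data.frame with `locus_a`, `locus_b`, `n_partners_a`,
#'   `n_partners_b`, `shared`, `score`, sorted by decreasing score.
#' @export
congruence_all <- function(profiles, min_partners = 1) {
  universe <- attr(profiles, "universe")
  sizes <- lengths(profiles)
  loci <- universe[sizes[universe] >= min_partners]
  if (length(loci) < 2)
    return(data.frame(locus_a = character(), locus_b = character(),
                      n_partners_a = integer(), n_partners_b = integer(),
                      shared = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  idx <- utils::combn(length(loci), 2)
  rows <- lapply(seq_len(ncol(idx)), function(i) {
    cs <- congruence_score(profiles, loci[idx[1, i]], loci[idx[2, i]])
    data.frame(locus_a = cs$loci[1], locus_b = cs$loci[2],
               n_partners_a = cs$n_partners_a, n_partners_b = cs$n_partners_b,
               shared = cs$shared, score = cs$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score), , drop = FALSE]
}
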