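# The two-step genome scan: block-representative screening, then marker-level
# fine mapping inside significant block pairs.

#' Genome-wide screen for two-locus allele-pair imbalances
#'
#' The main fitting function of the package. Partitions each chromosome into
#' LD blocks, picks one representative marker per block, and tests every pair
#' of representatives on different chromosomes: the pair imbalance statistic
#' S is computed from the 3x3 observed vs expected joint genotype table of
#' the trio offspring (expected under Mendelian transmission, corrected
#' per-marker for segregation distortion), and its significance is assessed
#' against a pair-specific pseudo-control permutation null. Benjamini-Hochberg
#' q-values are computed across all screened pairs.
#'
#' Restricting to different chromosomes rules out false positives from local
#' linkage disequilibrium; the block/representative reduction keeps the number
#' of permutation tests manageable.
#'
#' @param gm a [genotype_matrix()] object (after QC).
#' @param pedigree pedigree data.frame (see [read_pedigree()]); ignored when
#'   `trios` is supplied.
#' @param trios optionally a pre-built [extract_trios()] result.
#' @param B permutations per pair (default 1000).
#' @param r2_threshold adjacent-marker r-squared defining LD blocks.
#' @param fdr_cutoff block pairs with q-value at or below this are flagged
#'   significant (default 0.25; screening is deliberately permissive, the
#'   marker-level fine map sharpens the calls).
#' @param min_trios minimum pair-usable trios per pair.
#' @param max_pairs optional cap on the number of representative pairs tested;
#'   when set, a simple random subsample of the inter-chromosomal pairs is
#'   drawn (seeded). Useful for calibration studies.
#' @param seed global seed; all randomness (representative choice, pair
#'   subsampling, per-pair permutation streams) derives from it.
#' @param smooth add-one smoothing of permutation p-values (default `TRUE`).
#' @return Object of class `"trio_scan"`: list with `calls` (data.frame:
#'   `level`, `block_a`, `block_b`, `marker_a`, `marker_b`, `chrom_a`,
#'   `chrom_b`, `n_pair`, `S`, `p`, `q`, `significant`), `blocks`, `trios`,
#'   `config` and `skipped` (count of skipped pairs).
#' @export
trio_scan <- function(gm, pedigree = NULL, trios = NULL, B = 1000,
                      r2_threshold = 0.8, fdr_cutoff = 0.25, min_trios = 20,
                      max_pairs = NULL, seed = 1, smooth = TRUE) {
  if (is.null(trios)) {
    if (is.null(pedigree)) stop("supply either a pedigree or a trio_set")
    trios <- extract_trios(gm, pedigree)
  }
  blocks <- partition_ld_blocks(gm, r2_threshold,
                                individuals = parent_indices(trios))
  blocks <- choose_representatives(blocks, gm, seed = seed)
  reps <- blocks$representative
  chrom <- blocks$chromosome
  if (length(unique(chrom)) < 2) {
    warning("single chromosome in input: no inter-chromosomal pairs to test")
    empty <- empty_calls()
    return(new_trio_scan(empty, blocks, trios, gm, B, fdr_cutoff, seed,
                         skipped = 0L))
  }
  bp <- utils::combn(length(reps), 2)
  keep <- chrom[bp[1, ]] != chrom[bp[2, ]]
  bp <- bp[, keep, drop = FALSE]
  if (!is.null(max_pairs) && ncol(bp) > max_pairs) {
    sel <- .with_seed(.pair_seed(seed, "subsample", "pairs"),
                      sample(ncol(bp), max_pairs))
    bp <- bp[, sort(sel), drop = FALSE]
  }
  cache <- .marker_cache(gm, trios)
  mk <- gm$markers
  n <- ncol(bp)
  rows <- vector("list", n)
  skipped <- 0L
  for (i in seq_len(n)) {
    ba <- bp[1, i]; bb <- bp[2, i]
    a <- reps[ba]; b <- reps[bb]
    ca <- cache[[a]]; cb <- cache[[b]]
    px <- .pair_index(ca, cb)
    if (px$n < min_trios) {
      skipped <- skipped + 1L
      next
    }
    pseed <- .pair_seed(seed, mk$marker_id[a], mk$marker_id[b])
    res <- .with_seed(pseed, .pair_perm(ca, cb, px$ia, px$ib, B))
    k <- sum(res$null_S >= res$observed_S)
    p <- if (smooth) (1 + k) / (1 + B) else k / B
    rows[[i]] <- data.frame(level = "block",
                            block_a = blocks$block_id[ba],
                            block_b = blocks$block_id[bb],
                            marker_a = mk$marker_id[a],
                            marker_b = mk$marker_id[b],
                            chrom_a = mk$chromosome[a],
                            chrom_b = mk$chromosome[b],
                            n_pair = px$n, S = res$observed_S, p = p,
                            stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(calls)) calls <- empty_calls()
  if (nrow(calls)) {
    calls$q <- bh_fdr(calls$p)
    calls$significant <- calls$q <= fdr_cutoff
  }
  if (skipped > 0)
    message(sprintf("trio_scan: skipped %d pairs with < %d usable trios",
                    skipped, min_trios))
  new_trio_scan(calls, blocks, trios, gm, B, fdr_cutoff, seed, skipped)
}

empty_calls <- function() {
  data.frame(level = character(), block_a = character(), block_b = character(),
             marker_a = character(), marker_b = character(),
             chrom_a = character(), chrom_b = character(),
             n_pair = integer(), S = numeric(), p = numeric(), q = numeric(),
             significant = logical(), stringsAsFactors = FALSE)
}

new_trio_scan <- function(calls, blocks, trios, gm, B, fdr_cutoff, seed,
                          skipped) {
  structure(list(calls = calls, blocks = blocks, trios = trios,
                 config = list(B = B, fdr_cutoff = fdr_cutoff, seed = seed,
                               n_markers = n_markers(gm),
                               n_trios = n_trios(trios)),
                 skipped = skipped),
            class = "trio_scan")
}

#' @export
print.trio_scan <- function(x, ...) {
  cat(sprintf("trio_scan: %d block pairs tested (B = %d permutations, seed %s)\n",
              nrow(x$calls), x$config$B, format(x$config$seed)))
  if (nrow(x$calls))
    cat(sprintf("  significant at FDR <= %.2f: %d\n", x$config$fdr_cutoff,
                sum(x$calls$significant)))
  invisible(x)
}

#' @export
summary.trio_scan <- function(object, ...) {
  calls <- object$calls
  cat(sprintf("Two-locus imbalance screen over %d LD blocks (%d markers, %d trios)\n",
              nrow(object$blocks), object$config$n_markers,
              object$config$n_trios))
  cat(sprintf("Tested %d inter-chromosomal block pairs, B = %d permutations\n",
              nrow(calls), object$config$B))
  if (nrow(calls)) {
    cat(sprintf("p-value range: [%.4g, %.4g]; %d significant at FDR <= %.2f\n",
                min(calls$p), max(calls$p), sum(calls$significant),
                object$config$fdr_cutoff))
    top <- calls[order(calls$p, -calls$S), ][
      seq_len(min(5, nrow(calls))),
      c("marker_a", "marker_b", "n_pair", "S", "p", "q")]
    cat("Top pairs:\n")
    print(top, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Plot a trio_scan
#'
#' Simple diagnostic: -log10 permutation p-values of all screened block pairs
#' in test order, with the significance calls highlighted.
#'
#' @param x a [trio_scan()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trio_scan <- function(x, ...) {
  calls <- x$calls
  if (!nrow(calls)) {
    warning("nothing to plot: no tested pairs")
    return(invisible(x))
  }
  y <- -log10(calls$p)
  graphics::plot(seq_along(y), y, pch = 16, cex = 0.5,
                 col = ifelse(calls$significant, "firebrick", "grey40"),
                 xlab = "block pair index", ylab = expression(-log[10](p)),
                 main = "Two-locus imbalance screen", ...)
  graphics::abline(h = -log10(0.05), lty = 2, col = "grey60")
  invisible(x)
}

#' Marker-level fine mapping within significant block pairs
#'
#' For every significant block pair from a screen, tests all cross-block
#' marker pairs (statistic + pair-specific permutation p-value) and reports,
#' per block pair, the minimum-p marker pair as the putatively interacting
#' pair. Marker-level p-values are ranking scores: the tested pairs were
#' selected for showing a signal and markers within a block are correlated,
#' so no multiplicity correction is attached to them.
#'
#' @param scan a [trio_scan()] result.
#' @param gm the same [genotype_matrix()] the scan was run on.
#' @param B permutations per marker pair (default: the scan's `B`).
#' @param p_cutoff marker pairs with p-value at or below this are retained in
#'   the full table (default 0.001); the per-block-pair top pair is always
#'   reported.
#' @param seed global seed (default: the scan's seed).
#' @return Object of class `"fine_map"`: list with `calls` (marker-level
#'   data.frame: adds `top_pair` flag and parent `block_a`/`block_b`) and
#'   `config`.
#' @export
fine_map <- function(scan, gm, B = NULL, p_cutoff = 0.001, seed = NULL) {
  stopifnot(inherits(scan, "trio_scan"))
  if (is.null(B)) B <- scan$config$B
  if (is.null(seed)) seed <- scan$config$seed
  sig <- scan$calls[scan$calls$significant, , drop = FALSE]
  out <- list(calls = empty_fine_calls(),
              config = list(B = B, p_cutoff = p_cutoff, seed = seed))
  class(out) <- "fine_map"
  if (!nrow(sig)) return(out)
  blocks <- scan$blocks
  trios <- scan$trios
  cache <- .marker_cache(gm, trios)
  mk <- gm$markers
  rows <- list()
  for (r in seq_len(nrow(sig))) {
    ba <- which(blocks$block_id == sig$block_a[r])
    bb <- which(blocks$block_id == sig$block_b[r])
    ma <- blocks$start[ba]:blocks$end[ba]
    mb <- blocks$start[bb]:blocks$end[bb]
    best <- NULL
    for (a in ma) for (b in mb) {
      ca <- cache[[a]]; cb <- cache[[b]]
      px <- .pair_index(ca, cb)
      if (px$n < 1) next
      pseed <- .pair_seed(seed, mk$marker_id[a], mk$marker_id[b])
      res <- .with_seed(pseed, .pair_perm(ca, cb, px$ia, px$ib, B))
      p <- (1 + sum(res$null_S >= res$observed_S)) / (1 + B)
      row <- data.frame(level = "marker",
                        block_a = sig$block_a[r], block_b = sig$block_b[r],
                        marker_a = mk$marker_id[a], marker_b = mk$marker_id[b],
                        chrom_a = mk$chromosome[a], chrom_b = mk$chromosome[b],
                        n_pair = px$n, S = res$observed_S, p = p,
                        top_pair = FALSE, stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- row
      if (is.null(best) || p < best$p || (p == best$p && row$S > best$S))
        best <- row
    }
    if (!is.null(best)) {
      # flag the per-block-pair winner
      for (i in seq_along(rows))
        if (rows[[i]]$marker_a == best$marker_a &&
            rows[[i]]$marker_b == best$marker_b &&
            rows[[i]]$block_a == best$block_a &&
            rows[[i]]$block_b == best$block_b)
          rows[[i]]$top_pair <- TRUE
    }
  }
  calls <- do.call(rbind, rows)
  if (!is.null(calls)) {
    calls <- calls[calls$top_pair | calls$p <= p_cutoff, , drop = FALSE]
    rownames(calls) <- NULL
    out$calls <- calls
  }
  out
}

empty_fine_calls <- function() {
  data.frame(level = character(), block_a = character(), block_b = character(),
             marker_a = character(), marker_b = character(),
             chrom_a = character(), chrom_b = character(),
             n_pair = integer(), S = numeric(), p = numeric(),
             top_pair = logical(), stringsAsFactors = FALSE)
}

#' @export
print.fine_map <- function(x, ...) {
  cat(sprintf("fine_map: %d marker-level calls (%d block-pair top pairs)\n",
              nrow(x$calls), sum(x$calls$top_pair)))
  invisible(x)
}

#' Write interaction calls as a TSV table
#'
#' Writes the calls of a screen or fine map with a commented header recording
#' the seed and permutation count, so a run can be traced back to its
#' configuration.
#'
#' @param x a `trio_scan` or `fine_map` object.
#' @param path output path.
#' @export
write_calls <- function(x, path) {
  cfg <- x$config
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trioscan calls: seed=%s B=%d", format(cfg$seed),
                     cfg$B), con)
  utils::write.table(x$calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
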