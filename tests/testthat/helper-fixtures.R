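# Programmatic fixtures: all test data is built in code.

# Genotype matrix from a bare matrix, markers split across two chromosomes
# unless a chromosome vector is given.
make_gm <- function(mat, chrom = NULL, ids = NULL) {
  m <- ncol(mat)
  if (is.null(chrom))
    chrom <- as.character(rep(1:2, c(ceiling(m / 2), floor(m / 2))))
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(nrow(mat)))
  genotype_matrix(mat, ids,
                  data.frame(marker_id = sprintf("m%02d", seq_len(m)),
                             chromosome = chrom,
                             position = as.integer(ave(seq_len(m), chrom,
                                                       FUN = seq_along) * 1000),
                             allele_major = "A", allele_minor = "G",
                             stringsAsFactors = FALSE))
}

# Random trio fixture: n_trios independent trios, random parents, children
# drawn from the Mendelian distribution, optional missingness. Returns
# list(gm, ped, trios).
rand_trio_fixture <- function(n_trios = 5, n_markers = 4, miss_rate = 0,
                              seed = 1) {
  set.seed(seed)
  n_ind <- 3 * n_trios
  g <- matrix(NA_integer_, n_ind, n_markers)
  ids <- sprintf("i%02d", seq_len(n_ind))
  ped <- data.frame(individual_id = ids, father_id = NA_character_,
                    mother_id = NA_character_, stringsAsFactors = FALSE)
  for (t in seq_len(n_trios)) {
    fa <- 3 * t - 2; mo <- 3 * t - 1; ch <- 3 * t
    for (m in seq_len(n_markers)) {
      g[fa, m] <- sample(0:2, 1)
      g[mo, m] <- sample(0:2, 1)
      g[ch, m] <- sample(0:2, 1, prob = oracle_mendel(g[fa, m], g[mo, m]))
    }
    ped$father_id[ch] <- ids[fa]
    ped$mother_id[ch] <- ids[mo]
  }
  if (miss_rate > 0)
    g[runif(length(g)) < miss_rate] <- NA_integer_
  chrom <- as.character(rep(1:2, c(ceiling(n_markers / 2),
                                   floor(n_markers / 2))))
  gm <- make_gm(g, chrom = chrom, ids = ids)
  trios <- suppressMessages(extract_trios(gm, ped))
  list(gm = gm, ped = ped, trios = trios)
}

# Small simulated population shared by several test files (computed once).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_trio_dataset(seed = 2024, n_founders = 16,
                                 n_per_gen = c(40, 40), n_chrom = 3,
                                 n_markers = 8)
    cache
  }
})
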