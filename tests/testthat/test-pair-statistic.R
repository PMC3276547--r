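# Mendelian expectations, distortion correction, joint tables, statistic.

test_that("Mendelian offspring probabilities match the transmission law for all parent pairs", {
  # printed reference values for the six unordered combinations
  expect_equal(mendelian_offspring_probs(0, 0), c(1, 0, 0))
  expect_equal(mendelian_offspring_probs(0, 1), c(0.5, 0.5, 0))
  expect_equal(mendelian_offspring_probs(0, 2), c(0, 1, 0))
  expect_equal(mendelian_offspring_probs(1, 1), c(0.25, 0.5, 0.25))
  expect_equal(mendelian_offspring_probs(1, 2), c(0, 0.5, 0.5))
  expect_equal(mendelian_offspring_probs(2, 2), c(0, 0, 1))
  # symmetry and closed-form agreement over all 9 ordered pairs
  for (f in 0:2) for (m in 0:2) {
    expect_equal(mendelian_offspring_probs(f, m),
                 mendelian_offspring_probs(m, f))
    expect_equal(mendelian_offspring_probs(f, m), oracle_mendel(f, m))
  }
  expect_error(mendelian_offspring_probs(NA, 1), "missing")
})

test_that("expected field holds Mendelian 3-vectors exactly where usable", {
  fx <- rand_trio_fixture(n_trios = 6, n_markers = 4, miss_rate = 0.3,
                          seed = 21)
  fld <- expected_field(fx$gm, fx$trios)
  g <- fx$gm$genotypes
  tt <- fx$trios$trios
  for (t in seq_len(nrow(tt))) for (m in 1:4) {
    if (fx$trios$usable[t, m]) {
      expect_equal(fld$probs[t, m, ],
                   oracle_mendel(g[tt$father[t], m], g[tt$mother[t], m]))
      expect_equal(sum(fld$probs[t, m, ]), 1)
    } else {
      expect_true(all(is.na(fld$probs[t, m, ])))
    }
  }
})

# 10 het x het trios at one marker with children split 5/3/2 give the
# worked correction-factor example: observed (5,3,2) vs expected (2.5,5,2.5).
hetx10 <- function() {
  g <- matrix(1L, 30, 1)
  children <- rep(c(0L, 1L, 2L), c(5, 3, 2))
  g[seq(3, 30, by = 3), 1] <- children
  ids <- sprintf("i%02d", 1:30)
  ped <- data.frame(individual_id = ids, father_id = NA_character_,
                    mother_id = NA_character_, stringsAsFactors = FALSE)
  ped$father_id[seq(3, 30, 3)] <- ids[seq(1, 28, 3)]
  ped$mother_id[seq(3, 30, 3)] <- ids[seq(2, 29, 3)]
  gm <- genotype_matrix(g, ids, data.frame(marker_id = "m1",
                                           chromosome = "1", position = 1L))
  list(gm = gm, trios = extract_trios(gm, ped))
}

test_that("correction factors are observed/expected ratios with 0/0 -> 1", {
  fx <- hetx10()
  fld <- expected_field(fx$gm, fx$trios)
  expect_equal(correction_factors(fx$gm, fx$trios, fld),
               matrix(c(2.0, 0.6, 0.8), 1))
  # undistorted data: every factor 1 (children drawn to match expectation)
  g <- matrix(c(0L, 2L, 1L), 3, 1)  # parents AA x aa -> child always Aa
  ped <- data.frame(individual_id = c("f", "m", "c"),
                    father_id = c(NA, NA, "f"), mother_id = c(NA, NA, "m"))
  gm <- genotype_matrix(g, c("f", "m", "c"),
                        data.frame(marker_id = "m1", chromosome = "1",
                                   position = 1L))
  tr <- extract_trios(gm, ped)
  expect_equal(correction_factors(gm, tr, expected_field(gm, tr)),
               matrix(c(1, 1, 1), 1))  # vacuous classes get factor 1
})

test_that("correction + renormalization follows the worked example", {
  fx <- hetx10()
  fld <- expected_field(fx$gm, fx$trios)
  # identity factors leave the field unchanged
  same <- correct_and_normalize(fld, matrix(1, 1, 3))
  expect_equal(same$probs, fld$probs)
  expect_equal(same$stage, "normalized")
  # (0.25, 0.5, 0.25) * (2, 0.6, 0.8) -> (0.5, 0.3, 0.2), sum already 1
  out <- correct_and_normalize(fld, matrix(c(2, 0.6, 0.8), 1))
  expect_equal(out$probs[1, 1, ], c(0.5, 0.3, 0.2))
  # degenerate certainty is preserved under any positive factor
  g <- matrix(c(0L, 0L, 0L), 3, 1)
  ped <- data.frame(individual_id = c("f", "m", "c"),
                    father_id = c(NA, NA, "f"), mother_id = c(NA, NA, "m"))
  gm <- genotype_matrix(g, c("f", "m", "c"),
                        data.frame(marker_id = "m1", chromosome = "1",
                                   position = 1L))
  tr <- extract_trios(gm, ped)
  out2 <- correct_and_normalize(expected_field(gm, tr),
                                matrix(c(7, 1, 1), 1))
  expect_equal(out2$probs[1, 1, ], c(1, 0, 0))
})

test_that("iterated correction reaches the observed-frequency fixed point", {
  # interior regime: all genotype classes well populated (at boundary fixed
  # points — a class matchable only by zeroing some trios' probabilities —
  # convergence is O(1/iter) and the residual stays above tolerance)
  for (seed in c(7, 8)) {
    fx <- rand_trio_fixture(n_trios = 150, n_markers = 4, miss_rate = 0.05,
                            seed = seed)
    fld <- normalized_expected(fx$gm, fx$trios)
    gch <- fx$gm$genotypes[fx$trios$trios$child, , drop = FALSE]
    for (k in 1:3) {
      obs <- colSums((gch == (k - 1)) & fx$trios$usable, na.rm = TRUE)
      expd <- colSums(fld$probs[, , k] * fx$trios$usable, na.rm = TRUE)
      expect_lt(max(abs(obs - expd)), 1e-6)
    }
  }
})

test_that("joint table counts observed pairs and multiplies marginals for expected", {
  # single trio, hand-built normalized field
  g <- matrix(c(0L, 0L, 0L,   1L, 1L, 1L), 3, 2)  # child (0, 1)
  gm <- make_gm(g, chrom = c("1", "2"))
  ped <- data.frame(individual_id = gm$individual_ids,
                    father_id = c(NA, NA, "i01"),
                    mother_id = c(NA, NA, "i02"))
  tr <- extract_trios(gm, ped)
  fld <- expected_field(gm, tr)
  fld$probs[1, 1, ] <- c(1, 0, 0)
  fld$probs[1, 2, ] <- c(0.5, 0.5, 0)
  fld$stage <- "normalized"
  tab <- joint_genotype_table(gm, tr, fld, c(1, 2), min_trios = 1)
  O <- matrix(0, 3, 3); O[1, 2] <- 1
  E <- matrix(0, 3, 3); E[1, ] <- c(0.5, 0.5, 0)
  expect_equal(unname(tab$observed), O)
  expect_equal(unname(tab$expected), E)
  expect_equal(tab$n_pair, 1)
})

test_that("tables conserve mass and match the brute-force oracle", {
  for (seed in 1:6) {
    fx <- rand_trio_fixture(n_trios = 5, n_markers = 4, miss_rate = 0.1,
                            seed = 100 + seed)
    fld <- normalized_expected(fx$gm, fx$trios, tol = 1e-15, max_iter = 1000)
    for (pair in list(c(1, 3), c(2, 4))) {
      tab <- joint_genotype_table(fx$gm, fx$trios, fld, pair, min_trios = 1)
      if (is.null(tab)) next
      # conservation
      expect_equal(sum(tab$observed), tab$n_pair)
      expect_lt(abs(sum(tab$expected) - tab$n_pair), 1e-6)
      # zero expectation forces zero observation
      expect_true(all(tab$observed[tab$expected == 0] == 0))
      # brute-force oracle equivalence
      ora <- oracle_joint(fx$gm, fx$trios, pair)
      expect_equal(unname(tab$observed), ora$observed)
      expect_lt(max(abs(tab$expected - ora$expected)), 1e-12)
      s <- imbalance_statistic(tab)
      expect_lt(abs(s$statistic - oracle_statistic(ora$observed,
                                                   ora$expected)), 1e-12)
    }
  }
})

test_that("the statistic is zero iff observed equals expected, and errors on impossible cells", {
  tab <- structure(list(observed = diag(c(2, 3, 1)),
                        expected = diag(c(2, 3, 1)), n_pair = 6,
                        marker_a = "a", marker_b = "b"),
                   class = "joint_table")
  expect_equal(imbalance_statistic(tab)$statistic, 0)
  # one discrepant pattern across two cells: O=(2,0) vs E=(1,1) -> S = 2
  tab$observed[1, 2] <- 2; tab$expected[1, 2] <- 1
  tab$observed[2, 1] <- 0; tab$expected[2, 1] <- 1
  expect_equal(imbalance_statistic(tab)$statistic, 2)
  tab$observed[3, 1] <- 1; tab$expected[3, 1] <- 0
  expect_error(imbalance_statistic(tab), "zero-expectation")
})

test_that("pair order only transposes the table and leaves S unchanged", {
  fx <- rand_trio_fixture(n_trios = 12, n_markers = 4, miss_rate = 0.1,
                          seed = 33)
  fld <- normalized_expected(fx$gm, fx$trios)
  ab <- joint_genotype_table(fx$gm, fx$trios, fld, c(1, 4), min_trios = 1)
  ba <- joint_genotype_table(fx$gm, fx$trios, fld, c(4, 1), min_trios = 1)
  expect_equal(ab$observed, t(ba$observed), ignore_attr = TRUE)
  expect_equal(ab$expected, t(ba$expected), ignore_attr = TRUE)
  expect_equal(imbalance_statistic(ab)$statistic,
               imbalance_statistic(ba)$statistic)
})

test_that("the fast scan kernel agrees with the modular pipeline", {
  d <- small_sim()
  g <- suppressMessages(filter_markers(d$geno, min_maf = 0.05))
  tr <- extract_trios(g, d$pedigree)
  fld <- normalized_expected(g, tr)
  aps <- all_pair_statistics(g, tr, min_trios = 5)
  idx <- seq(1, nrow(aps), length.out = min(8, nrow(aps)))
  for (i in round(idx)) {
    pair <- match(c(aps$marker_a[i], aps$marker_b[i]), g$markers$marker_id)
    tab <- joint_genotype_table(g, tr, fld, pair, min_trios = 5)
    expect_equal(aps$S[i], imbalance_statistic(tab)$statistic,
                 tolerance = 1e-6)
  }
})

test_that("under-powered pairs are skipped with a message", {
  fx <- rand_trio_fixture(n_trios = 5, n_markers = 4, seed = 2)
  fld <- normalized_expected(fx$gm, fx$trios)
  expect_message(
    out <- joint_genotype_table(fx$gm, fx$trios, fld, c(1, 3),
                                min_trios = 20),
    "skipped")
  expect_null(out)
})
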