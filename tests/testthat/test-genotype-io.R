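# Parsing, QC filtering and trio extraction.

write_ped_fixture <- function(dir) {
  # 4 individuals, 3 markers; marker m2 has minor allele G (freq 3/8)
  ped <- c("FAM i1 0 0 0 -9  A A  A G  C C",
           "FAM i2 0 0 0 -9  A A  A G  C T",
           "FAM i3 i1 i2 0 -9  A A  A G  C T",
           "FAM i4 0 0 0 -9  0 0  A A  T T")
  map <- c("1 m1 0 1000", "1 m2 0 2000", "2 m3 0 500")
  writeLines(ped, file.path(dir, "fix.ped"))
  writeLines(map, file.path(dir, "fix.map"))
  file.path(dir, "fix")
}

test_that("PED/MAP parsing codes minor-allele dosage and missing calls", {
  prefix <- write_ped_fixture(withr::local_tempdir())
  gm <- read_genotypes(prefix, "ped")
  expect_equal(gm$individual_ids, c("i1", "i2", "i3", "i4"))
  # m1 monomorphic A with a PLINK "0 0" missing call
  expect_equal(unname(gm$genotypes[, "m1"]), c(0L, 0L, 0L, NA))
  # m2: alleles A (5 copies) vs G (3 copies) -> minor G
  mk <- gm$markers[gm$markers$marker_id == "m2", ]
  expect_equal(mk$allele_minor, "G")
  expect_equal(unname(gm$genotypes[, "m2"]), c(1L, 1L, 1L, 0L))
  # m3: 4 C vs 4 T tie -> major is the lexicographically smaller base (C)
  mk3 <- gm$markers[gm$markers$marker_id == "m3", ]
  expect_equal(mk3$allele_major, "C")
  expect_equal(mk3$allele_minor, "T")
  expect_equal(unname(gm$genotypes[, "m3"]), c(0L, 1L, 1L, 2L))
})

test_that("malformed and non-biallelic PED input is rejected with context", {
  dir <- withr::local_tempdir()
  writeLines(c("FAM i1 0 0 0 -9 A A", "FAM i2 0 0 0 -9 A"),
             file.path(dir, "bad.ped"))
  writeLines("1 m1 0 1000", file.path(dir, "bad.map"))
  expect_error(read_genotypes(file.path(dir, "bad"), "ped"), "line 2")
  writeLines(c("FAM i1 0 0 0 -9 A A", "FAM i2 0 0 0 -9 C G"),
             file.path(dir, "tri.ped"))
  writeLines("1 m1 0 1000", file.path(dir, "tri.map"))
  expect_error(read_genotypes(file.path(dir, "tri"), "ped"),
               "not biallelic")
})

test_that("TSV dialect round trip reproduces genotypes, ids and metadata", {
  fx <- rand_trio_fixture(n_trios = 4, n_markers = 6, miss_rate = 0.2,
                          seed = 11)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_genotypes(fx$gm, prefix, "tsv")
  back <- read_genotypes(prefix, "tsv")
  expect_identical(back$genotypes, fx$gm$genotypes)
  expect_identical(back$individual_ids, fx$gm$individual_ids)
  expect_identical(back$markers, fx$gm$markers)
})

test_that("PED round trip reproduces genotypes when coded alleles are minor", {
  fx <- rand_trio_fixture(n_trios = 6, n_markers = 5, seed = 3)
  gm <- fx$gm
  # restrict to markers whose coded-allele frequency is strictly below 0.5
  keep <- marker_maf(gm, fold = FALSE) < 0.5 & marker_maf(gm) > 0
  gm <- subset_genotypes(gm, markers = keep)
  skip_if(n_markers(gm) == 0)
  prefix <- file.path(withr::local_tempdir(), "pedrt")
  write_genotypes(gm, prefix, "ped", pedigree = fx$ped)
  back <- read_genotypes(prefix, "ped")
  expect_identical(back$genotypes, gm$genotypes)
  expect_identical(back$markers$allele_minor, gm$markers$allele_minor)
})

test_that("pedigree reading handles founders and rejects cycles", {
  dir <- withr::local_tempdir()
  writeLines(c("F1_01 F0_03 F0_07", "F0_03 0 0", "F0_07 0 0"),
             file.path(dir, "ped.txt"))
  ped <- read_pedigree(file.path(dir, "ped.txt"))
  expect_equal(ped$father_id, c("F0_03", NA, NA))
  writeLines("X X X", file.path(dir, "cyc.txt"))
  expect_error(read_pedigree(file.path(dir, "cyc.txt")), "cyclic")
  writeLines(c("A B 0", "B A 0"), file.path(dir, "cyc2.txt"))
  expect_error(read_pedigree(file.path(dir, "cyc2.txt")), "cyclic")
})

test_that("individual filter drops only rows above the missingness threshold", {
  g <- rbind(c(0L, 1L, 2L, 0L), c(NA, NA, 0L, 1L), c(0L, NA, NA, NA))
  gm <- make_gm(g)
  expect_equal(n_individuals(filter_individuals(gm, 1.0)), 3)
  f <- suppressMessages(filter_individuals(gm, 0.1))
  expect_equal(f$individual_ids, "i01")
  expect_equal(n_markers(f), 4)  # marker set untouched
})

test_that("marker MAF is computed over non-missing calls only", {
  g <- matrix(c(0L, 0L, 1L, 1L, 1L, 2L, 2L, NA, 0L, 1L), ncol = 1)
  gm <- genotype_matrix(g, sprintf("i%d", 1:10),
                        data.frame(marker_id = "m1", chromosome = "1",
                                   position = 1L))
  expect_equal(unname(marker_maf(gm)), 8 / 18)
})

test_that("marker filter enforces MAF, missingness and chromosome exclusion", {
  fx <- rand_trio_fixture(n_trios = 10, n_markers = 6, seed = 5)
  gm <- fx$gm
  gm$genotypes[, 2] <- 0L                      # monomorphic
  gm$genotypes[1:6, 3] <- NA_integer_          # 20% missing
  gm <- genotype_matrix(gm$genotypes, gm$individual_ids, gm$markers)
  f <- suppressMessages(
    filter_markers(gm, max_missing = 0.1, min_maf = 0.01,
                   exclude_chromosomes = "2"))
  expect_false(any(f$markers$chromosome == "2"))
  expect_false("m02" %in% f$markers$marker_id)
  expect_false("m03" %in% f$markers$marker_id)
  expect_true(all(marker_maf(f) >= 0.01))
})

test_that("surviving markers always satisfy the MAF floor on recomputation", {
  for (seed in 1:3) {
    fx <- rand_trio_fixture(n_trios = 12, n_markers = 8, miss_rate = 0.1,
                            seed = seed)
    f <- suppressMessages(filter_markers(fx$gm, min_maf = 0.1))
    if (n_markers(f) > 0) expect_true(all(marker_maf(f) >= 0.1))
  }
})

test_that("trio usability mask is exactly joint non-missingness plus Mendelian consistency", {
  for (seed in 1:5) {
    fx <- rand_trio_fixture(n_trios = 8, n_markers = 5, miss_rate = 0.25,
                            seed = seed)
    g <- fx$gm$genotypes
    tt <- fx$trios$trios
    for (t in seq_len(nrow(tt))) for (m in 1:5) {
      expected <- !is.na(g[tt$child[t], m]) && !is.na(g[tt$father[t], m]) &&
        !is.na(g[tt$mother[t], m])
      expect_identical(fx$trios$usable[t, m], expected,
                       info = sprintf("seed %d trio %d marker %d", seed, t, m))
    }
  }
})

test_that("Mendelian-inconsistent calls are masked per trio and marker", {
  fx <- rand_trio_fixture(n_trios = 3, n_markers = 4, seed = 9)
  g <- fx$gm$genotypes
  tt <- fx$trios$trios
  # plant an impossible child call: parents forced hom-major, child hom-minor
  g[tt$father[1], 2] <- 0L; g[tt$mother[1], 2] <- 0L; g[tt$child[1], 2] <- 2L
  gm <- genotype_matrix(g, fx$gm$individual_ids, fx$gm$markers)
  expect_message(trios <- extract_trios(gm, fx$ped), "inconsistent")
  expect_false(trios$usable[1, 2])
  expect_true(all(trios$usable[1, -2] ==
                    (!is.na(g[tt$child[1], -2]) &
                     !is.na(g[tt$father[1], -2]) &
                     !is.na(g[tt$mother[1], -2]))))
})

test_that("children without two genotyped parents are excluded, empty sets error", {
  fx <- rand_trio_fixture(n_trios = 2, n_markers = 3, seed = 1)
  ped <- fx$ped
  ped$father_id[6] <- "ghost"  # second trio's father not genotyped
  expect_warning(trios <- extract_trios(fx$gm, ped), "skipped")
  expect_equal(nrow(trios$trios), 1)
  ped_founders <- data.frame(individual_id = fx$gm$individual_ids,
                             father_id = NA_character_,
                             mother_id = NA_character_)
  expect_error(extract_trios(fx$gm, ped_founders), "no usable trios")
})
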