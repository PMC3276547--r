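# Gene-dropping pedigree simulator: phased founder lines, recombination,
# multi-generation random mating, genotyping error, missingness, and optional
# planted two-locus lethal incompatibilities. This is the null-calibration
# engine (no planted effect => no true interactions by construction) and the
# planted-truth power fixture.

#' Build an evenly spaced marker map
#'
#' @param n_chrom number of chromosomes (named "1", "2", ...).
#' @param n_markers markers per chromosome.
#' @param spacing base-pair distance between adjacent markers.
#' @return data.frame usable as the `markers` slot of a [genotype_matrix()]
#'   (alleles A = major, G = minor).
#' @export
make_marker_map <- function(n_chrom = 5, n_markers = 40, spacing = 1e6) {
  chrom <- rep(as.character(seq_len(n_chrom)), each = n_markers)
  within <- rep(seq_len(n_markers), n_chrom)
  data.frame(marker_id = sprintf("c%sm%02d", chrom, within),
             chromosome = chrom,
             position = as.integer(within * spacing),
             allele_major = "A", allele_minor = "G",
             stringsAsFactors = FALSE)
}

#' Uniform recombination map
#'
#' @param marker_map a [make_marker_map()]-style data.frame.
#' @param rate per-interval crossover probability, in \[0, 0.5\].
#' @return Named list (per chromosome) of crossover probabilities for each
#'   adjacent-marker interval.
#' @export
make_recomb_map <- function(marker_map, rate = 0.05) {
  stopifnot(rate >= 0, rate <= 0.5)
  chroms <- unique(marker_map$chromosome)
  stats::setNames(lapply(chroms, function(ch) {
    L <- sum(marker_map$chromosome == ch)
    rep(rate, max(L - 1, 0))
  }), chroms)
}

#' Simulate phased founders from inbred lines
#'
#' Emulates a heterogeneous stock: each of `n_lines` inbred lines carries one
#' haplotype per chromosome (alleles i.i.d. Bernoulli(`line_allele_freq`) per
#' marker), and each founder is fully homozygous for one line's haplotypes,
#' lines assigned round-robin.
#'
#' @param n_lines number of founder lines (>= 2 for any polymorphism to
#'   survive downstream MAF filtering).
#' @param n_founders number of founder individuals.
#' @param marker_map a [make_marker_map()]-style data.frame.
#' @param line_allele_freq per-marker probability that a line haplotype
#'   carries the alternative allele (scalar or vector over markers).
#' @param line_carriers optional named list (marker_id -> lines): at those
#'   markers exactly the given lines carry the alternative allele — used to
#'   pin the founder allele frequency of specific markers, e.g. the loci of a
#'   planted incompatibility. Each element is either a count (lines chosen at
#'   random) or an explicit vector of line indices.
#' @param seed integer seed (`NULL`: current RNG state).
#' @return Named list of founder haplotype sets; each is a per-chromosome list
#'   of 2 x L integer matrices. Attribute `"lines"` stores the line
#'   haplotypes, attribute `"map"` the marker map.
#' @export
generate_founders <- function(n_lines = 8, n_founders = 40, marker_map,
                              line_allele_freq = 0.5, line_carriers = NULL,
                              seed = NULL) {
  stopifnot(n_lines >= 1, n_founders >= 1)
  run <- function() {
    chroms <- unique(marker_map$chromosome)
    freq <- rep(line_allele_freq, length.out = nrow(marker_map))
    lines <- lapply(seq_len(n_lines), function(l) {
      stats::setNames(lapply(chroms, function(ch) {
        idx <- which(marker_map$chromosome == ch)
        as.integer(stats::runif(length(idx)) < freq[idx])
      }), chroms)
    })
    if (!is.null(line_carriers)) {
      for (mid in names(line_carriers)) {
        row <- which(marker_map$marker_id == mid)
        if (length(row) != 1) stop("unknown marker in line_carriers: ", mid)
        ch <- marker_map$chromosome[row]
        pos <- which(which(marker_map$chromosome == ch) == row)
        cc <- line_carriers[[mid]]
        # a scalar is a carrier count (lines drawn at random); a longer
        # vector lists the carrier lines explicitly
        carriers <- if (length(cc) == 1) sample(n_lines, cc)
                    else as.integer(cc)
        for (l in seq_len(n_lines))
          lines[[l]][[ch]][pos] <- as.integer(l %in% carriers)
      }
    }
    founders <- stats::setNames(lapply(seq_len(n_founders), function(i) {
      l <- ((i - 1) %% n_lines) + 1
      lapply(lines[[l]], function(h) rbind(h, h))
    }), sprintf("F0_%03d", seq_len(n_founders)))
    attr(founders, "lines") <- lines
    attr(founders, "map") <- marker_map
    founders
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Simulate one gamete from a phased parent
#'
#' Markov walk along each chromosome: the first marker's allele comes from
#' either parental haplotype with probability 1/2; at each inter-marker
#' interval the source haplotype switches with the interval's crossover
#' probability.
#'
#' @param parent_haps per-chromosome list of 2 x L haplotype matrices.
#' @param recomb_map a [make_recomb_map()]-style list matching the marker
#'   counts.
#' @return Per-chromosome list of allele vectors (one haplotype).
#' @export
simulate_gamete <- function(parent_haps, recomb_map) {
  lapply(stats::setNames(names(parent_haps), names(parent_haps)),
         function(ch) {
    hap <- parent_haps[[ch]]
    L <- ncol(hap)
    r <- recomb_map[[ch]]
    if (length(r) != max(L - 1, 0))
      stop("recombination map does not match marker count on chromosome ", ch)
    flips <- c(stats::runif(1) < 0.5, stats::runif(L - 1) < r)
    src <- (cumsum(flips) %% 2L) + 1L
    hap[cbind(src, seq_len(L))]
  })
}

#' Planted two-locus incompatibility specification
#'
#' Describes a viability-selection effect: offspring whose genotype
#' combination at two (inter-chromosomal) loci equals the lethal cell are
#' rejected with probability `s` during gene dropping and their gametes
#' resampled.
#'
#' @param marker_a,marker_b marker ids on different chromosomes.
#' @param lethal length-2 integer vector: the lethal dosage combination
#'   (j*, k*) in \{0, 1, 2\}^2. Default `c(2, 2)` (both loci homozygous
#'   minor), the classic recessive-recessive incompatibility — and the only
#'   cell for which fully lethal selection is guaranteed to terminate on a
#'   fixed pedigree, since carriers of the combination cannot be parents.
#' @param s selection coefficient in \[0, 1\] (1 = fully lethal).
#' @return Object of class `"incompatibility"`.
#' @export
incompatibility <- function(marker_a, marker_b, lethal = c(2, 2), s = 1) {
  stopifnot(length(lethal) == 2, all(lethal %in% 0:2), s >= 0, s <= 1)
  structure(list(marker_a = marker_a, marker_b = marker_b,
                 lethal = as.integer(lethal), s = s),
            class = "incompatibility")
}

#' Gene-drop genotypes through a pedigree
#'
#' Simulates every non-founder in pedigree (topological) order from two
#' freshly sampled parental gametes, optionally applying viability selection
#' against a planted two-locus incompatibility (rejection sampling, capped at
#' 10000 attempts per child).
#'
#' @param founder_haps a [generate_founders()] result covering every founder
#'   in `ped`.
#' @param ped pedigree data.frame (`individual_id`, `father_id`, `mother_id`;
#'   founders have `NA` parents).
#' @param recomb_map a [make_recomb_map()]-style list.
#' @param incompat an [incompatibility()] or `NULL`. With `s = 0` the output
#'   is identical (same seed) to `incompat = NULL`: the lethal check is only
#'   consulted, never the RNG, when `s = 0`.
#' @param seed integer seed (`NULL`: current RNG state).
#' @return List with `geno` (a [genotype_matrix()] over all pedigree members)
#'   and `haplotypes` (per individual, per chromosome 2 x L matrices).
#' @export
simulate_pedigree <- function(founder_haps, ped, recomb_map, incompat = NULL,
                              seed = NULL) {
  map <- attr(founder_haps, "map")
  if (is.null(map)) stop("founder_haps must carry a marker map attribute")
  run <- function() {
    depth <- pedigree_depth(ped)
    ord <- order(depth)
    haps <- list()
    founder <- is.na(ped$father_id) & is.na(ped$mother_id)
    for (i in which(founder)) {
      id <- ped$individual_id[i]
      if (!id %in% names(founder_haps))
        stop("founder without haplotypes: ", id)
      haps[[id]] <- founder_haps[[id]]
    }
    lcheck <- NULL
    if (!is.null(incompat)) {
      ra <- which(map$marker_id == incompat$marker_a)
      rb <- which(map$marker_id == incompat$marker_b)
      if (length(ra) != 1 || length(rb) != 1)
        stop("incompatibility markers not in map")
      cha <- map$chromosome[ra]; chb <- map$chromosome[rb]
      if (cha == chb)
        stop("incompatibility loci must lie on different chromosomes")
      pa <- which(which(map$chromosome == cha) == ra)
      pb <- which(which(map$chromosome == chb) == rb)
      lcheck <- list(cha = cha, chb = chb, pa = pa, pb = pb,
                     lethal = incompat$lethal, s = incompat$s)
    }
    for (i in ord) {
      if (founder[i]) next
      id <- ped$individual_id[i]
      fh <- haps[[ped$father_id[i]]]; mh <- haps[[ped$mother_id[i]]]
      if (is.null(fh) || is.null(mh))
        stop("parents of ", id, " not simulated before the child")
      attempts <- 0
      repeat {
        attempts <- attempts + 1
        if (attempts > 10000)
          stop("rejection cap exceeded for child ", id,
               ": parents may only produce lethal genotype combinations")
        g1 <- simulate_gamete(fh, recomb_map)
        g2 <- simulate_gamete(mh, recomb_map)
        if (!is.null(lcheck) && lcheck$s > 0) {
          ga <- g1[[lcheck$cha]][lcheck$pa] + g2[[lcheck$cha]][lcheck$pa]
          gb <- g1[[lcheck$chb]][lcheck$pb] + g2[[lcheck$chb]][lcheck$pb]
          if (ga == lcheck$lethal[1] && gb == lcheck$lethal[2] &&
              (lcheck$s >= 1 || stats::runif(1) < lcheck$s)) next
        }
        break
      }
      haps[[id]] <- stats::setNames(lapply(names(fh), function(ch)
        rbind(g1[[ch]], g2[[ch]])), names(fh))
    }
    ids <- ped$individual_id
    geno <- matrix(NA_integer_, length(ids), nrow(map))
    chroms <- unique(map$chromosome)
    col_of <- lapply(chroms, function(ch) which(map$chromosome == ch))
    names(col_of) <- chroms
    for (i in seq_along(ids)) {
      h <- haps[[ids[i]]]
      for (ch in chroms)
        geno[i, col_of[[ch]]] <- h[[ch]][1, ] + h[[ch]][2, ]
    }
    list(geno = genotype_matrix(geno, ids, map), haplotypes = haps)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Random-mating multi-generation pedigree
#'
#' Founders form generation 0; each later generation's children draw a father
#' from the previous generation's males and a mother from its females,
#' independently per child (random mating). Sexes alternate within each
#' generation.
#'
#' @param n_founders founder count (generation 0).
#' @param n_per_gen integer vector: children per subsequent generation.
#' @param seed integer seed (`NULL`: current RNG state).
#' @return Pedigree data.frame with `individual_id`, `father_id`, `mother_id`,
#'   `sex` ("M"/"F"), `generation`.
#' @export
random_mating_pedigree <- function(n_founders = 40,
                                   n_per_gen = c(167, 167, 167),
                                   seed = NULL) {
  run <- function() {
    make_gen <- function(g, n) {
      data.frame(individual_id = sprintf("F%d_%03d", g, seq_len(n)),
                 father_id = NA_character_, mother_id = NA_character_,
                 sex = rep_len(c("M", "F"), n), generation = g,
                 stringsAsFactors = FALSE)
    }
    ped <- make_gen(0, n_founders)
    prev <- ped
    for (g in seq_along(n_per_gen)) {
      cur <- make_gen(g, n_per_gen[g])
      males <- prev$individual_id[prev$sex == "M"]
      females <- prev$individual_id[prev$sex == "F"]
      if (!length(males) || !length(females))
        stop("generation ", g - 1, " lacks one sex entirely")
      cur$father_id <- sample(males, nrow(cur), replace = TRUE)
      cur$mother_id <- sample(females, nrow(cur), replace = TRUE)
      ped <- rbind(ped, cur)
      prev <- cur
    }
    ped
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Inject genotyping errors without creating Mendelian inconsistencies
#'
#' Flips a random fraction of non-missing calls to a different genotype drawn
#' uniformly from the alternatives consistent with the individual's trio
#' context: as a child (given its genotyped parents) and as a parent (given
#' each genotyped mate and child). Entries with no consistent alternative are
#' left unchanged and another entry is drawn instead, until the target count
#' is reached or candidates are exhausted.
#'
#' @param gm a [genotype_matrix()] object.
#' @param ped pedigree data.frame giving the trio context.
#' @param error_rate fraction of non-missing entries to corrupt, in
#'   \[0, 0.1\].
#' @param seed integer seed (`NULL`: current RNG state).
#' @return The corrupted `geno_matrix`.
#' @export
inject_genotyping_errors <- function(gm, ped, error_rate, seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 0.1)
  if (error_rate == 0) return(gm)
  run <- function() {
    g <- gm$genotypes
    ids <- gm$individual_ids
    fa_of <- match(ped$father_id[match(ids, ped$individual_id)], ids)
    mo_of <- match(ped$mother_id[match(ids, ped$individual_id)], ids)
    kids_of <- lapply(seq_along(ids), function(i)
      which(fa_of == i | mo_of == i))
    mate_of <- lapply(seq_along(ids), function(i)
      ifelse(fa_of[kids_of[[i]]] == i, mo_of[kids_of[[i]]],
             fa_of[kids_of[[i]]]))
    consistent_alts <- function(i, m) {
      alts <- setdiff(0:2, g[i, m])
      f <- fa_of[i]; mo <- mo_of[i]
      if (!is.na(f) && !is.na(mo) && !is.na(g[f, m]) && !is.na(g[mo, m]))
        alts <- alts[mendelian_consistent(alts, g[f, m], g[mo, m])]
      for (k in seq_along(kids_of[[i]])) {
        child <- kids_of[[i]][k]; other <- mate_of[[i]][k]
        if (is.na(other) || is.na(g[child, m]) || is.na(g[other, m])) next
        alts <- alts[mendelian_consistent(g[child, m], alts, g[other, m])]
        if (!length(alts)) break
      }
      alts
    }
    candidates <- which(!is.na(g))
    target <- round(error_rate * length(candidates))
    candidates <- sample(candidates)
    flipped <- 0
    nr <- nrow(g)
    for (e in candidates) {
      if (flipped >= target) break
      i <- ((e - 1) %% nr) + 1
      m <- ((e - 1) %/% nr) + 1
      alts <- consistent_alts(i, m)
      if (!length(alts)) next
      g[i, m] <- if (length(alts) == 1) alts else sample(alts, 1)
      flipped <- flipped + 1
    }
    if (flipped < target)
      warning(sprintf("only %d of %d requested errors could be injected",
                      flipped, target))
    genotype_matrix(g, ids, gm$markers)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Inject missing calls
#'
#' @param gm a [genotype_matrix()] object.
#' @param rate i.i.d. per-entry missingness probability, or
#' @param mask logical matrix of the same shape (`TRUE` = set missing), e.g.
#'   copied from a real dataset.
#' @param seed integer seed (`NULL`: current RNG state).
#' @return `geno_matrix` with the extra missing calls.
#' @export
inject_missing <- function(gm, rate = NULL, mask = NULL, seed = NULL) {
  g <- gm$genotypes
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(g))) stop("mask shape mismatch")
    g[mask] <- NA_integer_
  } else {
    stopifnot(!is.null(rate), rate >= 0, rate <= 1)
    if (rate > 0) {
      run <- function() {
        g[stats::runif(length(g)) < rate] <- NA_integer_
        g
      }
      g <- if (is.null(seed)) run() else .with_seed(seed, run())
    }
  }
  genotype_matrix(g, gm$individual_ids, gm$markers)
}

#' One-call synthetic trio dataset
#'
#' The package's standard study-condition generator: a heterogeneous-stock
#' style population (8 founder lines, 40 founders, 3 generations of ~167
#' children by random mating, so ~500 trios) genotyped at 5 chromosomes x 40
#' evenly spaced markers with inter-marker crossover probability 0.05, with
#' optional genotyping error, missingness, and a planted lethal two-locus
#' incompatibility. When an incompatibility is planted, the founder allele
#' frequency at its two loci is pinned via `planted_line_carriers` carrier
#' lines (default 3 of 8, i.e. founder MAF 0.375, close to 0.3 in the
#' offspring generations under selection), and the carrier line sets of the
#' two loci are drawn disjoint: no founder line carries both derived alleles,
#' which is the Dobzhansky-Muller premise (the incompatible alleles arose in
#' separate lineages) and is also what lets fully lethal (s = 1)
#' recessive-recessive selection terminate — a line carrying both would
#' produce founders homozygous for the lethal combination, i.e. matings that
#' can only yield lethal offspring.
#'
#' @param seed integer seed controlling the whole dataset.
#' @param n_lines,n_founders,n_per_gen,n_chrom,n_markers,crossover,
#'   line_allele_freq see [generate_founders()], [random_mating_pedigree()],
#'   [make_marker_map()], [make_recomb_map()].
#' @param incompat an [incompatibility()] or `NULL`.
#' @param planted_line_carriers founder lines carrying the minor allele at
#'   each planted locus.
#' @param error_rate,missing_rate post-hoc corruption rates (defaults 0).
#' @return List with `geno` (a [genotype_matrix()]), `pedigree`, `trios`
#'   (the [extract_trios()] result), `map`, `recomb_map`, and `truth`
#'   (seed, planted incompatibility, founder line haplotypes).
#' @export
sim_trio_dataset <- function(seed = 1, n_lines = 8, n_founders = 40,
                             n_per_gen = c(167, 167, 167), n_chrom = 5,
                             n_markers = 40, crossover = 0.05,
                             line_allele_freq = 0.5, incompat = NULL,
                             planted_line_carriers = 3,
                             error_rate = 0, missing_rate = 0) {
  map <- make_marker_map(n_chrom, n_markers)
  rmap <- make_recomb_map(map, crossover)
  .with_seed(seed, {
    carriers <- NULL
    if (!is.null(incompat)) {
      k <- planted_line_carriers
      if (2 * k > n_lines)
        stop("cannot draw disjoint carrier line sets: 2 * planted_line_carriers > n_lines")
      ca <- sample(n_lines, k)
      cb <- sample(setdiff(seq_len(n_lines), ca), k)
      carriers <- stats::setNames(list(ca, cb),
                                  c(incompat$marker_a, incompat$marker_b))
    }
    founders <- generate_founders(n_lines, n_founders, map, line_allele_freq,
                                  line_carriers = carriers)
    ped <- random_mating_pedigree(n_founders, n_per_gen)
    sim <- simulate_pedigree(founders, ped, rmap, incompat)
    geno <- sim$geno
    if (error_rate > 0)
      geno <- inject_genotyping_errors(geno, ped, error_rate)
    if (missing_rate > 0)
      geno <- inject_missing(geno, rate = missing_rate)
    trios <- extract_trios(geno, ped)
    list(geno = geno, pedigree = ped, trios = trios, map = map,
         recomb_map = rmap,
         truth = list(seed = seed, incompat = incompat,
                      lines = attr(founders, "lines")))
  })
}
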