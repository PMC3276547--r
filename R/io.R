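# File input/output: PLINK text PED/MAP, the package TSV dialect, pedigrees.

#' Read genotypes from PED/MAP or the TSV dialect
#'
#' Two plain-text dialects are supported. `format = "ped"` reads a PLINK text
#' fileset: `<prefix>.ped` (six leading columns, then two allele calls per
#' marker, `0` = missing) and `<prefix>.map` (chromosome, marker id, cM
#' (ignored), bp). `format = "tsv"` reads `<prefix>.tsv` (header of marker ids,
#' one row per individual with an `individual_id` first column, dosage cells in
#' 0/1/2/NA) and a sidecar `<prefix>.markers.tsv` carrying chromosome,
#' position and the major/minor allele assignment.
#'
#' For PED input the minor allele of each marker is the rarer allele among
#' non-missing calls; on an exact frequency tie the lexicographically smaller
#' base is taken as the major allele.
#'
#' @param prefix path prefix of the fileset (no extension).
#' @param format `"ped"` or `"tsv"`.
#' @return A [genotype_matrix()] object.
#' @export
read_genotypes <- function(prefix, format = c("ped", "tsv")) {
  format <- match.arg(format)
  switch(format,
         ped = read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map")),
         tsv = read_genotype_tsv(paste0(prefix, ".tsv"),
                                 paste0(prefix, ".markers.tsv")))
}

#' Write genotypes to PED/MAP or the TSV dialect
#'
#' @inheritParams read_genotypes
#' @param gm a [genotype_matrix()] object. For PED output every marker needs
#'   non-missing `allele_major`/`allele_minor` metadata.
#' @param pedigree optional data.frame (`individual_id`, `father_id`,
#'   `mother_id`, optional `sex`) used to fill the PED family columns;
#'   unknown parents are written as `0`.
#' @return Invisibly, the paths written.
#' @export
write_genotypes <- function(gm, prefix, format = c("ped", "tsv"),
                            pedigree = NULL) {
  format <- match.arg(format)
  switch(format,
         ped = write_ped_map(gm, prefix, pedigree),
         tsv = write_genotype_tsv(gm, prefix))
}

read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chromosome", "marker_id", "cm",
                                         "position"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  fathers <- character(n); mothers <- character(n)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop(sprintf("malformed PED line %d: expected %d fields, found %d",
                   i, 6 + 2 * m, length(f)))
    ids[i] <- f[2]; fathers[i] <- f[3]; mothers[i] <- f[4]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  geno <- matrix(NA_integer_, n, m)
  major <- character(m); minor <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    called <- x1 != "0" & x2 != "0"
    if (any(xor(x1 == "0", x2 == "0")))
      stop(sprintf("half-missing genotype at marker %s", map$marker_id[j]))
    alleles <- sort(unique(c(x1[called], x2[called])))
    if (length(alleles) > 2)
      stop(sprintf("marker %s is not biallelic (alleles: %s)",
                   map$marker_id[j], paste(alleles, collapse = ",")))
    if (length(alleles) == 0) {
      major[j] <- NA_character_; minor[j] <- NA_character_
      next
    }
    if (length(alleles) == 1) {
      major[j] <- alleles; minor[j] <- NA_character_
      geno[called, j] <- 0L
      next
    }
    counts <- c(sum(x1[called] == alleles[1]) + sum(x2[called] == alleles[1]),
                sum(x1[called] == alleles[2]) + sum(x2[called] == alleles[2]))
    # rarer allele is minor; tie -> lexicographically smaller base is major
    minor_idx <- if (counts[1] < counts[2]) 1L else 2L
    minor[j] <- alleles[minor_idx]; major[j] <- alleles[3L - minor_idx]
    geno[called, j] <- (x1[called] == minor[j]) + (x2[called] == minor[j])
  }
  map$allele_major <- major
  map$allele_minor <- minor
  gm <- genotype_matrix(geno, ids, map[, c("marker_id", "chromosome",
                                           "position", "allele_major",
                                           "allele_minor")])
  attr(gm, "ped_parents") <- data.frame(individual_id = ids,
                                        father_id = fathers,
                                        mother_id = mothers,
                                        stringsAsFactors = FALSE)
  gm
}

write_ped_map <- function(gm, prefix, pedigree = NULL) {
  mk <- gm$markers
  if (any(is.na(mk$allele_major) | is.na(mk$allele_minor)))
    stop("PED output needs complete allele metadata for every marker")
  n <- n_individuals(gm); m <- n_markers(gm)
  fa <- mo <- rep("0", n)
  if (!is.null(pedigree)) {
    idx <- match(gm$individual_ids, pedigree$individual_id)
    hit <- !is.na(idx)
    fa[hit] <- ifelse(is.na(pedigree$father_id[idx[hit]]), "0",
                      pedigree$father_id[idx[hit]])
    mo[hit] <- ifelse(is.na(pedigree$mother_id[idx[hit]]), "0",
                      pedigree$mother_id[idx[hit]])
  }
  g <- gm$genotypes
  rows <- vapply(seq_len(n), function(i) {
    gi <- g[i, ]
    x1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, mk$allele_minor,
                                        mk$allele_major))
    x2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, mk$allele_minor,
                                        mk$allele_major))
    paste(c("FAM", gm$individual_ids[i], fa[i], mo[i], "0", "-9",
            as.vector(rbind(x1, x2))), collapse = " ")
  }, character(1))
  ped_path <- paste0(prefix, ".ped"); map_path <- paste0(prefix, ".map")
  writeLines(rows, ped_path)
  writeLines(sprintf("%s %s 0 %d", mk$chromosome, mk$marker_id, mk$position),
             map_path)
  invisible(c(ped_path, map_path))
}

read_genotype_tsv <- function(geno_path, markers_path) {
  if (!file.exists(geno_path)) stop("no such file: ", geno_path)
  if (!file.exists(markers_path)) stop("no such file: ", markers_path)
  tab <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (names(tab)[1] != "individual_id")
    stop("TSV dialect requires an 'individual_id' first column")
  ids <- tab[[1]]
  geno <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(geno) <- "integer")
  bad <- !(geno %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype cell at row %d, marker %s",
                 idx[1], colnames(geno)[idx[2]]))
  }
  mk <- utils::read.table(markers_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!identical(mk$marker_id, colnames(geno)))
    stop("marker sidecar does not match genotype header")
  genotype_matrix(geno, ids, mk)
}

write_genotype_tsv <- function(gm, prefix) {
  geno_path <- paste0(prefix, ".tsv")
  markers_path <- paste0(prefix, ".markers.tsv")
  tab <- data.frame(individual_id = gm$individual_ids,
                    gm$genotypes, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(gm$markers, markers_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(geno_path, markers_path))
}

#' Read a pedigree table
#'
#' Reads a whitespace-delimited child/father/mother table (a PLINK FAM-like
#' layout, with or without the leading family column). Parent id `"0"` means
#' unknown (founder).
#'
#' @param path file path.
#' @return A data.frame with columns `individual_id`, `father_id`, `mother_id`
#'   (`NA` for unknown parents), validated to be acyclic.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) >= 6) {
    # FAM layout: fid iid pat mat sex pheno
    ped <- data.frame(individual_id = tab[[2]], father_id = tab[[3]],
                      mother_id = tab[[4]], stringsAsFactors = FALSE)
  } else if (ncol(tab) >= 3) {
    ped <- data.frame(individual_id = tab[[1]], father_id = tab[[2]],
                      mother_id = tab[[3]], stringsAsFactors = FALSE)
  } else stop("pedigree file needs at least child/father/mother columns")
  ped$father_id[ped$father_id == "0"] <- NA_character_
  ped$mother_id[ped$mother_id == "0"] <- NA_character_
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$individual_id))
    stop("duplicated individual ids in pedigree")
  # acyclicity by iterative peeling of parent-resolved individuals
  depth <- pedigree_depth(ped)
  if (anyNA(depth)) {
    bad <- ped$individual_id[is.na(depth)]
    stop("cyclic ancestry in pedigree involving: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

# Generation depth of every individual (founders = 0); NA marks members of a
# cycle (never resolvable).
pedigree_depth <- function(ped) {
  ids <- ped$individual_id
  fa <- match(ped$father_id, ids)
  mo <- match(ped$mother_id, ids)
  depth <- rep(NA_integer_, length(ids))
  # parents absent from the table count as founders
  fa[!is.na(ped$father_id) & is.na(fa)] <- 0L
  mo[!is.na(ped$mother_id) & is.na(mo)] <- 0L
  resolved_depth <- function(p) {
    if (is.na(p)) 0L else if (p == 0L) 0L else depth[p]
  }
  repeat {
    changed <- FALSE
    for (i in seq_along(ids)) {
      if (!is.na(depth[i])) next
      df <- resolved_depth(fa[i]); dm <- resolved_depth(mo[i])
      if (!is.na(df) && !is.na(dm)) {
        depth[i] <- max(df, dm) + ifelse(is.na(fa[i]) && is.na(mo[i]), 0L, 1L)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  names(depth) <- ids
  depth
}

#' Write a pedigree table
#'
#' @param ped data.frame with `individual_id`, `father_id`, `mother_id`.
#' @param path output path; unknown parents are written as `0`.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped[, c("individual_id", "father_id", "mother_id")]
  out$father_id[is.na(out$father_id)] <- "0"
  out$mother_id[is.na(out$mother_id)] <- "0"
  utils::write.table(out, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
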