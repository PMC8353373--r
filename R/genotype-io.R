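#' Read a PLINK text PED/MAP pair into a genotype matrix
#'
#' PED rows carry six metadata columns (FID IID PAT MAT SEX PHENO) followed
#' by two allele columns per marker; MAP rows carry chromosome, marker id,
#' genetic position (ignored; the 1 Mb = 1 cM convention is applied instead)
#' and bp position. Alleles are recoded to minor-allele dosage per marker;
#' an allele code of "0" marks a missing call, so a "0 0" pair becomes `NA`.
#' The breed label of each sample is taken from its family id (FID).
#'
#' Minor allele: the allele with frequency < 0.5 over all non-missing calls
#' in the file; at exactly 0.5 the lexicographically smaller allele symbol
#' is counted.
#'
#' Chromosome labels are opaque strings; markers on labels listed in
#' `exclude_chromosomes` (by default the unplaced/sex/mito-style codes
#' "0" and "30"-"33" of bovine array maps) are dropped after parsing.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file.
#' @param exclude_chromosomes chromosome labels to drop (character).
#' @return a [geno_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path,
                         exclude_chromosomes = c("0", "30", "31", "32", "33")) {
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric", "numeric"))
  if (ncol(mp) < 4) stop("MAP file needs 4 columns: chr, id, genetic pos, bp")
  map <- marker_map(marker_id = mp[[2]], chromosome = mp[[1]], position_bp = mp[[4]])
  # PED columns refer to MAP file order; remember the permutation into map order
  perm <- match(map$marker_id, mp[[2]])
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  n <- length(toks)
  want <- 6L + 2L * m
  for (i in seq_len(n)) {
    if (length(toks[[i]]) != want)
      stop("PED row ", i, ": expected ", want, " fields (6 + 2 alleles x ",
           m, " markers), found ", length(toks[[i]]))
  }
  meta <- t(vapply(toks, function(x) x[1:6], character(6)))
  a1 <- t(vapply(toks, function(x) x[6L + 2L * seq_len(m) - 1L], character(m)))
  a2 <- t(vapply(toks, function(x) x[6L + 2L * seq_len(m)], character(m)))
  if (m == 1L) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  a1 <- a1[, perm, drop = FALSE]
  a2 <- a2[, perm, drop = FALSE]

  dos <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    alle <- c(x1[!miss], x2[!miss])
    sym <- sort(unique(alle))
    if (length(sym) > 2L)
      stop("marker ", map$marker_id[j], " is not biallelic: alleles ",
           paste(sym, collapse = "/"))
    if (length(alle) == 0L) next    # all missing: dosage stays NA
    if (length(sym) == 1L) {
      minor <- NA_character_        # monomorphic: dosage 0 everywhere observed
      dos[!miss, j] <- 0L
      next
    }
    p1 <- mean(alle == sym[1])
    minor <- if (p1 < 0.5) sym[1] else if (p1 > 0.5) sym[2] else sym[1]
    dos[, j] <- (x1 == minor) + (x2 == minor)
    dos[miss, j] <- NA_integer_
  }
  g <- geno_matrix(dos,
                   data.frame(sample_id = meta[, 2], breed = meta[, 1],
                              stringsAsFactors = FALSE),
                   map)
  drop <- g$map$chromosome %in% exclude_chromosomes
  if (any(drop)) g <- subset_geno(g, markers = which(!drop))
  g
}

#' Write a genotype matrix as a PLINK text PED/MAP pair
#'
#' The inverse of [read_ped_map()] up to allele symbols: dosages are encoded
#' with synthetic alleles "A" (minor) and "B" (major), missing as "0 0".
#' Reading the written pair back reproduces dosages and positions exactly.
#'
#' @param geno a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(geno, ped_path, map_path) {
  map <- geno$map
  utils::write.table(
    data.frame(map$chromosome, map$marker_id,
               map$genetic_pos_morgan * 100, map$position_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  d <- geno$dosages
  code1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, "A", "B"))
  code2 <- ifelse(is.na(d), "0", ifelse(d == 2L, "A", "B"))
  n <- nrow(d)
  rows <- vapply(seq_len(n), function(i) {
    paste(c(geno$samples$breed[i], geno$samples$sample_id[i], "0", "0", "0", "-9",
            as.vector(rbind(code1[i, ], code2[i, ]))), collapse = " ")
  }, character(1))
  writeLines(rows, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read / write a dosage-matrix TSV
#'
#' Rows are samples (first two columns `sample_id`, `breed`), remaining
#' columns one per marker (header = marker id), cells 0/1/2/NA. The marker
#' map travels in a companion MAP-format file.
#'
#' @param tsv_path dosage TSV path.
#' @param map_path MAP file path (chr, id, genetic pos, bp).
#' @return a [geno_matrix()].
#' @export
read_dosage_tsv <- function(tsv_path, map_path) {
  tab <- utils::read.table(tsv_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  map <- marker_map(mp[[2]], mp[[1]], mp[[4]])
  d <- as.matrix(tab[, -(1:2), drop = FALSE])
  d <- d[, match(map$marker_id, colnames(d)), drop = FALSE]
  geno_matrix(d, data.frame(sample_id = tab[[1]], breed = tab[[2]],
                            stringsAsFactors = FALSE), map)
}

#' @rdname read_dosage_tsv
#' @param geno a [geno_matrix()] to write.
#' @export
write_dosage_tsv <- function(geno, tsv_path, map_path) {
  tab <- data.frame(sample_id = geno$samples$sample_id,
                    breed = geno$samples$breed,
                    geno$dosages, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(geno$map$chromosome, geno$map$marker_id,
               geno$map$genetic_pos_morgan * 100, geno$map$position_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(tsv = tsv_path, map = map_path))
}
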