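#' Construct a genotype matrix object
#'
#' Container for a diploid biallelic SNP panel: a samples x markers dosage
#' matrix (minor-allele counts 0/1/2, `NA` = missing), per-sample breed
#' labels, and a marker map. Dosage 0 and missing are never conflated:
#' missing calls are `NA`, not 0.
#'
#' @param dosages integer matrix, samples in rows, markers in columns;
#'   entries 0, 1, 2 or `NA`.
#' @param samples data.frame with columns `sample_id` and `breed`
#'   (one row per matrix row).
#' @param map marker map as returned by [marker_map()] (one row per
#'   matrix column).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, samples, map) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != nrow(samples))
    stop("dosage rows (", nrow(dosages), ") != sample count (", nrow(samples), ")")
  if (ncol(dosages) != nrow(map))
    stop("dosage columns (", ncol(dosages), ") != marker count (", nrow(map), ")")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (!all(c("sample_id", "breed") %in% names(samples)))
    stop("samples needs columns sample_id, breed")
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- map$marker_id
  structure(
    list(dosages = dosages,
         samples = data.frame(sample_id = as.character(samples$sample_id),
                              breed = as.character(samples$breed),
                              stringsAsFactors = FALSE),
         map = map),
    class = "geno_matrix")
}

#' Construct a marker map
#'
#' Positions are 1-based base pairs. Genetic positions are derived under the
#' 1 Mb = 1 cM convention used throughout: `genetic_pos_morgan =
#' position_bp * 1e-8`. Markers are sorted by (chromosome, position), with
#' chromosomes kept in order of first appearance (so "10" does not sort
#' before "2").
#'
#' @param marker_id character marker identifiers (unique).
#' @param chromosome chromosome labels (treated as opaque strings).
#' @param position_bp integer 1-based physical positions.
#' @return data.frame of class `marker_map` with columns `marker_id`,
#'   `chromosome`, `position_bp`, `genetic_pos_morgan`.
#' @export
marker_map <- function(marker_id, chromosome, position_bp) {
  marker_id <- as.character(marker_id)
  chromosome <- as.character(chromosome)
  position_bp <- as.numeric(position_bp)
  if (anyDuplicated(marker_id)) stop("duplicated marker ids")
  if (any(position_bp < 1)) stop("positions must be >= 1 (1-based)")
  chr_order <- match(chromosome, unique(chromosome))
  o <- order(chr_order, position_bp)
  m <- data.frame(marker_id = marker_id[o],
                  chromosome = chromosome[o],
                  position_bp = position_bp[o],
                  stringsAsFactors = FALSE)
  step <- stats::ave(m$position_bp, m$chromosome,
                     FUN = function(p) c(1, diff(p)))
  if (any(step <= 0))
    stop("positions must be strictly increasing within a chromosome")
  m$genetic_pos_morgan <- m$position_bp * 1e-8
  class(m) <- c("marker_map", "data.frame")
  m
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosages), "samples x", ncol(x$dosages), "markers\n")
  cat("breeds:", paste(sort(unique(x$samples$breed)), collapse = ", "), "\n")
  cat("chromosomes:", length(unique(x$map$chromosome)),
      " missing rate:", round(mean(is.na(x$dosages)), 4), "\n")
  invisible(x)
}

#' Number of samples / markers in a panel
#' @param geno a `geno_matrix`.
#' @return integer count.
#' @export
n_samples <- function(geno) nrow(geno$dosages)

#' @rdname n_samples
#' @export
n_markers <- function(geno) ncol(geno$dosages)

#' Subset a genotype panel
#'
#' @param geno a `geno_matrix`.
#' @param samples logical/integer/character index over samples (optional).
#' @param markers logical/integer/character index over markers (optional).
#' @return the subset `geno_matrix`.
#' @export
subset_geno <- function(geno, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(geno)) else samples
  mi <- if (is.null(markers)) seq_len(n_markers(geno)) else markers
  if (is.character(si)) si <- match(si, geno$samples$sample_id)
  if (is.character(mi)) mi <- match(mi, geno$map$marker_id)
  map <- geno$map[mi, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("marker_map", "data.frame")
  geno_matrix(geno$dosages[si, mi, drop = FALSE],
              geno$samples[si, , drop = FALSE],
              map)
}
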