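#' Euclidean distance between populations on allele frequencies
#'
#' d(a, b) = sqrt(sum over markers of (p_am - p_bm)^2), computed over the
#' markers whose frequency is defined in every population; markers with any
#' undefined (NA) population frequency are dropped and their count
#' reported via a message.
#'
#' @param freqs markers x populations frequency matrix, e.g. from
#'   [allele_frequencies()] with `by_breed = TRUE`.
#' @return symmetric distance matrix (class `matrix`), zero diagonal.
#' @export
population_distance <- function(freqs) {
  if (ncol(freqs) < 2) stop("need at least 2 populations")
  keep <- stats::complete.cases(freqs)
  if (any(!keep))
    message(sum(!keep), " marker(s) with undefined frequency dropped")
  f <- freqs[keep, , drop = FALSE]
  as.matrix(stats::dist(t(f), method = "euclidean"))
}

#' Neighbor-joining tree from a population distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]. Negative branch lengths
#' (possible for non-additive input) are clamped to zero, with a message
#' recording how many were clamped.
#'
#' @param dist_matrix symmetric distance matrix with labeled rows/columns
#'   (>= 3 populations).
#' @return an [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) < 3) stop("need at least 3 populations")
  if (max(abs(dist_matrix - t(dist_matrix))) > 1e-8)
    stop("distance matrix is not symmetric")
  tr <- ape::nj(stats::as.dist(dist_matrix))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Principal component analysis of a genotype panel
#'
#' Missing dosages are mean-imputed per marker; zero-variance markers are
#' dropped; components come from the eigen-decomposition of the
#' column-centered dosage covariance (optionally unit-variance
#' standardized). Sign convention: each component is flipped so its
#' largest-magnitude marker loading is positive.
#'
#' @param geno a [geno_matrix()].
#' @param n_components number of components to return.
#' @param standardize scale markers to unit variance before decomposition.
#' @return list of class `geno_pca`: `scores` (samples x components),
#'   `explained` (variance fractions), `breed` (per-sample labels),
#'   `loadings`.
#' @export
genotype_pca <- function(geno, n_components = 2, standardize = FALSE) {
  d <- geno$dosages
  storage.mode(d) <- "double"
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  v <- apply(d, 2, stats::var)
  keep <- which(is.finite(v) & v > 1e-12)
  d <- d[, keep, drop = FALSE]
  maxrank <- min(nrow(d) - 1L, ncol(d))
  if (n_components > maxrank) {
    warning("n_components reduced to rank ", maxrank)
    n_components <- maxrank
  }
  pc <- stats::prcomp(d, center = TRUE, scale. = standardize)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    l <- load[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, `*`)
  load <- sweep(load, 2, flip, `*`)
  structure(list(scores = scores,
                 explained = (pc$sdev^2 / sum(pc$sdev^2))[k],
                 breed = geno$samples$breed,
                 loadings = load),
            class = "geno_pca")
}

#' Greedy LD pruning
#'
#' Plumbing for structure analyses: walks each chromosome left to right
#' and drops any marker whose composite r2 with a kept marker inside the
#' trailing window exceeds the threshold.
#'
#' @param geno a [geno_matrix()].
#' @param r2_max prune threshold.
#' @param window_kb trailing window width in kb.
#' @return a pruned [geno_matrix()].
#' @export
ld_prune <- function(geno, r2_max = 0.2, window_kb = 1000) {
  d <- geno$dosages
  storage.mode(d) <- "double"
  keep <- logical(n_markers(geno))
  for (chr in unique(geno$map$chromosome)) {
    idx <- which(geno$map$chromosome == chr)
    pos <- geno$map$position_bp[idx]
    kept <- integer()
    for (j in seq_along(idx)) {
      inwin <- kept[pos[kept] >= pos[j] - window_kb * 1000]
      ok <- TRUE
      for (k in inwin) {
        r <- suppressWarnings(stats::cor(d[, idx[j]], d[, idx[k]],
                                         use = "pairwise.complete.obs"))
        if (is.finite(r) && r^2 > r2_max) { ok <- FALSE; break }
      }
      if (ok) kept <- c(kept, j)
    }
    keep[idx[kept]] <- TRUE
  }
  subset_geno(geno, markers = which(keep))
}
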