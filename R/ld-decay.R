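#' Pairwise composite r2 within a distance window
#'
#' For every same-chromosome marker pair at most `max_snp_sep` index
#' positions apart AND at most `max_dist_kb` kilobases apart, computes the
#' squared Pearson correlation of the two dosage vectors over samples
#' non-missing at both markers (composite / Rogers-Huff r2 for unphased
#' genotypes). Pairs where either marker has zero dosage variance over the
#' shared samples are skipped.
#'
#' The defaults mirror a short-range scan (adjacent-ish pairs within 1 Mb);
#' the effective-population-size module calls this with a much wider window.
#'
#' @param geno a [geno_matrix()].
#' @param max_dist_kb maximum pair distance in kb.
#' @param max_snp_sep maximum index separation between the two markers.
#' @param population label attached to the pair set (default: the panel's
#'   single breed, or "ALL").
#' @return an `ld_pairs` data.frame: `chr`, `snp_a`, `bp_a`, `snp_b`,
#'   `bp_b`, `dist_bp`, `r2`. Empty (with a warning) when no pair
#'   qualifies.
#' @export
pairwise_r2 <- function(geno, max_dist_kb = 1000, max_snp_sep = 5,
                        population = NULL) {
  if (is.null(population)) {
    b <- unique(geno$samples$breed)
    population <- if (length(b) == 1) b else "ALL"
  }
  d <- geno$dosages
  storage.mode(d) <- "double"
  map <- geno$map
  max_dist_bp <- max_dist_kb * 1000
  out <- list()
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    m <- length(idx)
    if (m < 2) next
    pos <- map$position_bp[idx]
    ids <- map$marker_id[idx]
    D <- d[, idx, drop = FALSE]
    obs <- !is.na(D)
    D0 <- D
    D0[!obs] <- 0
    for (s in seq_len(min(max_snp_sep, m - 1L))) {
      j <- seq_len(m - s)
      dist <- pos[j + s] - pos[j]
      keep <- dist <= max_dist_bp
      if (!any(keep)) next
      j <- j[keep]
      A <- D0[, j, drop = FALSE];  B <- D0[, j + s, drop = FALSE]
      Ma <- obs[, j, drop = FALSE]; Mb <- obs[, j + s, drop = FALSE]
      M <- Ma & Mb
      A[!M] <- 0; B[!M] <- 0
      n <- colSums(M)
      sx <- colSums(A);      sy <- colSums(B)
      sxx <- colSums(A * A); syy <- colSums(B * B)
      sxy <- colSums(A * B)
      vx <- sxx - sx^2 / n
      vy <- syy - sy^2 / n
      cv <- sxy - sx * sy / n
      ok <- n >= 2 & vx > 1e-12 & vy > 1e-12
      if (!any(ok)) next
      r2 <- (cv[ok]^2) / (vx[ok] * vy[ok])
      out[[length(out) + 1L]] <- data.frame(
        chr = chr,
        snp_a = ids[j[ok]], bp_a = pos[j[ok]],
        snp_b = ids[j[ok] + s], bp_b = pos[j[ok] + s],
        dist_bp = pos[j[ok] + s] - pos[j[ok]],
        r2 = pmin(1, r2),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    warning("no qualifying marker pairs in window (", max_dist_kb, " kb, ",
            max_snp_sep, " SNPs)")
    res <- data.frame(chr = character(), snp_a = character(), bp_a = numeric(),
                      snp_b = character(), bp_b = numeric(),
                      dist_bp = numeric(), r2 = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(match(res$chr, unique(map$chromosome)), res$bp_a, res$bp_b), ]
    rownames(res) <- NULL
  }
  class(res) <- c("ld_pairs", "data.frame")
  attr(res, "population") <- population
  res
}

#' Fit Sved's LD-decay model to a pair cloud
#'
#' Nonlinear least squares of r2 on 1 / (1 + 4 beta d), d in bp, via
#' [stats::nls()] (algorithm "port", beta bounded below by 1e-12). Starting
#' value beta0 = 1 / (4 x median distance), which makes the starting curve
#' pass mid-cloud; on failure up to 5 restarts at log-spaced perturbations
#' (beta0 x 10^{-2,-1,1,2, 0.5}). Residuals are treated as homoscedastic
#' Gaussian; the SE is the asymptotic one from the fit (0 for a noiseless,
#' exactly-fitting cloud).
#'
#' @param pairs an `ld_pairs` data.frame (needs `dist_bp`, `r2`).
#' @param population label override.
#' @return list of class `sved_fit`: `beta_hat`, `se`, `residual_sd`,
#'   `n_pairs`, `population`, `converged`.
#' @export
fit_sved <- function(pairs, population = NULL) {
  if (is.null(population))
    population <- attr(pairs, "population") %||% "ALL"
  d <- pairs$dist_bp
  r2 <- pairs$r2
  if (length(d) < 3) stop("need at least 3 pairs to fit")
  if (length(unique(d)) < 2)
    stop("degenerate pair set: all distances identical")
  beta0 <- 1 / (4 * stats::median(d))
  starts <- beta0 * c(1, 10^c(-2, -1, 1, 2, 0.5))
  fit <- NULL
  errs <- character()
  for (b0 in starts) {
    fit <- tryCatch(
      stats::nls(r2 ~ 1 / (1 + 4 * beta * d),
                 data = data.frame(d = d, r2 = r2),
                 start = list(beta = b0),
                 algorithm = "port", lower = c(beta = 1e-12),
                 control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                              warnOnly = FALSE)),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("Sved fit failed after ", length(starts), " starts: ",
         paste(unique(errs), collapse = " | "))
  sm <- summary(fit)
  structure(list(beta_hat = unname(stats::coef(fit)["beta"]),
                 se = unname(sm$coefficients["beta", "Std. Error"]),
                 residual_sd = sm$sigma,
                 n_pairs = length(d),
                 population = population,
                 converged = TRUE),
            class = "sved_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sved_fit <- function(x, ...) {
  cat(sprintf("Sved fit [%s]: beta = %.4g (SE %.3g), residual SD %.3g, %d pairs\n",
              x$population, x$beta_hat, x$se, x$residual_sd, x$n_pairs))
  invisible(x)
}

#' Pairwise equality test of LD-decay curves
#'
#' Wald test on the decay coefficients: z = (beta_a - beta_b) /
#' sqrt(SE_a^2 + SE_b^2), two-sided normal p-value, Bonferroni-adjusted
#' across the choose(k, 2) pairs.
#'
#' @param fits list of `sved_fit` objects (>= 2), each with a finite SE.
#' @return list of class `curve_comparison`: matrices `z`, `p_raw`,
#'   `p_adj` (symmetric, diagonal p = 1), `method = "bonferroni"`.
#' @export
curve_equality_test <- function(fits) {
  if (length(fits) < 2) stop("need at least 2 fits")
  beta <- vapply(fits, `[[`, numeric(1), "beta_hat")
  se <- vapply(fits, `[[`, numeric(1), "se")
  labs <- vapply(fits, `[[`, character(1), "population")
  if (any(!is.finite(se)) || any(se < 0))
    stop("non-finite or negative SE in fits: ",
         paste(labs[!is.finite(se) | se < 0], collapse = ", "))
  k <- length(beta)
  z <- outer(beta, beta, "-") / sqrt(outer(se^2, se^2, "+"))
  diag(z) <- 0
  p <- 2 * stats::pnorm(-abs(z))
  diag(p) <- 1
  npair <- k * (k - 1) / 2
  padj <- matrix(pmin(1, p * npair), k, k)
  diag(padj) <- 1
  dimnames(z) <- dimnames(p) <- dimnames(padj) <- list(labs, labs)
  structure(list(z = z, p_raw = p, p_adj = padj, method = "bonferroni",
                 n_tests = npair),
            class = "curve_comparison")
}

#' Cluster populations on their LD-decay coefficients
#'
#' Agglomerative clustering of the scalar beta-hat values: Euclidean
#' distance, Ward linkage (`hclust` method "ward.D2"). `k` may be fixed or
#' chosen by maximum average silhouette width over k in [2, min(8, n-1)].
#' Ties in beta are resolved by input order (deterministic).
#'
#' @param fits list of `sved_fit` objects, or a named numeric vector of
#'   beta values.
#' @param k number of clusters, or `"auto"`.
#' @return list of class `beta_clustering`: `hclust` (the tree), `k`,
#'   `cluster` (named assignment), `beta`, `silhouette` (average widths per
#'   candidate k when `k = "auto"`).
#' @export
cluster_breeds <- function(fits, k = "auto") {
  beta <- if (is.numeric(fits)) fits
          else stats::setNames(vapply(fits, `[[`, numeric(1), "beta_hat"),
                               vapply(fits, `[[`, character(1), "population"))
  n <- length(beta)
  if (n < 2) stop("need at least 2 populations")
  dd <- stats::dist(beta)
  hc <- stats::hclust(dd, method = "ward.D2")
  sil <- NULL
  if (identical(k, "auto")) {
    if (n <= 3) {
      k <- 2L    # silhouette needs >= 2 non-trivial clusterings to compare
    } else {
      ks <- 2:min(8, n - 1)
      sil <- vapply(ks, function(kk) {
        mean(cluster::silhouette(stats::cutree(hc, k = kk), dd)[, "sil_width"])
      }, numeric(1))
      names(sil) <- ks
      k <- ks[which.max(sil)]
    }
  }
  cl <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, k = as.integer(k), cluster = cl, beta = beta,
                 silhouette = sil),
            class = "beta_clustering")
}

#' Export a hierarchical clustering as a newick string
#'
#' Merge heights become branch lengths (via [ape::as.phylo()]).
#'
#' @param clustering a `beta_clustering` from [cluster_breeds()] (or a raw
#'   `hclust`).
#' @param file optional path to write to.
#' @return the newick string, invisibly when written to file.
#' @export
clustering_newick <- function(clustering, file = NULL) {
  hc <- if (inherits(clustering, "hclust")) clustering else clustering$hclust
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
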