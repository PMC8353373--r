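#' Mean r2 by genetic-distance bin
#'
#' Pair distances are converted from bp to Morgan under the 1 Mb = 1 cM
#' convention (d_morgan = d_bp x 1e-8) and grouped into four bins:
#' (0, e1], (e1, e2], (e2, e3], (e3, cap] with default edges 0.01, 0.03,
#' 0.05 Morgan and cap 0.125 Morgan (12.5 Mb). The bin means feed the
#' Ne-per-generation mapping: a bin's representative distance c gives the
#' generation T = 1/(2c).
#'
#' @param pairs an `ld_pairs` data.frame; the source scan must extend to at
#'   least the cap (a much wider window than the short-range LD-decay
#'   default).
#' @param bin_edges_morgan three inner bin edges, Morgan.
#' @param cap_morgan upper cap of the open-ended last bin, Morgan.
#' @return data.frame: `bin`, `c_lo`, `c_hi`, `mean_r2`, `n_pairs`; empty
#'   bins carry `mean_r2 = NA` and `n_pairs = 0`.
#' @export
bin_mean_r2 <- function(pairs, bin_edges_morgan = c(0.01, 0.03, 0.05),
                        cap_morgan = 0.125) {
  stopifnot(length(bin_edges_morgan) == 3,
            all(diff(c(0, bin_edges_morgan, cap_morgan)) > 0))
  d <- pairs$dist_bp * 1e-8
  edges <- c(0, bin_edges_morgan, cap_morgan)
  idx <- findInterval(d, edges, left.open = TRUE, rightmost.closed = FALSE)
  idx[d > cap_morgan | d <= 0] <- NA
  out <- data.frame(bin = 1:4,
                    c_lo = edges[1:4], c_hi = edges[2:5],
                    mean_r2 = NA_real_, n_pairs = 0L)
  for (b in 1:4) {
    sel <- which(idx == b)
    out$n_pairs[b] <- length(sel)
    if (length(sel)) out$mean_r2[b] <- mean(pairs$r2[sel])
  }
  out
}

#' Effective population size at one genetic distance
#'
#' Ne = (1 / (4c)) (1 / mean_r2 - 1), reflecting the population
#' T = 1/(2c) generations in the past. No sampling-size correction is
#' applied to mean_r2.
#'
#' @param c_morgan marker distance in Morgan (> 0).
#' @param mean_r2 mean r2 at that distance, in (0, 1].
#' @return list with `T` (generations) and `Ne`.
#' @export
ne_at <- function(c_morgan, mean_r2) {
  stopifnot(c_morgan > 0)
  if (any(mean_r2 <= 0))
    stop("mean_r2 must be > 0: Ne is infinite at r2 = 0")
  if (any(mean_r2 > 1)) stop("mean_r2 must be <= 1")
  list(T = 1 / (2 * c_morgan),
       Ne = (1 / (4 * c_morgan)) * (1 / mean_r2 - 1))
}

#' Ne trajectory across past generations from a genotype panel
#'
#' Runs a wide-window pair scan (out to the cap distance), bins mean r2 by
#' genetic distance via [bin_mean_r2()], and converts each bin to an
#' effective population size at the bin's representative distance
#' c = 0.01, 0.03, 0.05, 0.1 Morgan (generations T = 50, 16.6, 10, 5).
#' Representative distances are fixed at 1/(2T), not the empirical mean
#' pair distance, so the generation labels are exact. Bins with no pairs
#' yield `NA` rows rather than fabricated values.
#'
#' @param geno a [geno_matrix()] (expected to have passed QC).
#' @param bin_edges_morgan,cap_morgan as in [bin_mean_r2()].
#' @param rep_c_morgan representative distance per bin, Morgan.
#' @param max_snp_sep index-separation limit passed to the wide scan.
#' @param pairs optionally, a precomputed wide-window `ld_pairs` set (skips
#'   the scan).
#' @return data.frame of class `ne_trajectory`: `population`, `T`,
#'   `c_morgan`, `mean_r2`, `n_pairs`, `Ne`; attribute `delta_ne` =
#'   Ne(T=50) - Ne(T=5).
#' @export
ne_trajectory <- function(geno = NULL, bin_edges_morgan = c(0.01, 0.03, 0.05),
                          cap_morgan = 0.125,
                          rep_c_morgan = c(0.01, 0.03, 0.05, 0.1),
                          max_snp_sep = 10000, pairs = NULL) {
  stopifnot(length(rep_c_morgan) == 4)
  if (is.null(pairs)) {
    if (is.null(geno)) stop("need a geno_matrix or a precomputed pair set")
    pairs <- pairwise_r2(geno, max_dist_kb = cap_morgan * 1e5,
                         max_snp_sep = max_snp_sep)
  }
  pop <- attr(pairs, "population") %||% "ALL"
  bins <- bin_mean_r2(pairs, bin_edges_morgan, cap_morgan)
  Ne <- rep(NA_real_, 4)
  ok <- !is.na(bins$mean_r2) & bins$mean_r2 > 0
  if (any(ok))
    Ne[ok] <- (1 / (4 * rep_c_morgan[ok])) * (1 / bins$mean_r2[ok] - 1)
  out <- data.frame(population = pop,
                    T = 1 / (2 * rep_c_morgan),
                    c_morgan = rep_c_morgan,
                    mean_r2 = bins$mean_r2,
                    n_pairs = bins$n_pairs,
                    Ne = Ne,
                    stringsAsFactors = FALSE)
  class(out) <- c("ne_trajectory", "data.frame")
  attr(out, "delta_ne") <- Ne[1] - Ne[4]
  out
}
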