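#' Simulation configuration
#'
#' Parameters of the forward Wright-Fisher simulator. Genetic length is
#' physical length times `recomb_rate` (default 1e-8 Morgan/bp, i.e.
#' 1 cM/Mb, the same convention the analysis modules assume).
#'
#' @param effective_size diploid population size N (>= 2), constant over the
#'   run; piecewise-N histories are composed by chaining runs via
#'   [simulate_population()]'s `founders` argument.
#' @param sample_n number of diploids to draw at the end (<= N).
#' @param n_chromosomes,chromosome_length_bp genome layout (equal-length
#'   chromosomes).
#' @param marker_spacing_bp uniform inter-marker spacing.
#' @param generations number of Wright-Fisher generations; 0 returns the
#'   founder draw itself (Hardy-Weinberg, allele frequency 0.5).
#' @param recomb_rate Morgan per bp.
#' @param missing_rate fraction of calls masked to missing, in [0, 1).
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(effective_size = 100, sample_n = 50,
                       n_chromosomes = 10, chromosome_length_bp = 26e6,
                       marker_spacing_bp = 1e6, generations = 100,
                       recomb_rate = 1e-8, missing_rate = 0, seed = 1) {
  cfg <- list(effective_size = as.integer(effective_size),
              sample_n = as.integer(sample_n),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              marker_spacing_bp = as.numeric(marker_spacing_bp),
              generations = as.integer(generations),
              recomb_rate = as.numeric(recomb_rate),
              missing_rate = as.numeric(missing_rate),
              seed = as.integer(seed))
  stopifnot(cfg$effective_size >= 2, cfg$sample_n >= 1,
            cfg$n_chromosomes >= 1, cfg$chromosome_length_bp > 0,
            cfg$marker_spacing_bp > 0, cfg$generations >= 0,
            cfg$recomb_rate >= 0, cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (cfg$sample_n > cfg$effective_size)
    stop("sample_n (", cfg$sample_n, ") exceeds effective_size (",
         cfg$effective_size, "): cannot sample more diploids than the population")
  class(cfg) <- "sim_config"
  cfg
}

# one meiosis over one chromosome: recombine haplotypes hapA/hapB at
# marker genetic positions mpos (Morgan), chromosome genetic length L
.meiosis <- function(hapA, hapB, mpos, L, k, start) {
  if (k == 0L) return(if (start == 0L) hapA else hapB)
  xp <- sort(stats::runif(k)) * L
  use <- (findInterval(mpos, xp) + start) %% 2L
  ifelse(use == 0L, hapA, hapB)
}

#' Forward Wright-Fisher simulation of a diploid genotype panel
#'
#' Founder gametes carry allele frequency 0.5 per marker (no mutation;
#' standing variation only). Each generation, 2N gametes are formed by
#' recombining the two haplotypes of a randomly chosen parent: crossover
#' count ~ Poisson(chromosome genetic length), crossover positions uniform,
#' no interference; chromosomes assort independently. After `generations`
#' rounds, `sample_n` diploids are drawn without replacement and missing
#' calls are masked at `missing_rate`. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param breed breed label to give the sampled individuals.
#' @param founders optional haplotype set (the `haplotypes` attribute of a
#'   previous run) to start from instead of a fresh founder draw; used to
#'   chain epochs with different N. Haplotypes are resampled with
#'   replacement if the new N differs.
#' @return a [geno_matrix()]; the terminal haplotype pool is attached as
#'   attribute `haplotypes` (a list of 2N x markers 0/1 matrices per
#'   chromosome) so epochs can be chained.
#' @export
simulate_population <- function(cfg, breed = "SIM", founders = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  N <- cfg$effective_size
  nhap <- 2L * N
  pos_bp <- seq(cfg$marker_spacing_bp, cfg$chromosome_length_bp,
                by = cfg$marker_spacing_bp)
  mc <- length(pos_bp)
  if (mc < 1) stop("no markers fit on a chromosome; reduce marker_spacing_bp")
  mpos <- pos_bp * cfg$recomb_rate
  L <- cfg$chromosome_length_bp * cfg$recomb_rate

  H <- vector("list", cfg$n_chromosomes)
  for (c in seq_len(cfg$n_chromosomes)) {
    if (is.null(founders)) {
      H[[c]] <- matrix(stats::rbinom(nhap * mc, 1L, 0.5), nhap, mc)
    } else {
      src <- founders[[c]]
      if (ncol(src) != mc) stop("founder haplotypes do not match marker layout")
      idx <- if (nrow(src) == nhap) seq_len(nhap)
             else sample.int(nrow(src), nhap, replace = TRUE)
      H[[c]] <- src[idx, , drop = FALSE]
    }
  }

  for (t in seq_len(cfg$generations)) {
    par <- sample.int(N, nhap, replace = TRUE)
    rowA <- 2L * par - 1L
    rowB <- 2L * par
    for (c in seq_len(cfg$n_chromosomes)) {
      Hc <- H[[c]]
      k <- stats::rpois(nhap, L)
      start <- sample(c(0L, 1L), nhap, replace = TRUE)
      New <- Hc[ifelse(start == 0L, rowA, rowB), , drop = FALSE]
      for (g in which(k > 0L))
        New[g, ] <- .meiosis(Hc[rowA[g], ], Hc[rowB[g], ], mpos, L, k[g], start[g])
      H[[c]] <- New
    }
  }

  take <- sample.int(N, cfg$sample_n)
  dos <- do.call(cbind, lapply(H, function(Hc)
    Hc[2L * take - 1L, , drop = FALSE] + Hc[2L * take, , drop = FALSE]))
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(dos)) < cfg$missing_rate
    dos[mask] <- NA_integer_
  }
  map <- marker_map(
    marker_id = paste0("chr", rep(seq_len(cfg$n_chromosomes), each = mc),
                       "_", rep(seq_len(mc), cfg$n_chromosomes)),
    chromosome = as.character(rep(seq_len(cfg$n_chromosomes), each = mc)),
    position_bp = rep(pos_bp, cfg$n_chromosomes))
  g <- geno_matrix(dos,
                   data.frame(sample_id = sprintf("%s_%03d", breed, seq_len(cfg$sample_n)),
                              breed = breed, stringsAsFactors = FALSE),
                   map)
  attr(g, "haplotypes") <- H
  g
}

#' Implant a homozygous tract into a genotype panel
#'
#' For `ceiling(carrier_fraction * n)` samples (the first that many after a
#' seeded shuffle, so tests can enumerate the carriers), every marker in
#' `[start_bp, end_bp]` on `chromosome` is set homozygous for the major
#' allele of the panel at that marker. Genotypes outside the region, and in
#' non-carrier samples, are untouched.
#'
#' @param geno a [geno_matrix()].
#' @param chromosome chromosome label of the tract.
#' @param start_bp,end_bp tract bounds, 1-based inclusive, start < end.
#' @param carrier_fraction fraction of samples to implant, in (0, 1].
#' @param seed seed for the carrier shuffle.
#' @return the modified [geno_matrix()], with the carrier ids in attribute
#'   `carriers`.
#' @export
implant_roh <- function(geno, chromosome, start_bp, end_bp,
                        carrier_fraction = 0.7, seed = 1) {
  stopifnot(start_bp < end_bp, carrier_fraction > 0, carrier_fraction <= 1)
  inreg <- geno$map$chromosome == as.character(chromosome) &
    geno$map$position_bp >= start_bp & geno$map$position_bp <= end_bp
  if (!any(inreg))
    stop("region ", chromosome, ":", start_bp, "-", end_bp, " contains no markers")
  n <- n_samples(geno)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  carriers <- sample.int(n)[seq_len(ceiling(carrier_fraction * n))]
  p <- allele_frequencies(geno)[, 1]
  hom_major <- ifelse(!is.na(p) & p > 0.5, 2L, 0L)   # dosage of major-allele homozygote
  for (j in which(inreg))
    geno$dosages[carriers, j] <- hom_major[j]
  attr(geno, "carriers") <- geno$samples$sample_id[sort(carriers)]
  geno
}

#' Generate a (distance, r-squared) pair cloud on Sved's curve
#'
#' r2 = 1 / (1 + 4 beta d) + e, e ~ N(0, noise_sd^2), truncated into
#' [0, 1]. Distances are in bp, so beta has units 1/bp.
#'
#' @param beta decay coefficient (> 0), per bp.
#' @param distances_bp positive pair distances.
#' @param noise_sd additive Gaussian noise SD (0 = points exactly on the
#'   curve).
#' @param seed integer RNG seed.
#' @param population population label carried by the pair set.
#' @return an `ld_pairs` data.frame (columns `chr`, `snp_a`, `bp_a`,
#'   `snp_b`, `bp_b`, `dist_bp`, `r2`) with attribute `population`.
#' @export
sved_pair_generator <- function(beta, distances_bp, noise_sd = 0, seed = 1,
                                population = "SIM") {
  stopifnot(beta > 0, all(distances_bp >= 0), noise_sd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  d <- as.numeric(distances_bp)
  r2 <- 1 / (1 + 4 * beta * d)
  if (noise_sd > 0) r2 <- r2 + stats::rnorm(length(d), 0, noise_sd)
  r2 <- pmin(1, pmax(0, r2))
  out <- data.frame(chr = "1",
                    snp_a = paste0("g", seq_along(d), "a"),
                    bp_a = 1,
                    snp_b = paste0("g", seq_along(d), "b"),
                    bp_b = 1 + d,
                    dist_bp = d,
                    r2 = r2,
                    stringsAsFactors = FALSE)
  class(out) <- c("ld_pairs", "data.frame")
  attr(out, "population") <- population
  out
}
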