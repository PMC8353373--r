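# Fixtures and independent brute-force oracles used across the suite.

# small panel built directly from a dosage matrix
toy_geno <- function(dos, breed = "TST", chr = NULL, pos = NULL) {
  dos <- as.matrix(dos)
  m <- ncol(dos)
  if (is.null(chr)) chr <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1e5
  geno_matrix(dos,
              data.frame(sample_id = paste0("s", seq_len(nrow(dos))),
                         breed = breed),
              marker_map(paste0("m", seq_len(m)), chr, pos))
}

# write a PED/MAP pair from allele-character matrices (n x 2m alleles)
write_toy_ped <- function(dir, alleles, fid = "F1", chr = NULL, pos = NULL) {
  n <- nrow(alleles); m <- ncol(alleles) / 2
  if (is.null(chr)) chr <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  ped <- file.path(dir, "toy.ped"); mp <- file.path(dir, "toy.map")
  writeLines(vapply(seq_len(n), function(i)
    paste(c(fid, paste0("S", i), 0, 0, 0, -9, alleles[i, ]), collapse = " "),
    character(1)), ped)
  writeLines(sprintf("%s\tm%d\t0\t%d", chr, seq_len(m), pos), mp)
  list(ped = ped, map = mp)
}

# brute-force window scores: enumerate every window explicitly
oracle_window_scores <- function(dos, params) {
  m <- length(dos)
  w <- min(params$window_snp, m)
  nwin <- m - w + 1L
  hom <- logical(nwin)
  for (s in seq_len(nwin)) {
    win <- dos[s:(s + w - 1L)]
    hom[s] <- sum(win == 1L, na.rm = TRUE) <= params$window_het_max &&
      sum(is.na(win)) <= params$window_missing_max
  }
  vapply(seq_len(m), function(j) {
    ws <- max(1L, j - w + 1L):min(j, nwin)
    mean(hom[ws])
  }, numeric(1))
}

# brute-force single-chromosome segment caller from oracle scores
oracle_call_roh_1chr <- function(dos, pos, params) {
  sc <- oracle_window_scores(dos, params)
  hit <- which(sc > params$window_hit_threshold)
  if (length(hit) == 0) return(NULL)
  segs <- list()
  run <- hit[1]
  for (j in hit[-1]) {
    if (j == run[length(run)] + 1 &&
        pos[j] - pos[run[length(run)]] <= params$max_gap_kb * 1000) {
      run <- c(run, j)
    } else {
      segs[[length(segs) + 1]] <- run
      run <- j
    }
  }
  segs[[length(segs) + 1]] <- run
  out <- do.call(rbind, lapply(segs, function(r)
    data.frame(start_bp = pos[r[1]], end_bp = pos[r[length(r)]],
               n_snp = length(r))))
  out$length_bp <- out$end_bp - out$start_bp
  out[out$length_bp >= params$min_length_kb * 1000 &
        out$n_snp >= params$min_snp, , drop = FALSE]
}

# brute-force per-marker ROH incidence over a sample set
oracle_incidence <- function(segments, map, sample_ids) {
  vapply(seq_len(nrow(map)), function(j) {
    p <- map$position_bp[j]; ch <- map$chromosome[j]
    mean(vapply(sample_ids, function(s)
      any(segments$sample_id == s & segments$chr == ch &
            segments$start_bp <= p & segments$end_bp >= p), logical(1)))
  }, numeric(1))
}

# grid-search oracle for the Sved decay coefficient
oracle_sved_grid <- function(d, r2, n_grid = 1e5,
                             lo = 1e-7, hi = 1e-3) {
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  best_rss <- Inf; best <- NA_real_
  for (chunk in split(grid, ceiling(seq_along(grid) / 1000))) {
    pred <- 1 / (1 + 4 * outer(chunk, d))       # n_chunk x n_pairs
    rss <- rowSums((sweep(-pred, 2, r2, `+`))^2)
    i <- which.min(rss)
    if (rss[i] < best_rss) { best_rss <- rss[i]; best <- chunk[i] }
  }
  best
}

# two-epoch Wright-Fisher run: N1 for g1 generations, then N2 for g2
simulate_two_epoch <- function(N1, g1, N2, g2, sample_n, seed,
                               n_chromosomes = 10, chromosome_length_bp = 26e6,
                               marker_spacing_bp = 1e6) {
  c1 <- sim_config(effective_size = N1, sample_n = N1,
                   n_chromosomes = n_chromosomes,
                   chromosome_length_bp = chromosome_length_bp,
                   marker_spacing_bp = marker_spacing_bp,
                   generations = g1, seed = seed)
  old <- simulate_population(c1)
  c2 <- sim_config(effective_size = N2, sample_n = sample_n,
                   n_chromosomes = n_chromosomes,
                   chromosome_length_bp = chromosome_length_bp,
                   marker_spacing_bp = marker_spacing_bp,
                   generations = g2, seed = seed + 1)
  simulate_population(c2, founders = attr(old, "haplotypes"))
}
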