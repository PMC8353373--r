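test_that("window scores match the brute-force enumerator", {
  par <- roh_params(min_length_kb = 100, min_snp = 10)
  map200 <- marker_map(paste0("m", 1:200), rep("1", 200), (1:200) * 25e3)

  # all homozygous -> every marker scores 1; all het -> 0
  expect_equal(window_scan(rep(0L, 200), map200, par), rep(1, 200))
  expect_equal(window_scan(rep(1L, 200), map200, par), rep(0, 200))

  # two adjacent hets at index 100/101: exact agreement with enumerator
  dos <- rep(0L, 200); dos[100:101] <- 1L
  expect_equal(window_scan(dos, map200, par), oracle_window_scores(dos, par))
  # the dip is real: markers covered only by >=2-het windows score lower
  sc <- window_scan(dos, map200, par)
  expect_lt(min(sc), 1)

  # random panels with missingness, several window shapes
  set.seed(14)
  for (i in 1:10) {
    n <- sample(30:500, 1)
    dos <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                  prob = c(0.45, 0.08, 0.45, 0.02))
    mm <- marker_map(paste0("x", 1:n), rep("1", n), sort(sample(1e7, n)))
    p2 <- roh_params(window_snp = sample(c(10, 25, 50), 1),
                     window_het_max = sample(0:2, 1),
                     window_missing_max = sample(1:5, 1),
                     min_length_kb = 100, min_snp = 5)
    expect_equal(window_scan(dos, mm, p2), oracle_window_scores(dos, p2))
  }
})

test_that("chromosomes shorter than the window use the truncated window", {
  par <- roh_params()
  mm <- marker_map(paste0("m", 1:20), rep("1", 20), (1:20) * 1e5)
  sc <- window_scan(rep(0L, 20), mm, par)
  expect_equal(sc, rep(1, 20))
  sc2 <- window_scan(c(rep(0L, 18), 1L, 1L), mm, par)
  expect_equal(sc2, rep(0, 20))   # single 20-SNP window has 2 hets
})

test_that("called segments match a brute-force caller on small panels", {
  set.seed(15)
  par <- roh_params(window_snp = 20, min_length_kb = 500, min_snp = 25,
                    max_gap_kb = 500)
  for (i in 1:8) {
    n <- sample(100:500, 1)
    dos <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                  prob = c(0.46, 0.06, 0.46, 0.02))
    # implant a clean homozygous stretch to guarantee some segments
    a <- sample(n - 60, 1)
    dos[a:(a + 59)] <- 0L
    pos <- sort(sample(2e7, n))
    g <- toy_geno(matrix(dos, 1), pos = pos)
    segs <- call_roh(g, par)
    oracle <- oracle_call_roh_1chr(dos, pos, par)
    if (is.null(oracle)) {
      expect_equal(nrow(segs), 0L)
    } else {
      expect_equal(nrow(segs), nrow(oracle))
      expect_equal(segs$start_bp, oracle$start_bp)
      expect_equal(segs$end_bp, oracle$end_bp)
      expect_equal(segs$n_snp, oracle$n_snp)
    }
  }
})

test_that("every emitted segment satisfies the caller's thresholds", {
  cfg <- sim_config(effective_size = 30, sample_n = 30, n_chromosomes = 2,
                    chromosome_length_bp = 10e6, marker_spacing_bp = 25e3,
                    generations = 30, missing_rate = 0.01, seed = 91)
  g <- simulate_population(cfg)
  par <- roh_params(min_length_kb = 300, min_snp = 15)
  segs <- call_roh(g, par)
  expect_gt(nrow(segs), 0)
  expect_true(all(segs$length_bp >= par$min_length_kb * 1000))
  expect_true(all(segs$n_snp >= par$min_snp))
  expect_true(all(segs$end_bp > segs$start_bp))
  expect_equal(segs$length_bp, segs$end_bp - segs$start_bp)

  # sample-order invariance
  perm <- rev(seq_len(n_samples(g)))
  segs2 <- call_roh(subset_geno(g, samples = perm), par)
  o1 <- segs[order(segs$sample_id, segs$chr, segs$start_bp), -c(1:2)]
  o2 <- segs2[order(segs2$sample_id, segs2$chr, segs2$start_bp), -c(1:2)]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("gap splitting and the minimum-length rule apply per piece", {
  # homozygous run bisected by a 1.2 Mb gap: two pieces, each judged alone
  pos <- c((1:100) * 25e3, 1.2e6 + 2.5e6 + (1:100) * 25e3)
  mm <- marker_map(paste0("m", 1:200), rep("1", 200), pos)
  dos <- rep(0L, 200)
  par <- roh_params(window_snp = 20, min_length_kb = 1000, min_snp = 50,
                    max_gap_kb = 1000)
  g <- geno_matrix(matrix(dos, 1), data.frame(sample_id = "s1", breed = "T"), mm)
  segs <- call_roh(g, par)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$n_snp, c(100L, 100L))
  # each piece spans 99 * 25 kb = 2.475 Mb >= 1 Mb, so both survive
  expect_equal(segs$length_bp, c(2475e3, 2475e3))

  # a 900 kb homozygous run is below the 1 Mb minimum -> nothing
  mm2 <- marker_map(paste0("k", 1:37), rep("1", 37), (1:37) * 25e3)
  g2 <- geno_matrix(matrix(rep(0L, 37), 1),
                    data.frame(sample_id = "s1", breed = "T"), mm2)
  expect_equal(nrow(call_roh(g2, roh_params(window_snp = 10, min_snp = 10))), 0L)
})

test_that("length categories split percentages as direct arithmetic says", {
  segs <- data.frame(sample_id = "s1", breed = "B", chr = "1",
                     start_bp = c(1, 1, 1) * 1e6,
                     end_bp = c(3, 7, 41) * 1e6,
                     length_bp = c(2, 6, 40) * 1e6,
                     n_snp = c(10L, 20L, 50L), n_het = 0L, n_missing = 0L)
  s <- roh_length_summary(segs)
  expect_equal(unname(s$percent["B", ]),
               c(2 / 48, 6 / 48, 0, 0, 40 / 48) * 100, tolerance = 1e-9)

  one <- segs[1, ]; one$length_bp <- 4e6; one$end_bp <- 5e6
  expect_equal(unname(roh_length_summary(one)$percent["B", 1]), 100)

  empty <- segs[0, ]
  s0 <- roh_length_summary(empty)
  expect_equal(nrow(s0$per_sample), 0L)   # no division error
})

test_that("island detection applies the strict >50% rule per marker", {
  mm <- marker_map(paste0("m", 1:50), rep("1", 50), (1:50) * 1e5)
  g <- geno_matrix(matrix(0L, 10, 50),
                   data.frame(sample_id = paste0("s", 1:10), breed = "B"), mm)
  seg <- function(ids, from, to) data.frame(
    sample_id = ids, breed = "B", chr = "1",
    start_bp = from, end_bp = to, length_bp = to - from,
    n_snp = 0L, n_het = 0L, n_missing = 0L)

  # identical segment in 6/10 samples -> one island, carrier fraction 0.6
  isl <- find_islands(seg(paste0("s", 1:6), 1e6, 3e6), g)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start_bp, 1e6)
  expect_equal(isl$end_bp, 3e6)
  expect_equal(isl$carrier_fraction, 0.6)

  # exactly 5/10 -> no island (strict)
  expect_equal(nrow(find_islands(seg(paste0("s", 1:5), 1e6, 3e6), g)), 0L)

  # staggered segments: verified against the brute-force counter
  st <- rbind(seg(paste0("s", 1:6), 1e6, 3e6), seg(paste0("s", 4:9), 2e6, 4e6))
  isl2 <- find_islands(st, g)
  inc <- oracle_incidence(st, mm, paste0("s", 1:10))
  hit <- which(inc > 0.5)
  expect_equal(isl2$start_bp, mm$position_bp[min(hit)])
  expect_equal(isl2$end_bp, mm$position_bp[max(hit)])
  expect_equal(isl2$carrier_fraction, min(inc[hit]))

  # segment-order invariance
  isl3 <- find_islands(st[sample(nrow(st)), ], g)
  expect_equal(isl3, isl2)

  # adding a fully heterozygous sample (no segments) cannot enlarge islands
  g11 <- geno_matrix(matrix(0L, 11, 50),
                     data.frame(sample_id = paste0("s", 1:11), breed = "B"), mm)
  isl4 <- find_islands(st, g11)
  expect_true(nrow(isl4) == 0 ||
                all(isl4$n_snp <= isl2$n_snp & isl4$length_bp <= isl2$length_bp))
})

test_that("island length is end minus start", {
  expect_equal(island_length(42096163, 43741249), 1645086)
  expect_equal(island_length(54590248, 60271069), 5680821)
  expect_equal(island_length(10, 11), 1)
  expect_error(island_length(5, 5), "<")
})

test_that("implanted tracts are recovered end to end", {
  cfg <- sim_config(effective_size = 100, sample_n = 100, n_chromosomes = 1,
                    chromosome_length_bp = 20e6, marker_spacing_bp = 25e3,
                    generations = 0, seed = 19)
  g <- implant_roh(simulate_population(cfg), "1", 6e6, 11e6,
                   carrier_fraction = 0.7, seed = 20)
  segs <- call_roh(g)
  carriers <- attr(g, "carriers")
  # every carrier yields a segment covering >= 95% of the region
  cover <- vapply(carriers, function(s) {
    ss <- segs[segs$sample_id == s, ]
    any(pmin(ss$end_bp, 11e6) - pmax(ss$start_bp, 6e6) >= 0.95 * 5e6)
  }, logical(1))
  expect_true(all(cover))
  isl <- find_islands(segs, g)
  expect_equal(nrow(isl), 1L)
  expect_lte(abs(isl$start_bp - 6e6), 25e3)
  expect_lte(abs(isl$end_bp - 11e6), 25e3)
})

test_that("gene annotation uses the any-overlap rule in 1-based coordinates", {
  isl <- data.frame(population = "B", chr = c("1", "1", "2"),
                    start_bp = c(100, 1000, 50), end_bp = c(200, 2000, 500),
                    length_bp = c(100, 1000, 450), n_snp = 5L,
                    carrier_fraction = 0.6)
  genes <- data.frame(chromosome = c("1", "1", "1", "2", "3"),
                      start_bp = c(150, 201, 1999, 400, 1),
                      end_bp = c(250, 300, 2100, 600, 10),
                      gene_id = c("gA", "gB", "gC", "gD", "gE"))
  expect_warning(a <- annotate_islands(isl, genes), "skipped")
  expect_equal(a$genes, c("gA", "gC", "gD"))   # gB adjacent, not overlapping

  # quadratic brute-force agreement on random intervals
  set.seed(44)
  isl2 <- data.frame(population = "B", chr = "1",
                     start_bp = s <- sample(1000, 3),
                     end_bp = s + sample(200:800, 3),
                     length_bp = 0, n_snp = 1L, carrier_fraction = 0.6)
  gs <- sample(1500, 10)
  genes2 <- data.frame(chromosome = "1", start_bp = gs,
                       end_bp = gs + sample(50:400, 10),
                       gene_id = paste0("g", 1:10))
  a2 <- suppressWarnings(annotate_islands(isl2, genes2))
  for (i in 1:3) {
    manual <- genes2[genes2$start_bp <= isl2$end_bp[i] &
                       genes2$end_bp >= isl2$start_bp[i], ]
    manual <- manual[order(manual$start_bp, manual$end_bp), ]
    expect_equal(a2$genes[i], paste(manual$gene_id, collapse = ","))
  }
})

test_that("gene intervals read from BED arrive 1-based inclusive", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("1\t99\t200\tgeneX", "2\t0\t50\tgeneY"), bed)
  gi <- read_gene_intervals(bed)
  expect_equal(gi$start_bp, c(100, 1))
  expect_equal(gi$end_bp, c(200, 50))
  expect_equal(gi$gene_id, c("geneX", "geneY"))

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tsrc\tgene\t100\t200\t.\t+\t.\tID=geneZ",
               "1\tsrc\texon\t100\t150\t.\t+\t.\tID=exon1"), gff)
  gg <- read_gene_intervals(gff)
  expect_equal(nrow(gg), 1L)
  expect_equal(gg$gene_id, "geneZ")
  expect_equal(gg$start_bp, 100)
})
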