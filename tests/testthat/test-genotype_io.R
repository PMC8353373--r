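test_that("PED/MAP parsing recodes alleles to minor-allele dosage", {
  dir <- withr::local_tempdir()
  # 3 samples, 1 marker: AA, AG, GG -> allele counts A=3, G=3, tie broken
  # to the lexicographically smaller symbol (A), so dosages are 2, 1, 0
  f <- write_toy_ped(dir, rbind(c("A", "A"), c("A", "G"), c("G", "G")))
  g <- read_ped_map(f$ped, f$map)
  expect_equal(unname(g$dosages[, 1]), c(2L, 1L, 0L))
  expect_equal(g$samples$breed, rep("F1", 3))

  # hand tally with a clear minor allele: AA, AA, AG -> G is minor: 0, 0, 1
  f2 <- write_toy_ped(dir, rbind(c("A", "A"), c("A", "A"), c("A", "G")))
  g2 <- read_ped_map(f2$ped, f2$map)
  expect_equal(unname(g2$dosages[, 1]), c(0L, 0L, 1L))
})

test_that("a '0 0' allele pair becomes a missing call, never dosage 0", {
  dir <- withr::local_tempdir()
  f <- write_toy_ped(dir, rbind(c("A", "A"), c("0", "0"), c("A", "G")))
  g <- read_ped_map(f$ped, f$map)
  expect_true(is.na(g$dosages[2, 1]))
  expect_equal(sum(is.na(g$dosages)), 1L)
})

test_that("single-sample single-marker file parses to a homozygote dosage", {
  dir <- withr::local_tempdir()
  f <- write_toy_ped(dir, matrix(c("A", "A"), 1))
  g <- read_ped_map(f$ped, f$map)
  expect_equal(dim(g$dosages), c(1L, 1L))
  expect_true(g$dosages[1, 1] %in% c(0L, 2L))
})

test_that("malformed inputs fail loudly with row/marker named", {
  dir <- withr::local_tempdir()
  f <- write_toy_ped(dir, rbind(c("A", "A", "C", "C"), c("A", "G", "C", "T")))
  # drop one marker from the map: dimension mismatch names the row
  mp <- readLines(f$map)
  writeLines(mp[1], f$map)
  expect_error(read_ped_map(f$ped, f$map), "row 1")

  f2 <- write_toy_ped(dir, rbind(c("A", "A"), c("C", "G")))
  expect_error(read_ped_map(f2$ped, f2$map), "m1.*not biallelic|not biallelic")
})

test_that("excluded chromosome labels are dropped on read, configurably", {
  dir <- withr::local_tempdir()
  f <- write_toy_ped(dir, rbind(c("A", "A", "C", "C"), c("A", "G", "C", "G")),
                     chr = c("1", "30"))
  g <- read_ped_map(f$ped, f$map)                 # default list drops "30"
  expect_equal(unique(g$map$chromosome), "1")
  g2 <- read_ped_map(f$ped, f$map, exclude_chromosomes = character())
  expect_equal(n_markers(g2), 2L)
})

test_that("marker map enforces order and the 1 Mb = 1 cM convention", {
  m <- marker_map(c("a", "b", "c"), c("2", "2", "10"), c(5e6, 1e6, 3e6))
  expect_equal(m$marker_id, c("b", "a", "c"))           # sorted within chr
  expect_equal(m$genetic_pos_morgan, m$position_bp * 1e-8)
  expect_error(marker_map(c("a", "b"), c("1", "1"), c(100, 100)),
               "strictly increasing")
})

test_that("PED/MAP write-read round-trips dosages and positions exactly", {
  set.seed(11)
  dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 5, 12)
  raw <- toy_geno(dos, chr = rep(c("1", "2"), each = 6))
  # canonicalize to minor-allele coding first (a fresh parse does this),
  # then the write-read cycle must be bit-exact
  dir0 <- withr::local_tempdir()
  write_ped_map(raw, file.path(dir0, "c.ped"), file.path(dir0, "c.map"))
  g <- read_ped_map(file.path(dir0, "c.ped"), file.path(dir0, "c.map"))
  dir <- withr::local_tempdir()
  write_ped_map(g, file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  g2 <- read_ped_map(file.path(dir, "rt.ped"), file.path(dir, "rt.map"))
  expect_identical(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$map$position_bp, g$map$position_bp)
  expect_identical(g2$map$chromosome, g$map$chromosome)

  # dosage TSV dialect round-trips too
  write_dosage_tsv(g, file.path(dir, "rt.tsv"), file.path(dir, "rt2.map"))
  g3 <- read_dosage_tsv(file.path(dir, "rt.tsv"), file.path(dir, "rt2.map"))
  expect_identical(unname(g3$dosages), unname(g$dosages))
})

test_that("QC removes markers by call rate and MAF as specified", {
  # marker 1 fine; marker 2 monomorphic (MAF 0); marker 3 has 1 missing of 4
  dos <- cbind(c(0L, 1L, 2L, 1L), c(0L, 0L, 0L, 0L), c(0L, 1L, NA, 2L))
  g <- toy_geno(dos)
  res <- qc_filter(g, marker_call_rate = 0.95, maf_min = 0.01,
                   sample_call_rate = 0)
  expect_equal(res$report$markers_removed_maf, 1L)
  expect_equal(res$report$markers_removed_callrate, 1L)   # 3/4 = 0.75 < 0.95
  expect_equal(n_markers(res$geno), 1L)
  # removed + retained = input
  expect_equal(res$report$markers_removed_maf +
                 res$report$markers_removed_callrate +
                 res$report$markers_out, res$report$markers_in)
})

test_that("QC with zero thresholds is the identity and empty output errors", {
  set.seed(2)
  g <- toy_geno(matrix(sample(0:2, 40, replace = TRUE), 4, 10))
  res <- qc_filter(g, 0, 0, 0)
  expect_identical(res$geno$dosages, g$dosages)
  expect_equal(res$report$markers_removed_maf, 0L)
  expect_equal(res$report$samples_removed_callrate, 0L)

  mono <- toy_geno(matrix(0L, 4, 3))
  expect_error(qc_filter(mono), "empty panel")
})

test_that("QC is idempotent", {
  set.seed(5)
  dos <- matrix(sample(c(0:2, NA), 600, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), 20, 30)
  dos[1:3, ] <- NA   # three no-call samples
  g <- toy_geno(dos)
  r1 <- qc_filter(g, 0.8, 0.05, 0.5)
  expect_equal(r1$report$samples_removed_callrate, 3L)
  r2 <- qc_filter(r1$geno, 0.8, 0.05, 0.5)
  expect_identical(r2$geno$dosages, r1$geno$dosages)
  expect_equal(r2$report$markers_removed_callrate +
                 r2$report$markers_removed_maf +
                 r2$report$samples_removed_callrate, 0L)

  # and on a clean random panel with no sample removal at all
  g3 <- toy_geno(matrix(sample(c(0:2, NA), 400, replace = TRUE,
                               prob = c(0.32, 0.33, 0.33, 0.02)), 20, 20))
  a <- qc_filter(g3, 0.9, 0.05, 0.85)
  b <- qc_filter(a$geno, 0.9, 0.05, 0.85)
  expect_identical(b$geno$dosages, a$geno$dosages)
})

test_that("allele frequencies handle missingness and undefined populations", {
  g <- toy_geno(cbind(c(0L, 1L, 2L), c(2L, 2L, NA)))
  f <- allele_frequencies(g)
  expect_equal(unname(f[, "ALL"]), c(0.5, 1.0))

  # by breed, with one breed entirely missing at marker 2
  dos <- cbind(c(0L, 1L, 2L, 2L, NA), c(1L, 2L, NA, NA, NA))
  g2 <- geno_matrix(dos,
                    data.frame(sample_id = paste0("s", 1:5),
                               breed = c("A", "A", "B", "B", "B")),
                    marker_map(c("m1", "m2"), c("1", "1"), c(100, 200)))
  f2 <- allele_frequencies(g2, by_breed = TRUE)
  expect_equal(f2["m1", "A"], (0 + 1) / 4)        # hand tally
  expect_equal(f2["m1", "B"], (2 + 2) / 4)
  expect_equal(f2["m2", "A"], (1 + 2) / 4)
  expect_true(is.na(f2["m2", "B"]))               # undefined, not 0
})

test_that("dosage flip g -> 2 - g preserves call rate and MAF", {
  set.seed(9)
  for (rep in 1:5) {
    dos <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10, 20)
    g <- toy_geno(dos)
    flip <- toy_geno(2L - dos)
    s1 <- marker_stats(g); s2 <- marker_stats(flip)
    expect_equal(s1$call_rate, s2$call_rate)
    expect_equal(s1$maf, s2$maf)
  }
})
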