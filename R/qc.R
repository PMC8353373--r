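#' Per-marker and per-sample panel statistics
#'
#' @param geno a [geno_matrix()].
#' @return `marker_stats`: data.frame with `marker_id`, `call_rate`,
#'   `freq` (minor-allele frequency over non-missing calls, `NA` when no
#'   call), `maf`.
#' @export
marker_stats <- function(geno) {
  d <- geno$dosages
  nobs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * nobs)
  p[nobs == 0] <- NA_real_
  data.frame(marker_id = geno$map$marker_id,
             call_rate = nobs / nrow(d),
             freq = p,
             maf = pmin(p, 1 - p),
             stringsAsFactors = FALSE)
}

#' @rdname marker_stats
#' @return `sample_stats`: data.frame with `sample_id`, `breed`, `call_rate`.
#' @export
sample_stats <- function(geno) {
  data.frame(sample_id = geno$samples$sample_id,
             breed = geno$samples$breed,
             call_rate = rowSums(!is.na(geno$dosages)) / ncol(geno$dosages),
             stringsAsFactors = FALSE)
}

#' Quality-control filter for a genotype panel
#'
#' Markers are removed when their call rate falls below `marker_call_rate`
#' or their minor allele frequency below `maf_min`; samples are then removed
#' when their call rate over the *retained* markers falls below
#' `sample_call_rate`. This is a single pass: marker statistics are not
#' recomputed after sample removal, so the filter is idempotent.
#'
#' @param geno a [geno_matrix()].
#' @param marker_call_rate minimum fraction of non-missing calls per marker.
#' @param maf_min minimum minor allele frequency.
#' @param sample_call_rate minimum fraction of non-missing calls per sample.
#' @return list with elements `geno` (the filtered panel) and `report`
#'   (a `qc_report`: removal counts plus the thresholds used).
#' @export
qc_filter <- function(geno, marker_call_rate = 0.95, maf_min = 0.01,
                      sample_call_rate = 0.85) {
  stopifnot(marker_call_rate >= 0, marker_call_rate <= 1,
            maf_min >= 0, maf_min <= 1,
            sample_call_rate >= 0, sample_call_rate <= 1)
  ms <- marker_stats(geno)
  fail_cr <- ms$call_rate < marker_call_rate
  maf <- ifelse(is.na(ms$maf), -1, ms$maf)   # no-call markers fail call rate already
  fail_maf <- !fail_cr & maf < maf_min
  keep_m <- !(fail_cr | fail_maf)
  if (!any(keep_m))
    stop("empty panel: all ", length(keep_m), " markers removed by QC")
  g2 <- subset_geno(geno, markers = which(keep_m))
  ss <- sample_stats(g2)
  keep_s <- ss$call_rate >= sample_call_rate
  if (!any(keep_s))
    stop("empty panel: all samples removed by QC")
  out <- subset_geno(g2, samples = which(keep_s))
  report <- structure(
    list(markers_in = n_markers(geno),
         samples_in = n_samples(geno),
         markers_removed_callrate = sum(fail_cr),
         markers_removed_maf = sum(fail_maf),
         samples_removed_callrate = sum(!keep_s),
         markers_out = n_markers(out),
         samples_out = n_samples(out),
         thresholds = c(marker_call_rate = marker_call_rate,
                        maf_min = maf_min,
                        sample_call_rate = sample_call_rate)),
    class = "qc_report")
  list(geno = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", x$markers_in, "->", x$markers_out, "markers (",
      x$markers_removed_callrate, "call rate,", x$markers_removed_maf, "MAF );",
      x$samples_in, "->", x$samples_out, "samples (",
      x$samples_removed_callrate, "call rate )\n")
  invisible(x)
}

#' Allele frequencies per marker, overall or per breed
#'
#' Frequency of the counted (minor-coded) allele:
#' sum(dosages) / (2 x non-missing count), computed over non-missing calls
#' only. A population with zero non-missing calls at a marker gets `NA`
#' (undefined), never 0.
#'
#' @param geno a [geno_matrix()].
#' @param by_breed if `TRUE`, one column per breed; otherwise a single
#'   column `ALL`.
#' @return numeric matrix, markers x populations, rownames = marker ids.
#' @export
allele_frequencies <- function(geno, by_breed = FALSE) {
  d <- geno$dosages
  groups <- if (by_breed) split(seq_len(nrow(d)), geno$samples$breed)
            else list(ALL = seq_len(nrow(d)))
  out <- vapply(groups, function(idx) {
    di <- d[idx, , drop = FALSE]
    nobs <- colSums(!is.na(di))
    p <- colSums(di, na.rm = TRUE) / (2 * nobs)
    p[nobs == 0] <- NA_real_
    p
  }, numeric(ncol(d)))
  out <- matrix(out, nrow = ncol(d), dimnames = list(geno$map$marker_id, names(groups)))
  out
}
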