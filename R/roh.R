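#' Parameters of the sliding-window ROH caller
#'
#' Defaults reproduce the scan used throughout this package: a 50-SNP
#' sliding window allowing at most 1 heterozygote and 5 missing calls; a
#' marker belongs to a candidate run when more than 5% of the windows
#' covering it are homozygous; runs are split at inter-marker gaps above
#' 1,000 kb and emitted when at least 1,000 kb long AND carrying at least
#' 120 SNPs. `min_density_snp` is an additional per-segment floor on SNPs
#' per Mb-scaled length; it is exposed but off (`NULL`) by default.
#'
#' @param window_snp sliding-window length in SNPs.
#' @param window_het_max maximum heterozygotes for a window to count as
#'   homozygous.
#' @param window_missing_max maximum missing calls per homozygous window.
#' @param window_hit_threshold per-marker homozygous-window proportion that
#'   must be exceeded (strictly).
#' @param min_length_kb minimum emitted segment length, kb.
#' @param min_snp minimum SNPs in an emitted segment.
#' @param max_gap_kb split a run where adjacent markers are further apart
#'   than this.
#' @param min_density_snp optional minimum SNPs per segment per 50 kb of
#'   length (`NULL` = off).
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 50, window_het_max = 1,
                       window_missing_max = 5, window_hit_threshold = 0.05,
                       min_length_kb = 1000, min_snp = 120,
                       max_gap_kb = 1000, min_density_snp = NULL) {
  p <- list(window_snp = as.integer(window_snp),
            window_het_max = as.integer(window_het_max),
            window_missing_max = as.integer(window_missing_max),
            window_hit_threshold = as.numeric(window_hit_threshold),
            min_length_kb = as.numeric(min_length_kb),
            min_snp = as.integer(min_snp),
            max_gap_kb = as.numeric(max_gap_kb),
            min_density_snp = min_density_snp)
  stopifnot(p$window_snp >= 1, p$window_het_max >= 0, p$window_missing_max >= 0,
            p$window_hit_threshold > 0, p$window_hit_threshold <= 1,
            p$min_length_kb > 0, p$min_snp >= 1, p$max_gap_kb > 0)
  class(p) <- "roh_params"
  p
}

# rolling sum of x over windows of w consecutive entries
.rollsum <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Per-marker homozygous-window proportion for one sample
#'
#' Slides a `window_snp`-wide window along each chromosome; a window is
#' homozygous when it contains at most `window_het_max` heterozygotes
#' (dosage 1) and at most `window_missing_max` missing calls (missing
#' counts toward the missing budget only, never as a heterozygote). Each
#' marker's score is the fraction of windows covering it that are
#' homozygous; markers near chromosome ends are covered by fewer windows
#' and use that reduced denominator. A chromosome with fewer markers than
#' the window is scored from the single truncated whole-chromosome window.
#'
#' @param dosages dosage vector for one sample, aligned to `map` rows.
#' @param map a `marker_map`.
#' @param params a [roh_params()].
#' @return numeric vector of scores in [0, 1], aligned to `map`.
#' @export
window_scan <- function(dosages, map, params = roh_params()) {
  stopifnot(length(dosages) == nrow(map))
  score <- numeric(length(dosages))
  for (chr in unique(map$chromosome)) {
    idx <- which(map$chromosome == chr)
    g <- dosages[idx]
    m <- length(g)
    het <- as.integer(!is.na(g) & g == 1L)
    mis <- as.integer(is.na(g))
    w <- min(params$window_snp, m)
    nh <- .rollsum(het, w)
    nm <- .rollsum(mis, w)
    hom <- as.integer(nh <= params$window_het_max & nm <= params$window_missing_max)
    # windows covering marker j: starts in [max(1, j-w+1), min(j, m-w+1)]
    cs <- c(0, cumsum(hom))
    nw <- length(hom)
    lo <- pmax(1L, seq_len(m) - w + 1L)
    hi <- pmin(seq_len(m), nw)
    score[idx] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  score
}

#' Call runs of homozygosity for every sample of a panel
#'
#' Candidate runs are maximal stretches of markers whose window-scan score
#' strictly exceeds `window_hit_threshold`; runs are split where the gap
#' between adjacent markers exceeds `max_gap_kb`; a run is emitted iff its
#' length (end - start, bp) is at least `min_length_kb` x 1000 AND it
#' carries at least `min_snp` markers. Segment bounds are snapped to the
#' outermost marker positions of the run.
#'
#' @param geno a [geno_matrix()].
#' @param params a [roh_params()].
#' @return data.frame of class `roh_segments`: `sample_id`, `breed`,
#'   `chr`, `start_bp`, `end_bp`, `length_bp` (= end - start), `n_snp`,
#'   `n_het`, `n_missing`.
#' @export
call_roh <- function(geno, params = roh_params()) {
  map <- geno$map
  out <- vector("list", n_samples(geno))
  for (i in seq_len(n_samples(geno))) {
    g <- geno$dosages[i, ]
    sc <- window_scan(g, map, params)
    segs <- list()
    for (chr in unique(map$chromosome)) {
      idx <- which(map$chromosome == chr)
      hit <- sc[idx] > params$window_hit_threshold
      pos <- map$position_bp[idx]
      r <- rle(hit)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        run <- starts[k]:ends[k]
        # split at large gaps
        gaps <- diff(pos[run])
        cut <- which(gaps > params$max_gap_kb * 1000)
        piece_start <- c(run[1], run[cut + 1])
        piece_end <- c(run[cut], run[length(run)])
        for (pp in seq_along(piece_start)) {
          sel <- idx[piece_start[pp]:piece_end[pp]]
          len <- map$position_bp[sel[length(sel)]] - map$position_bp[sel[1]]
          nsnp <- length(sel)
          if (len < params$min_length_kb * 1000 || nsnp < params$min_snp) next
          if (!is.null(params$min_density_snp) &&
              nsnp < params$min_density_snp * len / 50e3) next
          gi <- g[sel]
          segs[[length(segs) + 1L]] <- data.frame(
            sample_id = geno$samples$sample_id[i],
            breed = geno$samples$breed[i],
            chr = chr,
            start_bp = map$position_bp[sel[1]],
            end_bp = map$position_bp[sel[length(sel)]],
            length_bp = len,
            n_snp = nsnp,
            n_het = sum(!is.na(gi) & gi == 1L),
            n_missing = sum(is.na(gi)),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(segs)) out[[i]] <- do.call(rbind, segs)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample_id = character(), breed = character(),
                      chr = character(), start_bp = numeric(),
                      end_bp = numeric(), length_bp = numeric(),
                      n_snp = integer(), n_het = integer(),
                      n_missing = integer(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("roh_segments", "data.frame")
  res
}

#' Summarize ROH by length category
#'
#' Segment lengths are binned into (1, 5], (5, 10], (10, 20], (20, 31],
#' (31, Inf) Mb. Returns per-sample total length per category and, per
#' population, the percentage of total ROH length in each category.
#'
#' @param segments a `roh_segments` data.frame.
#' @param categories_mb upper edges of the inner categories, Mb.
#' @return list with `per_sample` (sample_id, breed, category, total_bp)
#'   and `percent` (breed x category matrix of percentages, rows summing to
#'   100 where any ROH exists, otherwise 0).
#' @export
roh_length_summary <- function(segments, categories_mb = c(5, 10, 20, 31)) {
  edges <- c(1, categories_mb, Inf) * 1e6
  labels <- c(paste0("<=", categories_mb[1], "Mb"),
              paste0(utils::head(categories_mb, -1), "-",
                     utils::tail(categories_mb, -1), "Mb"),
              paste0(">", categories_mb[length(categories_mb)], "Mb"))
  cats <- factor(labels[findInterval(segments$length_bp, edges,
                                     left.open = TRUE)],
                 levels = labels)
  if (nrow(segments) == 0L)
    return(list(per_sample = data.frame(sample_id = character(),
                                        breed = character(),
                                        category = factor(character(),
                                                          levels = labels),
                                        total_bp = numeric()),
                percent = matrix(0, 0, length(labels),
                                 dimnames = list(NULL, labels))))
  per_sample <- stats::aggregate(
    list(total_bp = segments$length_bp),
    by = list(sample_id = segments$sample_id, breed = segments$breed,
              category = cats), FUN = sum)
  breeds <- unique(segments$breed)
  pct <- matrix(0, length(breeds), length(labels),
                dimnames = list(breeds, labels))
  for (b in breeds) {
    sel <- segments$breed == b
    tot <- sum(segments$length_bp[sel])
    if (tot > 0)
      pct[b, ] <- 100 * vapply(labels, function(L)
        sum(segments$length_bp[sel][cats[sel] == L]), numeric(1)) / tot
  }
  list(per_sample = per_sample, percent = pct)
}

#' Detect ROH islands shared by most individuals
#'
#' Per population: per-marker incidence = fraction of the population's
#' samples having an ROH segment covering that marker. Islands are maximal
#' marker runs with incidence strictly above `threshold`; bounds snap to
#' the outermost qualifying markers; the reported `carrier_fraction` is the
#' minimum incidence across the island's markers.
#'
#' @param segments a `roh_segments` data.frame (all samples of the panel).
#' @param geno the [geno_matrix()] the segments were called from (supplies
#'   the map and per-population sample counts).
#' @param threshold incidence that must be exceeded (default 0.5: shared by
#'   more than 50% of individuals).
#' @return data.frame of class `roh_islands`: `population`, `chr`,
#'   `start_bp`, `end_bp`, `length_bp` (= end - start), `n_snp`,
#'   `carrier_fraction`.
#' @export
find_islands <- function(segments, geno, threshold = 0.5) {
  map <- geno$map
  out <- list()
  for (pop in unique(geno$samples$breed)) {
    ids <- geno$samples$sample_id[geno$samples$breed == pop]
    npop <- length(ids)
    segs <- segments[segments$sample_id %in% ids, , drop = FALSE]
    inc <- numeric(nrow(map))
    if (nrow(segs)) {
      for (chr in unique(segs$chr)) {
        idx <- which(map$chromosome == chr)
        pos <- map$position_bp[idx]
        cover <- matrix(FALSE, npop, length(idx))
        sc <- segs[segs$chr == chr, , drop = FALSE]
        for (r in seq_len(nrow(sc))) {
          si <- match(sc$sample_id[r], ids)
          cover[si, ] <- cover[si, ] |
            (pos >= sc$start_bp[r] & pos <= sc$end_bp[r])
        }
        inc[idx] <- colSums(cover) / npop
      }
    }
    hit <- inc > threshold
    if (!any(hit)) next
    for (chr in unique(map$chromosome)) {
      idx <- which(map$chromosome == chr)
      r <- rle(hit[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        sel <- idx[starts[k]:ends[k]]
        out[[length(out) + 1L]] <- data.frame(
          population = pop,
          chr = chr,
          start_bp = map$position_bp[sel[1]],
          end_bp = map$position_bp[sel[length(sel)]],
          length_bp = map$position_bp[sel[length(sel)]] - map$position_bp[sel[1]],
          n_snp = length(sel),
          carrier_fraction = min(inc[sel]),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(population = character(), chr = character(),
               start_bp = numeric(), end_bp = numeric(),
               length_bp = numeric(), n_snp = integer(),
               carrier_fraction = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("roh_islands", "data.frame")
  res
}

#' Island length convention
#'
#' Length in bp is end - start (not end - start + 1), the convention used
#' for every segment and island length in this package.
#'
#' @param start_bp,end_bp 1-based positions, start < end.
#' @return end_bp - start_bp.
#' @export
island_length <- function(start_bp, end_bp) {
  if (any(start_bp >= end_bp)) stop("start_bp must be < end_bp")
  end_bp - start_bp
}

#' Read gene intervals from a BED or GFF3 file
#'
#' BED input (0-based half-open) is converted to 1-based inclusive
#' coordinates on read; GFF3 input keeps rows with feature type "gene" and
#' takes the `ID` (falling back to `Name`) attribute as the gene id.
#' Reading uses rtracklayer.
#'
#' @param path file path; format inferred from the extension
#'   (".bed" / ".gff", ".gff3") unless `format` is given.
#' @param format "bed" or "gff3" (optional).
#' @return data.frame: `chromosome`, `start_bp`, `end_bp`, `gene_id`
#'   (1-based inclusive).
#' @export
read_gene_intervals <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "bed") "bed" else "gff3"
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_intervals needs the rtracklayer package")
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  if (format == "gff3") {
    df <- df[df$type == "gene", , drop = FALSE]
    id <- if ("ID" %in% names(df)) df$ID else df$Name
    if (is.null(id)) id <- paste0("gene", seq_len(nrow(df)))
  } else {
    id <- if ("name" %in% names(df)) df$name else paste0("gene", seq_len(nrow(df)))
  }
  data.frame(chromosome = as.character(df$seqnames),
             start_bp = df$start, end_bp = df$end,
             gene_id = as.character(id), stringsAsFactors = FALSE)
}

#' Annotate ROH islands with overlapping genes
#'
#' A gene is assigned to an island when their 1-based inclusive intervals
#' share at least one bp (any-overlap rule); assigned genes are listed in
#' genomic order. Genes on chromosome labels absent from the island set
#' trigger a warning and are skipped.
#'
#' @param islands a `roh_islands` data.frame.
#' @param genes gene intervals from [read_gene_intervals()] (or any
#'   data.frame with `chromosome`, `start_bp`, `end_bp`, `gene_id`).
#' @return `islands` with an added `genes` column (comma-separated ids,
#'   "" when none).
#' @export
annotate_islands <- function(islands, genes) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE) ||
      !requireNamespace("IRanges", quietly = TRUE))
    stop("annotate_islands needs the GenomicRanges package")
  unknown <- setdiff(unique(genes$chromosome), unique(islands$chr))
  if (length(unknown)) {
    warning("gene annotation on chromosomes absent from islands skipped: ",
            paste(unknown, collapse = ", "))
    genes <- genes[!genes$chromosome %in% unknown, , drop = FALSE]
  }
  islands$genes <- ""
  if (nrow(islands) == 0L || nrow(genes) == 0L) return(islands)
  gri <- GenomicRanges::GRanges(
    islands$chr, IRanges::IRanges(islands$start_bp, islands$end_bp))
  grg <- GenomicRanges::GRanges(
    genes$chromosome, IRanges::IRanges(genes$start_bp, genes$end_bp))
  hits <- GenomicRanges::findOverlaps(gri, grg)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    g <- genes[sh[qh == i], , drop = FALSE]
    g <- g[order(g$start_bp, g$end_bp), , drop = FALSE]
    islands$genes[i] <- paste(g$gene_id, collapse = ",")
  }
  islands
}
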