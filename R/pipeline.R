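.default_config <- function() {
  list(
    input = list(ped = NULL, map = NULL, dosage_tsv = NULL),
    simulate = NULL,   # list of sim blocks: breed + sim_config fields
    qc = list(marker_call_rate = 0.95, maf_min = 0.01, sample_call_rate = 0.85),
    ld = list(max_dist_kb = 1000, max_snp_sep = 5),
    ne = list(bin_edges_morgan = c(0.01, 0.03, 0.05), cap_morgan = 0.125,
              rep_c_morgan = c(0.01, 0.03, 0.05, 0.1), max_snp_sep = 10000),
    roh = list(window_snp = 50, window_het_max = 1, window_missing_max = 5,
               window_hit_threshold = 0.05, min_length_kb = 1000,
               min_snp = 120, max_gap_kb = 1000, island_threshold = 0.5),
    structure = list(n_components = 2, prune = FALSE, prune_r2 = 0.2),
    genes = NULL,
    cluster_k = "auto",
    out_dir = "results",
    seed = 1,
    log_level = "info")
}

.check_range <- function(errs, cfg, path, lo, hi) {
  v <- cfg
  for (p in strsplit(path, "\\$")[[1]]) v <- v[[p]]
  if (!is.null(v) && (!is.numeric(v) || any(v < lo) || any(v > hi)))
    errs <- c(errs, paste0(path, ": must be numeric in [", lo, ", ", hi, "]"))
  errs
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a plain list. Unknown keys are rejected;
#' defaults are injected for absent optional keys; all problems are
#' reported together in one error.
#'
#' @param config path to a YAML config file, or a list.
#' @return the normalized config list (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  def <- .default_config()
  errs <- character()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  for (blk in c("input", "qc", "ld", "ne", "roh", "structure")) {
    if (!is.null(config[[blk]])) {
      bad <- setdiff(names(config[[blk]]), names(def[[blk]]))
      if (length(bad))
        errs <- c(errs, paste0(blk, ": unknown key(s): ",
                               paste(bad, collapse = ", ")))
    }
  }
  cfg <- def
  for (nm in intersect(names(config), names(def))) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]])) && is.list(config[[nm]])) {
      for (k in intersect(names(config[[nm]]), names(def[[nm]])))
        cfg[[nm]][[k]] <- config[[nm]][[k]]
    } else cfg[[nm]] <- config[[nm]]
  }
  errs <- .check_range(errs, cfg, "qc$marker_call_rate", 0, 1)
  errs <- .check_range(errs, cfg, "qc$maf_min", 0, 1)
  errs <- .check_range(errs, cfg, "qc$sample_call_rate", 0, 1)
  errs <- .check_range(errs, cfg, "roh$window_hit_threshold", 1e-12, 1)
  errs <- .check_range(errs, cfg, "roh$island_threshold", 0, 1)
  errs <- .check_range(errs, cfg, "ld$max_dist_kb", 0, Inf)
  errs <- .check_range(errs, cfg, "ne$cap_morgan", 0, Inf)
  if (!is.null(cfg$input$ped) && is.null(cfg$input$map))
    errs <- c(errs, "input$map: required when input$ped is given")
  for (p in c("ped", "map", "dosage_tsv"))
    if (!is.null(cfg$input[[p]]) && !file.exists(cfg$input[[p]]))
      errs <- c(errs, paste0("input$", p, ": file not found: ", cfg$input[[p]]))
  if (!is.null(cfg$genes) && !file.exists(cfg$genes))
    errs <- c(errs, paste0("genes: file not found: ", cfg$genes))
  if (length(errs))
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  class(cfg) <- c("run_config", "list")
  cfg
}

.stage_seed <- function(root, i) (as.integer(root) + 7919L * as.integer(i)) %% 2147483647L

.log <- function(cfg, level, ...) {
  lv <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (lv[[level]] >= lv[[cfg$log_level %||% "info"]])
    message("[", level, "] ", ...)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write ROH segments in a PLINK .hom-style layout
#' @param segments a `roh_segments` data.frame.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_roh_segments <- function(segments, path) {
  out <- data.frame(FID = segments$breed, IID = segments$sample_id,
                    CHR = segments$chr, POS1 = segments$start_bp,
                    POS2 = segments$end_bp, KB = segments$length_bp / 1000,
                    NSNP = segments$n_snp)
  invisible(.write_tsv(out, path))
}

#' Write ROH islands as a BED file
#'
#' 1-based inclusive island bounds are converted to BED's 0-based
#' half-open convention on write.
#'
#' @param islands a `roh_islands` data.frame.
#' @param path output BED path.
#' @return the path, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d", islands$chr,
                   as.integer(islands$start_bp) - 1L,
                   as.integer(islands$end_bp),
                   paste0(islands$population, "_island"),
                   as.integer(round(100 * islands$carrier_fraction)))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full genome-architecture pipeline
#'
#' Orchestrates, per breed: QC, short-range LD scan + Sved fit, Ne
#' trajectory, ROH calling, length summary and island detection; then,
#' across breeds: curve-equality tests, beta clustering, allele-frequency
#' distances, NJ tree and PCA. Every output is a pure function of
#' (inputs, config, seed); a rerun with the same config writes
#' byte-identical files. A failure in one breed's stages is recorded and
#' does not halt the other breeds.
#'
#' @param config a [validate_config()] result, config list, or YAML path.
#' @return invisibly, a report list: `outputs` (paths), `fits`,
#'   `trajectories`, `islands`, `failures` (named list of error messages;
#'   empty on full success).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  failures <- list()

  inputs_used <- character()
  if (!is.null(cfg$simulate)) {
    blocks <- cfg$simulate
    if (!is.null(blocks$breed)) blocks <- list(blocks)  # single block given flat
    panels <- lapply(seq_along(blocks), function(i) {
      b <- blocks[[i]]
      breed <- b$breed %||% paste0("POP", i)
      sd <- b$seed %||% .stage_seed(cfg$seed, i)
      b$breed <- NULL; b$seed <- NULL
      sc <- do.call(sim_config, c(b, list(seed = sd)))
      simulate_population(sc, breed = breed)
    })
  } else if (!is.null(cfg$input$ped)) {
    g <- read_ped_map(cfg$input$ped, cfg$input$map)
    inputs_used <- c(cfg$input$ped, cfg$input$map)
    panels <- lapply(split(seq_len(n_samples(g)), g$samples$breed),
                     function(i) subset_geno(g, samples = i))
  } else if (!is.null(cfg$input$dosage_tsv)) {
    g <- read_dosage_tsv(cfg$input$dosage_tsv, cfg$input$map)
    inputs_used <- c(cfg$input$dosage_tsv, cfg$input$map)
    panels <- lapply(split(seq_len(n_samples(g)), g$samples$breed),
                     function(i) subset_geno(g, samples = i))
  } else stop("config provides neither input files nor simulate blocks")
  names(panels) <- vapply(panels, function(p) p$samples$breed[1], character(1))

  rohp <- do.call(roh_params, cfg$roh[setdiff(names(cfg$roh), "island_threshold")])
  fits <- list(); trajs <- list(); segs <- list(); isls <- list()
  qcrep <- list(); qcpanels <- list()
  for (pop in names(panels)) {
    res <- tryCatch({
      qcr <- qc_filter(panels[[pop]], cfg$qc$marker_call_rate,
                       cfg$qc$maf_min, cfg$qc$sample_call_rate)
      g <- qcr$geno
      pr <- pairwise_r2(g, cfg$ld$max_dist_kb, cfg$ld$max_snp_sep, population = pop)
      fit <- fit_sved(pr)
      traj <- ne_trajectory(g, cfg$ne$bin_edges_morgan, cfg$ne$cap_morgan,
                            cfg$ne$rep_c_morgan, cfg$ne$max_snp_sep)
      traj$population <- pop
      sg <- call_roh(g, rohp)
      isl <- find_islands(sg, g, cfg$roh$island_threshold)
      list(qc = qcr$report, geno = g, fit = fit, traj = traj,
           segs = sg, isl = isl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[pop]] <- conditionMessage(res)
      .log(cfg, "warn", "breed ", pop, " failed: ", conditionMessage(res))
      next
    }
    qcrep[[pop]] <- res$qc; qcpanels[[pop]] <- res$geno
    fits[[pop]] <- res$fit; trajs[[pop]] <- res$traj
    segs[[pop]] <- res$segs; isls[[pop]] <- res$isl
    .log(cfg, "info", "breed ", pop, ": beta = ",
         signif(res$fit$beta_hat, 4), ", ", nrow(res$segs), " ROH segments")
  }
  if (length(fits) == 0) stop("all breeds failed: ",
                              paste(unlist(failures), collapse = " | "))

  f <- file.path(cfg$out_dir, "qc_report.tsv")
  outputs <- c(outputs, .write_tsv(do.call(rbind, lapply(names(qcrep), function(p)
    data.frame(population = p, markers_in = qcrep[[p]]$markers_in,
               markers_removed_callrate = qcrep[[p]]$markers_removed_callrate,
               markers_removed_maf = qcrep[[p]]$markers_removed_maf,
               samples_removed_callrate = qcrep[[p]]$samples_removed_callrate,
               markers_out = qcrep[[p]]$markers_out,
               samples_out = qcrep[[p]]$samples_out))), f))

  beta_tab <- data.frame(
    population = names(fits),
    beta = vapply(fits, `[[`, numeric(1), "beta_hat"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    residual_sd = vapply(fits, `[[`, numeric(1), "residual_sd"),
    n_pairs = vapply(fits, `[[`, integer(1), "n_pairs"))
  outputs <- c(outputs, .write_tsv(beta_tab, file.path(cfg$out_dir, "sved_fits.tsv")))

  if (length(fits) >= 2) {
    cmp <- curve_equality_test(fits)
    cm <- as.data.frame(as.table(cmp$p_adj))
    names(cm) <- c("pop_a", "pop_b", "p_adj")
    cm$z <- as.vector(cmp$z)
    outputs <- c(outputs, .write_tsv(cm, file.path(cfg$out_dir, "curve_equality.tsv")))
    cl <- cluster_breeds(fits, k = cfg$cluster_k)
    outputs <- c(outputs, .write_tsv(
      data.frame(population = names(cl$cluster), cluster = cl$cluster,
                 beta = cl$beta),
      file.path(cfg$out_dir, "beta_clusters.tsv")))
    if (length(fits) >= 3) {
      clustering_newick(cl, file.path(cfg$out_dir, "beta_dendrogram.nwk"))
      outputs <- c(outputs, file.path(cfg$out_dir, "beta_dendrogram.nwk"))
    }
  }

  traj_tab <- do.call(rbind, trajs)
  outputs <- c(outputs, .write_tsv(traj_tab, file.path(cfg$out_dir, "ne_trajectories.tsv")))

  seg_tab <- do.call(rbind, segs)
  outputs <- c(outputs, write_roh_segments(seg_tab, file.path(cfg$out_dir, "roh_segments.tsv")))
  if (nrow(seg_tab)) {
    lensum <- roh_length_summary(seg_tab)
    pcts <- data.frame(population = rownames(lensum$percent), lensum$percent,
                       check.names = FALSE)
    outputs <- c(outputs, .write_tsv(pcts, file.path(cfg$out_dir, "roh_length_pct.tsv")))
  }
  isl_tab <- do.call(rbind, isls)
  rownames(isl_tab) <- NULL
  if (!is.null(cfg$genes) && nrow(isl_tab))
    isl_tab <- annotate_islands(isl_tab, read_gene_intervals(cfg$genes))
  outputs <- c(outputs, .write_tsv(isl_tab, file.path(cfg$out_dir, "roh_islands.tsv")))
  outputs <- c(outputs, write_islands_bed(isl_tab, file.path(cfg$out_dir, "roh_islands.bed")))

  if (length(qcpanels) >= 2) {
    joint <- tryCatch(.merge_panels(qcpanels), error = function(e) NULL)
    if (!is.null(joint)) {
      if (isTRUE(cfg$structure$prune))
        joint <- ld_prune(joint, cfg$structure$prune_r2)
      fr <- allele_frequencies(joint, by_breed = TRUE)
      dm <- population_distance(fr)
      outputs <- c(outputs, .write_tsv(
        data.frame(population = rownames(dm), dm, check.names = FALSE),
        file.path(cfg$out_dir, "breed_distance.tsv")))
      if (ncol(dm) >= 3) {
        ape::write.tree(nj_tree(dm), file.path(cfg$out_dir, "nj_tree.nwk"))
        outputs <- c(outputs, file.path(cfg$out_dir, "nj_tree.nwk"))
      }
      pca <- genotype_pca(joint, cfg$structure$n_components)
      outputs <- c(outputs, .write_tsv(
        data.frame(sample_id = rownames(pca$scores), breed = pca$breed,
                   pca$scores, check.names = FALSE),
        file.path(cfg$out_dir, "pca_scores.tsv")))
    } else .log(cfg, "warn", "breeds share no common marker set; structure stage skipped")
  }

  manifest <- list(
    package = "bovarch",
    version = as.character(utils::packageVersion("bovarch")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "out_dir")],
    input_md5 = if (length(inputs_used))
      as.list(tools::md5sum(inputs_used)) else list(),
    outputs = basename(outputs))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))

  invisible(list(outputs = c(outputs, file.path(cfg$out_dir, "manifest.yaml")),
                 fits = fits, trajectories = trajs, segments = seg_tab,
                 islands = isl_tab, failures = failures))
}

# stack per-breed panels that share one marker map
.merge_panels <- function(panels) {
  common <- Reduce(intersect, lapply(panels, function(p) p$map$marker_id))
  if (length(common) < 2) stop("fewer than 2 shared markers across breeds")
  parts <- lapply(panels, function(p)
    subset_geno(p, markers = match(common, p$map$marker_id)))
  geno_matrix(do.call(rbind, lapply(parts, function(p) p$dosages)),
              do.call(rbind, lapply(parts, function(p) p$samples)),
              parts[[1]]$map)
}
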