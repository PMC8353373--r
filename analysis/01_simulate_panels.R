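#!/usr/bin/env Rscript
# Simulate four cattle-like populations with contrasting demographic
# histories and write them as PLINK-style PED/MAP panels. Downstream
# scripts (02-05) read these files, so the whole analysis is reproducible
# from this one seed.
#
# LARGE  : constant N = 200          (weak drift, fast LD decay)
# MID    : constant N = 100
# SMALL  : constant N = 40           (strong drift, long-range LD)
# BOTTLE : N = 200 contracting to 20 eight generations ago
#
# Genome: 10 chromosomes x 26 Mb, one marker per Mb (so pair distances sit
# at the representative distances of the Ne bins), 1 cM/Mb.

library(bovarch)

out <- "results/panels"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260924L

base <- function(N, sample_n, generations, seed)
  sim_config(effective_size = N, sample_n = sample_n, n_chromosomes = 10,
             chromosome_length_bp = 26e6, marker_spacing_bp = 1e6,
             generations = generations, missing_rate = 0.01, seed = seed)

panels <- list(
  LARGE = simulate_population(base(200, 50, 100, seed + 1), breed = "LARGE"),
  MID   = simulate_population(base(100, 50, 100, seed + 2), breed = "MID"),
  SMALL = simulate_population(base(40, 40, 100, seed + 3), breed = "SMALL"))

epoch1 <- simulate_population(base(200, 200, 60, seed + 4))
panels$BOTTLE <- simulate_population(base(20, 20, 8, seed + 5),
                                     breed = "BOTTLE",
                                     founders = attr(epoch1, "haplotypes"))

for (nm in names(panels)) {
  g <- panels[[nm]]
  write_ped_map(g, file.path(out, paste0(nm, ".ped")),
                file.path(out, paste0(nm, ".map")))
  cat(sprintf("%-6s N panel: %d samples x %d markers, het rate %.3f\n",
              nm, n_samples(g), n_markers(g),
              mean(g$dosages == 1L, na.rm = TRUE)))
}
cat("panels written to", out, "\n")
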