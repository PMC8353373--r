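# bovarch

Genome-architecture analysis of multi-breed SNP genotype panels, built for
the questions cattle geneticists ask of array data: how fast does linkage
disequilibrium (LD) decay in each breed, what effective population size
does that imply across past generations, where do runs of homozygosity
(ROH) concentrate, and how do the breeds relate to one another. A bundled
forward Wright–Fisher simulator provides ground truth so every estimator
is validated against data with known parameters.

## What it computes

* **Genotype I/O and QC** — PLINK-style text PED/MAP and dosage-TSV
  panels; marker filters (call rate < 0.95, MAF < 0.01) then a sample
  call-rate filter (< 0.85), in one deterministic pass.
* **LD decay** — composite (unphased) r² for marker pairs within
  configurable index/distance windows, fitted per population with Sved's
  drift model *E[r²] = 1/(1 + 4βd)*; Wald tests for equality of decay
  curves; Ward/Euclidean clustering of the β̂ coefficients.
* **Effective population size** — mean r² in genetic-distance bins
  (0–0.01, 0.01–0.03, 0.03–0.05, 0.05–0.125 Morgan under 1 Mb = 1 cM),
  converted per bin with *Ne = (1/4c)(1/r̄² − 1)* at the representative
  distances c = 0.01, 0.03, 0.05, 0.1 — generations T = 1/(2c) = 50,
  16.6, 10, 5.
* **ROH** — sliding-window caller (50-SNP windows, ≤1 heterozygote, ≤5
  missing; segments ≥1,000 kb and ≥120 SNPs, gaps >1,000 kb split runs),
  length-class summaries, and ROH islands: regions covered by segments in
  strictly more than 50% of a population's individuals, optionally
  annotated with overlapping genes from BED/GFF3.
* **Breed structure** — Euclidean distances on per-breed allele
  frequencies, neighbor-joining trees (via ape), genotype PCA.
* **Simulator** — forward Wright–Fisher with recombination (Poisson
  crossovers, 1 cM/Mb), chainable epochs for bottleneck histories,
  homozygous-tract implanting, and Sved-curve (distance, r²) generators.

Reference tables from a published survey of 19 cattle breeds raised in
Brazil (per-breed sample sizes, Sved β̂ estimates, reported ROH islands)
are bundled so the package's conventions can be checked against printed
values; see `?reference_tables`.

## Worked example

```r
library(bovarch)

# a population of 100 diploids, 10 chromosomes x 26 Mb, 1 marker/Mb
g <- simulate_population(sim_config(effective_size = 100, sample_n = 50,
                                    generations = 100, seed = 42))
g <- qc_filter(g)$geno

ne_trajectory(g)
#>   population        T c_morgan    mean_r2 n_pairs        Ne
#> 1        SIM 50.00000     0.01 0.18180923     177 112.50677
#> 2        SIM 16.66667     0.03 0.11450916     165  64.44105
#> 3        SIM 10.00000     0.05 0.07152418     471  64.90643
#> 4        SIM  5.00000     0.10 0.04400747     826  54.30853
```

The trajectory reads: pairs ~1 Mb apart (c = 0.01 Morgan) have mean
r² ≈ 0.18, implying an effective size of ≈ 113 about 50 generations ago;
the more distant bins reflect more recent generations and sit lower
because the uncorrected r̄² estimator carries a 1/(2n) sampling term — the
known downward bias of this classical estimator at modest sample sizes.
All four values bracket the simulated truth N = 100.

Fitting LD decay and recovering an implanted ROH island:

```r
p <- sved_pair_generator(beta = 2e-5, distances_bp = runif(5000, 1, 1e6),
                         noise_sd = 0.05, seed = 1)
fit_sved(p)
#> Sved fit [SIM]: beta = 1.922e-05 (SE 1.72e-07), residual SD 0.0417, 5000 pairs

g2 <- simulate_population(sim_config(effective_size = 100, sample_n = 100,
                                     n_chromosomes = 1,
                                     chromosome_length_bp = 20e6,
                                     marker_spacing_bp = 25e3,
                                     generations = 0, seed = 7))
g2 <- implant_roh(g2, "1", 8e6, 13e6, carrier_fraction = 0.7, seed = 11)
find_islands(call_roh(g2), g2)
#>   population chr start_bp  end_bp length_bp n_snp carrier_fraction
#> 1        SIM   1    8e+06 1.3e+07     5e+06   201             0.54
```

The island is recovered at exactly the implanted bounds; the carrier
fraction reported is the minimum per-marker incidence across the island
(edge markers sit slightly below the interior sharing level of 0.70).

## Analysis scripts

`analysis/01_simulate_panels.R` … `05_breed_structure.R` run the full
narrative on simulated panels with contrasting histories (large, mid,
small, bottlenecked populations): panel simulation and PED/MAP export, LD
decay and β clustering, Ne trajectories (the bottleneck shows
Ne(T=5) ≪ Ne(T=50)), ROH segments/length classes/islands with gene
annotation, and distances/NJ/PCA. Each writes its tables under
`results/`. `run_pipeline()` performs the same chain from a single YAML
config with per-breed failure isolation and a reproducibility manifest.

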