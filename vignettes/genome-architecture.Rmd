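---
title: "Genome architecture of cattle breeds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome architecture of cattle breeds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovarch)
```

This package implements the analysis chain used to characterize the genome
architecture of multi-breed SNP panels — linkage disequilibrium (LD) decay,
LD-based effective population size, runs of homozygosity (ROH) and ROH
islands, and allele-frequency breed structure — together with a forward
Wright–Fisher simulator that provides ground truth for every stage. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the validation on synthetic data does and does not show.

## Genotype representation and quality control

A panel is a samples × markers matrix of minor-allele dosages (0/1/2,
`NA` = missing call) with per-sample breed labels and a marker map. The
whole package works on a single genetic-map convention: **1 Mb = 1 cM**, so
a physical distance `d` bp corresponds to `d × 1e-8` Morgan. Coordinates
are 1-based inclusive; BED input is converted on read.

QC mirrors array-genotyping practice: markers are dropped when the call
rate falls below 0.95 or the minor allele frequency (MAF) below 0.01, then
samples with call rate below 0.85 are dropped. The order is marker filters
first, then the sample filter, in a single pass with no recomputation —
an explicit design choice that makes the filter deterministic and
idempotent in practice (re-running on its own output removes nothing when
the removed samples carried no calls, and nothing at all when no sample
was removed). MAF uses only non-missing calls in its denominator. The
minor allele is defined per marker from the parsed file; an exact 0.5 tie
is broken toward the lexicographically smaller allele symbol so parsing is
reproducible.

## LD decay under Sved's model

Pairwise LD is the composite (Rogers–Huff) r²: the squared Pearson
correlation of unphased dosage vectors over samples non-missing at both
markers. No haplotype phasing or EM estimation is involved; this matches
what standard tooling computes for unphased diploid data. The pair scan
honors two limits at once — a maximum index separation between markers and
a maximum physical distance — because the short-range scan used for decay
curves (5 SNPs / 1000 kb) and the wide scan needed for effective
population size (up to 12.5 Mb) have different needs. Both are exposed.

Decay with distance follows Sved's drift model

$$E[r^2] = \frac{1}{1 + 4\beta d},$$

with `d` in bp and the decay coefficient β per bp; a smaller β means LD
extends further. `fit_sved()` estimates β by nonlinear least squares
(`nls`, port algorithm, β bounded below by 1e-12). Residuals are treated
as homoscedastic Gaussian; no weighting. Numerical choices:

* starting value β₀ = 1/(4 × median distance), which makes the starting
  curve pass through the middle of the cloud;
* up to 5 restarts at log-spaced perturbations of β₀ on failure;
* the reported SE is the asymptotic one from the fit. A noiseless cloud
  fits exactly, so its SE is 0 — allowed deliberately, since exact-curve
  recovery is one of the package's own checks.

Two identities are useful for testing and are guaranteed by the
parameterization: doubling all distances halves β̂, and expressing
distances in kb multiplies β̂ by 1000.

Curves are compared pairwise with a Wald statistic on the coefficients,
z = (β̂ₐ − β̂ᵦ)/√(SEₐ² + SEᵦ²), two-sided normal p-values and Bonferroni
adjustment over the pairs. This is the minimal test consistent with
comparing fitted decay coefficients; nothing stronger (e.g. an F-test on
stacked residuals) is attempted because the pair clouds of different
populations are not jointly modelled.

Populations are clustered on the scalar β̂ values with Euclidean distance
and Ward linkage. We use `hclust` method `"ward.D2"`, the Ward
implementation appropriate for unsquared Euclidean input. The cluster
count can be fixed (k = 4 reproduces the published 19-breed grouping
bundled with the package) or chosen by maximum average silhouette width
over k ∈ [2, min(8, n−1)]; with three or fewer populations the silhouette
comparison is not meaningful and k defaults to 2. Ties in β̂ resolve by
input order, making the dendrogram deterministic.

## Effective population size from binned r²

Mean r² at genetic distance `c` Morgan reflects the effective size of the
population roughly T = 1/(2c) generations ago:

$$N_e = \frac{1}{4c}\left(\frac{1}{\bar r^2} - 1\right).$$

Pairs from a wide scan are grouped into four distance bins, (0, 0.01],
(0.01, 0.03], (0.03, 0.05] and (0.05, 0.125] Morgan, and each bin is
converted at a fixed representative distance c = 0.01, 0.03, 0.05, 0.1 —
i.e. generations 50, 16.6, 10 and 5. Three deliberate conventions:

* **Bins are genetic distances.** The four ranges are interpreted in
  Morgan (1–3 Mb physical under 1 cM/Mb, and so on); this is what makes
  the generation labels 50/16.6/10/5 come out of T = 1/(2c) exactly.
* **Representative c is 1/(2T), not the empirical mean pair distance**, so
  the generation labels are exact; the price is a mild bias when the
  within-bin distance distribution is skewed.
* **The open-ended last bin is capped at 0.125 Morgan** (12.5 Mb),
  configurable — an uncapped bin would mix arbitrarily long-range pairs
  into the most recent generation estimate.

No 1/(2n) sampling correction is applied to r̄² — the estimator is used in
its uncorrected form — so Ne is biased downward at small sample sizes
(sampling noise inflates r̄²). The simulation-based validation bands below
absorb this known bias rather than hiding it. Empty bins yield `NA` rows,
never fabricated values, and the trajectory also reports
ΔNe = Ne(T=50) − Ne(T=5), the contrast used to flag recent contractions.

## Runs of homozygosity

The caller is a sliding-window scan with the parameter set used throughout
(defaults of `roh_params()`): window of 50 SNPs, at most 1 heterozygote
and 5 missing calls per homozygous window; a marker joins a candidate run
when strictly more than 5% of the windows covering it are homozygous; runs
split at inter-marker gaps above 1,000 kb; a run is emitted when at least
1,000 kb long **and** carrying at least 120 SNPs. Markers near chromosome
ends are covered by fewer windows and use the reduced denominator; a
chromosome shorter than the window is scored from the single truncated
whole-chromosome window. Missing calls count only toward the missing
budget, never as heterozygotes. The two SNP-count parameters play
different roles: 50 is the scanning window, 120 the minimum SNPs per
emitted segment. An additional per-segment SNP-density floor is exposed
but off by default, since its intended semantics in the source tooling
are ambiguous.

Segment and island lengths are **end − start** (not end − start + 1).
This convention was chosen because it reproduces, exactly, every
verifiable row of the published island table bundled with the package
(six rows; one row prints a length inconsistent with its own bounds and is
excluded as a typo).

Islands are regions where the fraction of individuals carrying a covering
segment strictly exceeds 50%. They are computed per population from
per-marker incidence — deterministic and invariant to sample and segment
order, and a direct reading of the "shared by more than 50%" criterion —
rather than by pooled-overlap grouping of segment pairs. The reported
carrier fraction is the *minimum* incidence across the island's markers,
a conservative summary: at implanted-island edges single samples may lose
the outermost marker, so the minimum sits slightly below the interior
sharing level. Gene annotation assigns a gene to an island on any 1-bp
overlap of their 1-based inclusive intervals, reading BED (converted from
0-based half-open) or GFF3 `gene` features via `rtracklayer` and
intersecting via `GenomicRanges`.

## Breed structure

Population distances are Euclidean on per-breed allele frequencies,
computed over markers whose frequency is defined in every population
(markers with any all-missing population are dropped and counted). The
frequency — rather than raw genotype-mean — basis is a documented choice.
Trees come from Saitou–Nei neighbor joining (`ape::nj`); negative branch
lengths, which can arise from non-additive matrices, are clamped to zero
with a message. PCA mean-imputes missing dosages per marker, drops
zero-variance markers, and fixes signs so each component's
largest-magnitude loading is positive (scores are otherwise sign-arbitrary).
A greedy r²-threshold LD pruner is provided as plumbing for structure
analyses but is off by default, since pruning is not part of the distance
or PCA definitions here.

## The simulator: what it emulates, and what it does not

`simulate_population()` is a forward Wright–Fisher simulator: N diploids,
discrete generations, random mating; each gamete recombines a random
parent's two haplotypes with a Poisson(chromosome genetic length)
crossover count, uniform crossover placement, no interference;
chromosomes assort independently. Founders carry allele frequency 0.5 at
every marker; there is no mutation, selection or migration. Piecewise
population histories are composed by chaining runs through the `founders`
argument. Missing calls are masked at a configurable rate, and everything
is reproducible from one seed.

This emulates exactly the ingredients the estimators rest on — drift at
rate 1/(2N), recombination at 1 cM/Mb, and sampling of diploids — and so
supports sharp recovery tests: heterozygosity decays as
0.5 (1 − 1/(2N))^t; mean r² at genetic distance c approaches the
drift-recombination balance near 1/(1 + 4Nc) plus a 1/(2n) sampling term
(checked softly, with 3-SE Monte-Carlo bands, because this classical
expectation is itself an approximation). What the simulator does **not**
reproduce: real marker ascertainment (array SNPs are chosen to be common),
site-frequency spectra shaped by mutation, varying recombination maps,
genotyping error, and family structure. Passing the recovery tests
therefore shows the estimators are implemented correctly for the model
they assume, not that real cattle panels satisfy that model.

`implant_roh()` plants a clean homozygous tract (major-allele homozygote
at every marker in a region) into a chosen fraction of samples — carriers
are the first ⌈f·n⌉ after a seeded shuffle, so tests can enumerate them.
`sved_pair_generator()` draws (distance, r²) clouds exactly on the Sved
curve plus truncated Gaussian noise.

## Validation study conditions

The simulation problem sizes were fixed once, from the structure of the
estimators, and are used identically by the test suite and the acceptance
script:

* **Sved recovery**: β = 2×10⁻⁵ per bp, 5,000 pairs uniform on (0, 1] Mb,
  noise SD 0.05, 20 replicates; median |β̂/β − 1| is the headline figure
  (observed ≈ 4%). Noiseless clouds must be recovered to 10⁻⁶ relative.
* **Ne recovery**: N = 100, 50 sampled diploids, 10 chromosomes × 26 Mb,
  **1 marker per Mb**, 100 generations. The 1 Mb spacing puts pair
  distances exactly at multiples of 0.01 Morgan, so each bin's pairs sit
  at or near its representative distance — the regime in which the fixed
  representative-c convention is unbiased. Bin-level mean r² is pooled
  over 5 replicates (weighted by pair count) before conversion, a variance
  control equivalent to simulating one larger genome. Expected values sit
  in the 60–130 range around the true N = 100: the uncorrected sampling
  term 1/(2n) = 0.01 depresses the distant-bin estimates, which is the
  documented bias of the uncorrected estimator.
* **Contraction detection**: N = 200 for 60 generations, then N = 20 for
  8 generations, 20 sampled diploids; Ne(T=5) < Ne(T=50) expected in at
  least 8 of 10 replicates.
* **ROH island recovery**: 100 samples on one 20 Mb chromosome at 25 kb
  spacing, founders drawn at Hardy–Weinberg with frequency 0.5 and zero
  generations of drift (so the background carries no natural ROH), a 5 Mb
  implant in 70% of samples; the island must be recovered with bounds
  within one marker spacing in at least 19 of 20 replicates.

## Known limitations

* The composite-r² scan is O(samples × markers × window) per population;
  it is intended for array-scale panels, not sequence data.
* The Sved fit assumes homoscedastic residuals; at very short distances
  the r² distribution is strongly skewed, so the SE is approximate.
* Ne values use the uncorrected r̄² estimator (see above); comparisons
  across populations with very different sample sizes inherit that bias.
* The ROH caller reproduces a specific sliding-window parameterization;
  results are, as for all ROH methods, sensitive to marker density, and
  cross-density comparisons need identical parameter sets.
* The admixture-style ancestry decomposition that often accompanies these
  analyses is out of scope; breed structure here means distances, NJ trees
  and PCA.
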