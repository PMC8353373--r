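#' Published reference tables for 19 cattle breeds raised in Brazil
#'
#' Small reference tables transcribed from a published genome-architecture
#' survey of 19 Brazilian cattle breeds (taurine, indicine, Iberian-derived
#' locally adapted, and synthetic crossbred groups). They let the package's
#' conventions be checked against reported values without access to the
#' underlying (proprietary) genotypes:
#'
#' * `cattle_panel_summary()` — per-breed animal and post-QC marker counts
#'   plus group membership; group sample sizes sum to 432 (taurine), 366
#'   (indicine), 281 (locally adapted) and 241 (synthetic), total 1320.
#' * `cattle_beta_estimates()` — Sved decay coefficients (beta, per bp) and
#'   the standard errors as printed for each breed. Note the printed SE
#'   column is on a different scale than beta and is kept verbatim only.
#' * `cattle_roh_islands()` — the reported ROH islands (>50% of individuals)
#'   with bounds, printed length, SNP count and sharing frequency. The
#'   printed TAB length (823) is inconsistent with its bounds
#'   (end - begin = 822,809) and is carried as printed.
#'
#' @return a data.frame.
#' @name reference_tables
NULL

.extdata <- function(name) {
  path <- system.file("extdata", name, package = "bovarch")
  if (!nzchar(path)) stop("bundled table not found: ", name)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' @rdname reference_tables
#' @export
cattle_panel_summary <- function() .extdata("cattle_panel_summary.tsv")

#' @rdname reference_tables
#' @export
cattle_beta_estimates <- function() .extdata("cattle_beta_estimates.tsv")

#' @rdname reference_tables
#' @export
cattle_roh_islands <- function() .extdata("cattle_roh_islands.tsv")
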