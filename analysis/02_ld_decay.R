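#!/usr/bin/env Rscript
# LD decay per population: QC, wide-window composite r2, Sved-model fits,
# pairwise curve-equality tests, and Ward clustering of the decay
# coefficients (on the simulated panels and on the bundled 19-breed
# reference coefficients).

library(bovarch)

out <- "results/ld"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
panels <- c("LARGE", "MID", "SMALL", "BOTTLE")

fits <- list()
for (nm in panels) {
  g <- read_ped_map(file.path("results/panels", paste0(nm, ".ped")),
                    file.path("results/panels", paste0(nm, ".map")))
  g <- qc_filter(g)$geno
  pr <- pairwise_r2(g, max_dist_kb = 12500, max_snp_sep = 10000,
                    population = nm)
  fits[[nm]] <- fit_sved(pr)
  cat(sprintf("%-6s beta = %.3e (SE %.1e) from %d pairs\n",
              nm, fits[[nm]]$beta_hat, fits[[nm]]$se, fits[[nm]]$n_pairs))
}
write.table(data.frame(population = names(fits),
                       beta = sapply(fits, `[[`, "beta_hat"),
                       se = sapply(fits, `[[`, "se"),
                       n_pairs = sapply(fits, `[[`, "n_pairs")),
            file.path(out, "sved_fits.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# smaller populations hold LD longer, hence larger beta means faster decay:
# expect beta(LARGE) > beta(MID) > beta(SMALL)
b <- sapply(fits, `[[`, "beta_hat")
cat("decay order (fast -> slow): ",
    paste(names(sort(b, decreasing = TRUE)), collapse = " > "), "\n")

cmp <- curve_equality_test(fits)
write.table(data.frame(pair = outer(rownames(cmp$p_adj), colnames(cmp$p_adj),
                                    paste)[upper.tri(cmp$p_adj)],
                       p_adj = cmp$p_adj[upper.tri(cmp$p_adj)]),
            file.path(out, "curve_equality.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("curve pairs distinguishable at p_adj < 0.05:",
    sum(cmp$p_adj[upper.tri(cmp$p_adj)] < 0.05), "of",
    sum(upper.tri(cmp$p_adj)), "\n")

# reference coefficients: 19 breeds, Ward/Euclidean, cut at k = 4
bt <- cattle_beta_estimates()
cl <- cluster_breeds(setNames(bt$beta, bt$breed), k = 4)
write.table(data.frame(breed = names(cl$cluster), cluster = cl$cluster,
                       beta = cl$beta),
            file.path(out, "reference_beta_clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
clustering_newick(cl, file.path(out, "reference_beta_dendrogram.nwk"))
for (k in sort(unique(cl$cluster)))
  cat("cluster", k, ":", paste(names(cl$cluster)[cl$cluster == k],
                               collapse = ", "), "\n")
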