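#!/usr/bin/env Rscript
# Breed structure across the simulated populations: allele-frequency
# Euclidean distances, neighbor-joining tree, and genotype PCA.

library(bovarch)

out <- "results/structure"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

panels <- lapply(c("LARGE", "MID", "SMALL", "BOTTLE"), function(nm)
  qc_filter(read_ped_map(file.path("results/panels", paste0(nm, ".ped")),
                         file.path("results/panels", paste0(nm, ".map"))),
            maf_min = 0.01)$geno)

# stack on the shared marker set
common <- Reduce(intersect, lapply(panels, function(p) p$map$marker_id))
parts <- lapply(panels, function(p)
  subset_geno(p, markers = match(common, p$map$marker_id)))
joint <- geno_matrix(do.call(rbind, lapply(parts, `[[`, "dosages")),
                     do.call(rbind, lapply(parts, `[[`, "samples")),
                     parts[[1]]$map)
cat("joint panel:", n_samples(joint), "samples x", n_markers(joint),
    "shared markers\n")

freqs <- allele_frequencies(joint, by_breed = TRUE)
dm <- population_distance(freqs)
write.table(data.frame(population = rownames(dm), dm, check.names = FALSE),
            file.path(out, "breed_distance.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("population distances:\n")
print(round(dm, 2))

tr <- nj_tree(dm)
ape::write.tree(tr, file.path(out, "nj_tree.nwk"))
cat("NJ tree:", ape::write.tree(tr), "\n")

pca <- genotype_pca(joint, n_components = 2)
write.table(data.frame(sample_id = rownames(pca$scores), breed = pca$breed,
                       pca$scores, check.names = FALSE),
            file.path(out, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("PCA: PC1 %.1f%%, PC2 %.1f%% of variance\n",
            100 * pca$explained[1], 100 * pca$explained[2]))
# independently drifted populations should separate on the leading PCs
sp <- split(pca$scores[, 1], pca$breed)
rngs <- sapply(sp, range)
cat("PC1 ranges per breed:\n"); print(round(rngs, 1))
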