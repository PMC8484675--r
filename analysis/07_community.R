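#!/usr/bin/env Rscript
# Community structure on the copy-number table: Bray-Curtis dissimilarity,
# 2-D NMDS with Kruskal stress, and one-factor PERMANOVAs for reef vs
# surrounding stations and middle vs bottom layers.
library(reefquant)

out <- "results/community"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

q <- read.delim("results/quantified/copies_per_ml.tsv", check.names = FALSE)
copies <- as.matrix(q[, -1]); rownames(copies) <- q$sample_id
meta <- read.delim("results/synthetic/sample_metadata.tsv")
meta <- meta[match(rownames(copies), meta$sample_id), ]

d <- bray_curtis(copies)
ord <- nmds(d, k = 2, n_starts = 50, seed = 1)
reef <- ifelse(meta$station_id %in% c("AR1", "AR2"), "reef", "surrounding")
p_reef <- permanova(d, reef, n_perm = 999, seed = 1)
p_depth <- permanova(d, meta$depth_layer, n_perm = 999, seed = 1)

coords <- data.frame(sample_id = rownames(copies), ord$points,
                     station = meta$station_id, depth_layer = meta$depth_layer,
                     group = reef)
write.table(coords, file.path(out, "nmds_coordinates.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(
  test = c("reef_vs_surrounding", "middle_vs_bottom"),
  f = c(p_reef$f, p_depth$f),
  p_value = c(p_reef$p_value, p_depth$p_value),
  n_perm = 999, stress = ord$stress
), file.path(out, "permanova.tsv"), sep = "\t", quote = FALSE,
row.names = FALSE)

cat(sprintf("NMDS stress (2-D, 50 starts): %.3f\n", ord$stress))
cat(sprintf("PERMANOVA reef vs surrounding: F = %.3f, p = %.3f\n",
            p_reef$f, p_reef$p_value))
cat(sprintf("PERMANOVA middle vs bottom:    F = %.3f, p = %.3f\n",
            p_depth$f, p_depth$p_value))
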