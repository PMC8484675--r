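#!/usr/bin/env Rscript
# OTU table cleanup in the fixed order: assignment-quality filters ->
# taxonomy collapsing -> per-sample 0.05% noise filter -> contaminant
# removal. Emits the cleaned table, the taxon labels and a drop-reason audit.
library(reefquant)

indir <- "results/synthetic"
out <- "results/filtered"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read.delim(file.path(indir, "read_table.tsv"), check.names = FALSE)
m <- as.matrix(counts[, -1]); rownames(m) <- counts$sample_id
classes <- read.delim(file.path(indir, "otu_classes.tsv"))
rt <- read_table(m, standard_ids = classes$otu_id[classes$class == "standard"])
recs <- read.delim(file.path(indir, "assignments.tsv"))
checklist <- regional_checklist(unique(unlist(
  strsplit(recs$hit_species, ";", fixed = TRUE))))

res <- preprocess_reads(rt, recs, checklist)

write.table(res$audit, file.path(out, "otu_audit.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$labels, file.path(out, "taxon_labels.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample_id = rownames(res$read_table$counts),
                       res$read_table$counts, check.names = FALSE),
            file.path(out, "read_table_filtered.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d OTUs in, %d kept (%s)\n", nrow(res$audit),
            sum(res$audit$fate == "kept"),
            paste(sprintf("%s: %d", names(table(res$audit$fate)),
                          table(res$audit$fate)), collapse = ", ")))
cat(sprintf("ranks among kept labels: %s\n",
            paste(sprintf("%s %d", names(table(res$labels$rank)),
                          table(res$labels$rank)), collapse = ", ")))
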