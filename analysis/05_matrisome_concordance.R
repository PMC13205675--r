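#!/usr/bin/env Rscript
# Stage 5: matrisome statistics - categorization of a gene list against the
# reference, cross-species Venn overlap, DEG filtering, and the
# nine-quadrant mRNA-protein concordance of the simulated paired omics
# table.

suppressPackageStartupMessages(library(ovamat))
dir.create("results", showWarnings = FALSE)

ref <- load_reference()

## categorize a mixed list (matrisome + background genes)
ids <- c(ref$entries$identifier[1:20], sprintf("background%02d", 1:10))
ann <- annotate_list(ids, ref)
write.csv(data.frame(category = names(ann$counts), count = ann$counts,
                     pct_of_matrisome = round(ann$percentages, 1)),
          "results/matrisome_categories.csv", row.names = FALSE)
print(ann)

## cross-species overlap on synthetic species lists sharing a common core
set.seed(7)
core <- ref$entries$identifier
species <- list(
  human = c(core[1:22], sprintf("hs%02d", 1:8)),
  pig = c(core[5:26], sprintf("ss%02d", 1:6)),
  mouse = c(core[1:30])
)
ov <- overlap_sets(species)
write.csv(ov$regions, "results/matrisome_venn.csv", row.names = FALSE)
cat("Venn: union", ov$union_size, "identifiers;",
    "three-species core:", ov$regions$count[ov$regions$label == "human&pig&mouse"], "\n")

## DEG filter and nine-quadrant concordance on the paired table
omics <- gen_omics_table(omics_table_spec(n_genes = 5000, log2fc_correlation = 0.5,
                                          fraction_significant = 0.3, seed = 7L))
deg_m <- deg_filter(data.frame(log2fc = omics$log2fc_mrna, p = omics$p_mrna))
cat("mRNA DEGs (|log2FC| > 1, p < 0.05):", deg_m$n_total,
    "(", deg_m$n_up, "up /", deg_m$n_down, "down )\n")

qa <- nine_quadrant(omics)
write.csv(data.frame(quadrant = 1:9, count = qa$counts),
          "results/nine_quadrant_counts.csv", row.names = FALSE)
print(qa)
cat(sprintf("Fold-change concordance: Pearson r = %.4f over n = %d genes\n",
            qa$pearson_r, qa$n))
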