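#!/usr/bin/env Rscript
# Over-representation analysis of the screened gene lists.
#
# Hypergeometric ORA of each class's positively associated genes
# against a gene-set collection, with the intersected transcriptome as
# the background universe and the raw p < 0.05 call. Live GO/KEGG
# services are out of scope, so the collection here is synthetic: one
# set built around each planted module (the stand-in for a curated
# term) plus random decoy sets. Run 03_transcriptome_screen.R first.

library(nervatlas)

dir.create("results", showWarnings = FALSE)
stopifnot(file.exists("results/gene_universe.txt"))

universe <- readLines("results/gene_universe.txt")

# rebuild the generating truth to construct module-anchored sets
X <- atlas_densities()
profiled <- c("Gastrocnemius", "Tibialis anterior", "Gluteus maximus",
              "Triceps", "Extensor digitorum longus", "Soleus", "Plantaris")
sim <- simulate_expression(n_genes = 2000,
                           datasets_per_muscle = ifelse(profiled == "Soleus", 2, 1),
                           densities = X[profiled, ], seed = 2024)
mo <- sim$truth$gene_module_of

set.seed(2024)
collection <- list()
for (cl in c("sensory", "sympathetic", "motor")) {
  members <- names(mo)[!is.na(mo) & mo == cl]
  # dilute with unrelated genes so the set is not the module verbatim
  collection[[paste0("MODULE_", toupper(cl))]] <- list(
    description = paste(cl, "module stand-in (synthetic)"),
    members = c(members, sample(setdiff(universe, members), 40)))
}
for (i in 1:30) {
  collection[[sprintf("DECOY_%02d", i)]] <- list(
    description = "random decoy set (synthetic)",
    members = sample(universe, sample(30:120, 1)))
}
write_gene_sets(collection, "results/synthetic_sets.gmt")

for (cl in c("sensory", "sympathetic", "motor")) {
  lst <- readLines(sprintf("results/genes_up_%s.txt", cl))
  enr <- enrich_all(lst, collection, universe, alpha = 0.05, gate = "raw")
  enr$p_value <- signif(enr$p_value, 4)
  enr$bh_q <- signif(enr$bh_q, 4)
  write.table(enr, sprintf("results/enrichment_up_%s.tsv", cl), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat("\n==", cl, "positively associated genes: top terms ==\n")
  print(top_terms(enr, 5), row.names = FALSE)
}
# each class's module-anchored set rises to the top of its list while
# decoys stay non-significant; the sympathetic and motor lists each
# carry both of those classes' module sets because their density
# profiles are collinear over the profiled muscles (see
# 03_transcriptome_screen.R)
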