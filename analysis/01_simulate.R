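#!/usr/bin/env Rscript

# Generate the synthetic study inputs: a GWAS summary-statistic table, gene
# models, tissue-annotated eQTL records, a drug-gene interaction table and a
# human/worm ortholog table, with one planted full-pass candidate gene whose
# identity is recorded in truth.json. All downstream analysis scripts read
# this bundle from results/bundle/.

suppressPackageStartupMessages(library(gwasfunnel))

seed <- 20240227
cfg <- bundle_config(n_snps = 10000, n_genes = 500, n_planted = 1,
                     planted_support = 2)
bundle <- simulate_bundle(cfg, seed = seed)
write_bundle(bundle, "results/bundle")

cat("bundle written to results/bundle (seed", seed, ")\n")
cat("  SNPs:         ", nrow(bundle$gwas), "\n")
cat("  genes:        ", nrow(bundle$genes), "\n")
cat("  eQTL records: ", nrow(bundle$eqtls), "\n")
cat("  drug-gene:    ", nrow(bundle$dgi), "\n")
cat("  orthologs:    ", nrow(bundle$orthologs), "\n")
cat("planted candidate:", bundle$truth$candidates$gene_id,
    "requiring an", bundle$truth$candidates$required_action, "\n")
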