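# Small table builders for unit tests.

make_gwas <- function(snp_id, chrom = "chr1", pos = 1000L,
                      effect_allele = "A", other_allele = "G",
                      or = 1.5, p = 1e-4) {
  tibble::tibble(
    snp_id = snp_id, chrom = chrom, pos = as.integer(pos),
    effect_allele = effect_allele, other_allele = other_allele,
    or = or, p = p
  )
}

make_genes <- function(gene_id, chrom = "chr1", start = 0L, end = 1000L,
                       strand = "+") {
  tibble::tibble(
    gene_id = gene_id, chrom = chrom, start = as.integer(start),
    end = as.integer(end), strand = strand,
    tss = ifelse(strand == "+", as.integer(start), as.integer(end) - 1L)
  )
}

make_eqtls <- function(snp_id, gene_id, tissue = "Cerebellum",
                       direction = 1L, eqtl_p = 1e-6, effect_allele = "A") {
  tibble::tibble(
    snp_id = snp_id, gene_id = gene_id, tissue = tissue,
    direction = as.integer(direction), eqtl_p = eqtl_p,
    effect_allele = effect_allele
  )
}

make_dgi <- function(gene_id, drug_name = paste0("drug-", gene_id),
                     action = "inhibitor", approved = TRUE) {
  tibble::tibble(
    gene_id = gene_id, drug_name = drug_name, action = action,
    approved = approved
  )
}

make_orthologs <- function(human_gene, model_gene = paste0("m-", human_gene),
                           percent_identity = 50, source = "synthetic") {
  tibble::tibble(
    human_gene = human_gene, model_gene = model_gene,
    percent_identity = percent_identity, source = source
  )
}

# Random small funnel inputs for property tests. Each gene's eQTL records
# are risk-consistent (all its supporting SNPs imply the same mechanism
# after risk re-orientation), the regime in which threshold relaxation is
# provably monotone; see the methods vignette.
random_funnel_tables <- function(seed, n_snps = 120, n_genes = 15) {
  withr::with_seed(seed, {
    genes <- make_genes(
      sprintf("G%02d", seq_len(n_genes)),
      chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
      start = as.integer(seq_len(n_genes)) * 10000L,
      end = as.integer(seq_len(n_genes)) * 10000L + 5000L,
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
    eff <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
    oth <- vapply(eff, function(e) sample(setdiff(c("A", "C", "G", "T"), e), 1),
                  character(1))
    gwas <- make_gwas(
      sprintf("rs%04d", seq_len(n_snps)),
      chrom = sample(c("chr1", "chr2"), n_snps, replace = TRUE),
      pos = sample.int(200000L, n_snps, replace = TRUE),
      effect_allele = eff, other_allele = oth,
      or = exp(rnorm(n_snps, 0, 0.3)),
      p = runif(n_snps)
    )
    gene_dir <- setNames(sample(c(-1L, 1L), n_genes, replace = TRUE),
                         genes$gene_id)
    n_eq <- max(1L, rbinom(1, n_snps, 0.4))
    eq_rows <- sample.int(n_snps, n_eq)
    eq_gene <- sample(genes$gene_id, n_eq, replace = TRUE)
    use_eff <- runif(n_eq) < 0.5
    # harmonized risk direction fixed per gene; undo the per-SNP risk
    # re-orientation and the allele choice to get the stated direction
    dir_harm <- ifelse(gwas$or[eq_rows] > 1,
                       gene_dir[eq_gene], -gene_dir[eq_gene])
    eqtls <- make_eqtls(
      gwas$snp_id[eq_rows], eq_gene,
      tissue = sample(tissue_vocabulary(), n_eq, replace = TRUE),
      direction = ifelse(use_eff, dir_harm, -dir_harm),
      eqtl_p = runif(n_eq, 1e-8, 0.05),
      effect_allele = ifelse(use_eff, gwas$effect_allele[eq_rows],
                             gwas$other_allele[eq_rows])
    )
    n_dgi <- max(1L, rbinom(1, n_genes, 0.6))
    dgi_gene <- sample(genes$gene_id, n_dgi, replace = TRUE)
    dgi <- make_dgi(
      dgi_gene,
      drug_name = sprintf("d%03d", seq_len(n_dgi)),
      action = sample(c("inhibitor", "activator", "other"), n_dgi,
                      replace = TRUE),
      approved = runif(n_dgi) < 0.7
    )
    n_orth <- max(1L, rbinom(1, n_genes, 0.7))
    orth_gene <- sample(genes$gene_id, n_orth)
    orthologs <- make_orthologs(
      orth_gene, percent_identity = runif(n_orth, 0, 100)
    )
    list(gwas = gwas, genes = genes, eqtls = eqtls, dgi = dgi,
         orthologs = orthologs)
  })
}
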