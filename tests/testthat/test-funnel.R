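test_that("significance selection uses a strict threshold", {
  snps <- make_gwas(c("a", "b", "c"), pos = c(1, 2, 3) * 100L,
                    p = c(0.5, 0.009, 0.01))
  expect_equal(select_significant(snps, 0.01)$snp_id, "b")
  expect_equal(nrow(select_significant(snps, 1)), 3)
  expect_equal(nrow(select_significant(snps, 0)), 0)
})

test_that("retained count under uniform p-values follows the binomial law", {
  withr::with_seed(99, {
    snps <- make_gwas(sprintf("rs%05d", 1:10000),
                      pos = sample.int(1e6, 10000), p = runif(10000))
  })
  k <- nrow(select_significant(snps, 1e-3))
  # Binomial(10000, 1e-3): mean 10, sd ~3.16; 3 sigma band
  expect_gt(k, 10 - 3 * sqrt(10))
  expect_lt(k, 10 + 3 * sqrt(10))
})

test_that("eQTL intersection is restricted to the requested tissues", {
  snp <- make_gwas("rs1", p = 1e-5)
  in_cns <- make_eqtls("rs1", "G1", tissue = "Cerebellum")
  expect_equal(nrow(intersect_cns_eqtls(snp, in_cns)), 1)
  in_liver <- make_eqtls("rs1", "G1", tissue = "Liver")
  expect_equal(nrow(intersect_cns_eqtls(snp, in_liver)), 0)
  expect_error(intersect_cns_eqtls(snp, in_cns, character(0)),
               "empty tissue set")
})

test_that("planted eQTL overlap returns exactly the planted genes", {
  b <- simulate_bundle(
    bundle_config(n_snps = 2000, n_genes = 100, n_planted = 3,
                  eqtl_rate = 0, druggability_rate = 0, ortholog_rate = 0),
    seed = 17
  )
  sig <- select_significant(b$gwas, b$config$alpha)
  pairs <- intersect_cns_eqtls(sig, b$eqtls, cns_tissues())
  expect_setequal(unique(pairs$gene_id), b$truth$candidates$gene_id)
})

test_that("the mechanism rule maps risk-allele expression gain to inhibition", {
  up <- required_mechanism(1.5, 1L)
  expect_equal(up$required_action, "inhibitor")
  expect_equal(up$risk_or, 1.5)
  down <- required_mechanism(1.5, -1L)
  expect_equal(down$required_action, "activator")
  # OR < 1: re-orient to the risk allele (OR -> 1/OR, direction -> -direction)
  flip <- required_mechanism(0.8, 1L)
  expect_equal(flip$required_action, "activator")
  expect_equal(flip$risk_or, 1.25)
  expect_equal(flip$risk_direction, -1L)
  expect_error(required_mechanism(1, 1L), "no risk direction")
  expect_error(required_mechanism(-2, 1L), "must be > 0")
})

test_that("risk re-orientation is an involution consistent with allele flips", {
  withr::with_seed(5, {
    or <- exp(rnorm(50, 0, 0.4))
    dir <- sample(c(-1L, 1L), 50, replace = TRUE)
  })
  a <- required_mechanism(or, dir)
  b <- required_mechanism(1 / or, -dir)
  expect_equal(a, b)
})

test_that("drug matching selects by gene, action and approval", {
  dgi <- rbind(
    make_dgi("G1", "inh-approved", "inhibitor", TRUE),
    make_dgi("G1", "inh-unapproved", "inhibitor", FALSE),
    make_dgi("G1", "act-approved", "activator", TRUE),
    make_dgi("G2", "other-gene", "inhibitor", TRUE)
  )
  hit <- match_drugs("G1", "inhibitor", dgi)
  expect_equal(hit$drug_name, "inh-approved")
  expect_equal(match_drugs("G1", "inhibitor", dgi,
                           approved_only = FALSE)$drug_name,
               c("inh-approved", "inh-unapproved"))
  expect_equal(nrow(match_drugs("G2", "activator", dgi)), 0)

  # randomized tables against a brute-force filter
  withr::with_seed(31, {
    for (rep in 1:20) {
      tab <- make_dgi(
        sample(c("G1", "G2", "G3"), 15, replace = TRUE),
        drug_name = sprintf("d%02d", 1:15),
        action = sample(c("inhibitor", "activator", "other"), 15,
                        replace = TRUE),
        approved = sample(c(TRUE, FALSE), 15, replace = TRUE)
      )
      g <- sample(c("G1", "G2", "G3"), 1)
      act <- sample(c("inhibitor", "activator"), 1)
      got <- match_drugs(g, act, tab)
      want <- tab[tab$gene_id == g & tab$action == act & tab$approved, ]
      expect_equal(got, want)
    }
  })
})

test_that("ortholog filter keeps the best pair at or above the threshold", {
  orth <- rbind(
    make_orthologs("G1", "m-low", 35),
    make_orthologs("G1", "m-high", 62)
  )
  expect_equal(filter_orthologs("G1", orth)$model_gene, "m-high")
  at_40 <- make_orthologs("G1", "m-edge", 40.0)
  expect_equal(nrow(filter_orthologs("G1", at_40)), 1) # >= is inclusive
  expect_equal(nrow(filter_orthologs("G1", at_40, min_identity = 40.5)), 0)

  withr::with_seed(77, {
    for (rep in 1:20) {
      tab <- make_orthologs(
        sample(c("G1", "G2"), 12, replace = TRUE),
        model_gene = sprintf("m%02d", sample(12)),
        percent_identity = round(runif(12, 0, 100), 1)
      )
      got <- filter_orthologs("G1", tab, 40)
      pool <- tab[tab$human_gene == "G1" & tab$percent_identity >= 40, ]
      if (nrow(pool) == 0) {
        expect_equal(nrow(got), 0)
      } else {
        best <- max(pool$percent_identity)
        expect_equal(got$percent_identity, best)
        expect_equal(got$model_gene,
                     sort(pool$model_gene[pool$percent_identity == best])[1])
      }
    }
  })
})

test_that("allele harmonization negates direction for the other allele", {
  gwas <- make_gwas("rs1", effect_allele = "A", other_allele = "G", p = 1e-5)
  eq <- make_eqtls("rs1", "G1", direction = 1L, effect_allele = "G")
  pairs <- intersect_cns_eqtls(gwas, eq)
  harm <- harmonize_direction(pairs, "strict")
  expect_equal(harm$direction, -1L)

  eq_na <- make_eqtls("rs1", "G1", direction = 1L,
                      effect_allele = NA_character_)
  pairs_na <- intersect_cns_eqtls(gwas, eq_na)
  expect_error(harmonize_direction(pairs_na, "strict"), "unharmonized")
  expect_equal(harmonize_direction(pairs_na, "assume")$direction, 1L)

  eq_bad <- make_eqtls("rs1", "G1", direction = 1L, effect_allele = "T")
  expect_error(harmonize_direction(intersect_cns_eqtls(gwas, eq_bad)),
               "neither GWAS allele")
})

test_that("run_funnel recovers a single planted candidate at rank 1", {
  b <- simulate_bundle(
    bundle_config(n_snps = 1000, n_genes = 80, n_planted = 1,
                  eqtl_rate = 0, druggability_rate = 0, ortholog_rate = 0),
    seed = 23
  )
  rep <- run_funnel(b$gwas, b$genes, b$eqtls, b$dgi, b$orthologs)
  tc <- top_candidates(rep)
  expect_equal(tc$gene_id, b$truth$candidates$gene_id)
  expect_equal(tc$rank, 1L)
  expect_equal(tc$required_action, b$truth$candidates$required_action)
  expect_equal(tc$ortholog, b$truth$candidates$model_gene)
  expect_equal(unname(rep$stage_counts["ortholog_genes"]), 1L)
})

test_that("alpha = 0 empties every stage", {
  b <- simulate_bundle(bundle_config(n_snps = 300, n_genes = 30), seed = 2)
  rep <- run_funnel(b$gwas, b$genes, b$eqtls, b$dgi, b$orthologs,
                    funnel_config(alpha = 0))
  after_input <- rep$stage_counts[-1]
  expect_true(all(after_input == 0))
  expect_equal(nrow(rep$candidates), 0)
})

test_that("candidates are ranked by support, then best p-value", {
  b <- simulate_bundle(
    bundle_config(n_snps = 3000, n_genes = 100, n_planted = 2,
                  planted_support = c(3L, 1L),
                  eqtl_rate = 0, druggability_rate = 0, ortholog_rate = 0),
    seed = 31
  )
  rep <- run_funnel(b$gwas, b$genes, b$eqtls, b$dgi, b$orthologs)
  tc <- top_candidates(rep)
  expect_equal(nrow(tc), 2)
  expect_equal(tc$n_support, c(3L, 1L))
  expect_equal(tc$gene_id[1], b$truth$candidates$gene_id[1])
})

test_that("discordant mechanism calls exclude a gene unless majority is kept", {
  gwas <- make_gwas(c("rs1", "rs2", "rs3"), pos = c(100L, 200L, 300L),
                    or = c(1.5, 1.4, 1.3), p = 1e-5)
  genes <- make_genes("G1", start = 0, end = 1000)
  eq <- make_eqtls(c("rs1", "rs2", "rs3"), "G1",
                   direction = c(1L, 1L, -1L)) # rs3 implies activator
  dgi <- make_dgi("G1", action = "inhibitor")
  orth <- make_orthologs("G1", percent_identity = 80)

  excl <- run_funnel(gwas, genes, eq, dgi, orth)
  expect_equal(nrow(top_candidates(excl)), 0)
  expect_true(excl$candidates$discordant)

  maj <- run_funnel(gwas, genes, eq, dgi, orth,
                    funnel_config(discordant_policy = "majority"))
  tc <- top_candidates(maj)
  expect_equal(tc$gene_id, "G1")
  expect_equal(tc$required_action, "inhibitor")
  expect_equal(tc$n_support, 2L) # only concordant pairs count as support
})

test_that("the optional blood-brain-barrier filter drops impermeable drugs", {
  gwas <- make_gwas("rs1", or = 2, p = 1e-5)
  genes <- make_genes("G1", start = 0, end = 2000)
  eq <- make_eqtls("rs1", "G1", direction = 1L)
  dgi <- make_dgi("G1", "drugX", "inhibitor")
  orth <- make_orthologs("G1", percent_identity = 70)
  bbb_no <- tibble::tibble(drug_name = "drugX", bbb_permeable = FALSE)
  bbb_yes <- tibble::tibble(drug_name = "drugX", bbb_permeable = TRUE)

  cfg <- funnel_config(bbb_filter = TRUE)
  rep_no <- run_funnel(gwas, genes, eq, dgi, orth, cfg, bbb = bbb_no)
  expect_equal(unname(rep_no$stage_counts["bbb_genes"]), 0L)
  expect_equal(nrow(top_candidates(rep_no)), 0)
  rep_yes <- run_funnel(gwas, genes, eq, dgi, orth, cfg, bbb = bbb_yes)
  expect_equal(unname(rep_yes$stage_counts["bbb_genes"]), 1L)
})

test_that("funnel reports serialize to TSV and JSON", {
  b <- simulate_bundle(bundle_config(n_snps = 500, n_genes = 50), seed = 4)
  rep <- run_funnel(b$gwas, b$genes, b$eqtls, b$dgi, b$orthologs)
  prefix <- file.path(withr::local_tempdir(), "run")
  write_funnel_report(rep, prefix)
  expect_true(file.exists(paste0(prefix, ".candidates.tsv")))
  js <- jsonlite::read_json(paste0(prefix, ".report.json"))
  expect_equal(js$stage_counts$input_snps, 500)
  expect_equal(js$config$alpha, 1e-3)
})
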