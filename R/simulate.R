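# Synthetic-data generator: complete schema-valid input bundles with planted
# ground-truth candidates, so the whole funnel is testable without any
# external download. Background association p-values are uniform(0, 1] and
# background log odds ratios normal(0, 0.03), placing background per-SNP ORs
# in the ~1.03-1.04 band typical of a polygenic case-control scan; planted
# SNPs get p-values below the configured alpha and inflated |log-OR|, and
# are placed in cis (within 100 kb) of their target gene's TSS.

#' Generation parameters for a synthetic input bundle
#'
#' @param n_snps Number of GWAS SNPs.
#' @param n_genes Number of gene models.
#' @param n_chroms Number of chromosomes (genes and SNPs spread uniformly).
#' @param n_planted Number of planted full-pass candidate genes.
#' @param alpha Significance threshold the planted SNPs must beat.
#' @param tissues CNS tissue set planted eQTLs are drawn from.
#' @param eqtl_rate Probability a background SNP is an eQTL (for one random
#'   same-chromosome gene, in a random tissue from the full vocabulary).
#' @param druggability_rate Probability a background gene has a drug-gene
#'   interaction record.
#' @param ortholog_rate Probability a background gene has an ortholog record.
#' @param planted_support Supporting SNPs per planted gene (recycled).
#' @param log_or_sd Standard deviation of background log odds ratios.
#' @param chrom_length Chromosome length in bp.
#' @return List of class `bundle_config`.
#' @export
bundle_config <- function(n_snps = 10000, n_genes = 500, n_chroms = 5,
                          n_planted = 1, alpha = 1e-3,
                          tissues = cns_tissues(),
                          eqtl_rate = 0.05, druggability_rate = 0.05,
                          ortholog_rate = 0.05, planted_support = 1,
                          log_or_sd = 0.03, chrom_length = 2e6) {
  stopifnot(
    n_snps >= 1, n_genes >= 1, n_chroms >= 1, n_planted >= 0,
    alpha > 0, alpha < 1, length(tissues) > 0,
    eqtl_rate >= 0, eqtl_rate <= 1, druggability_rate >= 0,
    druggability_rate <= 1, ortholog_rate >= 0, ortholog_rate <= 1,
    all(planted_support >= 1), log_or_sd >= 0, chrom_length > 1e4
  )
  structure(
    list(
      n_snps = as.integer(n_snps), n_genes = as.integer(n_genes),
      n_chroms = as.integer(n_chroms), n_planted = as.integer(n_planted),
      alpha = alpha, tissues = tissues, eqtl_rate = eqtl_rate,
      druggability_rate = druggability_rate, ortholog_rate = ortholog_rate,
      planted_support = as.integer(planted_support), log_or_sd = log_or_sd,
      chrom_length = as.integer(chrom_length)
    ),
    class = "bundle_config"
  )
}

BASES <- c("A", "C", "G", "T")

# non-overlapping gene placement: each gene gets its own slot on its
# chromosome, with a random start and length inside the slot
simulate_genes <- function(cfg) {
  n <- cfg$n_genes
  chrom_of <- rep(paste0("chr", seq_len(cfg$n_chroms)), length.out = n)
  chrom_of <- sort(chrom_of)
  per_chrom <- table(chrom_of)
  starts <- integer(n)
  ends <- integer(n)
  i <- 1L
  for (ch in names(per_chrom)) {
    k <- per_chrom[[ch]]
    slot <- cfg$chrom_length %/% k
    glen <- pmin(pmax(as.integer(runif(k, 2000, 20000)), 100L), slot - 2L)
    off <- floor(runif(k) * (slot - glen - 1))
    starts[i:(i + k - 1L)] <- as.integer((seq_len(k) - 1L) * slot + off)
    ends[i:(i + k - 1L)] <- starts[i:(i + k - 1L)] + glen
    i <- i + k
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n)),
    chrom = chrom_of,
    start = starts,
    end = ends,
    strand = strand,
    tss = ifelse(strand == "+", starts, ends - 1L)
  )
}

#' Generate a complete synthetic input bundle with planted candidates
#'
#' Produces GWAS summary statistics, gene models, eQTL records, drug-gene
#' interactions and ortholog pairs, all passing the package's strict
#' readers, plus a `truth` record of the planted candidates. Each planted
#' gene is constructed to pass every funnel stage: its supporting SNPs are
#' significant at `alpha`, are CNS eQTLs for the gene with the direction the
#' planted mechanism requires, and the gene has an approved drug of the
#' required action and an ortholog above 40% identity. Background records
#' follow the configured rates. Deterministic for a fixed seed.
#'
#' @param config A [bundle_config()].
#' @param seed Integer seed.
#' @return List: gwas, genes, eqtls, dgi, orthologs (tibbles), truth (list
#'   with `candidates` tibble and `background` counts), config, seed.
#' @export
simulate_bundle <- function(config = bundle_config(), seed = 1L) {
  stopifnot(inherits(config, "bundle_config"))
  if (config$n_planted > config$n_genes) {
    stop("infeasible config: n_planted > n_genes", call. = FALSE)
  }
  with_seed(seed, {
    genes <- simulate_genes(config)
    n <- config$n_snps

    eff_i <- sample.int(4L, n, replace = TRUE)
    oth_i <- 1L + (eff_i - 1L + sample.int(3L, n, replace = TRUE)) %% 4L
    gwas <- tibble::tibble(
      snp_id = sprintf("rs%07d", sample.int(9.9e6, n)),
      chrom = sample(unique(genes$chrom), n, replace = TRUE),
      pos = sample.int(config$chrom_length, n, replace = TRUE),
      effect_allele = BASES[eff_i],
      other_allele = BASES[oth_i],
      or = exp(rnorm(n, 0, config$log_or_sd)),
      p = runif(n)
    )

    # planted candidates
    planted <- head(sample(genes$gene_id, config$n_planted), config$n_planted)
    support_n <- rep_len(config$planted_support, config$n_planted)
    m <- sum(support_n)
    planted_rows <- if (m > 0) sample.int(n, m) else integer(0)
    actions <- sample(c("inhibitor", "activator"), config$n_planted,
                      replace = TRUE)

    eqtl_planted <- NULL
    if (config$n_planted > 0) {
      gene_of_row <- rep(planted, times = support_n)
      action_of_row <- rep(actions, times = support_n)
      gi <- match(gene_of_row, genes$gene_id)
      # cis placement: within 100 kb of the target TSS, clamped to the chrom
      offset <- sample(c(-1L, 1L), m, replace = TRUE) *
        as.integer(runif(m, 500, 1e5))
      pos0 <- pmin(pmax(genes$tss[gi] + offset, 1L),
                   config$chrom_length - 2L)
      gwas$chrom[planted_rows] <- genes$chrom[gi]
      gwas$pos[planted_rows] <- pos_0to1(pos0)
      gwas$p[planted_rows] <- runif(m, 0, config$alpha / 2)
      lor <- sample(c(-1, 1), m, replace = TRUE) * runif(m, 0.15, 0.35)
      gwas$or[planted_rows] <- exp(lor)
      risk_dir <- ifelse(action_of_row == "inhibitor", 1L, -1L)
      # mechanism rule inverted: direction per effect allele such that after
      # risk re-orientation the planted action is required
      direction <- ifelse(gwas$or[planted_rows] > 1, risk_dir, -risk_dir)
      eqtl_planted <- tibble::tibble(
        snp_id = gwas$snp_id[planted_rows],
        gene_id = gene_of_row,
        tissue = sample(config$tissues, m, replace = TRUE),
        direction = as.integer(direction),
        eqtl_p = runif(m, 1e-8, 1e-4),
        effect_allele = gwas$effect_allele[planted_rows]
      )
    }

    # background eQTLs: one gene per record, cis (same chromosome)
    bg_rows <- setdiff(seq_len(n), planted_rows)
    is_eqtl <- bg_rows[runif(length(bg_rows)) < config$eqtl_rate]
    eqtl_bg <- NULL
    if (length(is_eqtl) > 0) {
      genes_by_chrom <- split(genes$gene_id, genes$chrom)
      gene_pick <- vapply(gwas$chrom[is_eqtl], function(ch) {
        pool <- genes_by_chrom[[ch]]
        pool[sample.int(length(pool), 1L)]
      }, character(1), USE.NAMES = FALSE)
      use_eff <- runif(length(is_eqtl)) < 0.5
      eqtl_bg <- tibble::tibble(
        snp_id = gwas$snp_id[is_eqtl],
        gene_id = gene_pick,
        tissue = sample(tissue_vocabulary(), length(is_eqtl), replace = TRUE),
        direction = sample(c(-1L, 1L), length(is_eqtl), replace = TRUE),
        eqtl_p = runif(length(is_eqtl), 1e-8, 0.05),
        effect_allele = ifelse(use_eff, gwas$effect_allele[is_eqtl],
                               gwas$other_allele[is_eqtl])
      )
    }
    eqtls <- dplyr::bind_rows(eqtl_planted, eqtl_bg)
    if (is.null(eqtls) || nrow(eqtls) == 0) {
      eqtls <- tibble::tibble(
        snp_id = character(0), gene_id = character(0), tissue = character(0),
        direction = integer(0), eqtl_p = numeric(0),
        effect_allele = character(0)
      )
    }

    # drug-gene interactions
    dgi_planted <- tibble::tibble(
      gene_id = planted,
      drug_name = paste0("DRUG-", planted),
      action = actions,
      approved = TRUE
    )
    bg_genes <- setdiff(genes$gene_id, planted)
    dgi_genes <- bg_genes[runif(length(bg_genes)) < config$druggability_rate]
    dgi_bg <- tibble::tibble(
      gene_id = dgi_genes,
      drug_name = paste0("drug-", tolower(dgi_genes)),
      action = sample(c("inhibitor", "activator", "other"),
                      length(dgi_genes), replace = TRUE),
      approved = runif(length(dgi_genes)) < 0.7
    )
    dgi <- dplyr::bind_rows(dgi_planted, dgi_bg)

    # orthologs
    orth_planted <- tibble::tibble(
      human_gene = planted,
      model_gene = paste0("ce-", tolower(planted)),
      percent_identity = runif(config$n_planted, 45, 90),
      source = "synthetic"
    )
    orth_genes <- bg_genes[runif(length(bg_genes)) < config$ortholog_rate]
    orth_bg <- tibble::tibble(
      human_gene = orth_genes,
      model_gene = paste0("ce-", tolower(orth_genes)),
      percent_identity = runif(length(orth_genes), 10, 95),
      source = "synthetic"
    )
    orthologs <- dplyr::bind_rows(orth_planted, orth_bg)

    truth_candidates <- tibble::tibble(
      gene_id = planted,
      required_action = actions,
      supporting_snps = vapply(
        split(gwas$snp_id[planted_rows], rep(seq_along(planted), support_n)),
        paste0, character(1), collapse = ","
      )[as.character(seq_along(planted))] %||% character(0),
      drug_name = dgi_planted$drug_name,
      model_gene = orth_planted$model_gene,
      percent_identity = orth_planted$percent_identity
    )

    list(
      gwas = gwas, genes = genes, eqtls = eqtls, dgi = dgi,
      orthologs = orthologs,
      truth = list(
        candidates = truth_candidates,
        background = list(
          n_snps = n, n_genes = config$n_genes, n_eqtls = nrow(eqtls),
          n_dgi = nrow(dgi), n_orthologs = nrow(orthologs)
        )
      ),
      config = config, seed = seed
    )
  })
}

#' Write / read a bundle on disk
#'
#' `write_bundle()` writes gwas.tsv, genes.bed, eqtls.tsv, dgi.tsv,
#' orthologs.tsv and truth.json into `dir`; `read_bundle()` reads them back
#' through the strict readers.
#'
#' @param bundle List from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (write); bundle-shaped list (read).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gwas(bundle$gwas, file.path(dir, "gwas.tsv"))
  write_genes(bundle$genes, file.path(dir, "genes.bed"))
  write_eqtls(bundle$eqtls, file.path(dir, "eqtls.tsv"))
  write_dgi(bundle$dgi, file.path(dir, "dgi.tsv"))
  write_orthologs(bundle$orthologs, file.path(dir, "orthologs.tsv"))
  jsonlite::write_json(
    list(
      candidates = bundle$truth$candidates,
      background = bundle$truth$background,
      seed = bundle$seed
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(
    gwas = read_gwas(file.path(dir, "gwas.tsv")),
    genes = read_genes(file.path(dir, "genes.bed")),
    eqtls = read_eqtls(file.path(dir, "eqtls.tsv")),
    dgi = read_dgi(file.path(dir, "dgi.tsv")),
    orthologs = read_orthologs(file.path(dir, "orthologs.tsv")),
    truth = list(
      candidates = tibble::as_tibble(truth$candidates),
      background = truth$background
    ),
    seed = truth$seed
  )
}

#' Simulate a paralysis-assay event table
#'
#' Exponential time-to-paralysis per group with a configurable hazard ratio,
#' mimicking a two-arm motility assay: subjects are scored on a periodic
#' observation grid (events recorded at the right endpoint of the
#' observation interval) and censored at the end of the assay.
#'
#' @param n_per_group Subjects per group (> 0).
#' @param hazard_ratio Hazard of each later group relative to the first.
#' @param groups Group labels (first = reference).
#' @param baseline_median Median event time of the reference group, hours.
#' @param censor_time Administrative censoring time, hours.
#' @param interval Observation interval, hours (0 = continuous times).
#' @param seed Integer seed.
#' @return Event tibble (`subject_id`, `group`, `time`, `event`).
#' @export
simulate_events <- function(n_per_group = 90, hazard_ratio = 1,
                            groups = c("control", "treated"),
                            baseline_median = 20, censor_time = 30,
                            interval = 2, seed = 1L) {
  if (n_per_group <= 0) stop("n_per_group must be > 0", call. = FALSE)
  stopifnot(hazard_ratio > 0, length(groups) >= 1, baseline_median > 0,
            censor_time > 0, interval >= 0)
  rate0 <- log(2) / baseline_median
  rates <- rate0 * hazard_ratio^(seq_along(groups) - 1)
  with_seed(seed, {
    out <- lapply(seq_along(groups), function(g) {
      t_true <- rexp(n_per_group, rates[g])
      t_obs <- if (interval > 0) ceiling(t_true / interval) * interval else t_true
      event <- as.integer(t_true <= censor_time)
      time <- ifelse(event == 1L, pmin(t_obs, censor_time), censor_time)
      tibble::tibble(
        subject_id = sprintf("%s_%03d", groups[g], seq_len(n_per_group)),
        group = groups[g],
        time = time,
        event = event
      )
    })
    dplyr::bind_rows(out)
  })
}
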