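# The candidate-prioritization funnel: significance filter -> annotation ->
# CNS-eQTL intersection -> mechanism inference -> approved-drug match ->
# ortholog filter -> optional blood-brain-barrier filter, with stage counts
# recorded after every stage.

#' Funnel configuration
#'
#' @param alpha Association p-value threshold (strict `<`). Default `1e-3`.
#' @param tissues Tissue names defining the eQTL restriction; default the 13
#'   CNS names of [cns_tissues()].
#' @param min_identity Minimum ortholog percent identity (inclusive `>=`),
#'   default 40.
#' @param approved_only Restrict drug matches to approved drugs. Default TRUE.
#' @param harmonization `"strict"` errors on eQTL records lacking an effect
#'   allele; `"assume"` treats them as already oriented to the GWAS effect
#'   allele.
#' @param discordant_policy What to do with a gene whose supporting SNPs
#'   imply conflicting mechanisms: `"exclude"` (default) drops it before drug
#'   matching; `"majority"` keeps the majority call (exact ties drop).
#' @param bbb_filter If TRUE and a blood-brain-barrier annotation table is
#'   supplied to [run_funnel()], require at least one matched drug with
#'   `bbb_permeable == TRUE`.
#' @return A list of class `funnel_config`.
#' @export
funnel_config <- function(alpha = 1e-3,
                          tissues = cns_tissues(),
                          min_identity = 40,
                          approved_only = TRUE,
                          harmonization = c("strict", "assume"),
                          discordant_policy = c("exclude", "majority"),
                          bbb_filter = FALSE) {
  harmonization <- match.arg(harmonization)
  discordant_policy <- match.arg(discordant_policy)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1,
    is.character(tissues),
    is.numeric(min_identity), min_identity >= 0, min_identity <= 100,
    is.logical(approved_only), is.logical(bbb_filter)
  )
  structure(
    list(
      alpha = alpha, tissues = tissues, min_identity = min_identity,
      approved_only = approved_only, harmonization = harmonization,
      discordant_policy = discordant_policy, bbb_filter = bbb_filter
    ),
    class = "funnel_config"
  )
}

#' Select significant SNPs
#'
#' Keeps exactly the SNPs with `p < alpha` (strict inequality), original
#' order preserved.
#'
#' @param snps GWAS tibble.
#' @param alpha Threshold in \[0, 1\].
#' @return Filtered tibble.
#' @export
select_significant <- function(snps, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0, alpha <= 1)
  snps[snps$p < alpha, , drop = FALSE]
}

#' Intersect significant SNPs with tissue-restricted eQTLs
#'
#' Returns every (SNP, eQTL) pair whose `snp_id` matches and whose tissue is
#' in `tissues`; a gene appears once per supporting pair. The eQTL table's
#' `effect_allele` is suffixed `_eqtl` to keep both allele columns.
#'
#' @param selected Significant GWAS tibble.
#' @param eqtls eQTL tibble.
#' @param tissues Nonempty character vector of tissue names.
#' @return Pair tibble (GWAS columns + gene_id, tissue, direction, eqtl_p,
#'   effect_allele_eqtl).
#' @export
intersect_cns_eqtls <- function(selected, eqtls, tissues = cns_tissues()) {
  if (length(tissues) == 0) {
    stop("empty tissue set: the eQTL filter would be vacuous", call. = FALSE)
  }
  unknown <- setdiff(tissues, c(tissue_vocabulary(), unique(eqtls$tissue)))
  if (length(unknown) > 0) {
    warning(
      "tissue name(s) outside the vocabulary: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  keep <- eqtls[eqtls$tissue %in% tissues, , drop = FALSE]
  dplyr::inner_join(selected, keep, by = "snp_id",
                    suffix = c("", "_eqtl"), relationship = "many-to-many")
}

#' Harmonize eQTL direction to the GWAS effect allele
#'
#' The mechanism rule compares the odds ratio and the eQTL direction for the
#' same allele. When the eQTL record's effect allele equals the GWAS other
#' allele, its direction is negated; when it is missing, strict mode errors
#' and assume mode keeps the direction unchanged.
#'
#' @param pairs Pair tibble from [intersect_cns_eqtls()].
#' @param harmonization `"strict"` or `"assume"`.
#' @return `pairs` with `direction` re-oriented to the GWAS effect allele.
#' @export
harmonize_direction <- function(pairs, harmonization = c("strict", "assume")) {
  harmonization <- match.arg(harmonization)
  if (nrow(pairs) == 0) return(pairs)
  ea <- pairs$effect_allele_eqtl
  if (anyNA(ea)) {
    if (harmonization == "strict") {
      stop(
        "unharmonized eQTL record(s) (missing effect_allele) for snp_id ",
        paste(head(unique(pairs$snp_id[is.na(ea)]), 5L), collapse = ", "),
        ": supply the eQTL effect allele or set harmonization = \"assume\"",
        call. = FALSE
      )
    }
    ea[is.na(ea)] <- pairs$effect_allele[is.na(ea)]
  }
  match_eff <- ea == pairs$effect_allele
  match_oth <- ea == pairs$other_allele
  if (any(!match_eff & !match_oth)) {
    stop(
      "eQTL effect allele matches neither GWAS allele for snp_id ",
      paste(head(unique(pairs$snp_id[!match_eff & !match_oth]), 5L),
            collapse = ", "),
      call. = FALSE
    )
  }
  pairs$direction <- ifelse(match_eff, pairs$direction, -pairs$direction)
  pairs
}

#' Required pharmacological mechanism from OR and eQTL direction
#'
#' If the risk allele (OR re-oriented above 1) raises target expression, an
#' inhibitor of the target is required; if it lowers expression, an
#' activator. An OR below 1 is re-oriented to the risk allele by the
#' involution OR -> 1/OR, direction -> -direction; an OR of exactly 1 has no
#' risk direction and errors.
#'
#' @param or Positive odds ratio(s), harmonized to the same allele as
#'   `direction`.
#' @param direction +1 or -1 expression change per copy of that allele.
#' @return Tibble: required_action ("inhibitor"/"activator"), risk_or (> 1),
#'   risk_direction (+1/-1).
#' @export
required_mechanism <- function(or, direction) {
  stopifnot(length(or) == length(direction))
  if (any(or <= 0)) stop("odds ratio must be > 0", call. = FALSE)
  if (any(or == 1)) {
    stop("odds ratio of exactly 1 has no risk direction", call. = FALSE)
  }
  if (any(!direction %in% c(-1, 1))) {
    stop("direction must be +1 or -1", call. = FALSE)
  }
  flip <- or < 1
  risk_or <- ifelse(flip, 1 / or, or)
  risk_direction <- as.integer(ifelse(flip, -direction, direction))
  tibble::tibble(
    required_action = ifelse(risk_direction == 1L, "inhibitor", "activator"),
    risk_or = risk_or,
    risk_direction = risk_direction
  )
}

#' Match drugs for one gene's mechanism call
#'
#' @param gene_id Gene identifier.
#' @param required_action `"inhibitor"` or `"activator"`.
#' @param dgi Drug-gene interaction tibble.
#' @param approved_only Restrict to approved drugs.
#' @return Rows of `dgi` for the gene whose action equals the requirement.
#' @export
match_drugs <- function(gene_id, required_action, dgi, approved_only = TRUE) {
  stopifnot(length(gene_id) == 1, required_action %in% c("inhibitor", "activator"))
  out <- dgi[dgi$gene_id == gene_id & dgi$action == required_action, ,
             drop = FALSE]
  if (approved_only) out <- out[out$approved, , drop = FALSE]
  out
}

#' Best ortholog above an identity threshold
#'
#' @param gene_id Human gene identifier.
#' @param orthologs Ortholog tibble.
#' @param min_identity Inclusive threshold (>=), default 40.
#' @return Zero- or one-row tibble: the highest-identity pair at or above the
#'   threshold (ties to the smallest model_gene id).
#' @export
filter_orthologs <- function(gene_id, orthologs, min_identity = 40) {
  stopifnot(length(gene_id) == 1)
  hits <- orthologs[
    orthologs$human_gene == gene_id &
      orthologs$percent_identity >= min_identity, ,
    drop = FALSE
  ]
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(-hits$percent_identity, hits$model_gene), , drop = FALSE]
  hits[1, , drop = FALSE]
}

# Best ortholog per gene for a vector of genes (same rule as
# filter_orthologs, vectorized for run_funnel).
best_orthologs <- function(gene_ids, orthologs, min_identity) {
  hits <- orthologs[
    orthologs$human_gene %in% gene_ids &
      orthologs$percent_identity >= min_identity, ,
    drop = FALSE
  ]
  if (nrow(hits) == 0) {
    return(tibble::tibble(gene_id = character(0),
                          ortholog = character(0),
                          percent_identity = numeric(0)))
  }
  hits <- hits[order(hits$human_gene, -hits$percent_identity, hits$model_gene), ]
  hits <- hits[!duplicated(hits$human_gene), ]
  tibble::tibble(
    gene_id = hits$human_gene,
    ortholog = hits$model_gene,
    percent_identity = hits$percent_identity
  )
}

empty_candidates <- function() {
  tibble::tibble(
    gene_id = character(0), n_support = integer(0), best_p = numeric(0),
    supporting_snp = character(0), required_action = character(0),
    risk_or = numeric(0), risk_direction = integer(0),
    discordant = logical(0), drugs = character(0), ortholog = character(0),
    percent_identity = numeric(0), bbb_permeable = logical(0),
    promoter_distance_bp = integer(0),
    passed_mechanism = logical(0), passed_drugs = logical(0),
    passed_ortholog = logical(0), passed_bbb = logical(0),
    rank = integer(0)
  )
}

#' Run the full candidate-prioritization funnel
#'
#' Executes, in order: significance filter; SNP annotation (for promoter
#' distances); CNS-eQTL intersection with allele harmonization; per-gene
#' mechanism inference (discordant genes handled per config); approved-drug
#' matching; ortholog filter; optional blood-brain-barrier filter. Stage
#' counts are recorded after each stage (SNP counts for the first stages,
#' gene counts from the eQTL intersection on). Final candidates are ranked
#' by: number of supporting SNP-eQTL pairs (descending), best supporting
#' association p-value (ascending), promoter distance to the candidate gene
#' (ascending), gene_id (ascending).
#'
#' @param gwas,genes,eqtls,dgi,orthologs Validated input tibbles (see the
#'   `read_*` readers).
#' @param config A [funnel_config()].
#' @param bbb Optional tibble `drug_name`, `bbb_permeable` (logical); used
#'   only when `config$bbb_filter` is TRUE.
#' @return A `funnel_report`: list with `stage_counts` (named integer
#'   vector, non-increasing under single-gene eQTL records), `candidates`
#'   (one row per gene reaching the eQTL stage, with per-stage pass flags
#'   and `rank` set for full passes), and `config`.
#' @export
run_funnel <- function(gwas, genes, eqtls, dgi, orthologs,
                       config = funnel_config(), bbb = NULL) {
  stopifnot(inherits(config, "funnel_config"))
  stages <- c(input_snps = nrow(gwas))

  sig <- select_significant(gwas, config$alpha)
  stages["significant_snps"] <- nrow(sig)

  ann <- suppressWarnings(annotate_snps(sig, genes))
  stages["annotated_snps"] <- nrow(ann)

  pairs <- intersect_cns_eqtls(sig, eqtls, config$tissues)
  pairs <- harmonize_direction(pairs, config$harmonization)
  stages["cns_eqtl_genes"] <- length(unique(pairs$gene_id))

  if (nrow(pairs) > 0 && any(pairs$or == 1)) {
    warning(
      sum(pairs$or == 1), " supporting pair(s) with OR exactly 1 dropped: ",
      "no risk direction",
      call. = FALSE
    )
    pairs <- pairs[pairs$or != 1, , drop = FALSE]
  }

  if (nrow(pairs) == 0) {
    stages["mechanism_genes"] <- 0L
    stages["drug_matched_genes"] <- 0L
    stages["ortholog_genes"] <- 0L
    if (config$bbb_filter) stages["bbb_genes"] <- 0L
    return(new_funnel_report(stages, empty_candidates(), config))
  }

  mech <- required_mechanism(pairs$or, pairs$direction)
  pairs <- dplyr::bind_cols(pairs, mech)

  # gene-level mechanism call
  calls <- pairs |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(
      n_inhibitor = sum(required_action == "inhibitor"),
      n_activator = sum(required_action == "activator"),
      .groups = "drop"
    )
  calls$discordant <- calls$n_inhibitor > 0 & calls$n_activator > 0
  if (config$discordant_policy == "exclude") {
    calls$call <- ifelse(calls$discordant, NA_character_,
                         ifelse(calls$n_inhibitor > 0, "inhibitor", "activator"))
  } else { # majority; exact tie drops the gene
    calls$call <- dplyr::case_when(
      calls$n_inhibitor > calls$n_activator ~ "inhibitor",
      calls$n_activator > calls$n_inhibitor ~ "activator",
      TRUE ~ NA_character_
    )
  }

  # per-gene support restricted to pairs agreeing with the retained call
  support <- pairs |>
    dplyr::inner_join(calls[, c("gene_id", "call", "discordant")],
                      by = "gene_id") |>
    dplyr::filter(!is.na(call), required_action == call) |>
    dplyr::group_by(gene_id) |>
    dplyr::arrange(p, snp_id, .by_group = TRUE) |>
    dplyr::summarise(
      n_support = dplyr::n(),
      best_p = p[1],
      supporting_snp = snp_id[1],
      required_action = call[1],
      risk_or = risk_or[1],
      risk_direction = risk_direction[1],
      discordant = discordant[1],
      .groups = "drop"
    )

  cand <- dplyr::left_join(
    tibble::tibble(gene_id = sort(unique(pairs$gene_id))),
    support, by = "gene_id"
  )
  cand$discordant[is.na(cand$discordant)] <- TRUE
  cand$passed_mechanism <- !is.na(cand$required_action)
  stages["mechanism_genes"] <- sum(cand$passed_mechanism)

  # approved-drug match by (gene, action)
  dgi_use <- if (config$approved_only) {
    dgi[dgi$approved, , drop = FALSE]
  } else {
    dgi
  }
  drug_hits <- dgi_use |>
    dplyr::inner_join(
      cand[cand$passed_mechanism, c("gene_id", "required_action")],
      by = c("gene_id", "action" = "required_action")
    ) |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(
      drugs = paste(sort(unique(drug_name)), collapse = ","),
      any_bbb = if (is.null(bbb)) NA else any(
        drug_name %in% bbb$drug_name[bbb$bbb_permeable]
      ),
      .groups = "drop"
    )
  cand <- dplyr::left_join(cand, drug_hits, by = "gene_id")
  cand$passed_drugs <- !is.na(cand$drugs)
  stages["drug_matched_genes"] <- sum(cand$passed_drugs)

  # ortholog filter
  orth <- best_orthologs(
    cand$gene_id[cand$passed_drugs], orthologs, config$min_identity
  )
  cand <- dplyr::left_join(cand, orth, by = "gene_id")
  cand$passed_ortholog <- cand$passed_drugs & !is.na(cand$ortholog)
  stages["ortholog_genes"] <- sum(cand$passed_ortholog)

  # optional blood-brain-barrier filter over matched drugs
  names(cand)[names(cand) == "any_bbb"] <- "bbb_permeable"
  if (config$bbb_filter && !is.null(bbb)) {
    cand$passed_bbb <- cand$passed_ortholog & !is.na(cand$bbb_permeable) &
      cand$bbb_permeable
    stages["bbb_genes"] <- sum(cand$passed_bbb)
  } else {
    cand$passed_bbb <- cand$passed_ortholog
  }

  # promoter distance from each candidate gene's own supporting SNPs
  cand$promoter_distance_bp <- candidate_promoter_distance(cand, pairs, genes)

  final <- cand$passed_bbb
  cand$rank <- NA_integer_
  if (any(final)) {
    f <- cand[final, ]
    ord <- order(-f$n_support, f$best_p, f$promoter_distance_bp, f$gene_id,
                 na.last = TRUE)
    ranks <- integer(sum(final))
    ranks[ord] <- seq_len(sum(final))
    cand$rank[which(final)] <- ranks
  }

  cols <- names(empty_candidates())
  cand <- cand[, cols]
  cand <- cand[order(!is.finite(cand$rank), cand$rank, cand$gene_id), ]
  new_funnel_report(stages, cand, config)
}

# Minimum |SNP pos0 - TSS| over a gene's supporting SNPs; NA when no
# supporting SNP shares the gene's chromosome.
candidate_promoter_distance <- function(cand, pairs, genes) {
  tss <- setNames(genes$tss, genes$gene_id)
  gchrom <- setNames(genes$chrom, genes$gene_id)
  vapply(cand$gene_id, function(g) {
    sup <- pairs[pairs$gene_id == g, , drop = FALSE]
    if (!g %in% names(tss)) return(NA_integer_)
    sup <- sup[sup$chrom == gchrom[[g]], , drop = FALSE]
    if (nrow(sup) == 0) return(NA_integer_)
    as.integer(min(abs(pos_1to0(sup$pos) - tss[[g]])))
  }, integer(1), USE.NAMES = FALSE)
}

new_funnel_report <- function(stage_counts, candidates, config) {
  structure(
    list(
      stage_counts = stage_counts,
      candidates = candidates,
      config = config
    ),
    class = "funnel_report"
  )
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Candidate-prioritization funnel\n")
  for (i in seq_along(x$stage_counts)) {
    cat(sprintf("  %-20s %d\n", names(x$stage_counts)[i], x$stage_counts[i]))
  }
  ranked <- x$candidates[!is.na(x$candidates$rank), ]
  if (nrow(ranked) == 0) {
    cat("no candidate passed all filters\n")
  } else {
    cat("ranked candidates:\n")
    print(ranked[, c("rank", "gene_id", "required_action", "drugs",
                     "ortholog", "percent_identity", "n_support", "best_p")])
  }
  invisible(x)
}

#' Ranked candidates of a funnel report
#'
#' @param report A `funnel_report`.
#' @return Tibble of candidates passing all active filters, in rank order.
#' @export
top_candidates <- function(report) {
  stopifnot(inherits(report, "funnel_report"))
  out <- report$candidates[!is.na(report$candidates$rank), , drop = FALSE]
  out[order(out$rank), , drop = FALSE]
}

#' Write a funnel report to disk
#'
#' Writes `<prefix>.candidates.tsv` (the full candidate table) and
#' `<prefix>.report.json` (stage counts and configuration echo). The
#' re-oriented odds ratio is serialized at 10 significant digits: risk
#' re-orientation (OR to 1/OR) is exact only to one unit in the last place
#' in floating point, and bounding the printed precision keeps reports
#' byte-stable under allele re-orientation.
#'
#' @param report A `funnel_report`.
#' @param prefix Output path prefix.
#' @return The two paths, invisibly.
#' @export
write_funnel_report <- function(report, prefix) {
  stopifnot(inherits(report, "funnel_report"))
  tsv <- paste0(prefix, ".candidates.tsv")
  json <- paste0(prefix, ".report.json")
  cand <- report$candidates
  cand$risk_or <- signif(cand$risk_or, 10)
  readr::write_tsv(cand, tsv, na = ".")
  jsonlite::write_json(
    list(
      stage_counts = as.list(report$stage_counts),
      config = unclass(report$config),
      n_ranked = sum(!is.na(report$candidates$rank))
    ),
    json,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(tsv, json))
}
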