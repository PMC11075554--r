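# SNP-vs-gene annotation: intragenic/intergenic classification and
# nearest-promoter assignment. A SNP's 1-based position is converted to the
# genes' 0-based system before any comparison (pos_1to0); "intragenic" means
# the point falls inside a gene body [start, end), introns and UTRs included.

# Core per-chromosome annotation. Genes are compared in gene_id order so that
# max.col(ties.method = "first") implements the documented tie-break
# (smallest gene_id) for both host gene and nearest promoter.
annotate_chrom <- function(pos0, genes_c, upstream) {
  g <- genes_c[order(genes_c$gene_id), ]
  # distance from each SNP to each promoter; the promoter is the TSS point,
  # optionally widened `upstream` bp on the gene's upstream side
  lo <- ifelse(g$strand == "+", g$tss - upstream, g$tss)
  hi <- ifelse(g$strand == "+", g$tss, g$tss + upstream)
  d_lo <- outer(pos0, lo, FUN = function(p, l) l - p)  # bp left of interval
  d_hi <- outer(pos0, hi, FUN = function(p, h) p - h)  # bp right of interval
  d <- pmax(d_lo, d_hi, 0L)
  nearest_idx <- max.col(-d, ties.method = "first")
  nearest_dist <- d[cbind(seq_along(pos0), nearest_idx)]

  contains <- outer(pos0, g$start, ">=") & outer(pos0, g$end, "<")
  inside <- rowSums(contains) > 0
  d_host <- d
  d_host[!contains] <- Inf
  host_idx <- max.col(-d_host, ties.method = "first")

  tibble::tibble(
    location_class = ifelse(inside, "intragenic", "intergenic"),
    host_gene = ifelse(inside, g$gene_id[host_idx], NA_character_),
    nearest_gene = g$gene_id[nearest_idx],
    promoter_distance_bp = as.integer(nearest_dist)
  )
}

#' Annotate SNPs against gene models
#'
#' Classifies each SNP as intragenic (inside any gene body, half-open
#' \[start, end)) or intergenic, and assigns the nearest gene by absolute
#' distance from the SNP to the strand-aware TSS ("promoter distance"). A SNP
#' inside several overlapping genes is assigned the host gene with the
#' closest TSS; all distance ties break to the lexicographically smallest
#' gene_id. SNPs on chromosomes absent from the gene set are classified
#' intergenic with no nearest gene, with a warning.
#'
#' @param snps GWAS tibble as from [read_gwas()] (1-based `pos`).
#' @param genes Gene-model tibble as from [read_genes()].
#' @param upstream Optional promoter half-width in bp upstream of the TSS;
#'   distance is 0 inside the widened promoter interval. Default 0 (promoter
#'   = TSS point).
#' @return Tibble with one row per SNP, input order preserved: snp_id,
#'   location_class, host_gene, nearest_gene, promoter_distance_bp.
#' @export
annotate_snps <- function(snps, genes, upstream = 0L) {
  stopifnot(is.data.frame(snps), is.data.frame(genes), upstream >= 0)
  n <- nrow(snps)
  out <- tibble::tibble(
    snp_id = snps$snp_id,
    location_class = rep("intergenic", n),
    host_gene = rep(NA_character_, n),
    nearest_gene = rep(NA_character_, n),
    promoter_distance_bp = rep(NA_integer_, n)
  )
  if (n == 0) return(out)
  pos0 <- pos_1to0(snps$pos)
  missing_chroms <- character(0)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    genes_c <- genes[genes$chrom == ch, ]
    if (nrow(genes_c) == 0) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    ann <- annotate_chrom(pos0[idx], genes_c, as.integer(upstream))
    out$location_class[idx] <- ann$location_class
    out$host_gene[idx] <- ann$host_gene
    out$nearest_gene[idx] <- ann$nearest_gene
    out$promoter_distance_bp[idx] <- ann$promoter_distance_bp
  }
  if (length(missing_chroms) > 0) {
    warning(
      "no gene models on chromosome(s) ",
      paste(missing_chroms, collapse = ", "),
      "; SNPs there classified intergenic with no nearest gene",
      call. = FALSE
    )
  }
  out
}

#' Classify SNP location
#'
#' Intragenic/intergenic classification only; see [annotate_snps()] for the
#' containment and tie-break rules.
#'
#' @inheritParams annotate_snps
#' @return Tibble: snp_id, location_class, host_gene.
#' @export
classify_location <- function(snps, genes) {
  annotate_snps(snps, genes)[, c("snp_id", "location_class", "host_gene")]
}

#' Nearest promoter for each SNP
#'
#' @inheritParams annotate_snps
#' @return Tibble: snp_id, nearest_gene, promoter_distance_bp.
#' @export
nearest_promoter <- function(snps, genes, upstream = 0L) {
  annotate_snps(snps, genes, upstream)[
    , c("snp_id", "nearest_gene", "promoter_distance_bp")
  ]
}
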