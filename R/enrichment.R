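# Characterization statistics for the reanalysis: control-SNP sampling,
# intragenic-fraction comparison, OR mean comparison, and overlap of the
# implicated genes with previously associated ones.

#' Sample control SNPs
#'
#' Simple random sample without replacement, used to draw a control set the
#' same size as the significant set. Deterministic for a fixed seed; the
#' caller's RNG state is restored afterwards.
#'
#' @param snps GWAS tibble.
#' @param n Number of SNPs to draw (`n <= nrow(snps)`).
#' @param seed Optional integer seed.
#' @return Tibble of `n` sampled rows.
#' @export
sample_control_snps <- function(snps, n, seed = NULL) {
  stopifnot(n >= 0, n <= nrow(snps))
  draw <- function() snps[sample.int(nrow(snps), n), , drop = FALSE]
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Two-proportion chi-square test
#'
#' Pearson chi-square on the 2x2 table (x1, n1-x1; x2, n2-x2), 1 df,
#' two-sided. Continuity correction is applied iff `correction`. A zero
#' margin (all successes or all failures pooled) carries no information and
#' returns p = 1 with a warning.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param correction Apply the Yates continuity correction. Default FALSE.
#' @return List: x1, n1, x2, n2, statistic, p_value.
#' @export
two_proportion_chisq <- function(x1, n1, x2, n2, correction = FALSE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; test carries no information",
            call. = FALSE)
    return(list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                statistic = 0, p_value = 1))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correction))
  list(
    x1 = x1, n1 = n1, x2 = x2, n2 = n2,
    statistic = unname(ct$statistic), p_value = ct$p.value
  )
}

#' Two-sample mean comparison t-test
#'
#' Two-sided t-test; the `student` variant pools variances, `welch` does
#' not.
#'
#' @param sample1,sample2 Numeric vectors.
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return List: per-group mean/sd/n, t_statistic, p_value, variant.
#' @export
mean_comparison_ttest <- function(sample1, sample2,
                                  variant = c("student", "welch")) {
  variant <- match.arg(variant)
  tt <- t.test(sample1, sample2, var.equal = variant == "student")
  list(
    mean1 = mean(sample1), sd1 = sd(sample1), n1 = length(sample1),
    mean2 = mean(sample2), sd2 = sd(sample2), n2 = length(sample2),
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    variant = variant
  )
}

#' Overlap of candidate genes with previously associated genes
#'
#' @param candidate_genes,known_genes Nonempty character vectors (treated as
#'   sets).
#' @return List: count (size of the intersection), percent (100 * count /
#'   number of candidate genes, rounded half-up to 1 decimal).
#' @export
overlap_with_known <- function(candidate_genes, known_genes) {
  stopifnot(length(candidate_genes) > 0, length(known_genes) > 0)
  cand <- unique(candidate_genes)
  count <- length(intersect(cand, unique(known_genes)))
  list(
    count = count,
    percent = round_half_up(100 * count / length(cand), 1)
  )
}

#' Intragenic fraction of an annotation table
#'
#' @param annotations Tibble from [annotate_snps()].
#' @return List: count of intragenic SNPs and their fraction of the total.
#' @export
intragenic_fraction <- function(annotations) {
  stopifnot(nrow(annotations) > 0)
  count <- sum(annotations$location_class == "intragenic")
  list(count = count, fraction = count / nrow(annotations))
}
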