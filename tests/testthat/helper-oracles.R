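# Independent brute-force / direct-formula oracles. These deliberately avoid
# the code paths (and, where the implementation delegates to a library
# routine, the routine) they are used to check.

# Pearson chi-square on a 2x2 table from the textbook formula.
oracle_chisq <- function(x1, n1, x2, n2, correction = FALSE) {
  o <- matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2, byrow = TRUE)
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  adj <- if (correction) pmin(0.5, abs(o - e)) else 0
  stat <- sum((abs(o - e) - adj)^2 / e)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

# Two-sample t from first principles.
oracle_ttest <- function(x, y, pooled = TRUE) {
  n1 <- length(x); n2 <- length(y)
  v1 <- var(x); v2 <- var(y)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (mean(x) - mean(y)) / se
  list(t_statistic = t, p_value = 2 * pt(-abs(t), df = df))
}

# Product-limit estimator by explicit loop over unique observed times.
oracle_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time))
  surv <- numeric(length(times))
  at_risk <- integer(length(times))
  n_event <- integer(length(times))
  s <- 1
  for (i in seq_along(times)) {
    at_risk[i] <- sum(time >= times[i])
    n_event[i] <- sum(time == times[i] & event == 1)
    s <- s * (1 - n_event[i] / at_risk[i])
    surv[i] <- s
  }
  data.frame(time = times, at_risk = at_risk, n_event = n_event,
             survival = surv)
}

# Two-group log-rank from the observed-minus-expected hypergeometric sums.
oracle_logrank <- function(time1, event1, time2, event2) {
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp <- rep(1:2, c(length(time1), length(time2)))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o1 - e1)^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Kruskal-Wallis H with tie correction from the rank-sum formula.
oracle_kw <- function(samples) {
  pooled <- unlist(samples)
  n <- length(pooled)
  r <- rank(pooled)
  sizes <- lengths(samples)
  idx <- rep(seq_along(samples), sizes)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, idx, sum)^2 / sizes) - 3 * (n + 1)
  ties <- table(pooled)
  c_tie <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- h / c_tie
  df <- length(samples) - 1
  list(statistic = h, p_value = pchisq(h, df, lower.tail = FALSE))
}

# Exhaustive per-gene re-test of the funnel predicates against the raw
# tables: plain base-R loops, no shared code with run_funnel.
brute_force_candidates <- function(bundle, cfg = funnel_config()) {
  gwas <- as.data.frame(bundle$gwas)
  eq <- as.data.frame(bundle$eqtls)
  dgi <- as.data.frame(bundle$dgi)
  orth <- as.data.frame(bundle$orthologs)
  sig <- gwas[gwas$p < cfg$alpha, ]
  passed <- character(0)
  for (g in unique(eq$gene_id)) {
    rows <- eq[eq$gene_id == g & eq$tissue %in% cfg$tissues &
                 eq$snp_id %in% sig$snp_id, ]
    if (nrow(rows) == 0) next
    acts <- character(0)
    for (i in seq_len(nrow(rows))) {
      s <- sig[sig$snp_id == rows$snp_id[i], ][1, ]
      dir <- rows$direction[i]
      ea <- rows$effect_allele[i]
      if (is.na(ea)) {
        if (cfg$harmonization == "strict") stop("unharmonized record")
      } else if (ea == s$other_allele) {
        dir <- -dir
      } else if (ea != s$effect_allele) {
        stop("allele mismatch")
      }
      or <- s$or
      if (or == 1) next
      if (or < 1) {
        or <- 1 / or
        dir <- -dir
      }
      acts <- c(acts, if (dir == 1) "inhibitor" else "activator")
    }
    if (length(acts) == 0 || length(unique(acts)) > 1) next
    dg <- dgi[dgi$gene_id == g & dgi$action == acts[1], ]
    if (cfg$approved_only) dg <- dg[dg$approved, ]
    if (nrow(dg) == 0) next
    oo <- orth[orth$human_gene == g &
                 orth$percent_identity >= cfg$min_identity, ]
    if (nrow(oo) == 0) next
    passed <- c(passed, g)
  }
  sort(passed)
}
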