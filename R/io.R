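#' Central-nervous-system tissue vocabulary
#'
#' The 13 brain and spinal-cord tissue names used to restrict the eQTL
#' intersection to the central nervous system.
#'
#' @return Character vector of 13 tissue names.
#' @export
cns_tissues <- function() {
  c(
    "Amygdala", "Anterior Cingulate Cortex BA24", "Caudate basal ganglia",
    "Cerebellar Hemisphere", "Cerebellum", "Cortex", "Frontal Cortex",
    "Hippocampus", "Hypothalamus", "Nucleus accumbens", "Putamen",
    "Spinal cord", "Substantia nigra"
  )
}

#' Default tissue vocabulary accepted by [read_eqtls()]
#'
#' The CNS names plus a small set of common non-CNS tissue labels, so that
#' eQTL tables covering the whole body validate while the funnel still
#' restricts to [cns_tissues()].
#'
#' @return Character vector of tissue names.
#' @export
tissue_vocabulary <- function() {
  c(
    cns_tissues(),
    "Adipose Subcutaneous", "Heart Left Ventricle", "Liver", "Lung",
    "Muscle Skeletal", "Thyroid", "Whole Blood"
  )
}

#' Coordinate-system conversion
#'
#' GWAS and eQTL positions are 1-based points; gene models use the BED
#' 0-based half-open convention. All conversion between the two systems goes
#' through this pair of functions.
#'
#' @param pos 1-based integer position(s).
#' @param pos0 0-based integer position(s).
#' @return Integer vector in the other coordinate system.
#' @export
pos_1to0 <- function(pos) as.integer(pos) - 1L

#' @rdname pos_1to0
#' @export
pos_0to1 <- function(pos0) as.integer(pos0) + 1L

# --- internal reading machinery ---------------------------------------------

# Read a TSV with mandatory header as all-character columns; `#` lines are
# comments. Returns a tibble. Errors if any required column is missing.
read_tsv_raw <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA", "."), progress = FALSE, show_col_types = FALSE
  )
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(
      "schema error in ", basename(path), ": missing column(s) ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  x
}

# Row-level validation error citing 1-based data row numbers (header and
# comment lines excluded; readr drops comments before rows can be counted).
stop_rows <- function(what, bad, path) {
  rows <- which(bad)
  stop(
    "validation error in ", basename(path), ": ", what,
    " at data row(s) ", paste(head(rows, 5L), collapse = ", "),
    if (length(rows) > 5L) sprintf(" (and %d more)", length(rows) - 5L) else "",
    call. = FALSE
  )
}

as_num <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) stop_rows(paste0("non-numeric '", col, "'"), bad, path)
  out
}

as_int <- function(x, col, path) {
  out <- as_num(x, col, path)
  bad <- !is.na(out) & out != floor(out)
  if (any(bad)) stop_rows(paste0("non-integer '", col, "'"), bad, path)
  as.integer(out)
}

check_not_na <- function(x, col, path) {
  if (anyNA(x)) stop_rows(paste0("missing '", col, "'"), is.na(x), path)
  x
}

# --- readers -----------------------------------------------------------------

#' Read GWAS summary statistics
#'
#' Tab-separated with mandatory header columns `snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `or`, `p`. Positions are 1-based. Each row
#' is one SNP: per-effect-allele odds ratio for case status and association
#' p-value.
#'
#' @param path Path to the TSV file.
#' @param verbose Report the record count with [message()].
#' @return Tibble of validated records, input row order preserved.
#' @export
read_gwas <- function(path, verbose = FALSE) {
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "or", "p")
  raw <- read_tsv_raw(path, req)
  x <- tibble::tibble(
    snp_id = check_not_na(raw$snp_id, "snp_id", path),
    chrom = check_not_na(raw$chrom, "chrom", path),
    pos = check_not_na(as_int(raw$pos, "pos", path), "pos", path),
    effect_allele = check_not_na(raw$effect_allele, "effect_allele", path),
    other_allele = check_not_na(raw$other_allele, "other_allele", path),
    or = check_not_na(as_num(raw$or, "or", path), "or", path),
    p = check_not_na(as_num(raw$p, "p", path), "p", path)
  )
  if (any(x$or <= 0)) stop_rows("odds ratio must be > 0", x$or <= 0, path)
  if (any(x$p <= 0 | x$p > 1)) {
    stop_rows("p-value must be in (0, 1]", x$p <= 0 | x$p > 1, path)
  }
  if (any(x$pos < 1)) stop_rows("pos must be >= 1 (1-based)", x$pos < 1, path)
  same <- x$effect_allele == x$other_allele
  if (any(same)) stop_rows("effect_allele equals other_allele", same, path)
  key <- paste(x$chrom, x$pos, x$snp_id)
  if (anyDuplicated(key) > 0) {
    stop_rows("duplicate (chrom, pos, snp_id)", duplicated(key), path)
  }
  # a snp_id on two chromosomes would make every downstream join ambiguous
  n_chrom <- tapply(x$chrom, x$snp_id, function(ch) length(unique(ch)))
  if (any(n_chrom > 1L)) {
    stop(
      "validation error in ", basename(path), ": snp_id on multiple ",
      "chromosomes: ",
      paste(head(names(n_chrom)[n_chrom > 1L], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  if (verbose) message("read ", nrow(x), " GWAS records from ", basename(path))
  x
}

#' Read gene models from BED
#'
#' Headerless 6-column BED: chrom, start, end, name, score, strand;
#' coordinates 0-based half-open. The transcription start site (TSS) is
#' `start` on the + strand and `end - 1` on the - strand.
#'
#' @inheritParams read_gwas
#' @return Tibble with columns gene_id, chrom, start, end, strand, tss.
#' @export
read_genes <- function(path, verbose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  x <- tibble::tibble(
    gene_id = check_not_na(raw$gene_id, "name", path),
    chrom = check_not_na(raw$chrom, "chrom", path),
    start = check_not_na(as_int(raw$start, "start", path), "start", path),
    end = check_not_na(as_int(raw$end, "end", path), "end", path),
    strand = check_not_na(raw$strand, "strand", path)
  )
  if (any(x$start >= x$end)) {
    stop_rows("start must be < end (0-based half-open)", x$start >= x$end, path)
  }
  bad_strand <- !x$strand %in% c("+", "-")
  if (any(bad_strand)) stop_rows("strand must be + or -", bad_strand, path)
  if (anyDuplicated(x$gene_id) > 0) {
    stop_rows("duplicate gene_id", duplicated(x$gene_id), path)
  }
  x$tss <- ifelse(x$strand == "+", x$start, x$end - 1L)
  if (verbose) message("read ", nrow(x), " gene models from ", basename(path))
  x
}

#' Read eQTL records
#'
#' Tab-separated with header `snp_id`, `gene_id`, `tissue`, `direction`,
#' `eqtl_p`, `effect_allele`. `direction` is the sign (+1/-1) of the
#' expression change per copy of the record's effect allele. A missing
#' `effect_allele` (written `.`) is accepted but the record cannot be
#' harmonized against GWAS alleles; strict-mode funnels reject it.
#'
#' @inheritParams read_gwas
#' @param vocabulary Allowed tissue names; defaults to [tissue_vocabulary()].
#' @return Tibble of validated records.
#' @export
read_eqtls <- function(path, vocabulary = tissue_vocabulary(), verbose = FALSE) {
  req <- c("snp_id", "gene_id", "tissue", "direction", "eqtl_p", "effect_allele")
  raw <- read_tsv_raw(path, req)
  x <- tibble::tibble(
    snp_id = check_not_na(raw$snp_id, "snp_id", path),
    gene_id = check_not_na(raw$gene_id, "gene_id", path),
    tissue = check_not_na(raw$tissue, "tissue", path),
    direction = check_not_na(as_int(raw$direction, "direction", path),
                             "direction", path),
    eqtl_p = check_not_na(as_num(raw$eqtl_p, "eqtl_p", path), "eqtl_p", path),
    effect_allele = raw$effect_allele
  )
  bad_dir <- !x$direction %in% c(-1L, 1L)
  if (any(bad_dir)) stop_rows("direction must be +1 or -1", bad_dir, path)
  if (any(x$eqtl_p <= 0 | x$eqtl_p > 1)) {
    stop_rows("eqtl_p must be in (0, 1]", x$eqtl_p <= 0 | x$eqtl_p > 1, path)
  }
  bad_tissue <- !x$tissue %in% vocabulary
  if (any(bad_tissue)) {
    stop(
      "validation error in ", basename(path), ": tissue not in vocabulary (",
      paste(unique(x$tissue[bad_tissue]), collapse = ", "),
      ") at data row(s) ", paste(head(which(bad_tissue), 5L), collapse = ", "),
      "; allowed: ", paste(vocabulary, collapse = ", "),
      call. = FALSE
    )
  }
  if (verbose) message("read ", nrow(x), " eQTL records from ", basename(path))
  x
}

#' Read drug-gene interactions
#'
#' Tab-separated with header `gene_id`, `drug_name`, `action`, `approved`;
#' `action` is one of inhibitor, activator, other.
#'
#' @inheritParams read_gwas
#' @return Tibble of validated records.
#' @export
read_dgi <- function(path, verbose = FALSE) {
  req <- c("gene_id", "drug_name", "action", "approved")
  raw <- read_tsv_raw(path, req)
  appr_chr <- tolower(check_not_na(raw$approved, "approved", path))
  bad_appr <- !appr_chr %in% c("true", "false", "1", "0")
  if (any(bad_appr)) stop_rows("approved must be TRUE/FALSE", bad_appr, path)
  x <- tibble::tibble(
    gene_id = check_not_na(raw$gene_id, "gene_id", path),
    drug_name = check_not_na(raw$drug_name, "drug_name", path),
    action = check_not_na(raw$action, "action", path),
    approved = appr_chr %in% c("true", "1")
  )
  bad_action <- !x$action %in% c("inhibitor", "activator", "other")
  if (any(bad_action)) {
    stop_rows("action must be inhibitor/activator/other", bad_action, path)
  }
  if (verbose) {
    message("read ", nrow(x), " drug-gene interactions from ", basename(path))
  }
  x
}

#' Read ortholog pairs
#'
#' Tab-separated with header `human_gene`, `model_gene`, `percent_identity`,
#' `source`; identity is a percentage in \[0, 100\].
#'
#' @inheritParams read_gwas
#' @return Tibble of validated records.
#' @export
read_orthologs <- function(path, verbose = FALSE) {
  req <- c("human_gene", "model_gene", "percent_identity", "source")
  raw <- read_tsv_raw(path, req)
  x <- tibble::tibble(
    human_gene = check_not_na(raw$human_gene, "human_gene", path),
    model_gene = check_not_na(raw$model_gene, "model_gene", path),
    percent_identity = check_not_na(
      as_num(raw$percent_identity, "percent_identity", path),
      "percent_identity", path
    ),
    source = check_not_na(raw$source, "source", path)
  )
  bad <- x$percent_identity < 0 | x$percent_identity > 100
  if (any(bad)) stop_rows("percent_identity must be in [0, 100]", bad, path)
  if (verbose) {
    message("read ", nrow(x), " ortholog pairs from ", basename(path))
  }
  x
}

#' Read a per-subject event table
#'
#' Tab-separated with header `subject_id`, `group`, `time`, `event`;
#' `time` is hours since assay start and `event` is 1 for an observed event
#' (e.g. paralysis) and 0 for censoring.
#'
#' @inheritParams read_gwas
#' @return Tibble of validated records.
#' @export
read_events <- function(path, verbose = FALSE) {
  req <- c("subject_id", "group", "time", "event")
  raw <- read_tsv_raw(path, req)
  x <- tibble::tibble(
    subject_id = check_not_na(raw$subject_id, "subject_id", path),
    group = check_not_na(raw$group, "group", path),
    time = check_not_na(as_num(raw$time, "time", path), "time", path),
    event = check_not_na(as_int(raw$event, "event", path), "event", path)
  )
  if (any(x$time < 0)) stop_rows("time must be >= 0", x$time < 0, path)
  bad_ev <- !x$event %in% c(0L, 1L)
  if (any(bad_ev)) stop_rows("event must be 0 or 1", bad_ev, path)
  if (verbose) message("read ", nrow(x), " event rows from ", basename(path))
  x
}

# --- writers -----------------------------------------------------------------

#' Write pipeline tables
#'
#' Writers matching the readers: tab-separated, header row, missing
#' `effect_allele` written as `.`. `write_genes()` emits headerless 6-column
#' BED with a `.` score. Round trips are lossless: `read(write(x))` equals
#' `x` field by field.
#'
#' @param x Tibble as returned by the corresponding reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(x, path) {
  readr::write_tsv(
    x[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele", "or", "p")],
    path
  )
  invisible(path)
}

#' @rdname write_gwas
#' @export
write_genes <- function(x, path) {
  bed <- tibble::tibble(
    chrom = x$chrom, start = x$start, end = x$end,
    name = x$gene_id, score = ".", strand = x$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_gwas
#' @export
write_eqtls <- function(x, path) {
  readr::write_tsv(
    x[, c("snp_id", "gene_id", "tissue", "direction", "eqtl_p", "effect_allele")],
    path,
    na = "."
  )
  invisible(path)
}

#' @rdname write_gwas
#' @export
write_dgi <- function(x, path) {
  readr::write_tsv(x[, c("gene_id", "drug_name", "action", "approved")], path)
  invisible(path)
}

#' @rdname write_gwas
#' @export
write_orthologs <- function(x, path) {
  readr::write_tsv(
    x[, c("human_gene", "model_gene", "percent_identity", "source")], path
  )
  invisible(path)
}

#' @rdname write_gwas
#' @export
write_events <- function(x, path) {
  readr::write_tsv(x[, c("subject_id", "group", "time", "event")], path)
  invisible(path)
}
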