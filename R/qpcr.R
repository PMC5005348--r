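#' Read a qRT-PCR Ct table
#'
#' TSV with columns `gene`, `sample`, `condition`, `replicate`, `ct` — one
#' row per well. Ct values must be finite and positive.
#'
#' @param path path to the TSV file.
#' @return data.frame of class `ct_table`.
#' @export
read_ct <- function(path) {
  if (!file.exists(path)) stop_fmt("Ct table not found: %s", path)
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("gene", "sample", "condition", "replicate", "ct")
  if (!all(need %in% colnames(df)))
    stop_fmt("Ct table %s must have columns: %s", path,
             paste(need, collapse = ", "))
  df <- df[need]
  df$ct <- as.numeric(df$ct)
  bad <- which(!is.finite(df$ct) | df$ct <= 0)
  if (length(bad))
    stop_fmt("invalid Ct at row %d (gene %s, sample %s)",
             bad[1], df$gene[bad[1]], df$sample[bad[1]])
  df$gene <- toupper(df$gene)
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Write a Ct table to TSV
#' @param x a `ct_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Delta-delta-Ct relative quantification
#'
#' Standard comparative-Ct analysis normalised to a housekeeping gene: per
#' sample, `dCt = mean Ct(gene) - mean Ct(reference)` (technical wells
#' averaged); per gene, `ddCt = mean dCt(condition B) - mean dCt(A)` and
#' `RQ = 2^(-ddCt)`, the fold change relative to the baseline condition.
#' Per-sample RQ values (each sample's `dCt` referenced to the baseline
#' mean) are retained for the between-condition t-test; the reported SEM is
#' that of the non-baseline samples' RQs, matching how validation figures
#' quote error bars over independent samples.
#'
#' @param table a `ct_table` data.frame (`gene`, `sample`, `condition`,
#'   `replicate`, `ct`).
#' @param reference_gene housekeeping gene (default GAPDH); must be
#'   measured in every sample.
#' @param baseline_condition condition treated as reference; defaults to
#'   the first condition in the table.
#' @param var_equal use the classical equal-variance Student t-test
#'   (default); `FALSE` gives Welch.
#' @return data.frame of class `rq_result` with per-gene `ddct`, `rq`,
#'   `log2_rq` (`= -ddct`), `sem` and `pval`; per-sample RQs in attribute
#'   `sample_rq`.
#' @examples
#' ct <- simulate_ct_table(c(GFAP = -2), noise_sd = 0, seed = 1)
#' compute_rq(ct)[, c("gene", "rq")]  # GAPDH 1, GFAP 0.25
#' @export
compute_rq <- function(table, reference_gene = "GAPDH",
                       baseline_condition = NULL, var_equal = TRUE) {
  need <- c("gene", "sample", "condition", "replicate", "ct")
  if (!all(need %in% colnames(table)))
    stop_fmt("Ct table must have columns: %s", paste(need, collapse = ", "))
  table$gene <- toupper(table$gene)
  reference_gene <- toupper(reference_gene)
  conds <- unique(table$condition)
  if (length(conds) != 2L)
    stop_fmt("exactly two conditions are required, got %d", length(conds))
  baseline_condition <- baseline_condition %||% conds[1]
  if (!baseline_condition %in% conds)
    stop_fmt("baseline condition '%s' not present", baseline_condition)
  other <- setdiff(conds, baseline_condition)

  # mean Ct per (gene, sample) over technical wells
  agg <- aggregate(ct ~ gene + sample + condition, data = table, FUN = mean)
  samples <- unique(agg$sample)
  ref <- agg[agg$gene == reference_gene, ]
  missing <- setdiff(samples, ref$sample)
  if (length(missing))
    stop_fmt("reference gene %s missing in sample %s", reference_gene,
             missing[1])
  ref_ct <- setNames(ref$ct, ref$sample)
  agg$dct <- agg$ct - ref_ct[agg$sample]

  genes <- unique(agg$gene)
  sample_rq <- list()
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- agg[agg$gene == g, ]
    dA <- sub$dct[sub$condition == baseline_condition]
    dB <- sub$dct[sub$condition == other]
    if (!length(dA) || !length(dB))
      stop_fmt("gene %s is not measured in both conditions", g)
    ddct <- mean(dB) - mean(dA)
    rq_s <- setNames(2^(-(sub$dct - mean(dA))), sub$sample)
    sample_rq[[g]] <<- rq_s
    rqB <- rq_s[sub$condition == other]
    rqA <- rq_s[sub$condition == baseline_condition]
    data.frame(gene = g, ddct = ddct, rq = 2^(-ddct), log2_rq = -ddct,
               sem = if (length(rqB) > 1) sd(rqB) / sqrt(length(rqB))
                     else NA_real_,
               pval = if (length(rqA) > 1 && length(rqB) > 1)
                 gene_t_test(rqA, rqB, var_equal = var_equal)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "sample_rq") <- sample_rq
  attr(out, "reference_gene") <- reference_gene
  attr(out, "baseline") <- baseline_condition
  class(out) <- c("rq_result", "data.frame")
  out
}

#' Two-sample t-test on replicate relative quantities
#'
#' Two-sided Student t-test (equal variances by default, Welch behind the
#' flag) comparing a gene's per-replicate RQ values between conditions.
#' Degenerate zero-variance input returns 1 when the group means are equal
#' and 0 when they differ.
#'
#' @param a,b numeric vectors (at least 2 values each).
#' @param var_equal pool the variances (classical Student test).
#' @return two-sided p-value.
#' @export
gene_t_test <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2)
    stop_fmt("both groups need at least 2 replicates")
  if (var(a) == 0 && var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  t.test(a, b, var.equal = var_equal)$p.value
}

#' Concordance between qRT-PCR and RNA-seq fold changes
#'
#' Pearson correlation of paired log2 fold changes from the two assays,
#' with a 95% confidence interval from the Fisher z-transform
#' (`tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`).
#'
#' @param qpcr_log2fc,rnaseq_log2fc named numeric vectors of log2 fold
#'   changes; at least 3 shared genes are required.
#' @param conf_level confidence level for the interval.
#' @return list with `r`, `r2`, `ci` (length-2 vector), `n` and the shared
#'   `genes`.
#' @export
concordance <- function(qpcr_log2fc, rnaseq_log2fc, conf_level = 0.95) {
  if (is.null(names(qpcr_log2fc)) || is.null(names(rnaseq_log2fc)))
    stop_fmt("fold-change vectors must be named by gene")
  names(qpcr_log2fc) <- toupper(names(qpcr_log2fc))
  names(rnaseq_log2fc) <- toupper(names(rnaseq_log2fc))
  shared <- intersect(names(qpcr_log2fc), names(rnaseq_log2fc))
  n <- length(shared)
  if (n < 3) stop_fmt("at least 3 shared genes are required, got %d", n)
  x <- qpcr_log2fc[shared]; y <- rnaseq_log2fc[shared]
  r <- cor(x, y)
  ci <- if (abs(r) >= 1 || n <= 3) {
    c(r, r)
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    tanh(z + c(-1, 1) * qnorm(1 - (1 - conf_level) / 2) * se)
  }
  list(r = r, r2 = r^2, ci = ci, n = n, genes = sort(shared))
}
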