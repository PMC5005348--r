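#' Median-of-ratios size factors
#'
#' Per-sample library scaling factors: each sample's counts are divided by
#' the per-gene geometric mean across samples, and the size factor is the
#' median of those ratios over genes whose geometric mean is positive (i.e.
#' genes observed in every sample).
#'
#' @param x a [count_matrix()] or integer matrix (genes x samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' estimate_size_factors(m)  # 1/sqrt(2), sqrt(2)
#' @export
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  if (!any(ok))
    stop_fmt(paste("no gene has positive counts in every sample;",
                   "median-of-ratios normalization is undefined",
                   "(a pseudo-reference fallback is deliberately not used)"))
  sf <- apply(log(counts[ok, , drop = FALSE]) - loggeo[ok], 2,
              function(lr) exp(median(lr)))
  setNames(sf, colnames(counts))
}

#' Negative-binomial dispersion estimation with a parametric 1/mu fit
#'
#' Per-gene method-of-moments dispersion on normalized counts,
#' `alpha_hat = max(0, (v - mu) / mu^2)`, where `mu` is the across-sample
#' mean of normalized counts and `v` the within-condition pooled variance.
#' A parametric curve `alpha(mu) = a0 + a1/mu` is fitted by regressing the
#' raw estimates on `1/mu`; the working dispersion is the maximum of the raw
#' and fitted values — the conservative sharing mode appropriate for designs
#' with very few replicates.
#'
#' @param x a [count_matrix()] or integer matrix.
#' @param size_factors per-sample size factors; estimated if missing.
#' @param conditions named condition assignment; taken from `x` if absent.
#'   At least one condition must have two or more replicates.
#' @return object of class `dispersion_fit`: list with `raw`, `fitted`,
#'   `final` (per-gene dispersions), `coef` (`a0`, `a1`) and `mean`
#'   (per-gene normalized means).
#' @export
fit_dispersions <- function(x, size_factors = NULL, conditions = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  conditions <- conditions %||%
    (if (inherits(x, "count_matrix")) x$conditions)
  if (is.null(conditions)) stop_fmt("condition assignment is required")
  conditions <- conditions[colnames(counts)]
  size_factors <- size_factors %||% estimate_size_factors(counts)
  norm <- sweep(counts, 2, size_factors[colnames(counts)], "/")
  mu <- rowMeans(norm)
  groups <- split(seq_len(ncol(norm)), conditions)
  df_tot <- sum(pmax(lengths(groups) - 1L, 0L))
  if (df_tot < 1L)
    stop_fmt("at least two replicates in one condition are required")
  ss <- rowSums(vapply(groups, function(idx) {
    if (length(idx) < 2L) return(numeric(nrow(norm)))
    sub <- norm[, idx, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }, numeric(nrow(norm))))
  v <- ss / df_tot
  if (all(v == 0)) stop_fmt("all genes are constant; dispersion is undefined")
  raw <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), 0)
  sel <- mu > 0 & is.finite(raw)
  fit <- lm(raw[sel] ~ I(1 / mu[sel]))
  a0 <- unname(coef(fit)[1]); a1 <- unname(coef(fit)[2])
  if (is.na(a1)) a1 <- 0
  fitted <- pmax(a0 + a1 / mu, 1e-8)
  fitted[mu == 0] <- 1e-8
  final <- pmax(raw, fitted, 1e-8)
  structure(list(raw = setNames(raw, rownames(counts)),
                 fitted = setNames(fitted, rownames(counts)),
                 final = setNames(final, rownames(counts)),
                 coef = c(a0 = a0, a1 = a1),
                 mean = setNames(mu, rownames(counts))),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("dispersion_fit: %d genes, alpha(mu) = %.4g + %.4g/mu, median final alpha %.4g\n",
              length(x$final), x$coef[["a0"]], x$coef[["a1"]],
              median(x$final)))
  invisible(x)
}

#' Conditional negative-binomial exact test for one gene
#'
#' Tests the null hypothesis of equal expression between two conditions
#' given the summed counts `kA` and `kB`. Conditional on the total
#' `kA + kB`, the probability of every split `(a, kA + kB - a)` is computed
#' from the negative-binomial distributions of the two condition sums
#' (means `q * sum(s)` and variances `q * sum(s) + alpha * q^2 * sum(s^2)`
#' with `q` the pooled mean estimate); the two-sided p-value is the summed
#' probability of all splits no more likely than the observed one, divided
#' by the total.
#'
#' @param kA,kB summed counts in condition A and B.
#' @param size_factors_A,size_factors_B size factors of the samples in each
#'   condition.
#' @param dispersion the gene's NB dispersion (must be positive; use a tiny
#'   value for the Poisson limit).
#' @return two-sided p-value in (0, 1]; `kA == kB` with equal size factors
#'   gives exactly 1.
#' @examples
#' nb_exact_test(30, 60, c(1, 1), c(1, 1), dispersion = 0.1)
#' @export
nb_exact_test <- function(kA, kB, size_factors_A = 1, size_factors_B = 1,
                          dispersion) {
  if (!all(is.finite(c(kA, kB, size_factors_A, size_factors_B, dispersion))))
    stop_fmt("all exact-test parameters must be finite")
  if (kA < 0 || kB < 0) stop_fmt("counts must be non-negative")
  if (dispersion <= 0) stop_fmt("dispersion must be positive")
  if (any(size_factors_A <= 0) || any(size_factors_B <= 0))
    stop_fmt("size factors must be positive")
  total <- kA + kB
  if (total == 0) return(1)
  if (total > 2e6)
    stop_fmt("total count %d too large for the exact test", total)
  sA <- sum(size_factors_A); sB <- sum(size_factors_B)
  sizeA <- sA^2 / (dispersion * sum(size_factors_A^2))
  sizeB <- sB^2 / (dispersion * sum(size_factors_B^2))
  q0 <- total / (sA + sB)
  muA <- q0 * sA
  muB <- q0 * sB
  ks <- 0:total
  pa <- dnbinom(ks, mu = muA, size = sizeA) *
    dnbinom(total - ks, mu = muB, size = sizeB)
  denom <- sum(pa)
  if (denom == 0) return(1)
  pobs <- pa[kA + 1]
  # relative tolerance catches floating-point ties between symmetric splits
  min(1, sum(pa[pa <= pobs * (1 + 1e-7)]) / denom)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]); output is
#' capped at 1 and elementwise no smaller than the input.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
adjust_bh <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop_fmt("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Differential expression between two conditions
#'
#' Runs the full per-gene analysis: genes with zero counts in every sample
#' are dropped ("detected transcripts" only), size factors are estimated by
#' median-of-ratios, dispersions by [fit_dispersions()], and each gene is
#' tested with the conditional NB exact test ([nb_exact_test()]) on the
#' summed counts per condition. Fold changes are `log2(meanB / meanA)` of
#' normalized means; when either mean is zero a pseudocount of 0.5 is added
#' to both and the gene is flagged.
#'
#' @param x a [count_matrix()] with conditions, or an integer matrix plus
#'   `conditions`.
#' @param conditions optional named condition vector overriding `x`'s.
#' @param baseline condition label used as reference (condition A); defaults
#'   to the first condition encountered in column order.
#' @return data.frame of class `de_result` with columns `gene`, `baseMeanA`,
#'   `baseMeanB`, `log2fc`, `pval`, `padj`, `pseudocount` (logical flag).
#'   Attributes: `size_factors`, `dispersion_fit`, `baseline`, `contrast`.
#' @examples
#' sim <- simulate_counts(n_genes = 100, seed = 7)
#' res <- run_de(sim$counts)
#' head(res)
#' @export
run_de <- function(x, conditions = NULL, baseline = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  conditions <- conditions %||%
    (if (inherits(x, "count_matrix")) x$conditions)
  if (is.null(conditions)) stop_fmt("condition assignment is required")
  conditions <- conditions[colnames(counts)]
  lev <- unique(unname(conditions))
  if (length(lev) != 2L) stop_fmt("exactly two conditions are required")
  baseline <- baseline %||% lev[1]
  if (!baseline %in% lev) stop_fmt("baseline '%s' is not a condition", baseline)
  other <- setdiff(lev, baseline)

  detected <- rowSums(counts) > 0
  counts <- counts[detected, , drop = FALSE]
  if (!nrow(counts)) stop_fmt("no detected transcripts (all counts zero)")
  sf <- estimate_size_factors(counts)
  disp <- fit_dispersions(counts, sf, conditions)
  norm <- sweep(counts, 2, sf, "/")
  idxA <- which(conditions == baseline)
  idxB <- which(conditions == other)
  baseMeanA <- rowMeans(norm[, idxA, drop = FALSE])
  baseMeanB <- rowMeans(norm[, idxB, drop = FALSE])
  pseudo <- baseMeanA == 0 | baseMeanB == 0
  log2fc <- ifelse(pseudo,
                   log2((baseMeanB + 0.5) / (baseMeanA + 0.5)),
                   log2(baseMeanB / baseMeanA))
  kA <- rowSums(counts[, idxA, drop = FALSE])
  kB <- rowSums(counts[, idxB, drop = FALSE])
  pval <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(kA[i], kB[i], sf[idxA], sf[idxB], disp$final[i])
  }, numeric(1))
  res <- data.frame(gene = rownames(counts),
                    baseMeanA = baseMeanA, baseMeanB = baseMeanB,
                    log2fc = log2fc, pval = pval, padj = adjust_bh(pval),
                    pseudocount = pseudo,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "size_factors") <- sf
  attr(res, "dispersion_fit") <- disp
  attr(res, "baseline") <- baseline
  attr(res, "contrast") <- c(A = baseline, B = other)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Summarise a differential-expression result
#'
#' Counts significant transcripts at the adjusted-p cutoff, splits them by
#' direction, and extracts the fold-change-filtered up/down gene lists used
#' as enrichment input.
#'
#' @param results a `de_result` data.frame (needs `gene`, `log2fc`, `padj`).
#' @param padj_cutoff significance threshold on the BH-adjusted p (strict
#'   `<`).
#' @param fold_cutoff linear fold-change threshold for the gene lists
#'   (inclusive, i.e. `|log2fc| >= log2(fold_cutoff)`).
#' @return list with `total_detected`, `n_de`, `n_down`, `n_up`, `pct_de`
#'   (percentage of detected, one decimal), `down_genes`, `up_genes` (the
#'   fold-filtered significant lists) and the thresholds used.
#' @export
de_summary <- function(results, padj_cutoff = 0.05, fold_cutoff = 1.5) {
  if (!nrow(results)) stop_fmt("empty differential-expression result")
  sig <- !is.na(results$padj) & results$padj < padj_cutoff
  n_de <- sum(sig)
  n_down <- sum(sig & results$log2fc < 0)
  n_up <- sum(sig & results$log2fc > 0)
  fold_ok <- abs(results$log2fc) >= log2(fold_cutoff)
  list(total_detected = nrow(results),
       n_de = n_de, n_down = n_down, n_up = n_up,
       pct_de = pct1(n_de / nrow(results)),
       down_genes = results$gene[sig & fold_ok & results$log2fc < 0],
       up_genes = results$gene[sig & fold_ok & results$log2fc > 0],
       padj_cutoff = padj_cutoff, fold_cutoff = fold_cutoff)
}

#' Principal-component analysis of samples
#'
#' PCA on `log2(normalized count + 1)` over all detected genes, samples as
#' observations. Used as the reproducibility check that replicate samples
#' cluster by condition.
#'
#' @param x a [count_matrix()] or matrix with at least 3 samples.
#' @param size_factors optional size factors; estimated if missing.
#' @return list with `coords` (data.frame: sample, PC1, PC2, condition if
#'   known), `var_frac` (variance fraction per component; all zero for
#'   degenerate input) and `degenerate` flag.
#' @export
pca_samples <- function(x, size_factors = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(counts) < 3L)
    stop_fmt("PCA needs at least 3 samples, got %d", ncol(counts))
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  size_factors <- size_factors %||% estimate_size_factors(counts)
  lmat <- log2(sweep(counts, 2, size_factors, "/") + 1)
  pc <- prcomp(t(lmat), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  degenerate <- tot < 1e-12
  var_frac <- if (degenerate) rep(0, length(pc$sdev)) else pc$sdev^2 / tot
  scores <- pc$x
  coords <- data.frame(sample = colnames(counts),
                       PC1 = if (ncol(scores) >= 1) scores[, 1] else 0,
                       PC2 = if (ncol(scores) >= 2) scores[, 2] else 0,
                       row.names = NULL, stringsAsFactors = FALSE)
  if (inherits(x, "count_matrix") && !is.null(x$conditions))
    coords$condition <- unname(x$conditions[coords$sample])
  list(coords = coords, var_frac = var_frac, degenerate = degenerate)
}

#' Replicate-to-replicate squared correlation
#'
#' Squared Pearson correlation of `log2(normalized count + 1)` between
#' same-condition replicate pairs, the reproducibility statistic quoted for
#' the sequencing libraries.
#'
#' @param x a [count_matrix()] (or matrix plus `conditions`).
#' @param size_factors optional size factors.
#' @param pairs list of length-2 character vectors of sample ids; defaults
#'   to all within-condition pairs.
#' @param conditions optional condition vector when `x` is a bare matrix.
#' @return named numeric vector of r-squared values (`"s1|s2"`).
#' @export
replicate_r2 <- function(x, size_factors = NULL, pairs = NULL,
                         conditions = NULL) {
  counts <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  conditions <- conditions %||%
    (if (inherits(x, "count_matrix")) x$conditions)
  if (is.null(pairs)) {
    if (is.null(conditions))
      stop_fmt("either pairs or a condition assignment is required")
    pairs <- list()
    for (grp in split(colnames(counts), conditions[colnames(counts)])) {
      if (length(grp) >= 2)
        pairs <- c(pairs, utils::combn(grp, 2, simplify = FALSE))
    }
  }
  if (!is.null(conditions)) {
    for (p in pairs) {
      if (length(unique(conditions[p])) != 1L)
        stop_fmt("replicate pair %s|%s spans two conditions", p[1], p[2])
    }
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  size_factors <- size_factors %||% estimate_size_factors(counts)
  lmat <- log2(sweep(counts, 2, size_factors, "/") + 1)
  out <- vapply(pairs, function(p) cor(lmat[, p[1]], lmat[, p[2]])^2,
                numeric(1))
  setNames(out, vapply(pairs, paste, character(1), collapse = "|"))
}
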