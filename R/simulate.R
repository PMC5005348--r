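#' Simulate a two-condition negative-binomial count matrix
#'
#' Draws read counts for a two-condition design mirroring the study layout
#' (two biological replicates per condition by default). Counts for gene `i`
#' in sample `j` are negative-binomial with mean
#' `q_i * 2^(lfc_i * [condition B]) * s_j` and dispersion
#' `alpha_i = a0 + a1 / q_i` (variance `mu + alpha * mu^2`). A stated
#' fraction of genes carries a non-zero log2 fold change; all other genes
#' have a fold change of exactly 0 (point null), matching the exact test's
#' null hypothesis.
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per condition.
#' @param de_fraction fraction of genes that are differentially expressed
#'   (default 0.18, the proportion observed in the astrocyte study).
#' @param lfc_sampler function(n) returning the non-zero log2 fold changes;
#'   the default draws balanced signs with magnitude at least log2(1.5).
#' @param mean_sampler function(n) returning baseline mean expression `q_i`.
#' @param dispersion named vector `c(a0=, a1=)` of the dispersion-mean model
#'   `alpha(mu) = a0 + a1/mu`; `c(0, 0)` gives Poisson counts.
#' @param size_factors per-sample library-size multipliers (length
#'   `2 * n_reps`), or `NULL` to draw them uniformly on a 2^(+/-0.8) range,
#'   emulating the roughly three-fold library-depth spread of the study.
#' @param conditions labels for the two conditions; the first is the
#'   baseline.
#' @param seed RNG seed; identical seeds give identical output.
#' @return list with elements `counts` (a [count_matrix()]) and `truth`, a
#'   `sim_truth` list holding `q`, `lfc`, `alpha`, `size_factors`,
#'   `de_genes`, `up_genes`, `down_genes` and `conditions` — sufficient to
#'   score any downstream stage.
#' @examples
#' sim <- simulate_counts(n_genes = 200, seed = 1)
#' sim$counts
#' length(sim$truth$de_genes)
#' @export
simulate_counts <- function(n_genes = 2000, n_reps = 2, de_fraction = 0.18,
                            lfc_sampler = function(n)
                              sample(c(-1, 1), n, replace = TRUE) *
                              (log2(1.5) + rexp(n, rate = 2)),
                            mean_sampler = function(n)
                              rlnorm(n, meanlog = log(100), sdlog = 1),
                            dispersion = c(a0 = 0.01, a1 = 1),
                            size_factors = NULL,
                            conditions = c("presenescent", "senescent"),
                            seed = NULL) {
  if (n_genes < 1 || n_reps < 1)
    stop_fmt("n_genes and n_reps must be at least 1")
  if (de_fraction < 0 || de_fraction > 1)
    stop_fmt("de_fraction must lie in [0, 1], got %g", de_fraction)
  if (length(dispersion) != 2 || any(dispersion < 0))
    stop_fmt("dispersion must be two non-negative coefficients (a0, a1)")
  if (length(conditions) != 2 || anyDuplicated(conditions))
    stop_fmt("exactly two distinct condition labels are required")
  n_samples <- 2L * n_reps
  if (!is.null(size_factors) &&
      (length(size_factors) != n_samples || any(size_factors <= 0)))
    stop_fmt("size_factors must be %d positive values", n_samples)

  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    samples <- paste(rep(conditions, each = n_reps), seq_len(n_reps),
                     sep = "_")
    cond_of <- setNames(rep(conditions, each = n_reps), samples)
    q <- mean_sampler(n_genes)
    if (any(!is.finite(q) | q <= 0))
      stop_fmt("mean_sampler must return positive finite means")
    n_de <- round(de_fraction * n_genes)
    lfc <- numeric(n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    if (n_de > 0) lfc[de_idx] <- lfc_sampler(n_de)
    alpha <- dispersion[[1]] + dispersion[[2]] / q
    s <- size_factors %||% 2 ^ runif(n_samples, -0.8, 0.8)
    is_b <- as.numeric(cond_of == conditions[2])
    mu <- matrix(q, n_genes, n_samples) * 2 ^ outer(lfc, is_b)
    mu <- sweep(mu, 2, s, "*")
    counts <- matrix(0L, n_genes, n_samples,
                     dimnames = list(genes, samples))
    for (j in seq_len(n_samples)) {
      pois <- alpha <= 1e-12
      col <- numeric(n_genes)
      if (any(pois)) col[pois] <- rpois(sum(pois), mu[pois, j])
      if (any(!pois)) col[!pois] <- rnbinom(sum(!pois),
                                            mu = mu[!pois, j],
                                            size = 1 / alpha[!pois])
      counts[, j] <- as.integer(col)
    }
    names(q) <- names(lfc) <- names(alpha) <- genes
    truth <- structure(list(
      q = q, lfc = lfc, alpha = alpha, size_factors = setNames(s, samples),
      de_genes = genes[de_idx],
      up_genes = genes[lfc > 0], down_genes = genes[lfc < 0],
      conditions = conditions), class = "sim_truth")
    list(counts = count_matrix(counts, cond_of), truth = truth)
  })
}

#' Simulate gene-set collections with planted structure
#'
#' Emits background terms sampled uniformly from the gene universe, terms
#' enriched for differentially expressed (DE) genes at a stated odds, and
#' blocks of terms that share an exact number of DE genes — above or below
#' the collapsing threshold — so the term-collapsing rule can be exercised
#' deterministically. Within a planted block, filler genes are drawn from
#' non-DE genes only, so the pairwise DE intersection of block members is
#' exactly the planted core.
#'
#' @param gene_ids gene universe.
#' @param de_genes DE genes within the universe.
#' @param n_background number of unenriched background terms.
#' @param size_range size range (min, max) for background terms.
#' @param n_enriched number of planted enriched terms.
#' @param enrich_odds sampling odds favouring DE genes in enriched terms
#'   (1 = no enrichment).
#' @param enriched_size_range size range for enriched terms.
#' @param collapse_blocks list of blocks, each a list with `n_terms`,
#'   `shared_de` (exact number of DE genes common to all block members) and
#'   `extra_size` (non-DE filler genes per member).
#' @param seed RNG seed.
#' @return list with `collection` (a [gene_set_collection()] carrying the
#'   universe) and `truth` (`enriched_terms`, `background_terms`,
#'   `block_terms`: list of term-id vectors per block).
#' @export
simulate_genesets <- function(gene_ids, de_genes, n_background = 40,
                              size_range = c(20, 150), n_enriched = 0,
                              enrich_odds = 5,
                              enriched_size_range = c(50, 150),
                              collapse_blocks = list(), seed = NULL) {
  gene_ids <- canon_genes(gene_ids)
  de_genes <- intersect(canon_genes(de_genes), gene_ids)
  non_de <- setdiff(gene_ids, de_genes)
  if (n_background > 0 && max(size_range) > length(gene_ids))
    stop_fmt("size_range exceeds the %d-gene universe", length(gene_ids))
  if (n_enriched > 0 && max(enriched_size_range) > length(gene_ids))
    stop_fmt("enriched_size_range exceeds the %d-gene universe",
             length(gene_ids))
  for (blk in collapse_blocks) {
    if (blk$shared_de > length(de_genes))
      stop_fmt("collapse block requests %d shared DE genes but only %d exist",
               blk$shared_de, length(de_genes))
    if (blk$extra_size > length(non_de))
      stop_fmt("collapse block filler size %d exceeds the %d non-DE genes",
               blk$extra_size, length(non_de))
  }
  if (n_enriched > 0 && enrich_odds <= 0)
    stop_fmt("enrich_odds must be positive")

  with_seed(seed, {
    sets <- list()
    truth <- list(background_terms = character(0),
                  enriched_terms = character(0), block_terms = list())
    weighted_draw <- function(size, odds) {
      w <- ifelse(gene_ids %in% de_genes, odds, 1)
      sample(gene_ids, size, prob = w)
    }
    if (n_background > 0) {
      for (i in seq_len(n_background)) {
        id <- sprintf("BG%04d", i)
        sets[[id]] <- sample(gene_ids,
                             sample(size_range[1]:size_range[2], 1))
        truth$background_terms <- c(truth$background_terms, id)
      }
    }
    if (n_enriched > 0) {
      for (i in seq_len(n_enriched)) {
        id <- sprintf("EN%04d", i)
        sz <- sample(enriched_size_range[1]:enriched_size_range[2], 1)
        sets[[id]] <- weighted_draw(sz, enrich_odds)
        truth$enriched_terms <- c(truth$enriched_terms, id)
      }
    }
    for (k in seq_along(collapse_blocks)) {
      blk <- collapse_blocks[[k]]
      core <- sample(de_genes, blk$shared_de)
      ids <- character(blk$n_terms)
      for (t in seq_len(blk$n_terms)) {
        id <- sprintf("CB%d_T%d", k, t)
        sets[[id]] <- c(core, sample(non_de, blk$extra_size))
        ids[t] <- id
      }
      truth$block_terms[[k]] <- ids
    }
    if (!length(sets))
      stop_fmt("no terms requested: all of n_background, n_enriched and collapse_blocks are empty")
    list(collection = gene_set_collection(sets, name = "simulated_go",
                                          universe = gene_ids),
         truth = structure(truth, class = "sim_truth"))
  })
}

#' Simulate a tissue-expression annotation
#'
#' Builds named tissue gene sets (blocks), at least one of which is
#' CNS-like; CNS blocks can oversample a supplied list of downregulated
#' genes at a stated odds, emulating the loss of brain-expressed genes seen
#' in senescent astrocytes. With all odds equal to 1 the annotation carries
#' no signal.
#'
#' @param gene_ids gene universe.
#' @param down_genes downregulated genes the CNS blocks oversample.
#' @param blocks named list; each element is a list with `size`, `cns`
#'   (logical) and `odds` (sampling odds for `down_genes`). The default
#'   emulates a brain/hippocampus CNS pair among five peripheral tissues.
#' @param seed RNG seed.
#' @return list with `collection` (a [gene_set_collection()]), `cns_terms`
#'   (ids of the CNS blocks) and `truth`.
#' @export
simulate_tissue_annotation <- function(gene_ids, down_genes,
                                       blocks = list(
                                         brain = list(size = 500, cns = TRUE, odds = 8),
                                         hippocampus = list(size = 120, cns = TRUE, odds = 8),
                                         liver = list(size = 300, cns = FALSE, odds = 1),
                                         kidney = list(size = 250, cns = FALSE, odds = 1),
                                         heart = list(size = 200, cns = FALSE, odds = 1),
                                         lung = list(size = 200, cns = FALSE, odds = 1),
                                         testis = list(size = 250, cns = FALSE, odds = 1)),
                                       seed = NULL) {
  if (!length(blocks)) stop_fmt("at least one tissue block is required")
  if (is.null(names(blocks)) || anyDuplicated(names(blocks)))
    stop_fmt("tissue blocks must be uniquely named")
  gene_ids <- canon_genes(gene_ids)
  down_genes <- intersect(canon_genes(down_genes), gene_ids)
  sizes <- vapply(blocks, `[[`, numeric(1), "size")
  if (any(sizes < 1) || any(sizes > length(gene_ids)))
    stop_fmt("block sizes must lie in [1, %d]", length(gene_ids))
  with_seed(seed, {
    sets <- lapply(blocks, function(blk) {
      w <- ifelse(gene_ids %in% down_genes, blk$odds, 1)
      sample(gene_ids, blk$size, prob = w)
    })
    cns <- names(blocks)[vapply(blocks, `[[`, logical(1), "cns")]
    list(collection = gene_set_collection(sets, name = "simulated_tissue",
                                          universe = gene_ids),
         cns_terms = cns,
         truth = structure(list(blocks = blocks, cns_terms = cns),
                           class = "sim_truth"))
  })
}

#' Simulate a qRT-PCR cycle-threshold table
#'
#' Generates per-well Ct values under the standard exponential-amplification
#' model `Ct = intercept - log2(expression) + noise`, so that delta-delta-Ct
#' quantification recovers `RQ = 2^lfc` for each gene. The reference gene is
#' measured in every sample with a true fold change of 0.
#'
#' @param log2fc named numeric vector of true log2 fold changes
#'   (condition B vs A) for the assayed genes.
#' @param reference_gene housekeeping gene used for normalisation; appended
#'   with fold change 0 if absent from `log2fc`.
#' @param noise_sd Gaussian Ct noise per well (cycles); 0 gives exact
#'   recovery.
#' @param n_samples biological samples per condition.
#' @param n_wells technical replicate wells per sample.
#' @param base_ct_range range of per-gene baseline Ct values.
#' @param conditions two condition labels, baseline first.
#' @param seed RNG seed.
#' @return data.frame of class `ct_table` with columns `gene`, `sample`,
#'   `condition`, `replicate`, `ct`.
#' @export
simulate_ct_table <- function(log2fc, reference_gene = "GAPDH",
                              noise_sd = 0.2, n_samples = 2, n_wells = 3,
                              base_ct_range = c(20, 28),
                              conditions = c("presenescent", "senescent"),
                              seed = NULL) {
  if (is.null(names(log2fc)) || !length(log2fc))
    stop_fmt("log2fc must be a named vector")
  if (noise_sd < 0) stop_fmt("noise_sd must be non-negative")
  if (n_samples < 1 || n_wells < 1)
    stop_fmt("n_samples and n_wells must be at least 1")
  names(log2fc) <- toupper(names(log2fc))
  reference_gene <- toupper(reference_gene)
  log2fc[reference_gene] <- 0
  with_seed(seed, {
    genes <- names(log2fc)
    base_ct <- setNames(runif(length(genes), base_ct_range[1],
                              base_ct_range[2]), genes)
    rows <- expand.grid(gene = genes, condition = conditions,
                        sample_no = seq_len(n_samples),
                        replicate = seq_len(n_wells),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    delta <- ifelse(rows$condition == conditions[2], log2fc[rows$gene], 0)
    rows$ct <- base_ct[rows$gene] - delta +
      rnorm(nrow(rows), sd = noise_sd)
    rows$sample <- paste(rows$condition, rows$sample_no, sep = "_")
    out <- rows[order(rows$gene, rows$condition, rows$sample_no,
                      rows$replicate),
                c("gene", "sample", "condition", "replicate", "ct")]
    rownames(out) <- NULL
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
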