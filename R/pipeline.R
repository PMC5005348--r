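#' Default analysis thresholds
#'
#' The cut-offs used throughout the pipeline: adjusted-p 0.05 and 1.5-fold
#' change for differential expression, minimum gene count 10, minimum
#' enrichment ratio 2 and FDR below 10% for enriched terms, 25 shared DE
#' transcripts for term collapsing, expression level 100 for the
#' matched-expression filter, and a 19580-transcript universe for overlap
#' statistics.
#'
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(padj_cutoff = 0.05, fold_cutoff = 1.5, min_count = 10,
       min_enrichment = 2.0, max_fdr = 0.10, collapse_shared = 25,
       expression_cutoff = 100, overlap_universe_size = 19580)
}

#' Build a run configuration
#'
#' @param counts path to the counts TSV (required for a pipeline run).
#' @param sample_sheet path to the sample sheet TSV.
#' @param outdir output directory.
#' @param seed RNG seed recorded in every output header.
#' @param baseline baseline condition label (condition A).
#' @param go_gmt,tissue_gmt,cns_terms,ct_table,overlap_list1,overlap_list2
#'   optional stage inputs: GO gene sets (GMT), tissue gene sets (GMT), a
#'   text file of CNS term ids, a Ct table TSV, and two plain gene lists.
#' @param thresholds named list overriding entries of
#'   [default_thresholds()].
#' @return list of class `run_config`.
#' @export
run_config <- function(counts = NULL, sample_sheet = NULL,
                       outdir = "senastro_out", seed = 1, baseline = NULL,
                       go_gmt = NULL, tissue_gmt = NULL, cns_terms = NULL,
                       ct_table = NULL, overlap_list1 = NULL,
                       overlap_list2 = NULL, thresholds = list()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  bad <- names(th)[!vapply(th, function(x) is.numeric(x) && x > 0, logical(1))]
  if (length(bad)) stop_fmt("threshold %s must be strictly positive", bad[1])
  structure(list(counts = counts, sample_sheet = sample_sheet,
                 outdir = outdir, seed = seed, baseline = baseline,
                 go_gmt = go_gmt, tissue_gmt = tissue_gmt,
                 cns_terms = cns_terms, ct_table = ct_table,
                 overlap_list1 = overlap_list1,
                 overlap_list2 = overlap_list2, thresholds = th),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Flat keys matching the arguments of [run_config()]; thresholds either
#' flat (e.g. `padj_cutoff: 0.05`) or under a `thresholds:` block.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_fmt("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  th <- y$thresholds %||% list()
  flat <- intersect(names(y), names(default_thresholds()))
  th[flat] <- y[flat]
  keep <- intersect(names(y), setdiff(names(formals(run_config)),
                                      "thresholds"))
  do.call(run_config, c(y[keep], list(thresholds = th)))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full analysis pipeline
#'
#' Chains the configured stages — differential expression, GO enrichment of
#' the down- and upregulated lists (with BY FDR, filtering, weighting and
#' collapsing), tissue-expression summary, gene-list overlap and qPCR
#' validation — writing TSV outputs with a commented provenance header
#' (package version, seed, thresholds) plus a machine-readable
#' `summary.json`. All configured input paths are checked before any
#' computation, and a failure in any stage aborts with the stage name.
#' Identical configurations (including seed) produce byte-identical
#' outputs.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @return invisibly, a list bundle with the per-stage results and the
#'   summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  if (is.null(config$counts)) stop_fmt("config has no counts path")
  paths <- c(counts = config$counts, sample_sheet = config$sample_sheet,
             go_gmt = config$go_gmt, tissue_gmt = config$tissue_gmt,
             cns_terms = config$cns_terms, ct_table = config$ct_table,
             overlap_list1 = config$overlap_list1,
             overlap_list2 = config$overlap_list2)
  for (k in names(paths)) {
    if (!file.exists(paths[[k]]))
      stop_fmt("config input '%s' not found: %s", k, paths[[k]])
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(seed = config$seed, thresholds = th)
  out <- function(f) file.path(config$outdir, f)
  set.seed(config$seed)
  bundle <- list(config = config)
  summary <- list(seed = config$seed, thresholds = th)

  # --- differential expression -------------------------------------------
  de <- stage("de", {
    cm <- read_counts(config$counts, sample_sheet = config$sample_sheet)
    if (is.null(cm$conditions))
      stop_fmt("a sample sheet with conditions is required")
    res <- run_de(cm, baseline = config$baseline)
    smry <- de_summary(res, padj_cutoff = th$padj_cutoff,
                       fold_cutoff = th$fold_cutoff)
    pca <- pca_samples(cm)
    r2 <- replicate_r2(cm)
    write_tsv_commented(as.data.frame(res), out("de_results.tsv"), hdr)
    write_tsv_commented(pca$coords, out("pca.tsv"), hdr)
    list(cm = cm, res = res, summary = smry, pca = pca, r2 = r2)
  })
  bundle$de <- de
  summary$de <- de$summary[c("total_detected", "n_de", "n_down", "n_up",
                             "pct_de")]
  summary$de$n_down_fold <- length(de$summary$down_genes)
  summary$de$n_up_fold <- length(de$summary$up_genes)
  summary$replicate_r2 <- as.list(de$r2)
  summary$pca_var_frac <- de$pca$var_frac
  universe <- de$res$gene

  # --- GO enrichment ------------------------------------------------------
  if (!is.null(config$go_gmt)) {
    enr <- stage("enrich", {
      go <- read_gmt(config$go_gmt)
      lapply(setNames(c("down", "up"), c("down", "up")), function(dir) {
        genes <- de$summary[[paste0(dir, "_genes")]]
        if (!length(genes)) return(NULL)
        recs <- enrich_collection(genes, go, universe = universe)
        hits <- add_term_weights(
          filter_enriched(recs, min_count = th$min_count,
                          min_enrichment = th$min_enrichment,
                          max_fdr = th$max_fdr))
        collapsed <- collapse_terms(hits,
                                    shared_threshold = th$collapse_shared)
        write_tsv_commented(recs, out(sprintf("enrichment_%s.tsv", dir)), hdr)
        write_tsv_commented(collapsed,
                            out(sprintf("collapsed_%s.tsv", dir)), hdr)
        list(records = recs, hits = hits, collapsed = collapsed)
      })
    })
    bundle$enrichment <- enr
    summary$enrichment <- lapply(enr, function(e) {
      if (is.null(e)) return(NULL)
      list(n_tested = nrow(e$records), n_enriched = nrow(e$hits),
           n_collapsed = nrow(e$collapsed))
    })
  }

  # --- tissue expression --------------------------------------------------
  if (!is.null(config$tissue_gmt)) {
    tis <- stage("tissue", {
      tgmt <- read_gmt(config$tissue_gmt)
      cns <- if (!is.null(config$cns_terms))
        trimws(readLines(config$cns_terms, warn = FALSE)) else character(0)
      down <- de$summary$down_genes
      hit_recs <- if (length(down)) {
        r <- enrich_collection(down, tgmt, universe = universe)
        r[r$fdr < th$max_fdr, , drop = FALSE]
      }
      uni_recs <- enrich_collection(universe, tgmt, universe = universe)
      uni_recs <- uni_recs[uni_recs$fdr < th$max_fdr | uni_recs$b > 0, ,
                           drop = FALSE]
      ts <- tissue_summary(hit_recs, uni_recs, cns_terms = cns)
      if (!is.null(hit_recs))
        write_tsv_commented(hit_recs, out("tissue_down.tsv"), hdr)
      write_tsv_commented(uni_recs, out("tissue_universe.tsv"), hdr)
      ts
    })
    bundle$tissue <- tis
    summary$tissue <- tis[c("cns_pct_hits", "cns_pct_universe")]
  }

  # --- gene-set overlap ---------------------------------------------------
  if (!is.null(config$overlap_list1) && !is.null(config$overlap_list2)) {
    ov <- stage("overlap", {
      l1 <- read_gene_list(config$overlap_list1)
      l2 <- read_gene_list(config$overlap_list2)
      gene_set_overlap(l1, l2,
                       universe_size = th$overlap_universe_size)
    })
    bundle$overlap <- ov
    summary$overlap <- ov[c("n1", "n2", "N", "x", "expected", "rf",
                            "p_over", "p_under")]
    write_tsv_commented(
      data.frame(gene = ov$intersection), out("overlap_genes.tsv"), hdr)
  }

  # --- qPCR validation ----------------------------------------------------
  if (!is.null(config$ct_table)) {
    qp <- stage("qpcr", {
      ct <- read_ct(config$ct_table)
      rq <- compute_rq(ct, baseline_condition = config$baseline)
      rnaseq <- setNames(de$res$log2fc, de$res$gene)
      qpcr <- setNames(rq$log2_rq, rq$gene)
      qpcr <- qpcr[names(qpcr) != attr(rq, "reference_gene")]
      conc <- if (sum(names(qpcr) %in% names(rnaseq)) >= 3)
        concordance(qpcr, rnaseq)
      write_tsv_commented(as.data.frame(rq), out("qpcr_rq.tsv"), hdr)
      list(rq = rq, concordance = conc)
    })
    bundle$qpcr <- qp
    if (!is.null(qp$concordance))
      summary$qpcr <- qp$concordance[c("r", "r2", "ci", "n")]
  }

  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$summary <- summary
  invisible(bundle)
}
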