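# fixtures built in code; all randomness goes through explicit seeds

rand_count_matrix <- function(n_genes, n_samples, max_count = 500) {
  m <- matrix(sample.int(max_count + 1L, n_genes * n_samples,
                         replace = TRUE) - 1L,
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  count_matrix(m)
}

rand_collection <- function(n_terms, genes, size_range = c(2, 8)) {
  sets <- lapply(seq_len(n_terms), function(i)
    sample(genes, sample(size_range[1]:size_range[2], 1)))
  names(sets) <- sprintf("T%03d", seq_len(n_terms))
  gene_set_collection(sets, universe = genes)
}

# enrichment-record table from a term -> DE-gene list, for collapse tests
records_from_sets <- function(term_genes, fdr = NULL) {
  ids <- names(term_genes)
  df <- data.frame(term_id = ids,
                   fdr = fdr %||% seq(0.001, 0.09,
                                      length.out = length(ids)),
                   stringsAsFactors = FALSE)
  df$genes <- unname(term_genes)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
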