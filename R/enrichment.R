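#' Enrichment of one gene set in a query list
#'
#' Computes the over-representation statistics of a term within a query
#' list against a fixed universe: with `N` the universe size, `B` the term
#' size within the universe, `n` the query size within the universe and `b`
#' the intersection, the enrichment ratio is `(b/n) / (B/N)` and the
#' p-value is the one-sided Fisher / hypergeometric upper tail
#' `P(X >= b)`.
#'
#' @param query character vector of query genes (evaluated within the
#'   universe).
#' @param term character vector of the term's member genes.
#' @param universe character vector of all detected genes.
#' @param term_id,term_name optional labels carried into the record.
#' @return one-row data.frame (an enrichment record) with columns
#'   `term_id`, `term_name`, `N`, `B`, `n`, `b`, `enrichment`, `p`, `count`
#'   and a list-column `genes` (the intersection).
#' @examples
#' enrich_term(letters[1:8], letters[c(1:4, 20)], letters[1:20])
#' @export
enrich_term <- function(query, term, universe, term_id = "term",
                        term_name = term_id) {
  u <- canon_genes(universe)
  q <- intersect(canon_genes(query), u)
  t_ <- intersect(canon_genes(term), u)
  N <- length(u); B <- length(t_); n <- length(q)
  if (n == 0L || B == 0L)
    stop_fmt("enrichment is undefined: %s within the universe",
             if (n == 0L) "empty query" else "empty term")
  hits <- intersect(q, t_)
  b <- length(hits)
  rec <- data.frame(term_id = term_id, term_name = term_name,
                    N = N, B = B, n = n, b = b,
                    enrichment = (b / n) / (B / N),
                    p = phyper(b - 1, B, N - B, n, lower.tail = FALSE),
                    count = b, stringsAsFactors = FALSE)
  rec$genes <- list(sort(hits))
  rec
}

#' Enrichment of every term in a collection
#'
#' Applies [enrich_term()] across a [gene_set_collection()], then attaches
#' Benjamini-Yekutieli FDR values (family = all terms tested) and
#' inverse-membership gene weights.
#'
#' @param query query gene list (e.g. downregulated DE genes).
#' @param collection a `gene_sets` object.
#' @param universe universe of detected genes; defaults to the collection's
#'   own universe. Terms with no member inside the universe are dropped.
#' @return data.frame of enrichment records with additional columns `fdr`
#'   (BY-adjusted p) and `weight` (see [gene_weights()]); rows ordered as
#'   the collection.
#' @export
enrich_collection <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_sets"))
  universe <- canon_genes(universe %||% collection$universe)
  if (!length(universe))
    stop_fmt("a universe is required (none supplied, none in the collection)")
  keep <- vapply(collection$sets,
                 function(s) length(intersect(s, universe)) > 0, logical(1))
  sets <- collection$sets[keep]
  if (!length(sets)) stop_fmt("no term overlaps the universe")
  recs <- do.call(rbind, lapply(names(sets), function(id) {
    enrich_term(query, sets[[id]], universe, term_id = id,
                term_name = collection$term_names[[id]])
  }))
  recs$fdr <- adjust_by(recs$p)
  add_term_weights(recs)
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up FDR adjustment with the harmonic-sum inflation
#' `c(m) = sum(1/i)`, valid under arbitrary dependence between tests
#' (delegates to [stats::p.adjust()]); capped at 1.
#'
#' @param pvals vector of p-values in `[0, 1]`.
#' @return adjusted p-values, elementwise at least as large as
#'   [adjust_bh()]'s.
#' @export
adjust_by <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop_fmt("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BY")
}

#' Filter enrichment records on count, ratio and FDR
#'
#' Keeps terms considered enriched: gene count of 10 or greater, fold
#' enrichment of 2 or greater (both inclusive) and FDR strictly below 10%.
#' Idempotent.
#'
#' @param records enrichment records carrying `count`, `enrichment`, `fdr`.
#' @param min_count inclusive minimum intersection size.
#' @param min_enrichment inclusive minimum enrichment ratio.
#' @param max_fdr strict FDR upper bound.
#' @return the filtered records.
#' @export
filter_enriched <- function(records, min_count = 10, min_enrichment = 2.0,
                            max_fdr = 0.10) {
  need <- c("count", "enrichment", "fdr")
  if (!all(need %in% colnames(records)))
    stop_fmt("records must carry columns: %s", paste(need, collapse = ", "))
  keep <- records$count >= min_count &
    records$enrichment >= min_enrichment &
    records$fdr < max_fdr
  records[keep, , drop = FALSE]
}

#' Inverse-membership gene weights
#'
#' Each gene receives weight `1 / k`, where `k` is the number of supplied
#' terms containing it; a term's weight is the summed weight of its member
#' DE genes. Weights are computed within the term list under analysis
#' (typically the filtered enriched terms) — the annotation-wide membership
#' count is not available from the inputs, and this within-list convention
#' makes the weights sum to the number of distinct annotated genes.
#'
#' @param term_genes named list: term id -> DE genes in the term.
#' @return named numeric vector of gene weights.
#' @export
gene_weights <- function(term_genes) {
  if (!length(term_genes)) stop_fmt("at least one term is required")
  tab <- table(unlist(lapply(term_genes, unique)))
  setNames(1 / as.numeric(tab), names(tab))
}

# attach the per-term summed weights to a record table
add_term_weights <- function(records) {
  tg <- setNames(records$genes, records$term_id)
  nonempty <- tg[lengths(tg) > 0]
  if (length(nonempty)) {
    w <- gene_weights(nonempty)
    records$weight <- vapply(tg, function(g) sum(w[g]), numeric(1))
  } else {
    records$weight <- 0
  }
  records
}

#' Collapse enriched terms sharing many DE genes
#'
#' Terms sharing at least `shared_threshold` differentially expressed
#' transcripts are considered functionally synonymous and merged. An edge
#' joins two terms when their DE intersections share at least the threshold
#' number of genes; connected components of that graph become the collapsed
#' terms (transitive closure, so the result is invariant under input
#' permutation). Each component is represented by its member with the
#' smallest FDR (ties broken lexicographically by term id).
#'
#' @param records enrichment records with `term_id`, `fdr` and the `genes`
#'   list-column of per-term DE genes (as produced by
#'   [enrich_collection()]).
#' @param shared_threshold minimum shared DE genes (inclusive).
#' @return data.frame of collapsed terms, sorted by combined weight
#'   descending: `representative`, `representative_name` (when names are
#'   present), `n_terms`, `members` and `genes` (list-columns), `count`
#'   (size of the DE-gene union) and `weight` (summed inverse-membership
#'   weights of the union, weights computed over the input records).
#' @export
collapse_terms <- function(records, shared_threshold = 25) {
  cols <- data.frame(representative = character(0), n_terms = integer(0),
                     count = integer(0), weight = numeric(0))
  if (!nrow(records)) {
    cols$members <- list(); cols$genes <- list()
    return(cols)
  }
  ids <- records$term_id
  tg <- setNames(lapply(records$genes, unique), ids)
  m <- length(ids)
  edges <- NULL
  if (m > 1) {
    pairs <- utils::combn(m, 2)
    shared <- vapply(seq_len(ncol(pairs)), function(k) {
      length(intersect(tg[[pairs[1, k]]], tg[[pairs[2, k]]]))
    }, numeric(1))
    keep <- shared >= shared_threshold
    if (any(keep)) edges <- cbind(ids[pairs[1, keep]], ids[pairs[2, keep]])
  }
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(0), to = character(0))
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  w <- if (any(lengths(tg) > 0)) gene_weights(tg[lengths(tg) > 0])
       else numeric(0)
  out <- lapply(split(ids, comp), function(members) {
    members <- sort(members)
    sub <- records[match(members, records$term_id), , drop = FALSE]
    rep_order <- order(sub$fdr, sub$term_id)
    union_genes <- sort(unique(unlist(tg[members])))
    row <- data.frame(
      representative = sub$term_id[rep_order[1]],
      n_terms = length(members),
      count = length(union_genes),
      weight = if (length(union_genes)) sum(w[union_genes]) else 0,
      stringsAsFactors = FALSE)
    if ("term_name" %in% colnames(sub))
      row$representative_name <- sub$term_name[rep_order[1]]
    row$members <- list(members)
    row$genes <- list(union_genes)
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$weight, out$representative), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tissue-expression summary with CNS fraction
#'
#' Summarises tissue-annotation enrichment records as the fraction of
#' annotated transcripts falling in CNS tissues, for a query hit list and
#' for the whole universe. Query-side sizes are the per-term hit counts
#' (`count`, i.e. `b`); universe-side sizes are the term sizes (`B`).
#' Fractions are `sum(CNS sizes) / sum(all sizes)`, reported as rounded
#' percentages.
#'
#' @param query_hits FDR-filtered tissue records for the query list (or
#'   `NULL`).
#' @param all_records FDR-filtered tissue records for the universe (or
#'   `NULL`).
#' @param cns_terms character vector of term ids labelled as CNS.
#' @return list with `hit_sizes`, `universe_sizes` (named vectors),
#'   `cns_pct_hits` and `cns_pct_universe` (rounded percentages, `NA` when
#'   the corresponding records are absent).
#' @examples
#' uni <- data.frame(term_id = c("brain", "rest"), B = c(7858, 21490))
#' tissue_summary(NULL, uni, cns_terms = "brain")$cns_pct_universe  # 27
#' @export
tissue_summary <- function(query_hits, all_records, cns_terms) {
  frac <- function(records, col) {
    if (is.null(records) || !nrow(records)) return(list(sizes = NULL, pct = NA_real_))
    sizes <- setNames(records[[col]], records$term_id)
    list(sizes = sizes,
         pct = round(100 * sum(sizes[names(sizes) %in% cns_terms]) /
                       sum(sizes)))
  }
  h <- frac(query_hits, "count")
  u <- frac(all_records, "B")
  list(hit_sizes = h$sizes, universe_sizes = u$sizes,
       cns_pct_hits = h$pct, cns_pct_universe = u$pct)
}
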