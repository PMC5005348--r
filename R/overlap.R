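#' Representation factor of a gene-list overlap
#'
#' Ratio of the observed intersection size to the size expected for two
#' independent lists drawn from a universe of `N` genes:
#' `rf = x / (n1 * n2 / N)`. Algebraically identical to the enrichment
#' ratio `(b/n)/(B/N)` of [enrich_term()].
#'
#' @param x intersection size.
#' @param n1,n2 list sizes within the universe.
#' @param N universe size (the study uses 19580 detected transcripts).
#' @return list with `rf` and `expected`.
#' @examples
#' representation_factor(40, 100, 200, 19580)$rf  # 39.16
#' @export
representation_factor <- function(x, n1, n2, N) {
  check_overlap_args(x, n1, n2, N)
  expected <- n1 * n2 / N
  list(rf = x / expected, expected = expected)
}

#' Hypergeometric significance of a gene-list overlap
#'
#' Models the intersection of two lists from a fixed universe as
#' hypergeometric (sampling without replacement):
#' `p_over = P(X >= x)`, `p_under = P(X <= x)`. The two tails share the
#' probability mass at `x`, so their sum is at least 1.
#'
#' @inheritParams representation_factor
#' @return named numeric vector `c(p_over =, p_under =)`.
#' @export
overlap_significance <- function(x, n1, n2, N) {
  check_overlap_args(x, n1, n2, N)
  c(p_over = phyper(x - 1, n1, N - n1, n2, lower.tail = FALSE),
    p_under = phyper(x, n1, N - n1, n2))
}

check_overlap_args <- function(x, n1, n2, N) {
  if (any(c(x, n1, n2, N) < 0) || n1 > N || n2 > N)
    stop_fmt("list sizes must satisfy 0 <= n1, n2 <= N")
  if (n1 == 0 || n2 == 0) stop_fmt("both lists must be non-empty")
  if (x > min(n1, n2))
    stop_fmt("intersection %d exceeds the smaller list (%d)", x, min(n1, n2))
  invisible(TRUE)
}

#' Full overlap analysis of two gene lists
#'
#' @param list1,list2 character vectors of gene symbols.
#' @param universe optional character vector; when given, both lists are
#'   intersected with it and `N` is its size.
#' @param universe_size `N` when no explicit universe is supplied.
#' @return object of class `overlap_result`: list with `n1`, `n2`, `N`,
#'   `x`, `expected`, `rf`, `p_over`, `p_under` and `intersection`.
#' @export
gene_set_overlap <- function(list1, list2, universe = NULL,
                             universe_size = NULL) {
  l1 <- canon_genes(list1); l2 <- canon_genes(list2)
  if (!is.null(universe)) {
    u <- canon_genes(universe)
    l1 <- intersect(l1, u); l2 <- intersect(l2, u)
    N <- length(u)
  } else {
    N <- universe_size %||%
      stop_fmt("either a universe or universe_size is required")
  }
  inter <- sort(intersect(l1, l2))
  rf <- representation_factor(length(inter), length(l1), length(l2), N)
  p <- overlap_significance(length(inter), length(l1), length(l2), N)
  structure(list(n1 = length(l1), n2 = length(l2), N = N,
                 x = length(inter), expected = rf$expected, rf = rf$rf,
                 p_over = unname(p["p_over"]),
                 p_under = unname(p["p_under"]),
                 intersection = inter),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of (%d, %d) in N=%d; expected %.3g, rf %.3g, p_over %.3g\n",
    x$x, x$n1, x$n2, x$N, x$expected, x$rf, x$p_over))
  invisible(x)
}

#' Matched-expression filter for cross-dataset comparison
#'
#' Keeps genes whose expression level is on the same side of the cutoff in
#' both datasets — both strictly above or both strictly below; genes equal
#' to the cutoff in either dataset are excluded. Symmetric in its two
#' arguments.
#'
#' @param exprA,exprB named numeric vectors of expression levels (in
#'   whatever matched units the two datasets share).
#' @param cutoff expression cutoff (the study uses 100).
#' @return character vector of genes passing the filter.
#' @export
matched_expression_filter <- function(exprA, exprB, cutoff = 100) {
  if (is.null(names(exprA)) || is.null(names(exprB)))
    stop_fmt("expression vectors must be named by gene")
  names(exprA) <- toupper(names(exprA))
  names(exprB) <- toupper(names(exprB))
  shared <- intersect(names(exprA), names(exprB))
  a <- exprA[shared]; b <- exprB[shared]
  sort(shared[(a > cutoff & b > cutoff) | (a < cutoff & b < cutoff)])
}

#' Genes changed in the same direction in two datasets
#'
#' Intersects two fold-change maps, keeping genes beyond the cutoff in the
#' stated direction in both: for `direction = "down"` a linear fold change
#' of at most `1/fold_cutoff`, for `"up"` at least `fold_cutoff` (both
#' inclusive).
#'
#' @param fcA,fcB named numeric vectors of linear-scale fold changes.
#' @param fold_cutoff linear threshold (default 1.5).
#' @param direction `"down"` or `"up"`.
#' @return sorted character vector of concordant genes.
#' @export
intersect_direction <- function(fcA, fcB, fold_cutoff = 1.5,
                                direction = c("down", "up")) {
  direction <- match.arg(direction)
  if (is.null(names(fcA)) || is.null(names(fcB)))
    stop_fmt("fold-change vectors must be named by gene")
  if (fold_cutoff <= 0) stop_fmt("fold_cutoff must be positive")
  names(fcA) <- toupper(names(fcA))
  names(fcB) <- toupper(names(fcB))
  shared <- intersect(names(fcA), names(fcB))
  a <- fcA[shared]; b <- fcB[shared]
  keep <- if (direction == "down") {
    a <= 1 / fold_cutoff & b <= 1 / fold_cutoff
  } else {
    a >= fold_cutoff & b >= fold_cutoff
  }
  sort(shared[keep])
}

#' Percentage of input genes in a term
#'
#' The "Percentage" column of an annotation summary: a term's gene count as
#' a percentage of the list total (the number of input genes belonging to
#' any ontology), rounded to one decimal.
#'
#' @param count genes of the input list in the term.
#' @param list_total input genes annotated to at least one term.
#' @return percentage, one decimal.
#' @examples
#' summarize_go_percentage(10, 20)  # 50
#' @export
summarize_go_percentage <- function(count, list_total) {
  if (list_total <= 0) stop_fmt("list_total must be positive")
  if (count < 0 || count > list_total)
    stop_fmt("count must lie in [0, list_total]")
  pct1(count / list_total)
}
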