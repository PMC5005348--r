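#' Construct a gene-set collection
#'
#' A named collection of gene sets (e.g. GO biological-process terms or
#' tissue-expression annotations). Gene symbols are upper-cased and
#' de-duplicated; every set must be non-empty and term ids unique. When a
#' universe is attached, downstream enrichment evaluates membership against
#' it.
#'
#' @param sets named list of character vectors (term id -> member genes).
#' @param name collection label.
#' @param term_names optional named character vector of human-readable term
#'   descriptions; defaults to the term ids.
#' @param universe optional character vector of gene symbols.
#' @return object of class `gene_sets`.
#' @export
gene_set_collection <- function(sets, name = "genesets", term_names = NULL,
                                universe = NULL) {
  if (!length(sets)) stop_fmt("a gene-set collection needs at least one set")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_fmt("term ids must be present and unique")
  sets <- lapply(sets, canon_genes)
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) stop_fmt("term %s has no member genes", empty[1])
  if (is.null(term_names)) {
    term_names <- setNames(names(sets), names(sets))
  } else {
    term_names <- setNames(as.character(term_names[names(sets)]), names(sets))
    term_names[is.na(term_names)] <- names(sets)[is.na(term_names)]
  }
  if (!is.null(universe)) universe <- canon_genes(universe)
  structure(list(name = name, sets = sets, term_names = term_names,
                 universe = universe),
            class = "gene_sets")
}

#' @export
length.gene_sets <- function(x) length(x$sets)

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets '%s': %d terms, sizes %d-%d%s\n", x$name,
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets)),
              if (is.null(x$universe)) ""
              else sprintf(", universe of %d genes", length(x$universe))))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One term per line: `term_id TAB description TAB gene TAB gene ...`.
#' Gene symbols are upper-cased; duplicates within a line are dropped.
#'
#' @param path path to the GMT file.
#' @param name collection label (defaults to the file name).
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_fmt("GMT file %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop_fmt("GMT file %s: line %d has %d fields, expected at least 3",
             path, short[1], lengths(fields)[short[1]])
  ids <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) canon_genes(f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, name = name %||% basename(path),
                      term_names = setNames(descs, ids))
}

#' Write gene sets in GMT format
#'
#' Inverse of [read_gmt()] up to gene order within a line.
#'
#' @param x a `gene_sets` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_sets"))
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$term_names[[id]], x$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain gene list (one symbol per line)
#' @param path text file; blank lines and `#` comments ignored.
#' @return upper-cased character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_fmt("gene list not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  canon_genes(x[nzchar(x) & !startsWith(x, "#")])
}
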