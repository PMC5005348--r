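#' Construct a validated count matrix
#'
#' Container for raw RNA-seq read counts with genes in rows and samples in
#' columns, optionally carrying the sample-to-condition assignment of a
#' two-condition design. Gene identifiers are canonicalised to upper case so
#' that symbol-style differences (e.g. `SynDIG1` vs `SYNDIG1`) never split a
#' gene in two.
#'
#' @param counts integer matrix (genes x samples) with unique rownames (gene
#'   symbols) and colnames (sample ids); all entries must be non-negative
#'   integers.
#' @param conditions optional named character vector mapping every sample id
#'   to one of exactly two condition labels, each with at least one replicate.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `conditions` (named character or `NULL`).
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(c("GFAP", "S100B", "KLF3"), paste0("s", 1:4)))
#' cm <- count_matrix(m, c(s1 = "pre", s2 = "pre", s3 = "sen", s4 = "sen"))
#' dim(cm)
#' @export
count_matrix <- function(counts, conditions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("counts must have gene rownames and sample colnames")
  rownames(counts) <- toupper(rownames(counts))
  if (anyDuplicated(rownames(counts)))
    stop_fmt("duplicate gene identifier: %s",
             rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stop_fmt("duplicate sample identifier: %s",
             colnames(counts)[duplicated(colnames(counts))][1])
  if (!is.numeric(counts) || anyNA(counts))
    stop_fmt("counts must be numeric with no missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_fmt("count at gene %s, sample %s is %s (must be a non-negative integer)",
             rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
             format(counts[bad[1, , drop = FALSE]]))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(conditions)) {
    conditions <- vapply(conditions, as.character, character(1))
    missing <- setdiff(colnames(counts), names(conditions))
    if (length(missing))
      stop_fmt("sample %s has no condition assignment", missing[1])
    conditions <- conditions[colnames(counts)]
    lev <- unique(conditions)
    if (length(lev) != 2L)
      stop_fmt("exactly two conditions are required, got %d (%s)",
               length(lev), paste(lev, collapse = ", "))
  }
  structure(list(counts = counts, conditions = conditions),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts),
              ncol(x$counts)))
  if (!is.null(x$conditions)) {
    tab <- table(x$conditions)
    cat("conditions:", paste(sprintf("%s (n=%d)", names(tab), tab),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a count matrix from a TSV file
#'
#' Expects tab-separated text with the gene identifier in the first column
#' and a header row of sample ids. Lines starting with `#` are ignored.
#' Row order is preserved.
#'
#' @param path path to the TSV file.
#' @param sample_sheet optional path to a two-column TSV (`sample`,
#'   `condition`) assigning each sample to a condition.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, sample_sheet = NULL) {
  if (!file.exists(path)) stop_fmt("counts file not found: %s", path)
  nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop_fmt("ragged counts file %s: line %d has %d fields, expected %d",
             path, bad, nf[bad], nf[1])
  }
  raw <- read.delim(path, check.names = FALSE, comment.char = "#",
                    colClasses = "character", quote = "")
  if (ncol(raw) < 2L) stop_fmt("counts file %s has no sample columns", path)
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  mat <- matrix(NA_real_, nrow(raw), length(samples),
                dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop_fmt("invalid count '%s' at gene %s, sample %s",
               raw[[j + 1]][bad[1]], genes[bad[1]], samples[j])
    mat[, j] <- v
  }
  conditions <- if (!is.null(sample_sheet)) read_sample_sheet(sample_sheet)
  count_matrix(mat, conditions)
}

#' Read a sample sheet
#'
#' @param path two-column TSV with header `sample`, `condition`.
#' @return named character vector: condition label per sample.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_fmt("sample sheet not found: %s", path)
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   colClasses = "character", quote = "")
  need <- c("sample", "condition")
  if (!all(need %in% colnames(df)))
    stop_fmt("sample sheet %s must have columns: %s", path,
             paste(need, collapse = ", "))
  setNames(df$condition, df$sample)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x, f))` reproduces
#' the object.
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @param gene_column header name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, gene_column = "gene") {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet
#' @param conditions named character vector (sample -> condition).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(conditions, path) {
  write.table(data.frame(sample = names(conditions),
                         condition = unname(conditions)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
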