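# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# percentage rounded to one decimal, as printed in result summaries
pct1 <- function(x) round(100 * x, 1)

# evaluate `code` under a fixed RNG state without disturbing the caller's
# stream; `seed = NULL` leaves the current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# provenance lines written atop every results table
provenance_header <- function(seed = NULL, thresholds = NULL) {
  h <- paste0("senastro ", as.character(packageVersion("senastro")))
  if (!is.null(seed)) h <- c(h, paste0("seed: ", seed))
  if (!is.null(thresholds) && length(thresholds)) {
    h <- c(h, paste0(names(thresholds), ": ",
                     vapply(thresholds, format, character(1))))
  }
  h
}

# TSV writer: commented header, fixed column order as supplied, doubles at
# 6 significant digits so repeated runs diff cleanly
write_tsv_commented <- function(df, path, header = character()) {
  is_dbl <- vapply(df, function(x) is.numeric(x) && !is.integer(x), logical(1))
  df[is_dbl] <- lapply(df[is_dbl], signif, digits = 6)
  is_list <- vapply(df, is.list, logical(1))
  df[is_list] <- lapply(df[is_list], function(col)
    vapply(col, function(x) paste(x, collapse = ","), character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

canon_genes <- function(x) unique(toupper(as.character(x)))
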