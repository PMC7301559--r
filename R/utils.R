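# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.msg <- function(...) message("[gwascomp] ", ...)

.stop_format <- function(...) stop(sprintf(...), call. = FALSE)

.check_file <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    .stop_format("path must be a single string")
  if (!file.exists(path))
    .stop_format("file not found: %s", path)
  invisible(path)
}

.read_tsv <- function(path) {
  .check_file(path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
  } else con <- path
  read.delim(con, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, quote = "", comment.char = "")
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    .stop_format("%s: missing mandatory column(s): %s", what,
                 paste(miss, collapse = ", "))
  invisible(df)
}

.valid_nt <- c("A", "C", "G", "T")

# standardize matrix rows to mean 0, sd 1 (sample sd, n-1 denominator)
.standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  if (any(s == 0))
    .stop_format("zero-variance gene(s): %s",
                 paste(head(rownames(x)[s == 0], 5), collapse = ", "))
  (x - mu) / s
}
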