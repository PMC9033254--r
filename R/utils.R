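## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a classed condition
#' @noRd
ag_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "alkagerm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ag_msg <- function(...) {
  if (isTRUE(getOption("alkagerm.quiet", TRUE))) return(invisible(NULL))
  message(sprintf(...))
}

## Sample standard deviation (n - 1 denominator) tolerating missing values.
sd_na <- function(x) stats::sd(x, na.rm = TRUE)

## Deterministic integer sub-seed derived from a master seed; kept < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + 12289L * as.double(offset)) %% 2147483647)
}

## Write a result table as TSV with a commented header block.
write_result_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
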