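#' Read a germination phenotype table
#'
#' Expects a long-format TSV with columns `accession`, `condition`
#' (`control`/`stress`), `replicate`, `day` (1..7), `new_germinated`,
#' `total_seeds` and optional `root_length_cm`, `shoot_length_cm` (the
#' replicate-level mean lengths; they may be present on any subset of a
#' replicate's rows). Days absent from the file are zero-filled, so each
#' accession x condition x replicate yields a complete day-1..7 count vector.
#'
#' @param path TSV file path.
#' @return A `germination_counts` data.frame: one row per
#'   accession x condition x replicate with columns `accession`, `condition`,
#'   `replicate`, `total_seeds`, `d1`..`d7`, `root_length_cm`,
#'   `shoot_length_cm`.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path))
    ag_stop(sprintf("phenotype file not found: %s", path), "alkagerm_io_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("accession", "condition", "replicate", "day", "new_germinated",
            "total_seeds")
  if (!all(need %in% names(df)))
    ag_stop(paste("phenotype table must have columns:",
                  paste(need, collapse = ", ")), "alkagerm_format_error")
  if (anyNA(df$new_germinated) || anyNA(df$total_seeds) || anyNA(df$day))
    ag_stop("day, new_germinated and total_seeds must be complete",
            "alkagerm_format_error")
  if (!all(df$condition %in% c("control", "stress")))
    ag_stop("condition must be 'control' or 'stress'", "alkagerm_format_error")
  if (any(df$day < 1 | df$day > 7))
    ag_stop("day must be in 1..7", "alkagerm_format_error")
  if (any(df$new_germinated < 0))
    ag_stop("counts must be non-negative", "alkagerm_format_error")
  key <- paste(df$accession, df$condition, df$replicate, df$day, sep = "|")
  if (anyDuplicated(key))
    ag_stop(sprintf("duplicate phenotype row(s) for key(s): %s",
                    paste(unique(key[duplicated(key)]), collapse = "; ")),
            "alkagerm_format_error")
  germination_counts(df)
}

## Assemble the wide per-replicate representation from long rows and validate.
germination_counts <- function(df) {
  grp <- paste(df$accession, df$condition, df$replicate, sep = "|")
  ug <- !duplicated(grp)
  out <- data.frame(
    accession = df$accession[ug], condition = df$condition[ug],
    replicate = df$replicate[ug], total_seeds = NA_integer_,
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, nrow(out), 7L,
                   dimnames = list(NULL, paste0("d", 1:7)))
  idx <- match(grp, grp[ug])
  for (r in seq_len(nrow(df)))
    counts[idx[r], df$day[r]] <- as.integer(df$new_germinated[r])
  n0 <- tapply(as.integer(df$total_seeds), idx, function(x) unique(x))
  if (any(lengths(n0) != 1))
    ag_stop("total_seeds must be constant within a replicate",
            "alkagerm_format_error")
  out$total_seeds <- as.integer(unlist(n0)[as.character(seq_len(nrow(out)))])
  over <- rowSums(counts) > out$total_seeds
  if (any(over))
    ag_stop(sprintf(
      "germinated counts exceed total seeds for: %s",
      paste(paste(out$accession[over], out$condition[over],
                  out$replicate[over], sep = "|"), collapse = "; ")),
      "alkagerm_validation_error")
  pick_len <- function(col) {
    if (!col %in% names(df)) return(rep(NA_real_, nrow(out)))
    v <- tapply(df[[col]], idx, function(x) {
      x <- x[!is.na(x)]
      if (length(x)) x[1] else NA_real_
    })
    as.numeric(v[as.character(seq_len(nrow(out)))])
  }
  out <- cbind(out, as.data.frame(counts))
  out$root_length_cm <- pick_len("root_length_cm")
  out$shoot_length_cm <- pick_len("shoot_length_cm")
  class(out) <- c("germination_counts", "data.frame")
  out
}

#' Write a germination-counts table in the long TSV layout
#'
#' Inverse of [read_phenotype_table()] for supported fields (zero-count days
#' are written explicitly so the round trip is lossless).
#'
#' @param gc a `germination_counts` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(gc, path) {
  long <- do.call(rbind, lapply(seq_len(nrow(gc)), function(i) {
    data.frame(
      accession = gc$accession[i], condition = gc$condition[i],
      replicate = gc$replicate[i], day = 1:7,
      new_germinated = as.integer(gc[i, paste0("d", 1:7)]),
      total_seeds = gc$total_seeds[i],
      root_length_cm = c(rep(NA, 6), gc$root_length_cm[i]),
      shoot_length_cm = c(rep(NA, 6), gc$shoot_length_cm[i]),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read accession metadata
#'
#' @param path TSV with columns `accession` and `subpopulation` (one of
#'   `Xian`, `Geng`, `Aus`, `Basmati`, `admix`).
#' @return data.frame with unique accession ids.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("accession", "subpopulation") %in% names(df)))
    ag_stop("metadata needs columns accession, subpopulation",
            "alkagerm_format_error")
  if (anyDuplicated(df$accession))
    ag_stop("accession ids must be unique", "alkagerm_format_error")
  ok <- c("Xian", "Geng", "Aus", "Basmati", "admix")
  if (!all(df$subpopulation %in% ok))
    ag_stop(paste("subpopulation must be one of:", paste(ok, collapse = ", ")),
            "alkagerm_format_error")
  df
}

#' Read a gene functional-annotation table
#'
#' @param path TSV with columns `gene_id`, `functional_annotation` and logical
#'   `stress_related`.
#' @return data.frame with unique gene ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("gene_id", "stress_related") %in% names(df)))
    ag_stop("annotation table needs columns gene_id, stress_related",
            "alkagerm_format_error")
  if (anyDuplicated(df$gene_id))
    ag_stop("gene ids must be unique", "alkagerm_format_error")
  df$stress_related <- as.logical(df$stress_related)
  df
}
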