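# Readers/writers for the small tabular formats the pipeline touches:
# embedding coordinates, censored abundance tokens, and survival records.
# All are UTF-8 TSV with a header; '#' comment lines allowed.

.read_tsv <- function(path, required, classes = NA) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = classes,
                   fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort("missing mandatory column: ", paste(missing, collapse = ", "))
  }
  df
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-image embedding coordinates
#'
#' One row per image: `image_id`, `gene_id`, 2D coordinates `x`, `y`
#' (e.g. from a UMAP of image features), and a `class_label`. A gene may
#' own several rows (several images per protein).
#'
#' @param path Path to a TSV file.
#' @return A tibble with one `embedding_record` per row.
#' @export
read_embedding_table <- function(path) {
  df <- .read_tsv(path, c("image_id", "gene_id", "x", "y", "class_label"))
  df$x <- as.numeric(df$x); df$y <- as.numeric(df$y)
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    abort("embedding coordinates must be finite")
  }
  tibble::as_tibble(df[c("image_id", "gene_id", "x", "y", "class_label")])
}

#' @rdname read_embedding_table
#' @param records Embedding tibble to write.
#' @export
write_embedding_table <- function(records, path) {
  .write_tsv(as.data.frame(records), path)
}

#' Read a censored abundance table
#'
#' One row per protein: `gene_id` and a `copies_per_cell` token that is
#' either a numeric literal or one of the censored tokens `"> 2e7"` /
#' `"< 5e2"` (as in published copies-per-cell proteome tables).
#'
#' @param path Path to a TSV file.
#' @return A tibble with character column `copies_per_cell`.
#' @seealso [cap_censored()] to convert tokens to numbers.
#' @export
read_abundance_table <- function(path) {
  df <- .read_tsv(path, c("gene_id", "copies_per_cell"),
                  classes = "character")
  tibble::as_tibble(df[c("gene_id", "copies_per_cell")])
}

#' @rdname read_abundance_table
#' @param abundance Abundance tibble to write.
#' @export
write_abundance_table <- function(abundance, path) {
  .write_tsv(as.data.frame(abundance), path)
}

#' Read a survival table
#'
#' One row per patient: positive follow-up `time`, `event` indicator
#' (0 censored, 1 death), and non-negative `expression` (FPKM).
#'
#' @param path Path to a TSV file.
#' @return A tibble of survival records.
#' @export
read_survival_table <- function(path) {
  df <- .read_tsv(path, c("time", "event", "expression"))
  df$time <- as.numeric(df$time)
  df$event <- as.integer(df$event)
  df$expression <- as.numeric(df$expression)
  if (any(!is.finite(df$time)) || any(df$time <= 0)) {
    abort("time must be positive")
  }
  if (!all(df$event %in% c(0L, 1L))) abort("event must be 0 or 1")
  if (any(!is.finite(df$expression)) || any(df$expression < 0)) {
    abort("expression must be non-negative")
  }
  tibble::as_tibble(df[c("time", "event", "expression")])
}

#' @rdname read_survival_table
#' @param records Survival tibble to write.
#' @export
write_survival_table <- function(records, path) {
  .write_tsv(as.data.frame(records), path)
}
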