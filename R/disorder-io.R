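#' Construct a per-residue disorder profile
#'
#' A disorder profile holds one disorder probability per residue, in order
#' from the N-terminus, each in \[0, 1\] (as produced by per-residue
#' disorder predictors such as IUPred2A).
#'
#' @param gene_id Protein identifier.
#' @param scores Numeric vector of per-residue scores in \[0, 1\],
#'   length >= 1.
#' @return An object of class `disorder_profile`.
#' @export
disorder_profile <- function(gene_id, scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 1L) abort("no residues: a profile needs length >= 1")
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    abort("disorder scores must lie in [0, 1]")
  }
  structure(list(gene_id = as.character(gene_id), scores = scores),
            class = "disorder_profile")
}

#' @export
print.disorder_profile <- function(x, ...) {
  cat(sprintf("<disorder_profile> %s: %d residues, mean score %.3f\n",
              x$gene_id, length(x$scores), mean(x$scores)))
  invisible(x)
}

#' @export
length.disorder_profile <- function(x) length(x$scores)

#' Read an IUPred2A long-format disorder score file
#'
#' Parses the long output format of IUPred2A: `#` comment lines followed by
#' tab-separated data lines `position <TAB> residue <TAB> score`. Positions
#' must be contiguous from 1 and scores must lie in \[0, 1\].
#'
#' @param path Path to the score file.
#' @param gene_id Protein identifier; defaults to the file name without
#'   extension.
#' @return A [disorder_profile()].
#' @export
read_disorder_scores <- function(path, gene_id = NULL) {
  if (is.null(gene_id)) {
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("no residues in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    abort("malformed data line (need position, residue, score) in ", path)
  }
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 1L)))
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(pos) || anyNA(score)) abort("non-numeric position or score in ", path)
  ord <- order(pos)
  pos <- pos[ord]; score <- score[ord]
  if (!identical(pos, seq_along(pos))) {
    abort("positions must be contiguous starting at 1 in ", path)
  }
  if (any(score < 0 | score > 1)) {
    abort("score outside [0, 1] at position ",
          pos[which(score < 0 | score > 1)[1]], " in ", path)
  }
  disorder_profile(gene_id, score)
}

#' Write a disorder profile in IUPred2A long format
#'
#' @param profile A [disorder_profile()].
#' @param path Output path.
#' @param residues Optional residue letters (recycled); defaults to `"X"`.
#' @return `path`, invisibly.
#' @export
write_disorder_scores <- function(profile, path, residues = "X") {
  n <- length(profile$scores)
  res <- rep_len(residues, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# Per-residue disorder scores for %s", profile$gene_id),
               "# POS\tRES\tIUPRED2"), con)
  writeLines(sprintf("%d\t%s\t%.4f", seq_len(n), res, profile$scores), con)
  invisible(path)
}
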