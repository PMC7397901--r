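#' Convert censored copies-per-cell tokens to numbers
#'
#' Right-censored proteins annotated `"> 2e7"` copies per cell are
#' estimated at 5e7 copies, left-censored `"< 5e2"` proteins at 100
#' copies; plain numeric literals pass through unchanged.
#'
#' @param tokens Character vector of abundance tokens.
#' @return Numeric vector of capped copy numbers.
#' @export
cap_censored <- function(tokens) {
  tokens <- trimws(as.character(tokens))
  out <- numeric(length(tokens))
  upper <- grepl("^>\\s*2e\\+?0*7$", tokens, ignore.case = TRUE)
  lower <- grepl("^<\\s*5e\\+?0*2$", tokens, ignore.case = TRUE)
  out[upper] <- 5e7
  out[lower] <- 100
  rest <- !(upper | lower)
  val <- suppressWarnings(as.numeric(tokens[rest]))
  if (anyNA(val)) {
    abort("unrecognized abundance token: ",
          paste(unique(tokens[rest][is.na(val)]), collapse = ", "))
  }
  out[rest] <- val
  out
}

#' Two-group Mann-Whitney (unpaired Wilcoxon) comparison
#'
#' The p-value is exact (full permutation distribution) when
#' `n1 + n2 <= 12` and there are no ties; otherwise the normal
#' approximation with tie correction is used, with continuity correction
#' by default.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param alternative `"two_sided"`, `"greater"`, or `"less"`.
#' @param correct Apply continuity correction in the normal approximation.
#' @param exact Force the exact (`TRUE`) or approximate (`FALSE`) branch;
#'   `NULL` selects automatically as above.
#' @return A `group_comparison` list: `n1`, `n2`, `median1`, `median2`,
#'   `statistic` (Mann-Whitney U of the first group), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two_sided", "greater", "less"),
                         correct = TRUE, exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) abort("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(wilcox.test(
    x, y,
    alternative = switch(alternative, two_sided = "two.sided",
                         greater = "greater", less = "less"),
    exact = exact, correct = correct))
  structure(
    list(n1 = length(x), n2 = length(y),
         median1 = median(x), median2 = median(y),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         method = if (exact && !ties) "exact" else "normal_approx"),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<group_comparison> n = %d vs %d, medians %.4g vs %.4g\n",
    "  U = %.1f, P = %.4g (%s)\n"),
    x$n1, x$n2, x$median1, x$median2, x$statistic, x$p_value, x$method))
  invisible(x)
}

#' Rim vs non-rim nucleolar abundance comparison
#'
#' Joins an abundance table onto a protein annotation table and compares
#' rim against non-rim nucleolar proteins with a two-sided Mann-Whitney
#' test. For the `copies` modality the censored tokens are capped with
#' [cap_censored()] first; for `tpm` the values are taken as numeric.
#' Proteins missing from the abundance table are dropped, not imputed.
#'
#' @param abundance Tibble with `gene_id` and either `copies_per_cell`
#'   (tokens) or `tpm` (numeric).
#' @param annotations A `protein_annotation` tibble; rim proteins are
#'   `rim == TRUE`, the comparison group is the remaining nucleolar
#'   proteins.
#' @param modality `"copies"` or `"tpm"`.
#' @return A `group_comparison` (rim is group 1).
#' @export
rim_abundance_comparison <- function(abundance, annotations,
                                     modality = c("copies", "tpm")) {
  modality <- match.arg(modality)
  col <- if (modality == "copies") "copies_per_cell" else "tpm"
  if (!col %in% names(abundance)) abort("abundance table lacks column ", col)
  values <- if (modality == "copies") cap_censored(abundance[[col]]) else
    as.numeric(abundance[[col]])
  keep <- !is.na(values)
  idx <- match(annotations$gene_id, abundance$gene_id[keep])
  nucleolar <- vapply(annotations$locations, function(l) {
    any(c("nucleoli", "nucleoli_fibrillar_center", "fibrillar_center") %in% l)
  }, logical(1))
  rim_vals <- values[keep][idx[annotations$rim & nucleolar]]
  non_vals <- values[keep][idx[!annotations$rim & nucleolar]]
  rim_vals <- rim_vals[!is.na(rim_vals)]
  non_vals <- non_vals[!is.na(non_vals)]
  if (length(rim_vals) == 0L) abort("no rim proteins left after joining")
  if (length(non_vals) == 0L) abort("no non-rim proteins left after joining")
  mann_whitney(rim_vals, non_vals, "two_sided")
}
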