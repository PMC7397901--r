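#' Sample one representative image per gene
#'
#' Each gene in the embedding is represented by one of its images, chosen
#' uniformly at random (deterministically under `seed`).
#'
#' @param records Embedding tibble (`image_id`, `gene_id`, `x`, `y`,
#'   `class_label`).
#' @param seed Integer seed.
#' @return Tibble with exactly one row per gene, ordered by `gene_id`.
#' @export
sample_representatives <- function(records, seed = 1L) {
  if (nrow(records) == 0L) abort("empty embedding table")
  with_seed(seed, {
    split_idx <- split(seq_len(nrow(records)), records$gene_id)
    pick <- vapply(split_idx, function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }, integer(1))
    records[pick, , drop = FALSE]
  })
}

#' Count focal-class representatives whose nearest neighbor shares the class
#'
#' For each representative of the focal class, the single nearest neighbor
#' among all other representatives is found (Euclidean distance in the
#' embedding plane, self excluded, ties broken by lowest `gene_id`); the
#' count of focal representatives whose neighbor is also focal-class is
#' returned.
#'
#' @param representatives Tibble with one row per gene (`gene_id`, `x`,
#'   `y`, `class_label`).
#' @param focal_class Class label of interest.
#' @return Integer count in \[0, n_focal\].
#' @export
same_class_nn_count <- function(representatives, focal_class) {
  n <- nrow(representatives)
  if (n < 2L) abort("need at least 2 representatives")
  # deterministic tie-break: pre-sort by gene_id so the first minimum wins
  ord <- order(representatives$gene_id)
  reps <- representatives[ord, , drop = FALSE]
  xy <- cbind(reps$x, reps$y)
  focal_idx <- which(reps$class_label == focal_class)
  count <- 0L
  for (i in focal_idx) {
    d2 <- (xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2
    d2[i] <- Inf
    nn <- which.min(d2)   # first (lowest gene_id) among tied minima
    if (reps$class_label[nn] == focal_class) count <- count + 1L
  }
  count
}

#' Randomized nearest-neighbor class-separation test
#'
#' Tests whether an embedding class forms a distinct cluster: one image is
#' sampled to represent each gene, the number of focal-class genes whose
#' nearest representative is also focal-class is counted, the
#' randomization is repeated `n_reps` times, and the rounded average count
#' is compared by a two-sided exact binomial test against the count
#' expected from the population size alone. With self-exclusion the null
#' probability that a neighbor is focal-class is
#' `p0 = (n_focal - 1) / (n_total - 1)` (the default); `null =
#' "population"` selects `n_focal / n_total` instead.
#'
#' @inheritParams sample_representatives
#' @inheritParams same_class_nn_count
#' @param n_reps Number of representative randomizations to average.
#' @param null Null-probability construction (see above).
#' @return Object of class `separation_result`: a list with `n_focal`,
#'   `n_total`, `mean_same_class_neighbors`, `k_rounded`, `p0`, `p_value`,
#'   `n_reps`, `seed`.
#' @export
separation_test <- function(records, focal_class, n_reps = 10L, seed = 1L,
                            null = c("exclude_self", "population")) {
  null <- match.arg(null)
  genes <- unique(records$gene_id[records$class_label == focal_class])
  n_focal <- length(genes)
  if (n_focal < 2L) abort("focal class needs at least 2 genes")
  counts <- vapply(seq_len(n_reps), function(r) {
    reps <- sample_representatives(records, seed = seed + r - 1L)
    same_class_nn_count(reps, focal_class)
  }, integer(1))
  n_total <- length(unique(records$gene_id))
  mean_count <- mean(counts)
  k <- as.integer(round(mean_count))
  p0 <- if (null == "exclude_self") (n_focal - 1) / (n_total - 1) else
    n_focal / n_total
  structure(
    list(n_focal = n_focal, n_total = n_total,
         mean_same_class_neighbors = mean_count, k_rounded = k, p0 = p0,
         p_value = binom_test(k, n_focal, p0, "two_sided"),
         n_reps = n_reps, seed = seed),
    class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<separation_result> n_focal = %d of %d genes\n",
    "  mean same-class nearest neighbors = %.2f (rounded %d), p0 = %.4f\n",
    "  two-sided binomial P = %.4g (%d randomizations)\n"),
    x$n_focal, x$n_total, x$mean_same_class_neighbors, x$k_rounded,
    x$p0, x$p_value, x$n_reps))
  invisible(x)
}
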