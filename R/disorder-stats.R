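#' Binarize a disorder profile
#'
#' A residue is disordered iff its score is strictly above the threshold
#' (the conventional "above 0.5" rule; a score exactly at the threshold is
#' ordered).
#'
#' @param profile A [disorder_profile()].
#' @param threshold Disorder threshold in \[0, 1\].
#' @return Logical vector, one element per residue.
#' @export
binarize_disorder <- function(profile, threshold = 0.5) {
  stopifnot(inherits(profile, "disorder_profile"))
  if (threshold < 0 || threshold > 1) abort("threshold must be in [0, 1]")
  profile$scores > threshold
}

#' Disorder fraction of a protein
#'
#' Number of disordered residues (score strictly above the threshold)
#' divided by the protein length.
#'
#' @inheritParams binarize_disorder
#' @return A value in \[0, 1\].
#' @export
disorder_fraction <- function(profile, threshold = 0.5) {
  mean(binarize_disorder(profile, threshold))
}

#' Consecutive disordered-domain statistics
#'
#' A qualifying long domain is a maximal run of consecutive disordered
#' residues of length strictly greater than `min_len` (>= 31 residues for
#' the default 30, matching the "more than 30 disordered residues"
#' definition of a functional disordered domain).
#'
#' @inheritParams binarize_disorder
#' @param min_len Minimum length bound (strict) in residues.
#' @return List with `longest_run`, `n_long_domains`, `has_long_domain`.
#' @export
long_domain_stats <- function(profile, min_len = 30L, threshold = 0.5) {
  if (min_len < 1L) abort("min_len must be >= 1")
  d <- binarize_disorder(profile, threshold)
  r <- rle(d)
  runs <- r$lengths[r$values]
  longest <- if (length(runs)) max(runs) else 0L
  n_long <- sum(runs > min_len)
  list(longest_run = as.integer(longest), n_long_domains = as.integer(n_long),
       has_long_domain = n_long >= 1L)
}

#' Per-protein disorder summary table
#'
#' @param profiles List of [disorder_profile()] objects.
#' @inheritParams long_domain_stats
#' @return Tibble with one row per protein: `gene_id`, `length`,
#'   `fraction`, `longest_run`, `n_long_domains`, `has_long_domain`.
#' @export
summarize_disorder <- function(profiles, threshold = 0.5, min_len = 30L) {
  stats <- vapply(profiles, function(p) {
    d <- p$scores > threshold
    r <- rle(d)
    runs <- r$lengths[r$values]
    c(length(d), mean(d),
      if (length(runs)) max(runs) else 0L,
      sum(runs > min_len))
  }, numeric(4))
  tibble::tibble(
    gene_id = vapply(profiles, `[[`, character(1), "gene_id"),
    length = as.integer(stats[1, ]),
    fraction = stats[2, ],
    longest_run = as.integer(stats[3, ]),
    n_long_domains = as.integer(stats[4, ]),
    has_long_domain = stats[4, ] >= 1)
}

#' Dunn's post hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with the tie correction
#' `sum(t^3 - t) / (12 (N - 1))` subtracted from `N (N + 1) / 12`
#' (Dunn 1964). Two-sided p-values are Bonferroni-multiplied by the
#' number of pairwise comparisons and capped at 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group label per observation.
#' @return Tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_unadjusted`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups) {
  groups <- as.character(groups)
  gl <- unique(groups)
  if (length(gl) < 2L) abort("need at least 2 groups")
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  pairs <- utils::combn(gl, 2)
  k <- ncol(pairs)
  z <- numeric(k); p <- numeric(k)
  for (j in seq_len(k)) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt(s2 * (1 / n_g[[g1]] + 1 / n_g[[g2]]))
    z[j] <- (mean_rank[[g1]] - mean_rank[[g2]]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
  }
  tibble::tibble(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
                 p_unadjusted = p, p_adjusted = pmin(1, p * k))
}

#' Multi-group disorder comparison
#'
#' Per-group medians of the disorder fraction and the fraction of proteins
#' with at least one long disordered domain, an omnibus Kruskal-Wallis
#' test on the disorder fractions, and Dunn's pairwise post hoc test with
#' Bonferroni correction. The group partition is taken exactly as passed
#' (e.g. with mitotic-chromosome proteins removed from the nucleolar group
#' to avoid redundancy).
#'
#' @param profiles_by_group Named list; each element a non-empty list of
#'   [disorder_profile()] objects for one group.
#' @inheritParams long_domain_stats
#' @return List with `groups` (tibble: `group`, `n`, `median_fraction`,
#'   `frac_long_domain`), `kruskal_p`, and `pairwise` (Dunn tibble).
#' @export
summarize_disorder_groups <- function(profiles_by_group, threshold = 0.5,
                                      min_len = 30L) {
  if (length(profiles_by_group) < 2L) abort("need at least 2 groups")
  if (any(lengths(profiles_by_group) == 0L)) {
    abort("empty group: ",
          paste(names(profiles_by_group)[lengths(profiles_by_group) == 0L],
                collapse = ", "))
  }
  summaries <- lapply(profiles_by_group, summarize_disorder,
                      threshold = threshold, min_len = min_len)
  groups <- tibble::tibble(
    group = names(summaries),
    n = unname(vapply(summaries, nrow, integer(1))),
    median_fraction = unname(vapply(summaries, function(s) median(s$fraction),
                                    numeric(1))),
    frac_long_domain = unname(vapply(summaries,
                                     function(s) mean(s$has_long_domain),
                                     numeric(1))))
  values <- unlist(lapply(summaries, `[[`, "fraction"), use.names = FALSE)
  glab <- rep(names(summaries), vapply(summaries, nrow, integer(1)))
  kw <- kruskal.test(values, factor(glab))
  list(groups = groups, kruskal_p = kw$p.value,
       pairwise = dunn_test(values, glab))
}
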