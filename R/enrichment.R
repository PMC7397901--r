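#' Exact binomial test
#'
#' Exact tail probabilities of the binomial distribution. `greater` is the
#' upper tail P(X >= k), `less` the lower tail P(X <= k), and `two_sided`
#' sums the probabilities of all outcomes no more likely than the observed
#' one (the minimum-likelihood construction, as in [stats::binom.test()]).
#' Tails are evaluated through [stats::pbinom()], which is accurate far
#' below double underflow of naive summation.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param alternative `"greater"`, `"less"`, or `"two_sided"`.
#' @return A single p-value.
#' @export
binom_test <- function(k, n, p0 = 0.5,
                       alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (k > n) abort("k must not exceed n")
  if (k < 0 || n < 0) abort("k and n must be non-negative")
  check_prob(p0, "p0")
  p <- switch(alternative,
    greater = pbinom(k - 1, n, p0, lower.tail = FALSE),
    less = pbinom(k, n, p0),
    two_sided = .binom_two_sided(k, n, p0)
  )
  min(1, p)
}

# minimum-likelihood two-sided p, mirroring stats::binom.test
.binom_two_sided <- function(k, n, p0) {
  if (p0 == 0) return(as.numeric(k == 0))
  if (p0 == 1) return(as.numeric(k == n))
  d <- dbinom(k, n, p0)
  rel <- 1 + 1e-7
  m <- n * p0
  if (k == m) return(1)
  if (k < m) {
    y <- sum(dbinom(seq(ceiling(m), n), n, p0) <= d * rel)
    pbinom(k, n, p0) + pbinom(n - y, n, p0, lower.tail = FALSE)
  } else {
    y <- sum(dbinom(seq(0, floor(m)), n, p0) <= d * rel)
    pbinom(y - 1, n, p0) + pbinom(k - 1, n, p0, lower.tail = FALSE)
  }
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Statistic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with no continuity
#' correction; the p-value comes from the chi-squared distribution with
#' one degree of freedom. Row 1 is the focal set (success/failure), row 2
#' the comparison set.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return List with `statistic`, `p_value`, and the 2x2 `table`.
#' @export
chisq_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) abort("cell counts must be non-negative")
  margins <- c(`row 1 (a+b)` = a + b, `row 2 (c+d)` = c + d,
               `column 1 (a+c)` = a + c, `column 2 (b+d)` = b + d)
  if (any(margins == 0)) {
    abort("zero margin: ", paste(names(margins)[margins == 0], collapse = ", "))
  }
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       table = matrix(c(a, c, b, d), 2, 2,
                      dimnames = list(c("focal", "comparison"),
                                      c("success", "failure"))))
}

#' Rounded integer percentage
#'
#' `100 k / n` rounded to the nearest integer, half away from zero (so 49%
#' for 73/150 and 87% for 1145/1318, as conventionally printed).
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @return Integer percent.
#' @export
proportion_pct <- function(k, n) {
  if (n <= 0) abort("n must be positive")
  x <- 100 * k / n
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Rim enrichment among mitotic-chromosome-recruited proteins
#'
#' Tests whether rim proteins are over-represented among the proteins
#' recruited to mitotic chromosomes, under the null that rim and non-rim
#' proteins of the stained target set are equally likely to relocate:
#' the null probability is the rim fraction of the stained set,
#' `p0 = n_rim_stained / n_stained`, and the observed statistic is the
#' number of rim proteins among the `n_recruited` recruited ones
#' (one-tailed greater exact binomial).
#'
#' @param annotations A `protein_annotation` tibble for the stained target
#'   set, with `rim` flags and `mitotic_recruitment` phases (`early` or
#'   `late` marks recruitment).
#' @return List with all counts, the rounded rim percentages, `p0`, and
#'   the one-tailed binomial `p_value`.
#' @export
recruitment_enrichment <- function(annotations) {
  recruited <- annotations$mitotic_recruitment %in% c("early", "late")
  n_stained <- nrow(annotations)
  n_recruited <- sum(recruited)
  if (n_recruited == 0L) abort("no recruited proteins in the annotation set")
  n_rim_stained <- sum(annotations$rim)
  n_rim_recruited <- sum(annotations$rim & recruited)
  p0 <- n_rim_stained / n_stained
  list(n_stained = n_stained, n_rim_stained = n_rim_stained,
       n_recruited = n_recruited, n_rim_recruited = n_rim_recruited,
       pct_rim_stained = proportion_pct(n_rim_stained, n_stained),
       pct_rim_recruited = proportion_pct(n_rim_recruited, n_recruited),
       p0 = p0,
       p_value = binom_test(n_rim_recruited, n_recruited, p0, "greater"))
}
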