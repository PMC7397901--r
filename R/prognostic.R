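#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function, right-continuous with
#' steps at event times only (computed through [survival::survfit()]).
#'
#' @param records Tibble with positive `time` and `event` (0/1) columns.
#' @return Object of class `km_curve`: tibble of `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, with an evaluator available via
#'   [km_survival()].
#' @export
km_curve <- function(records) {
  if (nrow(records) < 1L) abort("need at least 1 record")
  if (any(records$time <= 0)) abort("time must be positive")
  if (!all(records$event %in% c(0, 1))) abort("event must be 0 or 1")
  fit <- survival::survfit(survival::Surv(records$time, records$event) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  class(out) <- c("km_curve", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param curve A [km_curve()].
#' @param t Times at which to evaluate S(t); S(t) = 1 before the first
#'   event.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival <- function(curve, t) {
  ev <- curve[curve$n_event > 0, ]
  if (nrow(ev) == 0L) return(rep(1, length(t)))
  vapply(t, function(tt) {
    i <- findInterval(tt, ev$time)
    if (i == 0L) 1 else ev$survival[i]
  }, numeric(1))
}

# vectorized two-group log-rank core on pre-extracted vectors
.logrank_core <- function(time, event, in_high) {
  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]; z_s <- as.numeric(in_high[ord])
  n <- length(t_s)
  # block id per unique time (ascending)
  new_block <- c(TRUE, t_s[-1] != t_s[-n])
  block <- cumsum(new_block)
  starts <- which(new_block)
  n_at_risk <- n - starts + 1
  n1_at_risk <- rev(cumsum(rev(z_s)))[starts]
  d_j <- rowsum(d_s, block)[, 1]
  d1_j <- rowsum(d_s * z_s, block)[, 1]
  use <- d_j > 0
  D <- sum(d_j)
  if (D == 0) abort("zero total events")
  e1_j <- d_j[use] * n1_at_risk[use] / n_at_risk[use]
  nn <- n_at_risk[use]
  v_j <- ifelse(nn > 1,
                d_j[use] * (n1_at_risk[use] / nn) *
                  (1 - n1_at_risk[use] / nn) * (nn - d_j[use]) / (nn - 1),
                0)
  o1 <- sum(d1_j[use]); e1 <- sum(e1_j); v <- sum(v_j)
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  list(statistic = stat,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       observed = c(low = D - o1, high = o1),
       expected = c(low = D - e1, high = e1))
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-squared test (df = 1)
#' with the hypergeometric variance, returning per-group observed and
#' expected event counts.
#'
#' @param time Positive follow-up times.
#' @param event Event indicators (0 censored, 1 event).
#' @param group Logical or two-level vector; `TRUE` (or the second level)
#'   is reported as the `high` group.
#' @return List with `statistic`, `p_value`, `observed`, `expected`.
#' @export
logrank <- function(time, event, group) {
  if (!is.logical(group)) group <- group == sort(unique(group))[2]
  if (sum(event) == 0) abort("zero total events")
  .logrank_core(time, event, group)
}

#' Maximally separated Kaplan-Meier cutoff scan
#'
#' Classifies patients into high/low expression groups at every candidate
#' cutoff (distinct expression values at which both groups hold at least
#' `min_frac` of the cohort; "high" is expression strictly greater than
#' the cutoff), evaluates the log-rank test at each, and returns the
#' cutoff minimizing the p-value. A gene is prognostic when the unadjusted
#' minimum p-value is below `p_threshold` (0.001); it is unfavorable when
#' the high-expression group has more observed than expected events at the
#' best cutoff, favorable otherwise. Genes with median expression below
#' `fpkm_floor` (1 FPKM) are excluded. The reported minimum p-value is
#' deliberately unadjusted for the multiplicity of the scan, as in the
#' Pathology Atlas procedure; the selection inflation this causes under
#' the null is a documented property of the method.
#'
#' @param records Tibble with `time`, `event`, `expression` columns.
#' @param gene_id Identifier attached to the result.
#' @param min_frac Minimum fraction of patients per group at a candidate
#'   cutoff.
#' @param p_threshold Prognostic significance threshold on the minimum
#'   log-rank p.
#' @param fpkm_floor Exclusion threshold on median expression.
#' @param min_n Minimum cohort size.
#' @return Object of class `prognostic_result`: `gene_id`, `best_cutoff`,
#'   `min_logrank_p`, `is_prognostic`, `direction` (`"favorable"`,
#'   `"unfavorable"`, `"none"`), `excluded`, `reason`, `n`.
#' @export
scan_best_cutoff <- function(records, gene_id = "gene", min_frac = 0.1,
                             p_threshold = 0.001, fpkm_floor = 1,
                             min_n = 20L) {
  n <- nrow(records)
  if (n < min_n) abort(sprintf("cohort too small: %d < %d", n, min_n))
  res <- function(best_cutoff = NA_real_, min_p = NA_real_,
                  prognostic = FALSE, direction = "none",
                  excluded = FALSE, reason = NA_character_) {
    structure(list(gene_id = gene_id, best_cutoff = best_cutoff,
                   min_logrank_p = min_p, is_prognostic = prognostic,
                   direction = direction, excluded = excluded,
                   reason = reason, n = n),
              class = "prognostic_result")
  }
  expr <- records$expression
  if (median(expr) < fpkm_floor) {
    return(res(excluded = TRUE, reason = "median expression below floor"))
  }
  if (length(unique(expr)) == 1L) {
    return(res(reason = "constant expression"))
  }
  min_size <- ceiling(min_frac * n)
  cand <- sort(unique(expr))
  n_high <- vapply(cand, function(c) sum(expr > c), integer(1))
  ok <- n_high >= min_size & (n - n_high) >= min_size
  if (!any(ok)) return(res(reason = "no admissible cutoff"))
  cand <- cand[ok]
  time <- records$time; event <- records$event
  ps <- numeric(length(cand))
  fits <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    f <- .logrank_core(time, event, expr > cand[i])
    fits[[i]] <- f
    ps[i] <- f$p_value
  }
  best <- which.min(ps)   # ties: smallest cutoff wins
  f <- fits[[best]]
  direction <- if (f$observed[["high"]] > f$expected[["high"]])
    "unfavorable" else "favorable"
  res(best_cutoff = cand[best], min_p = ps[best],
      prognostic = ps[best] < p_threshold, direction = direction)
}

#' @export
print.prognostic_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<prognostic_result> %s: excluded (%s)\n", x$gene_id, x$reason))
  } else {
    cat(sprintf(paste0(
      "<prognostic_result> %s (n = %d): best cutoff %.3g, min log-rank ",
      "P = %.3g\n  prognostic: %s, direction: %s\n"),
      x$gene_id, x$n, x$best_cutoff, x$min_logrank_p,
      x$is_prognostic, x$direction))
  }
  invisible(x)
}
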