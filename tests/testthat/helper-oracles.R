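# Independent brute-force oracles used across the suite. These deliberately
# use naive scans/loops, not the package's vectorized code paths.

# per-residue scan: disorder fraction, longest run, number of runs > min_len
oracle_disorder_scan <- function(scores, threshold = 0.5, min_len = 30L) {
  n_dis <- 0L; longest <- 0L; n_long <- 0L; cur <- 0L
  for (s in scores) {
    if (s > threshold) {
      n_dis <- n_dis + 1L
      cur <- cur + 1L
      if (cur > longest) longest <- cur
    } else {
      if (cur > min_len) n_long <- n_long + 1L
      cur <- 0L
    }
  }
  if (cur > min_len) n_long <- n_long + 1L
  list(fraction = n_dis / length(scores), longest_run = longest,
       n_long_domains = n_long)
}

# exhaustive pairwise-distance nearest-neighbor count (ties by lowest gene_id)
oracle_nn_count <- function(reps, focal_class) {
  n <- nrow(reps)
  count <- 0L
  for (i in seq_len(n)) {
    if (reps$class_label[i] != focal_class) next
    best <- NULL; best_d <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      d <- sqrt((reps$x[i] - reps$x[j])^2 + (reps$y[i] - reps$y[j])^2)
      if (d < best_d ||
          (d == best_d && reps$gene_id[j] < reps$gene_id[best])) {
        best <- j; best_d <- d
      }
    }
    if (reps$class_label[best] == focal_class) count <- count + 1L
  }
  count
}

# full-permutation two-sided Mann-Whitney p-value (tie-free samples)
oracle_mw_perm_p <- function(x, y) {
  n1 <- length(x); pooled <- c(x, y); n <- length(pooled)
  u_of <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  mu <- n1 * (n - n1) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# direct-summation binomial tails
oracle_binom_tail <- function(k, n, p0, upper = TRUE) {
  xs <- if (upper) k:n else 0:k
  sum(dbinom(xs, n, p0))
}

zero_noise_config <- function(seed = 1L, ...) {
  synthetic_config(
    seed = seed,
    image_params = list(size = 128L, rim_band_width = 5L, rim_erosion = 5L,
                        rim_outer_intensity = 0.4, n_aggregates = 4L,
                        aggregate_radius = 5L, noise_sd = 0, shot_scale = 0),
    ...)
}
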