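test_that("generators are bit-identical under a fixed seed", {
  cfg <- synthetic_config(seed = 99)
  expect_identical(gen_annotations(cfg), gen_annotations(cfg))
  expect_identical(gen_disorder_profiles(cfg, "mitotic", 10),
                   gen_disorder_profiles(cfg, "mitotic", 10))
  expect_identical(gen_embeddings(cfg), gen_embeddings(cfg))
  expect_identical(gen_survival_cohort(cfg, 40), gen_survival_cohort(cfg, 40))
  expect_identical(gen_abundance_table(cfg, 10, 10),
                   gen_abundance_table(cfg, 10, 10))
  p1 <- gen_mitotic_image_pair(cfg, "WT", seed = 3)
  p2 <- gen_mitotic_image_pair(cfg, "WT", seed = 3)
  expect_identical(p1$dapi, p2$dapi)
  expect_identical(p1$protein, p2$protein)
  # and the generator does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(gen_annotations(cfg)); b <- runif(1)
  expect_identical(a, b)
})

test_that("annotation generator plants recruitment probabilities", {
  # degenerate probabilities force/forbid recruitment deterministically
  cfg <- synthetic_config(seed = 1, rim_recruit_prob = 1,
                          nonrim_recruit_prob = 0)
  ann <- gen_annotations(cfg)
  rec <- ann$mitotic_recruitment %in% c("early", "late")
  expect_true(all(rec[ann$rim]))
  expect_false(any(rec[!ann$rim]))

  expect_error(gen_annotations(synthetic_config(group_sizes = c(rim = 3))),
               "nonrim")
  expect_error(synthetic_config(rim_recruit_prob = 1.2), "probability")

  # binomial sampling check at the study's counts: mean recruited counts
  # approach 49 (rim) and 16 (non-rim) over many seeds
  counts <- vapply(1:300, function(s) {
    a <- gen_annotations(synthetic_config(seed = s))
    rec <- a$mitotic_recruitment %in% c("early", "late")
    c(sum(rec & a$rim), sum(rec & !a$rim))
  }, numeric(2))
  se_rim <- sqrt(73 * (49 / 73) * (1 - 49 / 73)) / sqrt(300)
  se_non <- sqrt(77 * (16 / 77) * (1 - 16 / 77)) / sqrt(300)
  expect_lt(abs(mean(counts[1, ]) - 49), 3 * se_rim)
  expect_lt(abs(mean(counts[2, ]) - 16), 3 * se_non)
})

test_that("disorder generator hits planted medians and honors degenerate targets", {
  cfg <- synthetic_config(seed = 21)
  s <- summarize_disorder(gen_disorder_profiles(cfg, "nucleoli", 500))
  expect_lt(abs(median(s$fraction) - 0.20), 0.03)

  # fully ordered degenerate group
  cfg0 <- synthetic_config(seed = 3, disorder_medians = c(flat = 0))
  profs <- gen_disorder_profiles(cfg0, "flat", 20)
  expect_true(all(vapply(profs, function(p) all(p$scores < 0.5), logical(1))))

  expect_error(gen_disorder_profiles(cfg, "no_such_group", 5), "unknown group")

  # scores never hit the 0.5 boundary exactly
  profs <- gen_disorder_profiles(cfg, "mitotic", 50)
  expect_false(any(vapply(profs, function(p) any(p$scores == 0.5), logical(1))))
})

test_that("embedding generator controls cluster separation", {
  far <- synthetic_config(seed = 4, embedding = list(
    classes = list(A = list(mean = c(0, 0), cov = diag(2), n_genes = 60L),
                   B = list(mean = c(100, 0), cov = diag(2), n_genes = 60L)),
    images_lambda = 1))
  emb <- gen_embeddings(far)
  reps <- sample_representatives(emb, seed = 1)
  purity <- (same_class_nn_count(reps, "A") + same_class_nn_count(reps, "B")) /
    nrow(reps)
  expect_gt(purity, 0.99)

  near <- synthetic_config(seed = 4, embedding = list(
    classes = list(A = list(mean = c(0, 0), cov = diag(2), n_genes = 60L),
                   B = list(mean = c(0, 0), cov = diag(2), n_genes = 60L)),
    images_lambda = 1))
  emb2 <- gen_embeddings(near)
  reps2 <- sample_representatives(emb2, seed = 1)
  purity2 <- (same_class_nn_count(reps2, "A") +
                same_class_nn_count(reps2, "B")) / nrow(reps2)
  expect_lt(abs(purity2 - 0.5), 0.15)  # ~ class prior for identical clusters

  sing <- synthetic_config(seed = 4, embedding = list(
    classes = list(A = list(mean = c(0, 0), cov = matrix(1, 2, 2), n_genes = 5L),
                   B = list(mean = c(1, 0), cov = diag(2), n_genes = 5L)),
    images_lambda = 1))
  expect_error(gen_embeddings(sing), "singular covariance")
})

test_that("zero-noise image pairs obey the rim-band and aggregate constructions", {
  for (s in 1:3) {
    cfg <- zero_noise_config(seed = s)
    w <- cfg$image_params$rim_band_width
    wt <- gen_mitotic_image_pair(cfg, "WT", seed = s)
    mask <- wt$dapi == 1
    din <- EBImage::imageData(EBImage::distmap(mask * 1))
    dout <- EBImage::imageData(EBImage::distmap((!mask) * 1))
    on_band <- (din > 0 & din <= w) | (dout > 0 & dout <= w)
    expect_true(all(on_band[wt$protein > 0]))

    ko <- gen_mitotic_image_pair(cfg, "KO", seed = s)
    peak <- which(ko$protein == max(ko$protein))[1]
    expect_false(mask[peak])  # brightest aggregate pixel is off the mask
    expect_lt(sum(ko$protein[mask]) / sum(ko$protein), 0.25)
  }
  expect_error(
    gen_mitotic_image_pair(
      synthetic_config(image_params = list(size = 64L, rim_band_width = 40L,
                                           rim_erosion = 2L,
                                           n_aggregates = 2L,
                                           aggregate_radius = 4L,
                                           noise_sd = 0, shot_scale = 0)),
      "WT"),
    "rim_band_width")
})

test_that("survival generator calibrates null, effect direction, and censoring", {
  # HR = 1: log-rank p at the planted cutoff is uniform over seeds
  ps <- vapply(1:200, function(s) {
    cfg <- synthetic_config(seed = s, survival_params = list(
      baseline_hazard = 0.1, hazard_ratio = 1, cutoff = 4.5,
      meanlog = 1.5, sdlog = 1, censoring_fraction = 0.3))
    sv <- gen_survival_cohort(cfg, 120)
    logrank(sv$time, sv$event, sv$expression > 4.5)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)

  # HR = 3: high-expression group dies sooner
  cfg <- synthetic_config(seed = 8)
  sv <- gen_survival_cohort(cfg, 500)
  hi <- sv$expression > cfg$survival_params$cutoff
  expect_lt(median(sv$time[hi & sv$event == 1]),
            median(sv$time[!hi & sv$event == 1]))
  # censoring fraction lands near its target
  expect_lt(abs(mean(sv$event == 0) - 0.3), 0.08)

  expect_equal(nrow(gen_survival_cohort(cfg, 0)), 0L)
  expect_error(synthetic_config(survival_params = list(
    baseline_hazard = 0.1, hazard_ratio = 3, cutoff = 4.5,
    meanlog = 1.5, sdlog = 1, censoring_fraction = 1)), "censoring_fraction")
})

test_that("abundance generator censors at the copy-number thresholds", {
  cfg <- synthetic_config(seed = 6)
  ab <- gen_abundance_table(cfg, 100, 100)
  vals <- cap_censored(ab$copies_per_cell)
  expect_true(all(vals[ab$copies_per_cell == "> 2e7"] == 5e7))
  expect_true(all(vals[ab$copies_per_cell == "< 5e2"] == 100))

  # all mass below the lower threshold -> every token censored low
  lo <- synthetic_config(seed = 6, abundance_params = list(
    meanlog = log(10), sdlog = 0.2, delta = 0, lower = 5e2, upper = 2e7))
  ab_lo <- gen_abundance_table(lo, 30, 30)
  expect_true(all(ab_lo$copies_per_cell == "< 5e2"))

  # delta = 0: Wilcoxon p on capped values is uniform over seeds
  ps <- vapply(1:200, function(s) {
    cfg0 <- synthetic_config(seed = s, abundance_params = list(
      meanlog = log(5e4), sdlog = 2, delta = 0, lower = 5e2, upper = 2e7))
    ab0 <- gen_abundance_table(cfg0, 157, 1161)
    v <- cap_censored(ab0$copies_per_cell)
    rim <- grepl("^rim", ab0$gene_id)
    mann_whitney(v[rim], v[!rim])$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
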