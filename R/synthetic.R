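#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators that emulate the study's
#' input modalities: annotation tables with planted mitotic-recruitment
#' probabilities, per-residue disorder profiles with planted group medians,
#' 2D image-embedding clusters, two-channel mitotic cell images with a
#' perichromosomal-rim (WT) or aggregate (KO) protein phenotype, survival
#' cohorts with a planted expression cutoff and hazard ratio, and censored
#' copies-per-cell abundance tables.
#'
#' Defaults are the study conditions: 73 rim / 77 non-rim stained proteins
#' with recruitment probabilities 49/73 and 16/77 and a 19/65 late fraction;
#' planted disorder medians cytosol 0.14, nucleoli 0.20, rim 0.31, mitotic
#' 0.36; an embedding with 27 rim and 208 nucleoli genes. All generators
#' are pure functions of (config, seed): a fixed seed reproduces output
#' bit-identically. A single global seed fans out to per-stream sub-seeds
#' by fixed offsets (annotations +11, disorder +23 plus a group offset,
#' embeddings +37, survival +53, abundance +67), so streams are independent
#' but jointly reproducible.
#'
#' @param seed Integer master seed.
#' @param group_sizes Named integer vector with at least `rim` and `nonrim`
#'   counts for the stained annotation set.
#' @param rim_recruit_prob,nonrim_recruit_prob Probability that a rim /
#'   non-rim stained protein is recruited to mitotic chromosomes.
#' @param late_frac Fraction of recruited proteins with late onset.
#' @param disorder_medians Named vector of target median disorder fractions
#'   per group, each in (0, 1) (0 allowed as a degenerate fully-ordered
#'   group for testing).
#' @param disorder_beta_conc Concentration (a + b) of the Beta distribution
#'   the per-protein disorder fraction is drawn from (spread around the
#'   group median; not a published value).
#' @param disorder_run_mean Mean length, in residues, of a disordered run
#'   (two-state Markov chain); >= 20 so >30-residue domains occur at
#'   realistic rates.
#' @param embedding List: `classes` is a named list of
#'   `list(mean = c(x, y), cov = 2x2 matrix, n_genes)`; `images_lambda` is
#'   the Poisson parameter of (images per protein − 1).
#' @param image_params List: `size` (canvas pixels, >= 64),
#'   `rim_band_width` and `rim_erosion` (pixels; outer/inner extent of the
#'   WT perichromosomal band around the chromosome mask boundary; keep
#'   `rim_erosion <= rim_band_width` so all band pixels lie within
#'   `rim_band_width` of the boundary), `rim_outer_intensity` (intensity
#'   of the band part outside the mask relative to 1 inside),
#'   `n_aggregates` and `aggregate_radius` (KO phenotype), `noise_sd`
#'   (Gaussian read noise; 0 disables all noise), `shot_scale` (photon
#'   count for Poisson-like shot noise).
#' @param survival_params List: `baseline_hazard`, `hazard_ratio`, planted
#'   expression `cutoff` (FPKM), `meanlog`/`sdlog` of the log-normal
#'   expression, `censoring_fraction` in \[0, 1).
#' @param abundance_params List: `meanlog`/`sdlog` of log-normal copies per
#'   cell, `delta` (shift of `meanlog` for rim proteins), censor thresholds
#'   `lower` (5e2) and `upper` (2e7).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    group_sizes = c(rim = 73L, nonrim = 77L),
    rim_recruit_prob = 49 / 73,
    nonrim_recruit_prob = 16 / 77,
    late_frac = 19 / 65,
    disorder_medians = c(cytosol = 0.14, nucleoli = 0.20,
                         rim = 0.31, mitotic = 0.36),
    disorder_beta_conc = 80,
    disorder_run_mean = 20,
    embedding = list(
      classes = list(
        nucleoli = list(mean = c(0, 0), cov = diag(2), n_genes = 208L),
        nucleoli_rim = list(mean = c(8, 0), cov = diag(2), n_genes = 27L)
      ),
      images_lambda = 2
    ),
    image_params = list(size = 128L, rim_band_width = 5L, rim_erosion = 5L,
                        rim_outer_intensity = 0.4, n_aggregates = 4L,
                        aggregate_radius = 5L, noise_sd = 0.05,
                        shot_scale = 500),
    survival_params = list(baseline_hazard = 0.1, hazard_ratio = 3,
                           cutoff = 4.5, meanlog = 1.5, sdlog = 1,
                           censoring_fraction = 0.3),
    abundance_params = list(meanlog = log(5e4), sdlog = 2, delta = 0.5,
                            lower = 5e2, upper = 2e7)) {
  if (!is_scalar_number(seed)) abort("seed must be a single integer")
  check_prob(rim_recruit_prob, "rim_recruit_prob")
  check_prob(nonrim_recruit_prob, "nonrim_recruit_prob")
  check_prob(late_frac, "late_frac")
  if (anyNA(disorder_medians) || any(disorder_medians < 0) ||
      any(disorder_medians >= 1)) {
    abort("disorder_medians must lie in [0, 1)")
  }
  if (disorder_run_mean < 1) abort("disorder_run_mean must be >= 1")
  if (!is.null(image_params$size) && image_params$size < 64L) {
    abort("image canvas must be at least 64x64")
  }
  cf <- survival_params$censoring_fraction
  if (!is_scalar_number(cf) || cf < 0 || cf >= 1) {
    abort("censoring_fraction must lie in [0, 1)")
  }
  if (survival_params$hazard_ratio <= 0) abort("hazard_ratio must be > 0")
  structure(
    list(seed = as.integer(seed), group_sizes = group_sizes,
         rim_recruit_prob = rim_recruit_prob,
         nonrim_recruit_prob = nonrim_recruit_prob, late_frac = late_frac,
         disorder_medians = disorder_medians,
         disorder_beta_conc = disorder_beta_conc,
         disorder_run_mean = disorder_run_mean,
         embedding = embedding, image_params = image_params,
         survival_params = survival_params,
         abundance_params = abundance_params),
    class = "synthetic_config")
}

#' Generate a stained annotation set with planted recruitment probabilities
#'
#' Creates `group_sizes["rim"]` rim proteins (locations `nucleoli` +
#' `nucleoli_rim`) and `group_sizes["nonrim"]` non-rim nucleolar proteins,
#' then assigns mitotic-chromosome recruitment independently per protein
#' with probability `rim_recruit_prob` / `nonrim_recruit_prob`; recruited
#' proteins get phase `early` or `late` (`late_frac`) and the
#' `mitotic_chromosome` location term.
#'
#' @param config A [synthetic_config()].
#' @return A `protein_annotation` tibble.
#' @export
gen_annotations <- function(config) {
  gs <- config$group_sizes
  if (length(gs) == 0L) abort("group_sizes is empty")
  if (!all(c("rim", "nonrim") %in% names(gs))) {
    abort("group_sizes needs 'rim' and 'nonrim' entries")
  }
  n_rim <- as.integer(gs[["rim"]]); n_non <- as.integer(gs[["nonrim"]])
  with_seed(config$seed + 11L, {
    gene_id <- c(sprintf("rim_%03d", seq_len(n_rim)),
                 sprintf("nonrim_%03d", seq_len(n_non)))
    rim <- rep(c(TRUE, FALSE), c(n_rim, n_non))
    p <- ifelse(rim, config$rim_recruit_prob, config$nonrim_recruit_prob)
    recruited <- runif(n_rim + n_non) < p
    phase <- rep("none", n_rim + n_non)
    phase[recruited] <- ifelse(runif(sum(recruited)) < config$late_frac,
                               "late", "early")
    locations <- lapply(seq_along(gene_id), function(i) {
      loc <- "nucleoli"
      if (rim[i]) loc <- c(loc, "nucleoli_rim")
      if (recruited[i]) loc <- c(loc, "mitotic_chromosome")
      loc
    })
    reliability <- sample(c("enhanced", "supported", "approved", "uncertain"),
                          n_rim + n_non, replace = TRUE,
                          prob = c(0.25, 0.35, 0.3, 0.1))
    protein_annotation(gene_id, locations, reliability, rim, phase)
  })
}

# median-matched Beta: pick a for fixed concentration so qbeta(0.5) == m
.beta_shape_for_median <- function(m, conc) {
  if (m <= 0) return(c(0, conc))
  f <- function(a) suppressWarnings(stats::qbeta(0.5, a, conc - a)) - m
  a <- uniroot(f, c(0.02, conc - 0.02), extendInt = "upX", tol = 1e-10)$root
  c(a, conc - a)
}

# one protein's residue states from a two-state Markov chain with
# stationary disorder probability f and mean disordered run length run_mean
.markov_states <- function(len, f, run_mean) {
  if (f <= 0) return(rep(FALSE, len))
  if (f >= 1) return(rep(TRUE, len))
  mean_ord <- max(1, run_mean * (1 - f) / f)
  start_dis <- runif(1) < f
  k <- as.integer(ceiling(len / (run_mean + mean_ord))) + 8L
  repeat {
    d <- 1L + rgeom(k, 1 / run_mean)
    o <- 1L + rgeom(k, 1 / mean_ord)
    runs <- if (start_dis) rbind(d, o) else rbind(o, d)
    if (sum(runs) >= len) break
    k <- 2L * k
  }
  vals <- if (start_dis) rep(c(TRUE, FALSE), k) else rep(c(FALSE, TRUE), k)
  rep(vals, as.vector(runs))[seq_len(len)]
}

#' Generate per-residue disorder profiles for one group
#'
#' Per protein, a target disorder fraction is drawn from a Beta
#' distribution whose median equals the group's planted target; residue
#' states then follow a two-state Markov chain with that stationary
#' disorder probability and mean disordered run length
#' `config$disorder_run_mean`, so long (>30 residue) disordered domains
#' occur at realistic rates. Disordered residues receive scores uniform on
#' (0.5, 1], ordered residues uniform on \[0, 0.5); a score of exactly 0.5
#' is never generated, so the strict "above 0.5" rule is unambiguous.
#'
#' @param config A [synthetic_config()].
#' @param group Group name; must have an entry in
#'   `config$disorder_medians`.
#' @param n Number of proteins.
#' @param length_range Protein length range (residues), sampled uniformly.
#' @return List of [disorder_profile()] objects.
#' @export
gen_disorder_profiles <- function(config, group, n,
                                  length_range = c(300L, 2500L)) {
  med <- config$disorder_medians
  if (!group %in% names(med)) abort("unknown group: ", group)
  target <- med[[group]]
  offset <- 23L + 97L * match(group, names(med))
  with_seed(config$seed + offset, {
    shapes <- .beta_shape_for_median(target, config$disorder_beta_conc)
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    fs <- if (target <= 0) rep(0, n) else rbeta(n, shapes[1], shapes[2])
    ids <- sprintf("%s_%04d", group, seq_len(n))
    lapply(seq_len(n), function(i) {
      st <- .markov_states(lens[i], fs[i], config$disorder_run_mean)
      # one uniform draw per residue, mapped to (0.5, 1) if disordered and
      # (0, 0.5) if ordered: a score of exactly 0.5 never occurs
      u <- runif(lens[i])
      structure(list(gene_id = ids[i],
                     scores = ifelse(st, 0.5 + u / 2, u / 2)),
                class = "disorder_profile")
    })
  })
}

#' Generate 2D embedding records with Gaussian class clusters
#'
#' Per gene, `1 + rpois(images_lambda)` image coordinates are drawn from
#' its class's Gaussian; class separation is controlled by the configured
#' means and covariances.
#'
#' @param config A [synthetic_config()].
#' @return A tibble of embedding records
#'   (`image_id`, `gene_id`, `x`, `y`, `class_label`).
#' @export
gen_embeddings <- function(config) {
  classes <- config$embedding$classes
  if (length(classes) < 2L) abort("need at least 2 embedding classes")
  lambda <- config$embedding$images_lambda
  with_seed(config$seed + 37L, {
    rows <- lapply(names(classes), function(cl) {
      spec <- classes[[cl]]
      cov <- as.matrix(spec$cov)
      ch <- tryCatch(chol(cov), error = function(e) NULL)
      if (is.null(ch) || any(diag(ch) < 1e-10)) {
        abort("singular covariance for class ", cl)
      }
      ng <- as.integer(spec$n_genes)
      k <- 1L + rpois(ng, lambda)
      gene <- rep(sprintf("%s_g%04d", cl, seq_len(ng)), k)
      m <- length(gene)
      xy <- matrix(rnorm(2 * m), m, 2) %*% ch
      tibble::tibble(
        image_id = sprintf("%s_im%05d", cl, seq_len(m)),
        gene_id = gene,
        x = spec$mean[1] + xy[, 1],
        y = spec$mean[2] + xy[, 2],
        class_label = cl)
    })
    do.call(rbind, rows)
  })
}

#' Generate a synthetic two-channel mitotic cell image
#'
#' The DAPI channel is the union of 1-4 random ellipses (a condensed
#' metaphase-plate-like chromosome mask) at intensity 1. The protein
#' channel depends on the condition: `WT` places a perichromosomal band
#' along the mask boundary (pixels within `rim_band_width` outside or
#' `rim_erosion` inside the boundary), partially overlapping the mask
#' edge; `KO` places `n_aggregates` Gaussian blobs centered just outside
#' but adjacent to the mask, emulating the aggregate phenotype of
#' MKI67-deficient cells. When `noise_sd > 0`, Poisson-like shot noise
#' (photon count `shot_scale`) and Gaussian read noise are applied to both
#' channels; `noise_sd = 0` yields the clean geometric construction.
#'
#' @param config A [synthetic_config()].
#' @param condition `"WT"` or `"KO"`.
#' @param seed Seed for this image; defaults to `config$seed`.
#' @param phase Mitotic phase label attached to the pair.
#' @return A [mitotic_image_pair()].
#' @export
gen_mitotic_image_pair <- function(config, condition = c("WT", "KO"),
                                   seed = config$seed,
                                   phase = "metaphase") {
  condition <- match.arg(condition)
  ip <- config$image_params
  sz <- as.integer(ip$size)
  if (ip$rim_band_width >= sz / 2) {
    abort("rim_band_width must be smaller than half the canvas")
  }
  with_seed(seed, {
    xg <- matrix(rep(seq_len(sz), sz), sz, sz)
    yg <- t(xg)
    mask <- matrix(FALSE, sz, sz)
    n_ell <- sample(1:4, 1)
    for (i in seq_len(n_ell)) {
      cx <- runif(1, 0.35 * sz, 0.65 * sz)
      cy <- runif(1, 0.35 * sz, 0.65 * sz)
      a <- runif(1, 0.10 * sz, 0.18 * sz)
      b <- runif(1, 0.06 * sz, 0.12 * sz)
      th <- runif(1, 0, pi)
      u <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
      v <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
      mask <- mask | (u^2 / a^2 + v^2 / b^2 <= 1)
    }
    dist_in <- EBImage::distmap(mask * 1)        # distance to background
    dist_out <- EBImage::distmap((!mask) * 1)    # distance to mask
    dapi <- mask * 1
    if (condition == "WT") {
      # perichromosomal band straddling the mask boundary; the part inside
      # the DNA mask is at full intensity, the part just outside dimmer
      # (projection of a 3D shell over the chromosome mass)
      outer_int <- if (is.null(ip$rim_outer_intensity)) 0.4 else
        ip$rim_outer_intensity
      protein <- (dist_in > 0 & dist_in <= ip$rim_erosion) * 1 +
        (dist_out > 0 & dist_out <= ip$rim_band_width) * outer_int
    } else {
      cand <- which(dist_out >= ip$aggregate_radius &
                      dist_out <= ip$aggregate_radius + 2)
      if (length(cand) == 0L) cand <- which(dist_out > 0)
      centers <- sample(cand, min(ip$n_aggregates, length(cand)))
      protein <- matrix(0, sz, sz)
      sig <- ip$aggregate_radius / 2
      for (cidx in centers) {
        cx <- (cidx - 1) %% sz + 1
        cy <- (cidx - 1) %/% sz + 1
        d2 <- (xg - cx)^2 + (yg - cy)^2
        protein <- pmax(protein, exp(-d2 / (2 * sig^2)))
      }
    }
    if (ip$noise_sd > 0) {
      shot <- function(im) {
        if (is.null(ip$shot_scale) || ip$shot_scale <= 0) return(im)
        matrix(rpois(length(im), as.vector(im) * ip$shot_scale) /
                 ip$shot_scale, nrow(im), ncol(im))
      }
      dapi <- shot(dapi) + rnorm(length(dapi), 0, ip$noise_sd)
      protein <- shot(protein) + rnorm(length(protein), 0, ip$noise_sd)
    }
    dapi <- pmin(pmax(dapi, 0), 1)
    protein <- pmin(pmax(protein, 0), 1)
    mitotic_image_pair(dapi, protein, condition = condition, phase = phase,
                       gene_id = "synthetic")
  })
}

#' Generate a survival cohort with a planted prognostic expression cutoff
#'
#' Expression is log-normal; event time is exponential with hazard
#' `baseline_hazard * hazard_ratio^(expression > cutoff)`. Independent
#' uniform censoring (censoring time uniform on (0, tau), tau solved so
#' the expected censored fraction equals `censoring_fraction`).
#'
#' @param config A [synthetic_config()].
#' @param n Cohort size.
#' @return A tibble of survival records (`time`, `event`, `expression`).
#' @export
gen_survival_cohort <- function(config, n) {
  sp <- config$survival_params
  if (n == 0L) {
    return(tibble::tibble(time = numeric(), event = integer(),
                          expression = numeric()))
  }
  with_seed(config$seed + 53L, {
    expr <- rlnorm(n, sp$meanlog, sp$sdlog)
    rate <- sp$baseline_hazard * sp$hazard_ratio^(expr > sp$cutoff)
    t_ev <- rexp(n, rate)
    if (sp$censoring_fraction > 0) {
      target <- sp$censoring_fraction
      frac_cens <- function(tau) {
        mean((1 - exp(-rate * tau)) / (rate * tau)) - target
      }
      tau <- uniroot(frac_cens, c(1e-8, 1e8), tol = 1e-8)$root
      t_c <- runif(n, 0, tau)
      tibble::tibble(time = pmin(t_ev, t_c),
                     event = as.integer(t_ev <= t_c),
                     expression = expr)
    } else {
      tibble::tibble(time = t_ev, event = 1L, expression = expr)
    }
  })
}

#' Generate a censored copies-per-cell abundance table
#'
#' True copy numbers are log-normal with the rim group's log-mean shifted
#' by `delta`; values above 2e7 are emitted as the token `"> 2e7"`, below
#' 5e2 as `"< 5e2"`, and numeric otherwise. Gene ids match
#' [gen_annotations()] naming (`rim_###` / `nonrim_###`) so the table
#' joins directly onto a generated annotation set.
#'
#' @param config A [synthetic_config()].
#' @param n_rim,n_nonrim Group sizes.
#' @return A tibble (`gene_id`, `copies_per_cell`).
#' @export
gen_abundance_table <- function(config, n_rim, n_nonrim) {
  ap <- config$abundance_params
  with_seed(config$seed + 67L, {
    gene_id <- c(sprintf("rim_%03d", seq_len(n_rim)),
                 sprintf("nonrim_%03d", seq_len(n_nonrim)))
    mu <- c(rep(ap$meanlog + ap$delta, n_rim), rep(ap$meanlog, n_nonrim))
    copies <- rlnorm(n_rim + n_nonrim, mu, ap$sdlog)
    token <- sprintf("%.6g", copies)
    token[copies > ap$upper] <- "> 2e7"
    token[copies < ap$lower] <- "< 5e2"
    tibble::tibble(gene_id = gene_id, copies_per_cell = token)
  })
}
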