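#' Segmentation parameters for nuclear/chromosomal masks
#'
#' @param sigma Gaussian smoothing sigma in pixels before thresholding.
#' @param threshold `"otsu"` (global Otsu on the smoothed image) or a
#'   fixed numeric threshold in \[0, 1\].
#' @param min_area Minimum object area in pixels; smaller components are
#'   discarded.
#' @param fill_holes Fill holes inside objects before labeling.
#' @param dilate_radius Radius in pixels by which each object mask is
#'   dilated to form the measurement region (captures perichromosomal
#'   signal adjacent to the DNA mask; 0 gives the strict nuclear area).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(sigma = 2, threshold = "otsu",
                                min_area = 64L, fill_holes = TRUE,
                                dilate_radius = 8L) {
  if (min_area < 1L) abort("min_area must be >= 1")
  if (dilate_radius < 0L) abort("dilate_radius must be >= 0")
  structure(list(sigma = sigma, threshold = threshold,
                 min_area = as.integer(min_area), fill_holes = fill_holes,
                 dilate_radius = as.integer(dilate_radius)),
            class = "segmentation_params")
}

# merge 4-connected labels that touch diagonally into 8-connected objects
.merge_diagonal <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (max(lab) == 0) return(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  k <- max(lab)
  if (nrow(pairs) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out <- lab
  out[lab > 0] <- comp[lab[lab > 0]]
  out
}

#' Segment nuclear/chromosomal objects in a DAPI image
#'
#' Gaussian smoothing, global Otsu (or fixed) threshold, hole filling,
#' removal of components below `min_area`, and 8-connected component
#' labeling. A blank image (zero variance) yields an empty label mask
#' with a warning.
#'
#' @param dapi 2D intensity matrix in \[0, 1\].
#' @param params A [segmentation_params()].
#' @return Integer label matrix (0 = background, 1..k = objects).
#' @export
segment_objects <- function(dapi, params = segmentation_params()) {
  dapi <- as.matrix(dapi)
  if (sd(dapi) == 0) {
    warning("blank image: zero variance, no objects segmented", call. = FALSE)
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  img <- EBImage::Image(dapi)
  if (params$sigma > 0) img <- EBImage::gblur(img, sigma = params$sigma)
  thr <- if (identical(params$threshold, "otsu")) EBImage::otsu(img) else
    params$threshold
  bw <- img > thr
  if (params$fill_holes) bw <- EBImage::fillHull(bw)
  lab <- EBImage::imageData(EBImage::bwlabel(bw))
  dim(lab) <- dim(dapi)
  lab <- .merge_diagonal(lab)
  # drop small components, relabel 1..k by first occurrence
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= params$min_area)
  lab[!(lab %in% keep)] <- 0L
  old <- unique(lab[lab > 0])
  lab[lab > 0] <- match(lab[lab > 0], old)
  matrix(as.integer(lab), nrow(dapi), ncol(dapi))
}

#' Overlap coefficient between two channels within a region
#'
#' The normalized intensity cross-product
#' `sum(ch1 * ch2) / sqrt(sum(ch1^2) * sum(ch2^2))` over the region
#' pixels, in \[0, 1\] (1 for proportional channels by the Cauchy-Schwarz
#' equality, 0 for disjoint supports). Defined as 0 when either channel
#' is all-zero in the region.
#'
#' @param ch1,ch2 Intensity matrices of identical shape.
#' @param region Logical matrix selecting the pixels to use; `NULL` means
#'   the whole frame.
#' @return A value in \[0, 1\].
#' @export
overlap_coefficient <- function(ch1, ch2, region = NULL) {
  if (!identical(dim(ch1), dim(ch2))) abort("channels must have identical shape")
  if (is.null(region)) region <- !logical(length(ch1))
  v1 <- ch1[region]; v2 <- ch2[region]
  if (length(v1) == 0L) abort("empty region")
  s1 <- sum(v1^2); s2 <- sum(v2^2)
  if (s1 == 0 || s2 == 0) return(0)
  sum(v1 * v2) / sqrt(s1 * s2)
}

#' Pearson correlation between two channels within a region
#'
#' Sample Pearson correlation over the region pixels. Returns `NA` when
#' either channel is constant in the region (correlation undefined).
#'
#' @inheritParams overlap_coefficient
#' @return A value in \[-1, 1\], or `NA` if undefined.
#' @export
pearson_in_region <- function(ch1, ch2, region = NULL) {
  if (!identical(dim(ch1), dim(ch2))) abort("channels must have identical shape")
  if (is.null(region)) region <- !logical(length(ch1))
  v1 <- ch1[region]; v2 <- ch2[region]
  if (length(v1) < 2L) abort("region must contain at least 2 pixels")
  if (sd(v1) == 0 || sd(v2) == 0) return(NA_real_)
  cor(v1, v2)
}

#' Per-object DAPI/protein colocalization for one image pair
#'
#' Segments the DAPI channel, dilates each object mask by
#' `params$dilate_radius` pixels to form the measurement region, and
#' computes the overlap coefficient and Pearson correlation between DAPI
#' and protein within that region.
#'
#' @param pair A [mitotic_image_pair()].
#' @param params A [segmentation_params()].
#' @return Tibble with one row per object: `object_id`, `area`,
#'   `overlap`, `pearson`, `condition`, `phase`, `gene_id`. Empty if no
#'   object is found.
#' @export
measure_pair <- function(pair, params = segmentation_params()) {
  lab <- suppressWarnings(segment_objects(pair$dapi, params))
  ids <- setdiff(unique(as.vector(lab)), 0L)
  empty <- tibble::tibble(object_id = integer(), area = integer(),
                          overlap = numeric(), pearson = numeric(),
                          condition = character(), phase = character(),
                          gene_id = character())
  if (length(ids) == 0L) return(empty)
  r <- params$dilate_radius
  rows <- lapply(sort(ids), function(id) {
    obj <- lab == id
    region <- if (r > 0) {
      EBImage::imageData(EBImage::distmap((!obj) * 1)) <= r
    } else obj
    dim(region) <- dim(obj)
    tibble::tibble(object_id = id, area = sum(obj),
                   overlap = overlap_coefficient(pair$dapi, pair$protein, region),
                   pearson = pearson_in_region(pair$dapi, pair$protein, region),
                   condition = pair$condition, phase = pair$phase,
                   gene_id = pair$gene_id)
  })
  do.call(rbind, rows)
}

#' WT vs KO colocalization comparison for one gene
#'
#' Two-sided Mann-Whitney tests of per-cell overlap and per-cell Pearson
#' correlation between conditions, with medians reported. Requires at
#' least `min_cells` measured cells per condition.
#'
#' @param measurements Tibble of [measure_pair()] rows for one gene,
#'   covering both conditions.
#' @param min_cells Minimum cells per condition.
#' @return Tibble with one row per metric (`overlap`, `pearson`):
#'   condition sizes, WT and KO medians, and the Wilcoxon `p_value`.
#' @export
compare_conditions <- function(measurements, min_cells = 3L) {
  for (cond in c("WT", "KO")) {
    n <- sum(measurements$condition == cond)
    if (n < min_cells) {
      abort(sprintf("condition %s has %d cells; need at least %d",
                    cond, n, min_cells))
    }
  }
  one <- function(metric) {
    v <- measurements[[metric]]
    ok <- !is.na(v)
    wt <- v[ok & measurements$condition == "WT"]
    ko <- v[ok & measurements$condition == "KO"]
    cmp <- mann_whitney(wt, ko, "two_sided")
    tibble::tibble(metric = metric, n_wt = cmp$n1, n_ko = cmp$n2,
                   median_wt = cmp$median1, median_ko = cmp$median2,
                   p_value = cmp$p_value)
  }
  rbind(one("overlap"), one("pearson"))
}

#' Simulate and measure a WT/KO colocalization cohort
#'
#' Generates `n_wt` WT and `n_ko` KO synthetic mitotic image pairs (seeds
#' `seed`, `seed + 1`, ...) and measures each with [measure_pair()]. Used
#' to recover the qualitative KO phenotype (lower overlap, negative
#' DAPI-protein correlation) end to end.
#'
#' @param config A [synthetic_config()].
#' @param n_wt,n_ko Cells per condition.
#' @param params A [segmentation_params()].
#' @param seed Base seed for the image series.
#' @return Tibble of per-cell measurements.
#' @export
simulate_coloc_cohort <- function(config, n_wt = 30L, n_ko = 30L,
                                  params = segmentation_params(),
                                  seed = config$seed) {
  pairs <- c(
    lapply(seq_len(n_wt), function(i)
      gen_mitotic_image_pair(config, "WT", seed = seed + i - 1L)),
    lapply(seq_len(n_ko), function(i)
      gen_mitotic_image_pair(config, "KO", seed = seed + n_wt + i - 1L)))
  out <- do.call(rbind, lapply(pairs, measure_pair, params = params))
  out
}
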