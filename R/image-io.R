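.conditions <- c("WT", "KO")
.phases <- c("prometaphase", "metaphase", "ana_telophase", "cytokinesis")

#' Construct a registered DAPI/protein image pair for one mitotic cell field
#'
#' @param dapi,protein Numeric matrices of identical shape with finite,
#'   non-negative intensities (conventionally scaled to \[0, 1\]).
#' @param condition `"WT"` or `"KO"` (MKI67 knockout).
#' @param phase Mitotic phase: one of `"prometaphase"`, `"metaphase"`,
#'   `"ana_telophase"`, `"cytokinesis"`.
#' @param gene_id Identifier of the stained protein.
#' @return An object of class `mitotic_image_pair`.
#' @export
mitotic_image_pair <- function(dapi, protein, condition, phase,
                               gene_id = "") {
  dapi <- as.matrix(dapi); protein <- as.matrix(protein)
  if (!identical(dim(dapi), dim(protein))) {
    abort("dapi and protein channels must have identical shape, got ",
          paste(dim(dapi), collapse = "x"), " vs ",
          paste(dim(protein), collapse = "x"))
  }
  if (!all(is.finite(dapi)) || !all(is.finite(protein))) {
    abort("intensities must be finite")
  }
  if (min(dapi) < 0 || min(protein) < 0) abort("intensities must be non-negative")
  condition <- match.arg(condition, .conditions)
  phase <- match.arg(phase, .phases)
  structure(list(dapi = dapi, protein = protein, condition = condition,
                 phase = phase, gene_id = as.character(gene_id)),
            class = "mitotic_image_pair")
}

#' @export
print.mitotic_image_pair <- function(x, ...) {
  cat(sprintf("<mitotic_image_pair> %s %s %s, %dx%d px\n",
              x$gene_id, x$condition, x$phase, nrow(x$dapi), ncol(x$dapi)))
  invisible(x)
}

.read_channel <- function(path) {
  img <- EBImage::readImage(path)          # scales by dtype max -> [0, 1]
  d <- dim(img)
  if (length(d) > 2L && d[3] > 1L) {
    abort("multi-channel image not supported: ", path)
  }
  m <- EBImage::imageData(img)
  dim(m) <- d[1:2]
  m
}

#' Read a two-channel mitotic image pair from single-channel image files
#'
#' Each channel is a single-channel TIFF or PNG; intensities are converted
#' to a common real scale in \[0, 1\] by dividing by the maximum value of
#' the stored integer type (not by the per-image maximum), so colocalization
#' values are comparable across images.
#'
#' @param dapi_path,protein_path Paths to the DAPI and protein channels.
#' @inheritParams mitotic_image_pair
#' @return A [mitotic_image_pair()].
#' @export
read_image_pair <- function(dapi_path, protein_path, condition, phase,
                            gene_id = "") {
  mitotic_image_pair(.read_channel(dapi_path), .read_channel(protein_path),
                     condition = condition, phase = phase, gene_id = gene_id)
}

#' Write one channel of an image pair to TIFF or PNG
#'
#' @param channel Numeric matrix in \[0, 1\].
#' @param path Output path; format follows the extension.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_channel <- function(channel, path, bits = 16L) {
  EBImage::writeImage(EBImage::Image(channel), path, bits.per.sample = bits)
  invisible(path)
}
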