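#' Subcellular location vocabulary
#'
#' The controlled vocabulary of subcellular structures used by annotation
#' tables. The registry is pre-seeded with the 33 structure classes of the
#' HPA Cell Atlas image annotation scheme (in snake_case) plus the
#' `nucleoli_rim` and `mitotic_chromosome` terms used by this package.
#' The registry is open: readers preserve unknown terms verbatim and warn
#' rather than fail, so project-specific vocabulary can flow through.
#'
#' @return Character vector of known location terms.
#' @export
location_registry <- function() {
  c(
    "actin_filaments", "aggresome", "cell_junctions", "centriolar_satellite",
    "centrosome", "cytokinetic_bridge", "cytoplasmic_bodies", "cytosol",
    "endoplasmic_reticulum", "endosomes", "focal_adhesion_sites",
    "golgi_apparatus", "intermediate_filaments", "lipid_droplets",
    "lysosomes", "microtubule_ends", "microtubules", "midbody",
    "midbody_ring", "mitochondria", "mitotic_spindle", "nuclear_bodies",
    "nuclear_membrane", "nuclear_speckles", "nucleoli",
    "nucleoli_fibrillar_center", "nucleoplasm", "peroxisomes",
    "plasma_membrane", "rods_and_rings", "vesicles", "nucleoli_rim",
    "mitotic_chromosome",
    # aliases kept for convenience in small hand-written tables
    "fibrillar_center"
  )
}

.reliability_levels <- c("enhanced", "supported", "approved", "uncertain")
.recruitment_levels <- c("none", "early", "late", "unresolved")

#' Construct a protein annotation table
#'
#' Builds and validates the central annotation structure: one row per
#' protein, with its set of subcellular locations, a location reliability
#' score, whether it shows the nucleoli-rim staining pattern, and its
#' mitotic-chromosome recruitment phase. Optional boolean columns carry
#' externally derived labels (pan-dependency, unfavorable prognosis).
#'
#' @param gene_id Character vector of unique protein/gene identifiers.
#' @param locations List of character vectors (one non-empty set per protein)
#'   of location terms; see [location_registry()].
#' @param reliability One of `"enhanced"`, `"supported"`, `"approved"`,
#'   `"uncertain"` per protein.
#' @param rim Logical; `TRUE` requires `"nucleoli_rim"` among `locations`.
#' @param mitotic_recruitment One of `"none"`, `"early"`, `"late"`,
#'   `"unresolved"` per protein.
#' @param pan_dependent,unfavorable Optional logical vectors (`NA` allowed).
#' @return A tibble of class `protein_annotation` with a list-column
#'   `locations`.
#' @export
protein_annotation <- function(gene_id, locations, reliability, rim,
                               mitotic_recruitment,
                               pan_dependent = NA, unfavorable = NA) {
  gene_id <- as.character(gene_id)
  n <- length(gene_id)
  if (n == 0L) {
    out <- tibble::tibble(
      gene_id = character(), locations = list(), reliability = character(),
      rim = logical(), mitotic_recruitment = character(),
      pan_dependent = logical(), unfavorable = logical()
    )
    class(out) <- c("protein_annotation", class(out))
    return(out)
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    abort("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  }
  if (!is.list(locations)) locations <- as.list(locations)
  locations <- lapply(locations, as.character)
  if (any(lengths(locations) == 0L)) {
    abort("every protein needs a non-empty locations set")
  }
  reliability <- as.character(reliability)
  bad <- setdiff(unique(reliability), .reliability_levels)
  if (length(bad)) abort("unknown reliability score: ", paste(bad, collapse = ", "))
  mitotic_recruitment <- as.character(mitotic_recruitment)
  bad <- setdiff(unique(mitotic_recruitment), .recruitment_levels)
  if (length(bad)) abort("unknown mitotic_recruitment phase: ", paste(bad, collapse = ", "))
  rim <- as.logical(rim)
  rim_no_term <- rim & !vapply(locations, function(l) "nucleoli_rim" %in% l, logical(1))
  if (any(rim_no_term)) {
    abort("rim = TRUE but 'nucleoli_rim' missing from locations for: ",
          paste(gene_id[rim_no_term], collapse = ", "))
  }
  unknown <- setdiff(unique(unlist(locations)), location_registry())
  if (length(unknown)) {
    warning("unknown location terms preserved verbatim: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    gene_id = gene_id,
    locations = locations,
    reliability = reliability,
    rim = rim,
    mitotic_recruitment = mitotic_recruitment,
    pan_dependent = as.logical(rep_len(pan_dependent, n)),
    unfavorable = as.logical(rep_len(unfavorable, n))
  )
  class(out) <- c("protein_annotation", class(out))
  out
}

.annotation_cols <- c("gene_id", "locations", "reliability", "rim",
                      "mitotic_recruitment")

#' Read a protein annotation table from TSV
#'
#' The file is UTF-8, tab-separated, with a mandatory header and optional
#' `#` comment lines. The `locations` column holds semicolon-separated
#' terms. Columns `pan_dependent` and `unfavorable` are optional; missing
#' entries become `NA`.
#'
#' @param path Path to a TSV file.
#' @return A `protein_annotation` tibble.
#' @seealso [write_annotation_table()] for the inverse.
#' @export
read_annotation_table <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character",
                   fileEncoding = "UTF-8")
  missing <- setdiff(.annotation_cols, names(df))
  if (length(missing)) {
    abort("missing mandatory column: ", paste(missing, collapse = ", "))
  }
  opt <- function(col) {
    if (col %in% names(df)) .parse_logical(df[[col]]) else rep(NA, nrow(df))
  }
  protein_annotation(
    gene_id = df$gene_id,
    locations = strsplit(df$locations, ";", fixed = TRUE),
    reliability = df$reliability,
    rim = .parse_logical(df$rim),
    mitotic_recruitment = df$mitotic_recruitment,
    pan_dependent = opt("pan_dependent"),
    unfavorable = opt("unfavorable")
  )
}

.parse_logical <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "True", "true", "1")] <- TRUE
  out[x %in% c("FALSE", "False", "false", "0")] <- FALSE
  out
}

#' Write a protein annotation table to TSV
#'
#' @param annotations A `protein_annotation` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  df <- data.frame(
    gene_id = annotations$gene_id,
    locations = vapply(annotations$locations, paste, character(1), collapse = ";"),
    reliability = annotations$reliability,
    rim = annotations$rim,
    mitotic_recruitment = annotations$mitotic_recruitment,
    pan_dependent = annotations$pan_dependent,
    unfavorable = annotations$unfavorable,
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
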