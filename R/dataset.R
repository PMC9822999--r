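#' Cell-type palette used throughout the package
#'
#' The default palette of segmented-cell phenotype labels for breast-tumor
#' immune microenvironment images: tumor and stromal compartments, the main
#' lymphoid and myeloid populations, and T-cell subtypes split by PD-1 status
#' (`PD1high` marks exhaustion-like cells, the defining feature of the IE1
#' immune environment).
#'
#' @return Character vector of cell-type labels.
#' @export
default_palette <- function() {
  c("tumor", "fibroblast", "endothelial", "B", "plasma", "NK", "NKT",
    "pDC", "migDC", "myeloid", "Treg",
    "T_CD4_PD1high", "T_CD4_PD1low", "T_CD8_PD1high", "T_CD8_PD1low")
}

#' Default cytokine probe panel
#'
#' Ten chemokine/cytokine mRNA probes measured alongside the `DapB`
#' negative-control probe. `DapB` is a bacterial transcript absent from human
#' tissue; its per-cell signal estimates the probe background and is never
#' listed as a cytokine.
#'
#' @return Character vector of probe names (excluding `DapB`).
#' @export
default_cytokines <- function() {
  c("CXCL9", "CXCL10", "CXCL13", "CCL2", "CCL4",
    "CCL5", "CCL17", "CCL18", "CCL22", "CSF1")
}

TLS_LEVELS <- c("none", "immature", "mature")
IE_LEVELS <- c("IE1", "IE2")

#' Construct a dataset of per-cell imaging records
#'
#' Bundles the three tables of the data model (cells, images, patients) with
#' the declared cell-type palette and cytokine panel into a validated
#' `tme_dataset` object, the substrate consumed by every analysis stage.
#'
#' @param cells data.frame with columns `cell_id`, `image_id`, `x_um`, `y_um`,
#'   `radius_um`, `cell_type`, plus any number of `mk_<marker>` intensity,
#'   `cy_<probe>` cytokine count (`cy_DapB` mandatory when any `cy_` column is
#'   present) and `gx_<gene>` count columns.
#' @param images data.frame with columns `image_id`, `patient_id`, `width_um`,
#'   `height_um`, `tls_status` (one of `"none"`, `"immature"`, `"mature"`).
#' @param patients data.frame with columns `patient_id`, `ie_label` (`"IE1"`
#'   or `"IE2"`) and optional `grade`.
#' @param palette ordered character vector of allowed cell-type labels.
#' @param cytokines ordered character vector of cytokine probe names
#'   (excluding `DapB`); defaults to the `cy_` columns present.
#' @param validate logical; run [validate_dataset()] (default `TRUE`).
#' @return An object of class `tme_dataset`.
#' @export
tme_dataset <- function(cells, images, patients,
                        palette = default_palette(),
                        cytokines = NULL, validate = TRUE) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  images <- as.data.frame(images, stringsAsFactors = FALSE)
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  if (is.null(cytokines)) {
    cyc <- grep("^cy_", names(cells), value = TRUE)
    cytokines <- sub("^cy_", "", setdiff(cyc, "cy_DapB"))
  }
  ds <- structure(
    list(cells = cells, images = images, patients = patients,
         palette = palette, cytokines = cytokines),
    class = "tme_dataset")
  if (validate) validate_dataset(ds)
  ds
}

#' @export
print.tme_dataset <- function(x, ...) {
  cat(sprintf(
    "tme_dataset: %d cells | %d images | %d patients | %d cell types | %d cytokines\n",
    nrow(x$cells), nrow(x$images), nrow(x$patients),
    length(x$palette), length(x$cytokines)))
  invisible(x)
}

marker_cols <- function(cells) grep("^mk_", names(cells), value = TRUE)
cytokine_cols <- function(cells) grep("^cy_", names(cells), value = TRUE)
gene_cols <- function(cells) grep("^gx_", names(cells), value = TRUE)

CELL_MANDATORY <- c("cell_id", "image_id", "x_um", "y_um", "radius_um", "cell_type")
IMAGE_MANDATORY <- c("image_id", "patient_id", "width_um", "height_um", "tls_status")
PATIENT_MANDATORY <- c("patient_id", "ie_label")

#' Validate a dataset against the data-model invariants
#'
#' Checks schema (mandatory columns), referential integrity (every cell's
#' image and every image's patient resolve), dataset-wide `cell_id`
#' uniqueness, positive radii, centroids inside the parent image bounds,
#' palette membership of every `cell_type`, presence of the `cy_DapB`
#' negative-control column whenever any cytokine probe column exists, and the
#' levels of `tls_status` and `ie_label`.
#'
#' @param ds a `tme_dataset`.
#' @param area_filter optional length-2 numeric `c(min_px, max_px)`; when
#'   supplied, cells whose disk area (in square micrometers, 1 px = 1 um)
#'   falls outside this range are reported as a validation error. Exposes the
#'   upstream segmentation-size filter as an opt-in rule rather than applying
#'   it silently.
#' @return `ds`, invisibly, on success; otherwise an error is thrown whose
#'   message names the offending column/ids.
#' @export
validate_dataset <- function(ds, area_filter = NULL) {
  stopifnot(inherits(ds, "tme_dataset"))
  cells <- ds$cells; images <- ds$images; patients <- ds$patients

  miss <- setdiff(CELL_MANDATORY, names(cells))
  if (length(miss)) stop("schema error: cells table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(IMAGE_MANDATORY, names(images))
  if (length(miss)) stop("schema error: images table missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(PATIENT_MANDATORY, names(patients))
  if (length(miss)) stop("schema error: patients table missing column(s): ",
                         paste(miss, collapse = ", "))

  dup <- cells$cell_id[duplicated(cells$cell_id)]
  if (length(dup)) stop("uniqueness error: duplicated cell_id(s): ",
                        paste(unique(dup), collapse = ", "))
  dangling <- setdiff(cells$image_id, images$image_id)
  if (length(dangling)) stop("referential error: cells reference unknown image_id(s): ",
                             paste(dangling, collapse = ", "))
  dangling <- setdiff(images$patient_id, patients$patient_id)
  if (length(dangling)) stop("referential error: images reference unknown patient_id(s): ",
                             paste(dangling, collapse = ", "))

  if (nrow(images)) {
    if (any(images$width_um <= 0 | images$height_um <= 0))
      stop("domain error: image width/height must be positive")
    bad <- !(images$tls_status %in% TLS_LEVELS)
    if (any(bad)) stop("domain error: tls_status must be one of ",
                       paste(TLS_LEVELS, collapse = "/"), "; offending image(s): ",
                       paste(images$image_id[bad], collapse = ", "))
  }
  if (nrow(patients)) {
    bad <- !(patients$ie_label %in% IE_LEVELS)
    if (any(bad)) stop("domain error: ie_label must be IE1 or IE2; offending patient(s): ",
                       paste(patients$patient_id[bad], collapse = ", "))
  }
  if (nrow(cells)) {
    if (any(!is.finite(cells$radius_um) | cells$radius_um <= 0))
      stop("domain error: radius_um must be positive for all cells; offending cell(s): ",
           paste(utils::head(cells$cell_id[!is.finite(cells$radius_um) | cells$radius_um <= 0], 5),
                 collapse = ", "))
    bad <- !(cells$cell_type %in% ds$palette)
    if (any(bad)) stop("domain error: cell_type outside declared palette: ",
                       paste(unique(cells$cell_type[bad]), collapse = ", "))
    idx <- match(cells$image_id, images$image_id)
    oob <- cells$x_um < 0 | cells$y_um < 0 |
      cells$x_um > images$width_um[idx] | cells$y_um > images$height_um[idx]
    if (any(oob)) stop("domain error: centroid outside image bounds for cell(s): ",
                       paste(utils::head(cells$cell_id[oob], 5), collapse = ", "))
    cyc <- cytokine_cols(cells)
    if (length(cyc) && !("cy_DapB" %in% cyc))
      stop("schema error: cytokine probe columns present but cy_DapB missing")
    num_cols <- c(marker_cols(cells), cyc, gene_cols(cells))
    for (cl in num_cols) {
      v <- cells[[cl]]
      if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
        stop("domain error: column ", cl, " must be finite and non-negative")
    }
    extra <- setdiff(ds$cytokines, sub("^cy_", "", cyc))
    if (length(cyc) && length(extra))
      stop("schema error: declared cytokine(s) without cy_ column: ",
           paste(extra, collapse = ", "))
    if (!is.null(area_filter)) {
      area <- pi * cells$radius_um^2
      bad <- area < area_filter[1] | area > area_filter[2]
      if (any(bad)) stop("area filter: ", sum(bad), " cell(s) outside [",
                         area_filter[1], ", ", area_filter[2], "] px, e.g. ",
                         paste(utils::head(cells$cell_id[bad], 5), collapse = ", "))
    }
  }
  invisible(ds)
}

#' Write a dataset to a directory of delimited tables
#'
#' Emits `cells.csv`, `images.csv`, `patients.csv` (UTF-8, comma-delimited,
#' `.` decimal separator, header row) plus a small `header.yaml` recording the
#' declared palette and cytokine panel so that [read_dataset()] restores the
#' dataset exactly, including label order. Numeric fields are written with 15
#' significant digits.
#'
#' @param ds a valid `tme_dataset`.
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("I/O error: cannot create directory ", path)
  write_tab <- function(df, file) {
    df2 <- df
    for (cl in names(df2)) if (is.numeric(df2[[cl]]) && !is.integer(df2[[cl]]))
      df2[[cl]] <- formatC(df2[[cl]], digits = 15, format = "g")
    utils::write.csv(df2, file.path(path, file), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  write_tab(ds$cells, "cells.csv")
  write_tab(ds$images, "images.csv")
  write_tab(ds$patients, "patients.csv")
  yaml::write_yaml(list(palette = as.list(ds$palette),
                        cytokines = as.list(ds$cytokines)),
                   file.path(path, "header.yaml"))
  invisible(path)
}

#' Read a dataset from a directory of delimited tables
#'
#' Inverse of [write_dataset()]. Columns prefixed `mk_`, `cy_` and `gx_` are
#' preserved as marker-intensity, cytokine-probe and gene-count mappings.
#' Parsing is locale-independent (`.` decimal separator always). If
#' `header.yaml` is absent, the palette defaults to the sorted set of observed
#' cell types and the cytokine list to the `cy_` columns minus `DapB`.
#'
#' @param path directory containing `cells.csv`, `images.csv`, `patients.csv`.
#' @param validate run [validate_dataset()] after reading (default `TRUE`).
#' @return A `tme_dataset`.
#' @export
read_dataset <- function(path, validate = TRUE) {
  for (f in c("cells.csv", "images.csv", "patients.csv"))
    if (!file.exists(file.path(path, f)))
      stop("I/O error: missing table ", f, " in ", path)
  read_tab <- function(file) {
    utils::read.csv(file.path(path, file), stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8",
                    numerals = "no.loss")
  }
  cells <- read_tab("cells.csv")
  images <- read_tab("images.csv")
  patients <- read_tab("patients.csv")
  hdr <- file.path(path, "header.yaml")
  palette <- NULL; cytokines <- NULL
  if (file.exists(hdr)) {
    h <- yaml::read_yaml(hdr)
    palette <- unlist(h$palette); cytokines <- unlist(h$cytokines)
    if (is.null(cytokines)) cytokines <- character(0)
  }
  if (is.null(palette)) palette <- sort(unique(cells$cell_type))
  ds <- tme_dataset(cells, images, patients, palette = palette,
                    cytokines = cytokines, validate = FALSE)
  if (validate) validate_dataset(ds)
  ds
}

# cells of one image, preserving row order
image_cells <- function(ds, image_id) {
  ds$cells[ds$cells$image_id == image_id, , drop = FALSE]
}
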