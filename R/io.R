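#' Write a 3D/4D volume as NIfTI-1
#'
#' @param data Numeric array (3D or 4D) or a [bold_series()] / `fc_map` /
#'   `atlas_parcellation` object.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param affine 4 x 4 voxel-to-mm affine (taken from the object when
#'   omitted).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(data, path, affine = NULL) {
  if (inherits(data, "bold_series")) {
    if (is.null(affine)) affine <- data$affine
    data <- data$data
  } else if (inherits(data, "fc_map")) {
    if (is.null(affine)) affine <- data$affine
    data <- data$z_values
  } else if (inherits(data, "atlas_parcellation")) {
    if (is.null(affine)) affine <- data$affine
    data <- data$labels
  }
  img <- RNifti::asNifti(data)
  if (!is.null(affine))
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path File path.
#' @return A list with `data` (array) and `affine`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim = dim(img)),
       affine = structure(unclass(RNifti::xform(img)), dimnames = NULL))
}

#' Write a table as TSV
#'
#' @param df Data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path File path.
#' @return Data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return Path or JSON string.
#' @export
write_qc_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
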