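#' @include AllClasses.R
NULL

# All volumes entering the pipeline pass through readLabelVolume(), which
# reorients to a single canonical axis convention ("RAS") so downstream
# voxel-space matching is well defined. Grids are never resampled: paired
# volumes on different grids are rejected.

CANONICAL_ORIENTATION <- "RAS"

#' Read a 3D label volume from NIfTI
#'
#' Reads a single-channel 3D NIfTI file, checks that the data are
#' non-negative integers, takes voxel spacing from the header, and
#' reorients the voxel data to the canonical axis convention so that all
#' downstream computation shares one frame. 4D inputs, missing/invalid
#' spacing and non-integer data are rejected with the offending field
#' named.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [LabelVolume-class] in canonical orientation.
#' @seealso [writeLabelVolume()]
#' @export
readLabelVolume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("format error in '%s': field 'dim' is %dD, expected a 3D single-channel volume",
                 path, length(d)))
  # reorient to canonical frame when the header defines an orientation
  if (!identical(RNifti::orientation(img), CANONICAL_ORIENTATION)) {
    xf <- RNifti::xform(img)
    if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0)
      RNifti::orientation(img) <- CANONICAL_ORIENTATION
  }
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop(sprintf("format error in '%s': field 'pixdim' has missing or non-positive spacing", path))
  v <- as.array(img)
  if (any(v != round(v)))
    stop(sprintf("format error in '%s': field 'datatype' holds non-integer voxel values", path))
  if (any(v < 0))
    stop(sprintf("format error in '%s': negative label values", path))
  arr <- array(as.integer(v), dim = dim(img))
  orig <- tryCatch(as.numeric(RNifti::xform(img)[1:3, 4]),
                   error = function(e) c(0, 0, 0))
  LabelVolume(arr, spacing = as.numeric(sp[1:3]), origin = orig,
              orientation = CANONICAL_ORIENTATION)
}

#' Write a LabelVolume to NIfTI
#'
#' Writes voxels, spacing and origin with a canonical-orientation sform,
#' so that [readLabelVolume()] round-trips voxels, spacing and origin
#' exactly for both `.nii` and `.nii.gz`.
#'
#' @param vol a [LabelVolume-class].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
writeLabelVolume <- function(vol, path) {
  stopifnot(is(vol, "LabelVolume"))
  validObject(vol)
  img <- RNifti::asNifti(vol@voxels)
  RNifti::pixdim(img) <- vol@spacing
  m <- diag(c(vol@spacing, 1))
  m[1:3, 4] <- vol@origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Lesion sidecar

SIDECAR_COLUMNS <- c("lesion_id", "category", "station_or_organ", "invasion",
                     "etiology_class", "etiology", "diameter_mm",
                     "center_x_mm", "center_y_mm", "center_z_mm")

#' Read and validate a lesion sidecar table
#'
#' A sidecar carries per-lesion metadata the masks themselves cannot:
#' the T/N/M category, nodal station or organ label, named invasion
#' flags (";"-separated), and, for rows describing non-tumour uptake,
#' the aetiology class and label assigned by an expert reading. Optional
#' columns give a diameter override in mm and a world-space marker point
#' (`center_*_mm`) used to attach aetiology annotations to predicted
#' false-positive components.
#'
#' @param path CSV or JSON file. JSON must be an array of row objects.
#' @return validated data.frame with the canonical sidecar columns.
#' @export
readSidecar <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(x) == 0) data.frame(lesion_id = character(), category = character())
    else as.data.frame(x, stringsAsFactors = FALSE)
  } else {
    readCsvProv(path)
  }
  validateSidecar(df)
}

#' @rdname readSidecar
#' @param df data.frame of sidecar rows.
#' @export
validateSidecar <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    out <- data.frame(matrix(nrow = 0, ncol = length(SIDECAR_COLUMNS)))
    names(out) <- SIDECAR_COLUMNS
    return(out)
  }
  if (!all(c("lesion_id", "category") %in% names(df)))
    stop("sidecar must contain columns 'lesion_id' and 'category'")
  df$lesion_id <- as.character(df$lesion_id)
  if (anyDuplicated(df$lesion_id))
    stop("sidecar validation error: duplicate lesion_id: ",
         paste(unique(df$lesion_id[duplicated(df$lesion_id)]), collapse = ", "))
  bad <- setdiff(unique(df$category), categoryLevels())
  if (length(bad))
    stop("sidecar validation error: category outside {T, N, M}: ",
         paste(bad, collapse = ", "))
  if ("etiology_class" %in% names(df)) {
    known <- c(etiologyLevels(), NA_character_, "")
    badE <- setdiff(unique(df$etiology_class), known)
    if (length(badE))
      stop("sidecar validation error: unknown etiology_class: ",
           paste(badE, collapse = ", "))
  }
  for (cl in setdiff(SIDECAR_COLUMNS, names(df)))
    df[[cl]] <- if (cl %in% c("diameter_mm", "center_x_mm", "center_y_mm",
                              "center_z_mm")) NA_real_ else NA_character_
  df[, SIDECAR_COLUMNS, drop = FALSE]
}

#' @rdname readSidecar
#' @param path output `.csv` or `.json` path.
#' @param provenance optional named list written as CSV comment header.
#' @export
writeSidecar <- function(df, path, provenance = NULL) {
  df <- validateSidecar(df)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    writeCsvProv(df, path, provenance)
  }
  invisible(path)
}

# Assert two volumes live on the same grid (shape + spacing); the
# package refuses to resample silently.
#' @keywords internal
#' @noRd
assertSameGrid <- function(a, b, what = "volumes") {
  if (!identical(dim(a@voxels), dim(b@voxels)))
    stop(sprintf("grid mismatch: %s have shapes %s vs %s (resampling is not performed)",
                 what, paste(dim(a@voxels), collapse = "x"),
                 paste(dim(b@voxels), collapse = "x")))
  if (max(abs(a@spacing - b@spacing)) > 1e-6)
    stop(sprintf("grid mismatch: %s have spacings %s vs %s", what,
                 paste(format(a@spacing), collapse = "x"),
                 paste(format(b@spacing), collapse = "x")))
  invisible(TRUE)
}
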