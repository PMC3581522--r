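#' Read a 3D volume from a NIfTI file
#'
#' Reads `.nii` / `.nii.gz`. A 4D file whose fourth dimension is a singleton
#' is accepted and squeezed to 3D. The NIfTI header is carried opaquely in
#' the returned object and round-trips unchanged through [writeVolume()];
#' it is never used for resampling.
#'
#' @param path path to a NIfTI file.
#' @return a [BrainVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI header/data in '",
                                           path, "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
  if (length(d) != 3L)
    stop("not a 3D volume: '", path, "' has dimensions ",
         paste(dim(img), collapse = "x"))
  vox <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vox) | vox <= 0)) vox <- c(1, 1, 1)
  new("BrainVolume", data = array(as.numeric(img), dim = d),
      voxelSize = as.numeric(vox), geometry = RNifti::niftiHeader(img))
}

#' Write a volume to a NIfTI file
#'
#' Values are stored as 64-bit float, so finite voxel values and `NaN`
#' sentinels round-trip exactly and masks reread as exact 0/1.
#'
#' @param img a [BrainVolume-class] (or subclass).
#' @param path output path (`.nii` or `.nii.gz`); parent directory must
#'   exist.
#' @return invisibly, `path`.
#' @export
writeVolume <- function(img, path) {
  stopifnot(is(img, "BrainVolume"))
  if (!dir.exists(dirname(path)))
    stop("unwritable path (no such directory): ", dirname(path))
  arr <- array(as.numeric(img@data), dim = dim(img@data))
  if (!is.null(img@geometry)) {
    nif <- RNifti::asNifti(arr, reference = img@geometry)
  } else {
    nif <- RNifti::asNifti(arr)
    RNifti::pixdim(nif) <- img@voxelSize
  }
  RNifti::writeNifti(nif, path, datatype = "double")
  invisible(path)
}

#' Assert that two volumes share a grid
#'
#' Joint analyses require identical shapes and voxel sizes (within 1e-5 mm);
#' a mismatch is an error, never a silent interpolation.
#'
#' @param a,b [BrainVolume-class] / [MaskVolume-class] objects.
#' @return invisibly `TRUE` on success.
#' @export
assertSameGrid <- function(a, b) {
  da <- dim(a@data); db <- dim(b@data)
  if (!identical(da, db))
    stop("grid mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  if (any(abs(a@voxelSize - b@voxelSize) > 1e-5))
    stop("voxel size mismatch: (", paste(format(a@voxelSize), collapse = ", "),
         ") vs (", paste(format(b@voxelSize), collapse = ", "), ") mm")
  invisible(TRUE)
}

#' Build a binary mask from parcellation labels
#'
#' Union semantics: the mask is 1 exactly where the label value is in
#' `wanted` (ids or parcel names from the label table), mirroring the use of
#' several atlas parcels as a single volume of interest.
#'
#' @param labels a [LabelVolume-class].
#' @param wanted integer label ids, or character parcel names.
#' @return a [MaskVolume-class] on the same grid.
#' @export
maskFromLabels <- function(labels, wanted) {
  stopifnot(is(labels, "LabelVolume"), length(wanted) >= 1L)
  if (is.character(wanted)) {
    unknown <- setdiff(wanted, names(labels@labelTable))
    if (length(unknown))
      stop("unknown parcel name(s): ", paste(unknown, collapse = ", "))
    ids <- labels@labelTable[wanted]
  } else {
    ids <- as.integer(wanted)
    unknown <- setdiff(ids, labels@labelTable)
    if (length(unknown))
      stop("unknown label id(s): ", paste(unknown, collapse = ", "))
  }
  new("MaskVolume", data = (labels@data %in% ids) + array(0, dim(labels@data)),
      voxelSize = labels@voxelSize, geometry = labels@geometry)
}

.validateManifest <- function(m) {
  need <- c("id", "group", "age", "sex")
  missingCols <- setdiff(need, names(m))
  if (length(missingCols))
    stop("manifest lacks column(s): ", paste(missingCols, collapse = ", "))
  if (anyDuplicated(m$id)) stop("manifest ids must be unique")
  if (!all(m$group %in% c("control", "patient")))
    stop("group must be coded 'control'/'patient'")
  if (!all(c("control", "patient") %in% m$group))
    stop("both groups must be non-empty")
  if (any(!is.finite(m$age))) stop("ages must be finite")
  if (!all(m$sex %in% c(0, 1))) stop("sex must be coded 0/1")
  invisible(m)
}

#' Read or validate a cohort manifest
#'
#' The manifest binds each image to its diagnosis and nuisance covariates.
#' CSV with header columns `id,group,age,sex,path`; `group` coded literally
#' `"control"`/`"patient"`, `sex` coded 0/1. `path` may be omitted when the
#' volumes are passed in memory.
#'
#' @param path CSV file path.
#' @return a validated data.frame.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validateManifest(m)
  m
}

#' @rdname readManifest
#' @param manifest a manifest data.frame to write.
#' @export
writeManifest <- function(manifest, path) {
  .validateManifest(manifest)
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
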