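#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file into a [VoxelVolume-class], taking the voxel spacing
#' from the header pixdims and the grid-to-world affine from the header
#' sform/qform. Intensities are returned unmodified. Voxel indices are
#' 0-based, matching the NIfTI affine convention.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A [VoxelVolume-class].
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(VoxelVolume(array(rnorm(60), c(5, 4, 3)), c(1, 1, 3)), f)
#' v <- readVolume(f)
#' voxelSpacing(v)
#' @export
readVolume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    cmbStop("cmbrst_missing_file", "volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    cmbStop("cmbrst_not_3d", "not a 3D volume: %s has %d dimensions",
            path, length(d))
  arr <- array(as.numeric(img), dim = d)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  dt <- det(aff)
  if (!is.finite(dt) || abs(dt) < 1e-12)
    cmbStop("cmbrst_bad_affine", "non-invertible affine in %s", path)
  VoxelVolume(arr, spacing, aff)
}

#' Write a 3D volume as NIfTI
#'
#' Stores the data at double precision with the volume's spacing and affine
#' in the header, so that [readVolume()] round-trips data, spacing and
#' affine exactly.
#'
#' @param volume a 3D [VoxelVolume-class].
#' @param path output .nii or .nii.gz path.
#' @return The path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "VoxelVolume"))
  if (length(dim(volume@data)) != 3L)
    cmbStop("cmbrst_not_3d", "writeVolume requires a 3D volume")
  img <- RNifti::asNifti(structure(volume@data, pixdim = volume@spacing),
                         datatype = "double")
  aff <- structure(volume@affine, code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  img <- RNifti::`qform<-`(img, aff)
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    cmbStop("cmbrst_unwritable", "cannot write volume to %s", path)
  invisible(path)
}

#' Convert voxel indices to world coordinates
#'
#' Applies the volume's affine to 0-based voxel indices.
#'
#' @param volume a [VoxelVolume-class].
#' @param index integer vector (one voxel) or matrix with one 0-based index
#'   per row.
#' @return World mm coordinates: a vector for one voxel, else a matrix with
#'   one row per input row.
#' @examples
#' v <- VoxelVolume(array(0, c(8, 8, 4)), c(1, 1, 3))
#' voxelToWorld(v, c(1, 1, 1))   # c(1, 1, 3) mm
#' @export
voxelToWorld <- function(volume, index) {
  nd <- length(dim(volume@data))
  idx <- if (is.matrix(index)) index else matrix(index, nrow = 1L)
  if (ncol(idx) != nd)
    cmbStop("cmbrst_out_of_grid", "index must have %d components", nd)
  d <- dim(volume@data)
  if (any(idx < 0) || any(sweep(idx, 2L, d - 1L, `>`)))
    cmbStop("cmbrst_out_of_grid", "voxel index outside the grid")
  w <- volume@affine %*% rbind(t(idx), 1)
  w <- t(w[seq_len(nd), , drop = FALSE])
  if (is.matrix(index)) w else drop(w)
}

#' Convert world coordinates to (continuous) voxel indices
#'
#' Inverse of [voxelToWorld()]; returns fractional 0-based indices which
#' callers round as needed.
#'
#' @param volume a [VoxelVolume-class].
#' @param world mm coordinate vector, or matrix with one point per row.
#' @return Continuous 0-based voxel indices, same shape convention as input.
#' @export
worldToVoxel <- function(volume, world) {
  nd <- length(dim(volume@data))
  w <- if (is.matrix(world)) world else matrix(world, nrow = 1L)
  v <- solve(volume@affine) %*% rbind(t(w), 1)
  v <- t(v[seq_len(nd), , drop = FALSE])
  if (is.matrix(world)) v else drop(v)
}

candidateColumns <- c("id", "i", "j", "k", "x_mm", "y_mm", "z_mm",
                      "s3d", "s2d", "status")

emptyCandidates <- function() {
  data.frame(id = character(0), i = integer(0), j = integer(0),
             k = integer(0), x_mm = numeric(0), y_mm = numeric(0),
             z_mm = numeric(0), s3d = numeric(0), s2d = numeric(0),
             status = character(0), stringsAsFactors = FALSE)
}

#' Validate a candidate table against its source grid
#'
#' Checks the column contract, that voxel indices lie inside the grid, and
#' that stored world coordinates round-trip through the affine to within
#' half a voxel per axis.
#'
#' @param candidates candidate data.frame (see [writeCandidates()]).
#' @param volume optional source [VoxelVolume-class] for the grid checks.
#' @return TRUE invisibly; errors otherwise.
#' @export
validateCandidates <- function(candidates, volume = NULL) {
  if (!all(candidateColumns %in% names(candidates)))
    cmbStop("cmbrst_bad_table", "candidate table missing columns: %s",
            paste(setdiff(candidateColumns, names(candidates)), collapse = ", "))
  bad <- setdiff(unique(candidates$status),
                 c("pending", "passed_2d", "rejected_2d"))
  if (length(bad))
    cmbStop("cmbrst_bad_table", "invalid status value(s): %s",
            paste(bad, collapse = ", "))
  if (!is.null(volume) && nrow(candidates) > 0) {
    d <- dim(volume@data)
    idx <- as.matrix(candidates[, c("i", "j", "k")])
    if (any(idx < 0) || any(sweep(idx, 2L, d - 1L, `>`)))
      cmbStop("cmbrst_out_of_grid", "candidate voxel index outside the grid")
    back <- worldToVoxel(volume, as.matrix(candidates[, c("x_mm", "y_mm", "z_mm")]))
    if (any(abs(back - idx) > 0.5 + 1e-9))
      cmbStop("cmbrst_bad_table",
              "candidate world coordinates do not round-trip to voxel indices")
  }
  invisible(TRUE)
}

formatNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

#' Write / read a candidate table as CSV
#'
#' Columns: id, i, j, k (0-based voxel index), x_mm, y_mm, z_mm, s3d, s2d,
#' status. An absent 2D score (stage 2 skipped) is written as an empty field
#' and read back as NA. Numeric values are written at full double precision
#' so the table round-trips exactly.
#'
#' @param candidates candidate data.frame.
#' @param path CSV path to write to / read from.
#' @return `writeCandidates` returns the path invisibly; `readCandidates`
#'   returns the candidate data.frame.
#' @export
writeCandidates <- function(candidates, path) {
  validateCandidates(candidates)
  df <- candidates[, candidateColumns]
  out <- data.frame(id = as.character(df$id),
                    i = as.integer(df$i), j = as.integer(df$j),
                    k = as.integer(df$k),
                    x_mm = formatNum(df$x_mm), y_mm = formatNum(df$y_mm),
                    z_mm = formatNum(df$z_mm), s3d = formatNum(df$s3d),
                    s2d = formatNum(df$s2d),
                    status = as.character(df$status),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    cmbStop("cmbrst_unwritable", "cannot write candidates to %s", path)
  invisible(path)
}

#' @rdname writeCandidates
#' @export
readCandidates <- function(path) {
  if (!file.exists(path))
    cmbStop("cmbrst_missing_file", "candidate file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        colClasses = c(id = "character", i = "integer",
                                       j = "integer", k = "integer",
                                       x_mm = "numeric", y_mm = "numeric",
                                       z_mm = "numeric", s3d = "numeric",
                                       s2d = "numeric", status = "character"))
  if (nrow(df) == 0) return(emptyCandidates())
  df
}

#' Write / read a ground-truth lesion table as CSV
#'
#' Columns: id, x_mm, y_mm, z_mm, label with label in {definite, possible}.
#'
#' @param truth ground-truth data.frame.
#' @param path CSV path.
#' @return `writeGroundTruth` returns the path invisibly; `readGroundTruth`
#'   the data.frame.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(all(c("id", "x_mm", "y_mm", "z_mm", "label") %in% names(truth)))
  if (nrow(truth) > 0 && !all(truth$label %in% c("definite", "possible")))
    cmbStop("cmbrst_bad_table", "labels must be 'definite' or 'possible'")
  out <- data.frame(id = as.character(truth$id),
                    x_mm = formatNum(truth$x_mm),
                    y_mm = formatNum(truth$y_mm),
                    z_mm = formatNum(truth$z_mm),
                    label = as.character(truth$label),
                    stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    cmbStop("cmbrst_unwritable", "cannot write ground truth to %s", path)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  if (!file.exists(path))
    cmbStop("cmbrst_missing_file", "ground-truth file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character", x_mm = "numeric",
                                       y_mm = "numeric", z_mm = "numeric",
                                       label = "character"))
  if (nrow(df) > 0 && !all(df$label %in% c("definite", "possible")))
    cmbStop("cmbrst_bad_table", "labels must be 'definite' or 'possible'")
  df
}
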