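#' Read a NIfTI-1 volume
#'
#' Reads a 3-D NIfTI image into a [scalar_volume()] or, with
#' `as_labels = TRUE`, a [label_volume()]. Label images must be integral to
#' within `1e-6`; the label lookup table is reconstructed from the CSV
#' sidecar written by [write_nifti()] (`<path sans .nii/.nii.gz>_labels.csv`)
#' when present.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param as_labels read as an integer label volume.
#' @return a `scalar_volume` or `label_volume`.
#' @export
read_nifti <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(as.array(img)), dim(img))  # strip niftiImage attributes
  if (length(dim(a)) != 3L) stop("non-3-D image: ", path)
  pd <- RNifti::pixdim(img)[1:3]
  # xform can be rank-deficient for synthetic headers; fall back to diagonal
  grid <- tryCatch(voxel_grid(dim(a), pd, affine = unclass(RNifti::xform(img))),
                   error = function(e) voxel_grid(dim(a), pd))
  if (as_labels) {
    r <- round(a)
    if (max(abs(a - r)) > 1e-6)
      stop("non-integral labels: max deviation ", format(max(abs(a - r))))
    lt <- read_label_sidecar(label_sidecar_path(path))
    label_volume(r, grid, lt)
  } else {
    scalar_volume(a, grid, contrast = sub("\\.nii(\\.gz)?$", "", basename(path)))
  }
}

label_sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.csv")
}

read_label_sidecar <- function(csv_path) {
  if (!file.exists(csv_path)) return(NULL)
  lt <- read.csv(csv_path, stringsAsFactors = FALSE)
  lt$id <- as.integer(lt$id)
  lt
}

#' Write a volume or displacement field as NIfTI-1
#'
#' Scalar volumes are written as 3-D float64 images, label volumes as int32
#' with the lookup table in a CSV sidecar, and displacement fields as 4-D
#' images with the vector dimension last plus a text sidecar documenting the
#' sampling convention (there is no universal NIfTI warp dialect).
#'
#' @param x a `scalar_volume`, `label_volume` or `displacement_field`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  UseMethod("write_nifti")
}

#' @export
write_nifti.scalar_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$grid$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @export
write_nifti.label_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$grid$voxel_size
  RNifti::writeNifti(img, path, datatype = "int32")
  write.csv(x$label_table, label_sidecar_path(path), row.names = FALSE)
  invisible(path)
}

#' @export
write_nifti.displacement_field <- function(x, path) {
  img <- RNifti::asNifti(x$vectors)
  RNifti::pixdim(img) <- c(x$grid$voxel_size, 1)
  RNifti::writeNifti(img, path, datatype = "double")
  conv <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_convention.txt")
  writeLines(c("morphoval displacement field",
               "units: voxels; vector dimension last (x,y,z)",
               "convention: warped(x) = moving sampled at x + d(x)"), conv)
  invisible(path)
}

#' Read a displacement field written by [write_nifti()]
#' @param path path to the 4-D NIfTI field.
#' @return a `displacement_field`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  a <- array(as.vector(as.array(img)), dim(img))
  if (length(dim(a)) != 4L || dim(a)[4] != 3L)
    stop("not a displacement field (expected 4-D with 3 components): ", path)
  grid <- voxel_grid(dim(a)[1:3], RNifti::pixdim(img)[1:3])
  displacement_field(a, grid)
}
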