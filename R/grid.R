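#' Voxel grid geometry
#'
#' A voxel grid couples an array shape with a physical voxel size and a
#' 4x4 voxel-to-world affine. All volumes, label maps and displacement
#' fields in morphoval carry one. Displacements and kernel sizes are
#' expressed in voxel units throughout; world (mm) coordinates are only
#' used when writing NIfTI headers.
#'
#' @param shape integer vector of length 3, array dimensions (voxels).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = c(0.1, 0.1, 0.1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive reals")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
      stop("affine must be an invertible 4x4 matrix")
  }
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %s @ %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$voxel_size - b$voxel_size) < tol)
}

#' Scalar image volume
#'
#' @param data 3-D numeric array.
#' @param grid a [voxel_grid()]; defaults to the array shape at 0.1 mm.
#' @param contrast contrast name, e.g. `"FA"`, `"DWI"`, `"logJac"`.
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, grid = NULL, contrast = "intensity") {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("non-3-D image")
  if (is.null(grid)) grid <- voxel_grid(dim(data))
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("data shape does not match grid shape")
  if (!all(is.finite(data))) stop("scalar volume contains non-finite values")
  structure(list(grid = grid, data = data, contrast = contrast),
            class = "scalar_volume")
}

#' Integer label volume with a label lookup table
#'
#' @param data 3-D array of non-negative integers; 0 is background.
#' @param grid a [voxel_grid()].
#' @param label_table data.frame with columns `id`, `name`, `hemisphere`
#'   (one of `"left"`, `"right"`, `"midline"`). Every nonzero value in
#'   `data` must appear in `id`.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(data, grid = NULL, label_table = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("non-3-D image")
  if (is.null(grid)) grid <- voxel_grid(dim(data))
  storage.mode(data) <- "integer"
  if (any(data < 0L)) stop("labels must be non-negative")
  ids <- sort(unique(as.vector(data)))
  ids <- ids[ids != 0L]
  if (is.null(label_table)) {
    label_table <- data.frame(id = ids,
                              name = if (length(ids)) paste0("label_", ids) else character(0),
                              hemisphere = rep("midline", length(ids)),
                              stringsAsFactors = FALSE)
  }
  if (!all(c("id", "name", "hemisphere") %in% names(label_table)))
    stop("label_table needs columns id, name, hemisphere")
  if (!all(ids %in% label_table$id))
    stop("labels present in data but missing from label_table: ",
         paste(setdiff(ids, label_table$id), collapse = ", "))
  if (!all(label_table$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be left, right or midline")
  structure(list(grid = grid, data = data, label_table = label_table),
            class = "label_volume")
}

#' Per-voxel displacement field
#'
#' Displacements are in voxel units with the pull-back convention
#' `warped(x) = moving(x + d(x))`: resampling an image through the field
#' reads the moving image at the displaced location.
#'
#' @param vectors 4-D array, shape `c(grid$shape, 3)`.
#' @param grid a [voxel_grid()].
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(vectors, grid = NULL) {
  vectors <- as.array(vectors)
  d <- dim(vectors)
  if (length(d) != 4L || d[4] != 3L)
    stop("vectors must have shape (nx, ny, nz, 3)")
  if (is.null(grid)) grid <- voxel_grid(d[1:3])
  if (!identical(as.integer(d[1:3]), grid$shape))
    stop("vector array shape does not match grid")
  if (!all(is.finite(vectors))) stop("displacement field contains non-finite values")
  structure(list(grid = grid, vectors = vectors), class = "displacement_field")
}

#' Zero displacement field on a grid
#' @param grid a [voxel_grid()].
#' @export
zero_field <- function(grid) {
  displacement_field(array(0, c(grid$shape, 3L)), grid)
}

#' Multi-contrast subject image
#'
#' @param subject_id subject identifier.
#' @param contrasts named list of [scalar_volume()]s sharing one grid.
#' @return an object of class `multi_contrast`.
#' @export
multi_contrast <- function(subject_id, contrasts) {
  if (!length(contrasts) || is.null(names(contrasts)))
    stop("contrasts must be a non-empty named list")
  g <- contrasts[[1]]$grid
  for (v in contrasts) {
    if (!inherits(v, "scalar_volume")) stop("contrasts must be scalar_volumes")
    if (!same_grid(v$grid, g)) stop("all contrasts must share one grid")
  }
  structure(list(subject_id = subject_id, contrasts = contrasts, grid = g),
            class = "multi_contrast")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume '%s' %s range [%.4g, %.4g]>\n", x$contrast,
              paste(dim(x$data), collapse = "x"), min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume %s, %d labels>\n",
              paste(dim(x$data), collapse = "x"), nrow(x$label_table)))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<displacement_field %s, max |d| = %.3f vox>\n",
              paste(x$grid$shape, collapse = "x"), max(m)))
  invisible(x)
}

# magnitude image of a field (voxel units)
field_magnitude <- function(field) {
  v <- field$vectors
  sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
}
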