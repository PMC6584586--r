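# Coordinate helpers. R arrays are 1-based internally; serialized voxel
# coordinates (affines, fields) use 0-based indices, converted at the edges.

coord_arrays <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(x = array(rep.int(seq_len(nx), ny * nz), shape),
       y = array(rep(seq_len(ny), each = nx, times = nz), shape),
       z = array(rep(seq_len(nz), each = nx * ny), shape))
}

sample_array <- function(arr, xi, yi, zi, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  d <- dim(arr)
  f <- if (mode == "linear") interp3_linear else interp3_nearest
  out <- f(as.double(arr), as.integer(d),
           as.double(xi), as.double(yi), as.double(zi))
  array(out, dim(xi))
}

#' Resample a volume through a displacement field
#'
#' Pull-back warping: `out(x) = vol(x + d(x))`. Out-of-grid samples take the
#' background value 0. Label volumes require nearest-neighbour interpolation.
#'
#' @param vol a `scalar_volume` or `label_volume`.
#' @param field a `displacement_field` on the same grid.
#' @param interpolation `"linear"` (trilinear) or `"nearest"`.
#' @return a volume of the same type as `vol`.
#' @export
resample <- function(vol, field, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (!same_grid(vol$grid, field$grid)) stop("volume and field grids differ")
  if (inherits(vol, "label_volume") && interpolation == "linear")
    stop("linear interpolation requested for label volume; use nearest")
  shp <- vol$grid$shape
  if (!inherits(vol, "label_volume") && interpolation == "linear") {
    out <- array(warp3_cpp(as.double(vol$data), as.integer(shp),
                           as.double(field$vectors)), shp)
    return(scalar_volume(out, vol$grid, vol$contrast))
  }
  co <- coord_arrays(shp)
  xi <- co$x + field$vectors[, , , 1]
  yi <- co$y + field$vectors[, , , 2]
  zi <- co$z + field$vectors[, , , 3]
  if (inherits(vol, "label_volume")) {
    out <- sample_array(vol$data, xi, yi, zi, "nearest")
    label_volume(out, vol$grid, vol$label_table)
  } else {
    out <- sample_array(vol$data, xi, yi, zi, interpolation)
    scalar_volume(out, vol$grid, vol$contrast)
  }
}

#' Apply a voxel-space affine to a volume
#'
#' Pull-back convention: `out(x) = vol(A x)` with `x` in 0-based voxel
#' coordinates (homogeneous 4-vector).
#'
#' @param vol a `scalar_volume` or `label_volume`.
#' @param mat 4x4 voxel-space matrix.
#' @param interpolation `"linear"` or `"nearest"`.
#' @export
apply_affine <- function(vol, mat, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(vol, "label_volume")) interpolation <- "nearest"
  co <- coord_arrays(vol$grid$shape)
  x0 <- co$x - 1; y0 <- co$y - 1; z0 <- co$z - 1
  xi <- mat[1, 1] * x0 + mat[1, 2] * y0 + mat[1, 3] * z0 + mat[1, 4] + 1
  yi <- mat[2, 1] * x0 + mat[2, 2] * y0 + mat[2, 3] * z0 + mat[2, 4] + 1
  zi <- mat[3, 1] * x0 + mat[3, 2] * y0 + mat[3, 3] * z0 + mat[3, 4] + 1
  out <- sample_array(vol$data, xi, yi, zi, interpolation)
  if (inherits(vol, "label_volume")) label_volume(out, vol$grid, vol$label_table)
  else scalar_volume(out, vol$grid, vol$contrast)
}

#' Convert a voxel-space affine into a displacement field
#'
#' Gives `d(x) = A x - x` on 0-based voxel coordinates so affine and
#' diffeomorphic warps can be composed with [compose_fields()].
#'
#' @param mat 4x4 voxel-space matrix.
#' @param grid target [voxel_grid()].
#' @export
affine_to_field <- function(mat, grid) {
  co <- coord_arrays(grid$shape)
  x0 <- co$x - 1; y0 <- co$y - 1; z0 <- co$z - 1
  v <- array(0, c(grid$shape, 3L))
  v[, , , 1] <- mat[1, 1] * x0 + mat[1, 2] * y0 + mat[1, 3] * z0 + mat[1, 4] - x0
  v[, , , 2] <- mat[2, 1] * x0 + mat[2, 2] * y0 + mat[2, 3] * z0 + mat[2, 4] - y0
  v[, , , 3] <- mat[3, 1] * x0 + mat[3, 2] * y0 + mat[3, 3] * z0 + mat[3, 4] - z0
  displacement_field(v, grid)
}
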