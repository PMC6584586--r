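#' Spherical structuring element
#'
#' Cubic logical array of side `2r + 1`; a voxel is included iff the
#' Euclidean norm of its offset from the centre is at most `r`. For
#' `r = 2` this is the 33-voxel discrete ball.
#'
#' @param radius integer radius in voxels, at least 1.
#' @return logical array of dim `rep(2*radius + 1, 3)`.
#' @export
spherical_element <- function(radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("radius must be an integer >= 1")
  o <- seq(-radius, radius)
  g <- expand.grid(x = o, y = o, z = o)
  array(g$x^2 + g$y^2 + g$z^2 <= radius^2, rep(2L * radius + 1L, 3L))
}

element_offsets <- function(radius) {
  o <- seq(-radius, radius)
  g <- expand.grid(x = o, y = o, z = o)
  as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE])
}

# shift a 3-D array by integer offset, padding with `fill`
shift_array <- function(a, off, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    s <- off[k]
    if (s >= d[k] || -s >= d[k]) return(out)
    if (s >= 0) { dst[[k]] <- (1 + s):d[k]; src[[k]] <- 1:(d[k] - s) }
    else { dst[[k]] <- 1:(d[k] + s); src[[k]] <- (1 - s):d[k] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

as_mask <- function(mask) {
  if (inherits(mask, "scalar_volume") || inherits(mask, "label_volume"))
    mask <- mask$data
  a <- as.array(mask) != 0
  if (length(dim(a)) != 3L) stop("mask must be 3-D")
  a
}

#' Binary dilation, erosion and closing with a spherical element
#'
#' Standard Minkowski operations; voxels outside the grid are treated as
#' background, so erosion removes a boundary layer from masks touching the
#' edge. `morph_close` is dilation followed by erosion.
#'
#' @param mask logical/0-1 3-D array (or a volume object).
#' @param radius integer radius of the spherical element.
#' @return logical 3-D array.
#' @export
dilate <- function(mask, radius) {
  m <- as_mask(mask)
  offs <- element_offsets(radius)
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offs))) out <- out | shift_array(m, offs[i, ], FALSE)
  out
}

#' @rdname dilate
#' @export
erode <- function(mask, radius) {
  m <- as_mask(mask)
  offs <- element_offsets(radius)
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_array(m, -offs[i, ], FALSE)
    if (!any(out)) break
  }
  out
}

#' @rdname dilate
#' @export
morph_close <- function(mask, radius) {
  erode(dilate(mask, radius), radius)
}

# connected components, 26-connectivity, via igraph
connected_components <- function(mask) {
  m <- as_mask(mask)
  d <- dim(m)
  idx <- which(m)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  key <- (pos[, 1] - 1L) + d[1] * ((pos[, 2] - 1L) + d[2] * (pos[, 3] - 1L))
  lookup <- integer(0)
  # half-neighbourhood: 13 positive-direction offsets of the 26-neighbourhood
  offs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  offs <- offs[offs[, 1] + 3 * offs[, 2] + 9 * offs[, 3] > 0, , drop = FALSE]
  edges <- vector("list", nrow(offs))
  ord <- order(key)
  skey <- key[ord]
  for (i in seq_len(nrow(offs))) {
    np <- sweep(pos, 2L, offs[i, ], `+`)
    ok <- np[, 1] >= 1L & np[, 1] <= d[1] & np[, 2] >= 1L & np[, 2] <= d[2] &
      np[, 3] >= 1L & np[, 3] <= d[3]
    nk <- (np[ok, 1] - 1L) + d[1] * ((np[ok, 2] - 1L) + d[2] * (np[ok, 3] - 1L))
    hit <- findInterval(nk, skey)
    good <- hit > 0L & skey[pmax(hit, 1L)] == nk
    from <- which(ok)[good]
    to <- ord[hit[good]]
    edges[[i]] <- rbind(from, to)
  }
  e <- do.call(cbind, edges)
  g <- igraph::make_graph(edges = as.vector(e), n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  lab
}

largest_component <- function(mask) {
  lab <- connected_components(mask)
  if (!any(lab > 0L)) return(array(FALSE, dim(lab)))
  tab <- tabulate(lab)
  lab == which.max(tab)
}

# fill internal holes: background components not touching the grid border
fill_holes <- function(mask) {
  m <- as_mask(mask)
  lab <- connected_components(!m)
  if (!any(lab > 0L)) return(m)
  d <- dim(m)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  m | (lab > 0L & !(lab %in% border))
}

#' Skull-strip parameters
#' @param n_ops number of alternating morphological operations (default 5).
#' @param radius spherical element radius in voxels (default 2).
#' @export
skull_strip_params <- function(n_ops = 5L, radius = 2L) {
  n_ops <- as.integer(n_ops); radius <- as.integer(radius)
  if (n_ops < 1L) stop("n_ops must be >= 1")
  if (radius < 1L) stop("radius must be >= 1")
  structure(list(n_ops = n_ops, radius = radius), class = "skull_strip_params")
}

#' Histogram-threshold + morphology brain mask
#'
#' Otsu thresholding on a 256-bin intensity histogram gives the initial
#' mask; `n_ops` alternating erosions/dilations (starting with an erosion,
#' with a balancing dilation when `n_ops` is odd) denoise it, a final
#' closing seals the surface, and the largest 26-connected component with
#' internal holes filled is returned.
#'
#' @param vol a `scalar_volume` (typically a DWI-like contrast).
#' @param params a [skull_strip_params()].
#' @return logical 3-D brain mask.
#' @export
skull_strip <- function(vol, params = skull_strip_params()) {
  a <- vol$data
  rng <- range(a)
  if (diff(rng) <= 0) stop("constant image: threshold undefined")
  th <- EBImage::otsu(EBImage::Image(as.vector(a), dim = c(length(a), 1L)),
                      range = rng, levels = 256)
  m <- a > th
  if (!any(m)) stop("empty initial mask")
  n_erode <- 0L; n_dilate <- 0L
  for (i in seq_len(params$n_ops)) {
    if (i %% 2L == 1L) { m <- erode(m, params$radius); n_erode <- n_erode + 1L }
    else { m <- dilate(m, params$radius); n_dilate <- n_dilate + 1L }
  }
  if (n_erode > n_dilate) m <- dilate(m, params$radius)
  m <- morph_close(m, params$radius)
  if (!any(m)) stop("mask emptied by morphological operations")
  fill_holes(largest_component(m))
}
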