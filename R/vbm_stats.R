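#' Erode the analysis mask by the smoothing kernel size
#'
#' The template-derived brain mask is eroded with a spherical element of
#' radius `ceiling(smoothing_sigma)` so voxels whose smoothed values draw
#' on out-of-mask neighbours are excluded from the statistics.
#'
#' @param template_mask logical 3-D brain mask.
#' @param smoothing_sigma the largest smoothing sigma used, in voxels.
#' @return logical analysis mask.
#' @export
make_analysis_mask <- function(template_mask, smoothing_sigma) {
  m <- as_mask(template_mask)
  if (!any(m)) stop("empty mask")
  if (smoothing_sigma <= 0) return(m)
  out <- erode(m, ceiling(smoothing_sigma))
  if (!any(out)) stop("erosion emptied the analysis mask")
  out
}

stack_maps <- function(maps) {
  if (inherits(maps, "scalar_volume")) maps <- list(maps)
  arrs <- lapply(maps, function(m) if (inherits(m, "scalar_volume")) m$data else m)
  do.call(cbind, lapply(arrs, as.vector))
}

#' Voxelwise two-sample t-test with two one-tailed p-maps
#'
#' Pooled-variance two-sample t per in-mask voxel with
#' `df = n1 + n2 - 2`. `p_greater` is the upper-tail probability
#' (group 2 > group 1), `p_less` the lower tail; the effect map is the
#' unstandardized mean difference `mean(group2) - mean(group1)` in the
#' map's native units (for log-Jacobian maps, log volume-ratio units).
#' Benjamini-Hochberg q-maps are computed separately for each tail over
#' in-mask voxels. Zero pooled variance yields t = 0 and p = 0.5 when the
#' means are equal, and p clamped to 1e-300 (or 1) when they differ.
#' Outside the mask p- and q-maps carry the sentinel value 1.
#'
#' @param group1_maps,group2_maps lists of `scalar_volume`s (or 3-D
#'   arrays) on a common grid; at least 2 per group.
#' @param mask logical analysis mask.
#' @return object of class `stat_maps`: list of `scalar_volume`s `t`,
#'   `p_greater`, `p_less`, `effect`, `q_greater`, `q_less`, plus
#'   `analysis_mask` and `df`.
#' @export
voxelwise_ttest <- function(group1_maps, group2_maps, mask) {
  x1 <- stack_maps(group1_maps); x2 <- stack_maps(group2_maps)
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  m <- as.vector(as_mask(mask))
  grid <- if (inherits(group1_maps[[1]], "scalar_volume"))
    group1_maps[[1]]$grid else voxel_grid(dim(as_mask(mask)))
  shp <- grid$shape
  mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
  v1 <- rowSums((x1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - mu2)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  eff <- mu2 - mu1
  tval <- ifelse(se > 0, eff / ifelse(se > 0, se, 1), 0)
  pg <- pt(tval, df, lower.tail = FALSE)
  pl <- pt(tval, df, lower.tail = TRUE)
  zero_var <- se == 0
  pg[zero_var] <- ifelse(eff[zero_var] > 0, 1e-300, ifelse(eff[zero_var] < 0, 1, 0.5))
  pl[zero_var] <- ifelse(eff[zero_var] < 0, 1e-300, ifelse(eff[zero_var] > 0, 1, 0.5))
  tval[zero_var & eff == 0] <- 0
  out_map <- function(vals, sentinel = 0) {
    a <- rep(sentinel, length(m))
    a[m] <- vals[m]
    scalar_volume(array(a, shp), grid)
  }
  maps <- list(
    t = out_map(tval),
    p_greater = out_map(pg, sentinel = 1),
    p_less = out_map(pl, sentinel = 1),
    effect = out_map(eff))
  maps$q_greater <- fdr_correct(maps$p_greater, mask)
  maps$q_less <- fdr_correct(maps$p_less, mask)
  maps$analysis_mask <- as_mask(mask)
  maps$df <- df
  class(maps) <- "stat_maps"
  maps
}

#' Benjamini-Hochberg q-value map
#'
#' Step-up FDR-adjusted p-values over in-mask voxels:
#' `q(i) = min over j >= i of p(j) * m / j` on the sorted p-values,
#' clipped at 1. Outside the mask the sentinel value is 1.
#'
#' @param p_map a `scalar_volume` of p-values (or 3-D array).
#' @param mask logical analysis mask.
#' @return a `scalar_volume` of q-values.
#' @export
fdr_correct <- function(p_map, mask) {
  grid <- if (inherits(p_map, "scalar_volume")) p_map$grid
          else voxel_grid(dim(p_map))
  p <- if (inherits(p_map, "scalar_volume")) p_map$data else p_map
  m <- as_mask(mask)
  q <- array(1, dim(p))
  q[m] <- stats::p.adjust(p[m], method = "BH")
  scalar_volume(q, grid, "q")
}

#' Voxelwise permutation p-map for the group mean difference
#'
#' Permutes group labels and recomputes the mean-difference statistic per
#' voxel, in the `p_greater` direction (group 2 > group 1). When the
#' number of distinct label assignments does not exceed `n_perm` the
#' enumeration is exhaustive and `p = #(perm stat >= observed) / n_assign`
#' (the identity assignment included); otherwise `n_perm` seeded random
#' assignments give `p = (1 + #(perm stat >= observed)) / (n_perm + 1)`.
#'
#' @param group1_maps,group2_maps as in [voxelwise_ttest()].
#' @param mask logical analysis mask.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the label draws.
#' @return a `scalar_volume` p-map (sentinel 1 outside the mask); the
#'   attribute `"exhaustive"` records which branch ran.
#' @export
permutation_pmap <- function(group1_maps, group2_maps, mask, n_perm = 5000L,
                             seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  x1 <- stack_maps(group1_maps); x2 <- stack_maps(group2_maps)
  n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
  x <- cbind(x1, x2)
  m <- as.vector(as_mask(mask))
  xm <- x[m, , drop = FALSE]
  obs <- rowMeans(xm[, (n1 + 1):n, drop = FALSE]) -
    rowMeans(xm[, 1:n1, drop = FALSE])
  n_assign <- choose(n, n1)
  exhaustive <- n_assign <= n_perm
  count <- numeric(length(obs))
  stat_for <- function(g1_idx) {
    rowMeans(xm[, setdiff(seq_len(n), g1_idx), drop = FALSE]) -
      rowMeans(xm[, g1_idx, drop = FALSE])
  }
  tol <- 1e-12
  if (exhaustive) {
    combos <- combn(n, n1)
    for (k in seq_len(ncol(combos)))
      count <- count + (stat_for(combos[, k]) >= obs - tol)
    pvals <- count / ncol(combos)
  } else {
    set.seed(as.integer(seed))
    for (k in seq_len(n_perm))
      count <- count + (stat_for(sample.int(n, n1)) >= obs - tol)
    pvals <- (1 + count) / (n_perm + 1)
  }
  grid <- if (inherits(group1_maps[[1]], "scalar_volume"))
    group1_maps[[1]]$grid else voxel_grid(dim(as_mask(mask)))
  a <- rep(1, length(m))
  a[m] <- pvals
  out <- scalar_volume(array(a, grid$shape), grid, "p_perm")
  attr(out, "exhaustive") <- exhaustive
  out
}
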