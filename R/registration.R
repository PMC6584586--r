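#' Diffeomorphic registration parameters
#'
#' The three knobs swept by the validation study are the gradient `step`
#' (voxels; the "SyN" parameter), `reg_update` (Gaussian sigma, in voxels,
#' applied to each update field; "RegU") and `reg_total` (Gaussian sigma
#' applied to the accumulated total field; "RegT"). Regularizers are
#' interpreted as sigmas throughout, which preserves the relative ordering
#' of the swept values.
#'
#' @param step gradient step in voxels; each update is normalized so its
#'   largest displacement equals `min(step, 0.4)` (the cap guarantees every
#'   increment is invertible, so the composed warp stays diffeomorphic).
#' @param reg_update update-field Gaussian sigma in voxels (swept 3/5).
#' @param reg_total total-field Gaussian sigma in voxels (swept 0/0.5).
#' @param metric `"ssd"` (mean squares) or `"lncc"` (local normalized
#'   cross-correlation over a cubic window).
#' @param lncc_radius LNCC window radius in voxels.
#' @param shrink_factors per-level subsampling strides (coarse to fine).
#' @param smoothing_sigmas per-level pre-smoothing sigmas in voxels.
#' @param max_iters maximum iterations per level.
#' @param conv_threshold relative metric improvement below which the level
#'   stops.
#' @param conv_window iterations over which the improvement is measured.
#' @export
registration_params <- function(step = 0.25, reg_update = 3, reg_total = 0.5,
                                metric = c("ssd", "lncc"), lncc_radius = 4L,
                                shrink_factors = c(4L, 2L, 1L),
                                smoothing_sigmas = c(2, 1, 0),
                                max_iters = 100L, conv_threshold = 1e-8,
                                conv_window = 20L) {
  metric <- match.arg(metric)
  if (step <= 0) stop("step must be > 0")
  if (reg_update < 0 || reg_total < 0) stop("regularization sigmas must be >= 0")
  if (length(shrink_factors) != length(smoothing_sigmas))
    stop("shrink_factors and smoothing_sigmas must have equal length")
  if (conv_window < 2L) stop("conv_window must be >= 2")
  structure(list(step = step, reg_update = reg_update, reg_total = reg_total,
                 metric = metric, lncc_radius = as.integer(lncc_radius),
                 shrink_factors = as.integer(shrink_factors),
                 smoothing_sigmas = as.numeric(smoothing_sigmas),
                 max_iters = as.integer(max_iters),
                 conv_threshold = conv_threshold,
                 conv_window = as.integer(conv_window)),
            class = "registration_params")
}

# ---- array-level helpers ----------------------------------------------------

grad3 <- function(a) {
  # central differences interior, one-sided at the two boundary faces
  d <- dim(a)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    off <- integer(3L); off[ax] <- 1L
    gk <- (shift_array(a, -off) - shift_array(a, off)) / 2
    if (n >= 2L) {
      if (ax == 1L) {
        gk[1, , ] <- a[2, , ] - a[1, , ]; gk[n, , ] <- a[n, , ] - a[n - 1, , ]
      } else if (ax == 2L) {
        gk[, 1, ] <- a[, 2, ] - a[, 1, ]; gk[, n, ] <- a[, n, ] - a[, n - 1, ]
      } else {
        gk[, , 1] <- a[, , 2] - a[, , 1]; gk[, , n] <- a[, , n] - a[, , n - 1]
      }
    }
    g[[ax]] <- gk
  }
  g
}

subsample_array <- function(a, stride) {
  if (stride == 1L) return(a)
  d <- dim(a)
  a[seq(1L, d[1], by = stride), seq(1L, d[2], by = stride),
    seq(1L, d[3], by = stride), drop = FALSE]
}

# resize a field between pyramid levels with strides s_old -> s_new over a
# common full-resolution grid; displacement values are rescaled to the new
# voxel units. Level grids share voxel 1, so index j at stride s sits at
# full-resolution position (j-1)*s + 1.
rescale_field_strided <- function(v, new_dim, s_old, s_new) {
  old <- dim(v)[1:3]
  co <- coord_arrays(new_dim)
  xi <- pmin((co$x - 1) * s_new / s_old + 1, old[1])
  yi <- pmin((co$y - 1) * s_new / s_old + 1, old[2])
  zi <- pmin((co$z - 1) * s_new / s_old + 1, old[3])
  out <- array(0, c(new_dim, 3L))
  for (k in 1:3)
    out[, , , k] <- sample_array(v[, , , k], xi, yi, zi) * (s_old / s_new)
  out
}

compose_arrays <- function(outer, inner) {
  # (outer o inner)(x) = inner(x) + outer(x + inner(x))
  d <- dim(inner)
  array(compose3_cpp(as.double(outer), as.double(inner), as.integer(d[1:3])), d)
}

# quantile-match moving intensities to fixed
hist_match <- function(m, f) {
  fs <- sort(as.vector(f))
  r <- rank(as.vector(m), ties.method = "average")
  q <- (r - 0.5) / length(r)
  array(fs[pmax(1L, pmin(length(fs), ceiling(q * length(fs))))], dim(m))
}

# ---- metric forces ----------------------------------------------------------

lncc_force <- function(f, mw, r, cnt, box_f, box_ff) {
  bm <- box_sum_array(mw, r)
  bmm <- box_sum_array(mw * mw, r)
  bfm <- box_sum_array(f * mw, r)
  mf <- box_f / cnt; mm <- bm / cnt
  A <- bfm / cnt - mf * mm
  B <- box_ff / cnt - mf^2
  C <- bmm / cnt - mm^2
  den <- B * C
  ok <- den > 1e-10
  cc <- ifelse(ok, A * A / den, 0)
  fac <- ifelse(ok, 2 * A / den, 0)
  fs <- fac * ((f - mf) - ifelse(C > 1e-10, A / pmax(C, 1e-10), 0) * (mw - mm))
  g <- grad3(mw)
  fo <- array(0, c(dim(f), 3L))
  for (k in 1:3) fo[, , , k] <- fs * g[[k]]
  list(metric = -mean(cc), force = fo)
}

# ---- greedy engine ----------------------------------------------------------

greedy_level <- function(f, m, d, params) {
  dim3 <- dim(f)
  step_eff <- min(params$step, 0.4)
  metric_hist <- numeric(0)
  stop_reason <- "max_iters"
  if (params$metric == "lncc") {
    co <- coord_arrays(dim3)
    cnt <- box_sum_array(array(1, dim3), params$lncc_radius)
    box_f <- box_sum_array(f, params$lncc_radius)
    box_ff <- box_sum_array(f * f, params$lncc_radius)
  }
  w_regu <- if (params$reg_update > 0) gauss_weights(params$reg_update) else 1
  w_regt <- if (params$reg_total > 0) gauss_weights(params$reg_total) else 1
  dvec <- as.double(d)
  for (it in seq_len(params$max_iters)) {
    if (params$metric == "ssd") {
      r <- ssd_force_cpp(as.double(f), as.double(m), as.integer(dim3), dvec)
      fr <- list(metric = r$metric, force = r$force, max_mag = r$max_mag)
    } else {
      d4 <- array(dvec, c(dim3, 3L))
      xi <- co$x + d4[, , , 1]; yi <- co$y + d4[, , , 2]; zi <- co$z + d4[, , , 3]
      mw <- sample_array(m, xi, yi, zi)
      fr <- lncc_force(f, mw, params$lncc_radius, cnt, box_f, box_ff)
      fr$max_mag <- sqrt(max(fr$force[, , , 1]^2 + fr$force[, , , 2]^2 +
                               fr$force[, , , 3]^2))
      fr$force <- as.double(fr$force)
    }
    if (!is.finite(fr$metric)) {
      stop_reason <- "diverged"
      break
    }
    metric_hist <- c(metric_hist, fr$metric)
    w <- params$conv_window
    if (it > w) {
      prev <- metric_hist[it - w]
      rel <- (prev - fr$metric) / max(abs(prev), 1e-12)
      if (rel < params$conv_threshold) {
        stop_reason <- "converged"
        break
      }
    }
    if (fr$max_mag < 1e-12) {
      stop_reason <- "converged"
      break
    }
    dvec <- update_step_cpp(dvec, fr$force, as.integer(dim3),
                            step_eff / fr$max_mag, w_regu, w_regt,
                            params$reg_update > 0, params$reg_total > 0)
  }
  list(field = array(dvec, c(dim3, 3L)), metric = metric_hist,
       stop_reason = stop_reason)
}

greedy_multires <- function(fa, ma, params) {
  nlev <- length(params$shrink_factors)
  d <- NULL
  s_prev <- 1L
  trace <- vector("list", nlev)
  for (l in seq_len(nlev)) {
    s <- params$shrink_factors[l]
    sg <- params$smoothing_sigmas[l]
    fl <- subsample_array(smooth_array(fa, sg), s)
    ml <- subsample_array(smooth_array(ma, sg), s)
    d <- if (is.null(d)) array(0, c(dim(fl), 3L))
         else rescale_field_strided(d, dim(fl), s_prev, s)
    res <- greedy_level(fl, ml, d, params)
    d <- res$field
    trace[[l]] <- list(metric = res$metric, stop_reason = res$stop_reason)
    s_prev <- s
    if (res$stop_reason == "diverged") break
  }
  if (s_prev != 1L)  # engine stopped before the full-resolution level
    d <- rescale_field_strided(d, dim(fa), s_prev, 1L)
  list(field = d, trace = trace)
}

#' Greedy diffeomorphic registration
#'
#' A multi-resolution greedy engine: each iteration takes a metric-gradient
#' force, normalizes it so the largest displacement equals
#' `min(step, 0.4)` voxels, smooths it with sigma `reg_update`, composes it
#' into the total field, and optionally smooths the total field with sigma
#' `reg_total`. Forward and inverse fields are produced by two independent
#' runs with the roles of fixed and moving swapped (not exact inverses; the
#' fixed-point [invert_field()] is available when an exact inverse is
#' needed). If the fixed and moving intensity ranges differ by more than
#' 10%, the moving image is histogram-matched to the fixed one first.
#'
#' @param fixed,moving `scalar_volume`s on the same grid.
#' @param params a [registration_params()].
#' @return list with `forward` and `inverse` `displacement_field`s (both in
#'   pull-back convention: `resample(moving, forward)` approximates
#'   `fixed`) and a `trace` of per-level metric histories.
#' @export
register_diffeo <- function(fixed, moving, params = registration_params()) {
  if (!same_grid(fixed$grid, moving$grid)) stop("fixed and moving grids differ")
  fa <- fixed$data; ma <- moving$data
  rf <- diff(range(fa)); rm_ <- diff(range(ma))
  if (rf > 0 && rm_ > 0 && abs(rf - rm_) / rf > 0.10) ma <- hist_match(ma, fa)
  fwd <- greedy_multires(fa, ma, params)
  inv <- greedy_multires(ma, fa, params)
  list(forward = displacement_field(fwd$field, fixed$grid),
       inverse = displacement_field(inv$field, fixed$grid),
       trace = list(forward = fwd$trace, inverse = inv$trace))
}

#' Linear (rigid or affine) registration
#'
#' Rigid alignment uses the intensity centre of mass and principal axes;
#' affine refines all 12 parameters by BFGS on the mean-squares metric with
#' an analytic gradient. Returns a 4x4 voxel-space matrix in pull-back
#' convention: sampling `moving` at `A x` reproduces `fixed` at `x`
#' (0-based voxel coordinates).
#'
#' @param fixed,moving `scalar_volume`s on the same grid.
#' @param mode `"rigid"` or `"affine"`.
#' @return 4x4 matrix.
#' @export
register_linear <- function(fixed, moving, mode = c("affine", "rigid")) {
  mode <- match.arg(mode)
  fa <- fixed$data; ma <- moving$data
  if (all(fa == 0) || all(ma == 0)) stop("empty (all-zero) image")
  wf <- pmax(fa, 0); wm <- pmax(ma, 0)
  co <- coord_arrays(dim(fa))
  com <- function(w) {
    s <- sum(w)
    c(sum(co$x * w), sum(co$y * w), sum(co$z * w)) / s - 1  # 0-based
  }
  cf <- com(wf); cm <- com(wm)
  covw <- function(w, cc) {
    s <- sum(w)
    xs <- co$x - 1 - cc[1]; ys <- co$y - 1 - cc[2]; zs <- co$z - 1 - cc[3]
    matrix(c(sum(xs * xs * w), sum(xs * ys * w), sum(xs * zs * w),
             sum(xs * ys * w), sum(ys * ys * w), sum(ys * zs * w),
             sum(xs * zs * w), sum(ys * zs * w), sum(zs * zs * w)) / s, 3, 3)
  }
  eg_f <- eigen(covw(wf, cf), symmetric = TRUE)
  eg_m <- eigen(covw(wm, cm), symmetric = TRUE)
  ef <- eg_f$vectors; em <- eg_m$vectors
  # principal axes are undefined for near-isotropic intensity distributions;
  # fall back to a pure translation there
  gaps <- abs(diff(eg_f$values)) / max(eg_f$values)
  if (any(gaps < 0.02)) {
    R <- diag(3)
  } else {
    # fix eigenvector signs toward the rotation nearest the identity
    for (k in 1:3) if (sum(em[, k] * ef[, k]) < 0) em[, k] <- -em[, k]
    R <- em %*% t(ef)
    if (det(R) < 0) { em[, 3] <- -em[, 3]; R <- em %*% t(ef) }
  }
  A <- diag(4)
  A[1:3, 1:3] <- R
  A[1:3, 4] <- cm - R %*% cf
  if (mode == "rigid") return(A)

  # affine refinement: minimize mean((moving(Ax) - fixed(x))^2)
  gm <- grad3(ma)
  x0 <- co$x - 1; y0 <- co$y - 1; z0 <- co$z - 1
  n <- length(fa)
  obj <- function(par) {
    M <- matrix(par, 3, 4)
    xi <- M[1, 1] * x0 + M[1, 2] * y0 + M[1, 3] * z0 + M[1, 4] + 1
    yi <- M[2, 1] * x0 + M[2, 2] * y0 + M[2, 3] * z0 + M[2, 4] + 1
    zi <- M[3, 1] * x0 + M[3, 2] * y0 + M[3, 3] * z0 + M[3, 4] + 1
    mw <- sample_array(ma, xi, yi, zi)
    mean((mw - fa)^2)
  }
  grd <- function(par) {
    M <- matrix(par, 3, 4)
    xi <- M[1, 1] * x0 + M[1, 2] * y0 + M[1, 3] * z0 + M[1, 4] + 1
    yi <- M[2, 1] * x0 + M[2, 2] * y0 + M[2, 3] * z0 + M[2, 4] + 1
    zi <- M[3, 1] * x0 + M[3, 2] * y0 + M[3, 3] * z0 + M[3, 4] + 1
    mw <- sample_array(ma, xi, yi, zi)
    r <- mw - fa
    g <- matrix(0, 3, 4)
    for (i in 1:3) {
      gi <- sample_array(gm[[i]], xi, yi, zi)
      rg <- r * gi
      g[i, ] <- 2 * c(sum(rg * x0), sum(rg * y0), sum(rg * z0), sum(rg)) / n
    }
    as.vector(g)
  }
  fit <- stats::optim(as.vector(A[1:3, ]), obj, grd, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-12,
                                     parscale = c(rep(0.02, 9), rep(1, 3))))
  out <- diag(4)
  out[1:3, ] <- matrix(fit$par, 3, 4)
  out
}

#' Compose two displacement fields
#'
#' `compose_fields(outer, inner)(x) = inner(x) + outer(x + inner(x))`, i.e.
#' resampling through the result equals resampling through `inner` after
#' `outer` has been applied to the moving image.
#'
#' @param outer,inner `displacement_field`s on the same grid.
#' @export
compose_fields <- function(outer, inner) {
  if (!same_grid(outer$grid, inner$grid)) stop("field grids differ")
  displacement_field(compose_arrays(outer$vectors, inner$vectors), inner$grid)
}

#' Invert a diffeomorphic displacement field
#'
#' Fixed-point iteration `d_inv <- -d(x + d_inv(x))`, stopping when the
#' largest update falls below `tol` voxels or after `max_iters` sweeps.
#' Convergence is flagged in the `converged` attribute.
#'
#' @param field a `displacement_field` with positive Jacobian.
#' @param max_iters maximum fixed-point sweeps.
#' @param tol convergence tolerance in voxels.
#' @export
invert_field <- function(field, max_iters = 30L, tol = 0.01) {
  v <- field$vectors
  inv <- -v
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    # v(x + inv(x)) = compose(v, inv) - inv
    new <- inv - compose_arrays(v, inv)
    delta <- max(abs(new - inv))
    inv <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- displacement_field(inv, field$grid)
  attr(out, "converged") <- converged
  out
}

#' Jacobian determinant of a deformation
#'
#' Computes `det(d phi / d x)` per voxel for `phi(x) = x + d(x)`, using
#' central differences in the interior and one-sided differences at the
#' boundary (the geometric Jacobian of the warp). With `log_scale = TRUE`
#' determinants are clamped at `1e-6` before taking the natural log, so
#' folding voxels yield a large negative value rather than `NaN`.
#'
#' @param field a `displacement_field`.
#' @param log_scale return the natural log of the determinant.
#' @return a `scalar_volume` (contrast `"jac"` or `"logJac"`).
#' @export
jacobian_determinant <- function(field, log_scale = FALSE) {
  v <- field$vectors
  g <- vector("list", 9L)
  idx <- 1L
  for (k in 1:3) {
    gk <- grad3(v[, , , k])
    for (ax in 1:3) {
      g[[idx]] <- gk[[ax]] + as.numeric(ax == k)  # d phi_k / d x_ax
      idx <- idx + 1L
    }
  }
  # rows: phi component, cols: derivative axis
  a11 <- g[[1]]; a12 <- g[[2]]; a13 <- g[[3]]
  a21 <- g[[4]]; a22 <- g[[5]]; a23 <- g[[6]]
  a31 <- g[[7]]; a32 <- g[[8]]; a33 <- g[[9]]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  if (log_scale) {
    scalar_volume(log(pmax(det, 1e-6)), field$grid, "logJac")
  } else {
    scalar_volume(det, field$grid, "jac")
  }
}

# exponentiate a velocity field by scaling and squaring
exp_velocity <- function(vel, grid, n_steps = 6L) {
  d <- vel / 2^n_steps
  for (i in seq_len(n_steps)) d <- compose_arrays(d, d)
  displacement_field(d, grid)
}
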