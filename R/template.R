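#' Template-construction configuration
#'
#' @param cohort `"C"` (controls only) or `"A"` (all subjects) — which
#'   subjects drive the template; kept as a tag, the caller selects images.
#' @param n_iters template iterations (default 6).
#' @param n_downsampled_iters how many initial iterations run on a 2x
#'   downsampled grid (default 3).
#' @param shape_update_step fraction of the averaged inverse warp applied
#'   to the template each iteration, in (0, 1].
#' @param registration a [registration_params()].
#' @export
template_config <- function(cohort = c("C", "A"), n_iters = 6L,
                            n_downsampled_iters = 3L,
                            shape_update_step = 0.25,
                            registration = registration_params()) {
  cohort <- match.arg(cohort)
  if (n_downsampled_iters > n_iters)
    stop("n_downsampled_iters must be <= n_iters")
  if (shape_update_step <= 0 || shape_update_step > 1)
    stop("shape_update_step must be in (0, 1]")
  structure(list(cohort = cohort, n_iters = as.integer(n_iters),
                 n_downsampled_iters = as.integer(n_downsampled_iters),
                 shape_update_step = shape_update_step,
                 registration = registration),
            class = "template_config")
}

#' Affine average target
#'
#' Affinely aligns every subject's driving contrast to the first image and
#' averages, producing the unbiased linear template that seeds the
#' iterative construction.
#'
#' @param images list of `scalar_volume`s (driving contrast per subject).
#' @return list with `average` (`scalar_volume`), `affines` (per-subject
#'   4x4 voxel matrices) and `aligned` (the linearly aligned images).
#' @export
affine_average_target <- function(images) {
  if (!length(images)) stop("empty image list")
  ref <- images[[1]]
  affines <- vector("list", length(images))
  aligned <- vector("list", length(images))
  for (i in seq_along(images)) {
    if (i == 1L) {
      affines[[i]] <- diag(4)
      aligned[[i]] <- ref
    } else {
      affines[[i]] <- register_linear(ref, images[[i]], "affine")
      aligned[[i]] <- apply_affine(images[[i]], affines[[i]], "linear")
    }
  }
  avg <- Reduce(`+`, lapply(aligned, `[[`, "data")) / length(aligned)
  list(average = scalar_volume(avg, ref$grid, ref$contrast),
       affines = affines, aligned = aligned)
}

downsample_volume <- function(vol, stride = 2L) {
  a <- subsample_array(smooth_array(vol$data, stride / 2), stride)
  scalar_volume(a, voxel_grid(dim(a), vol$grid$voxel_size * stride), vol$contrast)
}

upsample_volume <- function(vol, shape, voxel_size) {
  co <- coord_arrays(shape)
  old <- dim(vol$data)
  xi <- pmin((co$x - 1) / 2 + 1, old[1])
  yi <- pmin((co$y - 1) / 2 + 1, old[2])
  zi <- pmin((co$z - 1) / 2 + 1, old[3])
  scalar_volume(sample_array(vol$data, xi, yi, zi),
                voxel_grid(shape, voxel_size), vol$contrast)
}

#' Iterative minimal deformation template (MDT)
#'
#' Per iteration each subject is registered to the current template, the
#' warped subjects are averaged (appearance update), and the voxelwise
#' mean of the inverse warps, scaled by `shape_update_step`, is applied to
#' the intermediate average (shape update) so the template drifts toward
#' the cohort's mean geometry. The first `n_downsampled_iters` iterations
#' run on a 2x downsampled grid. Images are assumed already linearly
#' aligned (see [affine_average_target()]).
#'
#' @param images list of linearly aligned `scalar_volume`s.
#' @param config a [template_config()].
#' @return list with `template` (`scalar_volume`), `per_subject_fields`
#'   (registrations of the final iteration) and `history` (per-iteration
#'   mean shape-update displacement magnitude, in full-resolution voxels).
#' @export
build_mdt <- function(images, config = template_config()) {
  if (length(images) < 2L) stop("need at least 2 images")
  grid <- images[[1]]$grid
  avg0 <- Reduce(`+`, lapply(images, `[[`, "data")) / length(images)
  template <- scalar_volume(avg0, grid, images[[1]]$contrast)
  history <- numeric(config$n_iters)
  fields <- NULL
  for (it in seq_len(config$n_iters)) {
    down <- it <= config$n_downsampled_iters
    imgs_it <- if (down) lapply(images, downsample_volume) else images
    tpl_it <- if (down) downsample_volume(template) else template
    regs <- lapply(imgs_it, function(im)
      register_diffeo(tpl_it, im, config$registration))
    warped <- mapply(function(im, rg) resample(im, rg$forward, "linear")$data,
                     imgs_it, regs, SIMPLIFY = FALSE)
    intermediate <- scalar_volume(Reduce(`+`, warped) / length(warped),
                                  tpl_it$grid, template$contrast)
    inv_mean <- Reduce(`+`, lapply(regs, function(rg) rg$inverse$vectors)) /
      length(regs)
    upd <- displacement_field(inv_mean * config$shape_update_step, tpl_it$grid)
    history[it] <- mean(field_magnitude(upd)) * (if (down) 2 else 1)
    tpl_new <- resample(intermediate, upd, "linear")
    template <- if (down) upsample_volume(tpl_new, grid$shape, grid$voxel_size)
                else tpl_new
    fields <- regs
  }
  list(template = template, per_subject_fields = fields, history = history)
}

#' Fresh registration of every subject to the final template
#'
#' Registers each (linearly aligned) subject independently to the final
#' MDT, including subjects that did not contribute to it — this is what
#' keeps the statistics unbiased toward the template cohort. The forward
#' (to-MDT) fields carry the log-Jacobian maps analyzed by the VBM stage.
#'
#' @param images list of linearly aligned `scalar_volume`s.
#' @param template the MDT `scalar_volume`.
#' @param registration a [registration_params()].
#' @return list of per-subject `register_diffeo()` results.
#' @export
register_all_to_mdt <- function(images, template,
                                registration = registration_params()) {
  lapply(images, function(im) register_diffeo(template, im, registration))
}
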