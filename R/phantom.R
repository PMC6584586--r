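#' Phantom recipe: which structures to alter and how
#'
#' Each edit dilates or erodes one labeled structure's binary mask by a
#' spherical element. The merged original masks are then diffeomorphically
#' registered to the merged edited masks and the resulting warp is applied
#' to all contrasts, giving a phantom subject with a known, measurable
#' volume change. The default registration for mask matching uses a large
#' step (0.5), update sigma 3 and total-field sigma 1 with the mean-squares
#' metric: the induced change is a simple expansion/contraction, so strong
#' total-field regularization constrains the warp.
#'
#' @param edits list of `list(label, op, radius)` with `op` in
#'   `c("dilate", "erode")`; a label may be edited at most once.
#' @param registration a [registration_params()] for the mask registration.
#' @export
phantom_recipe <- function(edits,
                           registration = registration_params(
                             step = 0.5, reg_update = 3, reg_total = 1,
                             metric = "ssd")) {
  if (!length(edits)) edits <- list()
  ids <- vapply(edits, function(e) as.integer(e$label), integer(1))
  if (anyDuplicated(ids)) stop("no label may be edited twice")
  for (e in edits) {
    if (!e$op %in% c("dilate", "erode")) stop("op must be dilate or erode")
    if (as.integer(e$radius) < 1L) stop("edit radius must be >= 1")
  }
  structure(list(edits = edits, registration = registration),
            class = "phantom_recipe")
}

#' Build original and edited target masks for a phantom recipe
#'
#' Extracts each edited label's binary mask, applies its dilation/erosion,
#' and merges originals and targets by union. Errors if an erosion
#' annihilates a structure or two edited structures intersect after
#' editing.
#'
#' @param labels a `label_volume` (typically a subject's labels).
#' @param recipe a [phantom_recipe()].
#' @return list with `original_merged`, `target_merged` (logical arrays)
#'   and `per_label` (per-edit original/target masks).
#' @export
make_target_masks <- function(labels, recipe) {
  lab <- labels$data
  per_label <- list()
  for (e in recipe$edits) {
    id <- as.integer(e$label)
    if (!id %in% labels$label_table$id) stop("label ", id, " not in label table")
    orig <- lab == id
    if (!any(orig)) stop("label ", id, " is empty")
    tgt <- if (e$op == "dilate") dilate(orig, e$radius) else erode(orig, e$radius)
    if (!any(tgt)) stop("structure annihilated: erosion emptied label ", id)
    per_label[[as.character(id)]] <- list(label = id, op = e$op,
                                          radius = e$radius,
                                          original = orig, target = tgt)
  }
  n <- length(per_label)
  for (i in seq_len(n)) for (j in seq_len(i - 1L)) {
    if (any(per_label[[i]]$target & per_label[[j]]$target))
      stop("edited structures intersect after editing: labels ",
           per_label[[i]]$label, " and ", per_label[[j]]$label)
  }
  shp <- dim(lab)
  orig_m <- array(FALSE, shp); tgt_m <- array(FALSE, shp)
  for (pl in per_label) {
    orig_m <- orig_m | pl$original
    tgt_m <- tgt_m | pl$target
  }
  list(original_merged = orig_m, target_merged = tgt_m, per_label = per_label)
}

#' Register merged original masks to the edited target masks
#'
#' Both binary masks are pre-smoothed with sigma 0.5 voxels so the
#' mean-squares gradient has support at the boundary (pure binary SSD has
#' zero gradient away from the interface); the induced change is still
#' measured from the produced field. Returns the target-to-original
#' pull-back warp used to resample images into the phantom, and the
#' original-to-target inverse whose Jacobian carries the induced change.
#'
#' @param original_merged,target_merged logical arrays on one grid.
#' @param grid the shared [voxel_grid()].
#' @param registration a [registration_params()].
#' @return list with `warp` (pull-back, for resampling) and `inverse`
#'   (original-to-target).
#' @export
induce_warp <- function(original_merged, target_merged, grid,
                        registration = phantom_recipe(list())$registration) {
  om <- scalar_volume(smooth_array(original_merged + 0, 0.5), grid, "mask")
  tm <- scalar_volume(smooth_array(target_merged + 0, 0.5), grid, "mask")
  reg <- register_diffeo(fixed = tm, moving = om, params = registration)
  # The greedy engine's total-field smoothing leaves a long-range
  # displacement tail; the phantom model is a *local* expansion or
  # contraction, so the field is windowed by a smooth envelope that is 1
  # on the edited structures (where the truth is measured) and decays to
  # 0 a few voxels beyond them.
  win <- pmin(smooth_array(dilate(original_merged | target_merged, 4L) + 0, 2), 1)
  localize <- function(field) {
    v <- field$vectors
    for (k in 1:3) v[, , , k] <- v[, , , k] * win
    displacement_field(v, field$grid)
  }
  fwd <- localize(reg$forward)
  inv <- localize(reg$inverse)
  if (min(jacobian_determinant(fwd)$data) <= 0 ||
      min(jacobian_determinant(inv)$data) <= 0)
    stop("localized induced warp is not diffeomorphic; reduce the edit radius")
  # forward: sampling original at x + d(x) reproduces the target shapes
  list(warp = fwd, inverse = inv, trace = reg$trace)
}

measure_induced_change <- function(inverse_field, per_label) {
  jac <- jacobian_determinant(inverse_field)$data
  rows <- lapply(per_label, function(pl) {
    mj <- mean(jac[pl$original])
    mlj <- mean(log(pmax(jac[pl$original], 1e-6)))
    data.frame(label = pl$label, op = pl$op,
               mean_jacobian = mj, mean_log_jacobian = mlj,
               percent_change = (mj - 1) * 100)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Create a phantom subject with known induced volume change
#'
#' Applies the recipe's mask edits, registers original to target masks,
#' warps every contrast with linear interpolation (labels with nearest),
#' and measures the induced change as the mean Jacobian of the
#' original-to-target warp over each original structure mask.
#'
#' @param subject a `multi_contrast`.
#' @param labels the subject's `label_volume`.
#' @param recipe a [phantom_recipe()].
#' @return list with `phantom` (`multi_contrast`), `labels`
#'   (warped `label_volume`), `truth` (per-label data.frame with
#'   `mean_jacobian`, `mean_log_jacobian`, `percent_change`) and `field`
#'   (the pull-back warp).
#' @export
make_phantom_subject <- function(subject, labels, recipe) {
  if (!same_grid(subject$grid, labels$grid)) stop("subject and labels grids differ")
  if (!length(recipe$edits)) {
    return(list(phantom = subject, labels = labels,
                truth = data.frame(label = integer(0), op = character(0),
                                   mean_jacobian = numeric(0),
                                   mean_log_jacobian = numeric(0),
                                   percent_change = numeric(0)),
                field = zero_field(subject$grid)))
  }
  tm <- make_target_masks(labels, recipe)
  iw <- induce_warp(tm$original_merged, tm$target_merged, subject$grid,
                    recipe$registration)
  truth <- measure_induced_change(iw$inverse, tm$per_label)
  contrasts <- lapply(subject$contrasts, function(v) resample(v, iw$warp, "linear"))
  ph_labels <- resample(labels, iw$warp, "nearest")
  list(phantom = multi_contrast(paste0(subject$subject_id, "_phantom"), contrasts),
       labels = ph_labels, truth = truth, field = iw$warp)
}

#' Cohort-level summary of induced changes
#'
#' The across-subject mean percent change per structure is the simulated
#' volume change used as the recovery target by the evaluation metrics.
#'
#' @param truths list of per-subject truth data.frames from
#'   [make_phantom_subject()].
#' @return data.frame with per-label mean and sample-sd percent change and
#'   mean log-Jacobian.
#' @export
summarize_cohort_truth <- function(truths) {
  if (!length(truths)) stop("need at least one subject truth")
  all <- do.call(rbind, truths)
  out <- do.call(rbind, lapply(split(all, all$label), function(d) {
    data.frame(label = d$label[1], op = d$op[1], n = nrow(d),
               mean_percent_change = mean(d$percent_change),
               sd_percent_change = if (nrow(d) > 1) sd(d$percent_change) else 0,
               mean_log_jacobian = mean(d$mean_log_jacobian))
  }))
  rownames(out) <- NULL
  out
}

#' Phantom-ize every control subject of a cohort
#'
#' @param cohort a `synth_cohort` from [simulate_cohort()].
#' @param recipe a [phantom_recipe()].
#' @param subject_idx which subjects to phantom-ize (default: all controls).
#' @return list with `phantoms` (per-subject results) and `truth` (the
#'   cohort summary from [summarize_cohort_truth()]).
#' @export
make_phantom_cohort <- function(cohort, recipe, subject_idx = NULL) {
  if (is.null(subject_idx))
    subject_idx <- which(cohort$predictors$group == "control")
  phantoms <- lapply(subject_idx, function(i) {
    s <- cohort$subjects[[i]]
    make_phantom_subject(s$image, s$labels, recipe)
  })
  truth <- summarize_cohort_truth(lapply(phantoms, `[[`, "truth"))
  list(phantoms = phantoms, truth = truth, subject_idx = subject_idx)
}
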