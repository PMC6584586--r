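#' Volume change implied by a mean log-Jacobian effect
#'
#' `(exp(x) - 1) * 100` percent: converts a structure's mean effect in
#' log-Jacobian units into the implied percent volume change.
#'
#' @param mean_effect_logjac mean effect over the structure (log-Jacobian).
#' @return percent volume change.
#' @export
implied_volume_change <- function(mean_effect_logjac) {
  (exp(mean_effect_logjac) - 1) * 100
}

#' Absolute distance from the simulated target
#'
#' `|dV_simulated - dV_implied|` in percentage points; lower is better
#' (plots conventionally invert the axis).
#'
#' @param delta_v_simulated simulated percent volume change.
#' @param delta_v_implied recovered percent volume change.
#' @export
distance_from_target <- function(delta_v_simulated, delta_v_implied) {
  abs(delta_v_simulated - delta_v_implied)
}

#' Leakage region around an altered structure
#'
#' Dilates the structure mask by two voxels, removes the generating
#' structure itself and every other altered structure, and clips to the
#' brain mask. This is where falsely significant "leaked" effect is
#' measured.
#'
#' @param structure_mask logical mask of the altered structure.
#' @param all_altered_masks list of logical masks of every altered
#'   structure (including this one).
#' @param brain_mask logical brain mask.
#' @return logical leakage mask.
#' @export
leakage_region <- function(structure_mask, all_altered_masks, brain_mask) {
  s <- as_mask(structure_mask)
  out <- dilate(s, 2L) & !s & as_mask(brain_mask)
  for (o in all_altered_masks) {
    o <- as_mask(o)
    if (!identical(o, s)) out <- out & !o
  }
  if (!any(out)) stop("empty leakage region")
  out
}

#' Inner shell of a structure matched to a target volume
#'
#' `shell(k) = structure - erode(structure, k)`; returns the shell whose
#' voxel count is closest to `target_volume` (ties to the smaller depth).
#' If the whole structure is smaller than the target the full structure is
#' returned. The inner shell is the signal region paired against the
#' leakage (noise) region by the sensitivity index.
#'
#' @param structure_mask logical structure mask.
#' @param target_volume target voxel count (typically the leakage volume).
#' @return logical shell mask.
#' @export
inner_shell <- function(structure_mask, target_volume) {
  s <- as_mask(structure_mask)
  n_total <- sum(s)
  if (!n_total) stop("empty structure mask")
  if (n_total <= target_volume) return(s)
  # erosions only remove voxels, so work on the structure's bounding box
  pos <- which(s, arr.ind = TRUE)
  lo <- apply(pos, 2L, min); hi <- apply(pos, 2L, max)
  sc <- s[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  best_diff <- Inf; best_shell <- NULL
  k <- 1L
  repeat {
    er <- erode(sc, k)
    shell <- sc & !er
    cnt <- sum(shell)
    dff <- abs(cnt - target_volume)
    if (dff < best_diff) { best_diff <- dff; best_shell <- shell }
    if (!any(er) || cnt >= target_volume) break  # shell counts grow with k
    k <- k + 1L
  }
  out <- array(FALSE, dim(s))
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- best_shell
  out
}

#' Sensitivity index between signal and noise regions
#'
#' `d' = (mu_S - mu_N) / sqrt(var_S + var_N)` with sample variances of the
#' effect map over the signal (inner shell) and noise (leakage) masks.
#' For atrophy structures the caller negates the effect map first so that
#' larger means more signal.
#'
#' @param effect_map `scalar_volume` or 3-D array of effect values.
#' @param signal_mask,noise_mask logical masks with >= 2 voxels each.
#' @export
d_prime <- function(effect_map, signal_mask, noise_mask) {
  e <- if (inherits(effect_map, "scalar_volume")) effect_map$data else effect_map
  s <- e[as_mask(signal_mask)]; n <- e[as_mask(noise_mask)]
  if (length(s) < 2L || length(n) < 2L) stop("masks need at least 2 voxels")
  denom <- sqrt(var(s) + var(n))
  if (denom == 0) stop("zero combined variance")
  (mean(s) - mean(n)) / denom
}

#' ROC curve over p-value thresholds
#'
#' Thresholds are the sorted unique p-values within the brain mask plus
#' 0 and 1. At each threshold the TPR is the fraction of structure voxels
#' with `p <= theta` and the FPR the fraction of brain voxels outside the
#' structure with `p <= theta`; the AUC is the trapezoidal area under the
#' (FPR, TPR) polyline, and `tpr_at_p05` is the TPR at `theta = 0.05` in
#' percent.
#'
#' @param p_map `scalar_volume` or array of p-values.
#' @param structure_mask logical mask of the altered structure.
#' @param brain_mask logical mask of the evaluation domain.
#' @return list with `fpr`, `tpr`, `thresholds`, `auc`, `tpr_at_p05`.
#' @export
roc_curve <- function(p_map, structure_mask, brain_mask) {
  p <- if (inherits(p_map, "scalar_volume")) p_map$data else p_map
  s <- as_mask(structure_mask); b <- as_mask(brain_mask)
  if (!any(s & b)) stop("empty structure within brain mask")
  if (!any(b & !s)) stop("empty structure complement within brain mask")
  pv <- p[b]
  sv <- s[b]
  o <- order(pv)
  pv <- pv[o]; sv <- sv[o]
  np <- sum(sv); nn <- sum(!sv)
  thr <- sort(unique(c(0, pv, 1)))
  cum_tp <- cumsum(sv); cum_fp <- cumsum(!sv)
  # number of p-values <= threshold via the sorted vector
  pos <- findInterval(thr, pv)
  tp <- ifelse(pos > 0, cum_tp[pmax(pos, 1L)], 0)
  fp <- ifelse(pos > 0, cum_fp[pmax(pos, 1L)], 0)
  tpr <- tp / np; fpr <- fp / nn
  if (tpr[1] != 0 || fpr[1] != 0) {
    # p-values of exactly 0 exist: anchor the polyline at the origin so the
    # first tie block still gets its half-credit trapezoid
    tpr <- c(0, tpr); fpr <- c(0, fpr); thr <- c(thr[1], thr)
  }
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  t05 <- findInterval(0.05, pv)
  tpr05 <- 100 * (if (t05 > 0) cum_tp[t05] else 0) / np
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc, tpr_at_p05 = tpr05)
}

#' Dice coefficient for one label between two label volumes
#'
#' `2 |A intersect B| / (|A| + |B|)` for the voxel sets carrying
#' `label_id`.
#'
#' @param labels_a,labels_b `label_volume`s on a shared grid.
#' @param label_id the label to compare.
#' @export
dice <- function(labels_a, labels_b, label_id) {
  if (!same_grid(labels_a$grid, labels_b$grid)) stop("grids differ")
  a <- labels_a$data == label_id
  b <- labels_b$data == label_id
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("label ", label_id, " absent from both volumes")
  2 * sum(a & b) / (na + nb)
}

#' Evaluate recovery metrics for one altered structure
#'
#' Computes the four phantom metrics for a structure given the VBM stat
#' maps, the structure and brain masks in template space, and the
#' simulated target change. Atrophy structures use the atrophy-direction
#' p-map (`p_less`) and the negated effect; hypertrophy structures use
#' `p_greater` and the raw effect.
#'
#' @param stats a `stat_maps` object from [voxelwise_ttest()].
#' @param structure_mask logical mask of the structure in template space.
#' @param all_altered_masks list of all altered structures' masks.
#' @param brain_mask logical evaluation mask (typically the analysis mask).
#' @param direction `"atrophy"` or `"hypertrophy"`.
#' @param delta_v_simulated simulated percent change for this structure.
#' @return one-row data.frame with `delta_v_implied`, `delta_d`,
#'   `d_prime`, `auc`, `tpr_at_p05`.
#' @export
evaluate_structure <- function(stats, structure_mask, all_altered_masks,
                               brain_mask,
                               direction = c("atrophy", "hypertrophy"),
                               delta_v_simulated) {
  direction <- match.arg(direction)
  s <- as_mask(structure_mask); b <- as_mask(brain_mask)
  p <- if (direction == "atrophy") stats$p_less else stats$p_greater
  eff_signed <- stats$effect$data
  eff_directed <- if (direction == "atrophy") -eff_signed else eff_signed
  leak <- leakage_region(s, all_altered_masks, b)
  shell <- inner_shell(s, sum(leak))
  dp <- d_prime(eff_directed, shell & b, leak)
  roc <- roc_curve(p, s & b, b)
  dvi <- implied_volume_change(mean(eff_signed[s & b]))
  data.frame(direction = direction,
             delta_v_simulated = delta_v_simulated,
             delta_v_implied = dvi,
             delta_d = distance_from_target(delta_v_simulated, dvi),
             d_prime = dp, auc = roc$auc, tpr_at_p05 = roc$tpr_at_p05)
}

#' Rank parameter sets across metrics
#'
#' Per structure and metric, rank 1 is best under the metric's direction
#' (`delta_d` and `runtime_s`: lower is better; `d_prime`, `auc`,
#' `tpr_at_p05`, `dice`: higher is better), ties receiving the minimal
#' (competition) rank. The phantom average is the mean of the per-structure
#' phantom-metric ranks; the combined value averages the Dice rank, the
#' runtime rank and the phantom average, and the final ranking is the
#' competition rank of the combined values.
#'
#' @param records data.frame with columns `param_set`, `structure`, the
#'   phantom metrics `delta_d`, `d_prime`, `auc`, `tpr_at_p05`, and
#'   optionally `dice` and `runtime_s` (constant per param_set).
#' @return data.frame, one row per parameter set, with per-metric ranks,
#'   `phantom_average`, `phantom_rank` and (when Dice/runtime are present)
#'   `combined` and `final_rank`.
#' @export
rank_parameter_sets <- function(records) {
  needed <- c("param_set", "structure", "delta_d", "d_prime", "auc", "tpr_at_p05")
  if (!all(needed %in% names(records))) stop("records missing required columns")
  if (length(unique(records$param_set)) < 2L) stop("need >= 2 parameter sets")
  if (any(is.na(records[needed]))) stop("missing metric values")
  comp_rank <- function(x, lower_better) {
    v <- if (lower_better) x else -x
    rank(v, ties.method = "min")
  }
  sets <- unique(records$param_set)
  out <- data.frame(param_set = sets, stringsAsFactors = FALSE)
  rank_cols <- character(0)
  for (st in unique(records$structure)) {
    d <- records[records$structure == st, ]
    d <- d[match(sets, d$param_set), ]
    for (mt in c("delta_d", "d_prime", "auc", "tpr_at_p05")) {
      cn <- paste(st, mt, "rank", sep = "_")
      out[[cn]] <- comp_rank(d[[mt]], lower_better = mt == "delta_d")
      rank_cols <- c(rank_cols, cn)
    }
  }
  out$phantom_average <- rowMeans(out[rank_cols])
  out$phantom_rank <- comp_rank(out$phantom_average, lower_better = TRUE)
  per_set <- records[match(sets, records$param_set), ]
  combined_parts <- list(out$phantom_average)
  if ("dice" %in% names(records)) {
    mean_dice <- vapply(sets, function(s)
      mean(records$dice[records$param_set == s]), numeric(1))
    out$dice_rank <- comp_rank(mean_dice, lower_better = FALSE)
    combined_parts <- c(combined_parts, list(out$dice_rank))
  }
  if ("runtime_s" %in% names(records)) {
    out$runtime_rank <- comp_rank(per_set$runtime_s, lower_better = TRUE)
    combined_parts <- c(combined_parts, list(out$runtime_rank))
  }
  if (length(combined_parts) > 1L) {
    out$combined <- Reduce(`+`, combined_parts) / length(combined_parts)
    out$final_rank <- comp_rank(out$combined, lower_better = TRUE)
  }
  out[order(out$phantom_rank), ]
}
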