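# ---- headfile ---------------------------------------------------------------

headfile_schema <- function() {
  list(
    step = list(type = "numeric", default = 0.25),
    reg_update = list(type = "numeric", default = 3),
    reg_total = list(type = "numeric", default = 0.5),
    metric = list(type = "character", default = "ssd"),
    smoothing_sigma = list(type = "numeric", default = 3),
    mdt_cohort = list(type = "character", default = "C"),
    mdt_iters = list(type = "integer", default = 6L),
    mdt_downsampled_iters = list(type = "integer", default = 3L),
    driving_contrast = list(type = "character", default = "FA"),
    mask_contrast = list(type = "character", default = "DWI"),
    skull_strip_n_ops = list(type = "integer", default = 5L),
    skull_strip_radius = list(type = "integer", default = 2L),
    n_controls = list(type = "integer", default = 5L),
    n_treated = list(type = "integer", default = 0L),
    seed = list(type = "integer", default = 42L),
    in_dir = list(type = "character", default = "."),
    out_dir = list(type = "character", default = ".")
  )
}

#' Parse a key=value headfile configuration
#'
#' Flat `key=value` lines with `#` comments. Values are typed by a fixed
#' key schema; missing keys take documented defaults, unknown keys warn,
#' and type mismatches error naming the key and expected type.
#'
#' @param path path to the headfile (an empty or absent-key file yields
#'   all defaults).
#' @return named list of effective settings, class `headfile`.
#' @export
parse_headfile <- function(path) {
  schema <- headfile_schema()
  out <- lapply(schema, `[[`, "default")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed headfile line (expected key=value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(schema)) {
      warning("unknown headfile key: ", key)
      next
    }
    type <- schema[[key]]$type
    parsed <- switch(type,
      numeric = suppressWarnings(as.numeric(val)),
      integer = suppressWarnings(as.integer(val)),
      character = val)
    if (type != "character" && (is.na(parsed)))
      stop("headfile key '", key, "' expects a ", type, " value, got '", val, "'")
    out[[key]] <- parsed
  }
  structure(out, class = "headfile")
}

# ---- job planning and sweep grids -------------------------------------------

#' Registration job count for an MDT study
#'
#' An iterative template needs `mdt_iters` pairwise registrations per
#' template-cohort member, and every subject must then be registered to
#' the final template: `mdt_iters * n_mdt_cohort + n_total_subjects` jobs.
#' With 10 controls driving the template, 20 subjects total and 3
#' template iterations this is the canonical 50.
#'
#' @param n_mdt_cohort subjects contributing to the template.
#' @param n_total_subjects all subjects in the study.
#' @param mdt_iters template iterations (default 3, the minimum).
#' @return integer job count.
#' @export
plan_jobs <- function(n_mdt_cohort, n_total_subjects, mdt_iters = 3L) {
  if (n_mdt_cohort < 1L || n_total_subjects < 1L || mdt_iters < 1L)
    stop("counts must be positive")
  if (n_mdt_cohort > n_total_subjects)
    stop("n_mdt_cohort must be <= n_total_subjects")
  as.integer(mdt_iters * n_mdt_cohort + n_total_subjects)
}

#' Parameter sweep grid
#'
#' The swept space is (MDT cohort) x (step) x (RegU) x (RegT); the default
#' grid is the 2 x 3 x 2 x 2 = 24-configuration study design.
#'
#' @param mdt_cohorts character vector of template cohort tags.
#' @param steps gradient step values (voxels).
#' @param reg_updates update-field sigmas (voxels).
#' @param reg_totals total-field sigmas (voxels).
#' @export
sweep_grid <- function(mdt_cohorts = c("C", "A"),
                       steps = c(0.1, 0.25, 0.5),
                       reg_updates = c(3, 5),
                       reg_totals = c(0, 0.5)) {
  if (!length(mdt_cohorts) || !length(steps) || !length(reg_updates) ||
      !length(reg_totals)) stop("all grid dimensions must be nonempty")
  structure(list(mdt_cohorts = mdt_cohorts, steps = steps,
                 reg_updates = reg_updates, reg_totals = reg_totals),
            class = "sweep_grid")
}

#' Enumerate sweep configurations in deterministic order
#'
#' @param grid a [sweep_grid()].
#' @return data.frame with one row per configuration and a `config_id` of
#'   the form `"C(0.25,3,0.5)"`.
#' @export
enumerate_sweep <- function(grid) {
  g <- expand.grid(reg_total = grid$reg_totals, reg_update = grid$reg_updates,
                   step = grid$steps, mdt_cohort = grid$mdt_cohorts,
                   stringsAsFactors = FALSE)
  g <- g[, c("mdt_cohort", "step", "reg_update", "reg_total")]
  g$config_id <- sprintf("%s(%g,%g,%g)", g$mdt_cohort, g$step, g$reg_update,
                         g$reg_total)
  g
}

# ---- end-to-end phantom study -----------------------------------------------

#' Run the full phantom VBM study on a synthetic cohort
#'
#' Controls are phantom-ized with `recipe`, all driving-contrast images
#' are affinely aligned, a minimal deformation template is built from the
#' chosen cohort, every subject is freshly registered to it, and the
#' smoothed log-Jacobian maps of the to-MDT warps are compared between
#' controls and phantoms with two one-tailed t-tests. Atlas labels are
#' propagated to the template to define structure masks, and recovery of
#' each induced change is scored with the phantom metrics (plus Dice of
#' propagated vs ground-truth labels per subject).
#'
#' @param cohort a `synth_cohort` from [simulate_cohort()].
#' @param recipe a [phantom_recipe()].
#' @param params [registration_params()] for template building and
#'   to-MDT registration.
#' @param mdt_cohort `"C"` (controls only) or `"A"` (all subjects).
#' @param smooth_sigma Gaussian sigma (voxels) for map smoothing.
#' @param n_iters,n_downsampled_iters template iterations.
#' @param driving_contrast contrast driving all registrations.
#' @param compute_dice also propagate labels to every subject and compute
#'   Dice against the generator's ground-truth labels.
#' @return list with `stats` (`stat_maps`), `template`, `analysis_mask`,
#'   `brain_mask`, `labels_mdt`, `truth`, `eval` (per-structure metric
#'   rows), `dice` (per subject x structure, if computed), `fields`,
#'   `affines` and `runtime_s`.
#' @export
run_phantom_study <- function(cohort, recipe, params = registration_params(),
                              mdt_cohort = c("C", "A"), smooth_sigma = 3,
                              n_iters = 6L, n_downsampled_iters = 3L,
                              driving_contrast = "FA", compute_dice = TRUE) {
  mdt_cohort <- match.arg(mdt_cohort)
  t0 <- proc.time()[["elapsed"]]
  ctrl_idx <- which(cohort$predictors$group == "control")
  ph <- make_phantom_cohort(cohort, recipe, ctrl_idx)
  ctrl_driving <- lapply(ctrl_idx, function(i)
    cohort$subjects[[i]]$image$contrasts[[driving_contrast]])
  ph_driving <- lapply(ph$phantoms, function(p)
    p$phantom$contrasts[[driving_contrast]])
  all_driving <- c(ctrl_driving, ph_driving)
  n_ctrl <- length(ctrl_driving)
  n_all <- length(all_driving)

  lin <- affine_average_target(all_driving)
  mdt_members <- if (mdt_cohort == "C") seq_len(n_ctrl) else seq_len(n_all)
  cfg <- template_config(cohort = mdt_cohort, n_iters = n_iters,
                         n_downsampled_iters = n_downsampled_iters,
                         registration = params)
  mdt <- build_mdt(lin$aligned[mdt_members], cfg)
  regs <- register_all_to_mdt(lin$aligned, mdt$template, params)

  logj <- lapply(regs, function(rg)
    smooth_map(jacobian_determinant(rg$forward, log_scale = TRUE), smooth_sigma))
  brain_mask <- skull_strip(mdt$template, skull_strip_params())
  amask <- make_analysis_mask(brain_mask, smooth_sigma)
  stats <- voxelwise_ttest(logj[seq_len(n_ctrl)],
                           logj[(n_ctrl + 1):n_all], amask)

  # propagate atlas labels to the template
  atlas_fa <- cohort$atlas$contrasts[[driving_contrast]]
  A_atlas <- register_linear(mdt$template, atlas_fa, "affine")
  atlas_aligned <- apply_affine(atlas_fa, A_atlas, "linear")
  reg_atlas <- register_diffeo(mdt$template, atlas_aligned, params)
  labels_affine <- apply_affine(cohort$labels, A_atlas, "nearest")
  labels_mdt <- resample(labels_affine, reg_atlas$forward, "nearest")

  altered <- lapply(recipe$edits, function(e) labels_mdt$data == e$label)
  eval_rows <- list()
  for (k in seq_along(recipe$edits)) {
    e <- recipe$edits[[k]]
    tr <- ph$truth[ph$truth$label == e$label, ]
    row <- evaluate_structure(
      stats, altered[[k]], altered, amask,
      direction = if (e$op == "erode") "atrophy" else "hypertrophy",
      delta_v_simulated = tr$mean_percent_change)
    row <- cbind(data.frame(label = e$label, op = e$op), row)
    eval_rows[[k]] <- row
  }
  eval_df <- do.call(rbind, eval_rows)

  dice_df <- NULL
  if (compute_dice) {
    structure_ids <- intersect(c(2L, 3L, 4L, 5L), cohort$labels$label_table$id)
    truth_labels <- c(lapply(ctrl_idx, function(i) cohort$subjects[[i]]$labels),
                      lapply(ph$phantoms, `[[`, "labels"))
    rows <- list()
    for (i in seq_len(n_all)) {
      auto <- resample(labels_mdt, regs[[i]]$inverse, "nearest")
      truth_i <- apply_affine(truth_labels[[i]], lin$affines[[i]], "nearest")
      for (sid in structure_ids) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, label = sid, dice = dice(auto, truth_i, sid))
      }
    }
    dice_df <- do.call(rbind, rows)
  }

  list(stats = stats, template = mdt$template, brain_mask = brain_mask,
       analysis_mask = amask, labels_mdt = labels_mdt, truth = ph$truth,
       eval = eval_df, dice = dice_df, fields = regs, affines = lin$affines,
       mdt_history = mdt$history,
       runtime_s = proc.time()[["elapsed"]] - t0)
}

#' Run a parameter sweep and rank the configurations
#'
#' Enumerates the grid, runs the full phantom study once per
#' configuration, writes per-configuration metric CSVs plus a runtimes
#' table, and aggregates everything with [rank_parameter_sets()]. A
#' configuration that fails is recorded with a warning and excluded from
#' the ranking.
#'
#' @param grid a [sweep_grid()].
#' @param cohort a `synth_cohort`.
#' @param recipe a [phantom_recipe()].
#' @param out_dir output directory for CSVs (created if needed).
#' @param smooth_sigma map-smoothing sigma in voxels.
#' @param n_iters,n_downsampled_iters template iterations per run.
#' @param metric registration similarity metric for the sweep runs.
#' @return list with `records` (per config x structure), `ranking`,
#'   `runtimes` and `failed` (config ids).
#' @export
run_sweep <- function(grid, cohort, recipe, out_dir, smooth_sigma = 3,
                      n_iters = 6L, n_downsampled_iters = 3L,
                      metric = "ssd") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  configs <- enumerate_sweep(grid)
  records <- list()
  runtimes <- list()
  failed <- character(0)
  for (r in seq_len(nrow(configs))) {
    cf <- configs[r, ]
    res <- tryCatch(
      run_phantom_study(cohort, recipe,
                        params = registration_params(step = cf$step,
                                                     reg_update = cf$reg_update,
                                                     reg_total = cf$reg_total,
                                                     metric = metric),
                        mdt_cohort = cf$mdt_cohort,
                        smooth_sigma = smooth_sigma, n_iters = n_iters,
                        n_downsampled_iters = n_downsampled_iters),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("configuration ", cf$config_id, " failed: ",
              conditionMessage(res))
      failed <- c(failed, cf$config_id)
      next
    }
    ev <- res$eval
    ev$param_set <- cf$config_id
    ev$structure <- paste0("label", ev$label)
    ev$dice <- mean(res$dice$dice)
    ev$runtime_s <- res$runtime_s
    records[[cf$config_id]] <- ev
    runtimes[[cf$config_id]] <- data.frame(config_id = cf$config_id,
                                           runtime_s = res$runtime_s)
    write.csv(ev, file.path(out_dir, paste0("eval_", r, ".csv")),
              row.names = FALSE)
  }
  records <- do.call(rbind, records)
  runtimes <- do.call(rbind, runtimes)
  ranking <- if (length(unique(records$param_set)) >= 2L)
    rank_parameter_sets(records) else NULL
  if (!is.null(runtimes))
    write.csv(runtimes, file.path(out_dir, "runtimes.csv"), row.names = FALSE)
  if (!is.null(ranking))
    write.csv(ranking, file.path(out_dir, "ranking.csv"), row.names = FALSE)
  list(records = records, ranking = ranking, runtimes = runtimes,
       failed = failed)
}

# ---- provenance -------------------------------------------------------------

#' Append a provenance record to a JSON-lines audit log
#'
#' Records the stage name, UTC timestamp, parameter list and the MD5
#' content hash of every input file.
#'
#' @param log_path the JSON-lines log file (created if absent).
#' @param stage stage name.
#' @param inputs character vector of input file paths.
#' @param params named list of stage parameters.
#' @return the record, invisibly.
#' @export
log_provenance <- function(log_path, stage, inputs = character(0),
                           params = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  rec <- list(stage = stage,
              time = format(Sys.time(), tz = "UTC", usetz = TRUE),
              inputs = hashes, params = params)
  con <- file(log_path, open = "a")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  invisible(rec)
}

#' Verify a provenance log against current file contents
#'
#' Re-hashes every input file mentioned in the log and reports mismatches
#' (tampered or regenerated inputs) and missing files.
#'
#' @param log_path the JSON-lines log file.
#' @return data.frame with `stage`, `path`, `status`
#'   (`ok`/`mismatch`/`missing`).
#' @export
verify_provenance <- function(log_path) {
  lines <- readLines(log_path, warn = FALSE)
  rows <- list()
  for (ln in lines) {
    rec <- jsonlite::fromJSON(ln)
    for (p in names(rec$inputs)) {
      status <- if (!file.exists(p)) "missing"
        else if (unname(tools::md5sum(p)) == rec$inputs[[p]]) "ok"
        else "mismatch"
      rows[[length(rows) + 1L]] <- data.frame(stage = rec$stage, path = p,
                                              status = status)
    }
  }
  if (!length(rows)) return(data.frame(stage = character(0),
                                       path = character(0),
                                       status = character(0)))
  do.call(rbind, rows)
}

#' Write a mid-slice PNG preview of a volume or mask
#'
#' Quality-control previews of the three central orthogonal slices
#' (replaces the interactive pause recommended for mask inspection).
#'
#' @param vol a `scalar_volume` or logical array.
#' @param path output PNG path.
#' @export
write_preview_png <- function(vol, path) {
  a <- if (inherits(vol, "scalar_volume")) vol$data else as_mask(vol) + 0
  d <- dim(a)
  grDevices::png(path, width = 900, height = 300)
  op <- graphics::par(mfrow = c(1, 3), mar = rep(0.5, 4))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (sl in list(a[ceiling(d[1] / 2), , ], a[, ceiling(d[2] / 2), ],
                  a[, , ceiling(d[3] / 2)]))
    graphics::image(sl, axes = FALSE, col = grDevices::gray.colors(64))
  invisible(path)
}
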