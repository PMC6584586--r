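#' Synthetic cohort specification
#'
#' Describes a seeded synthetic labeled brain cohort: an ellipsoidal brain
#' shell containing bilateral hippocampus-like ("Hc") and caudate-putamen-
#' like ("CPu") structures and small bilateral ventricles, imaged in two
#' contrasts with distinct per-structure means. Inter-subject anatomical
#' variability is a smooth random diffeomorphism (Gaussian-smoothed random
#' velocity, exponentiated by scaling and squaring) composed with a small
#' random affine jitter; intensity noise is additive Gaussian.
#'
#' Geometry is expressed as fractions of the grid so the cohort scales with
#' `shape`; the defaults at 64^3 make the bilateral structures large enough
#' (semi-axes about 7-11 voxels) that a one-voxel mask edit induces a
#' 25-40% volume change.
#'
#' @param n_controls number of control subjects (>= 2 for group statistics).
#' @param n_treated number of additional "treated"-labeled subjects drawn
#'   from the same generator (no built-in treatment effect; effects are
#'   induced by the phantom module).
#' @param shape grid dimensions (default 64^3).
#' @param voxel_size voxel edge length in mm (default 0.1).
#' @param contrasts named list of per-structure mean intensities for each
#'   contrast; structures are `background`, `tissue`, `hc`, `cpu`,
#'   `ventricle`.
#' @param noise_sigma additive Gaussian intensity noise sd per contrast.
#' @param vel_smooth_sigma Gaussian sigma (voxels) smoothing the random
#'   velocity field.
#' @param max_displacement amplitude cap (voxels) of the generating warp.
#' @param n_squaring scaling-and-squaring steps for exponentiation.
#' @param affine_jitter list with `translate` (voxels), `rotate_deg` and
#'   `scale` (fractional) uniform jitter half-ranges.
#' @param seed integer master seed; the cohort is a pure function of the
#'   spec including this seed.
#' @export
cohort_spec <- function(n_controls = 5L, n_treated = 0L,
                        shape = c(64L, 64L, 64L), voxel_size = 0.1,
                        contrasts = list(
                          FA = c(background = 0, tissue = 0.30, hc = 0.55,
                                 cpu = 0.70, ventricle = 0.08),
                          DWI = c(background = 0.02, tissue = 0.85, hc = 0.65,
                                  cpu = 0.55, ventricle = 1.20)),
                        noise_sigma = 0.02,
                        vel_smooth_sigma = 4, max_displacement = 1.5,
                        n_squaring = 6L,
                        affine_jitter = list(translate = 1.0, rotate_deg = 2,
                                             scale = 0.02),
                        seed = 42L) {
  if (n_controls < 1L) stop("n_controls must be >= 1")
  if (noise_sigma < 0 || vel_smooth_sigma < 0 || max_displacement < 0)
    stop("sigmas and amplitudes must be >= 0")
  structure(list(n_controls = as.integer(n_controls),
                 n_treated = as.integer(n_treated),
                 shape = as.integer(shape), voxel_size = voxel_size,
                 contrasts = contrasts, noise_sigma = noise_sigma,
                 vel_smooth_sigma = vel_smooth_sigma,
                 max_displacement = max_displacement,
                 n_squaring = as.integer(n_squaring),
                 affine_jitter = affine_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# structure geometry in fractions of the grid (centres relative to the grid
# centre, semi-axes relative to shape); frozen design constants
cohort_geometry <- function() {
  list(
    brain = list(centre = c(0, 0, 0), semi = c(27, 23, 19) / 64),
    hc = list(offset = c(11, 6, 4) / 64, semi = c(9, 10, 8) / 64),
    cpu = list(offset = c(8.5, -11, -3) / 64, semi = c(6.5, 7.5, 7) / 64),
    ventricle = list(offset = c(3.5, -6.5, 4.5) / 64, semi = c(2, 4, 3) / 64)
  )
}

ellipsoid_mask <- function(shape, centre, semi) {
  co <- coord_arrays(shape)
  ((co$x - centre[1]) / semi[1])^2 + ((co$y - centre[2]) / semi[2])^2 +
    ((co$z - centre[3]) / semi[3])^2 <= 1
}

#' Base atlas: mirror-symmetric labeled brain
#'
#' Builds the clean (noise-free) multi-contrast atlas and its label volume.
#' Labels: 1 = brain tissue, 2/3 = left/right Hc, 4/5 = left/right CPu,
#' 6/7 = left/right ventricle; 0 = background. The construction is
#' analytically mirror-symmetric about the mid-sagittal plane. Errors if
#' any two structures overlap or a structure leaves the brain shell.
#'
#' @param spec a [cohort_spec()].
#' @return list with `atlas` (a `multi_contrast`) and `labels`
#'   (a `label_volume`).
#' @export
make_base_atlas <- function(spec) {
  shp <- spec$shape
  geo <- cohort_geometry()
  ctr <- (shp + 1) / 2
  sc <- function(fr) fr * shp
  brain <- ellipsoid_mask(shp, ctr + sc(geo$brain$centre), sc(geo$brain$semi))
  masks <- list()
  for (s in c("hc", "cpu", "ventricle")) {
    for (side in c("left", "right")) {
      off <- sc(geo[[s]]$offset)
      if (side == "left") off[1] <- -off[1]
      masks[[paste(s, side, sep = "_")]] <-
        ellipsoid_mask(shp, ctr + off, sc(geo[[s]]$semi))
    }
  }
  # contract checks: pairwise disjoint, strictly inside the shell
  nm <- names(masks)
  for (i in seq_along(masks)) {
    if (any(masks[[i]] & !erode(brain, 1L)))
      stop("structure ", nm[i], " not strictly inside the brain shell")
    for (j in seq_len(i - 1L))
      if (any(masks[[i]] & masks[[j]]))
        stop("structures overlap: ", nm[i], " and ", nm[j])
  }
  lab <- array(0L, shp)
  lab[brain] <- 1L
  ids <- c(hc_left = 2L, hc_right = 3L, cpu_left = 4L, cpu_right = 5L,
           ventricle_left = 6L, ventricle_right = 7L)
  for (k in names(ids)) lab[masks[[k]]] <- ids[[k]]
  lt <- data.frame(
    id = c(1L, ids),
    name = c("tissue", "Hc_L", "Hc_R", "CPu_L", "CPu_R", "Vent_L", "Vent_R"),
    hemisphere = c("midline", "left", "right", "left", "right", "left", "right"),
    stringsAsFactors = FALSE)
  grid <- voxel_grid(shp, rep(spec$voxel_size, 3))
  labels <- label_volume(lab, grid, lt)
  tissue_class <- c("background", "tissue", "hc", "hc", "cpu", "cpu",
                    "ventricle", "ventricle")[lab + 1L]
  contrasts <- lapply(names(spec$contrasts), function(cn) {
    means <- spec$contrasts[[cn]]
    scalar_volume(array(means[tissue_class], shp), grid, cn)
  })
  names(contrasts) <- names(spec$contrasts)
  list(atlas = multi_contrast("atlas", contrasts), labels = labels)
}

random_jitter_affine <- function(spec) {
  j <- spec$affine_jitter
  tr <- runif(3, -j$translate, j$translate)
  ang <- runif(3, -j$rotate_deg, j$rotate_deg) * pi / 180
  scl <- 1 + runif(3, -j$scale, j$scale)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0, sin(ang[2]), 0, cos(ang[2])), 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3)
  M <- Rx %*% Ry %*% Rz %*% diag(scl)
  ctr <- (spec$shape - 1) / 2  # 0-based grid centre
  A <- diag(4)
  A[1:3, 1:3] <- M
  A[1:3, 4] <- ctr - M %*% ctr + tr
  A
}

#' Generate one synthetic subject
#'
#' Warps the atlas by a random diffeomorphic perturbation (smoothed random
#' velocity exponentiated by scaling and squaring, composed with a small
#' affine jitter) and adds independent Gaussian intensity noise per
#' contrast. The generating field is returned as ground truth; if its
#' Jacobian is not strictly positive the velocity amplitude is halved and
#' the draw repeated (at most 5 times).
#'
#' @param atlas,labels output of [make_base_atlas()].
#' @param spec the [cohort_spec()].
#' @param subject_seed integer seed for this subject's draws.
#' @return list with `image` (`multi_contrast`), `labels` (`label_volume`)
#'   and `field` (the generating `displacement_field`, atlas pull-back).
#' @export
make_subject <- function(atlas, labels, spec, subject_seed) {
  if (!same_grid(atlas$grid, labels$grid)) stop("atlas and labels grids differ")
  grid <- atlas$grid
  shp <- grid$shape
  set.seed(as.integer(subject_seed %% .Machine$integer.max))
  A <- random_jitter_affine(spec)
  amp <- spec$max_displacement
  field <- NULL
  for (try in 0:5) {
    if (try == 5L) stop("could not generate a diffeomorphic perturbation")
    if (amp == 0 && spec$affine_jitter$translate == 0 &&
        spec$affine_jitter$rotate_deg == 0 && spec$affine_jitter$scale == 0) {
      field <- zero_field(grid)
      break
    }
    vel <- array(rnorm(prod(shp) * 3), c(shp, 3L))
    vel <- smooth_field_arrays(vel, spec$vel_smooth_sigma)
    mag <- sqrt(vel[, , , 1]^2 + vel[, , , 2]^2 + vel[, , , 3]^2)
    if (max(mag) > 0 && amp > 0) vel <- vel * (amp / max(mag)) else vel[] <- 0
    diffeo <- exp_velocity(vel, grid, spec$n_squaring)
    total <- compose_fields(affine_to_field(A, grid), diffeo)
    jd <- jacobian_determinant(total)$data
    if (min(jd) > 0) { field <- total; break }
    amp <- amp / 2
  }
  contrasts <- lapply(atlas$contrasts, function(v) {
    w <- resample(v, field, "linear")
    scalar_volume(w$data + rnorm(length(w$data), sd = spec$noise_sigma) *
                    (spec$noise_sigma > 0), grid, v$contrast)
  })
  sub_labels <- resample(labels, field, "nearest")
  list(image = multi_contrast(sprintf("S%02d", subject_seed %% 100L), contrasts),
       labels = sub_labels, field = field)
}

#' Simulate a full cohort in memory
#'
#' A pure function of `(spec, spec$seed)`: returns the atlas, labels, all
#' subjects and a predictors table (specimen_id, runno, group, age, gender,
#' treatment).
#'
#' @param spec a [cohort_spec()].
#' @export
simulate_cohort <- function(spec) {
  base <- make_base_atlas(spec)
  n <- spec$n_controls + spec$n_treated
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sseed <- (spec$seed * 1000L + i * 7919L) %% .Machine$integer.max
    subjects[[i]] <- make_subject(base$atlas, base$labels, spec, sseed)
    subjects[[i]]$image$subject_id <- sprintf("S%02d", i)
  }
  group <- c(rep("control", spec$n_controls), rep("treated", spec$n_treated))
  predictors <- data.frame(
    specimen_id = sprintf("S%02d", seq_len(n)),
    runno = sprintf("R%03d", seq_len(n)),
    group = group,
    age = 90L, gender = "F",
    treatment = ifelse(group == "control", "saline", "treated"),
    stringsAsFactors = FALSE)
  structure(list(spec = spec, atlas = base$atlas, labels = base$labels,
                 subjects = subjects, predictors = predictors),
            class = "synth_cohort")
}

#' Write a cohort to disk
#'
#' Writes per-subject NIfTI contrasts, label volumes and ground-truth
#' fields, the atlas and its labels, the predictors CSV and a JSON manifest
#' listing every path.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir writable output directory (created if absent).
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
make_cohort <- function(spec, out_dir) {
  cohort <- simulate_cohort(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, paste0(...))
  manifest <- list(atlas = list(), subjects = list())
  for (cn in names(cohort$atlas$contrasts)) {
    path <- p("atlas_", cn, ".nii.gz")
    write_nifti(cohort$atlas$contrasts[[cn]], path)
    manifest$atlas[[cn]] <- path
  }
  write_nifti(cohort$labels, p("atlas_labels.nii.gz"))
  manifest$atlas$labels <- p("atlas_labels.nii.gz")
  for (i in seq_along(cohort$subjects)) {
    id <- cohort$predictors$specimen_id[i]
    s <- cohort$subjects[[i]]
    entry <- list()
    for (cn in names(s$image$contrasts)) {
      path <- p(id, "_", cn, ".nii.gz")
      write_nifti(s$image$contrasts[[cn]], path)
      entry[[cn]] <- path
    }
    write_nifti(s$labels, p(id, "_labels.nii.gz"))
    entry$labels <- p(id, "_labels.nii.gz")
    write_nifti(s$field, p(id, "_truth_field.nii.gz"))
    entry$truth_field <- p(id, "_truth_field.nii.gz")
    manifest$subjects[[id]] <- entry
  }
  write.csv(cohort$predictors, p("predictors.csv"), row.names = FALSE)
  manifest$predictors <- p("predictors.csv")
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [make_cohort()]
#' @param dir the cohort directory containing `manifest.json`.
#' @return a `synth_cohort`-like list (without the generating spec).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  contrast_names <- setdiff(names(manifest$atlas), "labels")
  atlas <- multi_contrast("atlas", setNames(
    lapply(contrast_names, function(cn) {
      v <- read_nifti(manifest$atlas[[cn]]); v$contrast <- cn; v
    }), contrast_names))
  labels <- read_nifti(manifest$atlas$labels, as_labels = TRUE)
  predictors <- read.csv(manifest$predictors, stringsAsFactors = FALSE)
  subjects <- lapply(names(manifest$subjects), function(id) {
    entry <- manifest$subjects[[id]]
    cns <- setdiff(names(entry), c("labels", "truth_field"))
    img <- multi_contrast(id, setNames(lapply(cns, function(cn) {
      v <- read_nifti(entry[[cn]]); v$contrast <- cn; v
    }), cns))
    list(image = img, labels = read_nifti(entry$labels, as_labels = TRUE),
         field = read_field(entry$truth_field))
  })
  structure(list(spec = NULL, atlas = atlas, labels = labels,
                 subjects = subjects, predictors = predictors),
            class = "synth_cohort")
}
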