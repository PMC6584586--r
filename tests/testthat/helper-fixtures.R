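# Shared fixtures. Expensive objects (cohorts, pipeline runs) are built
# lazily once per test run and cached in this environment.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# gaussian ball image for registration tests
ball_image <- function(shape = c(64, 64, 64), centre = NULL, radius = 10) {
  if (is.null(centre)) centre <- (shape + 1) / 2
  co <- expand_coords(shape)
  a <- exp(-3 * (((co$x - centre[1]) / radius)^2 +
                   ((co$y - centre[2]) / radius)^2 +
                   ((co$z - centre[3]) / radius)^2))
  scalar_volume(array(a, shape))
}

expand_coords <- function(shape) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  list(x = array(rep.int(seq_len(nx), ny * nz), shape),
       y = array(rep(seq_len(ny), each = nx, times = nz), shape),
       z = array(rep(seq_len(nz), each = nx * ny), shape))
}

solid_ball_mask <- function(shape, centre, radius) {
  co <- expand_coords(shape)
  (co$x - centre[1])^2 + (co$y - centre[2])^2 + (co$z - centre[3])^2 <= radius^2
}

# analytic count of voxels with offsets |o| <= r from a centre (ball raster)
ball_count <- function(radius) {
  o <- seq(-ceiling(radius), ceiling(radius))
  g <- expand.grid(o, o, o)
  sum(g[[1]]^2 + g[[2]]^2 + g[[3]]^2 <= radius^2)
}

# smooth random displacement field with bounded amplitude
random_smooth_field <- function(shape, amplitude, sigma = 4, seed = 1) {
  set.seed(seed)
  v <- array(rnorm(prod(shape) * 3), c(shape, 3))
  for (k in 1:3) v[, , , k] <- morphoval:::smooth_array(v[, , , k], sigma)
  mag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  v <- v * (amplitude / max(mag))
  displacement_field(v, voxel_grid(shape))
}

# default study cohort (the desk-scale study conditions)
default_cohort <- function() {
  fixture("cohort", function() simulate_cohort(cohort_spec(seed = 42L)))
}

default_recipe <- function() {
  phantom_recipe(list(list(label = 3L, op = "erode", radius = 1L),
                      list(label = 4L, op = "dilate", radius = 1L)))
}

# two-subject translated-ball template for the unbiasedness checks:
# balls of radius 8 shifted +-2 voxels about the grid centre (20.5^3)
mdt_symmetry_fixture <- function() {
  fixture("mdt_symmetry", function() {
    shape <- c(40, 40, 40)
    a <- ball_image(shape, c(18.5, 20.5, 20.5), 8)
    b <- ball_image(shape, c(22.5, 20.5, 20.5), 8)
    cfg <- template_config(n_iters = 4, n_downsampled_iters = 2,
                           registration = registration_params(0.25, 3, 0.5))
    build_mdt(list(a, b), cfg)
  })
}

ball_template_centroid <- function(res) {
  tpl <- res$template$data
  w <- pmax(tpl - 0.05 * max(tpl), 0)
  co <- expand_coords(dim(tpl))
  c(sum(co$x * w), sum(co$y * w), sum(co$z * w)) / sum(w)
}

# the full desk-scale phantom study (64^3, 5 controls vs 5 phantoms)
full_study <- function() {
  fixture("full_study", function() {
    run_phantom_study(default_cohort(), default_recipe(),
                      params = registration_params(step = 0.25, reg_update = 3,
                                                   reg_total = 0.5),
                      mdt_cohort = "C", smooth_sigma = 3)
  })
}

# scaled-down study (48^3, 4 controls) for the RegT directional probe,
# run once per RegT arm on the same seeded cohort
probe_study <- function(reg_total) {
  key <- sprintf("probe_regt_%g", reg_total)
  fixture(key, function() {
    cohort <- fixture("probe_cohort", function()
      simulate_cohort(cohort_spec(n_controls = 4L, shape = c(40L, 40L, 40L),
                                  seed = 42L)))
    run_phantom_study(cohort, default_recipe(),
                      params = registration_params(step = 0.25, reg_update = 3,
                                                   reg_total = reg_total),
                      mdt_cohort = "C", smooth_sigma = 3,
                      n_iters = 3L, n_downsampled_iters = 1L,
                      compute_dice = FALSE)
  })
}
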