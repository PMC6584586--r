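test_that("self-registration returns the identity linear map", {
  v <- fixture("reg_ball", function() ball_image(c(48, 48, 48), radius = 9))
  A <- register_linear(v, v, "affine")
  expect_lt(max(abs(A - diag(4))), 1e-3)
})

test_that("linear registration recovers known translations and scalings", {
  shape <- c(48, 48, 48)
  fixed <- ball_image(shape, c(24.5, 24.5, 24.5), 9)
  moved <- ball_image(shape, c(27.5, 24.5, 24.5), 9)
  A <- register_linear(fixed, moved, "affine")
  expect_lt(abs(A[1, 4] - 3), 0.3)
  # scaled 1.1x about the centre: pull-back matrix has scale 1.1
  co <- expand_coords(shape)
  xs <- (co$x - 24.5) / 1.1 + 24.5
  scaled <- scalar_volume(array(
    morphoval:::sample_array(fixed$data, xs, co$y, co$z), shape))
  A2 <- register_linear(fixed, scaled, "affine")
  expect_lt(abs(A2[1, 1] / 1.1 - 1), 0.02)
  expect_error(register_linear(fixed, scalar_volume(array(0, shape))), "empty")
})

test_that("diffeomorphic self-registration is near-zero", {
  v <- ball_image(c(32, 32, 32), radius = 7)
  reg <- register_diffeo(v, v, registration_params(
    step = 0.25, shrink_factors = c(2, 1), smoothing_sigmas = c(1, 0),
    max_iters = 30))
  expect_lt(max(morphoval:::field_magnitude(reg$forward)), 0.05)
})

test_that("diffeo registration recovers a 2-voxel translation inside the object", {
  reg <- fixture("reg_translation", function() {
    fixed <- ball_image(c(64, 64, 64), c(32.5, 32.5, 32.5), 10)
    moving <- ball_image(c(64, 64, 64), c(34.5, 32.5, 32.5), 10)
    list(fixed = fixed, moving = moving,
         reg = register_diffeo(fixed, moving,
                               registration_params(0.25, 3, 0.5)))
  })
  inside <- solid_ball_mask(c(64, 64, 64), c(32.5, 32.5, 32.5), 8)
  mean_dx <- mean(reg$reg$forward$vectors[, , , 1][inside])
  expect_lt(abs(mean_dx - 2) / 2, 0.2)
  # descent contract: final metric below initial, SSD strictly reduced
  tr <- reg$reg$trace$forward
  expect_lte(tr[[length(tr)]]$metric[length(tr[[length(tr)]]$metric)],
             tr[[1]]$metric[1])
  w <- resample(reg$moving, reg$reg$forward, "linear")
  expect_lt(mean((reg$fixed$data - w$data)^2),
            mean((reg$fixed$data - reg$moving$data)^2))
  # the engine is deterministic
  reg2 <- register_diffeo(reg$fixed, reg$moving,
                          registration_params(0.25, 3, 0.5))
  expect_identical(reg2$forward$vectors, reg$reg$forward$vectors)
})

test_that("every returned forward field has positive Jacobian", {
  reg <- fixture("reg_translation", function() stop("built in earlier test"))
  expect_gt(min(jacobian_determinant(reg$reg$forward)$data), 0)
  expect_gt(min(jacobian_determinant(reg$reg$inverse)$data), 0)
})

test_that("the local correlation metric also aligns a translated ball", {
  fixed <- ball_image(c(32, 32, 32), c(16.5, 16.5, 16.5), 7)
  moving <- ball_image(c(32, 32, 32), c(18, 16.5, 16.5), 7)
  reg <- register_diffeo(fixed, moving, registration_params(
    step = 0.25, reg_update = 3, reg_total = 0.5, metric = "lncc",
    shrink_factors = c(2, 1), smoothing_sigmas = c(1, 0), max_iters = 50))
  w <- resample(moving, reg$forward, "linear")
  expect_lt(mean((fixed$data - w$data)^2),
            0.5 * mean((fixed$data - moving$data)^2))
})

test_that("field composition has the translation-group structure", {
  g <- voxel_grid(c(16, 16, 16))
  t1 <- zero_field(g); t1$vectors[, , , 1] <- 1.5
  t2 <- zero_field(g); t2$vectors[, , , 2] <- -2
  z <- zero_field(g)
  expect_equal(compose_fields(z, t1)$vectors, t1$vectors)
  expect_equal(compose_fields(t1, z)$vectors, t1$vectors)
  comp <- compose_fields(t2, t1)
  inner <- 4:12
  expect_equal(comp$vectors[inner, inner, inner, 1],
               array(1.5, c(9, 9, 9)))
  expect_equal(comp$vectors[inner, inner, inner, 2],
               array(-2, c(9, 9, 9)))
})

test_that("inversion is exact for translations and self-consistent for smooth fields", {
  g <- voxel_grid(c(20, 20, 20))
  tr <- zero_field(g); tr$vectors[, , , 1] <- 2
  inv <- invert_field(tr)
  inner <- 5:15
  expect_equal(inv$vectors[inner, inner, inner, 1], array(-2, c(11, 11, 11)),
               tolerance = 1e-10)
  expect_equal(max(abs(invert_field(zero_field(g))$vectors)), 0)
  f <- random_smooth_field(c(32, 32, 32), amplitude = 1.5, seed = 9)
  fi <- invert_field(f)
  resid <- compose_fields(f, fi)
  mag <- morphoval:::field_magnitude(resid)
  expect_lt(max(mag[7:26, 7:26, 7:26]), 0.05)
  resid2 <- compose_fields(fi, f)
  mag2 <- morphoval:::field_magnitude(resid2)
  expect_lt(max(mag2[7:26, 7:26, 7:26]), 0.1)
})

test_that("Jacobian determinants match closed forms", {
  g <- voxel_grid(c(20, 20, 20))
  expect_equal(jacobian_determinant(zero_field(g))$data,
               array(1, c(20, 20, 20)))
  expect_equal(jacobian_determinant(zero_field(g), log_scale = TRUE)$data,
               array(0, c(20, 20, 20)))
  # linear field d(x) = 0.1 (x - x0): det = 1.1^3 exactly
  co <- expand_coords(c(20, 20, 20))
  v <- array(0, c(20, 20, 20, 3))
  v[, , , 1] <- 0.1 * (co$x - 10)
  v[, , , 2] <- 0.1 * (co$y - 10)
  v[, , , 3] <- 0.1 * (co$z - 10)
  jd <- jacobian_determinant(displacement_field(v, g))$data
  expect_lt(max(abs(jd - 1.1^3)), 1e-6)
})

test_that("Jacobian of a composition multiplies approximately", {
  shape <- c(32, 32, 32)
  f <- random_smooth_field(shape, 1.2, seed = 21)
  h <- random_smooth_field(shape, 1.2, seed = 22)
  comp <- compose_fields(f, h)
  jf <- jacobian_determinant(f)$data
  jh <- jacobian_determinant(h)$data
  jc <- jacobian_determinant(comp)$data
  co <- expand_coords(shape)
  jf_at_h <- morphoval:::sample_array(
    jf, co$x + h$vectors[, , , 1], co$y + h$vectors[, , , 2],
    co$z + h$vectors[, , , 3])
  inner <- 7:26
  lhs <- jc[inner, inner, inner]
  rhs <- (jf_at_h * jh)[inner, inner, inner]
  expect_lt(median(abs(lhs - rhs)), 0.02)
})
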