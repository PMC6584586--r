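test_that("base atlas has seven mirror-symmetric labels with distinct contrasts", {
  spec <- cohort_spec()
  base <- fixture("base_atlas", function() make_base_atlas(cohort_spec()))
  expect_setequal(base$labels$label_table$id, 1:7)
  lab <- base$labels$data
  expect_equal(sum(lab == 2), sum(lab == 3))  # left/right Hc
  expect_equal(sum(lab == 4), sum(lab == 5))
  # mirror symmetry: reflection swaps the left/right label ids
  swap <- c(0L, 1L, 3L, 2L, 5L, 4L, 7L, 6L)
  mirrored <- array(swap[lab[dim(lab)[1]:1, , ] + 1L], dim(lab))
  expect_identical(lab, mirrored)
  # distinct per-structure means in each contrast
  fa <- base$atlas$contrasts$FA$data
  expect_gt(mean(fa[lab == 4]), mean(fa[lab == 2]))
  expect_gt(mean(fa[lab == 2]), mean(fa[lab == 1]))
  # determinism
  base2 <- make_base_atlas(spec)
  expect_identical(base2$labels$data, lab)
  expect_identical(base2$atlas$contrasts$FA$data, fa)
})

test_that("right-Hc voxel count matches the analytic ellipsoid rasterization", {
  base <- fixture("base_atlas", function() make_base_atlas(cohort_spec()))
  # independent oracle: count voxels inside the generating ellipsoid
  shp <- c(64, 64, 64)
  ctr <- (shp + 1) / 2 + c(11, 6, 4)
  semi <- c(9, 10, 8)
  co <- expand_coords(shp)
  oracle <- sum(((co$x - ctr[1]) / semi[1])^2 + ((co$y - ctr[2]) / semi[2])^2 +
                  ((co$z - ctr[3]) / semi[3])^2 <= 1)
  expect_equal(sum(base$labels$data == 3), oracle)
  # frozen regression constant for the default geometry
  expect_equal(oracle, 3016)
})

test_that("a degenerate spec reproduces the atlas exactly", {
  spec <- cohort_spec(noise_sigma = 0, max_displacement = 0,
                      affine_jitter = list(translate = 0, rotate_deg = 0,
                                           scale = 0))
  base <- make_base_atlas(spec)
  s <- make_subject(base$atlas, base$labels, spec, 1L)
  expect_equal(max(abs(s$field$vectors)), 0)
  expect_equal(s$image$contrasts$FA$data, base$atlas$contrasts$FA$data)
  expect_identical(s$labels$data, base$labels$data)
})

test_that("generating warps are diffeomorphic and seed-distinct", {
  cohort <- default_cohort()
  jmins <- vapply(cohort$subjects, function(s)
    min(jacobian_determinant(s$field)$data), numeric(1))
  expect_true(all(jmins > 0))
  d12 <- max(abs(cohort$subjects[[1]]$field$vectors -
                   cohort$subjects[[2]]$field$vectors))
  expect_gt(d12, 0)
  # structures deform but survive in every subject
  for (s in cohort$subjects)
    expect_setequal(unique(as.vector(s$labels$data)), 0:7)
})

test_that("cohort generation is a pure function of spec and seed", {
  spec <- cohort_spec(n_controls = 2L, shape = c(32L, 32L, 32L), seed = 9L)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$subjects[[1]]$image$contrasts$FA$data,
                   c2$subjects[[1]]$image$contrasts$FA$data)
  expect_identical(c1$subjects[[2]]$field$vectors, c2$subjects[[2]]$field$vectors)
})

test_that("written cohorts round-trip through the manifest", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_controls = 3L, n_treated = 2L,
                      shape = c(32L, 32L, 32L), seed = 5L)
  manifest <- make_cohort(spec, dir)
  pred <- read.csv(file.path(dir, "predictors.csv"))
  expect_equal(nrow(pred), 5)
  expect_equal(sum(pred$group == "control"), 3)
  expect_equal(sum(pred$group == "treated"), 2)
  expect_named(pred, c("specimen_id", "runno", "group", "age", "gender",
                       "treatment"))
  paths <- c(unlist(manifest$atlas), unlist(lapply(manifest$subjects, unlist)),
             manifest$predictors)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(dir)
  mem <- simulate_cohort(spec)
  expect_equal(back$subjects[[1]]$image$contrasts$FA$data,
               mem$subjects[[1]]$image$contrasts$FA$data)
  expect_identical(back$labels$data, mem$labels$data)
  expect_equal(back$subjects[[2]]$field$vectors,
               mem$subjects[[2]]$field$vectors)
})
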