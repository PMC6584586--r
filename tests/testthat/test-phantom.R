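test_that("phantom recipes validate their edits", {
  expect_error(phantom_recipe(list(list(label = 2, op = "grow", radius = 1))),
               "dilate or erode")
  expect_error(phantom_recipe(list(list(label = 2, op = "erode", radius = 0))),
               "radius")
  expect_error(phantom_recipe(list(list(label = 2, op = "erode", radius = 1),
                                   list(label = 2, op = "dilate", radius = 1))),
               "twice")
})

test_that("target masks apply the edits with voxel-count oracles", {
  shape <- c(36, 36, 36)
  lab <- array(0L, shape)
  lab[solid_ball_mask(shape, c(18, 18, 18), 6)] <- 1L
  lv <- label_volume(lab)
  rec <- phantom_recipe(list(list(label = 1L, op = "dilate", radius = 1L)))
  tm <- make_target_masks(lv, rec)
  # dilating the rasterized ball r=6 by a radius-1 spherical element
  oracle <- sum(dilate(solid_ball_mask(shape, c(18, 18, 18), 6), 1))
  expect_equal(sum(tm$target_merged), oracle)
  expect_identical(tm$original_merged, lab == 1L)
  # a thin structure eroded beyond existence errors
  thin <- array(0L, shape); thin[10:12, 10:30, 10:12] <- 7L
  lt <- label_volume(thin)
  expect_error(make_target_masks(
    lt, phantom_recipe(list(list(label = 7L, op = "erode", radius = 2L)))),
    "annihilated")
  # intersecting edits are rejected
  two <- array(0L, shape)
  two[solid_ball_mask(shape, c(14, 18, 18), 4)] <- 1L
  two[solid_ball_mask(shape, c(24, 18, 18), 4)] <- 2L
  expect_error(make_target_masks(
    label_volume(two),
    phantom_recipe(list(list(label = 1L, op = "dilate", radius = 2L),
                        list(label = 2L, op = "dilate", radius = 2L)))),
    "intersect")
})

test_that("a no-edit recipe returns the subject unchanged", {
  cohort <- default_cohort()
  s <- cohort$subjects[[1]]
  out <- make_phantom_subject(s$image, s$labels, phantom_recipe(list()))
  expect_identical(out$phantom$contrasts$FA$data, s$image$contrasts$FA$data)
  expect_equal(nrow(out$truth), 0)
  expect_equal(max(abs(out$field$vectors)), 0)
})

test_that("induced erosion tracks the voxel-count volume ratio", {
  res <- fixture("ball_erosion", function() {
    shape <- c(40, 40, 40)
    lab <- array(0L, shape)
    lab[solid_ball_mask(shape, c(20.5, 20.5, 20.5), 8)] <- 1L
    lv <- label_volume(lab)
    rec <- phantom_recipe(list(list(label = 1L, op = "erode", radius = 1L)))
    tm <- make_target_masks(lv, rec)
    iw <- induce_warp(tm$original_merged, tm$target_merged, lv$grid,
                      rec$registration)
    list(tm = tm, iw = iw)
  })
  ratio <- sum(res$tm$target_merged) / sum(res$tm$original_merged)
  jac <- jacobian_determinant(res$iw$inverse)$data
  mj <- mean(jac[res$tm$original_merged])
  expect_lt(abs(mj - ratio) / ratio, 0.15)
  # atrophy sign: negative log-Jacobian inside the eroded structure
  expect_lt(mean(log(pmax(jac[res$tm$original_merged], 1e-6))), 0)
  # locality: negligible volume change far from the edited structure
  far <- !dilate(res$tm$original_merged, 6)
  expect_lt(abs(mean(jac[far]) - 1), 0.01)
})

test_that("phantom subjects carry consistent measured truth", {
  ph <- fixture("phantom_s1", function() {
    cohort <- default_cohort()
    s <- cohort$subjects[[1]]
    make_phantom_subject(s$image, s$labels, default_recipe())
  })
  truth <- ph$truth
  expect_equal(sort(truth$label), c(3, 4))
  erode_row <- truth[truth$op == "erode", ]
  dilate_row <- truth[truth$op == "dilate", ]
  expect_lt(erode_row$percent_change, 0)
  expect_gt(dilate_row$percent_change, 0)
  expect_lt(erode_row$mean_log_jacobian, 0)
  expect_gt(dilate_row$mean_log_jacobian, 0)
  # log/linear consistency: the Jensen gap between exp(mean log J) and
  # mean J stays small relative to the induced change
  expect_lt(abs((exp(erode_row$mean_log_jacobian) - 1) * 100 -
                  erode_row$percent_change), 3)
  # deterministic given subject and recipe
  cohort <- default_cohort()
  again <- make_phantom_subject(cohort$subjects[[1]]$image,
                                cohort$subjects[[1]]$labels, default_recipe())
  expect_identical(again$field$vectors, ph$field$vectors)
})

test_that("cohort truth summarizes means and sample sds", {
  t1 <- data.frame(label = 3L, op = "erode", mean_jacobian = 0.90,
                   mean_log_jacobian = log(0.90), percent_change = -10)
  t2 <- data.frame(label = 3L, op = "erode", mean_jacobian = 0.86,
                   mean_log_jacobian = log(0.86), percent_change = -14)
  s <- summarize_cohort_truth(list(t1, t2))
  expect_equal(s$mean_percent_change, -12)
  expect_equal(s$sd_percent_change, sd(c(-10, -14)))
  s1 <- summarize_cohort_truth(list(t1))
  expect_equal(s1$mean_percent_change, -10)
  expect_equal(s1$sd_percent_change, 0)
})
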