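test_that("analysis-mask erosion matches the voxel-count oracle", {
  shape <- c(32, 32, 32)
  m <- solid_ball_mask(shape, c(16.5, 16.5, 16.5), 10)
  expect_identical(make_analysis_mask(m, 0), m)
  er <- make_analysis_mask(m, 3)
  expect_equal(sum(er), sum(erode(m, 3)))
  expect_true(all(m[er]))  # eroded subset of original
  expect_error(make_analysis_mask(solid_ball_mask(shape, c(16, 16, 16), 2), 3),
               "emptied")
})

test_that("separable smoothing matches a banded-matrix reference", {
  set.seed(8)
  a <- array(rnorm(22 * 18 * 26), c(22, 18, 26))
  for (sigma in c(0.5, 1, 3)) {
    ref <- a
    for (ax in 1:3)
      ref <- morphoval:::apply_axis(
        ref, morphoval:::gauss_kernel_matrix(dim(a)[ax], sigma), ax)
    expect_equal(morphoval:::smooth_array(a, sigma), ref, tolerance = 1e-13)
  }
})

test_that("map smoothing preserves constants and interior mass", {
  v <- scalar_volume(array(2.5, c(20, 20, 20)))
  expect_lt(max(abs(smooth_map(v, 3)$data - 2.5)), 1e-12)
  expect_identical(smooth_map(v, 0)$data, v$data)
  a <- array(0, c(31, 31, 31)); a[16, 16, 16] <- 1
  sm <- smooth_map(scalar_volume(a), 3)
  expect_lt(abs(sum(sm$data) - 1), 1e-3)
})

test_that("the voxelwise t-test matches the reference t distribution", {
  shape <- c(4, 4, 4)
  mask <- array(TRUE, shape)
  mk <- function(val) scalar_volume(array(val, shape))
  st <- voxelwise_ttest(list(mk(0), mk(2)), list(mk(3), mk(5)), mask)
  expect_equal(st$effect$data[1], 3)
  expect_equal(st$t$data[1], 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(st$df, 2)
  expect_equal(st$p_greater$data[1], pt(3 / sqrt(2), df = 2, lower.tail = FALSE))
  # oracle: t.test with pooled variance on the same numbers
  tt <- t.test(c(3, 5), c(0, 2), var.equal = TRUE, alternative = "greater")
  expect_equal(st$p_greater$data[1], tt$p.value, tolerance = 1e-12)
  # identical groups: t = 0, both tails 0.5
  st0 <- voxelwise_ttest(list(mk(1), mk(2)), list(mk(1), mk(2)), mask)
  expect_true(all(st0$t$data == 0))
  expect_true(all(st0$p_greater$data == 0.5))
  # swapping groups negates t and effect and swaps the tails
  sw <- voxelwise_ttest(list(mk(3), mk(5)), list(mk(0), mk(2)), mask)
  expect_equal(sw$t$data, -st$t$data)
  expect_equal(sw$effect$data, -st$effect$data)
  expect_equal(sw$p_greater$data, st$p_less$data)
  expect_error(voxelwise_ttest(list(mk(1)), list(mk(1), mk(2)), mask),
               "at least 2")
})

test_that("t-test sentinels and q-maps respect the analysis mask", {
  shape <- c(6, 6, 6)
  mask <- array(FALSE, shape); mask[2:5, 2:5, 2:5] <- TRUE
  set.seed(1)
  g1 <- replicate(3, scalar_volume(array(rnorm(prod(shape)), shape)),
                  simplify = FALSE)
  g2 <- replicate(3, scalar_volume(array(rnorm(prod(shape)), shape)),
                  simplify = FALSE)
  st <- voxelwise_ttest(g1, g2, mask)
  expect_true(all(st$p_greater$data[!mask] == 1))
  expect_true(all(st$q_greater$data[!mask] == 1))
  expect_true(all(st$q_greater$data[mask] >= st$p_greater$data[mask]))
  expect_true(all(st$p_greater$data[mask] >= 0 & st$p_greater$data[mask] <= 1))
})

test_that("BH q-values match a brute-force step-up implementation", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m)) {
      js <- i:m
      q[o[i]] <- min(pmin(p[o[js]] * m / js, 1))
    }
    q
  }
  # hand-executed example
  p4 <- c(0.01, 0.02, 0.03, 0.04)
  mask4 <- array(TRUE, c(4, 1, 1))
  q4 <- fdr_correct(array(p4, c(4, 1, 1)), mask4)$data
  expect_equal(as.vector(q4), rep(0.04, 4))
  # uniform case
  qc <- fdr_correct(array(0.2, c(5, 1, 1)), array(TRUE, c(5, 1, 1)))$data
  expect_equal(as.vector(qc), rep(0.2, 5))
  # random vectors, exact agreement
  set.seed(42)
  for (m in c(10, 101, 1000)) {
    p <- runif(m)^2
    q <- fdr_correct(array(p, c(m, 1, 1)), array(TRUE, c(m, 1, 1)))$data
    expect_equal(as.vector(q), brute_bh(p), tolerance = 1e-14)
  }
})

test_that("permutation p-values use exhaustive enumeration for tiny groups", {
  shape <- c(3, 1, 1)
  mask <- array(TRUE, shape)
  mk <- function(v) scalar_volume(array(v, shape))
  # group2 strictly above group1 -> observed stat is the unique maximum
  p <- permutation_pmap(list(mk(0), mk(1)), list(mk(10), mk(11)), mask,
                        n_perm = 100, seed = 1)
  expect_true(attr(p, "exhaustive"))
  expect_equal(as.vector(p$data), rep(1 / 6, 3))
  # all subjects identical: every permutation ties the observed stat
  p2 <- permutation_pmap(list(mk(2), mk(2)), list(mk(2), mk(2)), mask,
                         n_perm = 100, seed = 1)
  expect_equal(as.vector(p2$data), rep(1, 3))
})

test_that("sampled permutation p-values are seed-reproducible", {
  shape <- c(10, 1, 1)
  mask <- array(TRUE, shape)
  set.seed(3)
  g1 <- replicate(5, scalar_volume(array(rnorm(10), shape)), simplify = FALSE)
  g2 <- replicate(5, scalar_volume(array(rnorm(10, 0.5), shape)),
                  simplify = FALSE)
  pa <- permutation_pmap(g1, g2, mask, n_perm = 150, seed = 7)
  pb <- permutation_pmap(g1, g2, mask, n_perm = 150, seed = 7)
  pc <- permutation_pmap(g1, g2, mask, n_perm = 150, seed = 8)
  expect_false(attr(pa, "exhaustive"))
  expect_identical(pa$data, pb$data)
  expect_false(identical(pa$data, pc$data))
})
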