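test_that("implied volume change matches the closed form", {
  expect_equal(round(implied_volume_change(-0.146), 1), -13.6)
  expect_equal(implied_volume_change(0), 0)
  expect_equal(implied_volume_change(log(2)), 100)
})

test_that("distance from target is a symmetric absolute difference", {
  expect_equal(distance_from_target(-13.6, -13.6), 0)
  expect_equal(distance_from_target(-13.6, -11.7), 1.9)
  expect_equal(distance_from_target(-11.7, -13.6), 1.9)
})

test_that("leakage regions follow the dilation/exclusion/clipping rules", {
  shape <- c(40, 40, 40)
  brain <- array(TRUE, shape)
  s <- solid_ball_mask(shape, c(20.5, 20.5, 20.5), 6)
  leak <- leakage_region(s, list(s), brain)
  expect_equal(sum(leak), sum(dilate(s, 2)) - sum(s))
  expect_false(any(leak & s))
  # two altered structures exclude each other
  s2 <- solid_ball_mask(shape, c(30.5, 20.5, 20.5), 4)
  leak1 <- leakage_region(s, list(s, s2), brain)
  expect_false(any(leak1 & s2))
  # clipping to the brain mask
  small_brain <- solid_ball_mask(shape, c(20.5, 20.5, 20.5), 7)
  leak_clip <- leakage_region(s, list(s), small_brain)
  expect_true(all(small_brain[leak_clip]))
  expect_lt(sum(leak_clip), sum(leak))
})

test_that("inner shells match target volumes by erosion depth", {
  shape <- c(32, 32, 32)
  s <- solid_ball_mask(shape, c(16.5, 16.5, 16.5), 10)
  shell2 <- s & !erode(s, 2)
  out <- inner_shell(s, sum(shell2))
  expect_identical(out, shell2)
  # saturation: target beyond the structure returns the whole structure
  expect_identical(inner_shell(s, sum(s) + 100), s)
  # containment
  out1 <- inner_shell(s, 50)
  expect_true(all(s[out1]))
})

test_that("d-prime reproduces hand-computed values and its invariances", {
  e <- array(0, c(3, 2, 1))
  e[, 1, 1] <- c(1, 2, 3)
  e[, 2, 1] <- c(-1, 0, 1)
  sig <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), c(3, 2, 1))
  noi <- !sig
  expect_equal(d_prime(e, sig, noi), sqrt(2), tolerance = 1e-12)
  expect_equal(d_prime(e * 3.7, sig, noi), d_prime(e, sig, noi))
  expect_equal(d_prime(e + 5, sig, noi), d_prime(e, sig, noi))
  expect_equal(d_prime(e, sig, sig), 0)
  expect_error(d_prime(array(1, c(2, 2, 1)),
                       array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1)),
                       array(c(FALSE, FALSE, TRUE, TRUE), c(2, 2, 1))),
               "variance")
})

test_that("ROC handles perfect separation and matches Mann-Whitney", {
  shape <- c(10, 10, 5)
  brain <- array(TRUE, shape)
  s <- array(FALSE, shape); s[1:3, , ] <- TRUE
  p <- array(0.99, shape); p[s] <- 0.01
  roc <- roc_curve(p, s, brain)
  expect_equal(roc$auc, 1)
  expect_equal(roc$tpr_at_p05, 100)
  # Mann-Whitney concordance oracle with tie half-credit, small instances
  set.seed(13)
  for (rep in 1:5) {
    pv <- array(round(runif(500), 2), c(500, 1, 1))
    sv <- array(runif(500) < 0.3, c(500, 1, 1))
    if (!any(sv) || all(sv)) next
    roc2 <- roc_curve(pv, sv, array(TRUE, c(500, 1, 1)))
    ps <- pv[sv]; pn <- pv[!sv]
    conc <- 0
    for (x in ps) conc <- conc + sum(x < pn) + 0.5 * sum(x == pn)
    expect_equal(roc2$auc, conc / (length(ps) * length(pn)),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(p, array(FALSE, shape), brain), "empty")
})

test_that("ROC of uniform p-values is chance level", {
  set.seed(99)
  auc <- replicate(5, {
    pv <- array(runif(1e4), c(100, 10, 10))
    sv <- array(FALSE, c(100, 10, 10)); sv[1:20, , ] <- TRUE
    roc_curve(pv, sv, array(TRUE, c(100, 10, 10)))$auc
  })
  expect_true(all(abs(auc - 0.5) < 0.03))
})

test_that("Dice handles identity, disjoint and partial overlap", {
  mk <- function(idx) {
    a <- array(0L, c(4, 4, 4)); a[idx] <- 1L
    label_volume(a)
  }
  a <- mk(1:8); b <- mk(1:8)
  expect_equal(dice(a, b, 1L), 1)
  expect_equal(dice(mk(1:4), mk(5:8), 1L), 0)
  expect_equal(dice(mk(1:2), mk(2:3), 1L), 0.5)
  expect_error(dice(mk(1), mk(1), 2L), "absent")
})

test_that("parameter-set ranking uses competition ranks and dominance", {
  rec <- function(id, dd, dp, auc, tpr, dice, rt) {
    data.frame(param_set = id, structure = c("hc", "cpu"),
               delta_d = dd, d_prime = dp, auc = auc, tpr_at_p05 = tpr,
               dice = dice, runtime_s = rt)
  }
  # one set dominates every metric
  r <- rbind(rec("good", 1, 3, 0.95, 90, 0.95, 10),
             rec("bad", 5, 1, 0.80, 50, 0.85, 20))
  rk <- rank_parameter_sets(r)
  good <- rk[rk$param_set == "good", ]
  expect_equal(good$phantom_rank, 1L)
  expect_equal(good$final_rank, 1L)
  expect_true(all(unlist(good[grep("_rank$", names(good))]) == 1))
  # phantom averages 6.9 < 7.0 < 7.3 rank 1, 2, 3
  r3 <- rbind(rec("a", 1, 3, .9, 80, .9, 10), rec("b", 2, 2, .85, 70, .9, 10),
              rec("c", 3, 1, .8, 60, .9, 10))
  rk3 <- rank_parameter_sets(r3)
  expect_equal(rk3$phantom_rank[order(rk3$phantom_average)], c(1L, 2L, 3L))
  # ties get the minimal rank and the next rank is skipped
  rt <- rbind(rec("x", 1, 2, .9, 80, .9, 10), rec("y", 1, 2, .9, 80, .9, 10),
              rec("z", 4, 1, .8, 60, .8, 30))
  rkt <- rank_parameter_sets(rt)
  expect_equal(sort(rkt$final_rank), c(1L, 1L, 3L))
  expect_error(rank_parameter_sets(rec("solo", 1, 1, .9, 80, .9, 10)),
               ">= 2")
})
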