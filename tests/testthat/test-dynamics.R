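test_that("return maps slide within trials only", {
  s <- isi_series(list(rep(5, 6)))
  m <- build_return_map(s)
  expect_equal(dim(m), c(4, 3))
  expect_true(all(m == 5))

  s2 <- isi_series(list(c(1, 2, 3, 4)))
  m2 <- build_return_map(s2)
  expect_equal(unname(m2), rbind(c(1, 2, 3), c(2, 3, 4)))

  # two trials of 2 ISIs each admit no within-trial triplet
  s3 <- isi_series(list(c(1, 2), c(3, 4)))
  expect_equal(nrow(build_return_map(s3)), 0)

  expect_error(build_return_map(isi_series(list(c(1, 2)))), "shorter")
  expect_error(isi_series(list(c(1, -2))), "> 0")

  # point count = sum over trials of max(0, len - 2)
  set.seed(4)
  for (rep in 1:5) {
    lens <- sample(0:6, 4, replace = TRUE)
    trials <- lapply(lens, function(l) runif(l, 1, 20))
    s <- isi_series(trials)
    if (length(s$values) < 3) next
    expect_equal(nrow(build_return_map(s)), sum(pmax(0, lens - 2)))
  }
})

test_that("normalized entropy hits its anchor cases", {
  expect_equal(normalized_entropy(matrix(rep(c(1, 2, 3), 50), ncol = 3,
                                         byrow = TRUE)), 0)
  # 1-D counts {2,0,0,2} over 4 bins -> H = 1 bit over 2 bits
  expect_equal(normalized_entropy(c(1, 1, 2, 2), bins = 4), 0.5)
  # exactly uniform occupancy over all bins -> 1
  pts <- as.matrix(expand.grid(1:4, 1:4, 1:4))
  expect_equal(normalized_entropy(pts, bins = 4), 1)
  expect_error(normalized_entropy(matrix(numeric(0), ncol = 3)), "points")
  expect_error(normalized_entropy(1:5, bins = 1), "bins")

  # permutation invariance and range
  set.seed(9)
  m <- matrix(rexp(300), ncol = 3)
  e <- normalized_entropy(m)
  expect_equal(normalized_entropy(m[sample(100), ]), e)
  expect_true(e >= 0 && e <= 1)
})

test_that("the two-sample KS test behaves at its anchors", {
  x <- c(1, 2, 3, 4, 5)
  r <- ks_two_sample(x, x)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)

  set.seed(2)
  a <- runif(400, 0, 1); b <- runif(400, 2, 3)
  expect_equal(ks_two_sample(a, b)$D, 1)

  expect_error(ks_two_sample(numeric(0), 1:3), "empty")

  # asymptotic p agrees with a permutation estimate
  set.seed(31)
  a <- rnorm(60); b <- rnorm(60, 0.3)
  obs <- ks_two_sample(a, b)
  pool <- c(a, b)
  perm <- replicate(400, {
    idx <- sample(120, 60)
    ks_two_sample(pool[idx], pool[-idx])$D
  })
  p_perm <- mean(perm >= obs$D - 1e-12)
  expect_equal(obs$p, p_perm, tolerance = 0.1)
})

test_that("the local-constant predictor scores its anchor series", {
  expect_equal(predict_isi_series(rep(4, 200))$error, rep(0, 10))

  # noiseless period-3 series: every neighbour shares the exact future
  per3 <- rep(c(5, 8, 13), 80)
  expect_lt(predict_isi_series(per3)$error[1], 0.05)

  set.seed(5)
  iid <- rnorm(2000, 10, 2)
  e1 <- predict_isi_series(iid)$error[1]
  expect_equal(e1, 1, tolerance = 0.1)

  expect_error(predict_isi_series(rep(1:3, 10)), "short")
  pr <- predict_isi_series(per3)
  expect_true(all(pr$error >= 0))
})

test_that("shuffling a structured series cannot improve predictability", {
  set.seed(6)
  x <- rep(c(5, 8, 13, 21), 60) + rnorm(240, 0, 0.2)
  e_orig <- predict_isi_series(x)$error[1]
  e_shuf <- vapply(1:3, function(i) {
    predict_isi_series(sample(x))$error[1]
  }, numeric(1))
  expect_true(all(e_shuf > e_orig - 0.05))
})

test_that("sigmoid fits recover generating parameters", {
  truth <- c(base = 4.964, max = -3.962, xhalf = 111.31, rate = 20.152)
  f <- function(x) truth["base"] +
    truth["max"] / (1 + exp(-(x - truth["xhalf"]) / truth["rate"]))
  x <- delay_grid("full")
  fit <- fit_sigmoid(x, f(x))
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), unname(truth), tolerance = 0.01)
  expect_equal(unname(predict(fit, 111.31)),
               unname(truth["base"] + truth["max"] / 2),
               tolerance = 0.01)

  # flat response degrades to |max| ~ 0
  flat <- fit_sigmoid(x, rep(2, length(x)))
  expect_lt(abs(coef(flat)["max"]), 0.05)

  # noisy recovery: the half-activation delay is stable across seeds
  xh <- vapply(1:20, function(s) {
    set.seed(s)
    coef(fit_sigmoid(x, f(x) + rnorm(length(x), 0, 0.1)))["xhalf"]
  }, numeric(1))
  expect_lt(abs(mean(xh) - 111.31), 5)
})
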