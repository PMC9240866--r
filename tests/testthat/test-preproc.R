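flat_motion <- function(n = 20, value = 0.3) {
  as.data.frame(matrix(value, n, 6, dimnames = list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))))
}

test_that("constant motion gives zero framewise displacement", {
  fd <- framewise_displacement(flat_motion())
  expect_equal(fd$fd, rep(0, 20))
  expect_equal(fd$n_above, 0)
  expect_equal(fd$mean_fd, 0)
})

test_that("FD follows the additive displacement formula", {
  m <- flat_motion(10, 0)
  m$tx[5:10] <- 0.2  # single 0.2 mm translation step at volume 5
  fd <- framewise_displacement(m)
  expect_equal(fd$fd[5], 0.2)
  expect_equal(fd$fd[-5], rep(0, 9))
  # a 0.01 rad rotation step on a 50 mm sphere contributes 0.5 mm
  m2 <- flat_motion(10, 0)
  m2$rx[7:10] <- 0.01
  fd2 <- framewise_displacement(m2, sphere_radius = 50)
  expect_equal(fd2$fd[7], 0.5)
  expect_equal(fd2$n_above, 0)  # 0.5 is not > 0.5
})

test_that("FD is invariant to constant offsets and first volume is zero", {
  set.seed(2)
  m <- as.data.frame(matrix(rnorm(60), 10, 6))
  fd1 <- framewise_displacement(m)
  fd2 <- framewise_displacement(m + 5)
  expect_equal(fd1$fd, fd2$fd)
  expect_equal(fd1$fd[1], 0)
  expect_true(all(fd1$fd >= 0))
})

test_that("malformed motion input is rejected", {
  expect_error(framewise_displacement(matrix(0, 10, 5)), "6 columns")
  expect_error(framewise_displacement(flat_motion(1)), "at least 2")
})

test_that("motion exclusion policy with strict-inequality boundary rule", {
  good <- framewise_displacement(flat_motion())
  expect_true(motion_exclude(good)$keep)
  # 40/150 volumes above 0.5 mm: fraction 0.267 > 0.25 -> exclude
  m <- flat_motion(150, 0)
  m$tx <- cumsum(c(rep(0, 110), rep(0.6, 40)) * rep(c(1, -1), 75))
  fd <- framewise_displacement(m)
  expect_equal(fd$n_above, 40)
  dec <- motion_exclude(fd, max_fd_fraction = 0.25)
  expect_false(dec$keep)
  expect_equal(dec$reason, "motion")
  # exactly at the limit keeps the subject
  dec2 <- motion_exclude(fd, max_fd_fraction = 40 / 150)
  expect_true(dec2$keep)
})

test_that("winsorization clips at the percentile of the original row", {
  set.seed(9)
  x <- rnorm(100)
  x[13] <- 40  # one extreme spike
  pan <- ts_panel(matrix(x, 1), tr = 2)
  out <- winsorize_detrend(pan)
  # undo the (tiny) detrend to compare against the quantile oracle
  hi <- quantile(x, 0.95, names = FALSE)
  lo <- quantile(x, 0.05, names = FALSE)
  clipped <- pmin(pmax(x, lo), hi)
  tt <- 1:100
  fit <- lm(clipped ~ tt)
  expect_equal(out$values[1, ], unname(resid(fit)), tolerance = 1e-10)
  expect_equal(max(out$values[1, ] - (clipped - fitted(fit))), 0, tolerance = 1e-10)
})

test_that("detrending removes an exact line and zero-means each region", {
  ramp <- 3 + 0.5 * (1:50)
  pan <- ts_panel(rbind(ramp, rep(7, 50)), tr = 2)
  out <- winsorize_detrend(pan, winsor_upper_percentile = 99.9)
  # oracle: same clipping, then least-squares line removal
  clipped <- pmin(pmax(ramp, quantile(ramp, 0.001, names = FALSE)),
                  quantile(ramp, 0.999, names = FALSE))
  tt <- 1:50
  expect_equal(out$values[1, ], unname(resid(lm(clipped ~ tt))),
               tolerance = 1e-10, ignore_attr = TRUE)
  # and the residual of a near-exact line is tiny relative to its range
  expect_lt(max(abs(out$values[1, ])), 0.01 * diff(range(ramp)))
  expect_equal(out$values[2, ], rep(0, 50), ignore_attr = TRUE)  # constant row
  set.seed(4)
  noise <- ts_panel(matrix(rnorm(200), 2), tr = 2)
  out2 <- winsorize_detrend(noise)
  expect_equal(rowMeans(out2$values), c(0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("nuisance regression projects out the regressor span exactly", {
  set.seed(6)
  tt <- 80
  motion <- matrix(rnorm(tt * 6), tt, 6)
  nuis <- data.frame(wm = rnorm(tt), csf = rnorm(tt))
  X <- cbind(1, motion, nuis$wm, nuis$csf)
  combo <- drop(X %*% runif(9, -1, 1))          # exact linear combination
  orth <- qr.resid(qr(X), rnorm(tt))            # orthogonal by construction
  pan <- ts_panel(rbind(combo, orth + 3), tr = 2)
  out <- nuisance_regression(pan, motion, nuis)
  expect_equal(max(abs(out$values[1, ])), 0, tolerance = 1e-8)
  expect_equal(out$values[2, ], unname(orth), tolerance = 1e-8)
  # residuals orthogonal to every regressor
  for (k in 2:9) {
    expect_lt(abs(cor(out$values[2, ], X[, k])), 1e-8)
  }
})

test_that("collinear regressors are dropped with a warning, volume mismatch errors", {
  set.seed(1)
  pan <- ts_panel(matrix(rnorm(120), 2), tr = 2)
  motion <- matrix(rnorm(60 * 6), 60, 6)
  motion[, 2] <- 2 * motion[, 1]
  nuis <- data.frame(wm = rnorm(60), csf = rnorm(60))
  expect_warning(nuisance_regression(pan, motion, nuis), "collinear")
  expect_error(nuisance_regression(pan, motion[1:59, ], nuis), "do not match")
})

test_that("preprocessing is deterministic and order is fixed", {
  set.seed(12)
  pan <- ts_panel(matrix(rnorm(5 * 120), 5), tr = 2)
  motion <- matrix(rnorm(120 * 6, sd = 0.01), 120, 6)
  nuis <- data.frame(wm = rnorm(120), csf = rnorm(120))
  a <- preprocess_panel(pan, motion, nuis)
  b <- preprocess_panel(pan, motion, nuis)
  expect_identical(a$values, b$values)
  expect_true(all(is.finite(a$values)))
})
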