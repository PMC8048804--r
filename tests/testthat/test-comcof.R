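test_that("the COM proxy is the stated convex combination", {
  expect_equal(com_proxy(c(1, 2, 3), c(3, 4, 5), w = 0.5),
               matrix(c(2, 3, 4), ncol = 3))
  expect_equal(com_proxy(c(1, 2, 3), c(9, 9, 9), w = 1),
               matrix(c(1, 2, 3), ncol = 3))
  out <- com_proxy(c(0, 0, 1.2), c(0, -0.5, 1.4), w = 0.6)
  expect_equal(c(out), c(0, -0.2, 1.28), tolerance = 1e-12)
  expect_error(com_proxy(c(0, 0, 1), c(0, 0, 1), w = 1.2))
})

test_that("the COF is the force-weighted hoof centroid", {
  # equal forces at the corners of a rectangle -> centre
  f <- matrix(500, 1, 4)
  hx <- matrix(c(-0.2, 0.2, -0.2, 0.2), 1, 4)
  hy <- matrix(c(0.6, 0.6, -0.6, -0.6), 1, 4)
  expect_equal(c(cof(f, hx, hy)), c(0, 0))
  # a single supporting limb gives that hoof exactly
  f1 <- matrix(c(800, 0, 0, 0), 1, 4)
  expect_equal(c(cof(f1, hx, hy)), c(-0.2, 0.6))
  # hand-computed weighted mean
  f2 <- matrix(c(300, 0, 0, 100), 1, 4)
  hx2 <- matrix(c(-0.1, 0, 0, 0.1), 1, 4)
  hy2 <- matrix(c(1, 0, 0, -1), 1, 4)
  expect_equal(c(cof(f2, hx2, hy2)), c(-0.05, 0.5), tolerance = 1e-12)
  # zero total force -> undefined frame
  expect_true(all(is.na(cof(matrix(0, 1, 4), hx, hy))))
  # invariance under uniform force scaling
  expect_equal(cof(f2 * 7.3, hx2, hy2), cof(f2, hx2, hy2))
})

test_that("marker resampling is exact for constants and linear signals", {
  mt <- seq(0, 2, by = 1 / 256)
  ft <- seq(0, 2, by = 1 / 512)
  expect_equal(c(resample_markers(mt, rep(3.3, length(mt)), ft)),
               rep(3.3, length(ft)))
  expect_equal(c(resample_markers(mt, 2 * mt - 1, ft)), 2 * ft - 1,
               tolerance = 1e-12)
  z <- sin(2 * pi * 2 * mt)
  err <- abs(c(resample_markers(mt, z, ft)) - sin(2 * pi * 2 * ft))
  # linear-interpolation bound (2 pi f h)^2 / 8 at 256 Hz and 2 Hz
  expect_lt(max(err[ft <= max(mt)]), (2 * pi * 2 / 256)^2 / 8)
  expect_error(resample_markers(mt, z, ft + 10), "overlap")
})

test_that("the COF stays within the support polygon on a walk trial", {
  tr <- nf_trial("walk")
  path <- cof_path(tr)
  tf <- tr$forces$time_s
  mt <- tr$markers$time_s
  f <- as.matrix(tr$forces[, paste0(c("LF", "RF", "LH", "RH"), "_N")])
  hx <- hy <- matrix(NA_real_, length(tf), 4)
  for (k in seq_along(c("LF", "RF", "LH", "RH"))) {
    l <- c("LF", "RF", "LH", "RH")[k]
    hx[, k] <- stats::approx(mt, tr$markers[[paste0("hoof_", l, "_x_m")]], tf,
                             rule = 2)$y
    hy[, k] <- stats::approx(mt, tr$markers[[paste0("hoof_", l, "_y_m")]], tf,
                             rule = 2)$y
  }
  cf <- cof(f, hx, hy)
  act <- f > 0
  ok <- rowSums(f) > 0
  # bounding-box containment of the weighted mean, every defined frame
  lo_x <- apply(ifelse(act, hx, Inf), 1, min)
  hi_x <- apply(ifelse(act, hx, -Inf), 1, max)
  lo_y <- apply(ifelse(act, hy, Inf), 1, min)
  hi_y <- apply(ifelse(act, hy, -Inf), 1, max)
  expect_true(all(cf[ok, "x"] >= lo_x[ok] - 1e-9 &
                    cf[ok, "x"] <= hi_x[ok] + 1e-9))
  expect_true(all(cf[ok, "y"] >= lo_y[ok] - 1e-9 &
                    cf[ok, "y"] <= hi_y[ok] + 1e-9))
})

test_that("the walk COF-COM path closes over a stride", {
  tr <- nf_trial("walk")
  path <- cof_path(tr)
  st <- tr$ground_truth$stride_starts
  i0 <- which.min(abs(path$time_s - st[4]))
  i1 <- which.min(abs(path$time_s - st[5]))
  ext <- max(path$dy_m[i0:i1], na.rm = TRUE) -
    min(path$dy_m[i0:i1], na.rm = TRUE)
  closure <- sqrt((path$dx_m[i1] - path$dx_m[i0])^2 +
                    (path$dy_m[i1] - path$dy_m[i0])^2)
  expect_lt(closure, 0.05 * ext)
})

test_that("side metrics respond to a cranial shift and symmetric paths are balanced", {
  # constructed stride: left-side window phases 1-2, right-side 5-6
  tf <- seq(0, 1, by = 1 / 512)
  phases <- tibble::tibble(
    label = as.character(1:8),
    t_start = seq(0, 0.875, by = 0.125),
    t_end = seq(0.125, 1, by = 0.125),
    duration = 0.125, pct = 12.5)
  com <- cbind(rep(0, length(tf)), rep(0, length(tf)), rep(1.2, length(tf)))
  base_y <- 0.3 * sin(4 * pi * tf)
  cofxy <- cbind(x = rep(0, length(tf)), y = base_y)
  m0 <- cof_com_metrics(cofxy, com, tf, phases, c(0, 1), "left")
  expect_equal(m0$COF_asym, 0, tolerance = 1e-9)
  # shift the path cranially by delta within the right-side window only
  delta <- 0.04
  shifted <- base_y + delta * (tf >= 0.5 & tf < 0.75)
  m1 <- cof_com_metrics(cbind(x = 0 * tf, y = shifted), com, tf, phases,
                        c(0, 1), "left")
  expect_equal(m1$COF_asym, -delta, tolerance = 1e-9)
  # mirrored lameness convention
  m2 <- cof_com_metrics(cbind(x = 0 * tf, y = shifted), com, tf, phases,
                        c(0, 1), "right")
  expect_equal(m2$COF_asym, delta, tolerance = 1e-9)
})

test_that("COM translation ranges recover pure sinusoid amplitudes", {
  tf <- seq(0, 1, by = 1 / 512)
  a <- 0.03
  com <- cbind(a * sin(2 * pi * tf), rep(0, length(tf)), rep(1.2, length(tf)))
  phases <- tibble::tibble(label = character(), t_start = numeric(),
                           t_end = numeric(), duration = numeric(),
                           pct = numeric())
  m <- cof_com_metrics(cbind(x = 0 * tf, y = 0 * tf), com, tf, phases,
                       c(0, 1), "none")
  expect_equal(m$COM_ROM_x, 2 * a, tolerance = 1e-6)
  expect_equal(m$COM_ROM_y, 0)
  expect_equal(m$COM_ROM_z, 0)
})
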