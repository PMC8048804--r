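walk_shape <- list(peak1 = 6.3, dip = 4.5, peak2 = 6.6,
                   t_peak1 = 0.25, t_dip = 0.5, t_peak2 = 0.75)

test_that("stance waveforms vanish at the boundaries and hit control points", {
  expect_equal(grf_waveform(walk_shape, "walk", c(0, 1)), c(0, 0))
  expect_equal(grf_waveform(walk_shape, "walk", 0.25), 6.3)
  expect_equal(grf_waveform(walk_shape, "walk", 0.5), 4.5)
  expect_equal(grf_waveform(walk_shape, "walk", 0.75), 6.6)
  trot <- list(peak = 11, q = 1)
  expect_equal(grf_waveform(trot, "trot", c(0, 0.5, 1)), c(0, 11, 0))
})

test_that("walk waveform is C1, non-negative and has no overshoot", {
  s <- seq(0, 1, length.out = 5001)
  v <- grf_waveform(walk_shape, "walk", s)
  expect_true(all(v >= 0))
  expect_lte(max(v), 6.6 + 1e-9)
  # dip is the minimum between the peaks
  mid <- v[s > 0.25 & s < 0.75]
  expect_equal(min(mid), 4.5, tolerance = 1e-6)
  # derivative has no jumps (C1): successive finite-difference slopes change
  # by at most curvature * ds
  sl <- diff(v) / diff(s)[1]
  expect_lt(max(abs(diff(sl))), 1.0)
})

test_that("invalid walk control points are rejected", {
  bad <- walk_shape; bad$t_dip <- 0.2
  expect_error(grf_waveform(bad, "walk", 0.5), "ordering")
  bad2 <- walk_shape; bad2$dip <- 7
  expect_error(grf_waveform(bad2, "walk", 0.5), "dip")
})

test_that("head signal symmetry follows the once-per-stride amplitude", {
  timing <- list(stride_duration = 1.2)
  sym <- list(mean = 1.5, a2 = 0.02, phi2 = pi / 2, a1 = 0, phi1 = 0)
  t <- seq(0, 1.2, length.out = 4801)
  z <- head_signal(t, sym, timing)
  # the two per-stride minima are equal and ROMz = 2 * a2
  m1 <- min(z[t < 0.6]); m2 <- min(z[t >= 0.6])
  expect_equal(m1, m2, tolerance = 1e-9)
  expect_equal(max(z) - min(z), 0.04, tolerance = 1e-6)

  asym <- sym; asym$a1 <- 0.01; asym$phi1 <- 0
  za <- head_signal(t, asym, timing)
  # dense-grid oracle: per-half-cycle minima must differ once a1 is injected
  m1 <- min(za[t < 0.6]); m2 <- min(za[t >= 0.6])
  oracle <- function(lo, hi) {
    stats::optimize(function(x) head_signal(x, asym, timing),
                    c(lo, hi))$objective
  }
  expect_equal(m1, oracle(0, 0.6), tolerance = 1e-7)
  expect_equal(m2, oracle(0.6, 1.2), tolerance = 1e-7)
  expect_gt(abs(m2 - m1), 1e-3)
})

test_that("profile application multiplies targeted parameters only", {
  set.seed(31)
  hp <- make_horse("H1", "walk")
  bv <- base_values(hp)
  ident <- apply_profile(bv, lameness_profile("baseline"), "left")
  expect_identical(unname(ident[names(bv)]), unname(bv))

  prof <- lameness_profile("walk_moderate")
  tv <- apply_profile(bv, prof, "left")
  expect_equal(tv[["Iz_LF"]] / bv[["Iz_LF"]], 0.949)
  expect_equal(tv[["Fz_peak2_LF"]] / bv[["Fz_peak2_LF"]], 0.939)
  expect_equal(tv[["Fz_peak1_RH"]] / bv[["Fz_peak1_RH"]], 1.048)
  expect_equal(tv[["dFz_load_RF"]], 1.165)
  expect_equal(tv[["SD"]] / bv[["SD"]], 0.9795)
  # untargeted parameter unchanged
  expect_equal(tv[["Fz_peak1_LH"]], bv[["Fz_peak1_LH"]])

  # side mirroring: right induction puts the contralateral role on LF
  tvr <- apply_profile(bv, prof, "right")
  expect_equal(tvr[["dFz_load_LF"]], 1.165)
  expect_equal(tvr[["Iz_RF"]] / bv[["Iz_RF"]], 0.949)

  bad <- lameness_profile(factors = data.frame(parameter = "NotAVar",
                                               role = "lame_fore",
                                               factor = 0.9))
  expect_error(apply_profile(bv, bad, "left"), "unknown parameter")
})

test_that("cohort generation is reproducible from the seed", {
  a <- generate_cohort(1, "walk", "baseline", seed = 5, duration = 6,
                       noise = eq_noise())
  b <- generate_cohort(1, "walk", "baseline", seed = 5, duration = 6,
                       noise = eq_noise())
  expect_identical(a[[1]]$forces, b[[1]]$forces)
  expect_identical(a[[1]]$markers, b[[1]]$markers)
  expect_identical(a[[1]]$ground_truth, b[[1]]$ground_truth)
})

test_that("identity profile reproduces the baseline trial exactly without noise", {
  trials <- generate_cohort(1, "walk", c("baseline", "lame"),
                            lameness_profile("baseline"), seed = 6,
                            duration = 6, noise = eq_noise_free())
  expect_equal(trials[[1]]$forces, trials[[2]]$forces, tolerance = 1e-12)
})

test_that("trial durations give stride counts in the reported ranges", {
  walk <- nf_trial("walk")
  trot <- nf_trial("trot")
  n_walk <- length(walk$ground_truth$stride_durations)
  n_trot <- length(trot$ground_truth$stride_durations)
  expect_gte(n_walk, 11); expect_lte(n_walk, 17)
  expect_gte(n_trot, 15); expect_lte(n_trot, 29)
})

test_that("generated forces vanish at ground-truth events and stay non-negative", {
  for (g in c("walk", "trot")) {
    tr <- nf_trial(g)
    f <- as.matrix(tr$forces[, paste0(c("LF", "RF", "LH", "RH"), "_N")])
    expect_true(all(f >= 0))
    for (l in c("LF", "RF", "LH", "RH")) {
      ev <- tr$ground_truth$events[[l]]
      tt <- c(ev[, "on"], ev[, "off"])
      tt <- tt[tt >= 0 & tt <= tr$meta$duration]
      at_ev <- stats::approx(tr$forces$time_s,
                             tr$forces[[paste0(l, "_N")]], tt)$y
      # linear interpolation of the sampled waveform at the true zero times
      expect_lt(max(at_ev), 0.05 * tr$meta$body_mass)
    }
  }
})
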