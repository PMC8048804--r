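test_that("an all-zero trace yields no stances", {
  expect_equal(nrow(detect_stances(rep(0, 4096), 512)), 0)
})

test_that("half-sine stance timing matches the chord-intersection oracle", {
  rate <- 512
  t <- seq(0, 3, by = 1 / rate)
  f <- ifelse(t >= 1 & t <= 1.7, 3000 * sin(pi * (t - 1) / 0.7), 0)
  st <- detect_stances(f, rate)
  expect_equal(nrow(st), 1)
  # the LS chord of a half-sine flank extrapolates ~14 ms early
  expect_gte(unname(st[1, "on"]), 0.98); expect_lte(unname(st[1, "on"]), 1.02)
  expect_gte(unname(st[1, "off"]), 1.68); expect_lte(unname(st[1, "off"]), 1.72)
  # independent oracle: least-squares line through the analytic 20-80% band
  ss <- seq(0, 0.35, by = 1e-5)
  v <- 3000 * sin(pi * ss / 0.7)
  band <- ss[v >= 600 & v <= 2400]
  fit <- stats::lm(y ~ x, data.frame(x = band, y = 3000 * sin(pi * band / 0.7)))
  on_oracle <- 1 - unname(coef(fit)[1] / coef(fit)[2])
  expect_equal(unname(st[1, "on"]), on_oracle, tolerance = 2 / rate)
  expect_equal(unname(st[1, "off"]), 1 + 1.7 - on_oracle, tolerance = 2 / rate)
})

test_that("noise-free detection matches generator ground truth within 2 ms", {
  for (g in c("walk", "trot")) {
    tr <- nf_trial(g)
    ev <- suppressMessages(trial_events(tr))
    for (l in c("LF", "RF", "LH", "RH")) {
      tru <- tr$ground_truth$events[[l]]
      inner <- tru[tru[, "on"] > 0.02 &
                     tru[, "off"] < tr$meta$duration - 0.02, , drop = FALSE]
      expect_equal(nrow(ev[[l]]), nrow(inner))
      for (k in seq_len(nrow(inner))) {
        expect_lt(min(abs(ev[[l]][, "on"] - inner[k, "on"])), 0.002)
        expect_lt(min(abs(ev[[l]][, "off"] - inner[k, "off"])), 0.002)
      }
    }
  }
})

test_that("event detection is equivariant under time translation", {
  tr <- nf_trial("walk")
  f <- tr$forces$LF_N
  rate <- tr$meta$force_rate
  st0 <- detect_stances(f, rate)
  shift <- 64L
  st1 <- detect_stances(c(rep(0, shift), f[1:(length(f) - shift)]), rate)
  expect_equal(nrow(st0), nrow(st1))
  expect_equal(st1[, "on"], st0[, "on"] + shift / rate, tolerance = 1e-9)
})

test_that("stride segmentation pairs consecutive LF hoof-ons", {
  on <- seq(1, by = 1.2, length.out = 16)
  ev <- list(LF = cbind(on = on, off = on + 0.75))
  w <- segment_strides(ev)
  expect_equal(nrow(w), 15)
  expect_equal(unname(w[, "t_end"] - w[, "t_start"]), rep(1.2, 15))
  single <- list(LF = cbind(on = 1, off = 1.75))
  expect_warning(w1 <- segment_strides(single), "fewer than 2")
  expect_equal(nrow(w1), 0)
})

test_that("temporal parameters of the ideal walk match quarter-phase geometry", {
  ev <- ideal_walk_events(sd = 1.2, duty = 0.625)
  w <- c(10, 11.2)
  tp <- temporal_parameters(ev, w)
  expect_equal(tp$SD, 1.2)
  for (l in c("LF", "RF", "LH", "RH")) {
    expect_equal(tp[[paste0("StD_abs_", l)]], 0.75)
    expect_equal(tp[[paste0("StD_rel_", l)]], 0.625)
  }
  expect_equal(tp$StpDi_LF, 0.3)
  expect_equal(tp$StpDi_RF, 0.3)
  expect_equal(tp$StpDc_LF, 0.6)
  expect_equal(tp$StpDc_RF, 0.6)
  # diagonal dissociation: forelimb-first is negative
  expect_equal(tp$TAP_LF, -0.3)
  expect_equal(tp$TAP_RF, -0.3)
})

test_that("an injected trot diagonal dissociation is recovered", {
  sd <- 0.8; t0 <- 5; tap <- 0.010 # fore lands 10 ms after the hind
  mk <- function(ph, delay = 0) {
    on <- t0 + (0:4 + ph) * sd + delay
    cbind(on = on, off = on + 0.36)
  }
  ev <- list(LF = mk(0, 0), RH = mk(0, -tap), RF = mk(0.5, 0),
             LH = mk(0.5, -tap))
  tp <- temporal_parameters(ev, c(t0, t0 + sd))
  expect_equal(tp$TAP_LF, tap, tolerance = 1e-9)
  expect_equal(tp$TAP_RF, tap, tolerance = 1e-9)
})

test_that("incomplete windows are flagged and excluded", {
  ev <- ideal_walk_events()
  ev$RH <- ev$RH[ev$RH[, "on"] < 10 | ev$RH[, "on"] > 11.4, , drop = FALSE]
  expect_null(temporal_parameters(ev, c(10, 11.2)))
})

test_that("ideal walk shows all eight support phases at 12.5% each", {
  ev <- ideal_walk_events(sd = 1.2, duty = 0.625)
  ph <- support_phases(ev, c(10, 11.2), "walk")
  pct <- support_percentages(ph)
  expect_setequal(names(pct), as.character(1:8))
  expect_equal(unname(pct[as.character(1:8)]), rep(12.5, 8),
               tolerance = 1e-9)
  # brute-force grid oracle agrees on every support set
  oracle <- brute_support(ev, c(10, 11.2))
  key <- vapply(as.character(1:8), function(k) {
    paste(sort(equigait:::WALK_SUPPORT_LABELS[[k]]), collapse = "+")
  }, character(1))
  expect_equal(unname(pct[as.character(1:8)]), as.numeric(oracle[key]),
               tolerance = 0.05)
  # conservation: phases tile the stride
  expect_equal(sum(ph$duration), 1.2, tolerance = 1e-9)
})

test_that("duty factor 0.5 leaves only bipedal walk phases", {
  ev <- ideal_walk_events(sd = 1.2, duty = 0.5)
  pct <- support_percentages(support_phases(ev, c(10, 11.2), "walk"))
  expect_setequal(names(pct), as.character(c(2, 4, 6, 8)))
})

test_that("trot with suspension alternates diagonal support and suspension", {
  sd <- 0.8; t0 <- 5
  mk <- function(ph) {
    on <- t0 + (0:4 + ph) * sd
    cbind(on = on, off = on + 0.3) # duty 0.375 < 0.5 -> suspension
  }
  ev <- list(LF = mk(0), RH = mk(0), RF = mk(0.5), LH = mk(0.5))
  ph <- support_phases(ev, c(t0, t0 + sd), "trot")
  expect_setequal(unique(ph$label), c("diag_left", "diag_right", "suspension"))
  expect_equal(sum(ph$pct), 100, tolerance = 1e-9)
})
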