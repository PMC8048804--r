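# Shared lazily-built fixtures. Everything is generated in code; trials are
# cached per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# one noise-free trial per gait (full 20 s so stride counts are realistic)
nf_trial <- function(gait) {
  fixture(paste0("nf_", gait), function() {
    set.seed(11)
    generate_cohort(1, gait, "baseline", seed = 11,
                    noise = eq_noise_free())[[1]]
  })
}

# matching noisy trial (same horse-level seed)
noisy_trial <- function(gait) {
  fixture(paste0("noisy_", gait), function() {
    set.seed(12)
    generate_cohort(1, gait, "baseline", seed = 12, noise = eq_noise())[[1]]
  })
}

# idealised walk event set: quarter phases, configurable duty factor
ideal_walk_events <- function(sd = 1.2, duty = 0.625, n_strides = 3,
                              t0 = 10) {
  phases <- c(LF = 0, RH = 0.25, RF = 0.5, LH = 0.75)
  ev <- lapply(phases, function(ph) {
    on <- t0 + (seq_len(n_strides + 2) - 2 + ph) * sd
    cbind(on = on, off = on + duty * sd)
  })
  names(ev) <- names(phases)
  ev
}

# brute-force support-phase classifier over a dense grid (independent oracle)
brute_support <- function(events, window, n = 20000) {
  tt <- seq(window[1], window[2], length.out = n + 1)[-(n + 1)]
  sets <- vapply(tt, function(x) {
    limbs <- names(events)[vapply(events, function(ev) {
      any(ev[, "on"] <= x & x < ev[, "off"])
    }, logical(1))]
    paste(sort(limbs), collapse = "+")
  }, character(1))
  tab <- table(sets) / n * 100
  tab
}

# brute-force Youden search over every pooled value and both directions
brute_youden <- function(baseline, lame) {
  cand <- sort(unique(c(baseline, lame)))
  cand <- c(cand[1] - 1, (cand[-1] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1)
  best <- -Inf
  for (ct in cand) {
    j1 <- mean(lame > ct) + mean(baseline <= ct) - 1
    j2 <- mean(lame < ct) + mean(baseline >= ct) - 1
    best <- max(best, j1, j2)
  }
  best
}
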