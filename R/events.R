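# Gait-event detection from vertical ground reaction force traces.
# Hoof-on/off are located by intersecting a least-squares line through the
# 20-80% rising (falling) flank of the force curve with the zero baseline,
# so event times are real-valued and may fall between samples.

#' Detection configuration
#'
#' @param threshold_N force threshold for candidate stance detection, N.
#' @param min_peak_N minimum force a candidate run must reach to count as a
#'   stance (hysteresis against noise runs barely above threshold), N.
#' @param min_stance_s stances shorter than this are discarded, s.
#' @param flank_band fraction-of-peak band used for the slope-line fit.
#' @param smooth_cutoff_hz zero-lag low-pass cut-off used for peak finding, Hz.
#' @param marker_lowpass_hz zero-lag low-pass applied to upper-body marker
#'   signals before symmetry/translation extraction, Hz (NA = none).
#' @param angle_lowpass_hz zero-lag low-pass applied to joint-angle time
#'   series before extremum extraction, Hz (NA = none).
#' @return list of class `eq_config`.
#' @export
eq_config <- function(threshold_N = 50, min_peak_N = 200, min_stance_s = 0.1,
                      flank_band = c(0.2, 0.8), smooth_cutoff_hz = 30,
                      marker_lowpass_hz = 8, angle_lowpass_hz = 15) {
  stopifnot(threshold_N > 0, min_peak_N >= threshold_N, min_stance_s >= 0,
            length(flank_band) == 2, flank_band[1] < flank_band[2])
  structure(list(threshold_N = threshold_N, min_peak_N = min_peak_N,
                 min_stance_s = min_stance_s,
                 flank_band = flank_band, smooth_cutoff_hz = smooth_cutoff_hz,
                 marker_lowpass_hz = marker_lowpass_hz,
                 angle_lowpass_hz = angle_lowpass_hz),
            class = "eq_config")
}

# zero-lag Butterworth low-pass (2nd order forward-backward)
lowpass <- function(x, rate, cutoff) {
  if (is.na(cutoff) || cutoff <= 0 || cutoff >= rate / 2) return(x)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# least-squares line through (t, y), returns zero crossing time
line_zero <- function(t, y) {
  if (length(t) < 2) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, t), y)
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] == 0) return(NA_real_)
  unname(-b[1] / b[2])
}

#' Detect stance phases in a single-limb force trace
#'
#' Candidate stances are above-threshold runs of the baseline-corrected
#' trace. For each run, a line is fitted to the rising flank between the
#' configured fractions (default 20-80%) of the first local force maximum and
#' extrapolated to the zero baseline to give hoof-on; hoof-off is obtained
#' symmetrically from the falling flank of the last local maximum. Runs
#' touching the trace boundaries, and stances shorter than the configured
#' minimum, are discarded.
#'
#' @param force force trace in N (single limb).
#' @param rate sampling rate, Hz.
#' @param body_mass horse body mass, kg (retained for interface symmetry
#'   with downstream normalisation; detection operates on raw newtons).
#' @param config an [eq_config()].
#' @return matrix with columns `on`, `off` (seconds); zero rows if no stance.
#' @export
detect_stances <- function(force, rate, body_mass = NULL,
                           config = eq_config()) {
  stopifnot(rate > 0)
  n <- length(force)
  t <- (seq_len(n) - 1) / rate
  # baseline: median of the swing-phase plateau (samples below threshold)
  low <- force[force < config$threshold_N]
  bl <- if (length(low) > 0) stats::median(low) else 0
  f <- force - bl
  above <- f > config$threshold_N
  if (!any(above)) return(cbind(on = numeric(0), off = numeric(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  fs <- lowpass(f, rate, config$smooth_cutoff_hz)
  out <- matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("on", "off")))
  keep_max <- numeric(0)
  for (k in seq_len(nrow(runs))) {
    i1 <- runs[k, 1]; i2 <- runs[k, 2]
    if (i1 <= 1 || i2 >= n) next # truncated at trace edge
    if (max(f[i1:i2]) < config$min_peak_N) next # noise run above threshold
    pk <- local_maxima(fs, i1, i2)
    if (length(pk) == 0) pk <- i1 + which.max(fs[i1:i2]) - 1
    m1 <- fs[pk[1]]
    m2 <- fs[pk[length(pk)]]
    lo <- config$flank_band[1]; hi <- config$flank_band[2]
    # rising flank: walk back from the first peak to below lo*m1
    j <- pk[1]
    while (j > 1 && f[j - 1] < f[j] + m1 * 0.05 && f[j] > lo * m1 * 0.5) j <- j - 1
    rise <- j:pk[1]
    rise <- rise[f[rise] >= lo * m1 & f[rise] <= hi * m1]
    t_on <- line_zero(t[rise], f[rise])
    # falling flank
    j <- pk[length(pk)]
    while (j < n && f[j + 1] < f[j] + m2 * 0.05 && f[j] > lo * m2 * 0.5) j <- j + 1
    fall <- pk[length(pk)]:j
    fall <- fall[f[fall] >= lo * m2 & f[fall] <= hi * m2]
    t_off <- line_zero(t[fall], f[fall])
    if (is.na(t_on)) t_on <- t[i1]
    if (is.na(t_off)) t_off <- t[i2]
    if (t_off - t_on < config$min_stance_s) {
      message("discarding stance of ", round((t_off - t_on) * 1000), " ms at t=",
              round(t_on, 3), " s (below minimum stance duration)")
      next
    }
    out <- rbind(out, c(t_on, t_off))
    keep_max <- c(keep_max, max(f[i1:i2]))
  }
  colnames(out) <- c("on", "off")
  # resolve overlapping detections in favour of the stronger stance
  while (nrow(out) > 1 && any(out[-1, "on"] < out[-nrow(out), "off"])) {
    k <- which(out[-1, "on"] < out[-nrow(out), "off"])[1]
    drop <- if (keep_max[k] < keep_max[k + 1]) k else k + 1
    out <- out[-drop, , drop = FALSE]
    keep_max <- keep_max[-drop]
  }
  out
}

# indices of strict-ish local maxima of x within [i1, i2], at least half the
# run maximum (suppresses noise maxima on the flanks)
local_maxima <- function(x, i1, i2) {
  idx <- (i1 + 1):(i2 - 1)
  if (length(idx) < 1 || i2 - i1 < 2) return(integer(0))
  cand <- idx[x[idx] >= x[idx - 1] & x[idx] > x[idx + 1]]
  cand[x[cand] >= 0.5 * max(x[i1:i2])]
}

#' Detect stances for all four limbs of a trial
#'
#' @param trial an `eq_trial`.
#' @param config an [eq_config()].
#' @return named list (`LF`, `RF`, `LH`, `RH`) of on/off matrices.
#' @export
trial_events <- function(trial, config = eq_config()) {
  rate <- trial$meta$force_rate
  ev <- lapply(LIMBS, function(l) {
    detect_stances(trial$forces[[paste0(l, "_N")]], rate,
                   trial$meta$body_mass, config)
  })
  names(ev) <- LIMBS
  ev
}

#' Segment strides from left-forelimb hoof-on events
#'
#' One stride window per consecutive pair of LF hoof-ons; partial strides at
#' the trial edges are implicitly dropped.
#'
#' @param events per-limb event list as from [trial_events()].
#' @return matrix with columns `t_start`, `t_end`, one row per stride.
#' @export
segment_strides <- function(events) {
  on <- events$LF[, "on"]
  if (length(on) < 2) {
    warning("fewer than 2 LF hoof-on events; no strides segmented")
    return(cbind(t_start = numeric(0), t_end = numeric(0)))
  }
  cbind(t_start = on[-length(on)], t_end = on[-1])
}

# first event time in [t0, t1), NA if none
first_in <- function(x, t0, t1) {
  x <- x[x >= t0 - 1e-9 & x < t1 - 1e-9]
  if (length(x) == 0) NA_real_ else x[1]
}
# event row (on, off) whose on lies in [t0 - tol, t1 - tol). The tolerance
# admits contacts that nominally coincide with the stride boundary (the
# diagonal partner of the reference limb at trot) but were detected a few
# milliseconds early.
stance_in <- function(ev, t0, t1, tol = 0.05 * (t1 - t0)) {
  i <- which(ev[, "on"] >= t0 - tol & ev[, "on"] < t1 - tol)
  if (length(i) == 0) NULL else ev[i[1], ]
}

#' Temporal stride parameters
#'
#' Computes, for one stride window, stride duration (SD), absolute and
#' relative stance durations per limb (StD_abs, StD_rel), ipsilateral and
#' contralateral step durations (StpDi: ipsilateral hind hoof-on to the
#' following same-side fore hoof-on; StpDc: fore hoof-on to the following
#' contralateral fore hoof-on) and the diagonal time dissociation TAP
#' (fore-minus-hind contact time within each diagonal pair; forelimb-first
#' is negative).
#'
#' @param events per-limb event list.
#' @param window numeric length-2, stride start/end in seconds.
#' @return named list of parameters, or `NULL` (flagged incomplete) when an
#'   event is missing within the window.
#' @export
temporal_parameters <- function(events, window) {
  t0 <- window[1]; t1 <- window[2]
  sd <- t1 - t0
  tol <- 0.05 * sd
  n_on <- vapply(LIMBS, function(l) {
    sum(events[[l]][, "on"] >= t0 - tol & events[[l]][, "on"] < t1 - tol)
  }, numeric(1))
  if (any(n_on != 1)) return(NULL) # incomplete or corrupted event set
  st <- lapply(LIMBS, function(l) stance_in(events[[l]], t0, t1))
  names(st) <- LIMBS
  if (any(vapply(st, is.null, logical(1)))) return(NULL)
  on <- vapply(st, function(s) s[["on"]], numeric(1))
  off <- vapply(st, function(s) s[["off"]], numeric(1))
  std <- off - on
  # next-stride fore hoof-ons for the wrap-around steps
  lf_next <- first_in(events$LF[, "on"], t1, t1 + sd * 1.5)
  out <- list(SD = sd)
  for (l in LIMBS) {
    out[[paste0("StD_abs_", l)]] <- std[[l]]
    out[[paste0("StD_rel_", l)]] <- std[[l]] / sd
  }
  out$StpDi_LF <- if (is.na(lf_next)) NA_real_ else lf_next - on[["LH"]]
  out$StpDi_RF <- on[["RF"]] - on[["RH"]]
  out$StpDc_LF <- on[["RF"]] - on[["LF"]]
  out$StpDc_RF <- if (is.na(lf_next)) NA_real_ else lf_next - on[["RF"]]
  # diagonal dissociation pairs each fore contact with the nearest contact
  # of its diagonal hindlimb (which may precede the stride window)
  nearest <- function(x, target) x[which.min(abs(x - target))]
  out$TAP_LF <- on[["LF"]] - nearest(events$RH[, "on"], on[["LF"]])
  out$TAP_RF <- on[["RF"]] - nearest(events$LH[, "on"], on[["RF"]])
  out
}

WALK_SUPPORT_LABELS <- list(
  "1" = c("RF", "LH", "LF"), "2" = c("LH", "LF"),
  "3" = c("LH", "LF", "RH"), "4" = c("LF", "RH"),
  "5" = c("LF", "RH", "RF"), "6" = c("RH", "RF"),
  "7" = c("RH", "RF", "LH"), "8" = c("RF", "LH")
)

support_label <- function(limbs, gait) {
  key <- paste(sort(limbs), collapse = "+")
  if (gait == "walk") {
    for (lab in names(WALK_SUPPORT_LABELS)) {
      if (key == paste(sort(WALK_SUPPORT_LABELS[[lab]]), collapse = "+")) {
        return(lab)
      }
    }
    return("other")
  }
  if (length(limbs) == 0) return("suspension")
  if (key == "LF+RH") return("diag_left")
  if (key == "LH+RF") return("diag_right")
  "other"
}

#' Support-phase sequence of one stride
#'
#' Labels each interval between gait events by its supporting-limb set. At
#' walk the eight-phase catalogue alternates tripedal and bipedal phases
#' (1: tripedal RF+LH+LF, 2: left ipsilateral bipedal LH+LF, 3: tripedal
#' LH+LF+RH, 4: left diagonal bipedal LF+RH, 5: tripedal LF+RH+RF,
#' 6: right ipsilateral bipedal RH+RF, 7: tripedal RH+RF+LH, 8: right
#' diagonal bipedal RF+LH); other sets are labelled `"other"`. Trot labels
#' are `diag_left`, `diag_right` and `suspension`.
#'
#' @param events per-limb event list.
#' @param window stride window (start, end), s.
#' @param gait `"walk"` or `"trot"`.
#' @return tibble with `label`, `t_start`, `t_end`, `duration`, `pct` (% of
#'   stride); intervals tile the stride exactly.
#' @export
support_phases <- function(events, window, gait = c("walk", "trot")) {
  gait <- match.arg(gait)
  t0 <- window[1]; t1 <- window[2]
  brk <- sort(unique(c(t0, t1, unlist(lapply(events, function(ev) {
    v <- c(ev[, "on"], ev[, "off"])
    v[v > t0 & v < t1]
  })))))
  lab <- character(length(brk) - 1)
  for (i in seq_len(length(brk) - 1)) {
    mid <- (brk[i] + brk[i + 1]) / 2
    limbs <- LIMBS[vapply(LIMBS, function(l) {
      ev <- events[[l]]
      any(ev[, "on"] <= mid & mid < ev[, "off"])
    }, logical(1))]
    lab[i] <- support_label(limbs, gait)
    if (lab[i] == "other") {
      message("unrecognised support set {", paste(limbs, collapse = ","),
              "} at t=", round(mid, 3), " s")
    }
  }
  dur <- diff(brk)
  tibble::tibble(label = lab, t_start = brk[-length(brk)], t_end = brk[-1],
                 duration = dur, pct = 100 * dur / (t1 - t0))
}

# total percentage of stride per support label
support_percentages <- function(phases) {
  agg <- tapply(phases$pct, phases$label, sum)
  stats::setNames(as.numeric(agg), names(agg))
}
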