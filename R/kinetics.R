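# Per-stride, mass-normalised vertical force parameters.

# quadratic refinement of an extremum: fit a parabola through the points
# around index i, return c(t, value) of the vertex (falls back to the sample)
refine_peak <- function(t, y, i, halfwidth = 8L) {
  idx <- max(1, i - halfwidth):min(length(y), i + halfwidth)
  if (length(idx) < 3) return(c(t[i], y[i]))
  tc <- t[idx] - t[i]
  fit <- stats::lm.fit(cbind(1, tc, tc^2), y[idx])
  b <- unname(fit$coefficients)
  if (!is.finite(b[3]) || b[3] == 0) return(c(t[i], y[i]))
  tv <- -b[2] / (2 * b[3])
  if (abs(tv) > max(abs(tc))) return(c(t[i], y[i]))
  c(t[i] + tv, b[1] + b[2] * tv + b[3] * tv^2)
}

# LS slope of the flank of y between lo and hi fractions of peak value,
# walking from the peak index towards `dir` (-1 rising, +1 falling)
flank_slope <- function(t, y, peak_idx, peak_val, dir, band) {
  j <- peak_idx
  n <- length(y)
  while (j + dir >= 1 && j + dir <= n && y[j] > band[1] * peak_val * 0.5 &&
         y[j + dir] < y[j] + 0.05 * peak_val) {
    j <- j + dir
  }
  idx <- if (dir < 0) j:peak_idx else peak_idx:j
  idx <- idx[y[idx] >= band[1] * peak_val & y[idx] <= band[2] * peak_val]
  if (length(idx) < 2) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, t[idx]), y[idx])
  unname(fit$coefficients[2])
}

#' Kinetic parameters of one stance
#'
#' All forces are normalised to body mass. At walk the two largest local
#' maxima of the (zero-lag low-pass smoothed) curve give `Fz_peak1` and
#' `Fz_peak2` in stance order with the minimum between them as `Fz_dip`; at
#' trot the single maximum gives `Fz_peak`. The vertical impulse `Iz` is the
#' trapezoidal integral of the normalised force over the stance window
#' clipped at the (sub-sample) event times. Loading and unloading rates are
#' least-squares chord slopes over the 20-80% rising/falling flanks
#' (`dFz_unload` reported as a positive magnitude), and `t_Fz_peak1` is the
#' first-peak time as a percentage of stance.
#'
#' @param force full single-limb force trace, N.
#' @param stance numeric `(on, off)` in seconds.
#' @param mass body mass, kg.
#' @param rate sampling rate, Hz.
#' @param gait `"walk"` or `"trot"`.
#' @param config an [eq_config()] (smoothing cut-off and flank band).
#' @param smoothed optional pre-computed smoothed normalised trace (same
#'   length as `force`), to avoid re-filtering when extracting many stances.
#' @return named list; at walk a stance without two local maxima is flagged
#'   `monophasic = TRUE` with `Fz_peak2`/`Fz_dip` missing.
#' @export
kinetic_parameters <- function(force, stance, mass, rate,
                               gait = c("walk", "trot"),
                               config = eq_config(), smoothed = NULL) {
  gait <- match.arg(gait)
  stopifnot(mass > 0, stance[2] > stance[1])
  n <- length(force)
  t <- (seq_len(n) - 1) / rate
  on <- unname(stance[1]); off <- unname(stance[2])
  fn <- force / mass
  fs <- if (is.null(smoothed)) lowpass(fn, rate, config$smooth_cutoff_hz)
        else smoothed
  idx <- which(t > on & t < off)
  if (length(idx) < 5) stop("stance window too short for kinetic extraction")

  # sub-sample clipped trapezoid for the impulse
  ti <- c(on, t[idx], off)
  yi <- c(stats::approx(t, fn, on)$y, fn[idx], stats::approx(t, fn, off)$y)
  iz <- sum(diff(ti) * (yi[-1] + yi[-length(yi)]) / 2)

  out <- list(Iz = iz, monophasic = FALSE)
  pk <- local_maxima(fs, idx[1], idx[length(idx)])
  if (gait == "walk") {
    if (length(pk) < 2) {
      # monophasic stance: report the single maximum as peak1
      i1 <- if (length(pk) == 1) pk else idx[which.max(fs[idx])]
      p1 <- refine_peak(t, fn, i1)
      out <- c(out, list(Fz_peak1 = p1[2], Fz_peak2 = NA_real_,
                         Fz_dip = NA_real_,
                         t_Fz_peak1 = 100 * (p1[1] - on) / (off - on)))
      out$monophasic <- TRUE
      rate1 <- flank_slope(t, fn, i1, p1[2], -1L, config$flank_band)
      rate2 <- flank_slope(t, fn, i1, p1[2], +1L, config$flank_band)
      out$dFz_load <- rate1
      out$dFz_unload <- abs(rate2)
      return(out)
    }
    ord <- pk[order(fs[pk], decreasing = TRUE)][1:2]
    i1 <- min(ord); i2 <- max(ord)
    p1 <- refine_peak(t, fn, i1)
    p2 <- refine_peak(t, fn, i2)
    idip <- i1 + which.min(fs[i1:i2]) - 1
    dip <- refine_peak(t, fn, idip)
    out <- c(out, list(Fz_peak1 = p1[2], Fz_peak2 = p2[2], Fz_dip = dip[2],
                       t_Fz_peak1 = 100 * (p1[1] - on) / (off - on)))
    out$dFz_load <- flank_slope(t, fn, i1, p1[2], -1L, config$flank_band)
    out$dFz_unload <- abs(flank_slope(t, fn, i2, p2[2], +1L, config$flank_band))
  } else {
    i1 <- if (length(pk) > 0) pk[which.max(fs[pk])] else idx[which.max(fs[idx])]
    p1 <- refine_peak(t, fn, i1)
    out <- c(out, list(Fz_peak = p1[2],
                       t_Fz_peak1 = 100 * (p1[1] - on) / (off - on)))
    out$dFz_load <- flank_slope(t, fn, i1, p1[2], -1L, config$flank_band)
    out$dFz_unload <- abs(flank_slope(t, fn, i1, p1[2], +1L, config$flank_band))
  }
  out
}
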