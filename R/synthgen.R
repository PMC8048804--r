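# Synthetic treadmill trial generator: per-limb vertical GRF waveforms plus a
# minimal marker set (hoof, fetlock, carpus/tarsus, limb pivot, poll, withers,
# sternum, L3), with known ground-truth gait events and configurable lameness
# effect profiles. All effect factors are targets on the *extracted* stride
# parameters; realisation inverts the extraction relation so the downstream
# pipeline recovers them.

LIMBS <- c("LF", "RF", "LH", "RH")
GRAVITY <- 9.81 # N/kg

# half-width (fraction of stance) of the parabolic caps placed around the
# two walk force peaks, and the dimensionless curvature factor of the dip
# cap. Within a cap the curve is an exact parabola, so peak value and timing
# are recovered exactly by quadratic refinement; outside the caps the flanks
# are straight tangent lines, as in measured GRFz traces, which is what the
# chord-intersection event detector assumes.
WALK_CAP_HW <- 0.05
WALK_DIP_CURV <- 6

#' Measurement-noise and stride-jitter settings
#'
#' @param sigma_force additive force noise, N/kg (applied after mass scaling,
#'   clamped so forces stay non-negative).
#' @param sigma_marker additive marker position noise, m.
#' @param jitter_cv coefficient of variation of the multiplicative
#'   stride-to-stride jitter on stride duration, force amplitude and
#'   upper-body amplitudes.
#' @return a list of class `eq_noise`.
#' @export
eq_noise <- function(sigma_force = 0.05, sigma_marker = 0.001,
                     jitter_cv = 0.02) {
  stopifnot(sigma_force >= 0, sigma_marker >= 0, jitter_cv >= 0)
  structure(list(sigma_force = sigma_force, sigma_marker = sigma_marker,
                 jitter_cv = jitter_cv), class = "eq_noise")
}

#' Noise-free generator settings
#' @return an `eq_noise` object with all noise terms zero.
#' @export
eq_noise_free <- function() eq_noise(0, 0, 0)

# ---------------------------------------------------------------------------
# stance force waveforms

#' Stance-phase vertical force waveform
#'
#' Walk curves are continuously differentiable piecewise-quadratic
#' interpolants through `(0,0)`, `(t_peak1, peak1)`, `(t_dip, dip)`,
#' `(t_peak2, peak2)` and `(1,0)`: parabolic caps around the two peaks and
#' the dip, joined (and anchored to the zero baseline) by common tangent
#' lines, which keeps every segment monotone without overshoot and makes the
#' rising and falling flanks straight. Trot curves are `peak * sin(pi*s)^q`.
#' `s` is the fraction of stance.
#'
#' @param shape for walk a list with `peak1`, `dip`, `peak2`, `t_peak1`,
#'   `t_dip`, `t_peak2` (forces in N/kg, times as fractions of stance); for
#'   trot a list with `peak` (N/kg) and shape exponent `q`.
#' @param gait `"walk"` or `"trot"`.
#' @param s fraction of stance in `[0, 1]` (vectorised).
#' @return force in N/kg, zero at `s = 0` and `s = 1`.
#' @export
grf_waveform <- function(shape, gait, s) {
  stopifnot(all(s >= -1e-12 & s <= 1 + 1e-12))
  f <- grf_waveform_fun(shape, gait)
  f(pmin(pmax(s, 0), 1))
}

# returns a fast vectorised function of s in [0,1]
grf_waveform_fun <- function(shape, gait) {
  gait <- match.arg(gait, c("walk", "trot"))
  if (gait == "trot") {
    stopifnot(shape$peak >= 0, shape$q > 0)
    peak <- shape$peak
    q <- shape$q
    return(function(s) peak * sin(pi * s)^q)
  }
  with(shape, {
    if (!(0 < t_peak1 && t_peak1 < t_dip && t_dip < t_peak2 && t_peak2 < 1)) {
      stop("invalid walk control-point ordering: need 0 < t_peak1 < t_dip < t_peak2 < 1")
    }
    if (!(dip < min(peak1, peak2))) stop("invalid walk shape: dip must be below both peaks")
    if (min(peak1, dip, peak2) < 0) stop("invalid walk shape: negative force value")
  })
  p1 <- shape$peak1; p2 <- shape$peak2; dp <- shape$dip
  t1 <- shape$t_peak1; td <- shape$t_dip; t2 <- shape$t_peak2
  w <- WALK_CAP_HW
  if (t1 - w <= 0 || t2 + w >= 1) {
    stop("invalid walk shape: peak too close to stance boundary for cap width")
  }
  # peak caps tangent to lines anchored at the stance boundaries
  c1 <- p1 / (w * (2 * t1 - w))
  c2 <- p2 / (w * (2 * (1 - t2) - w))
  hmid <- (t2 - t1) / 2
  cd <- WALK_DIP_CURV * (max(p1, p2) - dp) / hmid^2
  # common tangent between a peak cap (top, curvature ct at tt) and the dip
  # cap: slope root of  k m^2 + B m + C = 0  nearest the chord slope
  tangent <- function(ct, top, tt) {
    k <- 1 / (4 * ct) + 1 / (4 * cd)
    B <- abs(td - tt)
    C <- top - dp
    disc <- B^2 - 4 * k * C
    if (disc < 0) stop("invalid walk shape: dip too deep for tangent construction")
    (-B + sqrt(disc)) / (2 * k) # negative (descending towards the dip)
  }
  mL <- tangent(c1, p1, t1)
  mR <- tangent(c2, p2, t2)
  saL <- t1 - mL / (2 * c1); sbL <- td + mL / (2 * cd)
  sbR <- td - mR / (2 * cd); saR <- t2 + mR / (2 * c2)
  stopifnot(saL <= sbL, sbL <= td, td <= sbR, sbR <= saR)
  function(s) {
    v <- numeric(length(s))
    r1 <- s < t1 - w
    v[r1] <- 2 * c1 * w * s[r1]
    r2 <- s >= t1 - w & s < saL
    v[r2] <- p1 - c1 * (s[r2] - t1)^2
    r3 <- s >= saL & s < sbL
    v[r3] <- p1 - c1 * (saL - t1)^2 + mL * (s[r3] - saL)
    r4 <- s >= sbL & s < sbR
    v[r4] <- dp + cd * (s[r4] - td)^2
    r5 <- s >= sbR & s < saR
    v[r5] <- dp + cd * (sbR - td)^2 - mR * (s[r5] - sbR)
    r6 <- s >= saR & s < t2 + w
    v[r6] <- p2 - c2 * (s[r6] - t2)^2
    r7 <- s >= t2 + w
    v[r7] <- 2 * c2 * w * (1 - s[r7])
    pmax(v, 0)
  }
}

# stance waveform with multiplicative jitter on its internal timing/shape
# parameters (clamped so the control-point ordering and the tangent
# construction stay valid)
jitter_shape_fun <- function(shape, gait, cv) {
  r <- function() max(0.5, 1 + cv * stats::rnorm(1))
  s2 <- shape
  if (gait == "trot") {
    s2$q <- shape$q * r()
    return(grf_waveform_fun(s2, "trot"))
  }
  w <- WALK_CAP_HW
  s2$t_peak1 <- min(max(shape$t_peak1 * r(), 1.1 * w), 0.45)
  s2$t_peak2 <- max(min(shape$t_peak2 * r(), 1 - 1.1 * w), 0.55)
  s2$t_dip <- min(max(shape$t_dip * r(), s2$t_peak1 + 0.02),
                  s2$t_peak2 - 0.02)
  s2$dip <- min(shape$dip * r(), 0.98 * min(s2$peak1, s2$peak2))
  grf_waveform_fun(s2, "walk")
}

# integral of the unit-stance waveform, by fine trapezoid
shape_integral <- function(shape, gait, n = 4001L) {
  s <- seq(0, 1, length.out = n)
  v <- grf_waveform(shape, gait, s)
  sum((v[-1] + v[-n]) / 2) * (1 / (n - 1))
}

# B(p) = integral of sin(pi u)^p over [0,1]
sinpow_integral <- function(p) {
  stats::integrate(function(u) sin(pi * u)^p, 0, 1,
                   rel.tol = 1e-10)$value
}

# normalised cumulative sin^p profile as a function on [0,1] (0 -> 0, 1 -> 1)
sinpow_cumfun <- function(p, n = 1001L) {
  u <- seq(0, 1, length.out = n)
  v <- sin(pi * u)^p
  cs <- c(0, cumsum((v[-1] + v[-n]) / 2)) * (1 / (n - 1))
  cs <- cs / cs[n]
  stats::approxfun(u, cs, rule = 2)
}

# ---------------------------------------------------------------------------
# upper-body vertical signal

#' Upper-body vertical displacement signal
#'
#' Vertical position of a trunk or head landmark as a sum of a symmetric
#' twice-per-stride harmonic and an asymmetric once-per-stride harmonic:
#' `z(t) = mean + a2 sin(4 pi t / SD + phi2) + a1 sin(2 pi t / SD + phi1)`.
#' With `a1 = 0` the two stride half-cycles are identical, so all symmetry
#' indices (MinDiff, RUD, RDD) are zero.
#'
#' @param t time in seconds (vectorised), measured from a stride start.
#' @param motion list with `mean`, `a2`, `phi2`, `a1`, `phi1` (m, rad).
#' @param timing list with `stride_duration` in seconds.
#' @return vertical position in metres.
#' @export
head_signal <- function(t, motion, timing) {
  sd <- timing$stride_duration
  stopifnot(sd > 0, motion$a2 >= 0, motion$a1 >= 0)
  motion$mean +
    motion$a2 * sin(4 * pi * t / sd + motion$phi2) +
    motion$a1 * sin(2 * pi * t / sd + motion$phi1)
}

# range of the (unit-stride) landmark signal over one stride, dense grid
landmark_range <- function(a2, phi2, a1, phi1, n = 4001L) {
  u <- seq(0, 1, length.out = n)
  z <- a2 * sin(4 * pi * u + phi2) + a1 * sin(2 * pi * u + phi1)
  max(z) - min(z)
}

# ---------------------------------------------------------------------------
# lameness effect profiles

PROFILE_ROLES <- c("lame_fore", "contralateral_fore", "ipsilateral_hind",
                   "diagonal_hind", "global")

#' Map limb roles to limbs for a given induction side
#' @param role one of `"lame_fore"`, `"contralateral_fore"`,
#'   `"ipsilateral_hind"`, `"diagonal_hind"`.
#' @param lame_side `"left"` or `"right"`.
#' @return a limb code (`"LF"`, `"RF"`, `"LH"`, `"RH"`).
#' @export
role_limb <- function(role, lame_side) {
  lame_side <- match.arg(lame_side, c("left", "right"))
  map <- if (lame_side == "left") {
    c(lame_fore = "LF", contralateral_fore = "RF",
      ipsilateral_hind = "LH", diagonal_hind = "RH")
  } else {
    c(lame_fore = "RF", contralateral_fore = "LF",
      ipsilateral_hind = "RH", diagonal_hind = "LH")
  }
  unname(map[match.arg(role, names(map))])
}

#' Lameness effect profiles
#'
#' A profile is a set of multiplicative factors on extracted stride
#' parameters, keyed by parameter name and limb role relative to the lame
#' limb, plus additive once-per-stride asymmetry injections for the head and
#' withers, a diagonal-dissociation shift, and centre-of-mass translation
#' amplitude factors.
#'
#' The `"walk_moderate"` and `"trot_moderate"` presets encode the group-level
#' percentage changes measured after moderate sole-pressure forelimb lameness
#' induction (e.g. lame-fore vertical impulse x0.949 at walk, x0.857 at trot;
#' lame-fore peak force x0.823 at trot; head ROMz x1.505 at trot). Effects
#' reported only directionally are encoded with small vignette-documented
#' values chosen to respect total weight support.
#' `"baseline"` is the identity profile.
#'
#' @param preset `"baseline"`, `"walk_moderate"` or `"trot_moderate"`, or
#'   `NULL` when building a custom profile from the other arguments.
#' @param factors a data frame with columns `parameter`, `role`, `factor`.
#' @param a1 named numeric, additive once-per-stride vertical amplitude
#'   injections in metres (names `poll`, `withers`).
#' @param tap_shift seconds by which forelimbs contact earlier relative to
#'   their diagonal hindlimb (positive = fore earlier, decreasing TAP).
#' @param com named numeric factors on trunk translation amplitudes
#'   (names `x`, `y`, `z`).
#' @return an object of class `lameness_profile`.
#' @export
lameness_profile <- function(preset = NULL, factors = NULL,
                             a1 = c(poll = 0, withers = 0),
                             tap_shift = 0, com = c(x = 1, y = 1, z = 1)) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("baseline", "walk_moderate", "trot_moderate"))
    return(profile_preset(preset))
  }
  if (is.null(factors)) {
    factors <- data.frame(parameter = character(), role = character(),
                          factor = numeric())
  }
  stopifnot(all(c("parameter", "role", "factor") %in% names(factors)),
            all(factors$role %in% PROFILE_ROLES),
            all(factors$factor > 0),
            all(c("poll", "withers") %in% names(a1)),
            all(c("x", "y", "z") %in% names(com)))
  structure(list(factors = factors, a1 = a1, tap_shift = tap_shift, com = com),
            class = "lameness_profile")
}

profile_preset <- function(preset) {
  fac <- function(parameter, role, factor) data.frame(parameter, role, factor)
  if (preset == "baseline") {
    return(lameness_profile(factors = NULL))
  }
  if (preset == "walk_moderate") {
    factors <- rbind(
      fac("SD",          "global",             0.9795),  # -2.05%
      fac("StD_rel",     "lame_fore",          1.004),
      fac("StD_rel",     "ipsilateral_hind",   1.004),
      fac("t_Fz_peak1",  "lame_fore",          1.084),   # +8.4%
      fac("t_Fz_peak1",  "ipsilateral_hind",   1.084),
      fac("t_Fz_peak1",  "diagonal_hind",      1.084),
      fac("Iz",          "lame_fore",          0.949),   # -5.1%
      fac("Iz",          "ipsilateral_hind",   0.980),   # directional only
      fac("Fz_peak1",    "lame_fore",          0.981),   # -1.9%
      fac("Fz_peak1",    "diagonal_hind",      1.048),   # +4.8%
      fac("Fz_peak1",    "contralateral_fore", 1.020),   # directional only
      fac("Fz_peak2",    "lame_fore",          0.939),   # -6.1%
      fac("Fz_peak2",    "contralateral_fore", 1.020),   # directional only
      fac("dFz_load",    "contralateral_fore", 1.165),   # +16.5%
      fac("dFz_unload",  "contralateral_fore", 1.150),   # +15%
      fac("A_fetlock",   "lame_fore",          0.967),   # -3.3%
      fac("A_fetlock",   "contralateral_fore", 1.020),   # directional only
      fac("A_fetlock",   "ipsilateral_hind",   1.020),
      fac("A_fetlock",   "diagonal_hind",      1.020),
      fac("Prot_speed",  "lame_fore",          0.954),   # -4.6%
      fac("Prot_speed",  "ipsilateral_hind",   1.024),   # +2.4%
      fac("Prot_speed",  "diagonal_hind",      1.027),   # +2.7%
      fac("Ret_max",     "lame_fore",          0.974),   # -2.6%
      fac("ProtH",       "contralateral_fore", 1.025)    # +2.5%
    )
    return(lameness_profile(factors = factors,
                            a1 = c(poll = 0.008, withers = 0.002),
                            com = c(x = 0.85, y = 1.10, z = 1.10)))
  }
  # trot_moderate
  factors <- rbind(
    fac("SD",         "global",             0.980),   # directional only
    fac("StD_rel",    "lame_fore",          1.055),   # +5.5%
    fac("StD_rel",    "contralateral_fore", 1.055),
    fac("StD_rel",    "ipsilateral_hind",   1.020),   # directional only
    fac("StD_rel",    "diagonal_hind",      1.020),
    fac("Iz",         "lame_fore",          0.857),   # -14.3%
    fac("Iz",         "contralateral_fore", 1.070),   # directional only
    fac("Iz",         "ipsilateral_hind",   0.980),   # directional only
    fac("Iz",         "diagonal_hind",      1.030),   # weight-support closure
    fac("Fz_peak",    "lame_fore",          0.823),   # -17.7%
    fac("Fz_peak",    "contralateral_fore", 1.010),   # "very mild increase"
    fac("ROMz_poll",  "global",             1.505),   # +50.5%
    fac("ProtH",      "lame_fore",          0.832),   # -16.8%
    fac("Prot_max",   "lame_fore",          1.016),   # +1.6%
    fac("Ret_max",    "lame_fore",          0.972),   # -2.8%
    fac("Prot_speed", "lame_fore",          0.960)    # directional only
  )
  lameness_profile(factors = factors,
                   a1 = c(poll = 0, withers = 0.004),
                   tap_shift = 0.005,
                   com = c(x = 1, y = 1, z = 0.90))
}

#' Apply a lameness profile to baseline extracted-parameter values
#'
#' Each targeted parameter is multiplied by its factor for the limb occupying
#' the stated role relative to `lame_side`; untargeted entries are unchanged.
#'
#' @param values named numeric vector of baseline extracted-parameter values
#'   (as produced by [base_values()]).
#' @param profile a [lameness_profile()].
#' @param lame_side `"left"` or `"right"`.
#' @return values with factors applied; injection terms are attached as the
#'   `"injections"` attribute.
#' @export
apply_profile <- function(values, profile, lame_side) {
  stopifnot(inherits(profile, "lameness_profile"))
  out <- values
  fc <- profile$factors
  if (nrow(fc) > 0) {
    for (i in seq_len(nrow(fc))) {
      nm <- if (fc$role[i] == "global") fc$parameter[i] else
        paste(fc$parameter[i], role_limb(fc$role[i], lame_side), sep = "_")
      if (!nm %in% names(out)) {
        stop("unknown parameter in profile: ", fc$parameter[i],
             " (role ", fc$role[i], ")")
      }
      out[nm] <- out[nm] * fc$factor[i]
    }
  }
  attr(out, "injections") <- list(a1 = profile$a1,
                                  tap_shift = profile$tap_shift,
                                  com = profile$com)
  out
}

# ---------------------------------------------------------------------------
# horse-level baseline parameters

#' Draw baseline generator parameters for one horse
#'
#' Body mass, belt speed, stride timing, stance force shapes, upper-body
#' oscillation amplitudes and limb geometry are drawn from physiological
#' ranges (belt speed 1.57-1.79 m/s at walk, 3.78-3.94 m/s at trot). Force
#' amplitudes are then calibrated so that the summed per-stride vertical
#' impulse equals `g * stride_duration` exactly (weight support).
#'
#' @param horse_id identifier.
#' @param gait `"walk"` or `"trot"`.
#' @return a list of generator parameters (class `eq_horse`).
#' @export
make_horse <- function(horse_id, gait = c("walk", "trot")) {
  gait <- match.arg(gait)
  ru <- function(lo, hi) stats::runif(1, lo, hi)
  walk <- gait == "walk"
  mass <- ru(470, 620)
  belt <- if (walk) ru(1.57, 1.79) else ru(3.78, 3.94)
  sd <- if (walk) ru(1.18, 1.32) else ru(0.74, 0.82)
  duty <- if (walk) 0.625 else 0.45
  duty <- stats::setNames(rep(duty, 4), LIMBS) * stats::runif(4, 0.99, 1.01)
  phase <- if (walk) c(LF = 0, RH = 0.25, RF = 0.5, LH = 0.75)
           else c(LF = 0, RH = 0, RF = 0.5, LH = 0.5)
  hind_scale <- ru(0.76, 0.84)
  shapes <- list()
  for (l in LIMBS) {
    hind <- l %in% c("LH", "RH")
    amp <- if (hind) hind_scale else 1
    if (walk) {
      t1 <- 0.25 * ru(0.96, 1.04)
      td <- 0.50 * ru(0.98, 1.02)
      t2 <- 0.75 * ru(0.97, 1.03)
      shapes[[l]] <- list(peak1 = 6.3 * amp, dip = 4.5 * amp, peak2 = 6.6 * amp,
                          t_peak1 = t1, t_dip = td, t_peak2 = t2)
    } else {
      shapes[[l]] <- list(peak = 11 * amp, q = 1.15 * ru(0.98, 1.02))
    }
  }
  upper <- list(
    poll    = list(mean = 1.55, a2 = (if (walk) 0.025 else 0.035) * ru(0.9, 1.1),
                   phi2 = pi / 2, a1 = 0, phi1 = 0),
    withers = list(mean = 1.65, a2 = (if (walk) 0.020 else 0.030) * ru(0.9, 1.1),
                   phi2 = pi / 2, a1 = 0, phi1 = 0),
    sternum = list(mean = 1.05, a2 = (if (walk) 0.012 else 0.025) * ru(0.9, 1.1),
                   phi2 = pi / 2, a1 = 0, phi1 = 0,
                   ax = (if (walk) 0.030 else 0.010) * ru(0.9, 1.1), phix = 0,
                   ay = (if (walk) 0.008 else 0.012) * ru(0.9, 1.1), phiy = 0),
    L3      = list(mean = 1.30, a2 = (if (walk) 0.015 else 0.030) * ru(0.9, 1.1),
                   phi2 = pi / 2, a1 = 0, phi1 = 0,
                   ax = (if (walk) 0.030 else 0.010) * ru(0.9, 1.1), phix = 0,
                   ay = (if (walk) 0.008 else 0.012) * ru(0.9, 1.1), phiy = 0)
  )
  geom <- list()
  for (l in LIMBS) {
    hind <- l %in% c("LH", "RH")
    left <- l %in% c("LF", "LH")
    geom[[l]] <- list(
      x = (if (left) -1 else 1) * (if (hind) 0.13 else 0.15),
      y_pivot = if (hind) -0.55 else 0.55,
      h_pivot = 1.0,
      z0 = 0.03,
      carpus_dy = 0.06, carpus_dz = if (hind) 0.50 else 0.45,
      gain = 3.0,                                    # deg per N/kg
      H = (if (walk) 0.08 else 0.18) * (if (hind) 0.8 else 1) * ru(0.9, 1.1),
      p_swing = 2
    )
  }
  hp <- list(horse_id = horse_id, gait = gait, mass = mass, belt = belt,
             SD = sd, duty = duty, phase = phase, tap_shift = 0,
             shapes = shapes, upper = upper, geom = geom)
  # weight-support calibration: sum of per-stride limb impulses = g * SD
  tot <- sum(vapply(LIMBS, function(l) {
    duty[[l]] * sd * shape_integral(shapes[[l]], gait)
  }, numeric(1)))
  cal <- GRAVITY * sd / tot
  for (l in LIMBS) {
    if (walk) {
      hp$shapes[[l]]$peak1 <- hp$shapes[[l]]$peak1 * cal
      hp$shapes[[l]]$dip <- hp$shapes[[l]]$dip * cal
      hp$shapes[[l]]$peak2 <- hp$shapes[[l]]$peak2 * cal
    } else {
      hp$shapes[[l]]$peak <- hp$shapes[[l]]$peak * cal
    }
  }
  class(hp) <- "eq_horse"
  hp
}

#' Baseline extracted-parameter values implied by generator parameters
#'
#' Computes, in closed form or by fine quadrature on the noise-free
#' waveforms, the stride parameters the extraction pipeline would recover
#' from a jitter-free trial of this horse. These are the quantities lameness
#' profiles act on.
#'
#' @param hp an `eq_horse` parameter set.
#' @return named numeric vector; loading/unloading-rate entries are relative
#'   multipliers (baseline 1).
#' @export
base_values <- function(hp) {
  walk <- hp$gait == "walk"
  v <- c(SD = hp$SD)
  for (l in LIMBS) {
    g <- hp$geom[[l]]
    duty <- hp$duty[[l]]
    tau <- duty * hp$SD
    stl <- hp$belt * tau
    tsw <- hp$SD - tau
    sh <- hp$shapes[[l]]
    maxfz <- if (walk) max(sh$peak1, sh$peak2) else sh$peak
    ent <- c(StD_rel = duty,
             Iz = tau * shape_integral(sh, hp$gait),
             dFz_load = 1, dFz_unload = 1,
             A_fetlock = g$gain * maxfz,
             Prot_speed = stl / tsw / sinpow_integral(g$p_swing),
             Prot_max = atan2(stl / 2, g$h_pivot) * 180 / pi,
             Ret_max = atan2(-stl / 2, g$h_pivot) * 180 / pi,
             ProtH = g$z0 + g$H)
    if (walk) {
      ent <- c(ent, Fz_peak1 = sh$peak1, Fz_peak2 = sh$peak2,
               t_Fz_peak1 = 100 * sh$t_peak1)
    } else {
      ent <- c(ent, Fz_peak = sh$peak)
    }
    names(ent) <- paste(names(ent), l, sep = "_")
    v <- c(v, ent)
  }
  pl <- hp$upper$poll
  v <- c(v, ROMz_poll = landmark_range(pl$a2, pl$phi2, pl$a1, pl$phi1))
  v
}

# realise targeted extracted-parameter values as generator internals.
# Inversions: walk dip and trot q are solved so the stance impulse hits the
# Iz target; the swing shape exponent is solved for Prot_speed; the fetlock
# gain for A_fetlock; the stance window position for the protraction angle;
# the once-per-stride poll amplitude for a ROMz target (when one is set).
realize_horse <- function(hp, targets, injections = NULL) {
  walk <- hp$gait == "walk"
  out <- hp
  out$SD <- targets[["SD"]]
  base <- base_values(hp)
  for (l in LIMBS) {
    tv <- function(p) targets[[paste(p, l, sep = "_")]]
    g <- hp$geom[[l]]
    duty <- tv("StD_rel")
    out$duty[[l]] <- duty
    tau <- duty * out$SD
    sh <- hp$shapes[[l]]
    tau_b <- hp$duty[[l]] * hp$SD
    if (walk) {
      bvl <- function(p) base[[paste(p, l, sep = "_")]]
      sh$peak1 <- tv("Fz_peak1")
      sh$peak2 <- tv("Fz_peak2")
      # the rising flank is the line 2*peak1/((2*t_peak1 - w)*tau): an
      # explicit loading-rate target is realised through t_peak1, otherwise
      # t_peak1 follows the first-peak timing target
      w <- WALK_CAP_HW
      if (abs(tv("dFz_load") - 1) > 1e-12) {
        ratio <- (sh$peak1 / bvl("Fz_peak1")) * (tau_b / tau) / tv("dFz_load")
        sh$t_peak1 <- (w + (2 * sh$t_peak1 - w) * ratio) / 2
      } else {
        sh$t_peak1 <- sh$t_peak1 * tv("t_Fz_peak1") / bvl("t_Fz_peak1")
      }
      if (abs(tv("dFz_unload") - 1) > 1e-12) {
        ratio <- (sh$peak2 / bvl("Fz_peak2")) * (tau_b / tau) / tv("dFz_unload")
        sh$t_peak2 <- 1 - (w + (2 * (1 - sh$t_peak2) - w) * ratio) / 2
      }
      stopifnot(sh$t_peak1 < sh$t_dip, sh$t_dip < sh$t_peak2)
      iz_of_dip <- function(d) {
        s2 <- sh; s2$dip <- d
        # dips too deep for the tangent construction undershoot the target
        tryCatch(tau * shape_integral(s2, "walk") - tv("Iz"),
                 error = function(e) -tv("Iz"))
      }
      hi <- min(sh$peak1, sh$peak2) * 0.999
      sh$dip <- stats::uniroot(iz_of_dip, c(1e-3, hi), tol = 1e-10)$root
      maxfz <- max(sh$peak1, sh$peak2)
    } else {
      sh$peak <- tv("Fz_peak")
      iz_of_q <- function(q) tau * sh$peak * sinpow_integral(q) - tv("Iz")
      sh$q <- stats::uniroot(iz_of_q, c(0.05, 8), tol = 1e-10)$root
      maxfz <- sh$peak
    }
    out$shapes[[l]] <- sh
    out$geom[[l]]$gain <- tv("A_fetlock") / maxfz
    out$geom[[l]]$H <- tv("ProtH") - g$z0
    stl <- out$belt * tau
    y_on <- g$h_pivot * tan(tv("Prot_max") * pi / 180)
    out$geom[[l]]$y_on <- y_on
    out$geom[[l]]$y_off <- y_on - stl
    tsw <- out$SD - tau
    bp <- function(p) sinpow_integral(p) - stl / (tsw * tv("Prot_speed"))
    out$geom[[l]]$p_swing <- stats::uniroot(bp, c(0.2, 20), tol = 1e-9)$root
  }
  if (!is.null(injections)) {
    romz_ratio <- targets[["ROMz_poll"]] / base[["ROMz_poll"]]
    if (abs(romz_ratio - 1) > 1e-9) {
      pl <- out$upper$poll
      f <- function(a1) landmark_range(pl$a2, pl$phi2, a1, pl$phi1) -
        targets[["ROMz_poll"]]
      out$upper$poll$a1 <- stats::uniroot(f, c(0, 10 * pl$a2), tol = 1e-10)$root
    } else {
      out$upper$poll$a1 <- out$upper$poll$a1 + injections$a1[["poll"]]
    }
    out$upper$withers$a1 <- out$upper$withers$a1 + injections$a1[["withers"]]
    for (mk in c("sternum", "L3")) {
      out$upper[[mk]]$ax <- out$upper[[mk]]$ax * injections$com[["x"]]
      out$upper[[mk]]$ay <- out$upper[[mk]]$ay * injections$com[["y"]]
      out$upper[[mk]]$a2 <- out$upper[[mk]]$a2 * injections$com[["z"]]
    }
    if (injections$tap_shift != 0) {
      # delay hind contacts so forelimbs land relatively earlier (TAP decreases)
      for (l in c("LH", "RH")) {
        out$phase[[l]] <- out$phase[[l]] + injections$tap_shift / out$SD
      }
    }
  } else {
    # stance window without profile: centred symmetric placement
    for (l in LIMBS) {
      stl <- out$belt * out$duty[[l]] * out$SD
      out$geom[[l]]$y_on <- stl / 2
      out$geom[[l]]$y_off <- -stl / 2
    }
  }
  out
}

# ---------------------------------------------------------------------------
# trial synthesis

#' Generate one synthetic treadmill trial
#'
#' Builds per-limb force traces at `force_rate` and marker trajectories at
#' `marker_rate` from a realised horse parameter set, applies stride jitter
#' and measurement noise, and records ground-truth hoof-on/off times.
#'
#' @param hp realised `eq_horse` parameters.
#' @param condition `"baseline"` or `"lame"`.
#' @param lame_side `"left"`, `"right"` or `"none"`.
#' @param duration trial duration, s.
#' @param force_rate,marker_rate sampling rates, Hz.
#' @param noise an [eq_noise()] object.
#' @param markers set `FALSE` to skip marker synthesis (force-only studies).
#' @return an `eq_trial`: list with `meta`, `forces` (tibble `time_s`,
#'   `LF_N` ... `RH_N`), `markers` (tibble `time_s`, `<marker>_{x,y,z}_m`)
#'   and `ground_truth` (per-limb event times and stride starts).
#' @export
generate_trial <- function(hp, condition = "baseline", lame_side = "none",
                           duration = 20, force_rate = 512, marker_rate = 256,
                           noise = eq_noise(), markers = TRUE) {
  stopifnot(inherits(noise, "eq_noise"))
  jcv <- noise$jitter_cv
  pad <- 0.25
  # stride schedule
  starts <- pad
  sds <- numeric(0)
  repeat {
    sdj <- hp$SD * max(0.5, 1 + jcv * stats::rnorm(1))
    if (starts[length(starts)] + sdj > duration - pad) break
    sds <- c(sds, sdj)
    starts <- c(starts, starts[length(starts)] + sdj)
  }
  n_strides <- length(sds)
  stride_starts <- starts[seq_len(n_strides)]
  if (n_strides < 2) stop("trial too short for the configured stride duration")

  t_force <- seq(0, duration, by = 1 / force_rate)
  t_marker <- seq(0, duration, by = 1 / marker_rate)
  nf <- length(t_force)

  # per-stride multiplicative jitter: loading amplitude, duty factor and the
  # stance shape's internal timing/shape parameters, plus upper-body
  # amplitude jitter
  jit <- function(n, cv = jcv) pmax(0.5, 1 + cv * stats::rnorm(n))
  amp <- matrix(jit(n_strides * 4), n_strides, 4,
                dimnames = list(NULL, LIMBS))
  duty_j <- matrix(jit(n_strides * 4), n_strides, 4,
                   dimnames = list(NULL, LIMBS))
  up_amp <- jit(n_strides)

  events <- list()
  forces <- matrix(0, nf, 4, dimnames = list(NULL, LIMBS))
  base_funs <- lapply(LIMBS, function(l) grf_waveform_fun(hp$shapes[[l]], hp$gait))
  names(base_funs) <- LIMBS
  stride_funs <- list()

  for (l in LIMBS) {
    on <- stride_starts + hp$phase[[l]] * sds
    tau <- pmin(hp$duty[[l]] * duty_j[, l], 0.95) * sds
    off <- on + tau
    events[[l]] <- cbind(on = on, off = off)
    stride_funs[[l]] <- vector("list", n_strides)
    for (j in seq_len(n_strides)) {
      fun <- if (jcv > 0) jitter_shape_fun(hp$shapes[[l]], hp$gait, jcv)
             else base_funs[[l]]
      stride_funs[[l]][[j]] <- fun
      idx <- which(t_force >= on[j] & t_force <= off[j])
      if (length(idx) == 0) next
      s <- (t_force[idx] - on[j]) / tau[j]
      forces[idx, l] <- forces[idx, l] + hp$mass * amp[j, l] * fun(s)
    }
  }
  if (noise$sigma_force > 0) {
    forces <- forces + matrix(stats::rnorm(length(forces),
                                           sd = noise$sigma_force * hp$mass),
                              nrow = nf)
    forces <- pmax(forces, 0)
  }

  # markers -----------------------------------------------------------------
  marker_tbl <- NULL
  if (markers) {
  stride_of <- findInterval(t_marker, stride_starts, rightmost.closed = FALSE)
  stride_of <- pmin(pmax(stride_of, 1L), n_strides)
  u_stride <- (t_marker - stride_starts[stride_of]) / sds[stride_of]

  mk <- list()
  for (nm in c("poll", "withers", "sternum", "L3")) {
    p <- hp$upper[[nm]]
    aj <- up_amp[stride_of]
    z <- p$mean + aj * (p$a2 * sin(4 * pi * u_stride + p$phi2) +
                          p$a1 * sin(2 * pi * u_stride + p$phi1))
    if (is.null(p$ax)) {
      x <- rep(0, length(t_marker))
      y <- rep(switch(nm, poll = 1.9, withers = 0.7), length(t_marker))
    } else {
      x <- aj * p$ax * sin(2 * pi * u_stride + p$phix)
      y <- switch(nm, sternum = 0.30, L3 = -0.50) +
        aj * p$ay * sin(4 * pi * u_stride + p$phiy)
    }
    mk[[nm]] <- cbind(x = x, y = y, z = z)
  }

  for (l in LIMBS) {
    g <- hp$geom[[l]]
    if (is.null(g$y_on)) {
      stl <- hp$belt * hp$duty[[l]] * hp$SD
      g$y_on <- stl / 2; g$y_off <- g$y_on - stl
    }
    on <- events[[l]][, "on"]; off <- events[[l]][, "off"]
    swing_fun <- sinpow_cumfun(g$p_swing)
    y <- numeric(length(t_marker))
    z <- rep(g$z0, length(t_marker))
    d <- numeric(length(t_marker)) # fetlock sagittal displacement
    Hj <- g$H * pmax(0.3, 1 + jcv * stats::rnorm(n_strides))
    for (j in seq_len(n_strides)) {
      st <- which(t_marker >= on[j] & t_marker <= off[j])
      if (length(st) > 0) {
        y[st] <- g$y_on - hp$belt * (t_marker[st] - on[j])
        fzn <- amp[j, l] * stride_funs[[l]][[j]]((t_marker[st] - on[j]) /
                                                   (off[j] - on[j]))
        theta <- g$gain * fzn * pi / 180
        seg_l <- sqrt(g$carpus_dy^2 + g$carpus_dz^2)
        d[st] <- (seg_l / 2) * tan(theta / 2)
      }
      nxt_on <- if (j < n_strides) on[j + 1] else NA_real_
      sw_end <- if (is.na(nxt_on)) duration + 1 else nxt_on
      sw <- which(t_marker > off[j] & t_marker < sw_end)
      if (length(sw) > 0) {
        y_off_j <- g$y_on - hp$belt * (off[j] - on[j])
        if (is.na(nxt_on)) {
          y[sw] <- y_off_j
        } else {
          u <- (t_marker[sw] - off[j]) / (nxt_on - off[j])
          y[sw] <- y_off_j + (g$y_on - y_off_j) * swing_fun(u)
          z[sw] <- g$z0 + Hj[j] * sin(pi * u)^2
        }
      }
    }
    pre <- which(t_marker < on[1])
    if (length(pre) > 0) { y[pre] <- g$y_on; z[pre] <- g$z0 }
    y <- y + g$y_pivot
    hoof <- cbind(x = rep(g$x, length(t_marker)), y = y, z = z)
    axis <- c(g$carpus_dy, g$carpus_dz) / sqrt(g$carpus_dy^2 + g$carpus_dz^2)
    nrm <- c(axis[2], -axis[1]) # perpendicular, in the sagittal plane
    carpus <- cbind(x = hoof[, "x"], y = y + g$carpus_dy, z = z + g$carpus_dz)
    fet <- cbind(x = hoof[, "x"],
                 y = y + g$carpus_dy / 2 + d * nrm[1],
                 z = z + g$carpus_dz / 2 + d * nrm[2])
    pivot <- cbind(x = rep(g$x, length(t_marker)),
                   y = rep(g$y_pivot, length(t_marker)),
                   z = rep(g$h_pivot + g$z0, length(t_marker)))
    hind <- l %in% c("LH", "RH")
    mk[[paste0("hoof_", l)]] <- hoof
    mk[[paste0("fetlock_", l)]] <- fet
    mk[[paste0(if (hind) "tarsus_" else "carpus_", l)]] <- carpus
    mk[[paste0(if (hind) "hip_" else "shoulder_", l)]] <- pivot
  }

  mmat <- do.call(cbind, lapply(names(mk), function(nm) {
    m <- mk[[nm]]
    colnames(m) <- paste0(nm, "_", c("x", "y", "z"), "_m")
    m
  }))
  if (noise$sigma_marker > 0) {
    mmat <- mmat + matrix(stats::rnorm(length(mmat),
                                       sd = noise$sigma_marker),
                          nrow = nrow(mmat))
  }
  marker_tbl <- tibble::as_tibble(cbind(time_s = t_marker,
                                        as.data.frame(mmat)))
  }

  meta <- list(horse_id = hp$horse_id, gait = hp$gait, condition = condition,
               lame_side = lame_side, induction_side = lame_side,
               body_mass = hp$mass, belt_speed = hp$belt,
               force_rate = force_rate, marker_rate = marker_rate,
               duration = duration, stride_duration = hp$SD)
  structure(list(
    meta = meta,
    forces = tibble::tibble(time_s = t_force,
                            LF_N = forces[, "LF"], RF_N = forces[, "RF"],
                            LH_N = forces[, "LH"], RH_N = forces[, "RH"]),
    markers = marker_tbl,
    ground_truth = list(events = events, stride_starts = stride_starts,
                        stride_durations = sds)
  ), class = "eq_trial")
}

#' Generate a synthetic cohort of treadmill trials
#'
#' Draws horse-level parameters once per horse, then generates one trial per
#' requested condition. The lameness profile is applied to the `"lame"`
#' condition only; the induction side is chosen at random per horse and
#' recorded in both conditions' metadata (`induction_side`), mirroring a
#' study design where one induction per horse is analysed.
#'
#' @param n_horses number of horses.
#' @param gait `"walk"` or `"trot"`.
#' @param conditions subset of `c("baseline", "lame")`.
#' @param profile a [lameness_profile()] applied under the `"lame"` condition.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @param duration trial duration, s.
#' @param noise an [eq_noise()] object.
#' @param markers set `FALSE` to skip marker synthesis.
#' @return list of `eq_trial` objects.
#' @export
generate_cohort <- function(n_horses = 10, gait = c("walk", "trot"),
                            conditions = c("baseline", "lame"),
                            profile = lameness_profile("baseline"),
                            seed = 1, duration = 20, noise = eq_noise(),
                            markers = TRUE) {
  gait <- match.arg(gait)
  stopifnot(n_horses >= 1, all(conditions %in% c("baseline", "lame")))
  set.seed(seed)
  trials <- list()
  for (h in seq_len(n_horses)) {
    hp <- make_horse(sprintf("H%02d", h), gait)
    side <- sample(c("left", "right"), 1)
    bv <- base_values(hp)
    for (cond in conditions) {
      if (cond == "baseline") {
        hpc <- realize_horse(hp, bv, injections = NULL)
        trial <- generate_trial(hpc, "baseline", "none", duration,
                                noise = noise, markers = markers)
      } else {
        tv <- apply_profile(bv, profile, side)
        hpc <- realize_horse(hp, tv, injections = attr(tv, "injections"))
        trial <- generate_trial(hpc, "lame", side, duration, noise = noise,
                                markers = markers)
      }
      trial$meta$induction_side <- side
      trials[[length(trials) + 1]] <- trial
    }
  }
  trials
}
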