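# Centre-of-mass proxy, centre-of-force and their relative dynamics.

#' Trunk centre-of-mass proxy from sternum and L3 markers
#'
#' Convex combination `w * sternum + (1 - w) * L3` per frame. The default
#' weighting (0.6 toward the sternum) reflects that the trunk mass centre
#' lies nearer the thorax; it is approximate and exposed for configuration.
#'
#' @param sternum,l3 marker matrices (frames x 3) or length-3 vectors.
#' @param w sternum weight in `[0, 1]`.
#' @return matrix (frames x 3); missing frames propagate as NA.
#' @export
com_proxy <- function(sternum, l3, w = 0.6) {
  stopifnot(w >= 0, w <= 1)
  if (is.null(dim(sternum))) sternum <- matrix(sternum, ncol = 3)
  if (is.null(dim(l3))) l3 <- matrix(l3, ncol = 3)
  w * sternum + (1 - w) * l3
}

#' Centre of force from per-limb forces and hoof positions
#'
#' Force-weighted mean of the hoof ground positions:
#' `COF = sum(Fz_i * p_i) / sum(Fz_i)` over the four limbs. Frames with
#' non-positive total force (trot suspension) are returned as NA.
#'
#' @param forces matrix (frames x 4, columns LF/RF/LH/RH), N; must be
#'   non-negative.
#' @param hoof_x,hoof_y matrices (frames x 4) of hoof ground positions, m.
#' @return matrix (frames x 2) of COF x/y, m.
#' @export
cof <- function(forces, hoof_x, hoof_y) {
  stopifnot(ncol(forces) == 4, all(forces >= 0, na.rm = TRUE))
  tot <- rowSums(forces)
  ok <- tot > 0
  x <- y <- rep(NA_real_, nrow(forces))
  x[ok] <- rowSums(forces[ok, , drop = FALSE] * hoof_x[ok, , drop = FALSE]) / tot[ok]
  y[ok] <- rowSums(forces[ok, , drop = FALSE] * hoof_y[ok, , drop = FALSE]) / tot[ok]
  cbind(x = x, y = y)
}

#' Resample marker series onto the force timeline
#'
#' Linear interpolation of each marker column onto the (higher-rate) force
#' timestamps, endpoints clamped.
#'
#' @param marker_time,marker_values marker sample times (s) and value matrix.
#' @param force_time target timestamps, s.
#' @return matrix of interpolated values at `force_time`.
#' @export
resample_markers <- function(marker_time, marker_values, force_time) {
  if (max(marker_time) < min(force_time) || min(marker_time) > max(force_time)) {
    stop("marker and force time bases do not overlap")
  }
  if (is.null(dim(marker_values))) marker_values <- matrix(marker_values)
  apply(marker_values, 2, function(v) {
    stats::approx(marker_time, v, xout = force_time, rule = 2)$y
  })
}

#' COF-COM path metrics and COM translation ranges for one stride
#'
#' For each body side, the maximal cranial displacement of the COF relative
#' to the COM (`max(COF_y - COM_y)`) during the transition from tripedal
#' support into that side's ipsilateral bipedal support (walk phases 1-2 on
#' the left, 5-6 on the right). The side asymmetry is reported as lame-side
#' maximum minus sound-side maximum. COM translation ranges are per-stride
#' max-min along each axis.
#'
#' @param cof_xy COF matrix (frames x 2) on the force timeline, m.
#' @param com_xyz COM matrix (frames x 3) on the force timeline, m.
#' @param time force timestamps, s.
#' @param phases support-phase tibble from [support_phases()].
#' @param window stride window, s.
#' @param lame_side `"left"`, `"right"` or `"none"` (then the asymmetry is
#'   reported as left minus right).
#' @return named list: `COM_ROM_x/y/z`, `COF_cranial_max_left/right`,
#'   `COF_asym` (m).
#' @export
cof_com_metrics <- function(cof_xy, com_xyz, time, phases, window,
                            lame_side = "none") {
  t0 <- window[1]; t1 <- window[2]
  i <- which(time >= t0 & time < t1)
  rom <- apply(com_xyz[i, , drop = FALSE], 2, function(v) {
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE) - min(v, na.rm = TRUE)
  })
  side_max <- function(labels) {
    ph <- phases[phases$label %in% labels, , drop = FALSE]
    if (nrow(ph) == 0) return(NA_real_)
    sel <- rep(FALSE, length(time))
    for (k in seq_len(nrow(ph))) {
      sel <- sel | (time >= ph$t_start[k] & time < ph$t_end[k])
    }
    d <- cof_xy[sel, "y"] - com_xyz[sel, 2]
    if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE)
  }
  left <- side_max(c("1", "2"))
  right <- side_max(c("5", "6"))
  asym <- switch(lame_side,
                 right = right - left,
                 left - right)
  list(COM_ROM_x = unname(rom[1]), COM_ROM_y = unname(rom[2]),
       COM_ROM_z = unname(rom[3]),
       COF_cranial_max_left = left, COF_cranial_max_right = right,
       COF_asym = asym)
}
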