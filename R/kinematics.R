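# Upper-body vertical movement symmetry indices and limb kinematics.

#' Vertical movement symmetry indices for one stride
#'
#' The stride is split into a left and a right half-cycle at the two
#' forelimb hoof-on events. Within the stride the two half-cycle minima and
#' the two intervening maxima are located (the second maximum wraps
#' cyclically across the stride boundary). The indices are
#' `MinDiff = min(right half) - min(left half)`;
#' `RUD = (upward range after the left minimum) - (upward range after the
#' right minimum)`; `RDD` the analogous difference of downward ranges; and
#' `ROMz = max - min` over the whole stride.
#'
#' @param time sample times of the signal, s.
#' @param z vertical displacement signal, m.
#' @param window stride window `(t_start, t_end)`, s (first forelimb hoof-on
#'   to the next).
#' @param split time of the opposite forelimb hoof-on inside the window, s.
#' @return named list with `MinDiff`, `RUD`, `RDD`, `ROMz` (metres) and
#'   `flagged` (TRUE when a half-cycle has no interior minimum, in which case
#'   the indices are NA).
#' @export
vertical_symmetry <- function(time, z, window, split) {
  t0 <- window[1]; t1 <- window[2]
  stopifnot(t0 < split, split < t1)
  i_all <- which(time >= t0 & time < t1)
  i_l <- which(time >= t0 & time < split)
  i_r <- which(time >= split & time < t1)
  bad <- list(MinDiff = NA_real_, RUD = NA_real_, RDD = NA_real_,
              ROMz = NA_real_, flagged = TRUE)
  if (length(i_l) < 3 || length(i_r) < 3) return(bad)
  jl <- i_l[which.min(z[i_l])]
  jr <- i_r[which.min(z[i_r])]
  # interior-extremum requirement per half-cycle
  if (jl == i_l[1] || jl == i_l[length(i_l)] ||
      jr == i_r[1] || jr == i_r[length(i_r)]) {
    return(bad)
  }
  # quadratic refinement of each extremum suppresses the upward bias of a
  # sample-wise max/min under measurement noise
  rp <- function(j) refine_peak(time, z, j, halfwidth = 5L)[2]
  min_l <- rp(jl); min_r <- rp(jr)
  # maxima between the minima; the second wraps across the stride boundary
  seg_a <- jl:jr
  seg_b <- c(jr:i_all[length(i_all)], i_all[1]:jl)
  max_a <- rp(seg_a[which.max(z[seg_a])]) # follows the left minimum
  max_b <- rp(seg_b[which.max(z[seg_b])]) # follows the right minimum
  list(MinDiff = min_r - min_l,
       RUD = (max_a - min_l) - (max_b - min_r),
       RDD = (max_a - min_r) - (max_b - min_l),
       ROMz = max(max_a, max_b) - min(min_l, min_r),
       flagged = FALSE)
}

#' Sagittal limb protraction/retraction angle
#'
#' Signed angle in the sagittal (y-z) plane between the pivot-to-hoof
#' segment and the vertical; cranial positive.
#'
#' @param pivot,hoof matrices (frames x 3, columns x/y/z) or length-3
#'   vectors.
#' @return angle(s) in degrees.
#' @export
limb_angle <- function(pivot, hoof) {
  if (is.null(dim(pivot))) pivot <- matrix(pivot, ncol = 3)
  if (is.null(dim(hoof))) hoof <- matrix(hoof, ncol = 3)
  dy <- hoof[, 2] - pivot[, 2]
  dz <- pivot[, 3] - hoof[, 3]
  if (any(abs(dy) < 1e-12 & abs(dz) < 1e-12)) {
    stop("zero-length pivot-to-hoof segment")
  }
  atan2(dy, dz) * 180 / pi
}

#' Fetlock hyperextension angle
#'
#' `180 degrees` minus the angle at the fetlock vertex between the proximal
#' and distal segments; larger values mean more hyperextension, collinear
#' markers give 0.
#'
#' @param proximal,fetlock,distal marker matrices (frames x 3) or length-3
#'   vectors.
#' @return hyperextension angle(s) in degrees, in `[0, 180)`.
#' @export
fetlock_angle <- function(proximal, fetlock, distal) {
  as3 <- function(m) if (is.null(dim(m))) matrix(m, ncol = 3) else m
  p <- as3(proximal); f <- as3(fetlock); d <- as3(distal)
  u <- p - f
  v <- d - f
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  if (any(nu < 1e-9) || any(nv < 1e-9)) {
    stop("degenerate coincident markers in fetlock angle")
  }
  cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
  180 - acos(cosang) * 180 / pi
}

#' Swing-phase and stance-length metrics for one stride of one limb
#'
#' `Prot_speed` is the maximal resultant hoof-marker speed during swing
#' (central differences at the marker rate, no smoothing); `ProtH` the
#' maximal hoof height during swing; `StL` the cranio-caudal hoof travel
#' between the (sub-sample interpolated) hoof-on and hoof-off positions.
#'
#' @param time marker sample times, s.
#' @param hoof hoof marker matrix (frames x 3).
#' @param stance `(on, off)` of the stance preceding the swing, s.
#' @param next_on hoof-on time ending the swing, s.
#' @return named list with `Prot_speed` (m/s), `ProtH` (m), `StL` (m) and
#'   `flagged` (TRUE when the swing holds fewer than 3 marker frames).
#' @export
swing_metrics <- function(time, hoof, stance, next_on) {
  on <- stance[1]; off <- stance[2]
  y_on <- stats::approx(time, hoof[, 2], on)$y
  y_off <- stats::approx(time, hoof[, 2], off)$y
  stl <- abs(y_off - y_on)
  sw <- which(time > off & time < next_on)
  if (length(sw) < 3) {
    return(list(Prot_speed = NA_real_, ProtH = NA_real_, StL = stl,
                flagged = TRUE))
  }
  idx <- max(1, sw[1] - 1):min(nrow(hoof), sw[length(sw)] + 1)
  vel <- apply(hoof[idx, , drop = FALSE], 2, function(p) {
    n <- length(p)
    (p[c(2:n, n)] - p[c(1, 1:(n - 1))]) / (time[idx][c(2:n, n)] - time[idx][c(1, 1:(n - 1))])
  })
  speed <- sqrt(rowSums(vel^2))
  inner <- which(idx %in% sw)
  list(Prot_speed = max(speed[inner]),
       ProtH = max(hoof[sw, 3]),
       StL = stl,
       flagged = FALSE)
}
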