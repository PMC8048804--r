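# End-to-end extraction: trial -> long-format per-stride parameter table,
# and cohort-level wrappers feeding the discrimination and model stages.

var_units <- function(v) {
  u <- function(pat, unit) grepl(pat, v)
  dplyr::case_when(
    u("^(SD$|StD_abs|StpDi|StpDc|TAP)", NA) ~ "s",
    u("^StD_rel", NA) ~ "fraction",
    u("^Supp_", NA) ~ "pct_stride",
    u("^t_Fz_peak", NA) ~ "pct_stance",
    u("^Fz_", NA) ~ "N/kg",
    u("^Iz", NA) ~ "N.s/kg",
    u("^dFz_", NA) ~ "N/kg/s",
    u("^Prot_speed", NA) ~ "m/s",
    u("^(Prot_max|Ret_max|A_fetlock)", NA) ~ "deg",
    u("^(MinDiff|RUD|RDD|ROMz|ProtH|StL|COM_ROM|COF_)", NA) ~ "m",
    TRUE ~ "unknown"
  )
}

marker_xyz <- function(trial, name) {
  cols <- paste0(name, "_", c("x", "y", "z"), "_m")
  missing <- setdiff(cols, names(trial$markers))
  if (length(missing) > 0) stop("missing marker columns: ",
                                paste(missing, collapse = ", "))
  as.matrix(trial$markers[, cols])
}

limb_marker_names <- function(l) {
  hind <- l %in% c("LH", "RH")
  list(hoof = paste0("hoof_", l),
       fetlock = paste0("fetlock_", l),
       prox = paste0(if (hind) "tarsus_" else "carpus_", l),
       pivot = paste0(if (hind) "hip_" else "shoulder_", l))
}

#' Extract all per-stride parameters from one trial
#'
#' Runs stance detection, stride segmentation and the requested extraction
#' modules, returning a long-format table with one row per stride, variable
#' and (where applicable) limb. Strides with an incomplete event set are
#' excluded.
#'
#' @param trial an `eq_trial`.
#' @param config an [eq_config()].
#' @param modules subset of `c("temporal", "kinetics", "kinematics",
#'   "comcof")`.
#' @return tibble with `horse_id`, `gait`, `condition`, `induction_side`,
#'   `stride_index`, `variable`, `value`, `units`.
#' @export
extract_strides <- function(trial, config = eq_config(),
                            modules = c("temporal", "kinetics",
                                        "kinematics", "comcof")) {
  stopifnot(inherits(trial, "eq_trial"))
  gait <- trial$meta$gait
  mass <- trial$meta$body_mass
  rate <- trial$meta$force_rate
  events <- trial_events(trial, config)
  strides <- segment_strides(events)
  if (nrow(strides) == 0) return(empty_stride_table())
  tf <- trial$forces$time_s
  mt <- trial$markers$time_s
  mrate <- trial$meta$marker_rate

  do_kin <- "kinetics" %in% modules
  do_kine <- "kinematics" %in% modules
  do_cc <- "comcof" %in% modules

  if (do_kin) {
    smoothed <- lapply(LIMBS, function(l) {
      lowpass(trial$forces[[paste0(l, "_N")]] / mass, rate,
              config$smooth_cutoff_hz)
    })
    names(smoothed) <- LIMBS
  }
  if (do_kine || do_cc) {
    lp <- function(m) apply(m, 2, lowpass, rate = mrate,
                            cutoff = config$marker_lowpass_hz)
    upper_z <- list(poll = lp(marker_xyz(trial, "poll"))[, 3],
                    withers = lp(marker_xyz(trial, "withers"))[, 3])
    limbm <- lapply(LIMBS, function(l) {
      nm <- limb_marker_names(l)
      list(hoof = marker_xyz(trial, nm$hoof),
           fetlock = marker_xyz(trial, nm$fetlock),
           prox = marker_xyz(trial, nm$prox),
           pivot = marker_xyz(trial, nm$pivot))
    })
    names(limbm) <- LIMBS
    fet_series <- lapply(LIMBS, function(l) {
      lowpass(fetlock_angle(limbm[[l]]$prox, limbm[[l]]$fetlock,
                            limbm[[l]]$hoof),
              mrate, config$angle_lowpass_hz)
    })
    names(fet_series) <- LIMBS
    angle_series <- lapply(LIMBS, function(l) {
      limb_angle(limbm[[l]]$pivot, limbm[[l]]$hoof)
    })
    names(angle_series) <- LIMBS
  }
  if (do_cc) {
    sternum_f <- resample_markers(mt, lp(marker_xyz(trial, "sternum")), tf)
    l3_f <- resample_markers(mt, lp(marker_xyz(trial, "L3")), tf)
    com_f <- com_proxy(sternum_f, l3_f)
    hoof_x <- hoof_y <- matrix(NA_real_, length(tf), 4)
    for (k in seq_along(LIMBS)) {
      hk <- resample_markers(mt, limbm[[LIMBS[k]]]$hoof[, 1:2], tf)
      hoof_x[, k] <- hk[, 1]
      hoof_y[, k] <- hk[, 2]
    }
    fmat <- as.matrix(trial$forces[, paste0(LIMBS, "_N")])
    cof_f <- cof(pmax(fmat, 0), hoof_x, hoof_y)
  }

  rows <- list()
  add <- function(i, vals) {
    vals <- vals[!vapply(vals, is.logical, logical(1))] # drop flags
    keep <- vapply(vals, function(x) is.numeric(x) && length(x) == 1,
                   logical(1))
    vals <- vals[keep]
    if (length(vals) == 0) return(invisible(NULL))
    rows[[length(rows) + 1]] <<- tibble::tibble(
      stride_index = i, variable = names(vals),
      value = unname(unlist(vals)))
  }

  for (i in seq_len(nrow(strides))) {
    w <- c(strides[i, "t_start"], strides[i, "t_end"])
    tp <- temporal_parameters(events, w)
    if (is.null(tp)) next
    if ("temporal" %in% modules) add(i, tp)
    needs_phases <- do_cc || ("temporal" %in% modules && gait == "walk")
    if (needs_phases) {
      ph <- suppressMessages(support_phases(events, w, gait))
      if ("temporal" %in% modules && gait == "walk") {
        sp <- support_percentages(ph)
        sp <- sp[names(sp) %in% as.character(1:8)]
        names(sp) <- paste0("Supp_", names(sp))
        add(i, as.list(sp))
      }
    }
    if (do_kin) {
      for (l in LIMBS) {
        st <- stance_in(events[[l]], w[1], w[2])
        if (is.null(st)) next
        kp <- kinetic_parameters(trial$forces[[paste0(l, "_N")]],
                                 c(st[["on"]], st[["off"]]), mass, rate,
                                 gait, config, smoothed = smoothed[[l]])
        kp$monophasic <- NULL
        names(kp) <- paste(names(kp), l, sep = "_")
        add(i, kp)
      }
    }
    if (do_kine) {
      rf_on <- stance_in(events$RF, w[1], w[2])
      if (!is.null(rf_on) && rf_on[["on"]] > w[1] && rf_on[["on"]] < w[2]) {
        for (lm in c("poll", "withers")) {
          vs <- vertical_symmetry(mt, upper_z[[lm]], w, rf_on[["on"]])
          if (!vs$flagged) {
            vs$flagged <- NULL
            names(vs) <- paste(names(vs), lm, sep = "_")
            add(i, vs)
          }
        }
      }
      for (l in LIMBS) {
        st <- stance_in(events[[l]], w[1], w[2])
        if (is.null(st)) next
        nxt <- first_in(events[[l]][, "on"], st[["off"]],
                        st[["off"]] + (w[2] - w[1]) * 1.5)
        if (is.na(nxt)) next
        cyc <- which(mt >= st[["on"]] & mt < nxt)
        kin <- list()
        if (length(cyc) > 2) {
          ang <- angle_series[[l]][cyc]
          kin$Prot_max <- max(ang)
          kin$Ret_max <- min(ang)
        }
        stf <- which(mt >= st[["on"]] & mt <= st[["off"]])
        if (length(stf) > 2) {
          imax <- stf[which.max(fet_series[[l]][stf])]
          kin$A_fetlock <- refine_peak(mt, fet_series[[l]], imax,
                                       halfwidth = 5L)[2]
        }
        sm <- swing_metrics(mt, limbm[[l]]$hoof,
                            c(st[["on"]], st[["off"]]), nxt)
        sm$flagged <- NULL
        kin <- c(kin, sm)
        names(kin) <- paste(names(kin), l, sep = "_")
        add(i, kin)
      }
    }
    if (do_cc) {
      cc <- cof_com_metrics(cof_f, com_f, tf, ph, w, lame_side = "none")
      add(i, cc)
    }
  }
  if (length(rows) == 0) return(empty_stride_table())
  out <- dplyr::bind_rows(rows)
  tibble::tibble(horse_id = trial$meta$horse_id, gait = gait,
                 condition = trial$meta$condition,
                 induction_side = trial$meta$induction_side %||% "none",
                 stride_index = out$stride_index,
                 variable = out$variable, value = out$value,
                 units = var_units(out$variable))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_stride_table <- function() {
  tibble::tibble(horse_id = character(), gait = character(),
                 condition = character(), induction_side = character(),
                 stride_index = integer(), variable = character(),
                 value = numeric(), units = character())
}

#' Extract per-stride parameters for a list of trials
#'
#' @param trials list of `eq_trial` objects (e.g. from [generate_cohort()]).
#' @param config an [eq_config()].
#' @param modules extraction modules, see [extract_strides()].
#' @param max_strides optional cap on the number of strides kept per trial.
#' @return combined long-format stride table.
#' @export
extract_cohort <- function(trials, config = eq_config(),
                           modules = c("temporal", "kinetics",
                                       "kinematics", "comcof"),
                           max_strides = Inf) {
  tabs <- lapply(trials, function(tr) {
    tab <- extract_strides(tr, config, modules)
    if (is.finite(max_strides)) {
      keep <- sort(unique(tab$stride_index))
      keep <- keep[seq_len(min(length(keep), max_strides))]
      tab <- tab[tab$stride_index %in% keep, ]
    }
    tab
  })
  dplyr::bind_rows(tabs)
}

#' Mirror a cohort stride table to left-induction convention
#'
#' Applies [mirror_right()] using each row's recorded induction side, so
#' limb-suffixed variables become role-suffixed (`lame`, `contra`, `ipsi`,
#' `diag`) and signed symmetry indices of right inductions are negated.
#'
#' @param strides table from [extract_cohort()].
#' @return mirrored table.
#' @export
mirror_cohort <- function(strides) {
  side <- ifelse(strides$induction_side %in% c("left", "right"),
                 strides$induction_side, "left")
  out <- mirror_right(strides, side)
  out$units <- var_units(out$variable)
  out
}

#' Run the full synthetic study for one gait
#'
#' Generates a baseline-versus-lame cohort, extracts stride parameters,
#' mirrors to the left-induction convention and fits the per-variable mixed
#' models; optionally also computes the per-horse Youden discrimination
#' table.
#'
#' @param gait `"walk"` or `"trot"`.
#' @param profile a [lameness_profile()].
#' @param n_horses cohort size.
#' @param seed integer seed.
#' @param strides_per_condition stride cap per trial.
#' @param noise an [eq_noise()].
#' @param modules extraction modules.
#' @param discriminate also compute the Youden table.
#' @return list with `strides` (mirrored), `models`, and optionally
#'   `heatmap` / `heatmap_summary`.
#' @export
run_study <- function(gait, profile, n_horses = 10, seed = 1,
                      strides_per_condition = 15, noise = eq_noise(),
                      modules = c("temporal", "kinetics", "kinematics",
                                  "comcof"),
                      discriminate = FALSE) {
  need_markers <- any(c("kinematics", "comcof") %in% modules)
  trials <- generate_cohort(n_horses, gait, c("baseline", "lame"),
                            profile, seed = seed, noise = noise,
                            markers = need_markers)
  strides <- extract_cohort(trials, modules = modules,
                            max_strides = strides_per_condition)
  mirrored <- mirror_cohort(strides)
  models <- model_table(mirrored)
  out <- list(strides = mirrored, models = models)
  if (discriminate) {
    cells <- discrimination_table(mirrored)
    out$heatmap <- cells
    out$heatmap_summary <- heatmap_table(cells)
  }
  out
}

#' COF-COM relative path of a trial
#'
#' Per-frame difference between the centre of force and the COM proxy on
#' the force timeline (the walk "butterfly" path).
#'
#' @param trial an `eq_trial`.
#' @param config an [eq_config()].
#' @return tibble with `time_s`, `dx_m` (lateral, right positive), `dy_m`
#'   (cranial positive).
#' @export
cof_path <- function(trial, config = eq_config()) {
  mt <- trial$markers$time_s
  tf <- trial$forces$time_s
  lp <- function(m) apply(m, 2, lowpass, rate = trial$meta$marker_rate,
                          cutoff = config$marker_lowpass_hz)
  com_f <- com_proxy(resample_markers(mt, lp(marker_xyz(trial, "sternum")), tf),
                     resample_markers(mt, lp(marker_xyz(trial, "L3")), tf))
  hoof_x <- hoof_y <- matrix(NA_real_, length(tf), 4)
  for (k in seq_along(LIMBS)) {
    hk <- resample_markers(mt, marker_xyz(trial, paste0("hoof_", LIMBS[k]))[, 1:2], tf)
    hoof_x[, k] <- hk[, 1]
    hoof_y[, k] <- hk[, 2]
  }
  fmat <- pmax(as.matrix(trial$forces[, paste0(LIMBS, "_N")]), 0)
  cf <- cof(fmat, hoof_x, hoof_y)
  tibble::tibble(time_s = tf, dx_m = cf[, "x"] - com_f[, 1],
                 dy_m = cf[, "y"] - com_f[, 2])
}
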