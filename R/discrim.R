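# Per-horse Youden-index discrimination, heat-map tables, trial-side
# selection and left/right mirroring of stride records.

#' Optimal Youden-index cutoff for one horse and variable
#'
#' Candidate cutoffs are the midpoints between consecutive sorted unique
#' pooled values; both classification directions are evaluated. Sensitivity
#' is the fraction of lame strides classified lame, specificity the fraction
#' of baseline strides classified baseline; the maximiser of
#' `J = sensitivity + specificity - 1` is returned. Ties are broken toward
#' the cutoff nearest the pooled median, then toward direction `"greater"`.
#'
#' @param baseline,lame numeric stride-level values (at least 2 each).
#' @return list with `sensitivity`, `specificity`, `cutoff`, `direction`
#'   (`"greater"` = lame classified when value > cutoff), `youden_J`,
#'   `n_baseline`, `n_lame`.
#' @export
youden <- function(baseline, lame) {
  baseline <- baseline[is.finite(baseline)]
  lame <- lame[is.finite(lame)]
  if (length(baseline) < 2 || length(lame) < 2) {
    stop("youden requires at least 2 finite values per condition")
  }
  pooled <- sort(unique(c(baseline, lame)))
  if (length(pooled) < 2) {
    return(list(sensitivity = 0.5, specificity = 0.5, cutoff = pooled[1],
                direction = "greater", youden_J = 0,
                n_baseline = length(baseline), n_lame = length(lame)))
  }
  cuts <- (pooled[-1] + pooled[-length(pooled)]) / 2
  med <- stats::median(c(baseline, lame))
  grid <- expand.grid(cutoff = cuts, direction = c("greater", "less"),
                      stringsAsFactors = FALSE)
  sens <- spec <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    if (grid$direction[i] == "greater") {
      sens[i] <- mean(lame > grid$cutoff[i])
      spec[i] <- mean(baseline <= grid$cutoff[i])
    } else {
      sens[i] <- mean(lame < grid$cutoff[i])
      spec[i] <- mean(baseline >= grid$cutoff[i])
    }
  }
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1) {
    d <- abs(grid$cutoff[best] - med)
    best <- best[d <= min(d) + 1e-12]
    if (length(best) > 1) {
      g <- best[grid$direction[best] == "greater"]
      best <- if (length(g) > 0) g else best
    }
    best <- best[1]
  }
  list(sensitivity = sens[best], specificity = spec[best],
       cutoff = grid$cutoff[best], direction = grid$direction[best],
       youden_J = j[best],
       n_baseline = length(baseline), n_lame = length(lame))
}

#' Per-horse Youden discrimination table for a stride table
#'
#' @param strides long-format stride table (columns `horse_id`, `gait`,
#'   `condition`, `variable`, `value`) with both conditions present.
#' @return tibble, one row per horse x gait x variable.
#' @export
discrimination_table <- function(strides) {
  strides <- strides[is.finite(strides$value), ]
  keys <- unique(strides[, c("horse_id", "gait", "variable")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- strides[strides$horse_id == k$horse_id & strides$gait == k$gait &
                     strides$variable == k$variable, ]
    b <- sub$value[sub$condition == "baseline"]
    l <- sub$value[sub$condition == "lame"]
    if (length(b) < 2 || length(l) < 2) return(NULL)
    y <- youden(b, l)
    tibble::tibble(horse_id = k$horse_id, gait = k$gait,
                   variable = k$variable,
                   sensitivity = y$sensitivity, specificity = y$specificity,
                   cutoff = y$cutoff, direction = y$direction,
                   youden_J = y$youden_J,
                   n_baseline = y$n_baseline, n_lame = y$n_lame)
  })
  dplyr::bind_rows(rows)
}

#' Group-median heat-map summary
#'
#' Per variable (and gait), the group medians of per-horse sensitivity,
#' specificity and J, ranked by median J.
#'
#' @param cells tibble from [discrimination_table()].
#' @return tibble with `variable`, `gait`, `median_sens`, `median_spec`,
#'   `median_J`, `n_horses`, sorted by decreasing `median_J`.
#' @export
heatmap_table <- function(cells) {
  out <- dplyr::summarise(
    dplyr::group_by(cells, .data$gait, .data$variable),
    median_sens = stats::median(.data$sensitivity),
    median_spec = stats::median(.data$specificity),
    median_J = stats::median(.data$youden_J),
    n_horses = dplyr::n_distinct(.data$horse_id),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$median_J))
}

#' Select the induction side to analyse
#'
#' Chooses the side with the larger trot head-position asymmetry `|MinDiff|`;
#' when the two are within a relative equivalence band, the side with the
#' larger between-forelimb peak-force difference decides. Exact ties go to
#' the left by convention. A missing side returns the other with a message.
#'
#' @param left,right lists with elements `mindiff` (m) and `dfzpeak` (N/kg)
#'   from the trot trial of each induction, or `NULL` when an induction was
#'   lost.
#' @param band relative equivalence band on `|MinDiff|`.
#' @return `"left"` or `"right"`.
#' @export
select_induction_side <- function(left, right, band = 0.05) {
  if (is.null(left) && is.null(right)) stop("no induction trial available")
  if (is.null(right)) {
    message("right induction missing; selecting left")
    return("left")
  }
  if (is.null(left)) {
    message("left induction missing; selecting right")
    return("right")
  }
  ml <- abs(left$mindiff); mr <- abs(right$mindiff)
  if (abs(ml - mr) > band * max(ml, mr)) {
    return(if (ml > mr) "left" else "right")
  }
  fl <- abs(left$dfzpeak); fr <- abs(right$dfzpeak)
  if (fl > fr) "left" else if (fr > fl) "right" else "left"
}

SIGNED_SYMMETRY_PREFIX <- c("MinDiff", "RUD", "RDD")

#' Mirror right-side inductions onto the left
#'
#' Signed symmetry variables (MinDiff/RUD/RDD) are multiplied by -1 for
#' right-side inductions, and limb-suffixed variables are relabelled to limb
#' roles relative to the lame limb (`lame`, `contra`, `ipsi`, `diag`), so
#' that all records read as left-forelimb inductions. Applying the mirror
#' twice with the same side map is the identity on signed variables.
#'
#' @param records long stride table with a `variable` column.
#' @param side `"left"` or `"right"`: the horse's induction side (vectorised
#'   over rows when of the same length as `records`).
#' @return records with mirrored values and role-relabelled variables.
#' @export
mirror_right <- function(records, side) {
  stopifnot(all(side %in% c("left", "right")))
  if (length(side) == 1) side <- rep(side, nrow(records))
  v <- records$variable
  base <- sub("_(LF|RF|LH|RH)$", "", v)
  limb <- ifelse(grepl("_(LF|RF|LH|RH)$", v), sub("^.*_", "", v), NA)
  signed <- base %in% SIGNED_SYMMETRY_PREFIX |
    sub("_(poll|withers)$", "", v) %in% SIGNED_SYMMETRY_PREFIX |
    v == "COF_asym"
  flip <- signed & side == "right"
  records$value[flip] <- -records$value[flip]
  role_map <- function(limb, side) {
    left <- c(LF = "lame", RF = "contra", LH = "ipsi", RH = "diag")
    right <- c(RF = "lame", LF = "contra", RH = "ipsi", LH = "diag")
    ifelse(side == "left", left[limb], right[limb])
  }
  has_limb <- !is.na(limb)
  records$variable[has_limb] <- paste(base[has_limb],
                                      role_map(limb[has_limb],
                                               side[has_limb]),
                                      sep = "_")
  # body-side suffixes (e.g. COF_cranial_max_left) become lame/sound roles
  lr <- grepl("_(left|right)$", records$variable)
  if (any(lr)) {
    stem <- sub("_(left|right)$", "", records$variable[lr])
    body <- sub("^.*_", "", records$variable[lr])
    role <- ifelse(body == ifelse(side[lr] == "right", "right", "left"),
                   "lame", "sound")
    records$variable[lr] <- paste(stem, role, sep = "_")
  }
  records
}
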