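# Stride-level linear mixed-model comparison of baseline versus lame, one
# model per variable and gait, with Bonferroni correction.

#' Bonferroni adjustment
#' @param p raw p-values in `[0, 1]`.
#' @param m number of comparisons (`m >= 1`).
#' @return `min(1, m * p)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1, na.rm = TRUE))
  pmin(1, m * p)
}

#' Mixed-model comparison of one variable between conditions
#'
#' Fits `value ~ condition + (1 | horse)` by REML (random intercept per
#' horse, fixed lameness condition), with least-square means of the two
#' conditions from the fitted model (for this one-factor design these equal
#' the fixed-effect predictions per condition) and a Satterthwaite p-value
#' for the condition effect. Horses lacking one of the two conditions are excluded
#' with a warning. On a singular or failed fit the function falls back to a
#' pooled two-sample comparison and flags the result.
#'
#' @param values stride-level numeric values.
#' @param horse horse identifiers (same length).
#' @param condition `"baseline"`/`"lame"` labels (same length).
#' @return list with `ls_mean_baseline`, `ls_mean_lame`, `difference`,
#'   `percent_change`, `p_raw`, `n_strides`, `n_horses`, `flagged`.
#' @export
fit_condition_model <- function(values, horse, condition) {
  d <- data.frame(value = values, horse = factor(horse),
                  condition = factor(condition,
                                     levels = c("baseline", "lame")))
  d <- d[is.finite(d$value), ]
  tab <- table(d$horse, d$condition)
  ok <- rownames(tab)[tab[, "baseline"] > 0 & tab[, "lame"] > 0]
  if (length(ok) < nrow(tab)) {
    warning(nrow(tab) - length(ok),
            " horse(s) lack one condition and were excluded")
  }
  d <- droplevels(d[d$horse %in% ok, ])
  if (nlevels(d$horse) < 2) stop("need at least 2 horses with both conditions")
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(value ~ condition + (1 | horse),
                                    data = d, REML = TRUE)),
    error = function(e) NULL)
  flagged <- FALSE
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    # for the one-factor model the least-square means are the fixed-effect
    # predictions at each condition (identical to emmeans output)
    fe <- lme4::fixef(fit)
    lsb <- unname(fe[["(Intercept)"]])
    lsl <- lsb + unname(fe[["conditionlame"]])
    co <- stats::coef(summary(fit))
    p <- co["conditionlame", "Pr(>|t|)"]
    diffv <- unname(co["conditionlame", "Estimate"])
  } else {
    # singular/failed fit: pooled two-sample comparison, flagged
    flagged <- TRUE
    lsb <- mean(d$value[d$condition == "baseline"])
    lsl <- mean(d$value[d$condition == "lame"])
    diffv <- lsl - lsb
    p <- tryCatch(stats::t.test(value ~ condition, data = d)$p.value,
                  error = function(e) NA_real_)
  }
  list(ls_mean_baseline = lsb, ls_mean_lame = lsl, difference = diffv,
       percent_change = if (abs(lsb) > 0) 100 * diffv / lsb else NA_real_,
       p_raw = unname(p), n_strides = nrow(d),
       n_horses = nlevels(d$horse), flagged = flagged)
}

#' Mixed-model table over all variables of a stride table
#'
#' Walk and trot are fitted in separate models; `m` for the Bonferroni
#' correction is the number of variables actually modelled within each gait.
#'
#' @param strides long stride table (typically after [mirror_right()]).
#' @param gait optional filter, `"walk"` or `"trot"`.
#' @return tibble of model results with `p_bonferroni`.
#' @export
model_table <- function(strides, gait = NULL) {
  if (!is.null(gait)) strides <- strides[strides$gait == gait, ]
  out <- list()
  for (g in unique(strides$gait)) {
    sg <- strides[strides$gait == g, ]
    vars <- unique(sg$variable)
    rows <- lapply(vars, function(v) {
      sv <- sg[sg$variable == v & is.finite(sg$value), ]
      if (length(unique(sv$condition)) < 2) return(NULL)
      res <- tryCatch(
        withCallingHandlers(
          fit_condition_model(sv$value, sv$horse_id, sv$condition),
          warning = function(w) invokeRestart("muffleWarning")),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      tibble::tibble(variable = v, gait = g,
                     ls_mean_baseline = res$ls_mean_baseline,
                     ls_mean_lame = res$ls_mean_lame,
                     difference = res$difference,
                     percent_change = res$percent_change,
                     p_raw = res$p_raw,
                     n_strides = res$n_strides, n_horses = res$n_horses,
                     flagged = res$flagged)
    })
    tab <- dplyr::bind_rows(rows)
    if (nrow(tab) > 0) {
      tab$p_bonferroni <- bonferroni(tab$p_raw, nrow(tab))
    }
    out[[g]] <- tab
  }
  dplyr::bind_rows(out)
}
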