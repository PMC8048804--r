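test_that("Youden search handles separated, identical and overlapping samples", {
  sep <- youden(c(1, 2, 3), c(10, 11, 12))
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  expect_equal(sep$youden_J, 1)
  same <- youden(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$youden_J, 0)
  ov <- youden(c(1, 2, 3, 4), c(3, 4, 5, 6))
  expect_equal(ov$youden_J, 0.5)
  expect_equal(ov$cutoff, 3.5) # tie broken toward the pooled median
  expect_equal(ov$direction, "greater")
  expect_equal(ov$sensitivity + ov$specificity - 1, ov$youden_J)
  expect_equal(ov$n_baseline, 4); expect_equal(ov$n_lame, 4)
})

test_that("Youden search equals exhaustive brute force on random samples", {
  set.seed(77)
  for (k in 1:200) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    b <- rnorm(n1, 0, 1)
    l <- rnorm(n2, runif(1, -1, 1), runif(1, 0.5, 2))
    y <- youden(b, l)
    expect_equal(y$youden_J, brute_youden(b, l), tolerance = 1e-12)
    expect_gte(y$youden_J, 0)
  }
})

test_that("Youden J matches the reference ROC implementation", {
  library(pROC)
  set.seed(42)
  for (k in 1:20) {
    b <- rnorm(15); l <- rnorm(20, 0.8)
    j_ref <- max(vapply(c("<", ">"), function(dir) {
      r <- pROC::roc(response = c(rep(0, 15), rep(1, 20)),
                     predictor = c(b, l), quiet = TRUE, direction = dir)
      max(r$sensitivities + r$specificities - 1)
    }, numeric(1)))
    expect_equal(youden(b, l)$youden_J, j_ref, tolerance = 1e-12)
  }
})

test_that("Youden J is invariant under strictly monotone transforms", {
  set.seed(5)
  b <- rnorm(12); l <- rnorm(15, 0.6)
  expect_equal(youden(exp(b), exp(l))$youden_J, youden(b, l)$youden_J)
  expect_equal(youden(-b, -l)$youden_J, youden(b, l)$youden_J)
})

test_that("heat-map summary uses group medians and ranks by J", {
  cells <- tibble::tibble(
    horse_id = rep(c("A", "B", "C"), 2),
    gait = "walk",
    variable = rep(c("v1", "v2"), each = 3),
    sensitivity = c(0.2, 0.8, 1.0, 0.5, 0.5, 0.5),
    specificity = c(1, 1, 0.6, 0.7, 0.9, 0.8),
    cutoff = 0, direction = "greater",
    youden_J = c(0.2, 0.8, 0.6, 0.2, 0.4, 0.3),
    n_baseline = 10, n_lame = 10)
  hm <- heatmap_table(cells)
  expect_equal(hm$median_sens[hm$variable == "v1"], 0.8)
  expect_equal(hm$median_J[hm$variable == "v1"], 0.6)
  expect_equal(hm$variable[1], "v1") # ranked by median J
  # with a single horse the medians equal that horse's values
  one <- heatmap_table(cells[cells$horse_id == "A", ])
  expect_equal(sort(one$median_sens), c(0.2, 0.5))
  expect_equal(one$n_horses, c(1, 1))
})

test_that("induction-side selection follows MinDiff then peak-force difference", {
  expect_equal(select_induction_side(list(mindiff = 0.008, dfzpeak = 0.2),
                                     list(mindiff = 0.003, dfzpeak = 0.9)),
               "left")
  # within the equivalence band the force difference decides
  expect_equal(select_induction_side(list(mindiff = 0.0100, dfzpeak = 0.4),
                                     list(mindiff = 0.0098, dfzpeak = 0.9)),
               "right")
  expect_equal(select_induction_side(list(mindiff = 0.01, dfzpeak = 0.5),
                                     list(mindiff = 0.01, dfzpeak = 0.5)),
               "left") # exact tie -> left by convention
  expect_message(
    expect_equal(select_induction_side(NULL,
                                       list(mindiff = 1, dfzpeak = 1)),
                 "right"),
    "missing")
})

test_that("mirroring negates signed indices and relabels limbs to roles", {
  rec <- tibble::tibble(
    horse_id = "H1", gait = "walk", condition = "lame",
    stride_index = 1,
    variable = c("MinDiff_poll", "RUD_poll", "ROMz_poll", "Iz_LF", "Iz_RF",
                 "StL_LH", "COF_cranial_max_left", "COF_asym"),
    value = c(0.004, 0.002, 0.05, 3.2, 3.4, 1.2, 0.1, 0.02),
    units = "x")
  left <- mirror_right(rec, "left")
  expect_equal(left$value[1], 0.004) # left induction is the identity on signs
  expect_equal(left$variable[4], "Iz_lame")
  expect_equal(left$variable[5], "Iz_contra")
  expect_equal(left$variable[6], "StL_ipsi")
  expect_equal(left$variable[7], "COF_cranial_max_lame")

  right <- mirror_right(rec, "right")
  expect_equal(right$value[1], -0.004)
  expect_equal(right$value[2], -0.002)
  expect_equal(right$value[3], 0.05) # ROMz is unsigned
  expect_equal(right$variable[4], "Iz_contra")
  expect_equal(right$variable[5], "Iz_lame")
  expect_equal(right$variable[6], "StL_diag")
  expect_equal(right$variable[7], "COF_cranial_max_sound")
  expect_equal(right$value[8], -0.02)

  # double mirror restores the signed values
  twice <- mirror_right(mirror_right(rec, "right"), "right")
  expect_equal(twice$value[1:3], rec$value[1:3])
})

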