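mk_avs <- function(ac_left, ac_right, si_left = 3.2, si_right = 3.5,
                   c_ivc = 300) {
  avs_run(cortisol_left = si_left * c_ivc, cortisol_right = si_right * c_ivc,
          cortisol_ivc = c_ivc,
          aldosterone_left = ac_left * si_left * c_ivc,
          aldosterone_right = ac_right * si_right * c_ivc,
          aldosterone_ivc = 5 * c_ivc)
}

mk_mto <- function(side = "left", hu = 5, ratio = 1.5, uptake = TRUE,
                   bg = 20) {
  nod <- if (is.null(side)) list() else
    list(list(side = side, hu = hu, suvmax = ratio * bg, uptake = uptake))
  mto_scan(nod, background_suvmax_left = bg, background_suvmax_right = bg)
}

test_that("selectivity index is the plain cortisol ratio with threshold at 3", {
  expect_equal(selectivity_index(900, 300), 3)
  expect_equal(selectivity_index(870, 300), 2.9)
  expect_equal(selectivity_index(123, 123), 1)
  expect_error(selectivity_index(900, 0), "positive")
})

test_that("AVS grading follows the LI bands and fails on poor cannulation", {
  g <- grade_avs(mk_avs(40, 8))
  expect_equal(g$level, "high")
  expect_equal(g$side, "left")
  expect_equal(g$indices$lateralization_index, 5)

  g <- grade_avs(mk_avs(8, 28))     # LI 3.5 -> intermediate, right dominant
  expect_equal(g$level, "intermediate")
  expect_equal(g$side, "right")

  g <- grade_avs(mk_avs(10, 8))     # LI 1.25 -> low, no side
  expect_equal(g$level, "low")
  expect_equal(g$side, "none")

  g <- grade_avs(mk_avs(40, 8, si_left = 2.5))
  expect_equal(g$level, "failed")
  expect_equal(g$side, "none")

  g <- grade_avs(mk_avs(40, 8, si_left = 3.0))  # inclusive threshold
  expect_equal(g$level, "high")

  run <- mk_avs(40, 8)
  run$cannulated_right <- FALSE
  expect_equal(grade_avs(run)$level, "failed")
})

test_that("AVS grade is invariant to rescaling all concentrations", {
  base <- mk_avs(40, 8)
  for (k in c(0.25, 3, 117)) {
    scaled <- base
    for (f in c("cortisol_left", "cortisol_right", "cortisol_ivc",
                "aldosterone_left", "aldosterone_right", "aldosterone_ivc"))
      scaled[[f]] <- base[[f]] * k
    expect_equal(grade_avs(scaled)$level, grade_avs(base)$level)
    expect_equal(grade_avs(scaled)$side, grade_avs(base)$side)
  }
})

test_that("raising the dominant A/C ratio never lowers the AVS grade", {
  order_of <- c(low = 1, intermediate = 2, high = 3)
  last <- 0
  for (ac in seq(9, 60, by = 3)) {          # contralateral fixed at 8
    lvl <- order_of[[grade_avs(mk_avs(ac, 8))$level]]
    expect_gte(lvl, last)
    last <- lvl
  }
})

test_that("MTO grading needs all three features, downgrades bilateral signal", {
  g <- grade_mto(mk_mto(side = "left", hu = 10, ratio = 1.3, bg = 20))
  expect_equal(g$level, "high")
  expect_equal(g$side, "left")
  expect_equal(g$indices$suv_ratio_left, 1.3)

  # cold indeterminate nodule: no feature met -> low
  expect_equal(grade_mto(mk_mto(hu = 25, ratio = 1.1, uptake = FALSE))$level,
               "low")
  expect_equal(grade_mto(mk_mto(side = NULL))$level, "low")

  # avid benign nodule below the ratio threshold: some features -> intermediate
  expect_equal(grade_mto(mk_mto(hu = 5, ratio = 1.2, uptake = TRUE))$level,
               "intermediate")

  # both sides meeting the high rule is a bilateral signal
  both <- mto_scan(list(list(side = "left", hu = 5, suvmax = 30, uptake = TRUE),
                        list(side = "right", hu = 5, suvmax = 28, uptake = TRUE)),
                   background_suvmax_left = 20, background_suvmax_right = 20)
  expect_equal(grade_mto(both)$level, "intermediate")

  expect_error(grade_mto(mto_scan(list(), NA, 20)), "ungradable")
})

test_that("raising nodule SUVmax never lowers the MTO grade", {
  order_of <- c(low = 1, intermediate = 2, high = 3)
  last <- 0
  for (ratio in seq(0.8, 2.4, by = 0.2)) {
    lvl <- order_of[[grade_mto(mk_mto(hu = 5, ratio = ratio, uptake = TRUE))$level]]
    expect_gte(lvl, last)
    last <- lvl
  }
})

test_that("MDT rule: either high operates, opposite sides defer, both-intermediate needs indication", {
  high_l <- test_grade("high", "left", list())
  high_r <- test_grade("high", "right", list())
  int_l <- test_grade("intermediate", "left", list())
  low <- test_grade("low", "none", list())
  failed <- test_grade("failed", "none", list())

  expect_equal(mdt_decision(high_l, low), list(management = "surgery", side = "left"))
  expect_equal(mdt_decision(low, high_r)$side, "right")
  expect_equal(mdt_decision(high_l, high_r)$management, "deferred")
  expect_equal(mdt_decision(high_l, high_l)$management, "surgery")
  expect_equal(mdt_decision(int_l, int_l, TRUE)$management, "surgery")
  expect_equal(mdt_decision(int_l, int_l, FALSE)$management, "medical")
  expect_equal(mdt_decision(int_l, failed, TRUE)$management, "medical")
  expect_equal(mdt_decision(low, low)$management, "medical")
})

test_that("MDT rule is symmetric under left/right relabeling", {
  flip <- function(side) c(left = "right", right = "left", none = "none")[[side]]
  grades <- list(test_grade("high", "left", list()),
                 test_grade("high", "right", list()),
                 test_grade("intermediate", "left", list()),
                 test_grade("intermediate", "right", list()),
                 test_grade("low", "none", list()),
                 test_grade("failed", "none", list()))
  for (g1 in grades) for (g2 in grades) for (ci in c(TRUE, FALSE)) {
    d <- mdt_decision(g1, g2, ci)
    f1 <- test_grade(g1$level, flip(g1$side), list())
    f2 <- test_grade(g2$level, flip(g2$side), list())
    df <- mdt_decision(f1, f2, ci)
    expect_equal(df$management, d$management)
    if (!is.na(d$side) && d$side != "none") expect_equal(df$side, flip(d$side))
  }
})
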