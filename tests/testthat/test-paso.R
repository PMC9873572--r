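visit <- function(sbp = 150, dbp = 95, ddd = 3, aldosterone = 900,
                  renin_activity = 0.2, potassium = 3.4, supp = FALSE) {
  list(sbp_home = sbp, dbp_home = dbp, ddd = ddd, aldosterone = aldosterone,
       renin_activity = renin_activity, potassium = potassium,
       on_potassium_supplements = supp)
}

test_that("clinical PASO classification: complete / partial / absent", {
  base <- visit(160, 100, ddd = 3)
  expect_equal(classify_clinical(base, visit(128, 80, ddd = 0))$level, "complete")
  # 135/85 are strict targets (baseline off medication so no partial route)
  expect_equal(classify_clinical(visit(150, 90, ddd = 0),
                                 visit(135, 84, ddd = 0))$level, "absent")
  expect_equal(classify_clinical(visit(150, 90, ddd = 0),
                                 visit(134.9, 84, ddd = 0))$level, "complete")
  expect_equal(classify_clinical(base, visit(138, 88, ddd = 3))$level, "partial")
  expect_equal(classify_clinical(visit(150, 95), visit(149, 94, ddd = 3))$level,
               "absent")
  # same BP on fewer medications is partial
  expect_equal(classify_clinical(visit(150, 95, ddd = 4),
                                 visit(150, 95, ddd = 2))$level, "partial")
  # a BP drop achieved by adding medication is not
  expect_equal(classify_clinical(visit(160, 100, ddd = 2),
                                 visit(138, 88, ddd = 4))$level, "absent")
  miss <- visit(); miss$sbp_home <- NA
  out <- classify_clinical(visit(), miss)
  expect_false(out$evaluable)
  expect_true(is.na(out$level))
})

test_that("biochemical PASO classification: complete / partial / absent", {
  base <- visit(aldosterone = 900, renin_activity = 0.1, potassium = 3.2)
  cured <- visit(aldosterone = 120, renin_activity = 1.2, potassium = 4.1)
  expect_equal(classify_biochemical(base, cured)$level, "complete")
  # large aldosterone fall with persistently suppressed renin: partial
  part <- visit(aldosterone = 200, renin_activity = 0.2, potassium = 4.0)
  expect_equal(classify_biochemical(base, part)$level, "partial")
  # small fall, suppressed renin: absent
  none <- visit(aldosterone = 720, renin_activity = 0.2, potassium = 4.0)
  expect_equal(classify_biochemical(base, none)$level, "absent")
  # normalized ARR but potassium still requiring supplements: not complete
  onsupp <- visit(aldosterone = 120, renin_activity = 1.2, potassium = 3.8,
                  supp = TRUE)
  expect_equal(classify_biochemical(base, onsupp)$level, "partial")
  # renin mass converted when activity is absent
  mass_only <- visit(aldosterone = 120, renin_activity = NA, potassium = 4.1)
  mass_only$renin_mass <- 12
  expect_equal(classify_biochemical(base, mass_only,
                                    paso_criteria(renin_conversion_factor = 0.1))$level,
               "complete")
  miss <- visit(); miss$aldosterone <- NA; miss$renin_activity <- NA
  expect_false(classify_biochemical(base, miss)$evaluable)
})

test_that("strengthening the follow-up never demotes the outcome", {
  rank3 <- c(absent = 1, partial = 2, complete = 3)
  base <- visit(165, 100, ddd = 4, aldosterone = 1000, renin_activity = 0.1,
                potassium = 3.1)
  set.seed(9)
  for (i in 1:60) {
    fu <- visit(sbp = runif(1, 110, 170), dbp = runif(1, 70, 105),
                ddd = sample(0:4, 1), aldosterone = runif(1, 50, 1200),
                renin_activity = runif(1, 0.05, 2), potassium = runif(1, 3, 4.8))
    lvl <- rank3[[classify_clinical(base, fu)$level]]
    better <- fu
    better$sbp_home <- fu$sbp_home - runif(1, 0, 25)
    better$dbp_home <- fu$dbp_home - runif(1, 0, 12)
    better$ddd <- max(0, fu$ddd - sample(0:2, 1))
    expect_gte(rank3[[classify_clinical(base, better)$level]], lvl)

    blvl <- rank3[[classify_biochemical(base, fu)$level]]
    bb <- fu
    bb$aldosterone <- fu$aldosterone * runif(1, 0.3, 1)
    bb$renin_activity <- fu$renin_activity + runif(1, 0, 1)
    bb$potassium <- min(4.5, fu$potassium + runif(1, 0, 0.8))
    expect_gte(rank3[[classify_biochemical(base, bb)$level]], blvl)
  }
})

test_that("hierarchical endpoints combine the two domains independently", {
  o <- function(level, domain) {
    # build outcomes through the classifiers rather than by hand
    switch(level,
      complete = if (domain == "biochemical")
        classify_biochemical(visit(), visit(aldosterone = 120,
                                            renin_activity = 1.2,
                                            potassium = 4.1))
      else classify_clinical(visit(160, 100, 3), visit(120, 75, 0)),
      partial = if (domain == "biochemical")
        classify_biochemical(visit(aldosterone = 900),
                             visit(aldosterone = 150, renin_activity = 0.1,
                                   potassium = 4))
      else classify_clinical(visit(160, 100, 3), visit(138, 88, 3)),
      absent = if (domain == "biochemical")
        classify_biochemical(visit(aldosterone = 900),
                             visit(aldosterone = 800, renin_activity = 0.1,
                                   potassium = 3.1))
      else classify_clinical(visit(150, 95, 3), visit(149, 94, 3)),
      unevaluable = {
        miss <- visit()
        if (domain == "biochemical") {
          miss$aldosterone <- NA; miss$renin_activity <- NA
          classify_biochemical(visit(), miss)
        } else {
          miss$sbp_home <- NA
          classify_clinical(visit(), miss)
        }
      })
  }
  expect_equal(hierarchical_endpoints(o("complete", "biochemical"),
                                      o("partial", "clinical")),
               c(h1 = TRUE, h2 = TRUE, h3 = TRUE, h4 = FALSE))
  expect_equal(hierarchical_endpoints(o("partial", "biochemical"),
                                      o("absent", "clinical")),
               c(h1 = TRUE, h2 = FALSE, h3 = FALSE, h4 = FALSE))
  expect_equal(hierarchical_endpoints(o("absent", "biochemical"),
                                      o("complete", "clinical")),
               c(h1 = FALSE, h2 = FALSE, h3 = TRUE, h4 = TRUE))
  part <- hierarchical_endpoints(o("unevaluable", "biochemical"),
                                 o("complete", "clinical"))
  expect_true(is.na(part[["h1"]]) && is.na(part[["h2"]]))
  expect_true(part[["h3"]] && part[["h4"]])
  expect_error(hierarchical_endpoints(o("unevaluable", "biochemical"),
                                      o("unevaluable", "clinical")),
               "no endpoint")
})

test_that("hierarchical success rates on the synthetic cohort are ordered", {
  co <- default_cohort_cached()
  op <- co[co$management == "surgery", ]
  f <- vapply(c("h1", "h2", "h4"), function(l) mean(op[[l]], na.rm = TRUE),
              numeric(1))
  expect_gt(f[["h1"]], f[["h2"]])
  expect_gt(f[["h2"]], f[["h4"]])
})
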