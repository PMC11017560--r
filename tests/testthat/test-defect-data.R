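test_that("panel construction validates domain and tracks missingness", {
  p <- defect_panel(region_panel_df())
  expect_equal(dim(p$y), c(4, 3))
  expect_equal(p$labels, c("cervical", "middle", "incisal"))
  expect_false(p$observed[3, 1])
  expect_false(p$observed[4, 3])
  expect_equal(sum(p$observed), 10)

  one <- defect_panel(data.frame(cervical = 0, middle = 0, incisal = 0))
  expect_true(all(one$observed))
  expect_true(all(one$y == 0))

  bad <- region_panel_df()
  bad$middle[2] <- 2
  expect_error(defect_panel(bad), "row 2.*middle|middle.*row 2")
  expect_error(defect_panel(region_panel_df()[, -2]), "cervical")
  expect_error(defect_panel(region_panel_df(), axis_kind = "defects"),
               "missing component")
  expect_error(defect_panel(region_panel_df(), axis_kind = "defects",
                            labels = c("EH", "OP")), "4 component")
})

test_that("panel CSV round-trip preserves values, mask and labels", {
  p <- defect_panel(region_panel_df())
  path <- withr::local_tempfile(fileext = ".csv")
  write_defect_panel(p, path)
  p2 <- read_defect_panel(path)
  expect_equal(p2$y, p$y, ignore_attr = TRUE)
  expect_equal(p2$observed, p$observed, ignore_attr = TRUE)
  expect_equal(p2$labels, p$labels)
  expect_equal(p2$subject_ids, p$subject_ids)
})

test_that("reading rejects out-of-domain outcome cells with location info", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cervical,middle,incisal", "0,1,0", "0,2,NA"), path)
  expect_error(read_defect_panel(path), "'2'.*row 2.*middle")
  writeLines(c("cervical,middle,incisal", "0,,1"), path)
  p <- read_defect_panel(path)
  expect_false(p$observed[1, 2])
  expect_true(all(p$observed[1, c(1, 3)]))
})

test_that("prevalence uses per-component observed denominators", {
  # printed-pair checks: 13/145 and 43/147, plus a zero numerator
  y <- data.frame(
    cervical = c(rep(1, 13), rep(0, 132), rep(NA, 3)),
    middle   = c(rep(0, 148)),
    incisal  = c(rep(1, 43), rep(0, 104), NA)
  )
  prev <- summarize_prevalence(defect_panel(y))
  expect_equal(prev$n_observed, c(145L, 148L, 147L))
  expect_equal(prev$percent[1], 100 * 13 / 145)
  expect_equal(round(prev$percent[1], 2), 8.97)
  expect_equal(round(prev$percent[3], 2), 29.25)
  expect_equal(prev$percent[2], 0)

  # invariant to subject order
  perm <- sample(nrow(y))
  prev2 <- summarize_prevalence(defect_panel(y[perm, ]))
  expect_equal(prev2, prev)

  # a fully masked component is reported as missing
  y$middle <- NA_real_
  prev3 <- summarize_prevalence(defect_panel(y))
  expect_true(is.na(prev3$percent[2]))
})

test_that("drop_unobserved filters by mask", {
  df <- region_panel_df()
  df[2, c("cervical", "middle", "incisal")] <- NA
  p <- defect_panel(df)
  expect_equal(nrow(drop_unobserved(p)$y), 3)
  expect_equal(nrow(drop_unobserved(p, "any_missing")$y), 1)
})

test_that("predictor encoding expands categoricals and validates domains", {
  pt <- predictor_table(small_predictor_df(), small_schema(), race_column = "race")
  expect_equal(colnames(pt$x), c("age", "formula", "vdbp_1f", "vdbp_2"))
  # subject 2 has genotype 1f under reference 1s -> dummies (1, 0)
  expect_equal(unname(pt$x[2, c("vdbp_1f", "vdbp_2")]), c(1, 0))
  expect_equal(unname(pt$x[1, c("vdbp_1f", "vdbp_2")]), c(0, 0))
  # dummy columns sum to at most one for every observed genotype
  expect_true(all(rowSums(pt$x[, c("vdbp_1f", "vdbp_2")]) <= 1))
  expect_equal(levels(pt$race), c("African American", "Caucasian", "Hispanic"))

  bad <- small_predictor_df()
  bad$formula[1] <- 0.5
  expect_error(predictor_table(bad, small_schema()), "binary.*0/1|0/1.*binary")
  bad2 <- small_predictor_df()
  bad2$vdbp[3] <- "zz"
  expect_error(predictor_table(bad2, small_schema()), "zz")
  bad3 <- small_predictor_df()
  bad3$age <- "text"
  expect_error(predictor_table(bad3, small_schema()), "non-numeric")
})

test_that("an all-missing continuous column loads fully masked with a warning", {
  df <- small_predictor_df()
  df$age <- NA_real_
  expect_warning(pt <- predictor_table(df, small_schema()), "entirely missing")
  expect_true(all(!pt$observed[, "age"]))
  expect_true(all(pt$observed[, "formula"]))
})

test_that("predictor CSV reader handles NA tokens and missing race levels", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,formula,vdbp,race",
               "1.5,0,1s,Caucasian",
               ",1,,Hispanic",
               "0.3,NA,2,NA"), path)
  pt <- read_predictor_table(path, small_schema(), race_column = "race")
  expect_false(pt$observed[2, "age"])
  expect_false(pt$observed[2, "vdbp_1f"])
  expect_false(pt$observed[3, "formula"])
  expect_true(is.na(pt$race[3]))
  ms <- missingness_summary(pt)
  expect_equal(ms$n_missing[ms$column == "age"], 1)
})
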