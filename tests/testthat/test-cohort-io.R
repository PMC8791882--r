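test_that("CSV round trip preserves a hand-written cohort", {
  co <- toy_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  expect_equal(nrow(back$patients), 2)
  expect_equal(nrow(back$teeth), 4)
  expect_equal(back$patients, co$patients)
  expect_equal(back$teeth, co$teeth)
  expect_true(is.na(back$patients$pcr[2]))
})

test_that("CSV round trip holds for randomly generated cohorts", {
  for (s in c(3, 11)) {
    co <- generate_cohort(sim_config(n_patients = 15, seed = s))
    f <- withr::local_tempfile(fileext = ".csv")
    write_cohort_csv(co, f)
    back <- read_cohort_csv(f)
    expect_equal(back$patients, co$patients)
    expect_equal(back$teeth, co$teeth)
  }
})

test_that("third-molar rows are rejected with row-indexed diagnostics", {
  co <- toy_cohort()
  dat <- cohort_data(co)[, periotree:::pt_csv_header]
  dat$tooth_id[2] <- "18"
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dat, f, row.names = FALSE, na = "")
  expect_error(read_cohort_csv(f), "row 2.*18")
  expect_warning(back <- read_cohort_csv(f, drop_invalid = TRUE), "row 2")
  expect_equal(nrow(back$teeth), 3)
  expect_equal(back$provenance$dropped_rows$row, 2L)
})

test_that("schema and level violations give informative errors", {
  co <- toy_cohort()
  dat <- cohort_data(co)[, periotree:::pt_csv_header]
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dat[, -which(names(dat) == "jaw")], f, row.names = FALSE, na = "")
  expect_error(read_cohort_csv(f), "missing required column.*jaw")
  dat2 <- dat
  dat2$smoking <- as.character(dat2$smoking)
  dat2$smoking[3] <- "pipe"
  utils::write.csv(dat2, f, row.names = FALSE, na = "")
  expect_error(read_cohort_csv(f), "smoking")
  expect_error(perio_cohort(co$patients, transform(co$teeth, tooth_type = "anterior")),
               "anterior tooth coded multi-rooted")
})

test_that("bone-loss merge maps both severe categories to >60", {
  x <- collapse_bone_loss(c("<=20", "21-40", "41-60", "61-80", ">80"))
  expect_equal(as.character(x), c("<=20", "21-40", "41-60", ">60", ">60"))
  expect_true(is.ordered(x))
  expect_error(collapse_bone_loss("55%"), "invalid bone_loss_raw")
})

test_that("complete-case filter removes exactly the injected missing rows", {
  co <- generate_cohort(sim_config(n_patients = 30, seed = 5))
  n0 <- nrow(co$teeth)
  miss_rows <- c(4, 19, 57, 103)
  teeth <- co$teeth
  teeth$furcation_class[miss_rows] <- NA
  teeth$bone_loss_cat <- NULL
  co2 <- perio_cohort(co$patients, teeth)
  res <- complete_case_filter(co2)
  expect_equal(nrow(res$cohort$teeth), n0 - length(miss_rows))
  kept <- paste(co2$teeth$patient_id, co2$teeth$tooth_id)[-miss_rows]
  expect_setequal(paste(res$cohort$teeth$patient_id, res$cohort$teeth$tooth_id),
                  kept)
  rep_row <- res$report[res$report$variable == "furcation_class", ]
  expect_equal(rep_row$n_teeth_removed, length(miss_rows))

  # idempotence
  res2 <- complete_case_filter(res$cohort)
  expect_equal(res2$cohort$teeth, res$cohort$teeth)
  expect_true(all(res2$report$n_teeth_removed == 0))
})

test_that("complete-case filter is a no-op without missing data and errors on empty result", {
  co <- toy_cohort()
  res <- complete_case_filter(co)
  expect_equal(res$cohort$teeth, co$teeth)
  expect_true(all(res$report$n_teeth_removed == 0))

  teeth <- co$teeth
  teeth$abutment <- NA
  teeth$bone_loss_cat <- NULL
  co2 <- perio_cohort(co$patients, teeth)
  expect_error(complete_case_filter(co2), "removed every tooth")
})

test_that("patients missing a required patient-level covariate drop with all their teeth", {
  co <- toy_cohort()
  co$patients$pcr[2] <- NA
  res <- complete_case_filter(co, required_vars = c("pcr", "jaw"))
  expect_equal(nrow(res$cohort$patients), 1)
  expect_equal(unique(res$cohort$teeth$patient_id), "p1")
  expect_equal(res$report$n_patients_removed[res$report$variable == "pcr"], 1)
})

test_that("descriptive tables reproduce printed jaw loss percentages and the Pearson statistic", {
  co <- make_block_cohort(data.frame(
    jaw = c("maxilla", "mandible"), n = c(1215, 1341), n_lost = c(96, 70)))
  tabs <- descriptive_tables(co)
  jaw <- tabs$teeth[tabs$teeth$variable == "jaw", ]
  expect_equal(jaw$n, c(1215, 1341))
  expect_equal(jaw$pct_lost[jaw$level == "maxilla"], 7.90)
  expect_equal(jaw$pct_lost[jaw$level == "mandible"], 5.22)
  expect_equal(jaw$pct_retained[jaw$level == "maxilla"], 92.10)

  # naive chi-squared equals the textbook Pearson statistic of the 2x2 table
  O <- matrix(c(1119, 96, 1271, 70), nrow = 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  p_hand <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  expect_equal(jaw$p_naive_chisq[1], p_hand, tolerance = 1e-12)

  # percentages within a variable are consistent with counts
  expect_equal(jaw$pct_lost + jaw$pct_retained, c(100, 100))
})

test_that("degenerate single-tooth cohort reports 100/0 percentages", {
  co <- make_block_cohort(data.frame(n = 1, n_lost = 0), teeth_per_patient = 1)
  tabs <- descriptive_tables(co)
  jaw <- tabs$teeth[tabs$teeth$variable == "jaw", ]
  expect_equal(jaw$pct_retained, 100)
  expect_equal(jaw$pct_lost, 0)
  expect_equal(tabs$patients$n[tabs$patients$variable == "n_patients"], 1)
})

test_that("annual loss rate matches printed arithmetic", {
  expect_equal(round(annual_loss_rate(make_rate_cohort(110, 166), years = 10), 2),
               0.15)
  expect_equal(annual_loss_rate(make_rate_cohort(110, 0), years = 10), 0)
  expect_equal(annual_loss_rate(make_rate_cohort(110, 55), years = 5), 0.10)
  expect_error(annual_loss_rate(make_rate_cohort(10, 1), years = 0), "years")
})
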