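test_that("fold error is symmetric, scale invariant, and >= 1", {
  expect_identical(fold_error(9, 3), 3)
  expect_identical(fold_error(3, 9), 3)
  expect_identical(fold_error(5, 5), 1)
  set.seed(21)
  a <- 10 ^ runif(200, -2, 2)
  b <- 10 ^ runif(200, -2, 2)
  expect_equal(fold_error(a, b), fold_error(b, a))
  expect_equal(fold_error(3.1 * a, 3.1 * b), fold_error(a, b),
               tolerance = 1e-12)
  expect_true(all(fold_error(a, b) >= 1))
  expect_identical(fold_error(a, a), rep(1, length(a)))
  expect_error(fold_error(0, 1), "positive")
  expect_error(fold_error(1, -2), "positive")
})

test_that("pct_within counts the boundary as within and rounds for display only", {
  fe <- c(rep(1.5, 5), rep(10, 25))
  expect_equal(pct_within(fe, 3), 100 * 5 / 30)
  expect_identical(format_pct(pct_within(fe, 3)), 16.7)
  expect_identical(pct_within(rep(1.1, 4), 3), 100)
  expect_identical(pct_within(c(3, 3, 9), 3), 100 * 2 / 3)
  expect_identical(pct_within(rep(10, 3), 3), 0)
  expect_error(pct_within(numeric(0), 3), "empty")
  expect_error(pct_within(c(1, 2), 0.5), ">= 1")
})

test_that("pct_within is monotone in k and matches a naive loop oracle", {
  naive_pct <- function(fe, k) {
    hits <- 0L
    for (f in fe) if (f <= k) hits <- hits + 1L
    100 * hits / length(fe)
  }
  set.seed(7)
  for (i in 1:50) {
    fe <- 10 ^ abs(rnorm(sample(3:40, 1), 0, 0.6))
    ks <- sort(c(1, runif(5, 1, 10)))
    pcts <- vapply(ks, function(k) pct_within(fe, k), numeric(1))
    expect_true(all(diff(pcts) >= 0))
    for (k in ks) expect_identical(pct_within(fe, k), naive_pct(fe, k))
  }
})

test_that("evaluate_records composes Day-1 normalization, prediction and fold error", {
  recs <- make_records(
    make_record("exact", nonclin_dose_value = 37, clin_dose_low = 3),
    make_record("nine", nonclin_dose_value = 10, clin_dose_low = 0.09),
    make_record("twice", nonclin_dose_value = 5, nonclin_n_admin_day1 = 2,
                clin_dose_low = 10 * 3 / 37)
  )
  rows <- evaluate_records(recs, method = "bsa")
  expect_identical(rows$fold_error[rows$drug_name == "exact"], 1)
  expect_true(rows$within_2x[rows$drug_name == "exact"])
  expect_equal(rows$fold_error[rows$drug_name == "nine"],
               (10 * 3 / 37) / 0.09)
  expect_false(rows$within_3x[rows$drug_name == "nine"])
  # two Day-1 administrations of 5 mg/kg behave as a 10 mg/kg total
  expect_identical(rows$fold_error[rows$drug_name == "twice"], 1)

  bw <- evaluate_records(make_record("id", nonclin_dose_value = 2,
                                     clin_dose_low = 2), method = "bw")
  expect_identical(bw$fold_error, 1)
})

test_that("BW fold errors are direct mg/kg comparisons with no factor leakage", {
  set.seed(31)
  n <- 40
  recs <- make_record(sprintf("d%02d", 1:n),
                      nonclin_dose_value = 10 ^ runif(n, -1, 2),
                      clin_dose_low = 10 ^ runif(n, -1, 2))
  rows <- evaluate_records(recs, method = "bw")
  expect_equal(rows$fold_error,
               fold_error(recs$nonclin_dose_value, recs$clin_dose_low))
})

test_that("auto method routes each drug by its molecular weight", {
  recs <- make_records(
    make_record("small", modality_class = "SM_PO", molecular_weight_kda = 0.4,
                nonclin_dose_value = 37, clin_dose_low = 3),
    make_record("big", modality_class = "mAb", molecular_weight_kda = 149,
                nonclin_dose_value = 2, clin_dose_low = 2),
    make_record("bite", modality_class = "bispecific",
                molecular_weight_kda = 54.1,
                nonclin_dose_value = 37, clin_dose_low = 3)
  )
  rows <- evaluate_records(recs, method = "auto")
  expect_identical(rows$method, c("BSA", "BW", "BSA"))
  expect_identical(rows$fold_error, rep(1, 3))
  recs$molecular_weight_kda[1] <- NA
  expect_error(evaluate_records(recs, method = "auto"), "small")
})

test_that("class summaries reproduce per-group percentages and omit empty groups", {
  set.seed(41)
  recs <- rbind(
    make_record(sprintf("iv%02d", 1:9), modality_class = "SM_IV",
                nonclin_dose_value = 37,
                clin_dose_low = 3 / c(rep(1.5, 7), 10, 10)),
    make_record(sprintf("po%02d", 1:3), modality_class = "SM_PO",
                nonclin_dose_value = 37, clin_dose_low = 3 * c(1, 1, 20))
  )
  rows <- rbind(evaluate_records(recs, "bsa"), evaluate_records(recs, "bw"))
  wrn <- character(0)
  smry <- withCallingHandlers(summarize_translation(rows), warning = function(w) {
    wrn <<- c(wrn, conditionMessage(w)); invokeRestart("muffleWarning")
  })
  expect_match(wrn, "no records", all = TRUE)
  iv <- smry[smry$subclass_label == "IV", ]
  expect_identical(iv$n, 9L)
  expect_equal(iv$pct_within_3x_bsa, 100 * 7 / 9)
  expect_identical(format_pct(iv$pct_within_3x_bsa), 77.8)
  # small-molecule groups report no BW columns
  expect_true(is.na(iv$pct_within_2x_bw))
  both <- smry[smry$subclass_label == "IV + PO", ]
  expect_identical(both$n, 12L)
  expect_equal(both$pct_within_3x_bsa,
               pct_within(rows$fold_error[rows$method == "BSA"], 3))
  # empty groups are omitted, not reported as zero
  expect_false("Checkpoint Inhibitor" %in% smry$subclass_label)

  # a group of 3 with no prediction within 3x reports 0
  cp <- make_record(sprintf("cp%d", 1:3), modality_class = "checkpoint",
                    molecular_weight_kda = 146, nonclin_dose_value = 37,
                    clin_dose_low = 100)
  cp_rows <- rbind(evaluate_records(cp, "bsa"), evaluate_records(cp, "bw"))
  cp_smry <- suppressWarnings(summarize_translation(cp_rows))
  expect_identical(
    cp_smry$pct_within_3x_bsa[cp_smry$subclass_label == "Checkpoint Inhibitor"], 0)
})

test_that("single all-inclusive group equals pct_within on the whole set", {
  set.seed(51)
  recs <- make_record(sprintf("d%02d", 1:20),
                      nonclin_dose_value = 10 ^ runif(20, 0, 2),
                      clin_dose_low = 10 ^ runif(20, -1, 1))
  rows <- evaluate_records(recs, "bsa")
  g <- list(list(class_label = "All", subclass_label = "all",
                 classes = "SM_PO", methods = "BSA"))
  smry <- summarize_translation(rows, g)
  expect_equal(smry$pct_within_2x_bsa, pct_within(rows, 2))
  expect_equal(smry$pct_within_3x_bsa, pct_within(rows, 3))
})

test_that("bootstrap interval is seeded, degenerate at the extremes, and covers the point", {
  expect_identical(unname(bootstrap_ci(rep(1.2, 10), 3, seed = 5)), c(100, 100))
  expect_identical(unname(bootstrap_ci(rep(9, 10), 3, seed = 5)), c(0, 0))
  set.seed(61)
  fe <- 10 ^ abs(rnorm(30, 0, 0.5))
  ci <- bootstrap_ci(fe, 3, n_boot = 500, seed = 9)
  expect_identical(ci, bootstrap_ci(fe, 3, n_boot = 500, seed = 9))
  p <- pct_within(fe, 3)
  expect_true(ci["low"] <= p && p <= ci["high"])
  expect_error(bootstrap_ci(fe, 3, n_boot = 50), ">= 100")
})

test_that("scatter export conserves rows and excludes unplottable doses", {
  recs <- make_record(sprintf("d%d", 1:6), nonclin_dose_value = 1:6,
                      clin_dose_low = c(1, 1, 2, 2, 3, 3) / 10)
  rows <- evaluate_records(recs, "bsa")
  csv <- withr::local_tempfile(fileext = ".csv")
  out <- export_scatter(rows, csv)
  expect_identical(nrow(out), nrow(rows))
  expect_identical(nrow(utils::read.csv(csv)), nrow(rows))

  rows_bad <- rows
  rows_bad$predicted_dose[1] <- -1
  expect_warning(out2 <- export_scatter(rows_bad, csv), "excluded")
  expect_identical(nrow(out2), nrow(rows) - 1L)
  rows_none <- rows
  rows_none$clinical_dose <- 0
  expect_error(suppressWarnings(export_scatter(rows_none, csv)), "no plottable")
})
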