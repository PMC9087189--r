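test_that("BSA conversions apply the species factors", {
  expect_identical(mgkg_to_mgm2(1, "mouse"), 3)
  expect_identical(mgkg_to_mgm2(0, "mouse"), 0)
  expect_identical(mgm2_to_mgkg(37, "human"), 1)
  expect_identical(mgm2_to_mgkg(0, "human"), 0)
  expect_identical(mgm2_to_mgkg(111, "human"), 3)
  expect_identical(bsa_predict_human_dose(37), 3)
  expect_equal(bsa_predict_human_dose(10), 10 * 3 / 37)
  expect_identical(bw_predict_human_dose(2), 2)
  expect_identical(bw_predict_human_dose(7.5), 7.5)
})

test_that("negative doses and unknown species are rejected", {
  expect_error(mgkg_to_mgm2(-1, "mouse"), ">= 0")
  expect_error(bsa_predict_human_dose(-0.1), ">= 0")
  expect_error(bw_predict_human_dose(-2), ">= 0")
  expect_error(mgkg_to_mgm2(1, "dog"), "unknown species")
  expect_error(normalize_to_mgkg(1, "mg", "dog"), "unknown species")
})

test_that("user species extend but never override the built-ins", {
  expect_setequal(intersect(list_species(), c("mouse", "human")),
                  c("mouse", "human"))
  register_species("testrat", bsa_factor = 6, default_body_weight_kg = 0.15,
                   overwrite = TRUE)
  expect_identical(mgkg_to_mgm2(2, "testrat"), 12)
  expect_error(register_species("mouse", 4, 0.03), "built-in")
  expect_error(register_species("HUMAN", 40, 60), "built-in")
  expect_identical(species_profile("mouse")$bsa_factor, 3)
})

test_that("species profiles load from config files without shadowing built-ins", {
  cfg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_name,bsa_factor,default_body_weight_kg",
               "minipig,27,20"), cfg)
  load_species_profiles(cfg)
  expect_identical(species_profile("minipig")$bsa_factor, 27)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_name,bsa_factor,default_body_weight_kg",
               "human,40,60"), bad)
  expect_error(load_species_profiles(bad), "built-in")
})

test_that("normalization to mg/kg honours unit basis and species defaults", {
  expect_identical(normalize_to_mgkg(140, "mg", "human"), 2)
  expect_identical(normalize_to_mgkg(0.5, "mg", "mouse"), 20)
  expect_identical(normalize_to_mgkg(74, "mg_per_m2", "human"), 2)
  expect_identical(normalize_to_mgkg(5, "mg_per_kg", "mouse"), 5)
  # vectorized with per-element units
  expect_equal(normalize_to_mgkg(c(140, 74), c("mg", "mg_per_m2"), "human"),
               c(2, 2))
  expect_error(normalize_to_mgkg(1, "g", "mouse"), "unknown dose unit")
})

test_that("Day-1 totals sum the first-24-h administrations only", {
  expect_identical(day1_total(dose_spec(5, administrations_day1 = c(5, 5))), 10)
  # once every 4 days: still a single Day-1 administration
  expect_identical(day1_total(dose_spec(10)), 10)
  expect_identical(day1_total(dose_spec(3, administrations_day1 = 3)), 3)
  # administrations in mixed-normalizable units
  expect_identical(
    day1_total(dose_spec(0.25, unit = "mg", species = "mouse",
                         administrations_day1 = c(0.25, 0.25))), 20)
  expect_error(dose_spec(5, administrations_day1 = numeric(0)), "non-empty")
  expect_error(dose_spec(-1), ">= 0")
})

test_that("method selection is a step function with its change at 100 kDa", {
  expect_identical(select_method(54.1), "BSA")
  expect_identical(select_method(150), "BW")
  expect_identical(select_method(100), "BSA")
  expect_identical(select_method(100 + 1e-9), "BW")
  mw <- sort(10 ^ runif(200, -1, 3))
  sel <- select_method(mw)
  expect_identical(sel, ifelse(mw > 100, "BW", "BSA"))
  # single change point: once BW, always BW as MW grows
  expect_true(!is.unsorted(match(sel, c("BSA", "BW"))))
  expect_error(select_method(0), "> 0")
  expect_error(select_method(-5), "> 0")
})

test_that("starting-dose helper divides the HED by the safety factor", {
  expect_identical(mrsd_from_hed(3, 10), 0.3)
  expect_identical(mrsd_from_hed(0, 10), 0)
  expect_identical(mrsd_from_hed(5, 1), 5)
  expect_error(mrsd_from_hed(3, 0.5), ">= 1")
})

test_that("conversion identities hold across doses and species", {
  set.seed(11)
  doses <- c(0, 10 ^ runif(50, -3, 3))
  for (sp in c("mouse", "human")) {
    expect_equal(mgm2_to_mgkg(mgkg_to_mgm2(doses, sp), sp), doses,
                 tolerance = 1e-12)
  }
  # composition: the one-shot predictor is the two-step chain, bit for bit
  expect_identical(bsa_predict_human_dose(doses),
                   mgm2_to_mgkg(mgkg_to_mgm2(doses, "mouse"), "human"))
  # degree-1 homogeneity
  c0 <- 2.7
  expect_equal(bsa_predict_human_dose(c0 * doses),
               c0 * bsa_predict_human_dose(doses), tolerance = 1e-12)
  expect_equal(mgkg_to_mgm2(c0 * doses, "mouse"),
               c0 * mgkg_to_mgm2(doses, "mouse"), tolerance = 1e-12)
})
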