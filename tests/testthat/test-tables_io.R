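test_that("registry validation enforces uniqueness, class labels and flag consistency", {
  reg <- make_registry(c("bap", "npx"), c("PAHs", "detergent metabolites"),
                       is_pah16 = c(TRUE, FALSE))
  expect_silent(validate_registry(reg))

  dup <- rbind(reg, reg[1, ])
  expect_error(validate_registry(dup), "duplicate chemical_id")

  bad_class <- make_registry("x", "not a class")
  expect_error(validate_registry(bad_class), "unknown chem_class")

  # a 16-PAH member outside the PAH class is inconsistent
  ok <- make_registry("bap", "PAHs", is_pah16 = TRUE)
  expect_silent(validate_registry(ok))
  bad <- make_registry("fuel1", "fuels", is_pah16 = TRUE)
  expect_error(validate_registry(bad), "is_pah16")

  expect_error(validate_registry(make_registry("x", "fuels", koc = -1)),
               "non-positive koc")
  expect_error(validate_registry(make_registry("x", "fuels", tef = 1.5)),
               "tef")
})

test_that("registry round-trips through CSV with missing constants kept missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "chemical_id,name,chem_class,koc_L_kg,mw_g_mol,reporting_limit_ug_kg,tef,fcv_ug_gOC,is_pah16,is_esb_pah,is_alkylphenol",
    "benzo_a_pyrene,benzo[a]pyrene,PAHs,968774,252.3,5,,965,TRUE,TRUE,FALSE",
    "nonylphenol,4-nonylphenol,detergent metabolites,10471,220.4,10,1.0,,FALSE,FALSE,TRUE"),
    f)
  reg <- read_registry(f)
  expect_equal(nrow(reg), 2)
  expect_true(is.na(reg$tef[1]))   # missing stays missing, never zero
  expect_true(is.na(reg$fcv[2]))
  expect_equal(reg$koc, c(968774, 10471))

  # duplicated key is a hard error
  writeLines(c(
    "chemical_id,name,chem_class,koc_L_kg,mw_g_mol,reporting_limit_ug_kg,tef,fcv_ug_gOC,is_pah16,is_esb_pah,is_alkylphenol",
    "benzo_a_pyrene,a,PAHs,1,1,1,,,FALSE,FALSE,FALSE",
    "benzo_a_pyrene,b,PAHs,1,1,1,,,FALSE,FALSE,FALSE"), f)
  expect_error(read_registry(f), "duplicate chemical_id")

  # non-numeric constant is a hard error naming the row
  writeLines(c(
    "chemical_id,name,chem_class,koc_L_kg,mw_g_mol,reporting_limit_ug_kg,tef,fcv_ug_gOC,is_pah16,is_esb_pah,is_alkylphenol",
    "x,a,PAHs,abc,1,1,,,FALSE,FALSE,FALSE"), f)
  expect_error(read_registry(f), "non-numeric koc.*x")
})

test_that("non-detects are stored as censored zeros and detects pass through", {
  reg <- make_registry("naph", "PAHs", reporting_limit = 5)
  raw <- data.frame(site_id = c("A", "B", "C"), chemical_id = "naph",
                    c_sed = c("12.0", "<5", "0"), stringsAsFactors = FALSE)
  m <- normalize_measurements(raw, reg)
  expect_equal(m$c_sed, c(12, 0, 0))
  expect_equal(m$censored, c(FALSE, TRUE, FALSE))

  # idempotent: normalizing an already-normal table changes nothing
  expect_equal(normalize_measurements(m, reg), m)

  expect_error(normalize_measurements(
    data.frame(site_id = "A", chemical_id = "naph", c_sed = -3), reg),
    "negative")
  expect_error(normalize_measurements(
    data.frame(site_id = "A", chemical_id = "unknown", c_sed = 1), reg),
    "unregistered")
})

test_that("detection frequency counts absent site-chemical pairs as non-detections", {
  reg <- make_registry(c("a", "b", "c"), "fuels")
  m <- make_measurements(
    site_id = c(sprintf("S%02d", 1:66), "S67", "S68"),
    chemical_id = c(rep("a", 66), "b", "c"),
    c_sed = c(rep(10, 66), 5, 0),
    censored = c(rep(FALSE, 67), TRUE))
  df <- detection_frequency(m, 71)
  expect_equal(round(df$detection_frequency[df$chemical_id == "a"], 2), 0.93)
  expect_equal(df$detection_frequency[df$chemical_id == "b"], 1 / 71)
  expect_equal(df$detection_frequency[df$chemical_id == "c"], 0)
  expect_error(detection_frequency(m, 0), "n_sites")

  # row order never matters
  perm <- m[sample.int(nrow(m)), ]
  expect_equal(detection_frequency(perm, 71), df)
})

test_that("relative percent difference matches the duplicate-QC formula", {
  expect_equal(relative_percent_difference(100, 100), 0)
  expect_equal(relative_percent_difference(100, 50), 200 / 3)
  expect_equal(relative_percent_difference(0, 10), 200)
  expect_warning(out <- relative_percent_difference(0, 0), "undefined")
  expect_true(is.na(out))
  expect_error(relative_percent_difference(-1, 5), "non-negative")
})

test_that("class totals partition the site total", {
  reg <- make_registry(c("a", "b", "c"), c("fuels", "fuels", "PAHs"))
  m <- make_measurements(rep("S1", 3), c("a", "b", "c"), c(1, 2, 4))
  tot <- class_concentration_totals(m, reg)
  expect_equal(sort(tot$by_class$class_total), c(3, 4))
  expect_equal(tot$by_site$site_total, 7)

  # censored contributes zero
  reg2 <- make_registry(c("p1", "p2", "p3"), "PAHs")
  m2 <- make_measurements(rep("S1", 3), c("p1", "p2", "p3"),
                          c(100, 200, 0), censored = c(FALSE, FALSE, TRUE))
  expect_equal(class_concentration_totals(m2, reg2)$by_class$class_total, 300)

  # random fixture: partition property
  set.seed(41)
  reg3 <- make_registry(sprintf("c%02d", 1:20),
                        sample(chem_classes(), 20, replace = TRUE))
  m3 <- make_measurements(rep(sprintf("T%d", 1:5), each = 20),
                          rep(reg3$chemical_id, 5),
                          runif(100, 0, 100))
  tot3 <- class_concentration_totals(m3, reg3)
  per_site <- tapply(tot3$by_class$class_total, tot3$by_class$site_id, sum)
  expect_equal(as.numeric(per_site[tot3$by_site$site_id]),
               tot3$by_site$site_total)
})
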