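test_that("ACC unit conversion follows dimensional analysis", {
  expect_equal(acc_to_ug_per_L(1, "micromolar", 228.29), 228.29)
  expect_equal(acc_to_ug_per_L(0.5, "micromolar", 100), 50)
  expect_equal(acc_to_ug_per_L(7, "ug_L", 100), 7) # already µg/L: identity
  expect_error(acc_to_ug_per_L(0, "micromolar", 100), "positive")
})

test_that("micromolar rows without molecular weight are dropped with a warning", {
  reg <- make_registry(c("a", "b"), "fuels", mw = c(100, NA))
  acc <- make_acc(c("a", "b"), c("E1", "E1"), c(2, 2), acc_unit = "micromolar")
  expect_warning(out <- prepare_acc(acc, reg), "no molecular weight")
  expect_equal(out$chemical_id, "a")
  expect_equal(out$acc_ugL, 200)
})

test_that("EARs divide porewater by ACC and respect exclusions and statuses", {
  reg <- make_registry(c("a", "b"), "fuels", koc = c(1000, NA), mw = 100)
  sites <- make_sites(c("S1", "S2"), toc_percent = c(2, 5))
  m <- make_measurements(rep(c("S1", "S2"), each = 2), rep(c("a", "b"), 2),
                         c(20, 50, 100, 10))
  pw <- porewater_table(m, reg, sites)
  acc <- make_acc(c("a", "a", "b"), c("E1", "E2", "E1"), c(1, 0.5, 1),
                  excluded = c(FALSE, TRUE, FALSE))
  ear <- compute_ear(pw, acc, reg)

  # excluded endpoint contributes nothing anywhere
  expect_false("E2" %in% ear$endpoint_id)
  # chemical without partition coefficient is absent
  expect_false("b" %in% ear$chemical_id)
  # oracle: elementwise division
  expect_equal(ear$ear[ear$site_id == "S1"], 20 / (1000 * 0.02) / 1)
  expect_equal(ear$ear[ear$site_id == "S2"], 100 / (1000 * 0.05) / 1)

  # removing the excluded row changes no output (exclusion completeness)
  ear2 <- compute_ear(pw, acc[!acc$excluded, ], reg)
  expect_equal(ear, ear2)

  # unit EAR at matched concentrations
  pw1 <- data.frame(site_id = "S", chemical_id = "a", c_pw = 1, status = "ok")
  expect_equal(compute_ear(pw1, make_acc("a", "E1", 1), reg)$ear, 1.0)
})

test_that("EAR aggregates: max over endpoints, additive classes and endpoints", {
  reg <- make_registry(c("a", "b"), c("fuels", "PAHs"))
  ear <- data.frame(site_id = "S1",
                    chemical_id = c("a", "a", "b"),
                    endpoint_id = c("E1", "E2", "E1"),
                    ear = c(0.2, 0.5, 0.3), stringsAsFactors = FALSE)
  agg <- aggregate_ear(ear, reg)
  expect_equal(agg$ear_max$ear_max, c(0.5, 0.3))
  expect_equal(agg$by_sample$ear_sample, 0.8)
  expect_equal(agg$by_endpoint$ear_endpoint[agg$by_endpoint$endpoint_id == "E1"],
               0.5)

  # ear_max never exceeds the chemical's endpoint sum
  sums <- tapply(ear$ear, paste(ear$site_id, ear$chemical_id), sum)
  mx <- tapply(ear$ear, paste(ear$site_id, ear$chemical_id), max)
  expect_true(all(mx <= sums + 1e-15))
})

test_that("EAR_Sample equals the class sum on random fixtures", {
  set.seed(23)
  reg <- make_registry(sprintf("c%02d", 1:15),
                       sample(chem_classes(), 15, replace = TRUE))
  for (i in 1:20) {
    n <- sample(20:60, 1)
    ear <- data.frame(
      site_id = sample(sprintf("S%d", 1:5), n, replace = TRUE),
      chemical_id = sample(reg$chemical_id, n, replace = TRUE),
      endpoint_id = sample(sprintf("E%d", 1:6), n, replace = TRUE),
      ear = rlnorm(n, -3), stringsAsFactors = FALSE)
    ear <- ear[!duplicated(ear[c("site_id", "chemical_id", "endpoint_id")]), ]
    agg <- aggregate_ear(ear, reg)
    cls <- tapply(agg$by_class$ear_class, agg$by_class$site_id, sum)
    expect_equal(as.numeric(cls[agg$by_sample$site_id]),
                 agg$by_sample$ear_sample, tolerance = 1e-12)
  }
})

test_that("chemical flagging is strict at the screening threshold", {
  em <- data.frame(site_id = c("S1", "S1", "S1"),
                   chemical_id = c("a", "b", "c"),
                   ear_max = c(0.001, 0.0011, 0.0001),
                   stringsAsFactors = FALSE)
  fl <- flag_chemicals(em, 0.001)
  expect_equal(fl$per_chemical$chemical_id, "b")
  expect_equal(fl$per_site$n_chemicals, 1L)
})

test_that("prevalence rule yields 14 required sites for a 71-site study", {
  ear <- data.frame(site_id = "S1", chemical_id = "a", endpoint_id = "E1",
                    ear = 1, stringsAsFactors = FALSE)
  pe <- priority_endpoints(ear, n_sites = 71)
  expect_equal(pe$required_sites, 14L)
  # an endpoint exceeding at 13 of 71 sites is not retained
  ear13 <- data.frame(site_id = sprintf("S%02d", 1:13), chemical_id = "a",
                      endpoint_id = "E1", ear = 0.2, stringsAsFactors = FALSE)
  expect_equal(nrow(priority_endpoints(ear13, 71)$endpoints), 0)
  ear14 <- rbind(ear13, data.frame(site_id = "S14", chemical_id = "a",
                                   endpoint_id = "E1", ear = 0.2))
  expect_equal(nrow(priority_endpoints(ear14, 71)$endpoints), 1)
})

test_that("priority endpoint selection matches brute-force enumeration on small fixtures", {
  set.seed(31)
  for (i in 1:10) {
    n_s <- sample(2:6, 1); n_e <- sample(2:5, 1); n_c <- sample(2:5, 1)
    grid <- expand.grid(site_id = sprintf("S%d", 1:n_s),
                        chemical_id = sprintf("c%d", 1:n_c),
                        endpoint_id = sprintf("E%d", 1:n_e),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- runif(nrow(grid)) < 0.7
    ear <- grid[keep, ]
    ear$ear <- 10^runif(nrow(ear), -4, 0.5)
    got <- priority_endpoints(ear, n_s, prevalence = 0.4)
    want <- brute_priority_endpoints(ear, n_s, prevalence = 0.4)
    expect_setequal(got$endpoints$endpoint_id, want$endpoints$endpoint_id)
    expect_equal(got$endpoints$n_sites_exceeding[
      order(got$endpoints$endpoint_id)],
      want$endpoints$n_sites_exceeding[order(want$endpoints$endpoint_id)])
    if (!is.null(want$members)) {
      key_got <- with(got$members, paste(endpoint_id, site_id, chemical_id))
      key_want <- with(want$members, paste(endpoint_id, site_id, chemical_id))
      expect_setequal(key_got, key_want)
    } else expect_equal(nrow(got$members), 0)
    if (!is.null(want$major_contributors)) {
      expect_setequal(
        with(got$major_contributors, paste(endpoint_id, chemical_id, n_sites)),
        with(want$major_contributors, paste(endpoint_id, chemical_id, n_sites)))
    } else expect_equal(nrow(got$major_contributors), 0)
  }
})

test_that("annotation is a left join that never drops endpoints", {
  ear <- data.frame(site_id = sprintf("S%d", 1:5),
                    chemical_id = "a", endpoint_id = "E1", ear = 0.5,
                    stringsAsFactors = FALSE)
  pe <- priority_endpoints(ear, 5, prevalence = 0.2)
  expect_equal(nrow(pe$endpoints), 1)

  map <- data.frame(endpoint_id = c("E1", "E1", "EX"),
                    gene_symbol = c("ESR1", "ESR2", "AHR"),
                    aop_ids = c("AOP:29", "AOP:30", "AOP:21"),
                    annotation = "x", stringsAsFactors = FALSE)
  ann <- annotate_endpoints(pe, map)
  expect_equal(nrow(ann$endpoints), nrow(pe$endpoints)) # cardinality preserved
  expect_equal(ann$endpoints$gene_symbol, "ESR1;ESR2")
  expect_equal(ann$endpoints$aop_ids, "AOP:29;AOP:30")

  # unmapped endpoint: kept, empty annotation
  ann2 <- annotate_endpoints(pe, map[map$endpoint_id == "EX", ])
  expect_equal(nrow(ann2$endpoints), 1)
  expect_equal(ann2$endpoints$aop_ids, "")
})
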