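test_that("chemical priority follows the exceedance-frequency rules", {
  n_sites <- 20
  reg <- make_registry(c("p1", "low1", "unc1", "nobm", "undet"), "fuels")
  m <- make_measurements(
    rep(sprintf("S%02d", 1:n_sites), 5),
    rep(c("p1", "low1", "unc1", "nobm", "undet"), each = n_sites),
    c(rep(100, n_sites), rep(1, n_sites), rep(1, n_sites), rep(1, n_sites),
      rep(0, n_sites)),
    censored = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), each = n_sites))

  # p1: sediment TQ_Max > 10 at 6 of 20 sites (30% > 20%)
  # unc1: TQ_Max > 0.1 at 2 of 20 sites (10%, in the 1-20% band)
  tqmax <- rbind(
    data.frame(site_id = sprintf("S%02d", 1:20), chemical_id = "p1",
               medium = "sediment",
               tq_max = c(rep(11, 6), rep(0.05, 14)),
               benchmark_used = 1, censored = FALSE),
    data.frame(site_id = sprintf("S%02d", 1:20), chemical_id = "low1",
               medium = "sediment", tq_max = rep(0.01, 20),
               benchmark_used = 1, censored = FALSE),
    data.frame(site_id = sprintf("S%02d", 1:20), chemical_id = "unc1",
               medium = "sediment",
               tq_max = c(rep(0.2, 2), rep(0.01, 18)),
               benchmark_used = 1, censored = FALSE))
  ear_max <- data.frame(site_id = character(), chemical_id = character(),
                        ear_max = numeric())
  cp <- chemical_priority(tqmax, ear_max, m, reg, n_sites)
  lv <- setNames(cp$level, cp$chemical_id)
  expect_equal(unname(lv["p1"]), "P1")
  expect_equal(unname(lv["low1"]), "low")
  expect_equal(unname(lv["unc1"]), "uncategorized")
  expect_equal(unname(lv["nobm"]), "no_benchmarks") # detected, unscreenable
  expect_equal(unname(lv["undet"]), "low")          # never detected
})

test_that("intermediate priority rungs follow the geometric ladder", {
  n_sites <- 10
  reg <- make_registry(c("p2", "p3"), "fuels")
  m <- make_measurements(rep(sprintf("S%02d", 1:n_sites), 2),
                         rep(c("p2", "p3"), each = n_sites), 10)
  tqmax <- rbind(
    data.frame(site_id = sprintf("S%02d", 1:10), chemical_id = "p2",
               medium = "sediment", tq_max = rep(2, 10),
               benchmark_used = 1, censored = FALSE),
    data.frame(site_id = sprintf("S%02d", 1:10), chemical_id = "p3",
               medium = "sediment", tq_max = rep(0.2, 10),
               benchmark_used = 1, censored = FALSE))
  em <- data.frame(site_id = character(), chemical_id = character(),
                   ear_max = numeric())
  cp <- chemical_priority(tqmax, em, m, reg, n_sites)
  expect_equal(cp$level[cp$chemical_id == "p2"], "P2")
  expect_equal(cp$level[cp$chemical_id == "p3"], "P3")
})

test_that("priority classification survives the removal of all bioactivity data", {
  n_sites <- 5
  reg <- make_registry("a", "fuels")
  m <- make_measurements(sprintf("S%d", 1:5), "a", 10)
  em <- data.frame(site_id = character(), chemical_id = character(),
                   ear_max = numeric())
  tq0 <- data.frame(site_id = character(), chemical_id = character(),
                    medium = character(), tq_max = numeric(),
                    benchmark_used = numeric(), censored = logical())
  cp <- chemical_priority(tq0, em, m, reg, n_sites)
  expect_equal(cp$level, "no_benchmarks")
})

test_that("site method levels reproduce every printed bin boundary", {
  # count-based methods: 0 | 1-9 | 10-19 | >=20
  for (method in c("sediment_tq_max_count", "porewater_tq_max_count",
                   "ear_max_count")) {
    expect_equal(site_method_level(method, 0), 4L)
    expect_equal(site_method_level(method, 1), 3L)
    expect_equal(site_method_level(method, 9), 3L)
    expect_equal(site_method_level(method, 10), 2L)
    expect_equal(site_method_level(method, 19), 2L)
    expect_equal(site_method_level(method, 20), 1L)
    expect_equal(site_method_level(method, 22), 1L)
  }
  # summed-quotient methods: 1-9 | 10-99 | 100-999 | 1000-10000, clamped
  for (method in c("sediment_tq_sample", "porewater_tq_sample")) {
    expect_equal(site_method_level(method, 0.5), 4L)  # clamp below
    expect_equal(site_method_level(method, 1), 4L)
    expect_equal(site_method_level(method, 9.9), 4L)
    expect_equal(site_method_level(method, 10), 3L)
    expect_equal(site_method_level(method, 99), 3L)
    expect_equal(site_method_level(method, 100), 2L)
    expect_equal(site_method_level(method, 999), 2L)
    expect_equal(site_method_level(method, 1000), 1L)
    expect_equal(site_method_level(method, 20000), 1L) # clamp above
  }
  # EAR sample: <0.1 | 0.1-0.99 | 1.0-9.9 | >=10
  expect_equal(site_method_level("ear_sample", 0.05), 4L)
  expect_equal(site_method_level("ear_sample", 0.1), 3L)
  expect_equal(site_method_level("ear_sample", 0.5), 3L)
  expect_equal(site_method_level("ear_sample", 1.0), 2L)
  expect_equal(site_method_level("ear_sample", 9.9), 2L)
  expect_equal(site_method_level("ear_sample", 10), 1L)
  # alkylphenol: 0 | 0.01-0.99 | 1.0-9.9 | >=10, with (0, 0.01) clamped to 3
  expect_equal(site_method_level("alkylphenol_mixture", 0), 4L)
  expect_equal(site_method_level("alkylphenol_mixture", 0.005), 3L)
  expect_equal(site_method_level("alkylphenol_mixture", 0.01), 3L)
  expect_equal(site_method_level("alkylphenol_mixture", 0.99), 3L)
  expect_equal(site_method_level("alkylphenol_mixture", 1.0), 2L)
  expect_equal(site_method_level("alkylphenol_mixture", 10), 1L)
  # PAH: none | TEC | PEC or toxic-unit sum | both
  expect_equal(site_method_level("pah_mixture", c(FALSE, FALSE, FALSE)), 4L)
  expect_equal(site_method_level("pah_mixture", c(TRUE, FALSE, FALSE)), 3L)
  expect_equal(site_method_level("pah_mixture", c(TRUE, TRUE, FALSE)), 2L)
  expect_equal(site_method_level("pah_mixture", c(TRUE, FALSE, TRUE)), 2L)
  expect_equal(site_method_level("pah_mixture", c(TRUE, TRUE, TRUE)), 1L)

  expect_error(site_method_level("not_a_method", 1), "unknown")
})

test_that("site method levels are monotone: larger burdens never lessen severity", {
  for (method in c("sediment_tq_max_count", "sediment_tq_sample", "ear_sample",
                   "alkylphenol_mixture")) {
    vals <- sort(c(0, 10^seq(-3, 5, length.out = 40)))
    lv <- vapply(vals, function(v) site_method_level(method, v), integer(1))
    expect_true(all(diff(lv) <= 0), info = method)
  }
})

test_that("overall score averages available methods and stays within bounds", {
  expect_equal(overall_score(rep(1, 8))$score, 1.0)
  expect_equal(overall_score(c(1, 1, 1, 2, 2, 3, 4, 4))$score, 2.25)
  r <- overall_score(c(NA, rep(4, 7)))
  expect_equal(r$score, 4.0)
  expect_equal(r$n_methods_available, 7)
  expect_error(overall_score(rep(NA_real_, 8)), "no methods")

  # permutation invariance and bounds
  set.seed(29)
  for (i in 1:20) {
    lv <- sample(1:4, 8, replace = TRUE)
    expect_equal(overall_score(lv)$score, overall_score(sample(lv))$score)
    expect_true(overall_score(lv)$score >= 1 && overall_score(lv)$score <= 4)
  }
})

test_that("site ranking is deterministic with documented tie-breaking", {
  sp <- data.frame(site_id = c("A", "B"), overall_score = c(1.5, 2.0),
                   sediment_tq_sample_value = c(1, 1), stringsAsFactors = FALSE)
  expect_equal(rank_sites(sp)$site_id, c("A", "B"))

  tied <- data.frame(site_id = c("A", "B"), overall_score = 2,
                     sediment_tq_sample_value = c(10, 100),
                     stringsAsFactors = FALSE)
  expect_equal(rank_sites(tied)$site_id, c("B", "A"))

  # permutation invariance over all orderings of 4 rows
  base <- data.frame(site_id = c("A", "B", "C", "D"),
                     overall_score = c(2, 2, 1.5, 3),
                     sediment_tq_sample_value = c(10, 100, 5, 1),
                     stringsAsFactors = FALSE)
  ref <- rank_sites(base)$site_id
  perms <- list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3), c(3, 1, 4, 2))
  for (p in perms) expect_equal(rank_sites(base[p, ])$site_id, ref)
})

test_that("rank correlations match the classical Spearman formula and flag degeneracies", {
  sites <- make_sites(sprintf("S%d", 1:5), toc_percent = 2,
                      pop = c(10, 20, 30, 40, 50))
  inc <- data.frame(site_id = sprintf("S%d", 1:5), m = c(1, 2, 3, 4, 5))
  out <- watershed_correlations(inc, sites)
  expect_equal(out$rho, 1.0)
  dec <- inc; dec$m <- rev(dec$m)
  expect_equal(watershed_correlations(dec, sites)$rho, -1.0)

  # n=5 untied fixture: rho equals 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(3, 1, 4, 2, 5)
  met <- data.frame(site_id = sprintf("S%d", 1:5), m = x)
  d <- rank(x) - rank(sites$pop)
  expect_equal(watershed_correlations(met, sites)$rho,
               1 - 6 * sum(d^2) / (5 * 24))

  # constant attribute: flagged, not an error
  sites2 <- make_sites(sprintf("S%d", 1:5), toc_percent = 2, flat = rep(7, 5))
  out2 <- watershed_correlations(inc, sites2)
  expect_true(is.na(out2$rho))
  expect_equal(out2$note, "constant input")

  # significance is consistent with alpha on raw p-values
  expect_equal(out$significant, out$p_value < 0.05)
})
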