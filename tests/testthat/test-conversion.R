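test_that("the stepwise statistic reproduces hand-evaluated tail sums", {
  tbl <- peak_tbl(c("20:5n-3", "22:5n-3", "24:5n-3"), c(800, 100, 100),
                  substrate = "20:5n-3")
  p <- stepwise_conversions(tbl)
  expect_equal(p$conversion[1:2], c(20.0, 50.0))   # 100*200/1000, 100*100/200
  expect_true(all(is.na(p$conversion[-(1:2)])))

  p2 <- stepwise_conversions(tbl, mode = "cumulative_literal")
  expect_equal(p2$conversion[1:2], c(20.0, 11.1))  # 100*100/(100+800)
})

test_that("undetected products report n.d. and fully dark assays error", {
  tbl <- peak_tbl(c("20:5n-3", "22:5n-3", "24:5n-3"), c(800, 0, 0),
                  substrate = "20:5n-3")
  p <- stepwise_conversions(tbl)
  expect_true(all(is.na(p$conversion)))

  dark <- peak_tbl(c("20:5n-3", "22:5n-3"), c(0, 0), substrate = "20:5n-3")
  expect_error(stepwise_conversions(dark), class = "vlcfa_degenerate_input")
  neg <- peak_tbl(c("20:5n-3", "22:5n-3"), c(800, -1), substrate = "20:5n-3")
  expect_error(stepwise_conversions(neg), class = "vlcfa_bad_schema")
})

test_that("raising the detection limit censors monotonically", {
  tbl <- peak_tbl(c("20:5n-3", "22:5n-3", "24:5n-3", "26:5n-3"),
                  c(800, 150, 40, 5), substrate = "20:5n-3")
  nd_at <- function(lod) is.na(stepwise_conversions(tbl, lod = lod)$conversion)
  prev <- nd_at(0)
  for (lod in c(1, 10, 50, 200, 600)) {
    cur <- nd_at(lod)
    expect_true(all(cur[prev]))  # once n.d., always n.d. as lod grows
    prev <- cur
  }
})

test_that("both statistic modes agree with a brute-force tail-sum oracle on random areas", {
  set.seed(101)
  for (rep in 1:50) {
    k_n <- sample(2:8, 1)
    sub_area <- runif(1, 50, 2000)
    prod_areas <- runif(k_n, 0, 500) * rbinom(k_n, 1, 0.8)
    tbl <- peak_tbl(c("20:5n-3", product_series("20:5n-3")[seq_len(k_n)]),
                    c(sub_area, prod_areas), substrate = "20:5n-3")
    for (mode in c("stepwise", "cumulative_literal")) {
      got <- stepwise_conversions(tbl, mode = mode, digits = NULL)
      want <- oracle_conversions(sub_area, prod_areas, mode)
      expect_equal(got$conversion[seq_len(k_n)], want, tolerance = 1e-12)
    }
  }
})

test_that("the stepwise statistic is the identity on cascade efficiencies", {
  # noise-free steady state with per-step efficiencies (0.8, 0.5)
  p <- cascade_params("20:5n-3", c(0.8, 0.5), noise_cv = 0)
  tbl <- simulate_peak_table(p, seed = 1)
  prof <- stepwise_conversions(tbl)
  expect_equal(prof$conversion[1:2], c(80.0, 50.0))
})

test_that("cumulative-literal conversions are non-increasing; stepwise can be non-monotone", {
  set.seed(202)
  for (rep in 1:200) {
    k_n <- sample(2:8, 1)
    tbl <- peak_tbl(c("20:5n-3", product_series("20:5n-3")[seq_len(k_n)]),
                    c(runif(1, 10, 1000), runif(k_n, 0, 400) * rbinom(k_n, 1, 0.7)),
                    substrate = "20:5n-3")
    conv <- stepwise_conversions(tbl, mode = "cumulative_literal", digits = NULL)$conversion
    conv <- conv[!is.na(conv)]
    if (length(conv) > 1) expect_true(all(diff(conv) <= 1e-9))
  }
  # a profile that rises again step over step is representable in stepwise mode
  tbl <- peak_tbl(c("22:6n-3", "24:6n-3", "26:6n-3"), c(10000, 0, 180),
                  substrate = "22:6n-3", detected = c(TRUE, FALSE, TRUE))
  conv <- stepwise_conversions(tbl)$conversion
  expect_lt(conv[1], conv[2])
  expect_equal(conv[2], 100)
})

test_that("efficiency estimation inverts both statistic modes", {
  prof <- as_conversion_profile(
    tibble::tibble(substrate = "20:5n-3",
                   product = product_series("20:5n-3")[1:2],
                   conversion = c(80, 50)))
  expect_equal(estimate_step_efficiencies(prof), c(0.8, 0.5))

  all_nd <- as_conversion_profile(
    tibble::tibble(substrate = "20:5n-3",
                   product = product_series("20:5n-3"),
                   conversion = NA_real_))
  expect_equal(estimate_step_efficiencies(all_nd), rep(0, 8))

  set.seed(303)
  for (rep in 1:50) {
    e <- runif(sample(1:8, 1), 0.05, 0.95)
    p <- cascade_params("20:5n-3", e, noise_cv = 0)
    tbl <- simulate_peak_table(p)
    for (mode in c("stepwise", "cumulative_literal")) {
      prof <- stepwise_conversions(tbl, mode = mode, digits = NULL)
      est <- estimate_step_efficiencies(prof, mode)
      expect_equal(est[seq_along(e)], e, tolerance = 1e-9)
    }
  }
})

test_that("rising cumulative-literal input is rejected as model-inconsistent", {
  prof <- as_conversion_profile(
    tibble::tibble(substrate = "20:5n-3",
                   product = product_series("20:5n-3")[1:3],
                   conversion = c(10, 40, 20)),
    mode = "cumulative_literal")
  expect_error(estimate_step_efficiencies(prof), "24:5n-3",
               class = "vlcfa_inconsistent_profile")
})

test_that("profiles round-trip through reconstructed areas at one decimal", {
  set.seed(404)
  for (rep in 1:30) {
    e <- round(runif(sample(2:8, 1), 0, 1), 3)
    prof <- as_conversion_profile(
      tibble::tibble(substrate = "20:5n-3",
                     product = product_series("20:5n-3")[seq_along(e)],
                     conversion = ifelse(e > 0 | rev(cumsum(rev(e))) > 0,
                                         100 * e, NA_real_)))
    # drop entries after the cascade dies
    alive <- cumprod(e) > 0
    prof$conversion[!alive] <- NA_real_
    areas <- conversions_to_areas(prof)
    back <- stepwise_conversions(areas)
    expect_equal(back$conversion[seq_along(e)], prof$conversion, tolerance = 0.051)
  }
})

test_that("SFA percentages normalize the >= C24 saturated tail to 100", {
  tbl <- peak_tbl(c("24:0", "26:0", "28:0", "30:0", "32:0"),
                  c(10, 60, 20, 8, 2))
  prof <- sfa_percent_profile(tbl)
  expect_equal(prof$percent, c(10, 60, 20, 8, 2, 0))
  expect_equal(prof$fatty_acid,
               c("24:0", "26:0", "28:0", "30:0", "32:0", "34:0"))

  single <- sfa_percent_profile(peak_tbl("26:0", 123))
  expect_equal(single$percent[single$fatty_acid == "26:0"], 100)
  expect_equal(sum(single$percent), 100)

  set.seed(9)
  for (rep in 1:20) {
    n_sp <- sample(1:6, 1)
    fas <- sample(c("24:0", "26:0", "28:0", "30:0", "32:0", "34:0"), n_sp)
    prof <- sfa_percent_profile(peak_tbl(fas, runif(n_sp, 1, 100)))
    expect_lte(abs(sum(prof$percent) - 100), 0.2)
  }
  expect_error(sfa_percent_profile(peak_tbl(c("16:0", "18:0"), c(5, 5))),
               class = "vlcfa_degenerate_input")
})
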