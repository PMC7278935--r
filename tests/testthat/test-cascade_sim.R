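test_that("a dead cascade leaves only substrate and background", {
  p <- cascade_params("22:6n-3", rep(0, 7), noise_cv = 0)
  tbl <- simulate_peak_table(p, seed = 1)
  detected <- tbl$fatty_acid[tbl$detected]
  expect_setequal(detected, c("22:6n-3", names(default_yeast_background())))
})

test_that("noise-free simulation recovers the configured efficiencies exactly", {
  p <- cascade_params("20:5n-3", c(0.8, 0.5), noise_cv = 0)
  tbl <- simulate_peak_table(p, seed = 1)
  prof <- stepwise_conversions(tbl, digits = NULL)
  est <- estimate_step_efficiencies(prof)
  expect_equal(est[1:2], c(0.8, 0.5), tolerance = 1e-12)
})

test_that("replicate means recover efficiencies under lognormal noise", {
  truth <- c(0.3, 0.9, 0.6)
  p <- cascade_params("20:5n-3", truth, noise_cv = 0.1, n_replicates = 3)
  tbl <- simulate_peak_table(p, seed = 2024)
  est <- tbl |>
    dplyr::group_split(sample_id) |>
    purrr::map(~ estimate_step_efficiencies(stepwise_conversions(.x, digits = NULL)))
  est_mean <- colMeans(do.call(rbind, est))[1:3]
  expect_lt(max(abs(est_mean - truth)), 0.05)
})

test_that("supplied concentration defaults follow chain-length compensation", {
  expect_equal(cascade_params("18:4n-3", 0.5)$supplied_concentration, 0.5)
  expect_equal(cascade_params("20:5n-3", 0.5)$supplied_concentration, 0.75)
  expect_equal(cascade_params("22:6n-3", 0.5)$supplied_concentration, 1.0)
  # substrate pool scales linearly with concentration x uptake
  a1 <- simulate_peak_table(cascade_params("20:5n-3", 0, noise_cv = 0), seed = 1)
  a2 <- simulate_peak_table(cascade_params("20:5n-3", 0, noise_cv = 0,
                                           supplied_concentration = 1.5,
                                           substrate_uptake = 0.5),
                            seed = 1)
  pool <- function(x) x$area[x$fatty_acid == "20:5n-3"]
  expect_equal(pool(a2) / pool(a1), 1.5 * 0.5 / 0.75)
})

test_that("identical parameters and seed reproduce identical tables", {
  p <- cascade_params("22:5n-3", c(0.4, 0.7, 0.2), noise_cv = 0.15, n_replicates = 3)
  t1 <- simulate_peak_table(p, seed = 99)
  t2 <- simulate_peak_table(p, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_peak_table(p, seed = 100)
  expect_false(identical(t1$area, t3$area))
})

test_that("raising the detection limit only censors, never reveals", {
  p <- cascade_params("20:5n-3", c(0.5, 0.3, 0.1), noise_cv = 0.1)
  base <- simulate_peak_table(p, seed = 3)
  for (lod in c(10, 1e3, 1e5)) {
    p2 <- cascade_params("20:5n-3", c(0.5, 0.3, 0.1), noise_cv = 0.1, lod = lod)
    cens <- simulate_peak_table(p2, seed = 3)
    expect_identical(cens$area, base$area)
    expect_true(all(cens$detected <= base$detected))
  }
})

test_that("the SFA assay shifts mass up the saturated tail for the construct group", {
  tbl <- simulate_sfa_assay(c(0, 0.6, 0.5, 0.4, 0.3), noise_cv = 0.05, seed = 7)
  profs <- tbl |>
    dplyr::group_split(sample_id) |>
    purrr::map_dfr(function(s) {
      dplyr::mutate(sfa_percent_profile(s), construct = s$construct[1])
    })
  res <- compare_groups(profs, percent, construct, variable = fatty_acid)
  r28 <- res[res$variable == "28:0", ]
  expect_false(r28$letter[r28$group == "control"] ==
                 r28$letter[r28$group == "elovl4a"])
  expect_gt(r28$mean[r28$group == "elovl4a"], r28$mean[r28$group == "control"])
  # a null shift leaves the groups statistically indistinguishable
  null_tbl <- simulate_sfa_assay(rep(0, 5), noise_cv = 0.05, seed = 8)
  null_profs <- null_tbl |>
    dplyr::group_split(sample_id) |>
    purrr::map_dfr(function(s) {
      dplyr::mutate(sfa_percent_profile(s), construct = s$construct[1])
    })
  null_res <- compare_groups(null_profs, percent, construct, variable = fatty_acid)
  expect_true(all(tapply(null_res$letter, null_res$variable,
                         function(l) length(unique(l)) == 1)))
})

test_that("group means of the SFA assay recover configured percentages", {
  shift <- c(0, 0.4, 0.3, 0.2, 0.1)
  cv <- 0.05
  tbl <- simulate_sfa_assay(shift, noise_cv = cv, n_replicates = 3, seed = 12)
  ctrl <- sfa_percent_profile(peak_tbl(
    names(default_yeast_background()), unname(default_yeast_background())))
  got <- tbl |>
    dplyr::filter(construct == "control") |>
    dplyr::group_split(sample_id) |>
    purrr::map_dfr(sfa_percent_profile) |>
    dplyr::group_by(fatty_acid) |>
    dplyr::summarise(percent = mean(percent))
  expect_lt(max(abs(got$percent - ctrl$percent[match(got$fatty_acid, ctrl$fatty_acid)])),
            100 * 2 * cv / sqrt(3))
})

test_that("simulated qPCR obeys the standard-curve law", {
  cp <- tibble::tibble(fish_id = "f1", tissue = "brain", gene = "elovl4a",
                       copies = 1e5)
  sim <- simulate_qpcr(cp, slope = -3.32, intercept = 38, ct_noise_sd = 0, seed = 1)
  expect_equal(round_half_up(sim$samples$ct, 1), 21.4)
  # halving the copies raises Ct by -slope * log10(2)
  sim2 <- simulate_qpcr(dplyr::mutate(cp, copies = copies / 2),
                        slope = -3.32, intercept = 38, ct_noise_sd = 0, seed = 1)
  expect_equal(sim2$samples$ct - sim$samples$ct, 3.32 * log10(2), tolerance = 1e-12)
  # the dilution series spans at least five decades
  span <- range(log10(sim$standards$copies))
  expect_gte(diff(span), 5)
  expect_error(simulate_qpcr(dplyr::mutate(cp, copies = 0), seed = 1),
               class = "vlcfa_bad_argument")
  expect_error(simulate_qpcr(cp, slope = 3.32, seed = 1),
               class = "vlcfa_bad_argument")
})

test_that("synthetic ORFs have the advertised length and embedded motifs", {
  orf <- make_orf(322, histidine_box_at = 150, seed = 7)
  expect_equal(nchar(orf$nucleotide), 969)
  expect_equal(nchar(orf$protein), 322)
  expect_equal(translate_orf(orf$nucleotide), orf$protein)

  orf2 <- make_orf(305, histidine_box_at = 140, seed = 8)
  expect_equal(nchar(orf2$nucleotide), 918)

  hits <- scan_motifs(orf$protein)
  expect_true(any(hits$motif == "histidine_box" & hits$start == 150))
  expect_true(any(hits$motif == "er_retention" & hits$start == 322 - 4))

  set.seed(31)
  for (L in sample(10:400, 10)) {
    o <- make_orf(L, er_retention_at = NA)
    expect_equal(nchar(translate_orf(o$nucleotide)), L)
  }
  expect_error(make_orf(20, histidine_box_at = 14, er_retention_at = 16),
               class = "vlcfa_bad_argument")
  expect_error(make_orf(20, histidine_box_at = 18), class = "vlcfa_bad_argument")
})
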