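test_that("degenerate category mixes produce the stated compositions", {
  bi <- generate_collection(20, c(biennial = 1), seed = 11)
  expect_true(all(bi$p_biennial == 1))
  expect_true(all(bi$p_early_annual == 0 & bi$p_late_annual == 0))
  expect_true(all(bi$true_category == "biennial"))

  ea <- generate_collection(20, c(uniformly_early_annual = 1), seed = 11)
  expect_true(all(ea$p_early_annual >= 0.85))
  expect_true(all(ea$true_category == "uniformly_early_annual"))
})

test_that("composition invariants hold across a mixed collection", {
  prof <- generate_collection(300, seed = 5)
  expect_true(all(abs(prof$p_early_annual + prof$p_late_annual +
                        prof$p_biennial - 1) < 1e-12))
  probs <- c(prof$p_early_annual, prof$p_late_annual, prof$p_biennial)
  expect_true(all(probs >= 0 & probs <= 1))
  ## truth labels always equal the classifier applied to the composition
  rec <- classify_carrotomics(100 * prof$p_early_annual,
                              100 * (prof$p_early_annual +
                                       prof$p_late_annual))
  leaf <- ifelse(rec$subcategory == "none", rec$category, rec$subcategory)
  expect_identical(truth_table(prof)$true_category, leaf)
})

test_that("empirical category frequencies track the requested mix", {
  mix <- c(biennial = 0.3, predominantly_biennial = 0.24,
           other_mixture = 0.37, annual = 0.09)
  prof <- generate_collection(1000, mix, seed = 42)
  freq <- table(prof$true_category) / 1000
  expect_equal(unname(freq[["biennial"]]), 0.3, tolerance = 0.1)
  expect_equal(unname(freq[["predominantly_biennial"]]), 0.24,
               tolerance = 0.125)
  expect_equal(unname(freq[["other_mixture"]]), 0.37, tolerance = 0.081)
  annual_leafs <- c("non_uniform_annual", "uniformly_early_annual",
                    "uniformly_late_annual")
  p_annual <- sum(prof$true_category %in% annual_leafs) / 1000
  expect_true(abs(p_annual - 0.09) <= 0.03)
})

test_that("collection and trial generation are deterministic given seed", {
  p1 <- generate_collection(30, seed = 9)
  p2 <- generate_collection(30, seed = 9)
  expect_identical(p1, p2)
  d <- trial_design(years = c("a", "b"), plants_per_plot = 20)
  r1 <- simulate_trial(p1, d, seed = 9)
  r2 <- simulate_trial(p2, d, seed = 9)
  expect_identical(r1, r2)
  r3 <- simulate_trial(p1, d, seed = 10)
  expect_false(identical(r1, r3))
})

test_that("obligate biennials never flower; pure early annuals always do", {
  bi <- manual_profiles(p_early = rep(0, 3), p_late = rep(0, 3))
  rec <- simulate_trial(bi, trial_design(), env_sds = c(year = 1, gy = 1,
                                                        block = 1),
                        seed = 2)
  expect_true(all(rec$frac60 == 0) && all(rec$frac100 == 0))

  ea <- manual_profiles(p_early = rep(1, 3), p_late = rep(0, 3))
  rec <- simulate_trial(ea, trial_design(emergence_rate = 1),
                        env_sds = c(year = 0, gy = 0, block = 0), seed = 2)
  expect_true(all(rec$frac60 == 1) && all(rec$frac100 == 1))
})

test_that("a 50/50 early-annual/biennial plot fraction is binomial", {
  prof <- manual_profiles(p_early = 0.5, p_late = 0)
  d <- trial_design(years = sprintf("y%03d", 1:150), blocks_per_year = 2,
                    plants_per_plot = 50, emergence_rate = 1)
  rec <- simulate_trial(prof, d, env_sds = c(year = 0, gy = 0, block = 0),
                        seed = 31)
  expect_equal(nrow(rec), 300)
  expect_equal(mean(rec$frac100), 0.5, tolerance = 0.02)
  expect_equal(var(rec$frac100), 0.25 / 50, tolerance = 0.3)
})

test_that("expected end-of-season fraction is monotone in annual fraction", {
  prof <- manual_profiles(p_early = c(0.1, 0.2, 0.35), p_late = 0.1)
  d <- trial_design(years = sprintf("y%02d", 1:40), blocks_per_year = 2,
                    plants_per_plot = 100, emergence_rate = 1)
  rec <- simulate_trial(prof, d, env_sds = c(year = 0, gy = 0, block = 0),
                        seed = 17)
  means <- tapply(rec$frac100, rec$accession_id, mean)
  expect_true(means[["M01"]] < means[["M02"]])
  expect_true(means[["M02"]] < means[["M03"]])
})

test_that("with no noise and many plants, fractions converge to truth", {
  prof <- manual_profiles(p_early = 0.2, p_late = 0.3)
  d <- trial_design(years = "y1", blocks_per_year = 2,
                    plants_per_plot = 20000, emergence_rate = 1)
  rec <- simulate_trial(prof, d, env_sds = c(year = 0, gy = 0, block = 0),
                        seed = 4)
  expect_equal(mean(rec$frac60), 0.2, tolerance = 0.02)
  expect_equal(mean(rec$frac100), 0.5, tolerance = 0.01)
})

test_that("early-biased stand loss depresses 60 DAS more than 100 DAS", {
  prof <- manual_profiles(p_early = rep(0.3, 30), p_late = rep(0.3, 30))
  loss <- data.frame(year = "bad", survival_fraction = 0.5, early_bias = 2)
  d <- trial_design(years = c("ok", "bad"), blocks_per_year = 2,
                    plants_per_plot = 100, emergence_rate = 1,
                    stand_loss_events = loss)
  rec <- simulate_trial(prof, d, env_sds = c(year = 0, gy = 0, block = 0),
                        seed = 8)
  m <- aggregate(cbind(frac60, frac100) ~ year, rec, mean)
  drop60 <- m$frac60[m$year == "ok"] - m$frac60[m$year == "bad"]
  drop100 <- m$frac100[m$year == "ok"] - m$frac100[m$year == "bad"]
  expect_true(drop60 > 0)
  expect_true(drop60 > drop100)
})

test_that("senescence simulation creates declines only when enabled", {
  prof <- manual_profiles(p_early = rep(0.8, 10), p_late = 0)
  d0 <- trial_design(years = "y1", plants_per_plot = 100,
                     emergence_rate = 1)
  rec0 <- simulate_trial(prof, d0, env_sds = c(year = 0, gy = 0,
                                               block = 0), seed = 3)
  expect_true(all(rec0$frac100 >= rec0$frac60))
  d1 <- trial_design(years = "y1", plants_per_plot = 100,
                     emergence_rate = 1, senescence_rate = 0.5)
  rec1 <- simulate_trial(prof, d1, env_sds = c(year = 0, gy = 0,
                                               block = 0), seed = 3)
  expect_true(any(rec1$frac100 < rec1$frac60))
})

test_that("generator rejects invalid configurations", {
  expect_error(generate_collection(0, c(biennial = 1)), "n_accessions")
  expect_error(generate_collection(5, c(biennial = 0.6, annual = 0.3)),
               "sum to 1")
  expect_error(generate_collection(5, c(biennial = 1.5, annual = -0.5)),
               "nonnegative")
  expect_error(generate_collection(5, c(weird = 1)), "unknown categories")
  expect_error(simulate_trial(manual_profiles(0.1, 0.1)[0, ]),
               "non-empty")
  expect_error(
    trial_design(years = "y1",
                 stand_loss_events = data.frame(year = "zz",
                                                survival_fraction = 0.5,
                                                early_bias = 0)),
    "unknown year")
})
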