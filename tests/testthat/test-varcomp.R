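test_that("worked 6-value fixture: exact sums of squares", {
  tab <- anova_single_year(toy_anova_obs(), 100)
  expect_equal(tab$SS[tab$Source == "Accession"], 1600)
  expect_equal(tab$SS[tab$Source == "Block"], 150)
  expect_equal(tab$SS[tab$Source == "Residuals"], 0)
  expect_equal(tab$df, c(2L, 1L, 2L))
  ## exact fit: F and p undefined
  expect_true(all(is.na(tab$F)))
})

test_that("no-variance input gives zero SS everywhere and absent F", {
  obs <- toy_anova_obs()
  obs$pct100 <- 42
  tab <- anova_single_year(obs, 100)
  expect_equal(tab$SS, rep(0, 3))
  expect_true(all(is.na(tab$F)))
})

test_that("Type III equals sequential SS on balanced data", {
  obs <- balanced_single_year_obs(n_accessions = 7, n_blocks = 3, seed = 4)
  tab <- anova_single_year(obs, 100)
  seq_tab <- withr::with_options(
    list(contrasts = c("contr.sum", "contr.poly")),
    anova(lm(pct100 ~ factor(accession_id) + factor(block), data = obs))
  )
  expect_equal(tab$SS[1:2], seq_tab$`Sum Sq`[1:2], tolerance = 1e-10)
  expect_equal(tab$SS[3], seq_tab$`Sum Sq`[3], tolerance = 1e-10)
  expect_equal(sum(tab$df), nrow(obs) - 1)
})

test_that("unbalanced Type III matches the model-comparison oracle (car)", {
  skip_if_not_installed("car")
  obs <- balanced_single_year_obs(n_accessions = 6, n_blocks = 3, seed = 9)
  obs <- obs[-c(4, 11), ] # delete cells -> unbalanced
  tab <- anova_single_year(obs, 100)
  fit <- withr::with_options(
    list(contrasts = c("contr.sum", "contr.poly")),
    lm(pct100 ~ factor(accession_id) + factor(block), data = obs)
  )
  oracle <- car::Anova(fit, type = "III")
  expect_equal(tab$SS[tab$Source == "Accession"],
               oracle["factor(accession_id)", "Sum Sq"], tolerance = 1e-9)
  expect_equal(tab$SS[tab$Source == "Block"],
               oracle["factor(block)", "Sum Sq"], tolerance = 1e-9)
  expect_equal(tab$F[tab$Source == "Accession"],
               oracle["factor(accession_id)", "F value"], tolerance = 1e-9)
})

test_that("multi-year ANOVA: replication across years zeroes year terms", {
  y1 <- toy_anova_obs()
  y2 <- dplyr::mutate(y1, year = "y2")
  tab <- anova_multi_year(dplyr::bind_rows(y1, y2), 100)
  expect_equal(tab$SS[tab$Source == "Year"], 0, tolerance = 1e-9)
  expect_equal(tab$SS[tab$Source == "Accession x Year"], 0,
               tolerance = 1e-9)
  expect_equal(tab$SS[tab$Source == "Accession"], 2 * 1600,
               tolerance = 1e-9)
  expect_equal(sum(tab$df), 11)
})

test_that("permuting year labels within accessions keeps SS_accession", {
  g <- simulate_gaussian_trial(12, 2, 2, seed = 21)
  g$pct100 <- g$y
  tab1 <- anova_multi_year(g, 100)
  flip <- g
  flip$year <- ifelse(flip$year == "year1", "year2", "year1")
  tab2 <- anova_multi_year(flip, 100)
  expect_equal(tab1$SS[tab1$Source == "Accession"],
               tab2$SS[tab2$Source == "Accession"], tolerance = 1e-9)
})

test_that("planted genotype-by-year interaction is detected", {
  hits <- 0
  for (s in 1:20) {
    g <- simulate_gaussian_trial(
      60, 2, 2, varcomps = c(Vg = 4, Vgy = 16, Vyear = 1, Vblock = 0.5,
                             Verror = 4), seed = 100 + s)
    g$pct100 <- g$y
    tab <- anova_multi_year(g, 100)
    p <- tab$p[tab$Source == "Accession x Year"]
    if (!is.na(p) && p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("method-of-moments solves the EMS equations", {
  vc <- estimate_varcomp(toy_anova_obs(), "single_year", 100, "ems_mom")
  ## MS_g = 800, MS_b = 150, MS_e = 0 here
  expect_equal(vc$components[["Vg"]], 400)
  expect_equal(vc$components[["Vblock"]], 50)
  expect_equal(vc$components[["Verror"]], 0)
  expect_equal(vc$n_reps, 2L)
})

test_that("negative moments solutions truncate to zero with a flag", {
  obs <- tibble::tibble(
    accession_id = rep(c("A", "B"), each = 2), year = "y1",
    block = rep(1:2, 2), pct60 = 0,
    pct100 = c(10, 30, 30, 10) # no accession signal, pure noise
  )
  vc <- estimate_varcomp(obs, "single_year", 100, "ems_mom")
  expect_equal(vc$components[["Vg"]], 0)
  expect_true("Vg" %in% vc$truncated)
})

test_that("ems_mom refuses unbalanced data; reml accepts it", {
  g <- simulate_gaussian_trial(10, 2, 2, seed = 5)
  g$pct100 <- g$y
  g_unbal <- g[-3, ]
  expect_error(estimate_varcomp(g_unbal, "multi_year", 100, "ems_mom"),
               "balanced")
  vc <- estimate_varcomp(g_unbal, "multi_year", 100, "reml")
  expect_true(all(vc$components[c("Vg", "Vgy", "Verror")] >= 0))
})

test_that("reml and moments agree on balanced data off the boundary", {
  for (s in 31:34) {
    g <- simulate_gaussian_trial(80, 2, 2, seed = s)
    g$pct100 <- g$y
    mom <- estimate_varcomp(g, "multi_year", 100, "ems_mom")
    reml <- estimate_varcomp(g, "multi_year", 100, "reml")
    if (length(mom$truncated) == 0) {
      rel <- abs(mom$components - reml$components) /
        pmax(abs(mom$components), 1e-12)
      expect_lt(max(rel[c("Vg", "Vgy", "Verror")]), 1e-6)
    } else {
      ## at a truncation boundary both estimators must pin the component
      ## to zero; the remaining components stay close but the exact
      ## balanced-data equivalence no longer applies
      expect_lt(max(abs(reml$components[mom$truncated])), 1e-6)
      expect_equal(reml$components[["Vg"]], mom$components[["Vg"]],
                   tolerance = 0.05)
    }
  }
})

test_that("variance components recover simulation truth", {
  truth <- c(Vg = 8, Vgy = 2, Vyear = 1, Vblock = 0.5, Verror = 4)
  est <- sapply(1:6, function(s) {
    g <- simulate_gaussian_trial(150, 2, 2, varcomps = truth,
                                 seed = 200 + s)
    g$pct100 <- g$y
    estimate_varcomp(g, "multi_year", 100,
                     "ems_mom")$components[c("Vg", "Vgy", "Verror")]
  })
  m <- rowMeans(est)
  expect_equal(m[["Vg"]], 8, tolerance = 0.25)
  expect_equal(m[["Vgy"]], 2, tolerance = 0.25)
  expect_equal(m[["Verror"]], 4, tolerance = 0.15)
})

test_that("heritability formulas evaluate exactly and stay bounded", {
  expect_equal(h2_single(9, 2, 2)$H2, 0.9)
  expect_equal(h2_single(0, 5, 2)$H2, 0)
  expect_equal(h2_single(3, 0, 1)$H2, 1)
  expect_equal(h2_multi(8, 2, 4, 2, 2)$H2, 0.8)
  expect_equal(h2_multi(8, 0, 0, 2, 2)$H2, 1)
  ## the multi-year formula with Vgy = 0 collapses to the single-year form
  expect_equal(h2_multi(5, 0, 6, 3, 2)$H2,
               5 / (5 + 6 / (3 * 2)))
  expect_error(h2_single(0, 0, 2), "undefined")
  expect_error(h2_single(-1, 2, 2), "nonnegative")
  expect_error(h2_multi(8, 2, 4, 1, 2), "n_years")
})

test_that("H2 is scale invariant and monotone in its components", {
  g <- simulate_gaussian_trial(40, 2, 2, seed = 77)
  g$pct100 <- g$y
  h <- heritability(g, "multi_year", 100, "ems_mom")
  g2 <- g
  g2$pct100 <- g2$pct100 * 3.7
  h2 <- heritability(g2, "multi_year", 100, "ems_mom")
  expect_equal(h$H2, h2$H2, tolerance = 1e-10)
  expect_true(h$H2 >= 0 && h$H2 <= 1)
  ## monotonicity of the formula itself
  expect_gt(h2_multi(9, 2, 4, 2, 2)$H2, h2_multi(8, 2, 4, 2, 2)$H2)
  expect_lt(h2_multi(8, 3, 4, 2, 2)$H2, h2_multi(8, 2, 4, 2, 2)$H2)
  expect_lt(h2_multi(8, 2, 5, 2, 2)$H2, h2_multi(8, 2, 4, 2, 2)$H2)
})

test_that("single-year models reject malformed inputs", {
  obs <- toy_anova_obs()
  expect_error(anova_single_year(obs[obs$accession_id == "A", ], 100),
               ">= 2 accessions")
  expect_error(anova_single_year(obs[obs$block == 1, ], 100),
               ">= 2 blocks")
  multi <- dplyr::bind_rows(obs, dplyr::mutate(obs, year = "y2"))
  expect_error(anova_single_year(multi, 100), "multiple years")
  expect_error(anova_multi_year(obs, 100), ">= 2 years")
  expect_error(anova_single_year(obs, 42), "timepoint")
})
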