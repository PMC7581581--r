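test_that("log transform handles offsets and names offenders", {
  expect_equal(log_transform(1), 0)
  expect_equal(log_transform(20), log(20), tolerance = 1e-12)
  expect_equal(round(log_transform(20), 4), 2.9957)
  expect_equal(log_transform(0, offset = 1), 0)
  expect_error(log_transform(c(3, 0, 5)), "observation\\(s\\) 2")
})

test_that("GG epsilon is 1 under sphericity and matches the oracle", {
  expect_equal(greenhouse_geisser_epsilon(diag(2) + 0.3), 1)
  cs <- matrix(0.4, 3, 3); diag(cs) <- 1  # compound symmetry
  expect_equal(greenhouse_geisser_epsilon(cs), 1)
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- matrix(rnorm(9), 3)
      s <- crossprod(a) + diag(3) * 0.1
      expect_equal(greenhouse_geisser_epsilon(s), oracle_gg_epsilon(s),
                   tolerance = 1e-10)
      eps <- greenhouse_geisser_epsilon(s)
      expect_gte(eps, 0.5); expect_lte(eps, 1)
    }
  })
  expect_error(greenhouse_geisser_epsilon(matrix(1, 2, 3)), "square")
})

test_that("partial eta squared follows its definition", {
  expect_equal(partial_eta_squared(0, 5), 0)
  expect_equal(partial_eta_squared(5, 5), 0.5)
  expect_equal(partial_eta_squared(3, 7), 0.3)
  expect_error(partial_eta_squared(0, 0), "both")
  expect_error(partial_eta_squared(-1, 2), ">= 0")
})

test_that("within-subject F equals the squared paired t", {
  for (seed in c(3, 4, 5)) {
    d <- make_paired_data(20, delta = 0.15, seed = seed)
    a <- mixed_anova(d, dv = "y", between = character(0))
    w <- d$y[d$background == "white"]; b <- d$y[d$background == "black"]
    tt <- t.test(b, w, paired = TRUE)
    expect_equal(a$f[a$effect == "background"], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(a$p[a$effect == "background"], tt$p.value,
                 tolerance = 1e-10)
    expect_equal(a$gg_epsilon[a$effect == "background"], 1)
    expect_equal(a$p_gg, a$p)  # epsilon 1 leaves p untouched
  }
})

test_that("mixed ANOVA validates pairing and factors", {
  d <- make_paired_data(10)
  expect_error(mixed_anova(d[-1, ], dv = "y", between = character(0)),
               "exactly one observation per within level")
  expect_error(mixed_anova(d, dv = "nope", between = character(0)),
               "missing from data")
})

test_that("GG epsilon reported by the ANOVA matches the covariance formula", {
  # 3-level within factor, non-spherical covariance, genuine effect
  withr::with_seed(6, {
    n <- 24
    base <- rnorm(n, 0, 1)
    y <- cbind(base + rnorm(n, 0, 0.2), base + 0.5 + rnorm(n, 0, 0.8),
               0.4 * base + 1 + rnorm(n, 0, 1.5))
    d <- data.frame(
      specimen_id = rep(sprintf("s%02d", 1:n), each = 3),
      background = rep(c("a", "b", "c"), n),
      y = as.vector(t(y))
    )
  })
  a <- mixed_anova(d, dv = "y", within = "background",
                   between = character(0))
  expect_equal(a$gg_epsilon[a$effect == "background"],
               oracle_gg_epsilon(cov(y)), tolerance = 1e-6)
  expect_lt(a$gg_epsilon[a$effect == "background"], 1)
  # for F >= 1 the df shrinkage can only weaken the evidence
  expect_gte(a$f[a$effect == "background"], 1)
  expect_gte(a$p_gg[a$effect == "background"],
             a$p[a$effect == "background"])
})

test_that("ANOVA detects an injected background effect and sized doses", {
  m <- effect_model(beta_concentration = c("0" = 0, "10" = 0, "100" = 0,
                                           "1000" = -0.6))
  d <- cohort_design(trials = 1, exposure_times = "1h",
                     replicates_per_treatment = 15, seed = 77)
  tab <- generate_cohort(d, m, params = NULL)$table
  tab$logc <- log_transform(tab$coefficient)
  a <- mixed_anova(tab, dv = "logc", between = "concentration_ng_per_L")
  expect_lt(a$p[a$effect == "background"], 0.001)
  expect_lt(a$p[a$effect == "concentration_ng_per_L"], 0.01)
  expect_true(all(a$ss >= 0))
  expect_true(all(a$partial_eta_sq >= 0 & a$partial_eta_sq <= 1))
})

test_that("pairwise post hocs enumerate pairs and adjust by Bonferroni", {
  withr::with_seed(8, {
    d <- data.frame(g = rep(c("a", "b", "c", "d"), each = 8),
                    y = rnorm(32) + rep(c(0, 0, 0, 1), each = 8))
  })
  ph <- pairwise_posthoc(d, "g", "y")
  expect_equal(nrow(ph), 6)            # 4 levels -> 6 pairs
  expect_true(all(ph$m == 6))
  expect_equal(ph$p_bonferroni, pmin(1, 6 * ph$p_raw))
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  # raw p agrees with pairwise.t.test on the pooled SD
  ref <- pairwise.t.test(d$y, d$g, p.adjust.method = "none")$p.value
  expect_equal(ph$p_raw[ph$level_a == "a" & ph$level_b == "b"],
               ref["b", "a"], tolerance = 1e-10)
  expect_equal(ph$p_raw[ph$level_a == "c" & ph$level_b == "d"],
               ref["d", "c"], tolerance = 1e-10)
})

test_that("identical groups give adjusted p of 1, tiny groups error", {
  d <- data.frame(g = rep(c("a", "b"), each = 5),
                  y = c(rep(c(1, 2, 3, 4, 5), 2)))
  ph <- pairwise_posthoc(d, "g", "y")
  expect_equal(ph$p_bonferroni, 1)
  expect_equal(ph$mean_diff, 0)
  expect_error(pairwise_posthoc(data.frame(g = c("a", "b", "b"), y = 1:3),
                                "g", "y"), "< 2 observations")
})

test_that("Pearson correlation matches the closed-form computation", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  x2 <- c(1, 2, 3, 4); y2 <- c(1, -1, 1, -1)
  manual <- sum((x2 - mean(x2)) * (y2 - mean(y2))) /
    sqrt(sum((x2 - mean(x2))^2) * sum((y2 - mean(y2))^2))
  res <- pearson_correlation(x2, y2)
  expect_equal(res$r, manual, tolerance = 1e-12)
  expect_equal(res$r_squared, res$r^2)
  # r of 0.793 corresponds to R^2 of 0.629 (to 3 dp)
  expect_equal(round(0.793^2, 3), 0.629)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("type-I error of the background test sits at the nominal level", {
  # 200 null cohorts of 60 specimens (4 doses x 15): rejection rate at
  # alpha = .05 must lie within 3 binomial SEs of .05
  m0 <- effect_model(beta_background = 0)
  des <- cohort_design(trials = 1, exposure_times = "1h",
                       replicates_per_treatment = 15)
  base_tab <- sample_design(des)
  reject <- withr::with_seed(2024, {
    vapply(1:200, function(i) {
      tab <- sample_stage_counts(base_tab, m0)
      tab$logc <- log_transform(chromatophore_coefficient(tab))
      a <- mixed_anova(tab, dv = "logc",
                       between = "concentration_ng_per_L")
      a$p[a$effect == "background"] < 0.05
    }, logical(1))
  })
  rate <- mean(reject)
  se3 <- 3 * sqrt(0.05 * 0.95 / 200)
  expect_gte(rate, 0.05 - se3)
  expect_lte(rate, 0.05 + se3)
})

test_that("the dataset battery reproduces its pieces and round-trips", {
  m <- effect_model(beta_trial = c("1" = 0, "2" = 0.25))
  d <- cohort_design(trials = 1:2, concentrations = c(0, 1000),
                     exposure_times = c("1h", "1wk"),
                     replicates_per_treatment = 8, seed = 55)
  tab <- generate_cohort(d, m, params = NULL)$table
  withr::with_seed(56, {
    tab$percent_dark <- pmax(0, (tab$coefficient - 18) / 4 + rnorm(nrow(tab)))
  })
  res <- analyze_dataset(tab)
  expect_lt(res$coefficient$anova$p[
    res$coefficient$anova$effect == "background"], 0.001)
  expect_true("trial" %in% names(res$coefficient$posthoc))
  expect_named(res$coefficient$trial_removed,
               c("without_trial_1", "without_trial_2"))
  # trial-removed refit drops the trial factor (single level left)
  expect_false("trial" %in% res$coefficient$trial_removed[[1]]$effect)
  expect_gt(res$correlation$overall$r, 0.85)
  expect_length(res$correlation$per_trial, 2)

  dir <- withr::local_tempdir()
  write_results(res, dir)
  back <- read_results(dir)
  expect_equal(back$coefficient$anova$f, res$coefficient$anova$f,
               tolerance = 1e-12)
  expect_equal(back$correlation$overall$r, res$correlation$overall$r,
               tolerance = 1e-12)
})
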