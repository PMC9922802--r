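test_that("population mean is the Hardy-Weinberg-weighted genotypic value", {
  fr <- allele_freqs(0.68)
  s <- example_summary()
  expect_equal(population_mean(s, fr),
               0.4624 * 10 + 0.4352 * 12 + 0.1024 * 12, tolerance = 1e-12)
  # identity and degenerate-frequency cases
  s_const <- genotypic_summary(c(TT = 7, TG = 7, GG = 7),
                               n = c(TT = 5, TG = 5, GG = 5),
                               s2 = c(TT = 1, TG = 1, GG = 1))
  expect_equal(population_mean(s_const, allele_freqs(0.3)), 7)
  expect_equal(population_mean(s, allele_freqs(1)), 10)
  # M always lies between the extreme genotypic values
  for (p in seq(0, 1, by = 0.1)) {
    M <- population_mean(s, allele_freqs(p))
    expect_gte(M, min(s$mean)); expect_lte(M, max(s$mean))
  }
})

test_that("invalid frequencies and missing classes are rejected", {
  expect_error(allele_freqs(1.2), "\\[0, 1\\]")
  expect_error(allele_freqs(0.6, 0.3), "p \\+ q = 1")
  s2cls <- genotypic_summary(c(TT = 10, GG = 12),
                             n = c(TT = 5, GG = 5), s2 = c(TT = 1, GG = 1))
  expect_error(population_mean(s2cls, allele_freqs(0.5)), "Aa")
  expect_error(genetic_variance_hw(s2cls, allele_freqs(0.5)), "Aa")
})

test_that("HW genetic variance matches hand example and vanishes when it should", {
  fr <- allele_freqs(0.68)
  expect_equal(genetic_variance_hw(example_summary(), fr), 0.99434496,
               tolerance = 1e-9)
  s_const <- genotypic_summary(c(TT = 7, TG = 7, GG = 7),
                               n = c(TT = 5, TG = 5, GG = 5),
                               s2 = c(TT = 1, TG = 1, GG = 1))
  expect_equal(genetic_variance_hw(s_const, fr), 0)
  expect_equal(genetic_variance_hw(example_summary(), allele_freqs(1)), 0)
})

test_that("HW variance equals a brute-force three-state expectation oracle", {
  set.seed(11)
  for (i in 1:200) {
    means <- rnorm(3, 10, 4)
    p <- runif(1, 0.01, 0.99)
    s <- genotypic_summary(c(TT = means[1], TG = means[2], GG = means[3]),
                           n = c(TT = 5, TG = 5, GG = 5),
                           s2 = c(TT = 1, TG = 1, GG = 1))
    oracle <- expectation_oracle(means, p)
    expect_equal(population_mean(s, allele_freqs(p)), oracle$mean,
                 tolerance = 1e-12)
    expect_equal(genetic_variance_hw(s, allele_freqs(p)), oracle$var,
                 tolerance = 1e-12)
    # HW weights are a probability distribution
    expect_equal(p^2 + 2 * p * (1 - p) + (1 - p)^2, 1, tolerance = 1e-12)
  }
})

test_that("random-effects variance component matches the ANOVA-table oracle", {
  set.seed(21)
  # balanced 3 x 5 with known group effects
  um <- list(TT = rnorm(5, 0, 1), TG = rnorm(5, 2, 1), GG = rnorm(5, 5, 1))
  est <- genetic_variance_ranef(um)
  y <- unlist(um); g <- factor(rep(names(um), each = 5))
  av <- anova(stats::aov(y ~ g))
  oracle <- (av["g", "Mean Sq"] - av["Residuals", "Mean Sq"]) / 5
  expect_equal(as.numeric(est), max(0, oracle), tolerance = 1e-10)
  expect_equal(attr(est, "ms_within"), av["Residuals", "Mean Sq"],
               tolerance = 1e-10)
  # unbalanced n0 check against direct formula
  um2 <- list(TT = rnorm(10), TG = rnorm(18), GG = rnorm(10))
  est2 <- genetic_variance_ranef(um2)
  n <- c(10, 18, 10); N <- sum(n)
  expect_equal(attr(est2, "n0"), (N - sum(n^2) / N) / 2, tolerance = 1e-12)
})

test_that("random-effects estimator agrees with lme4 REML on balanced data", {
  skip_if_not_installed("lme4")
  set.seed(31)
  um <- list(TT = rnorm(40, 0, 1), TG = rnorm(40, 3, 1),
             GG = rnorm(40, 5, 1))
  est <- genetic_variance_ranef(um)
  df <- data.frame(y = unlist(um), g = rep(names(um), each = 40))
  fit <- lme4::lmer(y ~ 1 + (1 | g), data = df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(as.numeric(est), vc$vcov[vc$grp == "g"], tolerance = 1e-4)
})

test_that("random-effects estimator recovers a known variance component", {
  set.seed(41)
  # 3 groups, n = 200/group, between-variance 4, within-variance 1;
  # the untruncated estimate is unbiased, so its mean over replicates
  # should sit within 3 Monte-Carlo SE of 4.
  raw <- replicate(200, {
    eff <- rnorm(3, 0, 2)
    um <- list(TT = rnorm(200, eff[1], 1), TG = rnorm(200, eff[2], 1),
               GG = rnorm(200, eff[3], 1))
    attr(genetic_variance_ranef(um), "raw")
  })
  expect_lt(abs(mean(raw) - 4), 3 * sd(raw) / sqrt(length(raw)))
})

test_that("random-effects estimator rejects degenerate groupings and truncates", {
  expect_error(genetic_variance_ranef(list(TT = 1:5)), "two genotype")
  expect_error(genetic_variance_ranef(list(TT = 1, GG = 2)), "singleton")
  um <- list(TT = c(5, 5, 5), TG = c(5, 5, 5), GG = c(5, 5, 5))
  expect_equal(as.numeric(genetic_variance_ranef(um)), 0)
  # identical group means but positive within-variance: raw negative,
  # truncated to zero and flagged
  um2 <- list(TT = c(4, 6), TG = c(4, 6), GG = c(4, 6))
  est <- genetic_variance_ranef(um2)
  expect_equal(as.numeric(est), 0)
  expect_true(attr(est, "truncated"))
})

test_that("pooled within-genotype variance is the df-weighted pool", {
  expect_equal(pooled_within_variance(example_summary()),
               (9 * 2 + 17 * 3 + 9 * 4) / 35, tolerance = 1e-12)
  # equal variances pass through; result bounded by the class variances
  s_eq <- genotypic_summary(c(TT = 1, TG = 2, GG = 3),
                            n = c(TT = 4, TG = 9, GG = 2),
                            s2 = c(TT = 2.5, TG = 2.5, GG = 2.5))
  expect_equal(pooled_within_variance(s_eq), 2.5)
  v <- pooled_within_variance(example_summary())
  expect_gte(v, 2); expect_lte(v, 4)
  # single eligible class: that class's s2, with a warning for the rest
  s_one <- genotypic_summary(c(TT = 1, TG = 2, GG = 3),
                             n = c(TT = 1, TG = 6, GG = 1),
                             s2 = c(TT = NA, TG = 3.7, GG = NA))
  expect_warning(v1 <- pooled_within_variance(s_one), "n < 2")
  expect_equal(v1, 3.7)
  s_none <- genotypic_summary(c(TT = 1, TG = 2, GG = 3),
                              n = c(TT = 1, TG = 1, GG = 1),
                              s2 = c(TT = NA, TG = NA, GG = NA))
  expect_error(suppressWarnings(pooled_within_variance(s_none)),
               "undefined")
})

test_that("intraclass correlation behaves as t = V_G/(V_within + V_G)", {
  expect_equal(intraclass_correlation(0.994, 6.370), 0.994 / 7.364,
               tolerance = 1e-12)
  expect_equal(intraclass_correlation(0, 3), 0)
  expect_equal(intraclass_correlation(2, 0), 1)
  expect_error(intraclass_correlation(0, 0), "undefined")
  expect_error(intraclass_correlation(-1, 2), "non-negative")
  # monotone increasing in V_G at fixed V_within
  ts <- sapply(seq(0.1, 5, by = 0.1), intraclass_correlation,
               V_within = 2)
  expect_true(all(diff(ts) > 0))
  expect_true(all(ts >= 0 & ts <= 1))
})

test_that("t is invariant under affine rescaling of the trait", {
  set.seed(51)
  um <- list(TT = rnorm(10, 10, 2), TG = rnorm(18, 12, 2),
             GG = rnorm(10, 13, 2))
  fr <- allele_freqs(0.68)
  t_of <- function(u) {
    s <- summarize_genotypes(u)
    intraclass_correlation(genetic_variance_hw(s, fr),
                           pooled_within_variance(s))
  }
  base <- t_of(um)
  shifted <- t_of(lapply(um, function(x) x + 100))
  scaled <- t_of(lapply(um, function(x) 3.7 * x))
  expect_equal(shifted, base, tolerance = 1e-9)
  expect_equal(scaled, base, tolerance = 1e-9)
})
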