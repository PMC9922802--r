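test_that("the same seed reproduces every generator bit-identically", {
  cfg <- f1_sim_config()
  expect_identical(simulate_f1_panel(cfg, seed = 3)$eggs,
                   simulate_f1_panel(cfg, seed = 3)$eggs)
  pcfg <- panel_sim_config(n_background_snps = 50, het_rate = 0.01)
  p1 <- simulate_genotype_panel(pcfg, seed = 4)
  p2 <- simulate_genotype_panel(pcfg, seed = 4)
  expect_identical(p1$calls, p2$calls)
  expect_identical(simulate_cq_table(0.2, seed = 5),
                   simulate_cq_table(0.2, seed = 5))
})

test_that("the F1 design matches the study layout", {
  sim <- simulate_f1_panel(f1_sim_config(), seed = 11)
  tab <- sim$eggs
  crosses <- unique(tab[c("cross_id", "genotype")])
  expect_equal(table(crosses$genotype)[c("TT", "TG", "GG")],
               c(TT = 10L, TG = 18L, GG = 10L), ignore_attr = TRUE)
  expect_equal(sort(unique(tab$day)), seq(3L, 30L, 3L))
  expect_equal(length(unique(tab$vial_id)), 38L * 3L)
  expect_true(all(tab$n_females == 2L))
  expect_true(all(tab$eggs >= 0 & tab$eggs == round(tab$eggs)))
  # realistic magnitudes: peak rates in the tens of eggs/female/day
  d9 <- tab[tab$day == 9, ]
  expect_gt(mean(d9$eggs / d9$n_females), 10)
  expect_lt(mean(d9$eggs / d9$n_females), 60)
})

test_that("full dominance makes TG and GG equal in expectation", {
  cfg <- f1_sim_config(dominance = 1)
  td <- true_decomposition(cfg)
  expect_equal(td$per_day$mean_TG, td$per_day$mean_GG, tolerance = 1e-12)
  # h = 0 makes TG equal TT instead
  td0 <- true_decomposition(f1_sim_config(dominance = 0))
  expect_equal(td0$per_day$mean_TG, td0$per_day$mean_TT,
               tolerance = 1e-12)
})

test_that("zero effect gives zero true t on every day", {
  td <- true_decomposition(f1_sim_config(genotype_effect = 0))
  expect_true(all(td$per_day$V_G == 0))
  expect_true(all(td$per_day$t == 0))
})

test_that("with no random effects and large panels the class means converge", {
  cfg <- f1_sim_config(n_crosses = c(TT = 500, TG = 500, GG = 500),
                       days = 9L, day_effect = c(`9` = 0),
                       cross_sd = 0, vial_sd = 0)
  sim <- simulate_f1_panel(cfg, seed = 21)
  tab <- validate_egg_table(sim$eggs)
  means <- tapply(tab$rate, tab$genotype, mean)
  expected <- exp(cfg$baseline_log_mean +
                    c(TT = 0, TG = 0.85, GG = 1) * cfg$genotype_effect)
  expect_equal(means[names(expected)], expected, tolerance = 0.01,
               ignore_attr = TRUE)
})

test_that("the closed-form truth matches a Monte-Carlo variance estimate", {
  cfg <- f1_sim_config(n_crosses = c(TT = 250, TG = 250, GG = 250),
                       days = 9L, day_effect = c(`9` = 0))
  td <- true_decomposition(cfg)
  sim <- simulate_f1_panel(cfg, seed = 31)
  tab <- validate_egg_table(sim$eggs)
  cm <- stats::aggregate(rate ~ cross_id + genotype, tab, mean)
  emp_mu <- tapply(cm$rate, cm$genotype, mean)
  emp_v <- tapply(cm$rate, cm$genotype, var)
  expect_equal(emp_mu[c("TT", "TG", "GG")],
               unlist(td$per_day[1, c("mean_TT", "mean_TG", "mean_GG")]),
               tolerance = 0.02, ignore_attr = TRUE)
  # pooled empirical within-class variance vs closed form (Poisson +
  # vial + cross components), 250 crosses/class: a few percent
  expect_equal(mean(emp_v), td$per_day$V_within[1], tolerance = 0.12)
})

test_that("effect calibration hits the requested generating t", {
  base <- f1_sim_config()
  for (target in c(0.05, 0.135, 0.3)) {
    cfg <- calibrate_genotype_effect(base, target)
    expect_equal(true_decomposition(cfg)$max_t, target, tolerance = 1e-8)
  }
  cfg0 <- calibrate_genotype_effect(base, 0)
  expect_equal(cfg0$genotype_effect, 0)
  expect_error(calibrate_genotype_effect(base, 0.999, upper = 0.5),
               "unattainable")
})

test_that("simulated genotype panels have the advertised structure", {
  pcfg <- panel_sim_config(n_background_snps = 300)
  panel <- simulate_genotype_panel(pcfg, seed = 41)
  expect_s3_class(panel, "panel_genotypes")
  expect_equal(panel$locus[panel$focal], "3L:18026199")
  expect_true(all(panel$calls[panel$panel1_lines, panel$focal] == "ref"))
  expect_true(all(panel$calls[panel$panel2_lines, panel$focal] == "alt"))
  # copies conserved under het/missing injection
  pcfg2 <- panel_sim_config(n_background_snps = 100, het_rate = 0.05,
                            missing_rate = 0.05)
  panel2 <- simulate_genotype_panel(pcfg2, seed = 43)
  pc <- pool_allele_counts(panel2, rownames(panel2$calls))
  expect_true(all(pc$ref_count + pc$alt_count + pc$excluded ==
                    2L * nrow(panel2$calls)))
})

test_that("simulated Cq tables encode the configured knockdown exactly", {
  tab <- simulate_cq_table(0.28, n_samples = 6, noise_sd = 0, seed = 51)
  res <- relative_expression(tab, "Eip75B", "0")
  expect_equal(mean(res$relative_expression[res$treatment == "200"]),
               0.72, tolerance = 1e-9)
  tab0 <- simulate_cq_table(0, n_samples = 6, noise_sd = 0.03, seed = 53)
  res0 <- relative_expression(tab0, "Eip75B", "0")
  expect_equal(mean(res0$relative_expression[res0$treatment == "200"]),
               1, tolerance = 0.05)
  # injected outliers are caught as one_removed for exactly those triples
  tab_o <- simulate_cq_table(0.2, n_samples = 5, noise_sd = 0.02,
                             seed = 55, outlier_rate = 0.2)
  outl <- attr(tab_o, "outliers")
  expect_gt(nrow(outl), 0)
  res_o <- relative_expression(tab_o, "Eip75B", "0")
  qc <- attr(res_o, "qc_log")
  got <- qc[qc$qc_status == "one_removed", c("sample", "gene")]
  expect_equal(got[order(got$sample, got$gene), ],
               outl[order(outl$sample, outl$gene), ],
               ignore_attr = TRUE)
})
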