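test_that("cross design yields Mendelian F1 genotypes without line reuse", {
  panel <- simulate_genotype_panel(panel_sim_config(n_background_snps = 5),
                                   seed = 1)
  cd <- design_crosses(panel, n_hom_per_allele = 10, n_het = 18, seed = 9)
  expect_equal(table(cd$expected_f1_genotype)[c("TT", "TG", "GG")],
               c(TT = 10L, TG = 18L, GG = 10L), ignore_attr = TRUE)
  hom <- cd[cd$expected_f1_genotype != "TG", ]
  expect_false(any(duplicated(c(hom$mother_line, hom$father_line))))
  # parents carry the allele their F1 genotype implies
  foc <- panel$calls[, panel$focal]
  expect_true(all(foc[cd$mother_line[cd$expected_f1_genotype == "TT"]] == "ref"))
  expect_true(all(foc[cd$father_line[cd$expected_f1_genotype == "GG"]] == "alt"))
  expect_true(all(foc[cd$mother_line[cd$expected_f1_genotype == "TG"]] == "ref" &
                    foc[cd$father_line[cd$expected_f1_genotype == "TG"]] == "alt"))
  # deterministic for a seed
  cd2 <- design_crosses(panel, 10, 18, seed = 9)
  expect_identical(cd, cd2)
  expect_error(design_crosses(panel, n_hom_per_allele = 11, n_het = 1),
               "homozygous 'T' lines")
})

test_that("pooled allele counts conserve copies and exclude het calls", {
  calls <- cbind(rep("ref", 20),
                 c(rep("ref", 10), rep("alt", 10)),
                 c(rep("ref", 19), "het"),
                 c(rep("alt", 18), NA, "het"))
  rownames(calls) <- sprintf("L%02d", 1:20)
  panel <- panel_genotypes(calls, chrom = rep("2R", 4), pos = 1:4,
                           ref = rep("A", 4), alt = rep("C", 4), focal = 1)
  pc <- pool_allele_counts(panel, rownames(calls))
  expect_equal(pc$ref_count, c(40L, 20L, 38L, 0L))
  expect_equal(pc$alt_count, c(0L, 20L, 0L, 36L))
  expect_equal(pc$excluded, c(0L, 0L, 2L, 4L))
  # conservation: ref + alt + excluded = 2 * n lines, at every SNP
  expect_true(all(pc$ref_count + pc$alt_count + pc$excluded == 40L))
  expect_error(pool_allele_counts(panel, "nope"), "not in panel")
})

test_that("F_ST is exactly 1 for fixed alternative alleles and 0 for identity", {
  expect_equal(fst_snp(c(40, 0), c(0, 40))$fst, 1)
  expect_equal(fst_snp(c(40, 0), c(0, 40))$fst_raw, 1)
  same <- fst_snp(c(30, 10), c(30, 10))
  expect_lte(same$fst_raw, 0)
  expect_equal(same$fst, 0)
  mono <- fst_snp(c(40, 0), c(40, 0))
  expect_false(mono$defined)
  expect_true(is.na(mono$fst))
})

test_that("Weir-Cockerham theta matches the independent component oracle", {
  got <- fst_snp(c(30, 10), c(10, 30))$fst_raw
  expect_equal(got, wc_oracle(0.75, 0.25, 20, 20), tolerance = 1e-12)
  # property: random pool sizes 4..100 allele copies, random counts
  set.seed(61)
  for (i in 1:300) {
    m1 <- 2 * sample(2:50, 1); m2 <- 2 * sample(2:50, 1)
    r1 <- sample(0:m1, 1); r2 <- sample(0:m2, 1)
    if ((r1 == 0 && r2 == 0) || (r1 == m1 && r2 == m2)) next
    got <- fst_snp(c(r1, m1 - r1), c(r2, m2 - r2))$fst_raw
    expect_equal(got, wc_oracle(r1 / m1, r2 / m2, m1 / 2, m2 / 2),
                 tolerance = 1e-9)
  }
})

test_that("Hudson's estimator is available and agrees at fixation", {
  expect_equal(fst_snp(c(40, 0), c(0, 40), method = "hudson")$fst, 1)
  wc <- fst_snp(c(30, 10), c(10, 30))$fst
  hu <- fst_snp(c(30, 10), c(10, 30), method = "hudson")$fst
  expect_gt(hu, 0); expect_lt(abs(wc - hu), 0.1)
})

test_that("LD r2 matches brute-force haplotype enumeration", {
  # 8-line toy: haplotype counts TA:3, TB:1, GA:1, GB:3
  calls <- cbind(c(rep("ref", 4), rep("alt", 4)),
                 c("ref", "ref", "ref", "alt", "ref", "alt", "alt", "alt"))
  rownames(calls) <- sprintf("L%d", 1:8)
  panel <- panel_genotypes(calls, chrom = c("3L", "3L"),
                           pos = c(100, 200), ref = c("T", "A"),
                           alt = c("G", "B"), focal = 1)
  pAB <- 3 / 8; pA <- 0.5; pB <- 0.5
  D <- pAB - pA * pB
  expect_equal(ld_r2(panel, 1, 2), D^2 / (pA * (1 - pA) * pB * (1 - pB)),
               tolerance = 1e-12)
  # self and perfect anti-correlation
  expect_equal(ld_r2(panel, 1, 1), 1)
  anti <- cbind(c(rep("ref", 4), rep("alt", 4)),
                c(rep("alt", 4), rep("ref", 4)))
  rownames(anti) <- sprintf("L%d", 1:8)
  p2 <- panel_genotypes(anti, chrom = c("3L", "3L"), pos = c(1, 2),
                        ref = c("T", "A"), alt = c("G", "B"), focal = 1)
  expect_equal(ld_r2(p2, 1, 2), 1)
  # symmetry and allele-label-swap invariance
  set.seed(71)
  rnd <- cbind(sample(c("ref", "alt"), 12, TRUE),
               sample(c("ref", "alt"), 12, TRUE))
  rownames(rnd) <- sprintf("L%d", 1:12)
  p3 <- panel_genotypes(rnd, chrom = c("X", "X"), pos = c(5, 6),
                        ref = c("A", "A"), alt = c("C", "C"), focal = 1)
  swapped <- rnd
  swapped[, 2] <- ifelse(rnd[, 2] == "ref", "alt", "ref")
  p3s <- panel_genotypes(swapped, chrom = c("X", "X"), pos = c(5, 6),
                         ref = c("A", "A"), alt = c("C", "C"), focal = 1)
  expect_equal(ld_r2(p3, 1, 2), ld_r2(p3, 2, 1), tolerance = 1e-12)
  expect_equal(ld_r2(p3s, 1, 2), ld_r2(p3, 1, 2), tolerance = 1e-12)
  # monomorphic SNP: undefined, not 0
  mono <- cbind(rep("ref", 8), c(rep("ref", 4), rep("alt", 4)))
  rownames(mono) <- sprintf("L%d", 1:8)
  p4 <- panel_genotypes(mono, chrom = c("2L", "2L"), pos = c(1, 2),
                        ref = c("A", "A"), alt = c("C", "C"), focal = 2)
  expect_true(is.na(ld_r2(p4, 1, 2)))
})

test_that("confounder report flags exactly the fixed and high-F_ST SNPs", {
  panel <- simulate_genotype_panel(
    panel_sim_config(n_background_snps = 200), seed = 13)
  fst <- fst_scan(panel, panel$panel1_lines, panel$panel2_lines)
  rep1 <- confounder_report(fst)
  expect_true(rep1$focal_is_unique_fixed)
  expect_equal(nrow(rep1$fixed), 1L)
  expect_equal(paste0(rep1$fixed$chrom, ":", rep1$fixed$pos),
               "3L:18026199")
  # force a background SNP to fixation -> warning
  panel2 <- simulate_genotype_panel(
    panel_sim_config(n_background_snps = 200,
                     fraction_differentiated = 0.01), seed = 13)
  fst2 <- fst_scan(panel2, panel2$panel1_lines, panel2$panel2_lines)
  expect_warning(rep2 <- confounder_report(fst2), "not the unique fixed")
  expect_false(rep2$focal_is_unique_fixed)
  expect_gt(nrow(rep2$fixed), 1)
  expect_output(print(rep1), "confounder screen")
})

test_that("undifferentiated background SNPs rarely exceed the F_ST flag", {
  panel <- simulate_genotype_panel(
    panel_sim_config(n_background_snps = 2000), seed = 17)
  fst <- fst_scan(panel, panel$panel1_lines, panel$panel2_lines)
  bg <- fst[-1, ]
  frac_high <- mean(bg$fst_clamped[bg$defined] > 0.5)
  # with 20 + 20 lines drawn from a shared frequency, F_ST > 0.5 by
  # chance is rare (a few per-mille at most)
  expect_lt(frac_high, 0.01)
  expect_true(all(bg$fst_clamped[bg$defined] >= 0 &
                    bg$fst_clamped[bg$defined] <= 1))
})
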