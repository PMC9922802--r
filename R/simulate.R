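#' Day-effect curve for simulated egg laying
#'
#' Log-scale multiplicative day effects with a linear rise to a peak day
#' followed by a linear decline, qualitatively matching the early peak and
#' post-peak decline of daily egg-laying rates in fly fecundity assays.
#'
#' @param days Integer vector of assay days.
#' @param peak_day Day of maximal laying (default 9).
#' @param start_frac Fraction of the peak rate at the first assay day
#'   (default 0.6).
#' @param end_frac Fraction of the peak rate at the last assay day
#'   (default 0.2).
#' @return Named numeric vector of log-scale day effects (0 at the peak).
#' @export
default_day_curve <- function(days, peak_day = 9, start_frac = 0.6,
                              end_frac = 0.2) {
  stopifnot(all(days > 0), start_frac > 0, end_frac > 0)
  frac <- ifelse(days <= peak_day,
                 start_frac + (1 - start_frac) *
                   (days - min(days)) / max(peak_day - min(days), 1),
                 1 + (end_frac - 1) *
                   (days - peak_day) / max(max(days) - peak_day, 1))
  stats::setNames(log(frac), days)
}

#' Configuration for the synthetic F1 fecundity panel
#'
#' Emulates a Mendelian-randomization F1 cross design: 10 homozygous
#' crosses per allele ("TT", "GG"), 18 heterozygous ("TG") crosses, 3
#' replicate vials per cross with 2 females each, and egg counts scored in
#' 24-h windows every third day from day 3 to day 30. Vial-day counts are
#' Poisson with a log-link mean combining a baseline, a genotype effect
#' with tunable dominance, a day curve, and lognormal cross- and
#' vial-level random effects that persist across days (the same vials are
#' followed) and supply overdispersion.
#'
#' The genotype effect is the log-scale increase of the "GG" class over
#' "TT"; the heterozygote sits at \code{dominance} times that effect
#' (\code{dominance = 1}: "G" fully dominant). Defaults give peak rates of
#' roughly 20-25 eggs per female per day and mimic the reported direction
#' of effect (higher laying with "G").
#'
#' @param n_crosses Named counts of crosses per F1 genotype.
#' @param vials_per_cross Replicate vials per cross (default 3).
#' @param females_per_vial Females per vial (default 2).
#' @param days Assay days (default \code{seq(3, 30, 3)}).
#' @param baseline_log_mean Log peak eggs/female/day of the "TT" class
#'   (default \code{log(22)}).
#' @param genotype_effect Log-scale "GG" minus "TT" effect (default
#'   \code{log(1.178)}, matching an 17.8\% higher rate).
#' @param dominance Dominance coefficient h of the "G" allele in \[0, 1\]
#'   (default 0.85).
#' @param day_effect Named numeric vector of log-scale day effects;
#'   default [default_day_curve()].
#' @param cross_sd,vial_sd Standard deviations of the lognormal cross- and
#'   vial-level random effects (log scale; defaults 0.15 and 0.10).
#' @param p Frequency of the "T" allele used when computing the
#'   generating-truth variance partition (default 0.68).
#' @return List of class \code{"f1_sim_config"}.
#' @export
f1_sim_config <- function(n_crosses = c(TT = 10, TG = 18, GG = 10),
                          vials_per_cross = 3, females_per_vial = 2,
                          days = seq(3, 30, 3),
                          baseline_log_mean = log(22),
                          genotype_effect = log(1.178),
                          dominance = 0.85,
                          day_effect = default_day_curve(days),
                          cross_sd = 0.15, vial_sd = 0.10,
                          p = 0.68) {
  stopifnot(all(c("TT", "TG", "GG") %in% names(n_crosses)),
            all(n_crosses >= 1), vials_per_cross >= 1,
            females_per_vial >= 1,
            cross_sd >= 0, vial_sd >= 0,
            dominance >= 0, dominance <= 1,
            length(day_effect) == length(days))
  structure(list(n_crosses = n_crosses[c("TT", "TG", "GG")],
                 vials_per_cross = vials_per_cross,
                 females_per_vial = females_per_vial,
                 days = as.integer(days),
                 baseline_log_mean = baseline_log_mean,
                 genotype_effect = genotype_effect,
                 dominance = dominance,
                 day_effect = day_effect,
                 cross_sd = cross_sd, vial_sd = vial_sd, p = p),
            class = "f1_sim_config")
}

genotype_log_effects <- function(cfg) {
  c(TT = 0, TG = cfg$dominance * cfg$genotype_effect,
    GG = cfg$genotype_effect)
}

#' Generating-truth variance partition of a simulation configuration
#'
#' Computes, in closed form, the per-day genotypic means and the variance
#' of a cross mean (vials averaged first) implied by the Poisson-lognormal
#' generating process, and from them the true per-day variance partition
#' via the Hardy-Weinberg population mean, the genotypic variance, the
#' pooled within-genotype variance (degrees-of-freedom weights at the
#' design sizes) and \eqn{t = V_G/(V_{within}+V_G)}. Truth is defined on
#' the cross-mean scale, the same scale on which the estimator operates,
#' so the within component includes the Poisson and vial-level sampling
#' contributions to cross-mean spread.
#'
#' @param cfg An [f1_sim_config()].
#' @return List: \code{per_day} (data frame with day, per-genotype means,
#'   V_G, V_within, t), \code{max_t}, \code{max_day}.
#' @export
true_decomposition <- function(cfg) {
  stopifnot(inherits(cfg, "f1_sim_config"))
  g_eff <- genotype_log_effects(cfg)
  fr <- allele_freqs(cfg$p)
  mc <- exp(cfg$cross_sd^2 / 2)
  mv <- exp(cfg$vial_sd^2 / 2)
  var_ec <- exp(cfg$cross_sd^2) * (exp(cfg$cross_sd^2) - 1)
  var_ev <- exp(cfg$vial_sd^2) * (exp(cfg$vial_sd^2) - 1)
  e2c <- exp(2 * cfg$cross_sd^2)
  V <- cfg$vials_per_cross
  nf <- cfg$females_per_vial
  n <- cfg$n_crosses
  rows <- lapply(seq_along(cfg$days), function(i) {
    lam <- exp(cfg$baseline_log_mean + g_eff + cfg$day_effect[i])
    mu <- lam * mc * mv
    var_c <- (lam * mv * mc / nf + lam^2 * var_ev * e2c) / V +
      (lam * mv)^2 * var_ec
    s <- genotypic_summary(c(AA = mu[["TT"]], Aa = mu[["TG"]],
                             aa = mu[["GG"]]),
                           n = c(AA = n[["TT"]], Aa = n[["TG"]],
                                 aa = n[["GG"]]),
                           s2 = c(AA = var_c[["TT"]], Aa = var_c[["TG"]],
                                  aa = var_c[["GG"]]))
    Vg <- genetic_variance_hw(s, fr)
    Vw <- pooled_within_variance(s)
    data.frame(day = cfg$days[i], mean_TT = mu[["TT"]],
               mean_TG = mu[["TG"]], mean_GG = mu[["GG"]],
               V_G = Vg, V_within = Vw,
               t = if (Vg == 0 && Vw == 0) NA_real_ else Vg / (Vg + Vw))
  })
  per_day <- do.call(rbind, rows)
  list(per_day = per_day,
       max_t = max(per_day$t, na.rm = TRUE),
       max_day = per_day$day[which.max(per_day$t)])
}

#' Calibrate the genotype effect to a target generating t
#'
#' Solves for the log-scale genotype effect such that the maximum-over-days
#' true intraclass correlation of [true_decomposition()] equals
#' \code{target_t}, holding all other configuration values fixed.
#'
#' @param cfg An [f1_sim_config()]; its \code{genotype_effect} is ignored.
#' @param target_t Target maximum-day t in \[0, 1).
#' @param upper Upper bound of the search interval (default 3 log units).
#' @return The configuration with the calibrated \code{genotype_effect}.
#' @export
calibrate_genotype_effect <- function(cfg, target_t, upper = 3) {
  stopifnot(inherits(cfg, "f1_sim_config"),
            target_t >= 0, target_t < 1)
  if (target_t == 0) {
    cfg$genotype_effect <- 0
    return(cfg)
  }
  f <- function(beta) {
    cfg$genotype_effect <- beta
    true_decomposition(cfg)$max_t - target_t
  }
  if (f(upper) < 0)
    stop("target t unattainable with genotype effect <= ", upper,
         call. = FALSE)
  cfg$genotype_effect <- stats::uniroot(f, c(0, upper),
                                        tol = 1e-10)$root
  cfg
}

#' Simulate an F1-cross egg-count table with known truth
#'
#' Draws vial-day egg counts from the Poisson-lognormal process described
#' in [f1_sim_config()] and attaches the generating-truth variance
#' partition of [true_decomposition()].
#'
#' @param cfg An [f1_sim_config()].
#' @param seed Integer seed; the same seed reproduces the table
#'   bit-identically.
#' @return List: \code{eggs} (long-format egg-count table with columns
#'   cross_id, genotype, vial_id, day, eggs, n_females) and \code{truth}
#'   (per-day truth record plus the configuration).
#' @export
simulate_f1_panel <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "f1_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  g_eff <- genotype_log_effects(cfg)
  rows <- list()
  for (g in names(cfg$n_crosses)) {
    for (cr in seq_len(cfg$n_crosses[[g]])) {
      cross_id <- sprintf("%s_%02d", g, cr)
      u_c <- stats::rnorm(1, 0, cfg$cross_sd)
      for (v in seq_len(cfg$vials_per_cross)) {
        u_v <- stats::rnorm(1, 0, cfg$vial_sd)
        lam <- cfg$females_per_vial *
          exp(cfg$baseline_log_mean + g_eff[[g]] + cfg$day_effect +
                u_c + u_v)
        rows[[length(rows) + 1L]] <- data.frame(
          cross_id = cross_id, genotype = g,
          vial_id = sprintf("%s_v%d", cross_id, v),
          day = cfg$days,
          eggs = stats::rpois(length(cfg$days), lam),
          n_females = cfg$females_per_vial,
          stringsAsFactors = FALSE)
      }
    }
  }
  eggs <- do.call(rbind, rows)
  rownames(eggs) <- NULL
  truth <- true_decomposition(cfg)
  truth$config <- cfg
  list(eggs = eggs, truth = truth)
}

#' Configuration for a synthetic inbred-line genotype panel
#'
#' Emulates the genomic structure probed by the F_ST confounder screen:
#' two sets of lines fixed for alternative alleles at the focal SNP, plus
#' background SNPs whose allele states are drawn independently per line
#' from a shared per-SNP frequency (so background differentiation between
#' the panels arises only from sampling). A fraction of background SNPs
#' can be forced to fixation for alternative alleles to test confounder
#' detection.
#'
#' @param n_lines_per_genotype Lines per focal genotype (default 20).
#' @param n_background_snps Number of background SNPs (default 1000).
#' @param freq_range Range of the shared background allele frequency,
#'   drawn uniformly per SNP (default \code{c(0.05, 0.95)}).
#' @param fraction_differentiated Fraction of background SNPs forced to
#'   fixation for alternative alleles between the panels (default 0).
#' @param het_rate,missing_rate Per-call probabilities of a residual
#'   heterozygous or missing call (defaults 0).
#' @param focal_locus Locus string of the focal SNP (default
#'   \code{"3L:18026199"}).
#' @return List of class \code{"panel_sim_config"}.
#' @export
panel_sim_config <- function(n_lines_per_genotype = 20,
                             n_background_snps = 1000,
                             freq_range = c(0.05, 0.95),
                             fraction_differentiated = 0,
                             het_rate = 0, missing_rate = 0,
                             focal_locus = "3L:18026199") {
  stopifnot(n_lines_per_genotype >= 1, n_background_snps >= 1,
            fraction_differentiated >= 0, fraction_differentiated <= 1,
            het_rate >= 0, missing_rate >= 0)
  structure(list(n_lines_per_genotype = n_lines_per_genotype,
                 n_background_snps = n_background_snps,
                 freq_range = freq_range,
                 fraction_differentiated = fraction_differentiated,
                 het_rate = het_rate, missing_rate = missing_rate,
                 focal_locus = focal_locus),
            class = "panel_sim_config")
}

#' Simulate an inbred-line genotype panel
#'
#' @param cfg A [panel_sim_config()].
#' @param seed Integer seed.
#' @return A [panel_genotypes()] with extra elements
#'   \code{panel1_lines} (fixed "T"/ref at the focal SNP) and
#'   \code{panel2_lines} (fixed "G"/alt).
#' @export
simulate_genotype_panel <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  nL <- cfg$n_lines_per_genotype
  lines1 <- sprintf("T_line%02d", seq_len(nL))
  lines2 <- sprintf("G_line%02d", seq_len(nL))
  n_snp <- cfg$n_background_snps + 1L
  arms <- c("X", "2L", "2R", "3L", "3R")
  chrom <- sample(arms, n_snp, replace = TRUE)
  pos <- sample.int(2.4e7, n_snp)
  focal_parts <- strsplit(cfg$focal_locus, ":")[[1]]
  chrom[1] <- focal_parts[1]
  pos[1] <- as.integer(focal_parts[2])
  ref <- sample(c("A", "C", "G", "T"), n_snp, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  ref[1] <- "T"; alt[1] <- "G"

  n_diff <- round(cfg$fraction_differentiated * cfg$n_background_snps)
  diff_idx <- if (n_diff > 0) 1L + sample.int(cfg$n_background_snps,
                                              n_diff) else integer(0)
  freq <- stats::runif(n_snp, cfg$freq_range[1], cfg$freq_range[2])
  calls <- matrix(NA_character_, nrow = 2L * nL, ncol = n_snp,
                  dimnames = list(c(lines1, lines2), NULL))
  for (j in seq_len(n_snp)) {
    if (j == 1L) {
      calls[lines1, j] <- "ref"
      calls[lines2, j] <- "alt"
    } else if (j %in% diff_idx) {
      calls[lines1, j] <- "ref"
      calls[lines2, j] <- "alt"
    } else {
      calls[, j] <- ifelse(stats::runif(2L * nL) < freq[j], "alt", "ref")
    }
  }
  if (cfg$het_rate > 0) {
    flip <- matrix(stats::runif(length(calls)) < cfg$het_rate,
                   nrow(calls))
    flip[, 1] <- FALSE  # keep the focal SNP clean
    calls[flip] <- "het"
  }
  if (cfg$missing_rate > 0) {
    drop <- matrix(stats::runif(length(calls)) < cfg$missing_rate,
                   nrow(calls))
    drop[, 1] <- FALSE
    calls[drop] <- NA
  }
  panel <- panel_genotypes(calls, chrom, pos, ref, alt, focal = 1L)
  panel$panel1_lines <- lines1
  panel$panel2_lines <- lines2
  panel
}

#' Simulate a qPCR Cq table with a known knockdown
#'
#' Target-gene Cq values of treated samples are shifted upward by
#' \eqn{\log_2(1/(1 - \mathrm{knockdown}))} cycles relative to controls
#' (so the recovered relative expression is \code{1 - knockdown} at 100\%
#' efficiency); reference genes are unshifted. Gaussian technical noise is
#' added per replicate, and an optional set of sample-gene triples
#' receives one outlier replicate (+1 cycle) to exercise replicate QC.
#'
#' @param knockdown_fraction Fractional reduction of target expression in
#'   treated samples, in \[0, 1).
#' @param n_samples Biological samples per treatment group (default 10).
#' @param noise_sd Technical-replicate Gaussian noise sd in cycles
#'   (default 0.05).
#' @param seed Integer seed.
#' @param treatments Treatment labels; the first is the control
#'   (default \code{c("0", "200")}, mifepristone in ug/ml).
#' @param target_gene,reference_genes Gene names (defaults: target
#'   "Eip75B"; references TBP, Cyp1, Ef1a48D, Rap2l).
#' @param outlier_rate Fraction of sample-gene triples given an outlier
#'   replicate (default 0).
#' @return Cq table (sample, treatment, gene, rep1..rep3) with attributes
#'   \code{"truth"} (knockdown fraction) and \code{"outliers"} (data frame
#'   of injected outlier triples).
#' @export
simulate_cq_table <- function(knockdown_fraction, n_samples = 10,
                              noise_sd = 0.05, seed = NULL,
                              treatments = c("0", "200"),
                              target_gene = "Eip75B",
                              reference_genes = c("TBP", "Cyp1",
                                                  "Ef1a48D", "Rap2l"),
                              outlier_rate = 0) {
  stopifnot(knockdown_fraction >= 0, knockdown_fraction < 1,
            n_samples >= 1, noise_sd >= 0, length(treatments) >= 2)
  if (!is.null(seed)) set.seed(seed)
  genes <- c(target_gene, reference_genes)
  base_cq <- stats::setNames(
    c(24, stats::runif(length(reference_genes), 19, 23)), genes)
  shift <- log2(1 / (1 - knockdown_fraction))
  grid <- expand.grid(sample_i = seq_len(n_samples),
                      treatment = treatments, gene = genes,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_s%02d", grid$treatment, grid$sample_i)
  cq0 <- base_cq[grid$gene] +
    ifelse(grid$gene == target_gene & grid$treatment != treatments[1],
           shift, 0)
  reps <- matrix(stats::rnorm(3 * nrow(grid), mean = rep(cq0, 3),
                              sd = noise_sd), ncol = 3)
  out_idx <- which(stats::runif(nrow(grid)) < outlier_rate)
  if (length(out_idx)) reps[out_idx, 3] <- reps[out_idx, 3] + 1.0
  tab <- data.frame(sample = grid$sample, treatment = grid$treatment,
                    gene = grid$gene, rep1 = reps[, 1], rep2 = reps[, 2],
                    rep3 = reps[, 3], stringsAsFactors = FALSE)
  attr(tab, "truth") <- list(knockdown = knockdown_fraction,
                             expected_expression = 1 - knockdown_fraction)
  attr(tab, "outliers") <- grid[out_idx, c("sample", "gene")]
  tab
}
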