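---
title: "Partitioning trait variance at a single SNP in F1 cross panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning trait variance at a single SNP in F1 cross panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelvar)
```

## The problem

A candidate SNP — here a regulatory variant near a nuclear-hormone-receptor
gene in *Drosophila melanogaster*, with alleles labelled "T" and "G" — has
been associated with a fitness trait (daily fecundity). Two questions follow.
First, is the association causal, or does it ride on other loci that differ
between the carriers of the two alleles? Second, if it is causal, how much of
the observed trait variance does the single nucleotide explain?

`mendelvar` implements the analysis chain for a Mendelian-randomization
panel design that answers both: F1 crosses of inbred lines chosen so that
the focal SNP's genotype ("TT", "TG", "GG") varies across many randomized
genetic backgrounds, a genomic screen for confounding background loci, and a
variance-partition estimator of the SNP's proportional contribution.

## The variance partition

For a biallelic locus with "T"-allele frequency $p$ and $q = 1 - p$, the
population mean of the genotypic values $\bar{AA}, \bar{Aa}, \bar{aa}$
(the class means of "TT", "TG", "GG") under Hardy–Weinberg proportions is

$$M = p^2\,\bar{AA} + 2pq\,\bar{Aa} + q^2\,\bar{aa},$$

and the genetic variance attributable to the locus is

$$V_G = p^2(\bar{AA}-M)^2 + 2pq(\bar{Aa}-M)^2 + q^2(\bar{aa}-M)^2.$$

Expected, never observed, genotype frequencies are used: an F1 panel
deliberately over-represents rare classes, so its class counts say nothing
about population frequencies. The default $p = 0.68$ is the "T" frequency
in the experimentally evolved populations from which the candidate locus
was identified; it is a user parameter, not an estimate made by this
package.

The spread of replicate units (crosses) within a genotype class is pooled
with degrees-of-freedom weights,

$$V_{within} = \frac{\sum_g (n_g - 1)s_g^2}{\sum_g (n_g - 1)},$$

and the proportional contribution of the locus — the intraclass correlation,
in the isofemale-line literature the "isofemale heritability" — is

$$t = \frac{V_G}{V_{within} + V_G} \in [0, 1].$$

`isoherit()` computes this partition for every assay day of an egg-count
table and reports the per-day profile and its maximum over days (the
"explains up to x%" statistic), under two estimators of $V_G$:

* `hw_weighted` — the Hardy–Weinberg-weighted expression above, evaluated
  at the sample class means;
* `random_effects` — the one-way method-of-moments (ANOVA) variance
  component treating genotype as a random grouping of cross means,
  $\hat\sigma^2_G = (MS_b - MS_w)/n_0$ with the usual unbalanced-design
  $n_0$.

The two are different functionals of the three class means. The
Hardy–Weinberg form weights classes by $p^2, 2pq, q^2$ (0.46/0.44/0.10 at
$p = 0.68$), the random-effects form treats the three classes as
exchangeable. Under dominance geometries they differ by roughly 25–35%,
with the random-effects component the larger; both are reported per day
rather than privileging one, and they rank days identically.

### Sampling-error correction

Class means estimated from $n_g$ crosses carry sampling variance
$V_{within}/n_g$, which inflates the plug-in $V_G$ by
$\sum_g w_g(1-w_g)\,V_{within}/n_g$ in expectation — about $0.05\,V_{within}$
at the default panel size (10/18/10 crosses), enough to push an estimated
$t$ from 0.135 to ~0.17. `isoherit(correct_sampling = TRUE)` (the default)
subtracts this inflation and truncates negative results at zero (flagged in
the output). `genetic_variance_hw()` itself stays the uncorrected textbook
expression so that the algebra is exactly reproducible. Simulation at the
design size shows the corrected estimator recovers the generating $t$ at a
fixed day essentially without bias (the test suite verifies a mean error
below 0.03 over 100 replicate panels).

### The maximum-over-days statistic

The "up to" statistic is a maximum of ten noisy per-day estimates. With
three genotype classes the between-class mean square has two degrees of
freedom, so each per-day estimate is noisy even when unbiased, and the
maximum selects on that noise. At the default design size the mean
estimated maximum-day $t$ exceeds the generating value by roughly +0.07
regardless of the estimator — a property of the statistic, not of an
implementation. Readers of the per-day profile should treat the maximum as
descriptive; the bootstrap utility (`confint()`, resampling crosses with
replacement within class) conveys its spread. No analytic correction for
the max-selection is attempted.

### Replicate units and other choices

* Vials are averaged within cross before crosses are averaged within
  class, so unequal vial survival does not reweight crosses; the cross is
  the independent unit (it is the unit of randomization). Vial-level
  analysis is available via `unit = "vial"`.
* Sample variances use $n-1$ denominators throughout.
* Days missing a genotype class are skipped with a warning; a day with
  $V_G = 0$ reports $t = 0$ even when $V_{within}$ is also degenerate.
* "Total eggs per female" sums per-female rates over the scored 24-h
  windows only; no interpolation between assay days.
* No mixed-model hypothesis tests, Tukey contrasts or survival fits are
  performed — only descriptive effect sizes and variance components.

## The confounder screen

`fst_scan()` computes SNP-wise $F_{ST}$ between the pooled genomes of the
two homozygous panels using the Weir–Cockerham two-population
$\hat\theta = a/(a+b+c)$ (1984 parameterization). Each fully inbred line
contributes one individual with heterozygosity zero and two allele copies;
residual heterozygous calls are excluded from pooling (and tallied), not
split. A SNP fixed for alternative alleles between the panels gives
exactly 1; negative estimates are clamped to 0 for reporting, with the raw
value retained. Hudson's estimator is available behind
`method = "hudson"` for sensitivity. SNPs monomorphic across both pools
are undefined and excluded from the scan denominator.

Linkage disequilibrium uses inbred lines as haplotypes:
$r^2 = D^2 / (p_i(1-p_i)p_j(1-p_j))$ over the shared homozygous,
non-missing lines. Monomorphic SNPs are flagged undefined rather than
zero. The confounder report lists SNPs with clamped $F_{ST}$ above 0.5
(configurable) and verifies that the focal SNP is the *unique* fixed SNP;
"strong LD" is flagged at $r^2 \ge 0.5$ by default, a conventional
threshold since none is dictated by the design. Coordinates are 1-based
with chromosome-arm naming (e.g. `3L:18026199`, genome release 6); VCF
input is read as-is with no liftover.

## The qPCR chain

Technical triplicates are accepted when no replicate, or exactly one,
differs by more than 0.5 Cq from *both* other replicates (the only reading
under which exactly one replicate of a triple can be divergent); a single
divergent value is dropped, anything worse fails QC. Comparisons carry a
$10^{-8}$-cycle guard so borderline differences are classified by their
decimal value rather than binary float error. Kept replicates are averaged
on the Cq scale. Relative quantities use the $E^{\Delta Cq}$ transform
with efficiency 2.0 (100%) by default, configurable per gene; the
per-sample normalization factor is the geometric mean over the reference
genes, and expression is scaled so the control group's mean is 1.
Reference-gene stability is the GeNorm $M$: the mean over partner genes of
the SD across samples of the pairwise $\log_2$ ratio.

## The synthetic-data generator

`simulate_f1_panel()` generates the full study design: 10 "TT", 18 "TG"
and 10 "GG" crosses, 3 vials per cross, 2 females per vial, counts scored
every third day from day 3 to 30. Vial-day counts are Poisson with
log-link mean

$$\log \mu = \log(\text{females}) + \mu_0 + g(\text{genotype}) +
  d(\text{day}) + u_{cross} + u_{vial},$$

with $g = 0,\ h\beta,\ \beta$ for TT/TG/GG and lognormal random effects
that persist across days (the same physical vials are followed), supplying
overdispersion beyond Poisson. Defaults, chosen once as realistic for fly
fecundity assays and not revisited: peak baseline $e^{\mu_0} = 22$
eggs/female/day; $\beta = \log 1.178$ (a 17.8% "GG" advantage);
dominance $h = 0.85$ (from the ratio of the reported heterozygote and
homozygote advantages, consistent with near-complete dominance of "G");
day curve rising linearly from 60% of peak at day 3 to the peak at day 9,
declining to 20% at day 30; $\sigma_{cross} = 0.15$ and
$\sigma_{vial} = 0.10$ on the log scale. A negative-binomial option is
not needed because the lognormal effects already overdisperse the counts.

Each simulated panel carries a truth record: closed-form per-day class
means and cross-mean variances of the generating process (Poisson + vial +
cross components propagated through the vials-first averaging), combined
through the same $M$, $V_G$, $V_{within}$, $t$ algebra as the estimator.
Truth is therefore defined on the cross-mean scale the estimator operates
on, not on the latent log scale. `calibrate_genotype_effect()` inverts
this map ($t$ is monotone in $\beta$) so panels can be generated with a
prescribed maximum-day $t$; the test suite uses generating
$t \in \{0, 0.05, 0.135, 0.30\}$.

What the generator does *not* emulate: day-to-day environmental shocks
shared across vials, age-dependent changes in the genotype effect,
mortality of females during the assay (per-female denominators are fixed),
and linkage between the focal SNP and background loci. Passing
parameter-recovery tests on these simulations therefore demonstrates
estimator correctness under the stated noise model, not robustness to
those real-data complications.

`simulate_genotype_panel()` builds the genomic side: two sets of 20 lines
fixed for alternative focal alleles, background SNPs drawn per line from a
shared per-SNP frequency (uniform on 0.05–0.95), optional forced-fixation
SNPs to exercise confounder detection, and optional residual-heterozygosity
and missingness injection. `simulate_cq_table()` shifts treated-sample
target Cq by $\log_2 1/(1-\text{knockdown})$ so the configured knockdown is
recovered exactly at zero noise, and can inject single-replicate outliers
to exercise QC.

All generators take an explicit integer seed and are bit-reproducible for
a given seed.

## Problem sizes used by the test suite

Monte-Carlo checks run at sizes chosen to keep the default suite fast while
leaving comfortable noise margins: 200 replicate panels per generating $t$
for the maximum-day recovery study, 100 for the fixed-day recovery study,
500–1000 random inputs for the estimator-vs-oracle property tests, 250–500
crosses per class for convergence checks of the truth record, and the full
9261-triple grid for the qPCR QC rule.

## Limitations

* The maximum-over-days $t$ is upward-biased at small panel sizes (see
  above); per-day estimates at a pre-specified day are unbiased after the
  sampling correction.
* $p$ and $q$ are inputs; mis-specifying them changes $V_G$ through the
  class weights.
* The F1 design estimates the locus contribution among *cross means*;
  this is not narrow-sense heritability in an outbred population.
* The random-effects variance component rests on three genotype classes —
  two between-class degrees of freedom — and is correspondingly noisy; it
  is reported alongside, not instead of, the Hardy–Weinberg form.
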