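# Shared fixtures built in code.

# The worked-example genotypic summary used across the quantgen tests.
example_summary <- function() {
  genotypic_summary(c(TT = 10, TG = 12, GG = 12),
                    n = c(TT = 10, TG = 18, GG = 10),
                    s2 = c(TT = 2, TG = 3, GG = 4))
}

# Minimal single-cross egg table.
tiny_egg_table <- function() {
  data.frame(cross_id = "c1", genotype = "TT", vial_id = "v1",
             day = c(3, 6), eggs = c(10, 6), n_females = 2,
             stringsAsFactors = FALSE)
}

# Independent brute-force expectation oracle over the three genotypic
# states: treats the locus as a discrete random variable with HW
# probabilities and computes E[(G - E[G])^2] generically.
expectation_oracle <- function(means, p) {
  probs <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  mu <- sum(probs * means)
  list(mean = mu, var = sum(probs * (means - mu)^2))
}

# Independent Weir & Cockerham (1984) two-population component oracle,
# written from the per-population sums (different arrangement from the
# package internals). n1, n2 in individuals; h = 0 (inbred lines).
wc_oracle <- function(p1, p2, n1, n2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
  a / (a + b)
}

# Small two-genotype-class panel: n lines fixed ref at the focal SNP and
# n fixed alt, with a handful of background SNPs supplied as a call
# matrix column list.
toy_panel <- function(background = list()) {
  n <- 4L
  lines <- c(sprintf("T%02d", 1:n), sprintf("G%02d", 1:n))
  calls <- cbind(c(rep("ref", n), rep("alt", n)))
  for (bg in background) calls <- cbind(calls, bg)
  rownames(calls) <- lines
  k <- ncol(calls)
  panel_genotypes(calls, chrom = rep("3L", k),
                  pos = 18026199L + seq_len(k) - 1L,
                  ref = rep("T", k), alt = rep("G", k), focal = 1L)
}
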