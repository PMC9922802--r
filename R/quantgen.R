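#' Allele frequencies at a biallelic locus
#'
#' Constructs and validates the pair of allele frequencies used to weight
#' genotypic values under Hardy-Weinberg expectations. By convention the
#' first allele (frequency \code{p}) is the "A" allele; for the fecundity
#' panel this is the "T" variant, with \code{p = 0.68} taken from the
#' evolve-and-resequence populations the candidate SNP came from.
#'
#' @param p Frequency of the A ("T") allele, in \[0, 1\].
#' @param q Frequency of the a ("G") allele; defaults to \code{1 - p}.
#' @return An object of class \code{"allele_freqs"}: a list with elements
#'   \code{p} and \code{q}.
#' @examples
#' allele_freqs(0.68)
#' @export
allele_freqs <- function(p, q = 1 - p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("'p' must be a single frequency in [0, 1]", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("'q' must be a single frequency in [0, 1]", call. = FALSE)
  if (abs(p + q - 1) > 1e-12)
    stop("allele frequencies must satisfy p + q = 1 (got p + q = ",
         format(p + q, digits = 15), ")", call. = FALSE)
  structure(list(p = p, q = q), class = "allele_freqs")
}

#' @method print allele_freqs
#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("Biallelic locus: p(A) = %.4f, q(a) = %.4f\n", x$p, x$q))
  invisible(x)
}

GENOTYPES <- c("AA", "Aa", "aa")

# Map panel genotype labels (TT/TG/GG) onto AA/Aa/aa. A = "T", a = "G".
normalize_genotype <- function(g) {
  g <- as.character(g)
  map <- c(TT = "AA", TG = "Aa", GT = "Aa", GG = "aa",
           AA = "AA", Aa = "Aa", aA = "Aa", aa = "aa")
  out <- unname(map[g])
  if (anyNA(out))
    stop("unknown genotype label(s): ",
         paste(unique(g[is.na(out)]), collapse = ", "),
         "; valid labels are TT, TG, GG (or AA, Aa, aa)", call. = FALSE)
  out
}

#' Per-genotype trait summary
#'
#' Holds, for each genotype class AA/Aa/aa, the genotypic value (mean trait
#' of independent units, e.g. eggs per female per day averaged over the
#' crosses of that class), the number of units, and the sample variance of
#' the unit means (n - 1 denominator).
#'
#' @param mean Named numeric vector of genotypic values; names must be
#'   AA/Aa/aa (or TT/TG/GG).
#' @param n Named integer vector of unit counts per class.
#' @param s2 Named numeric vector of sample variances of unit means; may be
#'   \code{NA} for classes with fewer than two units.
#' @return An object of class \code{"genotypic_summary"}: a data frame with
#'   one row per genotype class and columns \code{genotype}, \code{mean},
#'   \code{n}, \code{s2}.
#' @seealso [summarize_genotypes()] to build one from raw unit means.
#' @export
genotypic_summary <- function(mean, n, s2) {
  if (is.logical(s2) && all(is.na(s2))) s2 <- as.numeric(s2)
  stopifnot(is.numeric(mean), is.numeric(n), is.numeric(s2))
  gm <- normalize_genotype(names(mean))
  if (is.null(names(n))) names(n) <- names(mean)
  if (is.null(names(s2))) names(s2) <- names(mean)
  gn <- normalize_genotype(names(n))
  gs <- normalize_genotype(names(s2))
  out <- data.frame(genotype = gm, mean = unname(mean),
                    n = unname(n)[match(gm, gn)],
                    s2 = unname(s2)[match(gm, gs)],
                    stringsAsFactors = FALSE)
  out <- out[match(intersect(GENOTYPES, out$genotype), out$genotype), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (any(out$n < 0)) stop("unit counts must be non-negative", call. = FALSE)
  if (any(!is.na(out$s2) & out$s2 < 0))
    stop("sample variances must be non-negative", call. = FALSE)
  bad <- !is.na(out$s2) & out$n < 2
  if (any(bad))
    stop("s2 is defined only for classes with n >= 2 (offending: ",
         paste(out$genotype[bad], collapse = ", "), ")", call. = FALSE)
  class(out) <- c("genotypic_summary", "data.frame")
  out
}

#' Summarize unit means by genotype class
#'
#' @param unit_means Named list mapping genotype labels (TT/TG/GG or
#'   AA/Aa/aa) to numeric vectors of independent unit means (one value per
#'   cross or line).
#' @return A [genotypic_summary()].
#' @export
summarize_genotypes <- function(unit_means) {
  stopifnot(is.list(unit_means), length(unit_means) >= 1)
  m <- vapply(unit_means, mean, numeric(1))
  n <- vapply(unit_means, length, integer(1))
  s2 <- vapply(unit_means, function(x)
    if (length(x) >= 2) stats::var(x) else NA_real_, numeric(1))
  genotypic_summary(stats::setNames(m, names(unit_means)),
                    stats::setNames(n, names(unit_means)),
                    stats::setNames(s2, names(unit_means)))
}

hw_weights <- function(freqs) {
  c(AA = freqs$p^2, Aa = 2 * freqs$p * freqs$q, aa = freqs$q^2)
}

require_all_classes <- function(summary) {
  missing <- setdiff(GENOTYPES, summary$genotype)
  if (length(missing))
    stop("genotype class(es) missing from summary: ",
         paste(missing, collapse = ", "), call. = FALSE)
  m <- summary$mean[match(GENOTYPES, summary$genotype)]
  if (any(!is.finite(m)))
    stop("all three genotypic means must be finite", call. = FALSE)
  stats::setNames(m, GENOTYPES)
}

#' Population mean of a biallelic locus
#'
#' The mean genotypic value of a population in Hardy-Weinberg proportions:
#' \deqn{M = p^2 \bar{AA} + 2pq \bar{Aa} + q^2 \bar{aa}.}
#' Expected (not observed) genotype frequencies are always used, because F1
#' cross panels deliberately over-represent some classes and do not reflect
#' population genotype frequencies.
#'
#' @param summary A [genotypic_summary()] with all three classes.
#' @param freqs An [allele_freqs()] object.
#' @return The population mean, in trait units.
#' @examples
#' s <- genotypic_summary(c(TT = 10, TG = 12, GG = 12),
#'                        n = c(TT = 10, TG = 18, GG = 10),
#'                        s2 = c(TT = 2, TG = 3, GG = 4))
#' population_mean(s, allele_freqs(0.68))  # 11.0752
#' @export
population_mean <- function(summary, freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  m <- require_all_classes(summary)
  sum(hw_weights(freqs) * m)
}

#' Genetic variance attributable to the locus (Hardy-Weinberg weighting)
#'
#' The variance of genotypic values about the population mean, weighted by
#' expected Hardy-Weinberg genotype frequencies:
#' \deqn{V_G = p^2 (\bar{AA}-M)^2 + 2pq (\bar{Aa}-M)^2 + q^2 (\bar{aa}-M)^2.}
#'
#' @inheritParams population_mean
#' @return The genetic variance, in squared trait units.
#' @examples
#' s <- genotypic_summary(c(TT = 10, TG = 12, GG = 12),
#'                        n = c(TT = 10, TG = 18, GG = 10),
#'                        s2 = c(TT = 2, TG = 3, GG = 4))
#' genetic_variance_hw(s, allele_freqs(0.68))  # 0.99434496
#' @export
genetic_variance_hw <- function(summary, freqs) {
  stopifnot(inherits(freqs, "allele_freqs"))
  m <- require_all_classes(summary)
  M <- sum(hw_weights(freqs) * m)
  sum(hw_weights(freqs) * (m - M)^2)
}

#' Between-genotype variance component by one-way random effects
#'
#' Method-of-moments (ANOVA) estimator of the variance among genotype-class
#' effects, treating genotype as a random grouping of independent unit
#' means: \eqn{\hat\sigma^2_G = (MS_{between} - MS_{within}) / n_0}, with
#' \eqn{n_0 = (N - \sum_g n_g^2 / N) / (k - 1)} for unbalanced groups.
#' Negative estimates are truncated to zero (and flagged via the
#' \code{"truncated"} attribute).
#'
#' @param unit_means Named list mapping genotype labels to numeric vectors
#'   of unit means; at least two classes with at least two units each.
#' @return Variance component estimate (squared trait units), with
#'   attributes \code{ms_within}, \code{ms_between}, \code{n0},
#'   \code{truncated}.
#' @export
genetic_variance_ranef <- function(unit_means) {
  stopifnot(is.list(unit_means))
  unit_means <- unit_means[vapply(unit_means, length, 0L) >= 1L]
  k <- length(unit_means)
  if (k < 2L)
    stop("need at least two genotype classes with data", call. = FALSE)
  n <- vapply(unit_means, length, integer(1))
  if (all(n < 2L))
    stop("all genotype classes are singletons; within-class mean square ",
         "is undefined", call. = FALSE)
  N <- sum(n)
  y <- unlist(unit_means, use.names = FALSE)
  g <- rep(seq_len(k), n)
  gm <- tapply(y, g, mean)
  grand <- mean(y)
  ss_b <- sum(n * (gm - grand)^2)
  ss_w <- sum((y - gm[g])^2)
  ms_b <- ss_b / (k - 1)
  ms_w <- ss_w / (N - k)
  n0 <- (N - sum(n^2) / N) / (k - 1)
  raw <- (ms_b - ms_w) / n0
  structure(max(0, raw),
            ms_within = ms_w, ms_between = ms_b, n0 = n0,
            raw = raw, truncated = raw < 0)
}

#' Pooled within-genotype variance
#'
#' The variance among unit (cross/line) means within each genotype class,
#' pooled across classes with degrees-of-freedom weights:
#' \deqn{V_{within} = \sum_g (n_g - 1) s_g^2 / \sum_g (n_g - 1).}
#' Classes with fewer than two units carry no information about within-class
#' variance and are excluded with a warning.
#'
#' @param summary A [genotypic_summary()].
#' @return Pooled within-genotype variance, in squared trait units.
#' @examples
#' s <- genotypic_summary(c(TT = 10, TG = 12, GG = 12),
#'                        n = c(TT = 10, TG = 18, GG = 10),
#'                        s2 = c(TT = 2, TG = 3, GG = 4))
#' pooled_within_variance(s)  # 3
#' @export
pooled_within_variance <- function(summary) {
  ok <- summary$n >= 2 & !is.na(summary$s2)
  if (!any(ok))
    stop("no genotype class has n >= 2; pooled within-genotype variance ",
         "is undefined", call. = FALSE)
  if (any(!ok))
    warning("excluding class(es) with n < 2 from pooling: ",
            paste(summary$genotype[!ok], collapse = ", "), call. = FALSE)
  w <- summary$n[ok] - 1
  sum(w * summary$s2[ok]) / sum(w)
}

#' Intraclass correlation ("isofemale heritability")
#'
#' The proportion of the total variance among unit means attributable to
#' the locus: \eqn{t = V_G / (V_{within} + V_G)}.
#'
#' @param V_G Genetic variance (>= 0).
#' @param V_within Pooled within-genotype variance (>= 0).
#' @return \code{t} in \[0, 1\].
#' @examples
#' intraclass_correlation(0.994, 6.370)  # ~0.135
#' @export
intraclass_correlation <- function(V_G, V_within) {
  stopifnot(is.numeric(V_G), is.numeric(V_within))
  if (V_G < 0 || V_within < 0)
    stop("variance components must be non-negative", call. = FALSE)
  if (V_G == 0 && V_within == 0)
    stop("t is undefined when both variance components are zero",
         call. = FALSE)
  V_G / (V_within + V_G)
}

# Expected inflation of the Hardy-Weinberg-weighted plug-in V_G caused by
# sampling error of the class means: sum_g w_g (1 - w_g) * V_within / n_g.
# Subtracting it gives an (approximately) unbiased V_G when class means are
# estimated from finitely many crosses.
vg_sampling_inflation <- function(summary, freqs, V_within) {
  w <- hw_weights(freqs)[match(summary$genotype, GENOTYPES)]
  sum(w * (1 - w) * V_within / summary$n)
}
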