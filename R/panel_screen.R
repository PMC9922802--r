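#' Inbred-line genotype panel
#'
#' A line-by-SNP matrix of allele calls for a panel of inbred lines, with
#' one SNP annotated as the focal candidate. Calls are coded
#' \code{"ref"}, \code{"alt"}, \code{"het"} or \code{NA} (missing). Inbred
#' lines are expected homozygous; residual heterozygous calls are reported
#' and excluded from pooling.
#'
#' @param calls Character matrix (lines x SNPs) with entries
#'   ref/alt/het/NA; rownames are line ids.
#' @param chrom Character vector of chromosome arms, one per SNP.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Reference/alternative allele bases per SNP.
#' @param focal Index (or \code{"arm:pos"} locus string) of the focal SNP.
#' @return An object of class \code{"panel_genotypes"}.
#' @export
panel_genotypes <- function(calls, chrom, pos, ref, alt, focal) {
  stopifnot(is.matrix(calls), length(chrom) == ncol(calls),
            length(pos) == ncol(calls), length(ref) == ncol(calls),
            length(alt) == ncol(calls))
  bad <- !(calls %in% c("ref", "alt", "het") | is.na(calls))
  if (any(bad))
    stop("invalid call code(s): ",
         paste(unique(calls[bad]), collapse = ", "),
         "; use ref/alt/het/NA", call. = FALSE)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("line", seq_len(nrow(calls)))
  locus <- paste0(chrom, ":", pos)
  colnames(calls) <- locus
  if (is.character(focal)) {
    idx <- match(focal, locus)
    if (is.na(idx))
      stop("focal SNP ", focal, " not present in the panel", call. = FALSE)
    focal <- idx
  }
  stopifnot(focal >= 1, focal <= ncol(calls))
  het_rate <- colMeans(calls == "het", na.rm = TRUE)
  structure(list(calls = calls, chrom = chrom, pos = as.integer(pos),
                 ref = ref, alt = alt, locus = locus,
                 focal = as.integer(focal), het_rate = het_rate),
            class = "panel_genotypes")
}

#' @method print panel_genotypes
#' @export
print.panel_genotypes <- function(x, ...) {
  cat(sprintf("Inbred-line genotype panel: %d lines x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  focal SNP: %s (%s/%s)\n", x$locus[x$focal],
              x$ref[x$focal], x$alt[x$focal]))
  cat(sprintf("  mean residual het rate: %.4f\n", mean(x$het_rate)))
  invisible(x)
}

focal_genotype <- function(panel, line) {
  g <- panel$calls[line, panel$focal]
  ifelse(is.na(g), NA,
         c(ref = "TT", alt = "GG", het = "het")[g])
}

#' Design an F1 Mendelian-randomization cross panel
#'
#' Draws parent pairs from lines homozygous at the focal SNP: homozygous
#' crosses pair two distinct lines of the same focal genotype, heterozygous
#' crosses pair a "T" line with a "G" line. No line is used twice within a
#' panel of homozygous crosses, mirroring designs in which each of the
#' twenty lines per allele contributes to exactly one cross. The focal-SNP
#' reference allele is labelled "T" and the alternative "G".
#'
#' @param panel A [panel_genotypes()].
#' @param n_hom_per_allele Number of homozygous crosses per allele
#'   (default 10).
#' @param n_het Number of heterozygous crosses (default 18).
#' @param seed Integer seed making the draw reproducible.
#' @return Data frame of class \code{"cross_design"}: mother_line,
#'   father_line, expected_f1_genotype.
#' @export
design_crosses <- function(panel, n_hom_per_allele = 10, n_het = 18,
                           seed = NULL) {
  stopifnot(inherits(panel, "panel_genotypes"))
  if (!is.null(seed)) set.seed(seed)
  g <- panel$calls[, panel$focal]
  t_lines <- rownames(panel$calls)[!is.na(g) & g == "ref"]
  g_lines <- rownames(panel$calls)[!is.na(g) & g == "alt"]
  need_t <- 2 * n_hom_per_allele
  need_g <- 2 * n_hom_per_allele
  if (length(t_lines) < need_t)
    stop("need ", need_t, " homozygous 'T' lines, have ", length(t_lines),
         call. = FALSE)
  if (length(g_lines) < need_g)
    stop("need ", need_g, " homozygous 'G' lines, have ", length(g_lines),
         call. = FALSE)
  t_draw <- sample(t_lines, need_t)
  g_draw <- sample(g_lines, need_g)
  hom_t <- data.frame(mother_line = t_draw[seq_len(n_hom_per_allele)],
                      father_line = t_draw[n_hom_per_allele +
                                             seq_len(n_hom_per_allele)],
                      expected_f1_genotype = "TT",
                      stringsAsFactors = FALSE)
  hom_g <- data.frame(mother_line = g_draw[seq_len(n_hom_per_allele)],
                      father_line = g_draw[n_hom_per_allele +
                                             seq_len(n_hom_per_allele)],
                      expected_f1_genotype = "GG",
                      stringsAsFactors = FALSE)
  het <- data.frame(
    mother_line = sample(t_lines, n_het, replace = n_het > length(t_lines)),
    father_line = sample(g_lines, n_het, replace = n_het > length(g_lines)),
    expected_f1_genotype = "TG", stringsAsFactors = FALSE)
  out <- rbind(hom_t, hom_g, het)
  out$cross_id <- sprintf("%s_%02d", out$expected_f1_genotype,
                          stats::ave(seq_len(nrow(out)),
                                     out$expected_f1_genotype,
                                     FUN = seq_along))
  class(out) <- c("cross_design", "data.frame")
  out
}

#' Pool allele counts across a subset of inbred lines
#'
#' Each homozygous line contributes two copies of its allele; heterozygous
#' and missing calls are excluded and tallied, so
#' \code{ref + alt + excluded = 2 * length(lines)} at every SNP.
#'
#' @param panel A [panel_genotypes()].
#' @param lines Character vector of line ids (non-empty).
#' @return Data frame: chrom, pos, ref_count, alt_count, excluded,
#'   missing (TRUE when no line has a call).
#' @export
pool_allele_counts <- function(panel, lines) {
  stopifnot(inherits(panel, "panel_genotypes"), length(lines) >= 1)
  unknown <- setdiff(lines, rownames(panel$calls))
  if (length(unknown))
    stop("line(s) not in panel: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sub <- panel$calls[lines, , drop = FALSE]
  ref_count <- colSums(sub == "ref", na.rm = TRUE) * 2L
  alt_count <- colSums(sub == "alt", na.rm = TRUE) * 2L
  excluded <- 2L * length(lines) - ref_count - alt_count
  data.frame(chrom = panel$chrom, pos = panel$pos,
             ref_count = ref_count, alt_count = alt_count,
             excluded = excluded,
             missing = ref_count + alt_count == 0L,
             row.names = NULL, stringsAsFactors = FALSE)
}

wc_theta <- function(p1, p2, n1, n2) {
  # Weir & Cockerham (1984) two-population theta-hat for one biallelic
  # SNP, with observed heterozygosity 0 (fully inbred lines); n1, n2 are
  # numbers of individuals (lines).
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  c_ <- 0
  denom <- a + b + c_
  if (denom == 0) return(NA_real_)
  a / denom
}

hudson_fst <- function(p1, p2, n1, n2) {
  # Hudson estimator (ratio-of-averages form for one SNP), haploid sample
  # sizes in allele copies.
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) return(NA_real_)
  num / den
}

#' SNP-wise F_ST between two pooled panels
#'
#' Weir-Cockerham two-population \eqn{\hat\theta} (1984 parameterization,
#' \eqn{a/(a+b+c)}) computed from pooled allele counts of two panels of
#' inbred lines; each homozygous line counts as one individual with
#' heterozygosity 0. A SNP fixed for alternative alleles between the panels
#' gives exactly 1; a SNP monomorphic for the same allele in both panels is
#' undefined (\code{NA}). Hudson's estimator is available for sensitivity.
#'
#' @param counts1,counts2 Length-2 numeric vectors \code{c(ref, alt)} of
#'   pooled allele copies in each panel (>= 2 copies each).
#' @param method \code{"wc"} (default) or \code{"hudson"}.
#' @return List: \code{fst_raw}, \code{fst} (clamped to \[0, 1\]),
#'   \code{defined}.
#' @examples
#' fst_snp(c(40, 0), c(0, 40))$fst  # 1: fixed for alternative alleles
#' @export
fst_snp <- function(counts1, counts2, method = c("wc", "hudson")) {
  method <- match.arg(method)
  stopifnot(length(counts1) == 2, length(counts2) == 2,
            all(counts1 >= 0), all(counts2 >= 0))
  m1 <- sum(counts1); m2 <- sum(counts2)
  if (m1 < 2 || m2 < 2)
    stop("each pool needs at least 2 allele copies", call. = FALSE)
  p1 <- counts1[1] / m1
  p2 <- counts2[1] / m2
  if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1))
    return(list(fst_raw = NA_real_, fst = NA_real_, defined = FALSE))
  raw <- if (method == "wc") wc_theta(p1, p2, m1 / 2, m2 / 2)
         else hudson_fst(p1, p2, m1, m2)
  list(fst_raw = raw,
       fst = if (is.na(raw)) NA_real_ else min(1, max(0, raw)),
       defined = !is.na(raw))
}

#' Genome-wide F_ST scan between two line panels
#'
#' @param panel A [panel_genotypes()].
#' @param lines1,lines2 Disjoint line-id vectors defining the two pools.
#' @param method Passed to [fst_snp()].
#' @param flag_threshold Clamped-F_ST value above which a SNP is flagged
#'   (default 0.5).
#' @return Data frame of class \code{"fst_table"}: chrom, pos, ref, alt,
#'   n1, n2 (allele copies), fst_raw, fst_clamped, flag_high, defined.
#' @export
fst_scan <- function(panel, lines1, lines2, method = c("wc", "hudson"),
                     flag_threshold = 0.5) {
  method <- match.arg(method)
  overlap <- intersect(lines1, lines2)
  if (length(overlap))
    stop("line(s) present in both pools: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  c1 <- pool_allele_counts(panel, lines1)
  c2 <- pool_allele_counts(panel, lines2)
  n_snp <- nrow(c1)
  raw <- clamped <- rep(NA_real_, n_snp)
  defined <- rep(FALSE, n_snp)
  for (i in seq_len(n_snp)) {
    m1 <- c1$ref_count[i] + c1$alt_count[i]
    m2 <- c2$ref_count[i] + c2$alt_count[i]
    if (m1 < 2 || m2 < 2) next
    f <- fst_snp(c(c1$ref_count[i], c1$alt_count[i]),
                 c(c2$ref_count[i], c2$alt_count[i]), method = method)
    raw[i] <- f$fst_raw
    clamped[i] <- f$fst
    defined[i] <- f$defined
  }
  out <- data.frame(chrom = panel$chrom, pos = panel$pos,
                    ref = panel$ref, alt = panel$alt,
                    n1 = c1$ref_count + c1$alt_count,
                    n2 = c2$ref_count + c2$alt_count,
                    fst_raw = raw, fst_clamped = clamped,
                    flag_high = !is.na(clamped) & clamped > flag_threshold,
                    defined = defined, stringsAsFactors = FALSE)
  attr(out, "focal") <- panel$locus[panel$focal]
  attr(out, "method") <- method
  class(out) <- c("fst_table", "data.frame")
  out
}

#' Linkage disequilibrium r-squared between two SNPs of an inbred panel
#'
#' Inbred homozygous lines are treated as haplotypes. On the lines with
#' homozygous non-missing calls at both SNPs,
#' \eqn{r^2 = D^2 / (p_i(1-p_i) p_j(1-p_j))} with \eqn{D} the haplotype-
#' frequency covariance. Monomorphic SNPs give \code{NA} (undefined, not
#' zero).
#'
#' @param panel A [panel_genotypes()].
#' @param snp_i,snp_j SNP indices or \code{"arm:pos"} locus strings.
#' @return \eqn{r^2} in \[0, 1\], or \code{NA} when undefined.
#' @export
ld_r2 <- function(panel, snp_i, snp_j) {
  stopifnot(inherits(panel, "panel_genotypes"))
  idx <- function(s) {
    if (is.character(s)) {
      i <- match(s, panel$locus)
      if (is.na(i)) stop("SNP ", s, " not in panel", call. = FALSE)
      i
    } else as.integer(s)
  }
  i <- idx(snp_i); j <- idx(snp_j)
  gi <- panel$calls[, i]; gj <- panel$calls[, j]
  ok <- gi %in% c("ref", "alt") & gj %in% c("ref", "alt")
  if (sum(ok) < 2)
    stop("fewer than 2 informative homozygous lines", call. = FALSE)
  xi <- as.numeric(gi[ok] == "alt")
  xj <- as.numeric(gj[ok] == "alt")
  pi_ <- mean(xi); pj <- mean(xj)
  if (pi_ %in% c(0, 1) || pj %in% c(0, 1)) return(NA_real_)
  D <- mean(xi * xj) - pi_ * pj
  min(1, D^2 / (pi_ * (1 - pi_) * pj * (1 - pj)))
}

#' Confounder report for an F_ST scan
#'
#' Lists background SNPs with high differentiation and verifies that the
#' focal SNP is the unique fixed SNP (clamped F_ST = 1) between the panels;
#' otherwise a confounding warning is raised.
#'
#' @param fst_table A [fst_scan()] result.
#' @param focal Locus string \code{"arm:pos"} of the focal SNP; defaults to
#'   the scan's recorded focal SNP.
#' @param flag_threshold Differentiation flag level (default 0.5).
#' @return List of class \code{"confounder_report"}: \code{high} (data
#'   frame of flagged SNPs), \code{fixed} (data frame of F_ST = 1 SNPs),
#'   \code{focal}, \code{focal_is_unique_fixed}, \code{n_scanned} (SNPs
#'   with defined F_ST).
#' @export
confounder_report <- function(fst_table, focal = NULL,
                              flag_threshold = 0.5) {
  stopifnot(inherits(fst_table, "fst_table"))
  if (is.null(focal)) focal <- attr(fst_table, "focal")
  locus <- paste0(fst_table$chrom, ":", fst_table$pos)
  def <- fst_table[fst_table$defined, , drop = FALSE]
  def_locus <- paste0(def$chrom, ":", def$pos)
  high <- def[def$fst_clamped > flag_threshold, , drop = FALSE]
  fixed <- def[def$fst_clamped == 1, , drop = FALSE]
  fixed_locus <- paste0(fixed$chrom, ":", fixed$pos)
  unique_fixed <- identical(fixed_locus, focal)
  if (!(focal %in% def_locus))
    warning("focal SNP ", focal, " has no defined F_ST in the scan",
            call. = FALSE)
  else if (!unique_fixed)
    warning("focal SNP is not the unique fixed SNP between the panels; ",
            "fixed: ", paste(fixed_locus, collapse = ", "),
            " - possible confounding background locus", call. = FALSE)
  structure(list(high = high, fixed = fixed, focal = focal,
                 focal_is_unique_fixed = unique_fixed,
                 n_scanned = nrow(def),
                 flag_threshold = flag_threshold),
            class = "confounder_report")
}

#' @method print confounder_report
#' @export
print.confounder_report <- function(x, ...) {
  cat(sprintf("F_ST confounder screen (%d SNPs with defined F_ST)\n",
              x$n_scanned))
  cat(sprintf("  focal SNP %s unique fixed SNP: %s\n", x$focal,
              if (x$focal_is_unique_fixed) "yes" else "NO"))
  cat(sprintf("  SNPs with clamped F_ST > %.2f: %d (of which fixed: %d)\n",
              x$flag_threshold, nrow(x$high), nrow(x$fixed)))
  invisible(x)
}
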