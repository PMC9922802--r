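#' Validate a long-format egg-count table
#'
#' @param x Data frame with columns \code{cross_id}, \code{genotype}
#'   (TT/TG/GG), \code{vial_id}, \code{day} (positive integer),
#'   \code{eggs} (non-negative integer) and optionally \code{n_females}
#'   (default 2).
#' @return The validated data frame with a normalized \code{genotype}
#'   column (AA/Aa/aa) added as \code{genotype_class} and a per-female
#'   \code{rate} column.
#' @export
validate_egg_table <- function(x) {
  need <- c("cross_id", "genotype", "vial_id", "day", "eggs")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("egg table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!("n_females" %in% names(x))) x$n_females <- 2L
  if (any(x$eggs < 0)) stop("egg counts must be >= 0", call. = FALSE)
  if (any(x$day <= 0 | x$day != round(x$day)))
    stop("'day' must be a positive integer", call. = FALSE)
  if (any(x$n_females <= 0))
    stop("'n_females' must be positive", call. = FALSE)
  x$genotype_class <- normalize_genotype(x$genotype)
  x$rate <- x$eggs / x$n_females
  x
}

# Per-day unit means: average vials within cross first, so unequal vial
# survival does not weight crosses unequally; unit = "vial" treats each
# vial as the replicate unit instead.
unit_means_by_day <- function(tab, unit = c("cross", "vial")) {
  unit <- match.arg(unit)
  if (unit == "cross") {
    agg <- stats::aggregate(rate ~ genotype_class + cross_id + day,
                            data = tab, FUN = mean)
  } else {
    agg <- stats::aggregate(rate ~ genotype_class + cross_id + vial_id + day,
                            data = tab, FUN = mean)
  }
  split(agg, agg$day)
}

decompose_day <- function(day_df, freqs, correct_sampling = TRUE) {
  um <- split(day_df$rate, day_df$genotype_class)
  if (length(setdiff(GENOTYPES, names(um))))
    return(NULL)
  s <- summarize_genotypes(um)
  M <- population_mean(s, freqs)
  Vw <- pooled_within_variance(s)
  Vg_plug <- genetic_variance_hw(s, freqs)
  res <- list()
  if (correct_sampling) {
    raw <- Vg_plug - vg_sampling_inflation(s, freqs, Vw)
    Vg_hw <- max(0, raw)
    trunc_hw <- raw < 0
  } else {
    Vg_hw <- Vg_plug
    trunc_hw <- FALSE
  }
  Vg_re <- genetic_variance_ranef(um)
  # V_G = 0 means no variance attributable to the locus, so the profile
  # reports t = 0 even in the fully degenerate case V_within = 0 (where
  # the bare ratio would be undefined).
  t_of <- function(vg, vw) if (vg == 0) 0 else intraclass_correlation(vg, vw)
  rbind(
    data.frame(method = "hw_weighted", M = M, V_G = Vg_hw,
               V_within = Vw, t = t_of(Vg_hw, Vw),
               truncated = trunc_hw, stringsAsFactors = FALSE),
    data.frame(method = "random_effects", M = M, V_G = as.numeric(Vg_re),
               V_within = attr(Vg_re, "ms_within"),
               t = t_of(as.numeric(Vg_re), attr(Vg_re, "ms_within")),
               truncated = attr(Vg_re, "truncated"),
               stringsAsFactors = FALSE))
}

#' Estimate the proportional contribution of a SNP to daily trait variance
#'
#' Fits, for every assay day of an F1-cross egg-count table, the
#' variance partition of per-female egg-laying rate into a component
#' attributable to the focal biallelic SNP and a pooled within-genotype
#' component, and reports the intraclass correlation
#' \eqn{t = V_G / (V_{within} + V_G)} ("isofemale heritability") per day
#' together with its maximum over days ("up to" statistic).
#'
#' Two estimators of \eqn{V_G} are computed: \code{hw_weighted} weights the
#' genotypic values by expected Hardy-Weinberg frequencies from the supplied
#' allele frequencies, and \code{random_effects} is the one-way
#' method-of-moments variance component treating genotype as a random
#' grouping of cross means. With \code{correct_sampling = TRUE} (default)
#' the Hardy-Weinberg estimator subtracts the expected inflation caused by
#' sampling error of the class means
#' (\eqn{\sum_g w_g (1-w_g) V_{within}/n_g}), which would otherwise bias
#' \eqn{t} upward at the modest panel sizes typical of such designs;
#' negative corrected estimates are truncated at zero and flagged.
#'
#' @param data Long-format egg-count table; see [validate_egg_table()].
#' @param p Frequency of the "T" allele used for Hardy-Weinberg weighting
#'   (default 0.68, the evolve-and-resequence estimate for the candidate
#'   locus); alternatively pass an [allele_freqs()] via \code{freqs}.
#' @param freqs Optional [allele_freqs()]; overrides \code{p}.
#' @param unit Replicate unit for genotypic values and within-class
#'   variances: \code{"cross"} (default; vials averaged first) or
#'   \code{"vial"}.
#' @param correct_sampling Subtract the sampling-error inflation from the
#'   Hardy-Weinberg \eqn{V_G} (default \code{TRUE}).
#' @return An object of class \code{"isoherit"}: list with elements
#'   \code{by_day} (data frame: day, method, M, V_G, V_within, t,
#'   truncated), \code{max_t} (named per method), \code{max_day},
#'   \code{freqs}, \code{unit}, \code{n_crosses}, \code{skipped_days},
#'   \code{call}.
#' @examples
#' cfg <- f1_sim_config(genotype_effect = 0.15)
#' sim <- simulate_f1_panel(cfg, seed = 1)
#' fit <- isoherit(sim$eggs)
#' fit
#' coef(fit)
#' @export
isoherit <- function(data, p = 0.68, freqs = NULL,
                     unit = c("cross", "vial"), correct_sampling = TRUE) {
  cl <- match.call()
  unit <- match.arg(unit)
  if (is.null(freqs)) freqs <- allele_freqs(p)
  stopifnot(inherits(freqs, "allele_freqs"))
  tab <- validate_egg_table(as.data.frame(data))
  days <- unit_means_by_day(tab, unit)
  rows <- list()
  skipped <- integer(0)
  for (d in names(days)) {
    dec <- decompose_day(days[[d]], freqs, correct_sampling)
    if (is.null(dec)) {
      skipped <- c(skipped, as.integer(d))
      next
    }
    dec <- cbind(day = as.integer(d), dec)
    rows[[d]] <- dec
  }
  if (length(skipped))
    warning("skipped day(s) with a missing genotype class: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (!length(rows))
    stop("no assay day has all three genotype classes represented",
         call. = FALSE)
  by_day <- do.call(rbind, rows)
  rownames(by_day) <- NULL
  max_t <- tapply(by_day$t, by_day$method, function(v) max(v, na.rm = TRUE))
  max_day <- vapply(names(max_t), function(m) {
    sub <- by_day[by_day$method == m, ]
    sub$day[which.max(sub$t)]
  }, integer(1))
  structure(list(by_day = by_day,
                 max_t = max_t[c("hw_weighted", "random_effects")],
                 max_day = max_day[c("hw_weighted", "random_effects")],
                 freqs = freqs, unit = unit,
                 correct_sampling = correct_sampling,
                 n_crosses = table(unique(tab[c("cross_id",
                                                "genotype_class")])$genotype_class),
                 skipped_days = skipped,
                 call = cl),
            class = "isoherit")
}

#' @method print isoherit
#' @export
print.isoherit <- function(x, digits = 4, ...) {
  cat("Single-locus variance partition of daily per-female egg laying\n")
  cat(sprintf("  allele frequencies: p = %.3f, q = %.3f; unit: %s mean\n",
              x$freqs$p, x$freqs$q, x$unit))
  cat(sprintf("  days analysed: %d%s\n",
              length(unique(x$by_day$day)),
              if (length(x$skipped_days))
                paste0(" (skipped: ",
                       paste(x$skipped_days, collapse = ", "), ")") else ""))
  cat("  maximum intraclass correlation t over days:\n")
  for (m in names(x$max_t))
    cat(sprintf("    %-15s t = %.*f (day %d)\n", m, digits,
                x$max_t[[m]], x$max_day[[m]]))
  invisible(x)
}

#' @export
summary.isoherit <- function(object, ...) {
  structure(list(fit = object), class = "summary.isoherit")
}

#' @method print summary.isoherit
#' @export
print.summary.isoherit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-day decomposition:\n")
  df <- x$fit$by_day
  df[c("M", "V_G", "V_within", "t")] <-
    lapply(df[c("M", "V_G", "V_within", "t")], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.isoherit <- function(object, ...) {
  c(max_t_hw = unname(object$max_t[["hw_weighted"]]),
    max_t_ranef = unname(object$max_t[["random_effects"]]))
}

#' @method plot isoherit
#' @export
plot.isoherit <- function(x, ...) {
  df <- x$by_day
  methods <- unique(df$method)
  cols <- c(hw_weighted = "black", random_effects = "grey50")
  graphics::plot(range(df$day), c(0, max(df$t, na.rm = TRUE) * 1.1),
                 type = "n", xlab = "Assay day",
                 ylab = "Intraclass correlation t", ...)
  for (m in methods) {
    sub <- df[df$method == m, ]
    graphics::lines(sub$day, sub$t, type = "b", col = cols[[m]],
                    pch = 16)
  }
  graphics::legend("topright", legend = methods, col = cols[methods],
                   lty = 1, pch = 16, bty = "n")
  invisible(x)
}

#' Bootstrap confidence intervals for the maximum-day intraclass correlation
#'
#' Resamples crosses (the independent replicate units) with replacement
#' within genotype class and refits the variance partition, giving
#' percentile intervals for \code{max_t} under each estimator.
#'
#' @param object An \code{"isoherit"} fit.
#' @param parm Ignored; both estimators are reported.
#' @param level Confidence level (default 0.95).
#' @param B Number of bootstrap replicates (default 1000).
#' @param data The egg-count table used in the fit (required: the fit does
#'   not retain its data).
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Matrix with one row per estimator and columns for the interval
#'   bounds; attribute \code{"boot"} holds the replicate values.
#' @export
confint.isoherit <- function(object, parm, level = 0.95, B = 1000,
                             data, seed = NULL, ...) {
  if (missing(data))
    stop("supply the egg-count table via 'data'", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  tab <- validate_egg_table(as.data.frame(data))
  crosses <- unique(tab[c("cross_id", "genotype_class")])
  by_class <- split(crosses$cross_id, crosses$genotype_class)
  reps <- matrix(NA_real_, B, 2,
                 dimnames = list(NULL, c("hw_weighted", "random_effects")))
  for (b in seq_len(B)) {
    pieces <- lapply(names(by_class), function(g) {
      ids <- sample(by_class[[g]], replace = TRUE)
      do.call(rbind, lapply(seq_along(ids), function(i) {
        sub <- tab[tab$cross_id == ids[i], ]
        sub$cross_id <- paste0(g, "_bs", i)
        sub
      }))
    })
    bs <- do.call(rbind, pieces)
    fit <- suppressWarnings(
      isoherit(bs, freqs = object$freqs, unit = object$unit,
               correct_sampling = object$correct_sampling))
    reps[b, ] <- fit$max_t[colnames(reps)]
  }
  alpha <- (1 - level) / 2
  out <- t(apply(reps, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                 na.rm = TRUE))
  attr(out, "boot") <- reps
  out
}
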