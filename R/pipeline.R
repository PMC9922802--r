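write_manifest <- function(out_dir, step, inputs = character(),
                           params = list(), seed = NULL) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(step = step,
                   package_version = as.character(
                     utils::packageVersion("mendelvar")),
                   r_version = R.version.string,
                   seed = seed, params = params, input_md5 = hashes)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
}

#' Run the genetic-background confounder screen
#'
#' Reads a genotype panel (wide CSV or VCF), computes the SNP-wise
#' Weir-Cockerham F_ST scan between the two line pools and LD r-squared of
#' every SNP against the focal SNP, and writes the scan TSV, LD TSV,
#' confounder report and a reproducibility manifest to \code{out_dir}.
#'
#' @param genotypes Path to a panel file (\code{.csv} wide format or
#'   \code{.vcf}) or a [panel_genotypes()] object.
#' @param focal Locus string \code{"arm:pos"} of the focal SNP (ignored
#'   when \code{genotypes} is already a panel object).
#' @param lines1,lines2 Line ids of the two pools (must not overlap).
#' @param out_dir Output directory (created if needed).
#' @param method F_ST estimator, \code{"wc"} or \code{"hudson"}.
#' @param flag_threshold Differentiation flag level (default 0.5).
#' @param strict Turn warnings (e.g. a non-unique fixed SNP) into errors.
#' @return List: \code{fst} ([fst_scan()] table), \code{ld} (data frame of
#'   per-SNP r-squared against the focal SNP), \code{report}
#'   ([confounder_report()]), invisibly.
#' @export
run_screen <- function(genotypes, focal = NULL, lines1, lines2,
                       out_dir = ".", method = c("wc", "hudson"),
                       flag_threshold = 0.5, strict = FALSE) {
  method <- match.arg(method)
  input_path <- character(0)
  if (inherits(genotypes, "panel_genotypes")) {
    panel <- genotypes
  } else {
    input_path <- genotypes
    panel <- if (grepl("\\.vcf(\\.gz)?$", genotypes))
      read_panel_vcf(genotypes, focal)
    else read_panel_csv(genotypes, focal)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  run <- if (strict) function(expr) withCallingHandlers(
    expr, warning = function(w) stop(conditionMessage(w), call. = FALSE))
    else identity
  fst <- run(fst_scan(panel, lines1, lines2, method = method,
                      flag_threshold = flag_threshold))
  ld <- data.frame(chrom = panel$chrom, pos = panel$pos,
                   r2 = vapply(seq_along(panel$locus), function(j)
                     tryCatch(ld_r2(panel, panel$focal, j),
                              error = function(e) NA_real_),
                     numeric(1)),
                   stringsAsFactors = FALSE)
  report <- run(confounder_report(fst, flag_threshold = flag_threshold))
  utils::write.table(fst, file.path(out_dir, "fst_scan.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(ld, file.path(out_dir, "ld_focal.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(focal = report$focal,
         focal_is_unique_fixed = report$focal_is_unique_fixed,
         n_scanned = report$n_scanned,
         n_high = nrow(report$high), n_fixed = nrow(report$fixed)),
    file.path(out_dir, "confounder_report.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  write_manifest(out_dir, "screen", inputs = input_path,
                 params = list(focal = panel$locus[panel$focal],
                               method = method,
                               flag_threshold = flag_threshold,
                               n_lines1 = length(lines1),
                               n_lines2 = length(lines2)))
  invisible(list(fst = fst, ld = ld, report = report))
}

#' Run the per-day SNP contribution analysis
#'
#' Fits [isoherit()] on an egg-count table (path to a delimited file or a
#' data frame) and writes the per-day decomposition CSV, a JSON summary
#' with the maximum-day t per estimator, and a manifest.
#'
#' @param eggs Path to a CSV/TSV egg-count table or a data frame.
#' @param p Frequency of the "T" allele (default 0.68).
#' @param out_dir Output directory.
#' @param unit Replicate unit, \code{"cross"} or \code{"vial"}.
#' @param correct_sampling Passed to [isoherit()].
#' @param seed Recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return The \code{"isoherit"} fit, invisibly.
#' @export
run_contribution <- function(eggs, p = 0.68, out_dir = ".",
                             unit = c("cross", "vial"),
                             correct_sampling = TRUE, seed = NULL) {
  unit <- match.arg(unit)
  input_path <- character(0)
  if (is.character(eggs)) {
    input_path <- eggs
    sep <- if (grepl("\\.tsv$", eggs)) "\t" else ","
    eggs <- utils::read.table(eggs, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- isoherit(eggs, p = p, unit = unit,
                  correct_sampling = correct_sampling)
  utils::write.csv(fit$by_day,
                   file.path(out_dir, "contribution_by_day.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(max_t = as.list(fit$max_t), max_day = as.list(fit$max_day),
         p = fit$freqs$p, unit = unit, seed = seed,
         skipped_days = fit$skipped_days),
    file.path(out_dir, "contribution_summary.json"), auto_unbox = TRUE,
    pretty = TRUE, digits = NA)
  write_manifest(out_dir, "contribution", inputs = input_path,
                 params = list(p = p, unit = unit,
                               correct_sampling = correct_sampling),
                 seed = seed)
  invisible(fit)
}

#' Aggregate phenotype and qPCR effect summaries into one report
#'
#' Computes group totals and pairwise percent differences for the egg
#' assay, mean relative expression per treatment for the qPCR assay, and
#' writes a tidy effects CSV plus a JSON report; assays not provided are
#' marked \code{"not provided"}.
#'
#' @param eggs Optional egg-count table (data frame or path) with a
#'   \code{genotype} column.
#' @param cq Optional Cq table (data frame or path); requires
#'   \code{target_gene} and \code{control_label}.
#' @param target_gene,control_label qPCR target gene and control
#'   treatment label.
#' @param reference_group Genotype used as the reference for egg-total
#'   percent differences (default "TT").
#' @param out_dir Output directory.
#' @return List with elements \code{egg_effects} and \code{expression}
#'   (either may be \code{NULL}), invisibly.
#' @export
run_effects <- function(eggs = NULL, cq = NULL, target_gene = "Eip75B",
                        control_label = "0", reference_group = "TT",
                        out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  egg_effects <- NULL
  expression <- NULL
  if (!is.null(eggs)) {
    if (is.character(eggs))
      eggs <- utils::read.csv(eggs, stringsAsFactors = FALSE)
    groups <- unique(eggs$genotype)
    totals <- vapply(groups, function(g)
      total_eggs_per_female(eggs, group = g)$group, numeric(1))
    egg_effects <- trait_effects(totals, "total_eggs_per_female",
                                 reference = reference_group)
    utils::write.csv(egg_effects, file.path(out_dir, "egg_effects.csv"),
                     row.names = FALSE)
    report$eggs <- list(group_totals = as.list(totals))
  } else report$eggs <- "not provided"
  if (!is.null(cq)) {
    if (is.character(cq))
      cq <- utils::read.csv(cq, stringsAsFactors = FALSE)
    expression <- relative_expression(cq, target_gene, control_label)
    qc <- attr(expression, "qc_log")
    utils::write.csv(expression, file.path(out_dir, "expression.csv"),
                     row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qpcr_qc_log.csv"),
                     row.names = FALSE)
    mean_by_tr <- tapply(expression$relative_expression,
                         expression$treatment, mean)
    report$qpcr <- list(mean_relative_expression = as.list(mean_by_tr),
                        n_failed = sum(qc$qc_status == "failed"),
                        n_one_removed = sum(qc$qc_status == "one_removed"))
  } else report$qpcr <- "not provided"
  jsonlite::write_json(report, file.path(out_dir, "effects_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "effects",
                 params = list(target_gene = target_gene,
                               control_label = control_label,
                               reference_group = reference_group))
  invisible(list(egg_effects = egg_effects, expression = expression))
}
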