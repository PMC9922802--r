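#' Technical-replicate quality control for qPCR Cq triples
#'
#' A replicate is divergent when it differs by more than \code{cutoff}
#' cycles from each of the other replicates individually. With no
#' divergent replicate the triple is accepted as is; with exactly one, the
#' divergent value is removed (\code{"one_removed"}); otherwise the sample
#' fails QC. Comparisons use a 1e-8 cycle guard so that differences exactly
#' at the cutoff are not flipped by binary representation error.
#'
#' @param cqs Numeric vector of technical-replicate Cq values (usually 3).
#' @param cutoff Divergence cutoff in cycles (default 0.5).
#' @return List: \code{kept} (numeric vector) and \code{qc_status} in
#'   \code{c("accepted", "one_removed", "failed")}.
#' @examples
#' qc_replicates(c(20.0, 20.1, 21.0))  # drops 21.0
#' @export
qc_replicates <- function(cqs, cutoff = 0.5) {
  stopifnot(is.numeric(cqs))
  if (length(cqs) < 2 || any(!is.finite(cqs)))
    return(list(kept = numeric(0), qc_status = "failed"))
  eps <- 1e-8
  d <- abs(outer(cqs, cqs, "-"))
  divergent <- vapply(seq_along(cqs), function(i)
    all(d[i, -i] > cutoff + eps), logical(1))
  nd <- sum(divergent)
  if (nd == 0) list(kept = cqs, qc_status = "accepted")
  else if (nd == 1) list(kept = cqs[!divergent], qc_status = "one_removed")
  else list(kept = numeric(0), qc_status = "failed")
}

#' Relative quantity from a Cq value
#'
#' Standard \eqn{E^{\Delta Cq}} transform:
#' \code{efficiency^(calibrator_cq - cq)}; equals 1 at the calibrator.
#'
#' @param cq Cq value(s).
#' @param calibrator_cq Calibrator Cq.
#' @param efficiency Amplification efficiency as fold change per cycle
#'   (default 2, i.e. 100\% efficiency).
#' @return Dimensionless relative quantity.
#' @export
relative_quantity <- function(cq, calibrator_cq, efficiency = 2) {
  stopifnot(is.numeric(cq), is.numeric(calibrator_cq))
  if (efficiency <= 1)
    stop("efficiency must exceed 1 (fold change per cycle)", call. = FALSE)
  efficiency^(calibrator_cq - cq)
}

#' Geometric-mean normalization factor
#'
#' The per-sample geometric mean of reference-gene relative quantities.
#'
#' @param ref_quantities Positive numeric vector, one entry per reference
#'   gene.
#' @return Normalization factor (dimensionless).
#' @examples
#' normalization_factor(c(2, 8, 4, 1))  # 64^(1/4)
#' @export
normalization_factor <- function(ref_quantities) {
  stopifnot(is.numeric(ref_quantities), length(ref_quantities) >= 1)
  if (any(ref_quantities <= 0))
    stop("reference quantities must be positive", call. = FALSE)
  exp(mean(log(ref_quantities)))
}

#' Validate a long-format Cq table
#'
#' @param x Data frame with columns \code{sample}, \code{treatment},
#'   \code{gene} and replicate columns \code{rep1}, \code{rep2}, ...
#'   (at least 2).
#' @return The validated data frame.
#' @export
validate_cq_table <- function(x) {
  need <- c("sample", "treatment", "gene")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("Cq table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  reps <- grep("^rep[0-9]+$", names(x), value = TRUE)
  if (length(reps) < 2)
    stop("Cq table needs at least two replicate columns rep1, rep2, ...",
         call. = FALSE)
  x
}

#' Normalized relative expression of a target gene
#'
#' Implements the full processing chain: replicate QC ([qc_replicates()]),
#' averaging of kept replicates on the Cq scale, \eqn{E^{\Delta Cq}}
#' relative quantities per gene (calibrated to the per-gene mean Cq, an
#' arbitrary reference that cancels downstream), geometric-mean
#' normalization over the reference genes, and scaling so that the control
#' group's mean normalized expression is 1.
#'
#' @param table Long Cq table (see [validate_cq_table()]).
#' @param target_gene Target gene name.
#' @param control_label Treatment label of the control group.
#' @param reference_genes Character vector of reference genes; defaults to
#'   every gene except the target.
#' @param efficiency Amplification efficiency (default 2); may be a named
#'   vector per gene.
#' @return Data frame of class \code{"expression_result"}: sample,
#'   treatment, normalization_factor, relative_expression, plus a
#'   \code{"qc_log"} attribute recording per sample x gene QC status.
#' @export
relative_expression <- function(table, target_gene, control_label,
                                reference_genes = NULL, efficiency = 2) {
  tab <- validate_cq_table(as.data.frame(table))
  genes <- unique(tab$gene)
  if (!(target_gene %in% genes))
    stop("target gene ", target_gene, " absent from table", call. = FALSE)
  if (is.null(reference_genes))
    reference_genes <- setdiff(genes, target_gene)
  if (!length(reference_genes))
    stop("no reference genes available", call. = FALSE)
  eff <- function(g) {
    if (length(efficiency) == 1L && is.null(names(efficiency)))
      efficiency
    else if (g %in% names(efficiency)) efficiency[[g]]
    else stop("no efficiency supplied for gene ", g, call. = FALSE)
  }
  rep_cols <- grep("^rep[0-9]+$", names(tab), value = TRUE)

  qc_log <- data.frame(sample = tab$sample, gene = tab$gene,
                       qc_status = NA_character_,
                       stringsAsFactors = FALSE)
  tab$mean_cq <- NA_real_
  for (i in seq_len(nrow(tab))) {
    qc <- qc_replicates(unlist(tab[i, rep_cols], use.names = FALSE))
    qc_log$qc_status[i] <- qc$qc_status
    if (qc$qc_status != "failed") tab$mean_cq[i] <- mean(qc$kept)
  }
  tab <- tab[!is.na(tab$mean_cq), , drop = FALSE]

  # relative quantities per gene, calibrated to the gene's mean Cq
  tab$quantity <- NA_real_
  for (g in unique(tab$gene)) {
    sel <- tab$gene == g
    tab$quantity[sel] <- relative_quantity(tab$mean_cq[sel],
                                           mean(tab$mean_cq[sel]),
                                           efficiency = eff(g))
  }

  samples <- unique(tab[c("sample", "treatment")])
  res <- lapply(seq_len(nrow(samples)), function(i) {
    s <- samples$sample[i]
    sub <- tab[tab$sample == s, ]
    refs <- sub$quantity[match(reference_genes, sub$gene)]
    tq <- sub$quantity[match(target_gene, sub$gene)]
    if (anyNA(refs) || is.na(tq)) return(NULL)
    nf <- normalization_factor(refs)
    data.frame(sample = s, treatment = samples$treatment[i],
               normalization_factor = nf, normalized = tq / nf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out) || !nrow(out))
    stop("no sample passed QC with complete gene measurements",
         call. = FALSE)
  ctrl <- out$normalized[out$treatment == control_label]
  if (!length(ctrl))
    stop("control group '", control_label, "' is empty after QC",
         call. = FALSE)
  out$relative_expression <- out$normalized / mean(ctrl)
  out$normalized <- NULL
  attr(out, "qc_log") <- qc_log
  class(out) <- c("expression_result", "data.frame")
  out
}

#' GeNorm expression-stability measure M
#'
#' For each reference gene \eqn{j}, \eqn{M_j} is the mean over the other
#' genes \eqn{k} of the standard deviation across samples of
#' \eqn{\log_2(q_j / q_k)} (Vandesompele's pairwise-variation definition).
#' Stable reference genes have small M; a common acceptance level is
#' M < 0.25 for homogeneous sample sets.
#'
#' @param quantity_matrix Positive numeric matrix, samples x genes.
#' @return Named numeric vector of per-gene M values.
#' @export
genorm_stability <- function(quantity_matrix) {
  q <- as.matrix(quantity_matrix)
  if (ncol(q) < 2)
    stop("GeNorm M needs at least two genes", call. = FALSE)
  if (nrow(q) < 2)
    stop("GeNorm M needs at least two samples", call. = FALSE)
  if (any(q <= 0)) stop("quantities must be positive", call. = FALSE)
  lg <- log2(q)
  M <- vapply(seq_len(ncol(q)), function(j) {
    sds <- vapply(setdiff(seq_len(ncol(q)), j), function(k)
      stats::sd(lg[, j] - lg[, k]), numeric(1))
    mean(sds)
  }, numeric(1))
  stats::setNames(M, colnames(q))
}
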