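#' Read an inbred-line genotype panel from a minimal VCF
#'
#' Reads diploid GT calls (field \code{GT} only is required) with
#' \pkg{vcfR} and converts them to ref/alt/het codes. Coordinates are kept
#' 1-based as in the VCF.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param focal Locus string \code{"arm:pos"} of the focal SNP.
#' @return A [panel_genotypes()].
#' @export
read_panel_vcf <- function(path, focal) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- sub("\\|", "/", x)
    out <- rep(NA_character_, length(x))
    out[x %in% c("0/0", "0")] <- "ref"
    out[x %in% c("1/1", "1")] <- "alt"
    out[x %in% c("0/1", "1/0")] <- "het"
    out
  }
  calls <- t(apply(gt, 1, code))
  dimnames(calls) <- dimnames(gt)
  calls <- t(calls)  # lines x SNPs
  panel_genotypes(calls, chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]),
                  ref = fix[, "REF"], alt = fix[, "ALT"], focal = focal)
}

#' Read a genotype panel from a wide CSV (line x SNP)
#'
#' First column \code{line}; remaining column names are
#' \code{arm:pos_ref_alt} (e.g. \code{3L:18026199_T_G}); entries are
#' ref/alt/het or empty for missing.
#'
#' @param path CSV path.
#' @param focal Locus string of the focal SNP.
#' @return A [panel_genotypes()].
#' @export
read_panel_csv <- function(path, focal) {
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "line")
    stop("first column of a panel CSV must be 'line' (", path, ")",
         call. = FALSE)
  snp_cols <- names(df)[-1]
  parts <- regmatches(snp_cols,
                      regexec("^([^:]+):([0-9]+)_([A-Z]+)_([A-Z]+)$",
                              snp_cols))
  bad <- vapply(parts, length, 0L) != 5L
  if (any(bad))
    stop("malformed SNP column name(s): ",
         paste(snp_cols[bad], collapse = ", "),
         "; expected arm:pos_ref_alt", call. = FALSE)
  calls <- as.matrix(df[-1])
  calls[calls == ""] <- NA
  rownames(calls) <- df$line
  panel_genotypes(calls,
                  chrom = vapply(parts, `[`, "", 2),
                  pos = as.integer(vapply(parts, `[`, "", 3)),
                  ref = vapply(parts, `[`, "", 4),
                  alt = vapply(parts, `[`, "", 5),
                  focal = focal)
}

#' Write a genotype panel as a wide CSV
#'
#' @param panel A [panel_genotypes()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  cols <- paste0(panel$locus, "_", panel$ref, "_", panel$alt)
  df <- as.data.frame(panel$calls, stringsAsFactors = FALSE)
  names(df) <- cols
  df <- cbind(line = rownames(panel$calls), df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotypes (homozygous 0/0 or 1/1,
#' heterozygous 0/1, missing ./.), readable by [read_panel_vcf()] and
#' standard VCF tooling.
#'
#' @param panel A [panel_genotypes()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(panel$calls)), collapse = "\t")), con)
  gt_code <- c(ref = "0/0", alt = "1/1", het = "0/1")
  ord <- order(panel$chrom, panel$pos)
  for (i in ord) {
    g <- panel$calls[, i]
    g <- ifelse(is.na(g), "./.", gt_code[g])
    writeLines(paste(c(panel$chrom[i], panel$pos[i], ".",
                       panel$ref[i], panel$alt[i], ".", "PASS", ".",
                       "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}
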