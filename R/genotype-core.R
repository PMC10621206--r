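# Canonical sample x SNP genotype container and QC operations.

#' Construct a genotype matrix
#'
#' The canonical container consumed by every other module: an integer matrix
#' of minor-allele counts (states 0, 1, 2; `NA` = missing genotype) with
#' samples as rows and SNPs as columns, plus a SNP map carrying chromosome,
#' 1-based position, ref/alt alleles and whether the alt allele is the minor
#' allele in this cohort.
#'
#' @param states integer matrix, rownames = sample ids, colnames = SNP ids,
#'   values in \{0, 1, 2, NA\}.
#' @param snp_map data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `minor_is_alt`; one row per column of
#'   `states`, in the same order.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(states, snp_map) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(rownames(states)) || is.null(colnames(states))) {
    stop("states must have sample ids as rownames and SNP ids as colnames")
  }
  if (anyDuplicated(rownames(states))) {
    stop("validation error: duplicate sample ids")
  }
  if (anyDuplicated(colnames(states))) {
    stop("validation error: duplicate SNP ids")
  }
  bad <- !(states %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype states must be 0, 1, 2 or NA")
  need <- c("snp_id", "chrom", "pos", "ref_allele", "alt_allele", "minor_is_alt")
  if (!all(need %in% names(snp_map))) {
    stop("snp_map must have columns: ", paste(need, collapse = ", "))
  }
  snp_map <- as.data.frame(snp_map)[, need]
  if (!identical(as.character(snp_map$snp_id), colnames(states))) {
    stop("snp_map must cover exactly the SNP ids of states, in order")
  }
  if (any(snp_map$pos <= 0, na.rm = TRUE)) stop("positions must be positive")
  rownames(snp_map) <- NULL
  structure(list(states = states, snp_map = snp_map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$states), ncol(x$states),
              100 * mean(is.na(x$states))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$states)

#' Sample and SNP identifiers of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return character vector of ids.
#' @export
sample_ids <- function(gm) rownames(gm$states)

#' @rdname sample_ids
#' @export
snp_ids <- function(gm) colnames(gm$states)

#' Per-SNP minor allele frequency and call rate
#'
#' MAF is computed over non-missing genotypes only:
#' `f = (het + 2 * hom_minor) / (2 * n_called)` and `maf = min(f, 1 - f)`,
#' so the value is invariant under relabelling of minor and major alleles.
#' A SNP with no called genotypes gets `maf = NA` and `call_rate = 0`.
#'
#' @param gm a `genotype_matrix`.
#' @return data.frame with columns `snp_id`, `maf`, `call_rate`, `n_called`.
#' @export
compute_maf <- function(gm) {
  s <- gm$states
  n_called <- colSums(!is.na(s))
  f <- colSums(s, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(f, 1 - f)
  maf[n_called == 0] <- NA_real_
  data.frame(snp_id = colnames(s), maf = maf,
             call_rate = n_called / nrow(s), n_called = n_called,
             row.names = NULL)
}

#' Quality-control filtering of a genotype matrix
#'
#' Removes SNPs with minor allele frequency strictly below `maf_min`
#' (a SNP at exactly the threshold is retained), SNPs below the SNP
#' call-rate threshold and samples below the sample call-rate threshold.
#' Sample filtering is applied first, then SNP call rate, then MAF (computed
#' on the retained samples). Order of retained rows/columns is preserved.
#'
#' @param gm a `genotype_matrix`.
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param snp_call_min minimum per-SNP call rate (default 0.98).
#' @param sample_call_min minimum per-sample call rate (default 0.95).
#' @param verbose log the thresholds and removal counts (default TRUE).
#' @return filtered `genotype_matrix` with a `qc_report` attribute (list of
#'   removal counts per criterion and the thresholds applied).
#' @export
apply_qc <- function(gm, maf_min = 0.05, snp_call_min = 0.98,
                     sample_call_min = 0.95, verbose = TRUE) {
  stopifnot(maf_min >= 0, maf_min <= 1, snp_call_min >= 0, snp_call_min <= 1,
            sample_call_min >= 0, sample_call_min <= 1)
  eps <- 1e-9
  sample_cr <- rowMeans(!is.na(gm$states))
  keep_samples <- sample_cr >= sample_call_min - eps
  s <- gm$states[keep_samples, , drop = FALSE]

  snp_cr <- colMeans(!is.na(s))
  keep_call <- snp_cr >= snp_call_min - eps

  n_called <- colSums(!is.na(s))
  f <- colSums(s, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  maf <- pmin(f, 1 - f)
  maf[n_called == 0] <- NA_real_
  keep_maf <- !is.na(maf) & (maf >= maf_min - eps)

  keep_snps <- keep_call & keep_maf
  report <- list(
    thresholds = list(maf_min = maf_min, snp_call_min = snp_call_min,
                      sample_call_min = sample_call_min),
    samples_removed_call_rate = sum(!keep_samples),
    snps_removed_call_rate = sum(!keep_call),
    snps_removed_maf = sum(keep_call & !keep_maf),
    snps_retained = sum(keep_snps),
    samples_retained = sum(keep_samples)
  )
  if (verbose) {
    message(sprintf(
      "apply_qc: maf_min=%g snp_call_min=%g sample_call_min=%g; removed %d samples (call rate), %d SNPs (call rate), %d SNPs (MAF); retained %d x %d",
      maf_min, snp_call_min, sample_call_min,
      report$samples_removed_call_rate, report$snps_removed_call_rate,
      report$snps_removed_maf, report$samples_retained, report$snps_retained))
  }
  if (!any(keep_snps)) {
    stop("apply_qc removed every SNP; review maf_min/call-rate thresholds")
  }
  out <- genotype_matrix(s[, keep_snps, drop = FALSE],
                         gm$snp_map[keep_snps, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}

#' Write the QC report of a filtered matrix as JSON
#'
#' @param gm output of [apply_qc()] (must carry a `qc_report` attribute).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(gm, path) {
  report <- attr(gm, "qc_report")
  if (is.null(report)) stop("matrix carries no qc_report; run apply_qc first")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the genotype-state vectors of two SNPs over
#' the samples where both are called. Used to check that signature SNPs are
#' not merely tagging one another.
#'
#' @param gm a `genotype_matrix`.
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in `[0, 1]`, or `NA` if either vector has zero variance
#'   or fewer than two jointly called samples.
#' @export
pairwise_r2 <- function(gm, snp_a, snp_b) {
  stopifnot(snp_a %in% snp_ids(gm), snp_b %in% snp_ids(gm))
  a <- gm$states[, snp_a]
  b <- gm$states[, snp_b]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}
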