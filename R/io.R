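# Readers and writers for genotype data (tab-separated table, VCF 4.x with
# GT fields), phenotype tables and simulated-dataset bundles.
#
# Table dialect: tab-separated, samples as rows, header row of SNP ids,
# first column "sample_id", "NA" for missing. The SNP map travels in a
# sidecar TSV (snp_id, chrom, pos, ref_allele, alt_allele, minor_is_alt).

#' Load a genotype matrix from a file
#'
#' @param path genotype file.
#' @param format `"table"` (tab-separated state matrix, samples as rows) or
#'   `"vcf"` (VCF 4.x; GT fields required, phase ignored, multi-allelic
#'   records skipped with a warning).
#' @param map_path for `format = "table"`, optional sidecar TSV with the SNP
#'   map; defaults to `<path>.map` if that file exists, else a stub map is
#'   constructed.
#' @return a [genotype_matrix()]. For VCF input, states encode minor-allele
#'   counts after determining the minor allele empirically from the loaded
#'   samples (ties at frequency 0.5 keep the alt allele as minor).
#' @export
load_genotypes <- function(path, format = c("table", "vcf"), map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         table = .load_genotype_table(path, map_path),
         vcf = .load_genotype_vcf(path))
}

.load_genotype_table <- function(path, map_path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("format error in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, colClasses = "character")
  sample_id <- tab[[1]]
  snp_id <- colnames(tab)[-1]
  if (anyDuplicated(sample_id)) stop("validation error: duplicate sample ids")
  if (anyDuplicated(snp_id)) stop("validation error: duplicate SNP ids")
  states <- suppressWarnings(
    matrix(as.integer(as.matrix(tab[, -1, drop = FALSE])),
           nrow = nrow(tab), dimnames = list(sample_id, snp_id)))
  raw <- as.matrix(tab[, -1, drop = FALSE])
  bad <- !is.na(raw) & raw != "NA" & is.na(states)
  if (any(bad)) {
    stop(sprintf("format error in %s: line %d has non-integer genotype state",
                 path, which(rowSums(bad) > 0)[1] + 1L))
  }
  if (is.null(map_path) && file.exists(paste0(path, ".map"))) {
    map_path <- paste0(path, ".map")
  }
  if (!is.null(map_path)) {
    snp_map <- utils::read.table(map_path, header = TRUE, sep = "\t",
                                 quote = "", check.names = FALSE,
                                 colClasses = c(snp_id = "character",
                                                chrom = "character"))
  } else {
    snp_map <- data.frame(snp_id = snp_id, chrom = "unknown",
                          pos = seq_along(snp_id), ref_allele = "N",
                          alt_allele = "N", minor_is_alt = TRUE)
  }
  genotype_matrix(states, snp_map)
}

.load_genotype_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx) # single-record files come back as a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic VCF record(s)", sum(multi)))
  }
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  snp_id <- fix$ID
  snp_id[is.na(snp_id) | snp_id == "."] <-
    paste0(fix$CHROM, ":", fix$POS)[is.na(snp_id) | snp_id == "."]
  if (anyDuplicated(snp_id)) stop("validation error: duplicate SNP ids")
  if (anyDuplicated(colnames(gt))) stop("validation error: duplicate sample ids")
  # count alt alleles; phase separators both accepted
  alt_count <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(NA_integer_)
    sum(al == "1")
  }
  states <- matrix(vapply(gt, alt_count, integer(1)),
                   nrow = nrow(gt),
                   dimnames = list(snp_id, colnames(gt)))
  states <- t(states) # samples x SNPs
  # orient to minor-allele counts from the loaded cohort
  n_called <- colSums(!is.na(states))
  f_alt <- colSums(states, na.rm = TRUE) / (2 * pmax(n_called, 1L))
  minor_is_alt <- f_alt <= 0.5 # tie at 0.5 keeps alt as minor
  flip <- which(!minor_is_alt)
  if (length(flip)) states[, flip] <- 2L - states[, flip]
  snp_map <- data.frame(snp_id = snp_id, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), ref_allele = fix$REF,
                        alt_allele = fix$ALT, minor_is_alt = minor_is_alt)
  genotype_matrix(states, snp_map)
}

#' Write a genotype matrix as a tab-separated table plus SNP-map sidecar
#'
#' @param gm a [genotype_matrix()].
#' @param path output TSV (samples as rows, `NA` for missing).
#' @param map_path SNP-map sidecar TSV; default `<path>.map`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, map_path = paste0(path, ".map")) {
  tab <- data.frame(sample_id = rownames(gm$states),
                    gm$states, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$snp_map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Genotypes are written unphased relative to the ref/alt alleles of the SNP
#' map (states are converted back from minor-allele counts where the minor
#' allele is the ref allele).
#'
#' @param gm a [genotype_matrix()].
#' @param path output VCF path (uncompressed).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$states)),
                     collapse = "\t")), con)
  gt_strings <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(gm$states))) {
    s <- gm$states[, j]
    alt_cnt <- if (gm$snp_map$minor_is_alt[j]) s else 2L - s
    gt <- ifelse(is.na(alt_cnt), "./.", gt_strings[alt_cnt + 1L])
    writeLines(paste(c(gm$snp_map$chrom[j], gm$snp_map$pos[j],
                       gm$snp_map$snp_id[j], gm$snp_map$ref_allele[j],
                       gm$snp_map$alt_allele[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Tab-separated, one row per sample, a `sample_id` column, symptom columns
#' named `<symptom>_pre` / `<symptom>_post`, plus any covariate columns
#' (e.g. `ancestry`).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE,
                    colClasses = c(sample_id = "character"))
}

#' Write a simulated dataset bundle to a directory
#'
#' Writes `genotypes.tsv` (+ `.map`), `phenotypes.tsv` and `truth.json`
#' (planted signatures, multipliers, seed) so a simulated cohort can be
#' re-analysed from files alone.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$genotypes, file.path(dir, "genotypes.tsv"))
  phen <- sim$phenotypes
  utils::write.table(phen, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
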