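# Expanded Genotypes Analysis (EGA): disentangle a critical SNP's effect
# from its interacting partners by enumerating complete genotype
# assignments over a signature's SNPs, forming matched blocks that hold the
# interacting genotypes constant, and classifying the direction pattern.

#' All genotype assignments over k SNPs
#'
#' The full grid of 3^k expanded genotype assignments (states 0/1/2 per
#' SNP). Pure arithmetic; the data-facing enumerator
#' [enumerate_expanded()] additionally rejects orders above 3.
#'
#' @param k number of SNPs (at least 1).
#' @return data.frame with `k` columns and `3^k` rows.
#' @export
expanded_assignments <- function(k) {
  stopifnot(k >= 1)
  grid <- do.call(expand.grid, rep(list(0:2), k))
  names(grid) <- paste0("snp", seq_len(k))
  grid
}

#' Enumerate expanded genotype signatures for a disease signature
#'
#' Assigns every complete-genotype cohort sample to one of the `3^k`
#' expanded genotype signatures of a k-SNP disease signature and counts
#' cases and controls per assignment. Assignments carried by fewer than
#' `min_patients` samples are flagged excluded (they remain in the table so
#' that counts partition the complete-genotype cohort). Signatures of 4 or 5
#' SNPs are rejected: 81 or 243 expanded signatures leave too few patients
#' per assignment for directionality patterns to rise above stochastic
#' noise.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param snps character vector of the signature's SNP ids (1-3 SNPs).
#' @param min_patients minimum cases+controls per included assignment
#'   (default 15).
#' @return `expanded_genotypes` data.frame: one state column per SNP (named
#'   by SNP id), `case_count`, `control_count`, `n`, `included`; attributes
#'   `snps`, `n_complete`.
#' @export
enumerate_expanded <- function(gm, cohort, snps, min_patients = 15) {
  if (length(snps) > 3L) {
    stop("unsupported order ", length(snps),
         ": expanded genotypes analysis is limited to signatures of up to 3 ",
         "SNPs; 4- and 5-SNP signatures leave too few patients per expanded ",
         "genotype for adequate statistical power")
  }
  stopifnot(all(snps %in% snp_ids(gm)))
  k <- length(snps)
  grid <- expanded_assignments(k)
  names(grid) <- snps
  lab <- stats::setNames(cohort$label, cohort$sample_id)
  keep <- cohort$sample_id[cohort$label %in% c("case", "control")]
  keep <- keep[keep %in% rownames(gm$states)]
  s <- gm$states[keep, snps, drop = FALSE]
  complete <- rowSums(is.na(s)) == 0
  s <- s[complete, , drop = FALSE]
  y <- lab[rownames(s)] == "case"
  # assignment index in the same base-3 order as expanded_assignments
  idx <- as.vector(1L + s %*% 3L^(seq_len(k) - 1L))
  grid$case_count <- as.integer(tabulate(idx[y], nbins = 3L^k))
  grid$control_count <- as.integer(tabulate(idx[!y], nbins = 3L^k))
  grid$n <- grid$case_count + grid$control_count
  grid$included <- grid$n >= min_patients
  structure(grid, snps = snps, n_complete = nrow(s),
            class = c("expanded_genotypes", "data.frame"))
}

#' Build an expanded-genotype table from known counts
#'
#' Constructs the same structure as [enumerate_expanded()] directly from a
#' table of per-assignment case/control counts (e.g. published results),
#' so block odds ratios and classifications can be computed without the
#' underlying genotypes.
#'
#' @param assignments data.frame with one state column per SNP.
#' @param case_count,control_count integer vectors aligned to `assignments`.
#' @param min_patients inclusion threshold (default 15).
#' @return an `expanded_genotypes` data.frame.
#' @export
expanded_from_counts <- function(assignments, case_count, control_count,
                                 min_patients = 15) {
  grid <- as.data.frame(assignments)
  grid$case_count <- as.integer(case_count)
  grid$control_count <- as.integer(control_count)
  grid$n <- grid$case_count + grid$control_count
  grid$included <- grid$n >= min_patients
  structure(grid, snps = names(assignments), n_complete = sum(grid$n),
            class = c("expanded_genotypes", "data.frame"))
}

#' EGA blocks: critical-SNP odds ratios holding interacting genotypes fixed
#'
#' Groups expanded genotype signatures by the states of the interacting
#' (non-critical) SNPs. Within each group the assignment with critical state
#' 0 (homozygous wild type) is the denominator; the assignments with
#' critical state 1 and state 2 give separate numerator blocks. The EGA odds
#' ratio is `variant_odds / wt_odds` with
#' `odds = case_count / control_count`, with a Woolf 95% confidence interval
#' on the log odds ratio. A block is incomplete (OR reported `NA`) when
#' either side is excluded by the patient-count rule or has a zero cell (no
#' continuity correction is applied).
#'
#' @param expanded an `expanded_genotypes` table.
#' @param critical_snp the critical SNP (must be one of the table's SNPs).
#' @return data.frame of blocks: interacting state columns,
#'   `critical_state` (1 or 2), `wt_case`, `wt_control`, `var_case`,
#'   `var_control`, `wt_odds`, `variant_odds`, `ega_odds_ratio`, `ci_lower`,
#'   `ci_upper`, `complete`; attribute `critical_snp`, `interacting`.
#' @export
ega_blocks <- function(expanded, critical_snp) {
  snps <- attr(expanded, "snps")
  if (!(critical_snp %in% snps)) {
    stop("critical SNP ", critical_snp, " is not a member of the signature")
  }
  inter <- setdiff(snps, critical_snp)
  df <- as.data.frame(expanded)
  if (length(inter)) {
    grp_key <- do.call(paste, c(df[inter], sep = "|"))
  } else {
    grp_key <- rep("", nrow(df))
  }
  out <- list()
  for (gk in unique(grp_key)) {
    rows <- df[grp_key == gk, , drop = FALSE]
    wt <- rows[rows[[critical_snp]] == 0L, , drop = FALSE]
    for (vs in c(1L, 2L)) {
      var <- rows[rows[[critical_snp]] == vs, , drop = FALSE]
      if (nrow(var) == 0L || nrow(wt) == 0L) next
      wt_ok <- wt$included && wt$case_count > 0L && wt$control_count > 0L
      var_ok <- var$included && var$case_count > 0L && var$control_count > 0L
      complete <- wt_ok && var_ok
      wt_odds <- if (wt$control_count > 0L) wt$case_count / wt$control_count else NA_real_
      var_odds <- if (var$control_count > 0L) var$case_count / var$control_count else NA_real_
      if (complete) {
        or <- var_odds / wt_odds
        ci <- woolf_ci(var$case_count, var$control_count,
                       wt$case_count, wt$control_count)
      } else {
        or <- NA_real_
        ci <- c(lower = NA_real_, upper = NA_real_)
      }
      block <- c(
        as.list(if (length(inter)) wt[1, inter, drop = FALSE] else NULL),
        list(critical_state = vs,
             wt_case = wt$case_count, wt_control = wt$control_count,
             var_case = var$case_count, var_control = var$control_count,
             wt_odds = wt_odds, variant_odds = var_odds,
             ega_odds_ratio = or, ci_lower = unname(ci["lower"]),
             ci_upper = unname(ci["upper"]), complete = complete))
      out[[length(out) + 1L]] <- as.data.frame(block)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, critical_snp = critical_snp, interacting = inter,
            class = c("ega_blocks", "data.frame"))
}

#' Classify the causality pattern of a critical SNP from its EGA blocks
#'
#' Operational formalisation of the seven published category labels, built
#' from their prose descriptions (this package's own decision rules):
#' direction of a complete block is the sign of `log(ega_odds_ratio)`
#' (OR = 1 is consistent with either direction).
#' \itemize{
#' \item universal: every complete block shares one direction.
#' \item SNP-specific: blocks in which at least one interacting SNP carries
#'   a minor allele share one direction, and the all-wild-type block(s) show
#'   the opposite direction or are absent; the category direction is the one
#'   seen alongside interacting minor alleles.
#' \item combination-specific: exactly one interacting assignment shows a
#'   direction and every other complete block shows the opposite or none.
#' \item otherwise ambiguous (also when fewer than 2 complete blocks exist,
#'   flagged `insufficient_data`).
#' }
#'
#' @param blocks an `ega_blocks` table (possibly row-bound across all
#'   validated signatures containing the critical SNP).
#' @return list: `category` (one of `universally_causative`,
#'   `universally_protective`, `snp_specific_causative`,
#'   `snp_specific_protective`, `combination_specific_causative`,
#'   `combination_specific_protective`, `ambiguous`), `n_complete_blocks`,
#'   `insufficient_data`.
#' @export
classify_ega <- function(blocks) {
  inter <- attr(blocks, "interacting")
  b <- blocks[blocks$complete, , drop = FALSE]
  n <- nrow(b)
  if (n < 2L) {
    return(list(category = "ambiguous", n_complete_blocks = n,
                insufficient_data = TRUE))
  }
  dir <- sign(log(b$ega_odds_ratio))
  lab <- function(d) if (d > 0) "causative" else "protective"
  nonzero <- dir[dir != 0]
  done <- function(category) list(category = category, n_complete_blocks = n,
                                  insufficient_data = FALSE)
  # universal
  if (length(nonzero) > 0 && length(unique(nonzero)) == 1L) {
    return(done(paste0("universally_", lab(nonzero[1]))))
  }
  if (length(inter)) {
    any_minor <- rowSums(b[, inter, drop = FALSE] > 0) > 0
    d_minor <- dir[any_minor]
    d_wt <- dir[!any_minor]
    nz_minor <- unique(d_minor[d_minor != 0])
    if (length(d_minor) > 0 && length(nz_minor) == 1L &&
        all(d_wt != nz_minor[1])) {
      return(done(paste0("snp_specific_", lab(nz_minor[1]))))
    }
    # combination-specific: one interacting assignment carries the effect
    key <- do.call(paste, c(b[inter], sep = "|"))
    for (d in c(1, -1)) {
      with_d <- unique(key[dir == d])
      if (length(with_d) == 1L && sum(dir == d) >= 1L &&
          all(dir[key != with_d] != d)) {
        return(done(paste0("combination_specific_", lab(d))))
      }
    }
  }
  done("ambiguous")
}

#' Pooled minor-allele carrier test for a critical SNP
#'
#' 2 x 2 Fisher exact test of (critical-SNP minor-allele carrier vs
#' homozygous wild type) against (case vs control), optionally within a
#' stratum defined on the interacting SNPs' genotypes.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param critical_snp SNP id.
#' @param stratum optional logical vector named by sample id (TRUE =
#'   in-stratum), e.g. built from interacting-SNP states; `NULL` = all
#'   cohort samples.
#' @param carrier_states genotype states counted as carriers (default
#'   `c(1, 2)`, i.e. one or two copies of the minor allele).
#' @return list: `odds_ratio`, `fisher_p`, and the four counts
#'   (`case_carrier`, `control_carrier`, `case_wt`, `control_wt`).
#' @export
pooled_allele_test <- function(gm, cohort, critical_snp, stratum = NULL,
                               carrier_states = c(1, 2)) {
  stopifnot(critical_snp %in% snp_ids(gm))
  lab <- stats::setNames(cohort$label, cohort$sample_id)
  ids <- cohort$sample_id[cohort$label %in% c("case", "control")]
  ids <- ids[ids %in% rownames(gm$states)]
  if (!is.null(stratum)) {
    ids <- ids[!is.na(stratum[ids]) & stratum[ids]]
  }
  if (length(ids) == 0L) stop("empty stratum")
  g <- gm$states[ids, critical_snp]
  ok <- !is.na(g)
  g <- g[ok]; ids <- ids[ok]
  carrier <- g %in% carrier_states
  wt <- g == 0L
  y <- lab[ids] == "case"
  allele_test_from_counts(sum(carrier & y), sum(carrier & !y),
                          sum(wt & y), sum(wt & !y))
}

#' @rdname pooled_allele_test
#' @param case_carrier,control_carrier,case_wt,control_wt the four cell
#'   counts, for computing the same test directly from published counts.
#' @export
allele_test_from_counts <- function(case_carrier, control_carrier,
                                    case_wt, control_wt) {
  or <- (case_carrier / control_carrier) / (case_wt / control_wt)
  p <- stats::fisher.test(matrix(c(case_carrier, control_carrier,
                                   case_wt, control_wt), 2))$p.value
  list(odds_ratio = or, fisher_p = p, case_carrier = case_carrier,
       control_carrier = control_carrier, case_wt = case_wt,
       control_wt = control_wt)
}

#' Write EGA blocks and classification
#'
#' @param blocks an `ega_blocks` table.
#' @param classification result of [classify_ega()].
#' @param path output TSV for the blocks; the classification goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_ega <- function(blocks, classification, path) {
  utils::write.table(as.data.frame(blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(c(list(critical_snp = attr(blocks, "critical_snp")),
                         classification),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
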