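# Ancestry-confounder screening, phenotype enrichment of signature-carrier
# subgroups, and seeded (hypothesis-driven) overlap mining.

#' Ancestry confounder check for validated signatures
#'
#' For each signature, fits the logistic regression
#' `case_status ~ membership + ancestry` by maximum likelihood and takes the
#' Wald p-value of the membership coefficient; signatures whose adjusted p
#' (Bonferroni across tested signatures, as published; `"BH"` available) is
#' 0.05 or larger are flagged as ancestry-confounded false positives.
#' Incomplete-membership samples are excluded from the fit. Perfect
#' separation triggers a penalised refit (Clogg-style data augmentation:
#' half-weight pseudo-observations of both outcomes per covariate pattern)
#' with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param signatures a `signature_set`, or a plain list of feature
#'   data.frames (`snp_id`, `state`).
#' @param ancestry named vector (sample id -> 0/1 or two-level factor),
#'   e.g. white-European vs other.
#' @param method `"bonferroni"` (default) or `"BH"`.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame: `features`, `p_membership`, `p_adjusted`, `verdict`
#'   (`pass`/`fail`).
#' @export
ancestry_confounder_check <- function(gm, cohort, signatures, ancestry,
                                      method = c("bonferroni", "BH"),
                                      alpha = 0.05) {
  method <- match.arg(method)
  if (inherits(signatures, "signature_set")) {
    feat_sets <- attr(signatures, "feature_sets")
    feat_str <- signatures$features
  } else {
    feat_sets <- signatures
    feat_str <- vapply(feat_sets, function(fs) {
      paste(paste0(fs$snp_id, ":", fs$state), collapse = ";")
    }, character(1))
  }
  ids <- c(cohort_cases(cohort), cohort_controls(cohort))
  if (anyNA(ancestry[ids])) {
    stop("ancestry must be defined for all cohort samples")
  }
  anc <- as.numeric(factor(ancestry[ids])) - 1
  y <- as.numeric(ids %in% cohort_cases(cohort))
  p_raw <- vapply(feat_sets, function(fs) {
    memb <- match_signature(gm, fs)[ids]
    ok <- memb != "incomplete"
    .membership_wald_p(y[ok], as.numeric(memb[ok] == "member"), anc[ok])
  }, numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = method)
  data.frame(features = feat_str, p_membership = p_raw,
             p_adjusted = p_adj,
             verdict = ifelse(p_adj < alpha, "pass", "fail"))
}

.membership_wald_p <- function(y, memb, anc) {
  dat <- data.frame(y = y, memb = memb, anc = anc)
  fit <- withCallingHandlers(
    stats::glm(y ~ memb + anc, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  separated <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separated) {
    warning("perfect separation detected; using penalized fallback fit")
    aug <- expand.grid(y = c(0, 1), memb = unique(memb), anc = unique(anc))
    w <- c(rep(1, nrow(dat)), rep(0.5, nrow(aug)))
    dat2 <- rbind(dat, aug)
    fit <- suppressWarnings(
      stats::glm(y ~ memb + anc, family = stats::binomial(), data = dat2,
                 weights = w))
  }
  co <- summary(fit)$coefficients
  if (!"memb" %in% rownames(co)) return(1)
  co["memb", "Pr(>|z|)"]
}

#' Per-gene survival of the ancestry screen
#'
#' A gene survives when at least one signature mapped to it passes the
#' confounder check.
#'
#' @param check output of [ancestry_confounder_check()].
#' @param signature_genes list (aligned to `check` rows) of gene-id vectors.
#' @return data.frame: `gene_id`, `survives`.
#' @export
genes_surviving_confounder <- function(check, signature_genes) {
  genes <- unique(unlist(signature_genes))
  survives <- vapply(genes, function(g) {
    any(check$verdict == "pass" &
          vapply(signature_genes, function(v) g %in% v, logical(1)))
  }, logical(1))
  data.frame(gene_id = genes, survives = survives, row.names = NULL)
}

#' Phenotype enrichment of signature carriers among cases
#'
#' Compares the cases carrying a signature against the rest of the case
#' population: two-proportion Z-test with pooled variance for categorical
#' phenotypes, two-sided Mann-Whitney U (normal approximation with tie
#' correction) for continuous ones, Benjamini-Hochberg adjustment across all
#' phenotypes tested. Groups smaller than 5 are flagged underpowered but
#' still reported.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param features signature feature data.frame (`snp_id`, `state`).
#' @param phenotypes data.frame with `sample_id` and phenotype columns.
#' @param types named character vector: phenotype column ->
#'   `"categorical"` or `"continuous"`.
#' @return data.frame: `phenotype`, `test`, `carrier_n`, `other_n`,
#'   `statistic`, `direction`, `p`, `p_adjusted`, `underpowered`.
#' @export
phenotype_enrichment <- function(gm, cohort, features, phenotypes, types) {
  cases <- cohort_cases(cohort)
  memb <- match_signature(gm, features)[cases]
  carrier <- cases[memb == "member"]
  other <- cases[memb == "non-member"]
  ph <- phenotypes[match(cases, phenotypes$sample_id), , drop = FALSE]
  rownames(ph) <- cases
  res <- lapply(names(types), function(v) {
    xc <- ph[carrier, v]; xo <- ph[other, v]
    xc <- xc[!is.na(xc)]; xo <- xo[!is.na(xo)]
    if (types[[v]] == "categorical") {
      tst <- two_proportion_z(sum(xc == 1), length(xc), sum(xo == 1),
                              length(xo))
      stat <- tst$z
      dirn <- sign(mean(xc == 1) - mean(xo == 1))
      p <- tst$p_value
      test <- "two_proportion_z"
    } else {
      wt <- stats::wilcox.test(xc, xo, exact = FALSE, correct = FALSE)
      stat <- unname(wt$statistic)
      dirn <- sign(stats::median(xc) - stats::median(xo))
      p <- wt$p.value
      test <- "mann_whitney_u"
    }
    data.frame(phenotype = v, test = test, carrier_n = length(xc),
               other_n = length(xo), statistic = stat, direction = dirn,
               p = p, underpowered = min(length(xc), length(xo)) < 5)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out[, c("phenotype", "test", "carrier_n", "other_n", "statistic",
          "direction", "p", "p_adjusted", "underpowered")]
}

#' Seeded (hypothesis-driven) signature mining
#'
#' [mine_signatures()] with the candidate space restricted to combinations
#' containing at least one feature on a seed SNP; FDR validation runs within
#' this reduced space, which is what lets associations found in one cohort
#' be tested with adequate power in a second. With every SNP seeded the
#' search space (and output) coincides with the hypothesis-free search.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param seed_snps character vector of seed SNP ids (seeds absent from the
#'   matrix are logged and dropped; an empty effective seed list yields an
#'   empty result).
#' @param config a [mining_config()].
#' @return a `signature_set`.
#' @export
seeded_mine <- function(gm, cohort, seed_snps, config = mining_config()) {
  mine_signatures(gm, cohort, config, seed_snps = seed_snps)
}
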