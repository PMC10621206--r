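# Shared fixtures: tiny genotype matrices, minimal signature sets, and an
# independent exhaustive mining oracle used for equivalence checks.

toy_gm <- function(states, sample_prefix = "s", snp_prefix = "snp",
                   chrom = "1", pos = NULL) {
  states <- as.matrix(states)
  if (is.null(rownames(states))) {
    rownames(states) <- paste0(sample_prefix, seq_len(nrow(states)))
  }
  if (is.null(colnames(states))) {
    colnames(states) <- paste0(snp_prefix, seq_len(ncol(states)))
  }
  if (is.null(pos)) pos <- 1000L * seq_len(ncol(states))
  genotype_matrix(states,
                  data.frame(snp_id = colnames(states), chrom = chrom,
                             pos = pos, ref_allele = "A", alt_allele = "C",
                             minor_is_alt = TRUE))
}

# minimal signature-set stand-in: just the feature_sets attribute plus the
# features column that consumers read
fake_signature_set <- function(feat_sets) {
  df <- data.frame(
    order = vapply(feat_sets, nrow, integer(1)),
    features = vapply(feat_sets, function(fs) {
      paste(paste0(fs$snp_id, ":", fs$state), collapse = ";")
    }, character(1)),
    validated = TRUE)
  structure(df, feature_sets = feat_sets,
            class = c("signature_set", "data.frame"))
}

# independent two-sided Fisher p: direct dhyper mass summation
oracle_fisher_p <- function(k, m, n_case, n_ctrl) {
  lo <- max(0L, m - n_ctrl)
  hi <- min(m, n_case)
  d <- dhyper(lo:hi, n_case, n_ctrl, m)
  sum(d[d <= d[k - lo + 1L] * (1 + 1e-7)])
}

# Independent exhaustive miner for max_order <= 2: enumerates every
# singleton and every pair of features on distinct SNPs, applies the
# prevalence / alpha / OR filters, the nested-membership dedup, and the
# permutation-calibrated BH validation, all with its own code.
oracle_mine <- function(gm, cohort, config) {
  ids <- sort(intersect(c(cohort_cases(cohort), cohort_controls(cohort)),
                        rownames(gm$states)))
  s <- gm$states[ids, sort(colnames(gm$states)), drop = FALSE]
  y <- as.numeric(ids %in% cohort_cases(cohort))
  n_case <- sum(y); n_ctrl <- sum(1 - y)
  feats <- expand.grid(state = 0:2, snp = colnames(s),
                       stringsAsFactors = FALSE)[, 2:1]
  combos <- c(lapply(seq_len(nrow(feats)), function(i) feats[i, ]),
              unlist(lapply(seq_len(nrow(feats) - 1), function(i) {
                lapply((i + 1):nrow(feats), function(j) {
                  if (feats$snp[i] == feats$snp[j]) return(NULL)
                  rbind(feats[i, ], feats[j, ])
                })
              }), recursive = FALSE))
  combos <- Filter(Negate(is.null), combos)
  memb <- vapply(combos, function(cb) {
    g <- s[, cb$snp, drop = FALSE]
    as.numeric(rowSums(g == rep(cb$state, each = nrow(g))) == nrow(cb) &
                 rowSums(is.na(g)) == 0)
  }, numeric(length(ids)))
  min_count <- ceiling(config$min_case_prevalence * n_case)
  eval_labels <- function(yy) {
    k <- as.vector(crossprod(memb, yy))
    m <- colSums(memb)
    keep <- which(k >= min_count)
    p <- vapply(keep, function(i) oracle_fisher_p(k[i], m[i], n_case, n_ctrl),
                numeric(1))
    ctrl <- m[keep] - k[keep]
    or <- ifelse(k[keep] == 0 | ctrl == 0,
                 (k[keep] + 0.5) / (ctrl + 0.5), k[keep] / ctrl) /
      (n_case / n_ctrl)
    pass <- p < config$alpha & or > 1
    list(idx = keep[pass], p = p[pass], or = or[pass], k = k[keep][pass],
         m = m[keep][pass])
  }
  obs <- eval_labels(y)
  B <- config$n_permutations
  perm_p <- withr::with_seed(config$random_seed, {
    L <- matrix(0, length(y), B)
    for (b in seq_len(B)) L[sample.int(length(y)), b] <- y
    lapply(seq_len(B), function(b) eval_labels(L[, b])$p)
  })
  # permutation-calibrated BH step-up, reimplemented
  all_perm <- sort(unlist(perm_p))
  o <- order(obs$p)
  q <- numeric(length(o))
  fdr <- vapply(seq_along(o), function(i) {
    e <- sum(all_perm <= obs$p[o[i]] * (1 + 1e-12)) / B
    min(e / i, 1)
  }, numeric(1))
  for (i in seq_along(o)) q[o[i]] <- min(fdr[i:length(o)])
  # nested-membership dedup
  drop <- rep(FALSE, length(obs$idx))
  for (a in seq_along(obs$idx)) for (b in seq_along(obs$idx)) {
    ca <- combos[[obs$idx[a]]]; cb <- combos[[obs$idx[b]]]
    if (nrow(ca) < nrow(cb) &&
        all(paste(ca$snp, ca$state) %in% paste(cb$snp, cb$state)) &&
        identical(memb[, obs$idx[a]], memb[, obs$idx[b]])) {
      drop[b] <- TRUE
    }
  }
  data.frame(
    features = vapply(obs$idx, function(i) {
      cb <- combos[[i]][order(combos[[i]]$snp, combos[[i]]$state), ]
      paste(paste0(cb$snp, ":", cb$state), collapse = ";")
    }, character(1)),
    order = vapply(obs$idx, function(i) nrow(combos[[i]]), integer(1)),
    case_count = obs$k, control_count = obs$m - obs$k,
    odds_ratio = obs$or, p = obs$p, q = q,
    validated = q <= config$fdr_q)[!drop, ]
}

write_fixture_gff <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t10000\t12000\t.\t+\t.\tID=geneA;Name=GA",
    "1\tsrc\tmRNA\t10000\t12000\t.\t+\t.\tID=mrnaA;Parent=geneA",
    "1\tsrc\tCDS\t10000\t10500\t.\t+\t0\tID=cdsA1;Parent=mrnaA",
    "1\tsrc\tCDS\t11500\t12000\t.\t+\t0\tID=cdsA2;Parent=mrnaA",
    "1\tsrc\tgene\t50000\t56000\t.\t-\t.\tID=geneB;Name=GB",
    "1\tsrc\tCDS\t51000\t52000\t.\t-\t0\tID=cdsB1;Parent=geneB"), path)
}

# direct constructor for ega_blocks-shaped tables, for classifier tests
make_blocks <- function(inter_df, ega_or, complete = TRUE,
                        critical = "crit") {
  df <- inter_df
  df$critical_state <- 1L
  df$ega_odds_ratio <- ega_or
  df$complete <- complete
  structure(df, critical_snp = critical, interacting = names(inter_df),
            class = c("ega_blocks", "data.frame"))
}
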