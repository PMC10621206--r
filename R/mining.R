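# Layered combinatorial mining of SNP-genotype disease signatures with
# permutation-calibrated FDR validation.
#
# A feature is one exact genotype state (0/1/2) at one SNP. Signatures of
# order k are conjunctions of k features on distinct SNPs. The search runs
# in layers of increasing order: the candidate pool at each layer is every
# combination whose case prevalence (case members / total cases) reaches
# min_case_prevalence -- prevalence is anti-monotone under conjunction, so
# extending only prevalence-passing combinations loses nothing -- and a beam
# of the most associated prevalence-passing combinations is carried forward.
# Combinations additionally passing p < alpha (two-sided Fisher exact) with
# odds ratio > 1 relative to the cohort mean odds become candidate
# signatures. Validation re-runs the identical search on label-permuted data
# and applies a Benjamini-Hochberg-style step-up in which the expected
# number of false discoveries at each observed p-value is estimated from the
# permutation searches.

#' Mining configuration
#'
#' @param max_order largest signature order searched (default 5).
#' @param min_case_prevalence minimum fraction of cases carrying the
#'   combination (default 0.05).
#' @param alpha per-combination Fisher p threshold (default 0.05).
#' @param fdr_q validation FDR level (default 0.05).
#' @param n_permutations label permutations used for validation
#'   (default 199; must be at least 19).
#' @param beam_width prevalence-passing combinations carried to the next
#'   layer, ranked by p (ties broken lexicographically by snp id and state);
#'   `Inf` disables beam truncation (default 25).
#' @param random_seed governs the label permutations (default 1).
#' @return list of class `mining_config`.
#' @export
mining_config <- function(max_order = 5, min_case_prevalence = 0.05,
                          alpha = 0.05, fdr_q = 0.05, n_permutations = 199,
                          beam_width = 25, random_seed = 1) {
  stopifnot(max_order >= 1, min_case_prevalence > 0, min_case_prevalence < 1,
            alpha > 0, alpha < 1, fdr_q > 0, fdr_q < 1, beam_width >= 1)
  structure(list(max_order = as.integer(max_order),
                 min_case_prevalence = min_case_prevalence, alpha = alpha,
                 fdr_q = fdr_q, n_permutations = as.integer(n_permutations),
                 beam_width = beam_width,
                 random_seed = as.integer(random_seed)),
            class = "mining_config")
}

#' Match a signature's features against every sample
#'
#' A sample is a `member` iff it has exactly the feature's genotype state at
#' every feature SNP, `incomplete` iff any component genotype is missing,
#' otherwise a `non-member`. Incomplete samples are excluded from counts
#' downstream.
#'
#' @param gm a [genotype_matrix()].
#' @param features data.frame with columns `snp_id`, `state` (distinct SNPs).
#' @return named character vector over samples with values `"member"`,
#'   `"non-member"`, `"incomplete"`. The empty feature set matches everyone.
#' @export
match_signature <- function(gm, features) {
  if (nrow(features) == 0L) {
    return(stats::setNames(rep("member", nrow(gm$states)),
                           rownames(gm$states)))
  }
  if (anyDuplicated(features$snp_id)) {
    stop("validation error: duplicate SNP across signature features")
  }
  missing_snps <- setdiff(features$snp_id, snp_ids(gm))
  if (length(missing_snps)) {
    stop("feature SNPs absent from matrix: ",
         paste(missing_snps, collapse = ", "))
  }
  s <- gm$states[, features$snp_id, drop = FALSE]
  eq <- sweep(s, 2, as.integer(features$state), "==")
  any_na <- rowSums(is.na(s)) > 0
  member <- rowSums(eq, na.rm = TRUE) == nrow(features) & !any_na
  out <- ifelse(any_na, "incomplete", ifelse(member, "member", "non-member"))
  stats::setNames(out, rownames(gm$states))
}

#' Signature statistics against a cohort
#'
#' Counts complete members among cases and controls and computes the odds
#' ratio relative to the cohort mean odds and the two-sided Fisher exact
#' p-value (totals are the full case and control counts of the cohort).
#'
#' @param membership output of [match_signature()].
#' @param cohort a `cohort_assignment`.
#' @return list: `case_count`, `control_count`, `odds_ratio`, `p_value`,
#'   `corrected`.
#' @export
signature_stats <- function(membership, cohort) {
  cases <- cohort_cases(cohort)
  controls <- cohort_controls(cohort)
  stopifnot(length(cases) >= 1, length(controls) >= 1)
  if (all(membership[c(cases, controls)] == "incomplete")) {
    stop("membership is incomplete for every cohort sample")
  }
  cc <- sum(membership[cases] == "member", na.rm = TRUE)
  nc <- sum(membership[controls] == "member", na.rm = TRUE)
  st <- signature_stats_from_counts(cc, nc, length(cases), length(controls))
  c(list(case_count = cc, control_count = nc), st)
}

# ---- internal search machinery -------------------------------------------

# Canonical analysis space: samples sorted by id and restricted to
# case/control, SNPs sorted by id, features = 3 states per SNP.
.mining_space <- function(gm, cohort) {
  analysis <- sort(c(cohort_cases(cohort), cohort_controls(cohort)))
  dropped <- sum(!analysis %in% rownames(gm$states))
  if (dropped > 0) {
    message(dropped, " cohort sample(s) absent from the genotype matrix, dropped")
    analysis <- analysis[analysis %in% rownames(gm$states)]
  }
  snps <- sort(colnames(gm$states))
  s <- gm$states[analysis, snps, drop = FALSE]
  n <- nrow(s); K <- ncol(s)
  X <- matrix(0, n, 3L * K)
  for (st in 0:2) {
    idx <- 3L * (seq_len(K) - 1L) + st + 1L
    Xs <- (s == st)
    Xs[is.na(Xs)] <- FALSE
    X[, idx] <- Xs
  }
  feat <- data.frame(snp = rep(seq_len(K), each = 3L),
                     snp_id = rep(snps, each = 3L), state = rep(0:2, K))
  feat$key <- paste0(feat$snp_id, ":", feat$state)
  lab <- stats::setNames(cohort$label, cohort$sample_id)[analysis]
  y <- as.numeric(lab == "case")
  # fixed 48-bit per-feature hashes: canonical combination keys are exact
  # integer-valued double sums, order-independent, identical across scans
  hash <- withr::with_seed(193L, floor(stats::runif(3L * K) * 2^48))
  list(X = X, feat = feat, y = y, m_all = colSums(X), hash = hash,
       samples = analysis, n_case = sum(y), n_ctrl = sum(1 - y))
}

.or_vec <- function(k, m, mean_odds) {
  ctrl <- m - k
  zero <- (k == 0) | (ctrl == 0)
  or <- ifelse(zero, (k + 0.5) / (ctrl + 0.5), k / pmax(ctrl, 1)) / mean_odds
  list(or = or, corrected = zero)
}

# One full layered search for a given 0/1 case label vector. Returns the
# p-values of every combination passing all filters; with detail = TRUE also
# the feature index sets, counts and odds ratios. Combinations are extended
# by any feature on a SNP not already in the combination; the same set
# reached via different parents is collapsed through its canonical hash key,
# so each combination is evaluated exactly once per scan.
.scan <- function(sp, y, config, ft, detail = FALSE, seed_feats = NULL) {
  X <- sp$X
  nF <- ncol(X)
  n_case <- sum(y)
  n_ctrl <- length(y) - n_case
  min_count <- ceiling(config$min_case_prevalence * n_case)
  mean_odds <- n_case / n_ctrl
  seeded <- !is.null(seed_feats)

  out_p <- list(); out_sets <- list(); out_k <- list(); out_m <- list()
  out_or <- list(); out_corr <- list(); out_order <- list()
  layer_sizes <- integer(0)

  record <- function(layer, pass, set_fn, k, m, p, orv) {
    layer_sizes[layer] <<- sum(pass)
    out_p[[layer]] <<- p[pass]
    if (detail) {
      out_sets[[layer]] <<- set_fn(which(pass))
      out_k[[layer]] <<- k[pass]; out_m[[layer]] <<- m[pass]
      out_or[[layer]] <<- orv$or[pass]; out_corr[[layer]] <<- orv$corrected[pass]
      out_order[[layer]] <<- rep(layer, sum(pass))
    }
  }

  # layer 1
  k1 <- as.vector(crossprod(X, y))
  elig <- if (seeded) sort(seed_feats) else seq_len(nF)
  cand <- elig[k1[elig] >= min_count]
  p1 <- fisher_lookup(ft, k1[cand], sp$m_all[cand])
  orv1 <- .or_vec(k1[cand], sp$m_all[cand], mean_odds)
  pass1 <- p1 < config$alpha & orv1$or > 1
  record(1L, pass1, function(idx) as.list(cand[idx]),
         k1[cand], sp$m_all[cand], p1, orv1)

  bw <- config$beam_width
  bo <- order(p1, cand)
  bo <- bo[seq_len(min(bw, length(bo)))]
  if (length(bo) == 0L || config$max_order < 2L) {
    return(.scan_result(out_p, out_sets, out_k, out_m, out_or, out_corr,
                        out_order, layer_sizes, detail))
  }
  beam_sets <- as.list(cand[bo])
  beam_keys <- sp$hash[cand[bo]]
  V <- X[, cand[bo], drop = FALSE]

  for (layer in 2:config$max_order) {
    b <- ncol(V)
    if (b == 0L) break
    totals <- crossprod(X, V)             # nF x b
    kc <- crossprod(X, V * y)
    mask <- matrix(TRUE, nF, b)
    for (j in seq_len(b)) {
      mask[sp$feat$snp %in% sp$feat$snp[beam_sets[[j]]], j] <- FALSE
    }
    sel <- which(mask & kc >= min_count, arr.ind = TRUE)
    if (nrow(sel) == 0L) break
    f_i <- sel[, 1L]; j_i <- sel[, 2L]
    keys <- beam_keys[j_i] + sp$hash[f_i]
    keep <- !duplicated(keys)
    f_i <- f_i[keep]; j_i <- j_i[keep]; keys <- keys[keep]
    idx2 <- cbind(f_i, j_i)
    kk <- kc[idx2]; mm <- totals[idx2]
    pp <- fisher_lookup(ft, kk, mm)
    orv <- .or_vec(kk, mm, mean_odds)
    pass <- pp < config$alpha & orv$or > 1
    record(layer, pass, function(idx) {
      lapply(idx, function(i) sort(c(beam_sets[[j_i[i]]], f_i[i])))
    }, kk, mm, pp, orv)
    if (layer == config$max_order) break
    bo <- order(pp, j_i, f_i)
    bo <- bo[seq_len(min(bw, length(bo)))]
    beam_sets <- lapply(bo, function(i) c(beam_sets[[j_i[i]]], f_i[i]))
    beam_keys <- keys[bo]
    V <- V[, j_i[bo], drop = FALSE] * X[, f_i[bo], drop = FALSE]
  }
  .scan_result(out_p, out_sets, out_k, out_m, out_or, out_corr, out_order,
               layer_sizes, detail)
}

.scan_result <- function(out_p, out_sets, out_k, out_m, out_or, out_corr,
                         out_order, layer_sizes, detail) {
  res <- list(p = unlist(out_p, use.names = FALSE),
              layer_sizes = layer_sizes)
  if (detail) {
    res$sets <- do.call(c, out_sets)
    res$k <- unlist(out_k, use.names = FALSE)
    res$m <- unlist(out_m, use.names = FALSE)
    res$or <- unlist(out_or, use.names = FALSE)
    res$corrected <- unlist(out_corr, use.names = FALSE)
    res$order <- unlist(out_order, use.names = FALSE)
    if (is.null(res$sets)) res$sets <- list()
  }
  res
}

# ---- public mining interface ---------------------------------------------

#' Mine and validate combinatorial disease signatures
#'
#' Layered beam search over SNP-genotype combinations (see the package
#' vignette for the search and validation model), followed by permutation
#' validation: the identical search is re-run on `n_permutations`
#' label-permuted datasets and candidates are marked validated when their
#' permutation-calibrated BH q-value is at most `config$fdr_q`. Signatures
#' whose feature sets are nested and whose memberships are identical are
#' collapsed to the smaller set. Fully deterministic given
#' `config$random_seed`; output is invariant to the sample and SNP order of
#' the input matrix (both are canonicalised internally).
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param cohort a `cohort_assignment` with at least one case and one control.
#' @param config a [mining_config()].
#' @param seed_snps optional character vector of seed SNP ids: the search is
#'   then restricted to combinations containing at least one seed-SNP
#'   feature (hypothesis-driven "seeded" mining). Seeds absent from the
#'   matrix are logged and dropped.
#' @return a `signature_set`: data.frame with columns `order`, `features`
#'   (semicolon-joined `snp:state`), `case_count`, `control_count`,
#'   `odds_ratio`, `p`, `q`, `validated`, `or_corrected`, sorted by `q` then
#'   descending odds ratio; attributes `config`, `layer_sizes`, `n_case`,
#'   `n_control`, `feature_sets` (list of data.frames).
#' @export
mine_signatures <- function(gm, cohort, config = mining_config(),
                            seed_snps = NULL) {
  if (config$n_permutations < 19L) {
    stop("n_permutations must be at least 19 to resolve alpha 0.05")
  }
  sp <- .mining_space(gm, cohort)
  seed_feats <- NULL
  if (!is.null(seed_snps)) {
    missing_seed <- setdiff(seed_snps, sp$feat$snp_id)
    if (length(missing_seed)) {
      message("seeded_mine: dropping ", length(missing_seed),
              " seed SNP(s) absent from matrix")
    }
    seed_feats <- which(sp$feat$snp_id %in% seed_snps)
    if (length(seed_feats) == 0L) {
      return(.empty_signature_set(config, sp))
    }
  }
  ft <- fisher_table(sp$n_case, sp$n_ctrl)
  obs <- .scan(sp, sp$y, config, ft, detail = TRUE, seed_feats = seed_feats)
  if (length(obs$p) == 0L) return(.empty_signature_set(config, sp))

  L <- perm_label_matrix(sp$y, config$n_permutations, config$random_seed)
  perm_p <- lapply(seq_len(ncol(L)), function(b) {
    .scan(sp, L[, b], config, ft, detail = FALSE, seed_feats = seed_feats)$p
  })
  q <- perm_bh_q(obs$p, perm_p)

  # memberships of all candidates (complete members only; missing genotype
  # at any component excludes the sample)
  Vc <- vapply(obs$sets, function(set) {
    v <- sp$X[, set[1L]]
    for (f in set[-1L]) v <- v * sp$X[, f]
    v
  }, numeric(nrow(sp$X)))
  Vc <- matrix(Vc, nrow = nrow(sp$X))

  drop <- .dedup_nested(obs$sets, obs$k, obs$m, Vc)

  keep <- which(!drop)
  feat_sets <- lapply(obs$sets[keep], function(set) {
    fs <- sp$feat[sort(set), c("snp_id", "state")]
    rownames(fs) <- NULL
    fs
  })
  feat_str <- vapply(feat_sets, function(fs) {
    paste(paste0(fs$snp_id, ":", fs$state), collapse = ";")
  }, character(1))
  df <- data.frame(order = obs$order[keep], features = feat_str,
                   case_count = obs$k[keep],
                   control_count = obs$m[keep] - obs$k[keep],
                   odds_ratio = obs$or[keep], p = obs$p[keep], q = q[keep],
                   validated = q[keep] <= config$fdr_q,
                   or_corrected = obs$corrected[keep])
  o <- order(df$q, -df$odds_ratio, df$features)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  feat_sets <- feat_sets[o]
  message(sprintf(
    "mine_signatures: seed=%d, candidates per order [%s], %d validated",
    config$random_seed, paste(attr(obs, "layer_sizes") %||% obs$layer_sizes,
                              collapse = ", "), sum(df$validated)))
  structure(df, config = config, layer_sizes = obs$layer_sizes,
            n_case = sp$n_case, n_control = sp$n_ctrl,
            feature_sets = feat_sets,
            class = c("signature_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_signature_set <- function(config, sp) {
  df <- data.frame(order = integer(0), features = character(0),
                   case_count = integer(0), control_count = integer(0),
                   odds_ratio = numeric(0), p = numeric(0), q = numeric(0),
                   validated = logical(0), or_corrected = logical(0))
  structure(df, config = config, layer_sizes = integer(0),
            n_case = sp$n_case, n_control = sp$n_ctrl, feature_sets = list(),
            class = c("signature_set", "data.frame"))
}

# drop candidates whose feature set strictly contains another candidate's
# set with identical (complete-member) membership
.dedup_nested <- function(sets, k, m, Vc) {
  drop <- logical(length(sets))
  key_cnt <- paste(k, m)
  for (grp in split(seq_along(sets), key_cnt)) {
    if (length(grp) < 2L) next
    memb_key <- apply(Vc[, grp, drop = FALSE], 2,
                      function(v) paste(which(v > 0), collapse = ","))
    for (sub in split(grp, memb_key)) {
      if (length(sub) < 2L) next
      for (i in sub) for (j in sub) {
        if (i != j && length(sets[[i]]) < length(sets[[j]]) &&
            all(sets[[i]] %in% sets[[j]])) {
          drop[j] <- TRUE
        }
      }
    }
  }
  drop
}

#' Validated subset of a signature set
#' @param signatures a `signature_set`.
#' @return `signature_set` restricted to validated rows.
#' @export
validated_signatures <- function(signatures) {
  keep <- which(signatures$validated)
  out <- signatures[keep, , drop = FALSE]
  attributes(out)[c("config", "layer_sizes", "n_case", "n_control")] <-
    attributes(signatures)[c("config", "layer_sizes", "n_case", "n_control")]
  attr(out, "feature_sets") <- attr(signatures, "feature_sets")[keep]
  class(out) <- c("signature_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' Parse a semicolon-joined feature string
#' @param features_str e.g. `"rs1:0;rs2:1"`.
#' @return data.frame with `snp_id`, `state`.
#' @export
parse_features <- function(features_str) {
  parts <- strsplit(features_str, ";", fixed = TRUE)[[1]]
  sp <- strsplit(parts, ":", fixed = TRUE)
  data.frame(snp_id = vapply(sp, function(x) paste(x[-length(x)], collapse = ":"),
                             character(1)),
             state = as.integer(vapply(sp, function(x) x[length(x)],
                                       character(1))))
}

#' Write a signature table
#' @param signatures a `signature_set`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  utils::write.table(as.data.frame(signatures), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fraction of cases carrying at least one validated signature
#'
#' The case-coverage summary of a mining run: how much of the case
#' population is explained by at least one validated signature.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param signatures a `signature_set`.
#' @return fraction in `[0, 1]` (0 when nothing validated).
#' @export
case_coverage <- function(gm, cohort, signatures) {
  val <- validated_signatures(signatures)
  cases <- cohort_cases(cohort)
  if (nrow(val) == 0L || length(cases) == 0L) return(0)
  covered <- rep(FALSE, length(cases))
  for (fs in attr(val, "feature_sets")) {
    covered <- covered | (match_signature(gm, fs)[cases] == "member")
  }
  mean(covered)
}

#' Per-candidate permutation FDR for pre-specified signatures
#'
#' The classic per-candidate permutation procedure, for an externally
#' fixed candidate list: for each label permutation every candidate's Fisher
#' p is recomputed, the empirical p is
#' `(1 + #\{perm p <= observed p\}) / (1 + n_permutations)`, and
#' Benjamini-Hochberg adjustment across candidates yields q. Appropriate for
#' candidates specified independently of the data (e.g. replication of known
#' signatures); candidates selected by the search itself are validated
#' inside [mine_signatures()], which repeats the selection on permuted data.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param candidates list of feature data.frames (`snp_id`, `state`), or a
#'   `signature_set`.
#' @param n_permutations at least 19.
#' @param seed RNG seed for the permutations.
#' @return data.frame with `features`, `p_obs`, `p_emp`, `q`, `validated`
#'   (q at most 0.05).
#' @export
permutation_fdr <- function(gm, cohort, candidates, n_permutations = 199,
                            seed = 1) {
  if (n_permutations < 19L) {
    stop("n_permutations must be at least 19 to resolve alpha 0.05")
  }
  if (inherits(candidates, "signature_set")) {
    candidates <- attr(candidates, "feature_sets")
  }
  sp <- .mining_space(gm, cohort)
  ft <- fisher_table(sp$n_case, sp$n_ctrl)
  V <- vapply(candidates, function(fs) {
    idx <- match(paste0(fs$snp_id, ":", fs$state), sp$feat$key)
    if (anyNA(idx)) stop("candidate features absent from matrix")
    v <- sp$X[, idx[1L]]
    for (f in idx[-1L]) v <- v * sp$X[, f]
    v
  }, numeric(nrow(sp$X)))
  V <- matrix(V, nrow = nrow(sp$X))
  m <- colSums(V)
  k_obs <- as.vector(crossprod(V, sp$y))
  p_obs <- fisher_lookup(ft, k_obs, m)
  L <- perm_label_matrix(sp$y, n_permutations, seed)
  Kp <- crossprod(V, L) # candidates x B
  p_emp <- vapply(seq_along(candidates), function(j) {
    pj <- fisher_lookup(ft, Kp[j, ], rep(m[j], ncol(Kp)))
    (1 + sum(pj <= p_obs[j] * (1 + 1e-12))) / (1 + n_permutations)
  }, numeric(1))
  q <- stats::p.adjust(p_emp, method = "BH")
  data.frame(
    features = vapply(candidates, function(fs) {
      paste(paste0(fs$snp_id, ":", fs$state), collapse = ";")
    }, character(1)),
    p_obs = p_obs, p_emp = p_emp, q = q, validated = q <= 0.05)
}

#' Single-SNP (allelic) association baseline
#'
#' Per-SNP two-sided Fisher exact test on minor-allele counts (2 x 2 table
#' of minor vs major alleles in cases vs controls), flagging any SNP passing
#' the genome-wide significance threshold 5e-8. Monomorphic SNPs report
#' p = 1.
#'
#' @param gm a QC'd [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @return data.frame: `snp_id`, `case_minor`, `case_alleles`,
#'   `control_minor`, `control_alleles`, `p`, `genome_wide_significant`.
#' @export
single_snp_association <- function(gm, cohort) {
  cases <- cohort_cases(cohort)
  controls <- cohort_controls(cohort)
  sc <- gm$states[cases, , drop = FALSE]
  sn <- gm$states[controls, , drop = FALSE]
  a <- colSums(sc, na.rm = TRUE)              # minor alleles in cases
  an <- 2 * colSums(!is.na(sc))               # called alleles in cases
  b <- colSums(sn, na.rm = TRUE)
  bn <- 2 * colSums(!is.na(sn))
  p <- vapply(seq_len(ncol(gm$states)), function(j) {
    tot_minor <- a[j] + b[j]
    if (tot_minor == 0 || tot_minor == an[j] + bn[j]) return(1)
    .fisher_p_one(as.integer(a[j]), as.integer(tot_minor),
                  as.integer(an[j]), as.integer(bn[j]))
  }, numeric(1))
  data.frame(snp_id = colnames(gm$states), case_minor = a, case_alleles = an,
             control_minor = b, control_alleles = bn, p = p,
             genome_wide_significant = p < 5e-8, row.names = NULL)
}
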