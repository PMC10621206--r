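# Disease-architecture network construction from validated signatures, and
# critical-SNP scoring by cross-validated Random Forest prediction plus a
# permutation test on signature counts.

#' Merge validated signatures into a disease-architecture network
#'
#' Nodes are SNP-genotype features; every validated signature induces a
#' clique over its features with edge weight equal to the number of cases
#' carrying the signature, and features of different signatures are linked
#' with weight equal to the number of cases carrying both signatures
#' (union over all signature pairs connecting the two features; pairs
#' sharing no case add no edge). Communities come from greedy modularity
#' maximisation on the weighted graph.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param signatures a `signature_set` (typically
#'   [validated_signatures()] output) with at least one row.
#' @return a `disease_architecture`: list with `graph` (igraph, weighted),
#'   `nodes` (data.frame `feature`, `snp_id`, `state`, `community`),
#'   `edges` (data.frame `from`, `to`, `weight`).
#' @export
build_architecture <- function(gm, cohort, signatures) {
  feat_sets <- attr(signatures, "feature_sets")
  if (length(feat_sets) == 0L) stop("need at least one validated signature")
  cases <- cohort_cases(cohort)
  case_sets <- lapply(feat_sets, function(fs) {
    memb <- match_signature(gm, fs)
    cases[memb[cases] == "member"]
  })
  feat_keys <- lapply(feat_sets, function(fs) paste0(fs$snp_id, ":", fs$state))
  edge_cases <- new.env(parent = emptyenv())
  add_edge <- function(a, b, ids) {
    if (a == b) return(invisible())
    key <- paste(sort(c(a, b)), collapse = "\r")
    prev <- get0(key, envir = edge_cases, ifnotfound = character(0))
    assign(key, union(prev, ids), envir = edge_cases)
  }
  ns <- length(feat_sets)
  for (i in seq_len(ns)) {
    for (j in i:ns) {
      shared <- if (i == j) case_sets[[i]] else
        intersect(case_sets[[i]], case_sets[[j]])
      if (length(shared) == 0L) next
      for (a in feat_keys[[i]]) for (b in feat_keys[[j]]) add_edge(a, b, shared)
    }
  }
  keys <- ls(edge_cases)
  nodes <- sort(unique(unlist(feat_keys)))
  if (length(keys)) {
    pair <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    edges <- data.frame(from = pair[, 1], to = pair[, 2],
                        weight = vapply(keys, function(k) {
                          length(get(k, envir = edge_cases))
                        }, numeric(1)), row.names = NULL)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  gr <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                      vertices = data.frame(name = nodes))
  comm <- igraph::cluster_fast_greedy(gr, weights = igraph::E(gr)$weight)
  node_df <- data.frame(feature = nodes,
                        snp_id = sub(":[0-2]$", "", nodes),
                        state = as.integer(sub("^.*:", "", nodes)),
                        community = igraph::membership(comm)[nodes])
  rownames(node_df) <- NULL
  structure(list(graph = gr, nodes = node_df, edges = edges),
            class = "disease_architecture")
}

#' @export
print.disease_architecture <- function(x, ...) {
  cat(sprintf("disease_architecture: %d features, %d edges, %d communities\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$community))))
  invisible(x)
}

#' Export a disease architecture as GraphML and a weighted edge list
#'
#' @param arch a `disease_architecture`.
#' @param graphml_path GraphML output path (skipped if `NULL`).
#' @param edgelist_path tab-separated `from`, `to`, `weight` (skipped if
#'   `NULL`).
#' @return `arch`, invisibly.
#' @export
export_architecture <- function(arch, graphml_path = NULL,
                                edgelist_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(arch$graph, graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    utils::write.table(arch$edges, edgelist_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(arch)
}

#' Score candidate critical SNPs by cross-validated Random Forest accuracy
#'
#' For each candidate SNP, a Random Forest (100 trees) is trained to predict
#' the case-control split from the SNP's genotype state -- by default
#' together with the states of its signature partners -- under stratified
#' k-fold cross-validation; the report carries the mean held-out accuracy
#' and the majority-class baseline. Deterministic given `seed`.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param signatures a `signature_set`; candidates default to every SNP
#'   appearing in at least one validated signature.
#' @param candidate_snps optional explicit SNP ids (must appear in the
#'   signatures).
#' @param folds cross-validation folds (default 5).
#' @param seed RNG seed (default 1).
#' @param include_partners include signature-partner SNP states as
#'   predictors (default TRUE).
#' @param ntree forest size (default 100).
#' @return data.frame: `snp_id`, `n_signatures`, `rf_accuracy`,
#'   `majority_baseline`.
#' @export
rf_score_critical_snps <- function(gm, cohort, signatures,
                                   candidate_snps = NULL, folds = 5,
                                   seed = 1, include_partners = TRUE,
                                   ntree = 100) {
  feat_sets <- attr(signatures, "feature_sets")
  sig_snps <- lapply(feat_sets, function(fs) fs$snp_id)
  all_sig_snps <- unique(unlist(sig_snps))
  if (is.null(candidate_snps)) candidate_snps <- sort(all_sig_snps)
  bad <- setdiff(candidate_snps, all_sig_snps)
  if (length(bad)) {
    stop("candidate SNP(s) not in any signature: ", paste(bad, collapse = ", "))
  }
  ids <- c(cohort_cases(cohort), cohort_controls(cohort))
  y <- factor(ifelse(ids %in% cohort_cases(cohort), "case", "control"))
  maj <- max(table(y)) / length(y)
  res <- lapply(candidate_snps, function(snp) {
    in_sig <- vapply(sig_snps, function(s) snp %in% s, logical(1))
    preds <- snp
    if (include_partners) {
      preds <- unique(c(snp, unlist(sig_snps[in_sig])))
    }
    x <- as.data.frame(lapply(as.data.frame(gm$states[ids, preds,
                                                      drop = FALSE]),
                              function(v) {
                                factor(ifelse(is.na(v), "miss",
                                              as.character(v)),
                                       levels = c("0", "1", "2", "miss"))
                              }))
    names(x) <- make.names(preds)
    acc <- withr::with_seed(seed, {
      fold_id <- .stratified_folds(y, folds)
      vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) {
          stop("stratification error: a fold contains a single class")
        }
        fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                          ntree = ntree)
        mean(stats::predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
      }, numeric(1))
    })
    data.frame(snp_id = snp, n_signatures = sum(in_sig),
               rf_accuracy = mean(acc), majority_baseline = maj)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.stratified_folds <- function(y, folds) {
  fold_id <- integer(length(y))
  for (lvl in levels(y)) {
    idx <- sample(which(y == lvl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Permutation test for a critical SNP's signature count
#'
#' The statistic is the number of combinations containing the SNP that pass
#' the mining filters (case prevalence, Fisher p < alpha, odds ratio > 1)
#' when the search is restricted, for tractability, to the SNP's observed
#' partner feature space (all features of the validated signatures
#' containing the SNP). The same restricted search is re-run under label
#' permutations; the empirical p is
#' `(1 + #\{perm stat >= observed stat\}) / (1 + n_permutations)`.
#'
#' @param gm a [genotype_matrix()].
#' @param cohort a `cohort_assignment`.
#' @param snp SNP id appearing in at least one validated signature.
#' @param signatures a `signature_set`.
#' @param n_permutations at least 19 (default 199).
#' @param seed RNG seed (default 1).
#' @param config a [mining_config()] supplying the filter thresholds.
#' @return list: `observed_count`, `permutation_p`.
#' @export
critical_permutation_test <- function(gm, cohort, snp, signatures,
                                      n_permutations = 199, seed = 1,
                                      config = mining_config()) {
  if (n_permutations < 19L) {
    stop("n_permutations must be at least 19 to resolve alpha 0.05")
  }
  feat_sets <- attr(signatures, "feature_sets")
  in_sig <- vapply(feat_sets, function(fs) snp %in% fs$snp_id, logical(1))
  if (!any(in_sig)) stop("SNP ", snp, " is not in any validated signature")
  partner_feats <- unique(do.call(rbind, feat_sets[in_sig]))
  max_ord <- max(vapply(feat_sets[in_sig], nrow, integer(1)))
  sp <- .mining_space(gm, cohort)
  feat_idx <- match(paste0(partner_feats$snp_id, ":", partner_feats$state),
                    sp$feat$key)
  snp_feats <- feat_idx[partner_feats$snp_id == snp]
  other <- feat_idx[partner_feats$snp_id != snp]
  # enumerate all combos: one feature of the SNP + up to max_ord-1 partners
  combos <- list()
  for (s0 in snp_feats) {
    for (k in 0:(max_ord - 1L)) {
      if (k > length(other)) next
      sub <- if (k == 0L) list(integer(0)) else
        utils::combn(other, k, simplify = FALSE)
      for (cs in sub) {
        set <- c(s0, cs)
        if (anyDuplicated(sp$feat$snp[set])) next
        combos[[length(combos) + 1L]] <- set
      }
    }
  }
  V <- vapply(combos, function(set) {
    v <- sp$X[, set[1L]]
    for (f in set[-1L]) v <- v * sp$X[, f]
    v
  }, numeric(nrow(sp$X)))
  V <- matrix(V, nrow = nrow(sp$X))
  m <- colSums(V)
  ft <- fisher_table(sp$n_case, sp$n_ctrl)
  stat <- function(y) {
    n_case <- sum(y)
    min_count <- ceiling(config$min_case_prevalence * n_case)
    k <- as.vector(crossprod(V, y))
    ok <- which(k >= min_count)
    if (!length(ok)) return(0L)
    p <- fisher_lookup(ft, k[ok], m[ok])
    orv <- .or_vec(k[ok], m[ok], n_case / (length(y) - n_case))
    sum(p < config$alpha & orv$or > 1)
  }
  obs <- stat(sp$y)
  L <- perm_label_matrix(sp$y, n_permutations, seed)
  perm <- vapply(seq_len(ncol(L)), function(b) stat(L[, b]), integer(1))
  list(observed_count = obs,
       permutation_p = (1 + sum(perm >= obs)) / (1 + n_permutations))
}

#' Critical-SNP report combining RF accuracy and the permutation test
#'
#' A SNP is called critical when its permutation p is at most `p_max` and
#' its cross-validated RF accuracy exceeds the majority-class baseline.
#'
#' @param rf_report output of [rf_score_critical_snps()].
#' @param perm_p named numeric vector of permutation p-values (names = SNP
#'   ids), from [critical_permutation_test()].
#' @param p_max permutation p threshold (default 0.05).
#' @return the report with `permutation_p` and logical `critical` columns.
#' @export
critical_snp_report <- function(rf_report, perm_p, p_max = 0.05) {
  rf_report$permutation_p <- unname(perm_p[rf_report$snp_id])
  rf_report$critical <- rf_report$permutation_p <= p_max &
    rf_report$rf_accuracy > rf_report$majority_baseline
  rf_report
}
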