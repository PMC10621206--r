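# Shared statistical primitives: fast exact Fisher p-values for 2x2 tables
# with fixed margins, odds ratios relative to cohort mean odds, and small
# helpers used across the mining / EGA / secondary modules.

#' Two-sided Fisher exact p-values for case-membership tables
#'
#' Computes, for each candidate, the two-sided Fisher exact test p-value of
#' the 2x2 table `[[k, n_case - k], [m - k, n_ctrl - (m - k)]]`, i.e. the
#' association between membership in a genotype combination (`m` members of
#' whom `k` are cases) and case status in a cohort of `n_case` cases and
#' `n_ctrl` controls. Identical to `stats::fisher.test()$p.value` but
#' vectorised over `(k, m)`, which the layered mining scan needs at the scale
#' of ~1e5 candidate tables per pass.
#'
#' @param k integer vector, members that are cases.
#' @param m integer vector (recycled), total members (cases + controls).
#' @param n_case,n_ctrl scalar cohort totals.
#' @return numeric vector of p-values.
#' @export
fisher_p2 <- function(k, m, n_case, n_ctrl) {
  m <- rep_len(as.integer(m), length(k))
  k <- as.integer(k)
  vapply(seq_along(k), function(i) {
    if (is.na(k[i]) || is.na(m[i])) return(NA_real_)
    .fisher_p_one(k[i], m[i], n_case, n_ctrl)
  }, numeric(1))
}

.fisher_p_one <- function(k, m, n_case, n_ctrl) {
  lo <- max(0L, m - n_ctrl)
  hi <- min(m, n_case)
  if (hi < lo) return(NA_real_)
  d <- stats::dhyper(lo:hi, n_case, n_ctrl, m)
  sum(d[d <= d[k - lo + 1L] * (1 + 1e-7)])
}

# Precomputed lookup of two-sided Fisher p for every (m, k) with fixed cohort
# margins. p for all k at a given m is obtained in one sorted cumulative sum,
# so building the full table is O(N^2 log N) and each subsequent mining or
# permutation scan is a pure table lookup.
fisher_table <- function(n_case, n_ctrl) {
  n <- n_case + n_ctrl
  tabs <- vector("list", n + 1L)
  tabs[[1L]] <- 1 # m = 0: only k = 0, p = 1
  for (m in seq_len(n)) {
    tabs[[m + 1L]] <- .fisher_row(m, n_case, n_ctrl)
  }
  lens <- vapply(tabs, length, integer(1))
  offset <- c(0L, cumsum(lens))[seq_along(tabs)] # start index - 1, per m
  structure(list(tabs = tabs, flat = unlist(tabs, use.names = FALSE),
                 offset = offset, n_case = n_case, n_ctrl = n_ctrl),
            class = "fisher_table")
}

.fisher_row <- function(m, n_case, n_ctrl) {
  lo <- max(0L, m - n_ctrl)
  hi <- min(m, n_case)
  d <- stats::dhyper(lo:hi, n_case, n_ctrl, m)
  o <- order(d)
  ds <- d[o]
  p_sorted <- cumsum(ds)
  # near-ties (fisher.test's 1e-7 relative tolerance) share the cumulative
  # mass of the last member of the tie group
  if (length(ds) > 1L) {
    new_grp <- c(TRUE, ds[-1L] > ds[-length(ds)] * (1 + 1e-7))
    grp_id <- cumsum(new_grp)
    p_sorted <- stats::ave(p_sorted, grp_id, FUN = max)
  }
  p <- numeric(length(d))
  p[o] <- pmin(p_sorted, 1)
  p
}

# Vectorised O(1) lookup: p for tables with k cases among m members.
fisher_lookup <- function(ft, k, m) {
  lo <- pmax(0L, m - ft$n_ctrl)
  ft$flat[ft$offset[m + 1L] + (k - lo) + 1L]
}

#' Signature statistics from raw contingency counts
#'
#' Odds ratio of a disease signature relative to the cohort mean odds,
#' together with the two-sided Fisher exact p-value, computed from the four
#' printed counts. The odds ratio convention is
#' `(case_count / control_count) / (total_cases / total_controls)`: a
#' signature carried by a perfectly representative subgroup has odds ratio 1.
#' When `case_count` or `control_count` is zero a Haldane-Anscombe +0.5
#' correction is applied to the signature arm and flagged.
#'
#' @param case_count,control_count members of the signature among cases and
#'   controls.
#' @param total_cases,total_controls cohort sizes.
#' @return list with `odds_ratio`, `p_value`, `corrected` (logical, TRUE if
#'   the continuity correction was used).
#' @export
signature_stats_from_counts <- function(case_count, control_count,
                                        total_cases, total_controls) {
  stopifnot(case_count <= total_cases, control_count <= total_controls,
            total_cases >= 1, total_controls >= 1)
  mean_odds <- total_cases / total_controls
  corrected <- (case_count == 0L || control_count == 0L)
  if (corrected) {
    or <- ((case_count + 0.5) / (control_count + 0.5)) / mean_odds
  } else {
    or <- (case_count / control_count) / mean_odds
  }
  p <- .fisher_p_one(as.integer(case_count),
                     as.integer(case_count + control_count),
                     as.integer(total_cases), as.integer(total_controls))
  list(odds_ratio = or, p_value = p, corrected = corrected)
}

# Benjamini-Hochberg step-up with a permutation-estimated expected false
# discovery count. `p_obs` are the observed candidate p-values; `perm_p` is a
# list (one element per permutation) of the p-values of candidates discovered
# when the identical selection procedure is re-run on label-permuted data.
# q_i = min over thresholds t >= p_(i) of  E_perm[#discoveries with p <= t] /
# #observed with p <= t  -- the direct permutation analogue of BH's m*t/i.
perm_bh_q <- function(p_obs, perm_p) {
  m <- length(p_obs)
  if (m == 0L) return(numeric(0))
  B <- length(perm_p)
  o <- order(p_obs)
  ps <- p_obs[o]
  all_perm <- sort(unlist(perm_p, use.names = FALSE))
  # expected false count at each observed threshold
  e_false <- findInterval(ps * (1 + 1e-12), all_perm) / max(B, 1L)
  fdr <- e_false / seq_len(m)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  out <- numeric(m)
  out[o] <- q
  out
}

# Woolf (log-OR normal approximation) 95% CI for an odds ratio formed from
# four positive cell counts.
woolf_ci <- function(a, b, c, d, z = 1.96) {
  or <- (a / b) / (c / d)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(lower = exp(log(or) - z * se), upper = exp(log(or) + z * se))
}

#' Pooled two-proportion Z test
#'
#' Z statistic and two-sided p-value for the difference between two
#' proportions using the pooled-variance formula
#' `Z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with `p` the pooled proportion.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `z` and `p_value`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

# deterministic permutation matrix of case labels: n x B, each column a
# permutation of y (0/1).
perm_label_matrix <- function(y, B, seed) {
  n <- length(y)
  withr::with_seed(seed, {
    L <- matrix(0, n, B)
    for (b in seq_len(B)) L[sample.int(n), b] <- y
    L
  })
}
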