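test_that("vectorised Fisher p equals fisher.test on random tables", {
  set.seed(31)
  for (i in 1:100) {
    nc <- sample(10:80, 1); nn <- sample(10:80, 1)
    m <- sample(0:(nc + nn), 1)
    lo <- max(0, m - nn); hi <- min(m, nc)
    k <- if (lo == hi) lo else sample(lo:hi, 1)
    expect_equal(fisher_p2(k, m, nc, nn),
                 fisher.test(matrix(c(k, nc - k, m - k, nn - (m - k)),
                                    2))$p.value,
                 tolerance = 1e-10)
  }
  # table-based lookup agrees with the direct computation
  ft <- combsig:::fisher_table(25, 35)
  k <- c(0L, 3L, 10L, 20L); m <- c(5L, 9L, 30L, 44L)
  expect_equal(combsig:::fisher_lookup(ft, k, m), fisher_p2(k, m, 25, 35))
})

test_that("match_signature handles empty sets, lookups and missingness", {
  gm <- toy_gm(cbind(snpX = c(0L, 1L, 1L, 2L, NA),
                     snpY = c(1L, 1L, 0L, 1L, 1L)))
  expect_true(all(match_signature(gm, data.frame(snp_id = character(0),
                                                 state = integer(0))) ==
                    "member"))
  m <- match_signature(gm, data.frame(snp_id = "snpX", state = 1L))
  expect_equal(unname(m), c("non-member", "member", "member", "non-member",
                            "incomplete"))
  # conjunction membership is a subset of any sub-signature's membership
  m2 <- match_signature(gm, data.frame(snp_id = c("snpX", "snpY"),
                                       state = c(1L, 1L)))
  expect_true(all(names(m2)[m2 == "member"] %in% names(m)[m == "member"]))
  expect_error(match_signature(gm, data.frame(snp_id = c("snpX", "snpX"),
                                              state = c(0L, 1L))),
               "duplicate SNP")
})

test_that("signature statistics use the cohort mean-odds convention", {
  gm <- toy_gm(matrix(c(rep(1L, 30), rep(0L, 70)), ncol = 1))
  co <- cohort_from_labels(sample_ids(gm), c(rep(TRUE, 40), rep(FALSE, 60)))
  everyone <- match_signature(gm, data.frame(snp_id = character(0),
                                             state = integer(0)))
  st <- signature_stats(everyone, co)
  expect_equal(st$case_count, 40)
  expect_equal(st$control_count, 60)
  expect_equal(st$odds_ratio, 1)
  expect_equal(st$p_value, 1)
  # zero-control membership gets the flagged continuity correction
  st0 <- signature_stats_from_counts(5, 0, 40, 60)
  expect_true(st0$corrected)
  expect_equal(st0$odds_ratio, (5.5 / 0.5) / (40 / 60))
})

test_that("conjunction monotonicity: extending never increases counts", {
  set.seed(41)
  states <- matrix(as.integer(rbinom(200 * 6, 2, 0.4)), 200)
  states[sample(length(states), 30)] <- NA
  gm <- toy_gm(states)
  co <- cohort_from_labels(sample_ids(gm), rbinom(200, 1, 0.4) == 1)
  for (i in 1:10) {
    snps <- sample(snp_ids(gm), 3)
    f2 <- data.frame(snp_id = snps[1:2], state = sample(0:2, 2, TRUE))
    f3 <- rbind(f2, data.frame(snp_id = snps[3], state = sample(0:2, 1)))
    s2 <- signature_stats(match_signature(gm, f2), co)
    s3 <- signature_stats(match_signature(gm, f3), co)
    expect_lte(s3$case_count, s2$case_count)
    expect_lte(s3$control_count, s2$control_count)
  }
})

mine_fixture <- function(n = 500, n_snps = 12, seed = 1, multiplier = 6) {
  ov <- list("1" = 0.4, "2" = 0.4, "3" = 0.4)
  cfg <- simulation_config(n_samples = n, n_snps = n_snps, missing_rate = 0.01,
                           planted = list(planted_signature(1:3, c(1, 1, 1),
                                                            multiplier)),
                           baseline_odds = 0.35, pop_freq_overrides = ov,
                           random_seed = seed)
  sim <- simulate_cohort(cfg)
  list(sim = sim,
       cohort = cohort_from_labels(names(sim$is_case), sim$is_case))
}

test_that("mining is deterministic and invariant to sample/SNP order", {
  fx <- mine_fixture(seed = 3)
  cfg <- mining_config(max_order = 2, n_permutations = 49, beam_width = 10,
                       random_seed = 5)
  s1 <- suppressMessages(mine_signatures(fx$sim$genotypes, fx$cohort, cfg))
  s2 <- suppressMessages(mine_signatures(fx$sim$genotypes, fx$cohort, cfg))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  # shuffle samples and SNPs
  gm <- fx$sim$genotypes
  rp <- sample(nrow(gm$states)); cp <- sample(ncol(gm$states))
  gm_sh <- genotype_matrix(gm$states[rp, cp], gm$snp_map[cp, ])
  s3 <- suppressMessages(mine_signatures(gm_sh, fx$cohort, cfg))
  expect_identical(as.data.frame(s1), as.data.frame(s3))
})

test_that("beam search with unlimited width equals the exhaustive oracle", {
  fx <- mine_fixture(n = 300, n_snps = 10, seed = 8)
  cfg <- mining_config(max_order = 2, n_permutations = 49, beam_width = Inf,
                       random_seed = 17)
  got <- suppressMessages(mine_signatures(fx$sim$genotypes, fx$cohort, cfg))
  want <- oracle_mine(fx$sim$genotypes, fx$cohort, cfg)
  got <- as.data.frame(got)[order(got$features), ]
  want <- want[order(want$features), ]
  expect_equal(got$features, want$features)
  expect_equal(got$order, want$order)
  expect_equal(got$case_count, want$case_count)
  expect_equal(got$control_count, want$control_count)
  expect_equal(got$odds_ratio, want$odds_ratio, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_equal(got$q, want$q, tolerance = 1e-12)
  expect_equal(got$validated, want$validated)
})

test_that("permutation validation needs at least 19 permutations", {
  fx <- mine_fixture(n = 200, n_snps = 5, seed = 2)
  expect_error(suppressMessages(
    mine_signatures(fx$sim$genotypes, fx$cohort,
                    mining_config(n_permutations = 10))), "at least 19")
  expect_error(permutation_fdr(fx$sim$genotypes, fx$cohort,
                               list(data.frame(snp_id = "snp_00001",
                                               state = 1L)),
                               n_permutations = 5), "at least 19")
})

test_that("fixed-candidate permutation FDR follows the empirical-p contract", {
  set.seed(13)
  states <- matrix(as.integer(rbinom(300 * 4, 2, 0.4)), 300)
  gm <- toy_gm(states)
  y <- rbinom(300, 1, 0.4) == 1
  co <- cohort_from_labels(sample_ids(gm), y)
  cands <- list(data.frame(snp_id = "snp1", state = 0L),
                data.frame(snp_id = c("snp2", "snp3"), state = c(1L, 1L)))
  res <- permutation_fdr(gm, co, cands, n_permutations = 99, seed = 3)
  expect_true(all(res$p_emp >= 1 / 100 & res$p_emp <= 1))
  expect_equal(res$q, p.adjust(res$p_emp, "BH"))
  # a null-consistent candidate (observed p = 1) has empirical p 1
  gm1 <- toy_gm(matrix(rep(c(0L, 0L, 1L, 1L), 75), ncol = 1))
  co1 <- cohort_from_labels(sample_ids(gm1), rep(c(TRUE, FALSE), 150))
  r1 <- permutation_fdr(gm1, co1, list(data.frame(snp_id = "snp1",
                                                  state = 0L)),
                        n_permutations = 49, seed = 1)
  expect_equal(r1$p_obs, 1)
  expect_equal(r1$p_emp, 1)
  expect_equal(r1$q, r1$p_emp)  # BH with m = 1
})

test_that("case coverage counts cases holding any validated signature", {
  fx <- mine_fixture(seed = 6)
  cfg <- mining_config(max_order = 2, n_permutations = 49, beam_width = 10,
                       random_seed = 5)
  ss <- suppressMessages(mine_signatures(fx$sim$genotypes, fx$cohort, cfg))
  cov <- case_coverage(fx$sim$genotypes, fx$cohort, ss)
  expect_gte(cov, 0)
  expect_lte(cov, 1)
  if (any(ss$validated)) {
    # at least the carriers of the top validated signature are covered
    top <- parse_features(validated_signatures(ss)$features[1])
    memb <- match_signature(fx$sim$genotypes, top)
    frac <- mean(memb[cohort_cases(fx$cohort)] == "member")
    expect_gte(cov, frac)
  }
})

test_that("single-SNP association flags separators, not monomorphic SNPs", {
  y <- c(rep(TRUE, 50), rep(FALSE, 50))
  gm <- toy_gm(cbind(sep = as.integer(ifelse(y, 2L, 0L)),
                     mono = rep(0L, 100)))
  co <- cohort_from_labels(sample_ids(gm), y)
  res <- single_snp_association(gm, co)
  expect_lt(res$p[res$snp_id == "sep"], 1e-20)
  expect_true(res$genome_wide_significant[res$snp_id == "sep"])
  expect_equal(res$p[res$snp_id == "mono"], 1)
})

test_that("null single-SNP p-values are approximately uniform", {
  cfg <- simulation_config(n_samples = 1000, n_snps = 200,
                           missing_rate = 0, baseline_odds = 1,
                           random_seed = 1)
  sim <- simulate_cohort(cfg)
  co <- cohort_from_labels(names(sim$is_case), sim$is_case)
  res <- single_snp_association(sim$genotypes, co)
  expect_gt(suppressWarnings(ks.test(res$p, "punif"))$p.value, 0.01)
  expect_false(any(res$genome_wide_significant))
})
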