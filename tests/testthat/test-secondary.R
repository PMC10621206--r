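test_that("pooled two-proportion Z matches the hand formula", {
  res <- two_proportion_z(30, 100, 10, 100)
  expect_equal(res$z, 0.2 / sqrt(0.2 * 0.8 * 0.02), tolerance = 1e-12)
  expect_equal(round(res$z, 2), 3.54)
  same <- two_proportion_z(25, 100, 25, 100)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
})

enrich_fixture <- function(n = 200, shift = 1, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(TRUE, n)  # all cases; half carry the signature
    carrier <- rep(c(1L, 0L), n / 2)
    gm <- toy_gm(cbind(sig = carrier, other = as.integer(rbinom(n, 2, 0.3))))
    co <- cohort_from_labels(sample_ids(gm), y)
    ph <- data.frame(sample_id = sample_ids(gm),
                     hospitalized = rbinom(n, 1, ifelse(carrier == 1, 0.4,
                                                        0.15)),
                     severity = rnorm(n, ifelse(carrier == 1, shift, 0), 1))
    list(gm = gm, co = co, ph = ph)
  })
}

test_that("phenotype enrichment picks the right test per variable type", {
  fx <- enrich_fixture()
  res <- phenotype_enrichment(fx$gm, fx$co,
                              data.frame(snp_id = "sig", state = 1L),
                              fx$ph,
                              c(hospitalized = "categorical",
                                severity = "continuous"))
  expect_equal(res$test, c("two_proportion_z", "mann_whitney_u"))
  expect_true(all(res$p_adjusted >= res$p))           # BH is monotone
  expect_true(all(res$p_adjusted < 0.05))
  expect_true(all(res$direction == 1))
  expect_false(any(res$underpowered))
})

test_that("a shifted continuous phenotype is detected across seeds", {
  hits <- vapply(1:10, function(sd) {
    fx <- enrich_fixture(shift = 1, seed = sd)
    res <- phenotype_enrichment(fx$gm, fx$co,
                                data.frame(snp_id = "sig", state = 1L),
                                fx$ph, c(severity = "continuous"))
    res$p_adjusted < 0.05
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("tiny carrier groups are flagged underpowered but reported", {
  fx <- enrich_fixture()
  # signature carried by 3 cases only
  fx$gm$states[, "sig"] <- c(rep(1L, 3), rep(0L, 197))
  res <- phenotype_enrichment(fx$gm, fx$co,
                              data.frame(snp_id = "sig", state = 1L),
                              fx$ph, c(severity = "continuous"))
  expect_true(res$underpowered)
  expect_false(is.na(res$p))
})

test_that("constant ancestry reproduces the unadjusted membership test", {
  set.seed(71)
  n <- 300
  carrier <- rbinom(n, 1, 0.3)
  y <- rbinom(n, 1, ifelse(carrier == 1, 0.6, 0.3)) == 1
  gm <- toy_gm(cbind(sig = as.integer(carrier),
                     oth = as.integer(rbinom(n, 2, 0.3))))
  co <- cohort_from_labels(sample_ids(gm), y)
  anc <- setNames(rep(0, n), sample_ids(gm))
  chk <- ancestry_confounder_check(gm, co, list(data.frame(snp_id = "sig",
                                                           state = 1L)), anc)
  plain <- summary(glm(y ~ carrier,
                       family = binomial()))$coefficients["carrier", 4]
  expect_equal(chk$p_membership, plain, tolerance = 1e-6)
  expect_equal(chk$verdict, "pass")
})

test_that("adjusted p-values are monotone transforms of raw p-values", {
  set.seed(72)
  n <- 400
  gm <- toy_gm(matrix(as.integer(rbinom(n * 6, 2, 0.4)), n))
  co <- cohort_from_labels(sample_ids(gm), rbinom(n, 1, 0.35) == 1)
  anc <- setNames(rbinom(n, 1, 0.3), sample_ids(gm))
  sigs <- lapply(1:6, function(i) {
    data.frame(snp_id = snp_ids(gm)[i], state = 1L)
  })
  chk <- ancestry_confounder_check(gm, co, sigs, anc)
  expect_true(all(chk$p_adjusted >= chk$p_membership))
  chk_bh <- ancestry_confounder_check(gm, co, sigs, anc, method = "BH")
  expect_true(all(chk_bh$p_adjusted <= chk$p_adjusted + 1e-12))
})

test_that("seeding every SNP reproduces the hypothesis-free search", {
  ov <- list("1" = 0.4, "2" = 0.4)
  cfg <- simulation_config(n_samples = 300, n_snps = 8, missing_rate = 0.01,
                           planted = list(planted_signature(1:2, c(1, 1), 6)),
                           baseline_odds = 0.35, pop_freq_overrides = ov,
                           random_seed = 4)
  sim <- simulate_cohort(cfg)
  co <- cohort_from_labels(names(sim$is_case), sim$is_case)
  mc <- mining_config(max_order = 2, n_permutations = 49, beam_width = Inf,
                      random_seed = 6)
  free <- suppressMessages(mine_signatures(sim$genotypes, co, mc))
  seeded <- suppressMessages(seeded_mine(sim$genotypes, co,
                                         snp_ids(sim$genotypes), mc))
  a <- as.data.frame(free)[order(free$features), ]
  b <- as.data.frame(seeded)[order(seeded$features), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("seeded output is a subset of the unrestricted search", {
  ov <- list("1" = 0.4, "2" = 0.4)
  cfg <- simulation_config(n_samples = 300, n_snps = 8, missing_rate = 0.01,
                           planted = list(planted_signature(1:2, c(1, 1), 6)),
                           baseline_odds = 0.35, pop_freq_overrides = ov,
                           random_seed = 11)
  sim <- simulate_cohort(cfg)
  co <- cohort_from_labels(names(sim$is_case), sim$is_case)
  mc <- mining_config(max_order = 2, n_permutations = 49, beam_width = Inf,
                      random_seed = 2)
  free <- suppressMessages(mine_signatures(sim$genotypes, co, mc))
  seeded <- suppressMessages(seeded_mine(sim$genotypes, co,
                                         snp_ids(sim$genotypes)[1], mc))
  expect_true(all(seeded$features %in% free$features))
  expect_true(all(grepl("snp_00001:", seeded$features)))
  # absent seeds are dropped with a message; empty effective seeds are empty
  expect_message(none <- seeded_mine(sim$genotypes, co, "nonexistent", mc),
                 "dropping")
  expect_equal(nrow(none), 0)
})

test_that("a signature planted in two cohorts replicates under seeding", {
  hits <- vapply(1:5, function(sd) {
    ov <- list("1" = 0.4, "2" = 0.4, "3" = 0.4)
    make <- function(seed) {
      cfg <- simulation_config(n_samples = 1000, n_snps = 60,
                               missing_rate = 0.01,
                               planted = list(
                                 planted_signature(1:3, c(1, 1, 1), 5)),
                               baseline_odds = 0.4, pop_freq_overrides = ov,
                               random_seed = seed)
      sim <- simulate_cohort(cfg)
      list(sim = sim,
           co = cohort_from_labels(names(sim$is_case), sim$is_case))
    }
    b <- make(1000 + sd)
    seeds <- b$sim$truth$planted[[1]]$snp_ids
    mc <- mining_config(max_order = 3, n_permutations = 49, beam_width = 25,
                        random_seed = sd)
    rec <- suppressMessages(seeded_mine(b$sim$genotypes, b$co, seeds, mc))
    recovery_rate(rec, b$sim$truth) == 1
  }, logical(1))
  expect_gte(sum(hits), 4)
})
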