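test_that("compute_maf matches hand counts and handles missing data", {
  gm <- toy_gm(cbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 2L, 0L),
                     c(0L, 0L, 1L, NA), c(NA, NA, NA, NA)))
  maf <- compute_maf(gm)
  expect_equal(maf$maf[1], 0)               # monomorphic
  expect_equal(maf$maf[3], 1 / 6)           # over non-missing only
  expect_true(is.na(maf$maf[4]))            # all missing is NA, not 0
  expect_equal(maf$call_rate[4], 0)
  gm2 <- toy_gm(matrix(c(0L, 1L, 2L), ncol = 1))
  expect_equal(compute_maf(gm2)$maf, 0.5)   # allele frequency 0.5
})

test_that("maf is invariant under minor/major relabelling", {
  set.seed(11)
  for (i in 1:20) {
    v <- sample(0:2, 40, replace = TRUE)
    gm_a <- toy_gm(matrix(as.integer(v), ncol = 1))
    gm_b <- toy_gm(matrix(as.integer(2L - v), ncol = 1))
    expect_equal(compute_maf(gm_a)$maf, compute_maf(gm_b)$maf)
  }
})

test_that("apply_qc removes below-threshold MAF but keeps the boundary", {
  # snp1: maf 0.04 (4 minor alleles / 100); snp2: maf exactly 0.05
  s1 <- as.integer(c(rep(1, 4), rep(0, 46)))
  s2 <- as.integer(c(rep(1, 5), rep(0, 45)))
  gm <- toy_gm(cbind(snp1 = s1, snp2 = s2, snp3 = s2))
  out <- suppressMessages(apply_qc(gm, maf_min = 0.05))
  expect_false("snp1" %in% snp_ids(out))
  expect_true("snp2" %in% snp_ids(out))
  expect_equal(attr(out, "qc_report")$snps_removed_maf, 1)
  # every retained SNP satisfies the threshold
  expect_true(all(compute_maf(out)$maf >= 0.05 - 1e-9))
})

test_that("apply_qc is the identity on a clean matrix and errors when empty", {
  set.seed(4)
  states <- matrix(as.integer(rbinom(500, 2, 0.3)), 50)
  gm <- toy_gm(states)
  out <- suppressMessages(apply_qc(gm, maf_min = 0.05))
  expect_identical(out$states, gm$states)
  expect_identical(out$snp_map, gm$snp_map)
  mono <- toy_gm(matrix(0L, 20, 2))
  expect_error(suppressMessages(apply_qc(mono)), "review")
})

test_that("pairwise r2 covers self, complement, independence, degenerate", {
  set.seed(7)
  n <- 10000
  a <- as.integer(rbinom(n, 2, 0.3))
  b <- as.integer(rbinom(n, 2, 0.4))
  gm <- toy_gm(cbind(a = a, flip = 2L - a, b = b, mono = rep(1L, n)))
  expect_equal(pairwise_r2(gm, "a", "a"), 1)
  expect_equal(pairwise_r2(gm, "a", "flip"), 1)
  expect_lt(pairwise_r2(gm, "a", "b"), 0.01)
  expect_true(is.na(pairwise_r2(gm, "a", "mono")))
})

test_that("genotype_matrix enforces its invariants", {
  s <- matrix(0L, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  map <- data.frame(snp_id = c("x", "y"), chrom = "1", pos = 1:2,
                    ref_allele = "A", alt_allele = "C", minor_is_alt = TRUE)
  expect_error(genotype_matrix(s, map), "duplicate sample")
  s2 <- matrix(c(0L, 3L, 0L, 0L), 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(genotype_matrix(s2, map), "states")
  s3 <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(genotype_matrix(s3, map[2:1, ]), "in order")
  bad_pos <- map; bad_pos$pos <- c(0L, 2L)
  expect_error(genotype_matrix(s3, bad_pos), "positive")
})

test_that("tabular load/write round-trips states, ids and snp map", {
  dir <- withr::local_tempdir()
  # hand-written 3-sample, 2-SNP table loads as-is
  p <- file.path(dir, "hand.tsv")
  writeLines(c("sample_id\trs1\trs2", "a\t0\t2", "b\t1\tNA", "c\t2\t0"), p)
  gm <- load_genotypes(p, "table")
  expect_equal(unname(gm$states),
               matrix(c(0L, 1L, 2L, 2L, NA, 0L), 3))
  expect_equal(sample_ids(gm), c("a", "b", "c"))
  # full round trip incl. snp map
  sim <- simulate_cohort(simulation_config(n_samples = 25, n_snps = 6,
                                           missing_rate = 0.1,
                                           random_seed = 9))
  p2 <- file.path(dir, "geno.tsv")
  write_genotypes(sim$genotypes, p2)
  back <- load_genotypes(p2, "table")
  expect_identical(back$states, sim$genotypes$states)
  expect_identical(back$snp_map, sim$genotypes$snp_map)
})

test_that("table loader reports malformed lines and duplicate ids", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ragged.tsv")
  writeLines(c("sample_id\trs1\trs2", "a\t0\t1", "b\t1"), p)
  expect_error(load_genotypes(p, "table"), "line 3")
  p2 <- file.path(dir, "dup.tsv")
  writeLines(c("sample_id\trs1\trs2", "a\t0\t1", "a\t1\t1"), p2)
  expect_error(load_genotypes(p2, "table"), "duplicate sample")
})

test_that("VCF load orients to the cohort minor allele and round-trips", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "one.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1"), p)
  gm <- load_genotypes(p, "vcf")
  expect_equal(unname(gm$states[1, 1]), 1L)  # heterozygote, alt is minor
  sim <- simulate_cohort(simulation_config(n_samples = 20, n_snps = 5,
                                           missing_rate = 0.1,
                                           random_seed = 2))
  p2 <- file.path(dir, "rt.vcf")
  write_vcf(sim$genotypes, p2)
  back <- load_genotypes(p2, "vcf")
  expect_identical(back$states[sample_ids(sim$genotypes),
                               snp_ids(sim$genotypes)],
                   sim$genotypes$states)
})

test_that("multi-allelic VCF records are skipped with a warning", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "multi.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
               "1\t200\trsB\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/0"), p)
  expect_warning(gm <- load_genotypes(p, "vcf"), "multi-allelic")
  expect_equal(snp_ids(gm), "rsA")
})
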