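# Synthetic genotype/phenotype cohorts with planted combinatorial disease
# signatures, optional two-population structure and symptom-change scores,
# so the full pipeline is testable end-to-end without access to study
# genotypes.
#
# Genotypes: per SNP an ancestral minor-allele frequency is drawn uniformly
# from maf_range; each population perturbs it by a Balding-Nichols Beta draw
# parameterised by an Fst-like divergence; genotypes follow Hardy-Weinberg
# proportions; missingness is uniform. Disease: per-sample odds are
# baseline_odds times the multiplier of every planted signature the sample
# carries in full (interaction-only penetrance: component genotypes alone
# carry no effect, mirroring signatures whose single SNPs have near-null
# odds ratios), optionally times a per-population factor; case status is
# Bernoulli(odds / (1 + odds)).

#' Simulation configuration
#'
#' Defaults emulate the study scale this package targets: ~1,300 samples,
#' common SNPs (MAF 0.05-0.5) in Hardy-Weinberg proportions, a single
#' ancestry, ~25% baseline case odds, and symptom scores on a 0-10 scale in
#' three groups (respiratory, fatigue, mental health) whose deterioration is
#' much larger in diseased samples.
#'
#' @param n_samples number of samples (default 1300).
#' @param n_snps number of SNPs (default 2000).
#' @param maf_range ancestral minor-allele frequency range (default
#'   `c(0.05, 0.5)`).
#' @param missing_rate per-genotype missingness (default 0.01).
#' @param populations list of `list(fraction=, fst=)`; fractions must sum to
#'   1 (default one population, fst 0).
#' @param planted list of [planted_signature()] objects.
#' @param baseline_odds disease odds for carriers of no planted signature
#'   (default 0.25, i.e. 20% baseline risk).
#' @param population_odds optional per-population multiplicative odds factor
#'   (for testing ancestry confounding); default all 1.
#' @param pop_freq_overrides optional named list: SNP index -> per-population
#'   allele-frequency vector, for SNPs whose frequency must differ across
#'   populations by design.
#' @param symptom_groups named character vector symptom -> group; default 7
#'   symptoms in 3 groups.
#' @param deterioration_disease,deterioration_healthy mean per-symptom
#'   post-pre shift (defaults 3 and 0.5).
#' @param symptom_noise_sd noise SD on the shift (default 1.5).
#' @param scale_max symptom scale maximum (default 10).
#' @param random_seed governs all draws (default 1).
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 1300, n_snps = 2000,
                              maf_range = c(0.05, 0.5), missing_rate = 0.01,
                              populations = list(list(fraction = 1, fst = 0)),
                              planted = list(), baseline_odds = 0.25,
                              population_odds = NULL,
                              pop_freq_overrides = NULL,
                              symptom_groups = c(
                                breathlessness = "respiratory",
                                cough = "respiratory",
                                fatigue = "fatigue",
                                post_exertional_malaise = "fatigue",
                                muscle_pain = "fatigue",
                                anxiety = "mental_health",
                                low_mood = "mental_health"),
                              deterioration_disease = 3,
                              deterioration_healthy = 0.5,
                              symptom_noise_sd = 1.5, scale_max = 10,
                              random_seed = 1) {
  fr <- vapply(populations, `[[`, numeric(1), "fraction")
  fst <- vapply(populations, `[[`, numeric(1), "fst")
  stopifnot(abs(sum(fr) - 1) < 1e-8, all(fst >= 0), all(fst < 1),
            maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1, baseline_odds > 0)
  if (is.null(population_odds)) population_odds <- rep(1, length(populations))
  structure(list(n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 missing_rate = missing_rate, populations = populations,
                 planted = planted, baseline_odds = baseline_odds,
                 population_odds = population_odds,
                 pop_freq_overrides = pop_freq_overrides,
                 symptom_groups = symptom_groups,
                 deterioration_disease = deterioration_disease,
                 deterioration_healthy = deterioration_healthy,
                 symptom_noise_sd = symptom_noise_sd, scale_max = scale_max,
                 random_seed = as.integer(random_seed)),
            class = "simulation_config")
}

#' A planted combinatorial signature
#'
#' @param snps SNP indices (distinct; 2-3 for the study design, any number
#'   accepted).
#' @param states genotype states (0/1/2) the carrier must hold at each SNP.
#' @param odds_multiplier target fold-change in disease odds for carriers of
#'   the full combination (> 0).
#' @return list of class `planted_signature`.
#' @export
planted_signature <- function(snps, states, odds_multiplier) {
  stopifnot(length(snps) == length(states), !anyDuplicated(snps),
            all(states %in% 0:2), odds_multiplier > 0)
  structure(list(snps = as.integer(snps), states = as.integer(states),
                 odds_multiplier = odds_multiplier),
            class = "planted_signature")
}

#' Simulate a genotype matrix
#'
#' @param config a [simulation_config()].
#' @param seed RNG seed; default the config's `random_seed`.
#' @return list: `genotypes` (a [genotype_matrix()]), `population` (integer
#'   vector per sample).
#' @export
simulate_genotypes <- function(config, seed = config$random_seed) {
  withr::with_seed(seed, {
    n <- config$n_samples; K <- config$n_snps
    fr <- vapply(config$populations, `[[`, numeric(1), "fraction")
    fst <- vapply(config$populations, `[[`, numeric(1), "fst")
    pop <- sample(rep(seq_along(fr), times = round(fr * n))[seq_len(n)])
    p_anc <- stats::runif(K, config$maf_range[1], config$maf_range[2])
    states <- matrix(NA_integer_, n, K)
    for (ppi in seq_along(fr)) {
      rows <- which(pop == ppi)
      if (!length(rows)) next
      f <- fst[ppi]
      p_pop <- if (f > 0) {
        stats::rbeta(K, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
      } else p_anc
      if (!is.null(config$pop_freq_overrides)) {
        for (nm in names(config$pop_freq_overrides)) {
          p_pop[as.integer(nm)] <- config$pop_freq_overrides[[nm]][ppi]
        }
      }
      states[rows, ] <- stats::rbinom(length(rows) * K, 2,
                                      rep(p_pop, each = length(rows)))
    }
    if (config$missing_rate > 0) {
      miss <- stats::runif(n * K) < config$missing_rate
      states[miss] <- NA_integer_
    }
    dimnames(states) <- list(sprintf("sample_%04d", seq_len(n)),
                             sprintf("snp_%05d", seq_len(K)))
    alleles <- c("A", "C", "G", "T")
    ra <- sample(alleles, K, replace = TRUE)
    aa <- vapply(ra, function(r) sample(setdiff(alleles, r), 1), character(1))
    snp_map <- data.frame(snp_id = colnames(states),
                          chrom = as.character(1 + (seq_len(K) - 1) %% 22),
                          pos = 10000L + 1000L * seq_len(K),
                          ref_allele = ra, alt_allele = aa,
                          minor_is_alt = TRUE)
    list(genotypes = genotype_matrix(states, snp_map), population = pop)
  })
}

#' Assign disease labels from planted signatures
#'
#' Per sample, `odds = baseline_odds * prod(multipliers of fully matched
#' planted signatures) * population_odds[population]`; disease is drawn
#' Bernoulli(odds / (1 + odds)). Samples with a missing genotype at any
#' signature SNP never match that signature.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [simulation_config()] (supplies `planted`,
#'   `baseline_odds`, `population_odds`).
#' @param population integer per-sample population (default all 1).
#' @param seed RNG seed; default the config's `random_seed` plus 1.
#' @param odds_modifier optional penetrance hook: a function taking the
#'   genotype matrix and returning a per-sample odds multiplier, for effect
#'   patterns beyond exact-combination multipliers (e.g. stratum-dependent
#'   critical-SNP effects).
#' @return list: `is_case` (named logical), `report` (data.frame per planted
#'   signature with realized carrier counts and odds ratio vs target).
#' @export
assign_disease <- function(gm, config, population = NULL,
                           seed = config$random_seed + 1L,
                           odds_modifier = NULL) {
  n <- nrow(gm$states)
  if (is.null(population)) population <- rep(1L, n)
  odds <- rep(config$baseline_odds, n) * config$population_odds[population]
  if (!is.null(odds_modifier)) odds <- odds * odds_modifier(gm)
  carrier <- lapply(config$planted, function(pl) {
    s <- gm$states[, pl$snps, drop = FALSE]
    hit <- rowSums(sweep(s, 2, pl$states, "==")) == length(pl$snps)
    hit & rowSums(is.na(s)) == 0
  })
  for (i in seq_along(carrier)) {
    odds[carrier[[i]]] <- odds[carrier[[i]]] *
      config$planted[[i]]$odds_multiplier
  }
  is_case <- withr::with_seed(seed, {
    stats::runif(n) < odds / (1 + odds)
  })
  names(is_case) <- rownames(gm$states)
  report <- do.call(rbind, lapply(seq_along(carrier), function(i) {
    cc <- carrier[[i]]
    a <- sum(is_case & cc); b <- sum(!is_case & cc)
    c2 <- sum(is_case & !cc); d <- sum(!is_case & !cc)
    data.frame(signature = i,
               target_multiplier = config$planted[[i]]$odds_multiplier,
               carriers = sum(cc), carrier_cases = a,
               realized_or = (a / b) / (c2 / d))
  }))
  if (is.null(report)) {
    report <- data.frame(signature = integer(0),
                         target_multiplier = numeric(0),
                         carriers = integer(0), carrier_cases = integer(0),
                         realized_or = numeric(0))
  }
  list(is_case = is_case, report = report)
}

#' Synthesize pre/post symptom scores correlated with disease status
#'
#' Pre scores are drawn near the low end of the scale; post = pre + a
#' group-independent deterioration whose mean is `deterioration_disease` for
#' diseased samples and `deterioration_healthy` otherwise, plus Gaussian
#' noise, rounded and clipped to `[0, scale_max]`.
#'
#' @param is_case named logical vector (sample id -> diseased).
#' @param config a [simulation_config()].
#' @param seed RNG seed; default the config's `random_seed` plus 2.
#' @return data.frame with `sample_id` and `<symptom>_pre` /
#'   `<symptom>_post` columns.
#' @export
synthesize_symptoms <- function(is_case, config,
                                seed = config$random_seed + 2L) {
  withr::with_seed(seed, {
    n <- length(is_case)
    syms <- names(config$symptom_groups)
    out <- data.frame(sample_id = names(is_case))
    for (s in syms) {
      pre <- pmin(pmax(round(stats::rnorm(n, 2, 1)), 0), config$scale_max)
      shift <- stats::rnorm(n,
                            ifelse(is_case, config$deterioration_disease,
                                   config$deterioration_healthy),
                            config$symptom_noise_sd)
      post <- pmin(pmax(round(pre + shift), 0), config$scale_max)
      out[[paste0(s, "_pre")]] <- pre
      out[[paste0(s, "_post")]] <- post
    }
    out
  })
}

#' Simulate a complete cohort: genotypes, disease labels, symptoms, truth
#'
#' @param config a [simulation_config()].
#' @return list: `genotypes`, `population`, `is_case`, `phenotypes` (symptom
#'   table with an `ancestry` column), `disease_report`, `truth` (planted
#'   signatures with SNP ids, states, multipliers, seed).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  geno <- simulate_genotypes(config)
  dis <- assign_disease(geno$genotypes, config, population = geno$population)
  phen <- synthesize_symptoms(dis$is_case, config)
  phen$ancestry <- geno$population - 1L
  truth <- list(
    random_seed = config$random_seed,
    planted = lapply(config$planted, function(pl) {
      list(snp_ids = snp_ids(geno$genotypes)[pl$snps], states = pl$states,
           odds_multiplier = pl$odds_multiplier)
    }))
  list(genotypes = geno$genotypes, population = geno$population,
       is_case = dis$is_case, phenotypes = phen,
       disease_report = dis$report, truth = truth)
}

#' Score mining recovery against the planted truth
#'
#' A planted signature is recovered when some validated signature carries
#' every planted (SNP, state) feature -- the planted combination itself or a
#' superset signature sharing all its SNP genotypes.
#'
#' @param signatures a `signature_set`.
#' @param truth the `truth` element of [simulate_cohort()].
#' @return fraction of planted signatures recovered (NaN with no plants).
#' @export
recovery_rate <- function(signatures, truth) {
  val <- validated_signatures(signatures)
  got <- lapply(attr(val, "feature_sets"), function(fs) {
    paste0(fs$snp_id, ":", fs$state)
  })
  found <- vapply(truth$planted, function(pl) {
    want <- paste0(pl$snp_ids, ":", pl$states)
    any(vapply(got, function(g) all(want %in% g), logical(1)))
  }, logical(1))
  mean(found)
}
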