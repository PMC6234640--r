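# panel where every SNP has the same frequency in every population
uniform_panel <- function(n, daf) {
  df <- data.frame(id = sprintf("u%05d", seq_len(n)), chrom = "1",
                   pos = seq_len(n), aa = "A", da = "G",
                   daf_AFR = daf, daf_AMR = daf, daf_EAS = daf,
                   daf_EUR = daf, daf_SAS = daf, platforms = "WGS",
                   stringsAsFactors = FALSE)
  as_panel(df)
}

test_that("study-population risk frequency honours state and cohort", {
  df <- as.data.frame(make_tiny_panel())[1, ]
  df[paste0("daf_", ASC_POPULATIONS)] <- list(0.1, 0.2, 0.3, 0.4, 0.5)
  panel <- as_panel(df)

  cfg <- sim_config(study_pop = "EUR", risk_state = "ancestral")
  expect_equal(study_population_risk_frequency(panel, cfg), 1 - 0.4)

  cfg <- sim_config(study_pop = "MIX", risk_state = "derived")
  expect_equal(study_population_risk_frequency(panel, cfg), 0.3)

  flat <- uniform_panel(1, 0.2)
  cfg <- sim_config(study_pop = "MIX", risk_state = "derived")
  expect_equal(study_population_risk_frequency(flat, cfg), 0.2)
})

test_that("effect-size models draw, perturb, shift, and truncate GRRs", {
  g <- sample_genotype_relative_risk(10, "fixed")
  expect_true(all(g == 1.211))
  expect_equal(dim(g), c(10L, 5L))

  set.seed(31)
  g <- sample_genotype_relative_risk(2e5, "gamma")
  expect_true(all(g >= 1))
  expect_equal(unname(g[, 1]), unname(g[, 5]))  # shared locus effect
  # truncated-mean oracle: E[max(X, 1)] for X ~ Gamma(1.24, scale 0.85)
  oracle <- stats::integrate(function(x) pmax(x, 1) * dgamma(x, 1.24, scale = 0.85),
                             0, Inf)$value
  se <- sd(g[, 1]) / sqrt(nrow(g))
  expect_lt(abs(mean(g[, 1]) - oracle), 3 * se)

  set.seed(32)
  gn <- sample_genotype_relative_risk(5e4, "gamma_pop_noise")
  expect_true(all(gn >= 1))
  expect_gt(sd(gn[, 1] - gn[, 4]), 0)          # populations now differ

  # the +0.5 shift survives truncation at 1 only partially
  set.seed(33)
  ge <- sample_genotype_relative_risk(5e4, "gamma_shift_eur")
  expect_gt(mean(ge[, "EUR"]), mean(ge[, "EAS"]) + 0.2)
  expect_lt(mean(ge[, "EUR"]), mean(ge[, "EAS"]) + 0.5)
  set.seed(33)
  ga <- sample_genotype_relative_risk(5e4, "gamma_shift_afr")
  expect_gt(mean(ga[, "AFR"]), mean(ga[, "EAS"]) + 0.2)
})

test_that("rejection sampling accepts every draw when power is one", {
  panel <- uniform_panel(5000, 0.5)
  cfg <- sim_config(platform = "WGS", n_cases = 1e6, n_target = 100L,
                    seed = 41)
  rep <- rejection_sample_associations(panel, cfg)

  # replay oracle: with power one, the accepted set is the first 100
  # distinct uniform draws, and attempts is the draw index of the 100th
  set.seed(41)
  draws <- sample.int(5000, max(2000L, 4L * 100L), replace = TRUE)
  distinct <- !duplicated(draws)
  expected_attempts <- which(cumsum(distinct) == 100L)[1]
  expected_ids <- panel$id[draws[distinct][1:100]]

  expect_equal(rep$attempts, expected_attempts)
  expect_equal(rep$loci$id, expected_ids)
  expect_false(anyDuplicated(rep$loci$id) > 0)
  expect_true(all(rep$loci$power == 1))
})

test_that("a zero-power pool hits the draw cap with a diagnostic", {
  panel <- uniform_panel(500, 0)  # fixed sites can never be detected
  cfg <- sim_config(platform = "WGS", n_target = 100L, seed = 42,
                    draw_cap = 1e4)
  expect_error(rejection_sample_associations(panel, cfg), "draw cap")
})

test_that("attempts follow the negative-binomial waiting time", {
  panel <- uniform_panel(10000, 0.3)
  P <- analytic_power(power_params())  # acceptance probability per draw
  n_target <- 20L
  runs <- 100L
  attempts <- sapply(seq_len(runs), function(i) {
    cfg <- sim_config(platform = "WGS", n_target = n_target,
                      seed = 5000 + i)
    rejection_sample_associations(panel, cfg)$attempts
  })
  expected <- n_target / P
  se <- sqrt(n_target * (1 - P) / P^2 / runs)
  # small extra slack absorbs duplicate-draw rejections in the finite pool
  expect_lt(abs(mean(attempts) - expected), 3 * se + 0.05 * expected)
})

test_that("population-difference summaries are plain arithmetic", {
  loci <- data.frame(id = c("a", "b"), risk_state = "ancestral",
                     rf_AFR = c(0.8, 0.6), rf_AMR = c(0.7, 0.5),
                     rf_EAS = c(0.7, 0.5), rf_EUR = c(0.7, 0.5),
                     rf_SAS = c(0.7, 0.5), stringsAsFactors = FALSE)
  rep <- structure(list(loci = loci, attempts = 2L,
                        config = sim_config(risk_state = "ancestral")),
                   class = "asc_sim_replicate")
  s <- summarize_population_differences(rep)
  expect_equal(s$delta_afr_eur, 0.10)
  expect_equal(s$delta_afr_nonafr, 0.10)

  loci_eq <- loci
  loci_eq[paste0("rf_", ASC_POPULATIONS)] <- 0.5
  rep_eq <- structure(list(loci = loci_eq, attempts = 2L,
                           config = sim_config(risk_state = "ancestral")),
                      class = "asc_sim_replicate")
  s_eq <- summarize_population_differences(rep_eq)
  expect_equal(s_eq$delta_afr_eur, 0)
  expect_equal(s_eq$delta_afr_nonafr, 0)
})

test_that("replicates are seeded deterministically and reproducibly", {
  panel <- study_panel()
  cfg <- sim_config(platform = "SYNTH", n_target = 50L, seed = 77)

  s1 <- run_replicates(panel, cfg, n_reps = 3L)
  s2 <- run_replicates(panel, cfg, n_reps = 3L)
  expect_identical(s1$replicates, s2$replicates)

  # one replicate reproduces a direct call under the derived child seed
  cfg1 <- cfg
  cfg1$seed <- ascertainr:::.child_seed(77, 1)
  direct <- summarize_population_differences(
    rejection_sample_associations(panel, cfg1))
  expect_equal(s1$replicates$delta_afr_nonafr[1], direct$delta_afr_nonafr)
  expect_equal(s1$replicates$mean_AFR[1], direct$mean_AFR)
})

test_that("across-replicate spread shrinks with more accepted loci", {
  panel <- study_panel()
  sd_at <- function(n_target) {
    cfg <- sim_config(platform = "SYNTH", n_target = n_target, seed = 88)
    run_replicates(panel, cfg, n_reps = 12L)$sd[["delta_afr_nonafr"]]
  }
  expect_gt(sd_at(40L), sd_at(400L))
})

test_that("sample-size sweeps lay out the requested log10 grid", {
  panel <- study_panel()
  cfg <- sim_config(platform = "SYNTH", n_target = 30L, seed = 9)
  sw <- sweep_sample_sizes(panel, cfg, 3, 6, step = 3, n_reps = 2L)
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$n, c(1e3, 1e6))

  grid <- seq(3, 6, by = 0.1)
  expect_length(grid, 31L)  # the full default grid has 31 points
})

test_that("accepted loci are enriched for intermediate study-population MAF", {
  panel <- study_panel()
  cfg <- sim_config(platform = "SYNTH", study_pop = "EUR",
                    risk_state = "derived", n_target = 300L, seed = 10)
  rep <- rejection_sample_associations(panel, cfg)
  pool <- filter_platform(panel, "SYNTH")
  maf <- function(f) pmin(f, 1 - f)
  acc_maf <- maf(rep$loci$rf_EUR)
  pool_maf <- maf(panel_daf(pool)[, "EUR"])
  expect_gt(mean(acc_maf), mean(pool_maf))
  ks <- suppressWarnings(ks.test(acc_maf, pool_maf))
  expect_lt(ks$p.value, 0.01)
})

test_that("acceptance truncates small effect sizes under the gamma model", {
  panel <- study_panel()
  cfg <- sim_config(platform = "SYNTH", effect_model = "gamma",
                    n_target = 300L, seed = 12)
  rep <- rejection_sample_associations(panel, cfg)
  set.seed(13)
  pool_grr <- sample_genotype_relative_risk(3e4, "gamma")[, "EUR"]
  expect_gt(mean(rep$loci$grr_EUR), mean(pool_grr))
})
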