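# exact two-sided signed-rank p-value by enumerating all sign assignments
enumerate_signed_rank_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p <- if (w_obs > n * (n + 1) / 4) {
    2 * mean(w_all >= w_obs)
  } else {
    2 * mean(w_all <= w_obs)
  }
  min(p, 1)
}

test_that("paired signed-rank test matches exhaustive enumeration", {
  # all six differences positive: p = 2 / 2^6
  afr <- c(0.5, 0.6, 0.7, 0.4, 0.3, 0.8)
  non <- afr - c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  t6 <- paired_wilcoxon_frequency_test(afr, non)
  expect_equal(t6$p.value, 2 / 64)

  # random small fixtures against the enumeration oracle
  set.seed(71)
  for (n in c(5, 7, 8)) {
    d <- round(runif(n, -0.2, 0.2), 7)
    d <- d[d != 0][seq_len(n - 1)]
    x <- runif(length(d))
    expect_equal(paired_wilcoxon_frequency_test(x + d, x)$p.value,
                 enumerate_signed_rank_p(d))
  }

  # rank statistic is invariant to positive rescaling of differences
  x <- c(0.1, 0.4, 0.3, 0.6, 0.2)
  y <- c(0.15, 0.30, 0.33, 0.48, 0.26)  # distinct |differences|
  a <- paired_wilcoxon_frequency_test(x, y)
  b <- paired_wilcoxon_frequency_test(10 * x, 10 * y)
  expect_equal(a$p.value, b$p.value)
  expect_equal(unname(a$statistic), unname(b$statistic))

  expect_error(paired_wilcoxon_frequency_test(x, x), "zero")

  # antisymmetric differences sit at the null centre of the statistic
  d <- c(0.05, -0.05, 0.11, -0.11)
  base <- c(0.3, 0.4, 0.5, 0.6)
  t_sym <- suppressWarnings(paired_wilcoxon_frequency_test(base + d, base))
  expect_equal(unname(t_sym$statistic), length(d) * (length(d) + 1) / 4)
  expect_gt(t_sym$p.value, 0.5)
})

test_that("state-stratified frequency differences are plain averages", {
  panel <- make_tiny_panel()

  # identical frequencies everywhere: zero deltas, every locus a tie
  df <- as.data.frame(panel)
  df[paste0("daf_", ASC_POPULATIONS)] <- 0.4
  flat <- as_panel(df)
  tab <- data.frame(id = df$id[1:4],
                    risk_state = c("ancestral", "ancestral",
                                   "derived", "derived"),
                    category = "miscellaneous", stringsAsFactors = FALSE)
  d0 <- frequency_difference_by_state(tab, flat)
  expect_equal(d0$delta, c(0, 0))
  expect_equal(d0$n_ties, c(2L, 2L))
  expect_equal(d0$fraction_higher_afr, c(0, 0))

  # two ancestral-risk loci: AFR risk 0.8 / 0.5, pooled non-AFR 0.6 / 0.6
  df2 <- df[1:2, ]
  df2$daf_AFR <- 1 - c(0.8, 0.5)
  df2[paste0("daf_", ASC_NONAFR)] <- 1 - 0.6
  tab2 <- data.frame(id = df2$id, risk_state = "ancestral",
                     category = "miscellaneous", stringsAsFactors = FALSE)
  d2 <- frequency_difference_by_state(tab2, as_panel(df2))
  anc <- d2[d2$risk_state == "ancestral", ]
  expect_equal(anc$delta, 0.05)
  expect_equal(anc$fraction_higher_afr, 0.5)

  expect_error(frequency_difference_by_state(
    data.frame(id = "nope", risk_state = "derived", category = "x"),
    panel), "nope")
})

test_that("state differences are antisymmetric under AFR/non-AFR exchange", {
  panel <- study_panel()
  tab <- synthesize_disease_table(panel, n_loci = 500L, seed = 72)
  fwd <- frequency_difference_by_state(tab, panel)

  # swap AFR with the pooled non-African frequency at every SNP
  df <- as.data.frame(panel)
  pooled <- pooled_nonafrican_daf(panel)
  df[paste0("daf_", ASC_NONAFR)] <- df$daf_AFR
  df$daf_AFR <- pooled
  rev <- frequency_difference_by_state(tab, as_panel(df))
  expect_equal(rev$delta, -fwd$delta)
})

test_that("state-weighted overall difference reproduces the percent bookkeeping", {
  expect_equal(overall_weighted_difference(3, 3, 0.7), 3)
  expect_equal(overall_weighted_difference(9.51, -5.40, 0), -5.40)
  expect_equal(round(overall_weighted_difference(9.51, -5.40, 0.44), 2), 1.16)
})

test_that("DAF bins are closed-left on the lowest bin", {
  panel <- make_tiny_panel()
  df <- as.data.frame(panel)[1:2, ]
  df[paste0("daf_", ASC_POPULATIONS)] <- list(c(0.2, 0.1), c(0.2, 0.1),
                                              c(0.2, 0.1), c(0.2, 0.1),
                                              c(0.2, 0.1))
  tab <- data.frame(id = df$id, risk_state = "derived",
                    category = "miscellaneous", stringsAsFactors = FALSE)
  bins <- daf_bin_differences(tab, as_panel(df))
  populated <- bins[!is.na(bins$delta) & bins$risk_state == "derived", ]
  # both loci (mean DAF 0.2 and 0.1) land in the single lowest bin
  expect_equal(populated$bin, "[0,0.2]")
  expect_equal(populated$n_loci, 2L)

  expect_error(daf_bin_differences(tab, as_panel(df), bin_width = 0.3),
               "divide 1")
})

test_that("young low-DAF loci carry less continental bias than older loci", {
  panel <- study_panel()
  tab <- eur_ascertained_table(panel, n_anc = 700L, n_der = 900L, seed = 73)
  bins <- daf_bin_differences(tab, panel)
  for (state in c("ancestral", "derived")) {
    b <- bins[bins$risk_state == state, ]
    low <- abs(b$delta[b$bin == "[0,0.2]"])
    mid <- abs(b$delta[b$bin == "(0.2,0.4]"])
    expect_lt(low, mid)
  }
})

test_that("allele ages follow the drift estimator", {
  expect_equal(allele_age(0.2), 125000)
  expect_equal(allele_age(0.5), 500000)
  expect_error(allele_age(0), "\\(0, 1\\)")
  expect_error(allele_age(1), "\\(0, 1\\)")

  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(allele_age(p)) > 0))
  # the alternative segregating-age estimator is also increasing in p
  expect_true(all(diff(allele_age(p, method = "kimura")) > 0))
})

test_that("category bias correlates with ancestral-risk proportion", {
  collinear <- data.frame(delta_afr_nonafr = c(0.01, 0.02, 0.03),
                          prop_ancestral = c(0.2, 0.4, 0.6))
  expect_equal(category_correlation(collinear), 1)

  flat <- data.frame(delta_afr_nonafr = c(0.01, 0.01, 0.01),
                     prop_ancestral = c(0.2, 0.4, 0.6))
  expect_error(category_correlation(flat), "zero variance")

  # seven-point fixture against the explicit Pearson formula
  s7 <- data.frame(delta_afr_nonafr = c(0.021, -0.004, 0.013, 0.008,
                                        0.017, -0.011, 0.002),
                   prop_ancestral = c(0.61, 0.30, 0.52, 0.47, 0.58,
                                      0.22, 0.41))
  x <- s7$delta_afr_nonafr; y <- s7$prop_ancestral; n <- 7
  r_hand <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(category_correlation(s7), r_hand^2)
})

test_that("category summaries assemble counts, deltas, and tests", {
  panel <- study_panel()
  tab <- synthesize_disease_table(panel, n_loci = 700L, seed = 74)
  cs <- category_summaries(tab, panel)
  expect_setequal(cs$category, unique(tab$category))
  expect_equal(sum(cs$n_loci), nrow(tab))
  expect_true(all(cs$prop_ancestral >= 0 & cs$prop_ancestral <= 1))
  expect_true(all(cs$p_value >= 0 & cs$p_value <= 1, na.rm = TRUE))
})
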