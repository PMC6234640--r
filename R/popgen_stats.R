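#' Paired Wilcoxon signed-rank test on African vs non-African frequencies
#'
#' Two-sided signed-rank test on per-locus paired differences, exact for
#' n <= 25 (no ties), normal approximation above.
#'
#' @param afr,non_afr paired per-locus frequencies.
#' @return `htest` object.
#' @export
paired_wilcoxon_frequency_test <- function(afr, non_afr) {
  stopifnot(length(afr) == length(non_afr))
  d <- afr - non_afr
  if (all(d == 0)) stop("all paired differences are zero")
  n <- sum(d != 0)
  stats::wilcox.test(afr, non_afr, paired = TRUE, exact = n <= 25,
                     correct = n > 25)
}

## join a disease table to its panel records; error on unjoinable ids
.join_loci <- function(disease_table, panel) {
  idx <- match(disease_table$id, panel$id)
  if (anyNA(idx)) {
    bad <- disease_table$id[is.na(idx)]
    stop("disease-table ids absent from the panel: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...")
  }
  idx
}

#' African/non-African risk-frequency differences by risk-allele state
#'
#' For each locus the risk-allele frequency difference
#' `AFR - pooled non-AFR` is computed (pooled = unweighted mean of AMR,
#' EAS, EUR, SAS); loci are split by whether the risk allele is ancestral
#' or derived. Ties (`AFR` exactly equal to the pool) count as not-higher
#' and are reported separately.
#'
#' @param disease_table disease-locus data frame (`id`, `risk_state`).
#' @param panel an `asc_panel` containing every table locus.
#' @return data frame with one row per risk state: `risk_state`, `n_loci`,
#'   `delta` (mean frequency difference, on the 0-1 scale),
#'   `fraction_higher_afr` (strictly higher), `n_ties`.
#' @export
frequency_difference_by_state <- function(disease_table, panel) {
  idx <- .join_loci(disease_table, panel)
  daf <- panel_daf(panel)[idx, , drop = FALSE]
  rf <- ifelse(matrix(disease_table$risk_state == "ancestral",
                      nrow(daf), 5), 1 - daf, daf)
  colnames(rf) <- ASC_POPULATIONS
  afr <- rf[, "AFR"]
  nonafr <- rowMeans(rf[, ASC_NONAFR, drop = FALSE])
  rows <- lapply(c("ancestral", "derived"), function(state) {
    sel <- disease_table$risk_state == state
    if (!any(sel)) {
      return(data.frame(risk_state = state, n_loci = 0L, delta = NA_real_,
                        fraction_higher_afr = NA_real_, n_ties = 0L,
                        stringsAsFactors = FALSE))
    }
    d <- afr[sel] - nonafr[sel]
    data.frame(risk_state = state, n_loci = sum(sel), delta = mean(d),
               fraction_higher_afr = mean(d > 0), n_ties = sum(d == 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overall risk-frequency difference weighted by ancestral proportion
#'
#' `prop * delta_ancestral + (1 - prop) * delta_derived`. Works on any
#' scale (proportions or percent) as long as the two deltas share it.
#'
#' @param delta_ancestral,delta_derived mean African/non-African
#'   differences for ancestral- and derived-risk loci.
#' @param prop_ancestral proportion of loci with ancestral risk alleles.
#' @export
overall_weighted_difference <- function(delta_ancestral, delta_derived,
                                        prop_ancestral) {
  stopifnot(prop_ancestral >= 0, prop_ancestral <= 1)
  prop_ancestral * delta_ancestral + (1 - prop_ancestral) * delta_derived
}

#' Risk-frequency differences binned by derived-allele frequency
#'
#' Each locus is binned by its across-population mean DAF. The lowest bin
#' is closed, `[0, bin_width]`, and subsequent bins are `(lo, hi]` (so a
#' locus with mean DAF exactly 0.2 falls in the lowest default bin).
#' Within each bin and risk state the mean `AFR - pooled non-AFR`
#' risk-frequency difference is reported.
#'
#' @param disease_table disease-locus data frame.
#' @param panel an `asc_panel`.
#' @param bin_width bin width; must divide 1.
#' @return data frame: `bin` (label), `risk_state`, `n_loci`, `delta`.
#' @export
daf_bin_differences <- function(disease_table, panel, bin_width = 0.2) {
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-8) stop("bin_width must divide 1")
  idx <- .join_loci(disease_table, panel)
  daf <- panel_daf(panel)[idx, , drop = FALSE]
  mean_daf <- rowMeans(daf)
  rf <- ifelse(matrix(disease_table$risk_state == "ancestral",
                      nrow(daf), 5), 1 - daf, daf)
  colnames(rf) <- ASC_POPULATIONS
  d <- rf[, "AFR"] - rowMeans(rf[, ASC_NONAFR, drop = FALSE])
  breaks <- seq(0, 1, by = bin_width)
  bin <- cut(mean_daf, breaks = breaks, include.lowest = TRUE, right = TRUE)
  out <- expand.grid(bin = levels(bin),
                     risk_state = c("ancestral", "derived"),
                     stringsAsFactors = FALSE)
  out$n_loci <- NA_integer_
  out$delta <- NA_real_
  for (k in seq_len(nrow(out))) {
    sel <- bin == out$bin[k] & disease_table$risk_state == out$risk_state[k]
    out$n_loci[k] <- sum(sel)
    out$delta[k] <- if (any(sel)) mean(d[sel]) else NA_real_
  }
  out
}

#' Allele age implied by a derived-allele frequency
#'
#' The default drift-based estimator is `2 N p / (1 - p)` generations,
#' times the generation time in years; at `p = 0.2`, `N = 10000`, and 25
#' years per generation this gives 125,000 years. The Kimura-Ohta
#' estimator for the mean age of a segregating derived allele,
#' `-4 N p log(p) / (1 - p)` generations, is available as an alternative.
#'
#' @param p derived-allele frequency in (0, 1), vectorized.
#' @param N effective population size.
#' @param gen_time generation time in years.
#' @param method `"drift"` (default) or `"kimura"`.
#' @return age in years.
#' @export
allele_age <- function(p, N = 10000, gen_time = 25,
                       method = c("drift", "kimura")) {
  method <- match.arg(method)
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  generations <- switch(method,
                        drift = 2 * N * p / (1 - p),
                        kimura = -4 * N * p * log(p) / (1 - p))
  generations * gen_time
}

#' Per-category summaries of risk-allele frequencies
#'
#' For each disease category: locus count, mean risk-allele frequency per
#' population, the mean `AFR - pooled non-AFR` difference, the proportion
#' of ancestral risk alleles, and the paired Wilcoxon signed-rank p-value
#' comparing per-locus African vs pooled non-African risk frequencies.
#'
#' @param disease_table disease-locus data frame.
#' @param panel an `asc_panel`.
#' @return data frame with one row per category present in the table.
#' @export
category_summaries <- function(disease_table, panel) {
  idx <- .join_loci(disease_table, panel)
  daf <- panel_daf(panel)[idx, , drop = FALSE]
  rf <- ifelse(matrix(disease_table$risk_state == "ancestral",
                      nrow(daf), 5), 1 - daf, daf)
  colnames(rf) <- ASC_POPULATIONS
  nonafr <- rowMeans(rf[, ASC_NONAFR, drop = FALSE])
  cats <- intersect(ASC_CATEGORIES, unique(disease_table$category))
  rows <- lapply(cats, function(cat) {
    sel <- disease_table$category == cat
    pval <- tryCatch(
      paired_wilcoxon_frequency_test(rf[sel, "AFR"], nonafr[sel])$p.value,
      error = function(e) NA_real_)
    out <- data.frame(category = cat, n_loci = sum(sel),
                      stringsAsFactors = FALSE)
    out[paste0("mean_", ASC_POPULATIONS)] <-
      as.list(colMeans(rf[sel, , drop = FALSE]))
    out$delta_afr_nonafr <- mean(rf[sel, "AFR"] - nonafr[sel])
    out$prop_ancestral <- mean(disease_table$risk_state[sel] == "ancestral")
    out$p_value <- pval
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation between category bias and ancestral-risk proportion
#'
#' Squared Pearson correlation, across disease categories, between the
#' African/non-African risk-frequency difference and the proportion of
#' risk alleles that are ancestral.
#'
#' @param summaries data frame from [category_summaries()] (needs columns
#'   `delta_afr_nonafr` and `prop_ancestral`), >= 3 rows.
#' @return squared correlation r^2.
#' @export
category_correlation <- function(summaries) {
  if (nrow(summaries) < 3) stop("need at least 3 categories")
  x <- summaries$delta_afr_nonafr
  y <- summaries$prop_ancestral
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in category deltas or ancestral proportions")
  }
  stats::cor(x, y)^2
}
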