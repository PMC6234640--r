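#' Ancestral/derived correction constants for African genetic risk scores
#'
#' Diploid African genomes carry, on average, `delta_ancestral` additional
#' copies of each ancestral risk allele and `delta_derived` fewer copies of
#' each derived risk allele than non-African genomes. The defaults are twice
#' the empirical mean frequency differences of +9.51% (ancestral) and
#' 5.41% (derived): 0.1902 and 0.1082. Constants for any panel can be
#' recomputed with [estimate_correction_constants()].
#'
#' @param delta_ancestral per-locus count subtracted at ancestral-risk loci.
#' @param delta_derived per-locus count added at derived-risk loci.
#' @export
correction_constants <- function(delta_ancestral = 0.1902,
                                 delta_derived = 0.1082) {
  structure(list(delta_ancestral = delta_ancestral,
                 delta_derived = delta_derived),
            class = "asc_correction_constants")
}

#' Estimate correction constants from a panel and disease table
#'
#' `delta_ancestral = 2 * mean(AFR - pooled non-AFR)` risk-allele frequency
#' difference over ancestral-risk loci, and
#' `delta_derived = -2 * mean(AFR - pooled non-AFR)` over derived-risk loci
#' (positive when African genomes carry fewer derived risk alleles).
#'
#' @param disease_table disease-locus data frame (`id`, `risk_state`, ...).
#' @param panel an `asc_panel` containing all table loci.
#' @export
estimate_correction_constants <- function(disease_table, panel) {
  d <- frequency_difference_by_state(disease_table, panel)
  correction_constants(
    delta_ancestral = 2 * d$delta[d$risk_state == "ancestral"],
    delta_derived = -2 * d$delta[d$risk_state == "derived"])
}

#' Effective risk-allele counts under the ancestral/derived correction
#'
#' Maps raw risk-allele counts (0, 1, 2) to corrected "effective" counts:
#' `count - delta_ancestral` at ancestral-risk loci and
#' `count + delta_derived` at derived-risk loci. With the default constants
#' the corrected counts are -0.1902 / 0.8098 / 1.8098 (ancestral) and
#' 0.1082 / 1.1082 / 2.1082 (derived).
#'
#' @param counts numeric vector of risk-allele counts.
#' @param risk_state `"ancestral"` or `"derived"`, recycled against
#'   `counts`.
#' @param constants a [correction_constants()] object.
#' @export
effective_risk_counts <- function(counts, risk_state,
                                  constants = correction_constants()) {
  stopifnot(all(risk_state %in% c("ancestral", "derived")))
  ifelse(risk_state == "ancestral",
         counts - constants$delta_ancestral,
         counts + constants$delta_derived)
}

## risk-allele count matrix (individuals x loci) for one category's loci;
## genotype counts are derived-allele counts, so ancestral-risk loci use
## the complement 2 - count
.risk_count_matrix <- function(genotypes, loci) {
  missing_ids <- setdiff(loci$id, colnames(genotypes$counts))
  if (length(missing_ids) > 0) {
    stop("loci absent from the genotype matrix: ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) " ...")
  }
  cnt <- genotypes$counts[, loci$id, drop = FALSE]
  anc <- loci$risk_state == "ancestral"
  cnt[, anc] <- 2L - cnt[, anc, drop = FALSE]
  cnt
}

.category_loci <- function(disease_table, category) {
  if (is.null(category)) return(disease_table)
  loci <- disease_table[disease_table$category == category, , drop = FALSE]
  if (nrow(loci) == 0) stop("no loci in category: ", category)
  loci
}

#' Raw genetic risk score
#'
#' Per-individual sum of risk-allele counts over a disease category's loci
#' (derived-allele count at derived-risk loci, its complement at
#' ancestral-risk loci). No effect-size weighting is applied.
#'
#' @param genotypes an `asc_genotypes` object.
#' @param disease_table disease-locus data frame.
#' @param category disease category, or `NULL` for all loci.
#' @return named numeric vector over individuals.
#' @export
raw_grs <- function(genotypes, disease_table, category = NULL) {
  loci <- .category_loci(disease_table, category)
  rowSums(.risk_count_matrix(genotypes, loci))
}

#' Standardize raw scores to Z-scores across all individuals
#'
#' @param raw numeric vector of raw scores over all individuals (>= 2).
#' @return list with `z`, `center` (mean), and `scale` (SD). If the SD is
#'   zero, all Z-scores are 0 and a warning is raised.
#' @export
standardize_grs <- function(raw) {
  if (length(raw) < 2) stop("standardization needs at least 2 individuals")
  center <- mean(raw)
  scale <- stats::sd(raw)
  if (scale == 0) {
    warning("zero variance in raw scores; all Z-scores set to 0")
    return(list(z = raw * 0, center = center, scale = 0))
  }
  list(z = (raw - center) / scale, center = center, scale = scale)
}

#' Corrected genetic risk scores for African genomes
#'
#' Replaces raw risk-allele counts with effective counts
#' ([effective_risk_counts()]), sums them per individual, and maps the
#' corrected raw scores through the *uncorrected* standardization (the same
#' mean and SD used for all individuals).
#'
#' @param genotypes an `asc_genotypes` object.
#' @param disease_table disease-locus data frame.
#' @param category disease category, or `NULL` for all loci.
#' @param constants a [correction_constants()] object.
#' @param center,scale mean and SD of the uncorrected raw scores.
#' @param individuals row names (or logical/integer index) of the
#'   individuals to correct; defaults to the African individuals.
#' @return list with `raw` (corrected raw scores) and `z` (corrected
#'   Z-scores) for the selected individuals.
#' @export
corrected_african_grs <- function(genotypes, disease_table, category = NULL,
                                  constants = correction_constants(),
                                  center, scale,
                                  individuals = genotypes$population == "AFR") {
  loci <- .category_loci(disease_table, category)
  cnt <- .risk_count_matrix(genotypes, loci)[individuals, , drop = FALSE]
  eff <- sweep(cnt, 2, ifelse(loci$risk_state == "ancestral",
                              constants$delta_ancestral,
                              -constants$delta_derived))
  raw <- rowSums(eff)
  z <- if (scale == 0) raw * 0 else (raw - center) / scale
  list(raw = raw, z = z)
}

#' Per-individual, per-category risk-score table
#'
#' Computes raw and standardized scores for every individual and disease
#' category, plus corrected scores (via the ancestral/derived effective
#' counts) for individuals of the populations in `correct_populations`.
#'
#' @param genotypes an `asc_genotypes` object.
#' @param disease_table disease-locus data frame.
#' @param constants a [correction_constants()] object.
#' @param correct_populations populations whose scores are corrected
#'   (default African only); corrected columns are `NA` elsewhere.
#' @return data frame with columns `individual`, `population`, `category`,
#'   `raw`, `z`, `corrected_raw`, `corrected_z`.
#' @export
grs_table <- function(genotypes, disease_table,
                      constants = correction_constants(),
                      correct_populations = "AFR") {
  cats <- intersect(ASC_CATEGORIES, unique(disease_table$category))
  sel <- genotypes$population %in% correct_populations
  rows <- lapply(cats, function(cat) {
    raw <- raw_grs(genotypes, disease_table, cat)
    std <- standardize_grs(raw)
    out <- data.frame(individual = rownames(genotypes$counts),
                      population = as.character(genotypes$population),
                      category = cat, raw = raw, z = std$z,
                      corrected_raw = NA_real_, corrected_z = NA_real_,
                      stringsAsFactors = FALSE)
    if (any(sel)) {
      corr <- corrected_african_grs(genotypes, disease_table, cat,
                                    constants, std$center, std$scale,
                                    individuals = sel)
      out$corrected_raw[sel] <- corr$raw
      out$corrected_z[sel] <- corr$z
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare score distributions between two groups
#'
#' Two-sided Mann-Whitney U test (exact for small untied samples).
#'
#' @param scores_a,scores_b numeric score vectors for the two groups.
#' @return `htest` object with the U statistic and p-value.
#' @export
compare_grs_distributions <- function(scores_a, scores_b) {
  if (length(scores_a) == 0 || length(scores_b) == 0) {
    stop("both groups must be non-empty")
  }
  stats::wilcox.test(scores_a, scores_b, alternative = "two.sided")
}

#' Write a risk-score table as tab-separated text
#'
#' @param scores data frame from [grs_table()].
#' @param path file path.
#' @export
write_grs_tsv <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
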