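#' Disease categories
#'
#' The seven non-overlapping disease categories used to bin disease loci.
#'
#' @export
ASC_CATEGORIES <- c("GI/liver", "metabolic", "morphological", "cancer",
                    "neurological", "miscellaneous", "cardiovascular")

## deterministic child seed (< 2^31) for the i-th stream derived from `seed`
.child_seed <- function(seed, i) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 +
                as.numeric(i)) %% 2147483647)
}

#' Sample ancestral derived-allele frequencies from the neutral SFS
#'
#' Draws pre-divergence derived-allele frequencies from the standing neutral
#' site frequency spectrum: `P(p0 = i / n_chrom)` proportional to `1/i` on
#' `i = 1, ..., n_chrom - 1`. All draws are strictly inside (0, 1).
#'
#' @param n number of frequencies to draw.
#' @param n_chrom (even) number of chromosomes defining the frequency grid.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_ancestral_frequency <- function(n, n_chrom = 1000L, seed = NULL) {
  stopifnot(n >= 1, n_chrom >= 4)
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(n_chrom - 1)
  sample(i / n_chrom, size = n, replace = TRUE, prob = 1 / i)
}

## Balding-Nichols draw: Beta around p with drift coefficient f.
## Mean-preserving: E = p, Var = f p (1 - p). Degenerate inputs (p = 0 or 1)
## and the zero-drift limit return p unchanged.
.rbn <- function(p, f) {
  out <- p
  live <- p > 0 & p < 1
  if (f <= 1e-12 || !any(live)) return(out)
  k <- (1 - f) / f
  out[live] <- stats::rbeta(sum(live), p[live] * k, (1 - p[live]) * k)
  pmin(pmax(out, 0), 1)
}

#' Simulate post-divergence population frequencies under hierarchical drift
#'
#' African frequencies drift one Balding-Nichols step from the ancestral
#' frequency (coefficient `f_afr`). Non-African frequencies drift through a
#' shared out-of-Africa bottleneck step (`f_ooa`) followed by an independent
#' per-population step (`f_pop`), so the four non-African populations are
#' correlated with each other and carry more drift variance than Africa.
#' The model is mean-preserving: every population frequency has expectation
#' `p0`.
#'
#' @param p0 ancestral derived-allele frequency (vectorized), each in (0, 1).
#' @param f_afr,f_ooa,f_pop drift coefficients in (0, 1); `f_ooa > f_afr`.
#' @param seed optional integer seed.
#' @return numeric matrix with one row per `p0`, columns `AFR` ... `SAS`.
#' @export
simulate_population_frequencies <- function(p0, f_afr = 0.01, f_ooa = 0.10,
                                            f_pop = 0.02, seed = NULL) {
  if (any(p0 <= 0 | p0 >= 1)) stop("p0 must be in (0, 1)")
  for (f in c(f_afr, f_ooa, f_pop)) {
    if (f < 0 || f >= 1) stop("drift coefficients must be in [0, 1)")
  }
  if (f_ooa <= f_afr) {
    stop("f_ooa must exceed f_afr (bottlenecked populations drift more)")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(p0)
  out <- matrix(NA_real_, n, 5, dimnames = list(NULL, ASC_POPULATIONS))
  out[, "AFR"] <- .rbn(p0, f_afr)
  ooa <- .rbn(p0, f_ooa)
  for (pop in ASC_NONAFR) out[, pop] <- .rbn(ooa, f_pop)
  out
}

#' Generate a synthetic multi-population variant panel
#'
#' Ancestral frequencies are drawn from the neutral SFS
#' ([sample_ancestral_frequency()]) and diffused into five population
#' frequencies under the hierarchical bottleneck drift model
#' ([simulate_population_frequencies()]). Loci that drift to fixation in
#' some population are kept, mirroring real panels. Ancestral/derived
#' alleles are random distinct bases; all records carry the `WGS` flag.
#'
#' @param n_snps number of SNPs.
#' @param f_afr,f_ooa,f_pop drift coefficients, see
#'   [simulate_population_frequencies()].
#' @param n_chrom SFS frequency grid, see [sample_ancestral_frequency()].
#' @param seed integer seed (required: synthetic panels are reproducible).
#' @return an `asc_panel` with provenance recording all parameters.
#' @export
synthetic_panel <- function(n_snps = 20000L, f_afr = 0.01, f_ooa = 0.10,
                            f_pop = 0.02, n_chrom = 1000L, seed = 1L) {
  stopifnot(n_snps >= 1)
  set.seed(seed)
  p0 <- sample_ancestral_frequency(n_snps, n_chrom = n_chrom)
  daf <- simulate_population_frequencies(p0, f_afr, f_ooa, f_pop)
  aa <- sample(.bases, n_snps, replace = TRUE)
  da <- vapply(aa, function(b) sample(setdiff(.bases, b), 1), character(1))
  df <- data.frame(
    id = sprintf("snp%06d", seq_len(n_snps)),
    chrom = "1", pos = seq_len(n_snps),
    aa = aa, da = unname(da), stringsAsFactors = FALSE)
  df[.daf_cols] <- as.data.frame(daf)
  df$platforms <- "WGS"
  as_panel(df, provenance = sprintf(
    "synthetic panel: n_snps=%d f_afr=%g f_ooa=%g f_pop=%g n_chrom=%d seed=%d",
    n_snps, f_afr, f_ooa, f_pop, n_chrom, seed))
}

#' Probability a SNP is polymorphic in a small discovery sample
#'
#' With derived-allele frequency `q` and `d` sampled chromosomes, the SNP is
#' seen as polymorphic unless all chromosomes carry the same allele:
#' `1 - q^d - (1 - q)^d`.
#'
#' @param q derived-allele frequency (vectorized).
#' @param d number of discovery chromosomes (>= 2).
#' @export
polymorphism_probability <- function(q, d) {
  stopifnot(d >= 2)
  pmin(pmax(1 - q^d - (1 - q)^d, 0), 1)
}

#' Emulate array SNP ascertainment in a small discovery panel
#'
#' Each SNP is retained with the probability that it is polymorphic in a
#' discovery sample of `n_discovery_chrom` chromosomes drawn from the
#' discovery population ([polymorphism_probability()]); retained SNPs get
#' the `SYNTH` platform flag. Small discovery panels preferentially retain
#' intermediate-frequency SNPs, emulating commercial array content.
#'
#' @param panel an `asc_panel`.
#' @param discovery_pop population whose frequency drives ascertainment.
#' @param n_discovery_chrom discovery panel size in chromosomes (>= 2).
#' @param seed optional integer seed.
#' @return the panel with the `SYNTH` flag set on retained records.
#' @export
ascertain_array_subset <- function(panel, discovery_pop = "EUR",
                                   n_discovery_chrom = 4L, seed = NULL) {
  discovery_pop <- match.arg(discovery_pop, ASC_POPULATIONS)
  if (!is.null(seed)) set.seed(seed)
  q <- .pop_freq(panel, discovery_pop)
  keep <- stats::runif(nrow(panel)) < polymorphism_probability(q, n_discovery_chrom)
  sets <- .split_platforms(panel$platforms)
  sets[keep] <- lapply(sets[keep], function(s) c(s, "SYNTH"))
  df <- as.data.frame(panel)
  df$platforms <- .join_platforms(sets)
  as_panel(df, provenance = paste0(
    attr(panel, "provenance"),
    sprintf(" | SYNTH ascertained in %s, d=%d (%d retained)",
            discovery_pop, n_discovery_chrom, sum(keep))))
}

#' Simulate Hardy-Weinberg diploid genotypes from panel frequencies
#'
#' Each individual's derived-allele count at each locus is
#' `Binomial(2, daf[pop])`.
#'
#' @param panel an `asc_panel`.
#' @param n_per_pop named integer vector of individuals per population;
#'   populations absent from the vector get none.
#' @param seed optional integer seed.
#' @return an object of class `asc_genotypes`: a list with `counts` (an
#'   individuals x loci integer matrix of derived-allele counts, columns
#'   named by SNP id) and `population` (factor over individuals).
#' @export
simulate_genotypes <- function(panel, n_per_pop, seed = NULL) {
  stopifnot(all(names(n_per_pop) %in% ASC_POPULATIONS), all(n_per_pop > 0))
  if (!is.null(seed)) set.seed(seed)
  daf <- panel_daf(panel)
  blocks <- lapply(names(n_per_pop), function(pop) {
    n <- n_per_pop[[pop]]
    m <- matrix(stats::rbinom(n * nrow(daf), 2L, rep(daf[, pop], each = n)),
                nrow = n)
    rownames(m) <- sprintf("%s_%04d", pop, seq_len(n))
    m
  })
  counts <- do.call(rbind, blocks)
  colnames(counts) <- panel$id
  structure(list(
    counts = counts,
    population = factor(rep(names(n_per_pop), times = unlist(n_per_pop)),
                        levels = ASC_POPULATIONS)),
    class = "asc_genotypes")
}

#' @export
print.asc_genotypes <- function(x, ...) {
  cat(sprintf("<asc_genotypes> %d individuals x %d loci\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(x$population))
  invisible(x)
}

#' Synthesize a category-labeled disease-locus table
#'
#' Samples `n_loci` distinct panel variants; each locus's risk allele is
#' ancestral with probability `prop_ancestral` (otherwise derived), and its
#' disease category is multinomial with `category_weights` over the seven
#' categories. Genotype relative risks are left unset (`NA`) unless
#' `grr` is supplied.
#'
#' @param panel an `asc_panel`.
#' @param n_loci number of disease loci (<= number of panel records).
#' @param prop_ancestral probability a risk allele is ancestral.
#' @param category_weights length-7 nonnegative weights over
#'   [ASC_CATEGORIES], summing to 1.
#' @param grr optional fixed genotype relative risk applied to all loci and
#'   populations.
#' @param seed optional integer seed.
#' @return data frame with columns `id`, `risk_state`
#'   (`"ancestral"`/`"derived"`), `category`, and `grr_AFR` ... `grr_SAS`.
#' @export
synthesize_disease_table <- function(panel, n_loci = 3036L,
                                     prop_ancestral = 0.44,
                                     category_weights = rep(1 / 7, 7),
                                     grr = NULL, seed = NULL) {
  if (n_loci > nrow(panel)) {
    stop("n_loci exceeds the number of panel records")
  }
  stopifnot(length(category_weights) == 7,
            abs(sum(category_weights) - 1) < 1e-8,
            prop_ancestral >= 0, prop_ancestral <= 1)
  if (!is.null(seed)) set.seed(seed)
  ids <- sample(panel$id, n_loci, replace = FALSE)
  df <- data.frame(
    id = ids,
    risk_state = ifelse(stats::runif(n_loci) < prop_ancestral,
                        "ancestral", "derived"),
    category = sample(ASC_CATEGORIES, n_loci, replace = TRUE,
                      prob = category_weights),
    stringsAsFactors = FALSE)
  df[paste0("grr_", ASC_POPULATIONS)] <-
    if (is.null(grr)) NA_real_ else as.numeric(grr)
  df
}

#' Write / read a disease-locus table as tab-separated text
#'
#' @param table disease-locus data frame (see [synthesize_disease_table()]).
#' @param path file path.
#' @export
write_disease_table_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_disease_table_tsv
#' @export
read_disease_table_tsv <- function(path) {
  utils::read.delim(path, colClasses = c(id = "character",
                                         risk_state = "character",
                                         category = "character"))
}

#' Write / read a genotype matrix as tab-separated text
#'
#' Individuals in rows with `individual` and `population` columns followed
#' by per-locus derived-allele counts.
#'
#' @param genotypes an `asc_genotypes` object.
#' @param path file path.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(individual = rownames(genotypes$counts),
                   population = as.character(genotypes$population),
                   genotypes$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("individual", "population")),
                         drop = FALSE])
  rownames(counts) <- df$individual
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 population = factor(df$population, levels = ASC_POPULATIONS)),
            class = "asc_genotypes")
}
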