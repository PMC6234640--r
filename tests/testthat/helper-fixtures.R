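# Shared fixtures, all built in code at test time.

# Hand-specified five-SNP panel with simple frequencies.
make_tiny_panel <- function() {
  df <- data.frame(
    id = paste0("rs", 1:5),
    chrom = c("1", "1", "7", "8", "8"),
    pos = c(100L, 200L, 100000000L, 50000000L, 100000000L),
    aa = c("A", "C", "G", "T", "A"),
    da = c("G", "T", "A", "C", "G"),
    daf_AFR = c(0.10, 0.20, 0.50, 0.80, 1.00),
    daf_AMR = c(0.20, 0.20, 0.10, 0.60, 0.00),
    daf_EAS = c(0.20, 0.20, 0.20, 0.70, 0.25),
    daf_EUR = c(0.20, 0.30, 0.30, 0.90, 0.50),
    daf_SAS = c(0.20, 0.40, 0.40, 0.80, 0.75),
    platforms = "WGS",
    stringsAsFactors = FALSE)
  as_panel(df, provenance = "tiny fixture")
}

# Six-sample VCF with hand-countable genotypes. Expected outcome:
#  rs1 kept, AA=REF:        AFR daf 3/4, AMR 0, EAS 1/2, EUR 1, SAS 0
#  rs2 kept, AA=alt (lc) -> flipped: AFR 3/4, AMR 0, EAS 1, EUR 1/2, SAS 0
#  rs3 dropped (AA matches neither allele)
#  rs4 skipped silently (indel, not a biallelic SNP)
#  rs5 dropped (AA unknown ".")
#  rs6 kept on chr8 inside the default mask
write_fixture_vcf <- function(path) {
  gt <- function(...) paste(c(...), collapse = "\t")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral Allele">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:6)), collapse = "\t"),
    paste("1", 100, "rs1", "A", "G", ".", "PASS", "AA=A", "GT",
          gt("0|1", "1|1", "0|0", "0|1", "1|1", "0|0"), sep = "\t"),
    paste("1", 200, "rs2", "C", "T", ".", "PASS", "AA=t|||", "GT",
          gt("0|0", "0|1", "1|1", "0|0", "0|1", "1|1"), sep = "\t"),
    paste("1", 300, "rs3", "G", "A", ".", "PASS", "AA=C", "GT",
          gt("0|0", "0|0", "0|0", "0|0", "0|0", "0|0"), sep = "\t"),
    paste("1", 400, "rs4", "T", "TA", ".", "PASS", "AA=T", "GT",
          gt("0|0", "0|0", "0|0", "0|0", "0|0", "0|0"), sep = "\t"),
    paste("1", 500, "rs5", "A", "C", ".", "PASS", "AA=.", "GT",
          gt("0|0", "0|0", "0|0", "0|0", "0|0", "0|0"), sep = "\t"),
    paste("8", 100000000, "rs6", "A", "G", ".", "PASS", "AA=A", "GT",
          gt("0|1", "0|0", "0|1", "0|1", "0|1", "0|1"), sep = "\t"))
  writeLines(lines, path)
  path
}

fixture_pop_assignment <- function() {
  c(S1 = "AFR", S2 = "AFR", S3 = "AMR", S4 = "EAS", S5 = "EUR", S6 = "SAS")
}

# Genotypes object built directly from a count matrix.
make_genotypes <- function(counts, population) {
  structure(list(counts = counts,
                 population = factor(population, levels = ASC_POPULATIONS)),
            class = "asc_genotypes")
}

# The shared synthetic study panel: bottleneck WGS panel plus the
# EUR-ascertained synthetic array subset. Built once per test run.
study_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- ascertain_array_subset(synthetic_panel(n_snps = 20000L, seed = 3),
                                       discovery_pop = "EUR",
                                       n_discovery_chrom = 4L, seed = 4)
    }
    cache
  }
})

# Disease table ascertained by simulated EUR-cohort GWAS on the synthetic
# array, mixing ancestral- and derived-risk runs.
eur_ascertained_table <- function(panel, n_anc, n_der, seed,
                                  categories = "miscellaneous",
                                  category_prop_anc = NULL) {
  cfg <- function(state, n, s) {
    sim_config(platform = "SYNTH", study_pop = "EUR", risk_state = state,
               n_target = n, seed = s)
  }
  anc <- rejection_sample_associations(panel, cfg("ancestral", n_anc, seed))$loci
  der <- rejection_sample_associations(panel, cfg("derived", n_der, seed + 1))$loci
  df <- rbind(data.frame(id = anc$id, risk_state = "ancestral",
                         stringsAsFactors = FALSE),
              data.frame(id = der$id, risk_state = "derived",
                         stringsAsFactors = FALSE))
  df <- df[!duplicated(df$id), , drop = FALSE]
  if (is.null(category_prop_anc)) {
    df$category <- categories
  } else {
    # assign categories with specified ancestral-risk proportions
    df$category <- NA_character_
    anc_idx <- which(df$risk_state == "ancestral")
    der_idx <- which(df$risk_state == "derived")
    sizes <- rep(floor(nrow(df) / length(categories)), length(categories))
    for (k in seq_along(categories)) {
      na <- round(sizes[k] * category_prop_anc[k])
      nd <- sizes[k] - na
      take_a <- utils::head(anc_idx[is.na(df$category[anc_idx])], na)
      take_d <- utils::head(der_idx[is.na(df$category[der_idx])], nd)
      df$category[c(take_a, take_d)] <- categories[k]
    }
    df <- df[!is.na(df$category), , drop = FALSE]
  }
  df[paste0("grr_", ASC_POPULATIONS)] <- NA_real_
  rownames(df) <- NULL
  df
}
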