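#' @keywords internal
"_PACKAGE"

#' Continental populations of the reference panel
#'
#' The five continental groupings used throughout the package: Africa (AFR),
#' Americas (AMR), East Asia (EAS), Europe (EUR), and South Asia (SAS).
#'
#' @export
ASC_POPULATIONS <- c("AFR", "AMR", "EAS", "EUR", "SAS")

#' Non-African continental populations
#' @export
ASC_NONAFR <- c("AMR", "EAS", "EUR", "SAS")

#' Genotyping platform flags
#'
#' `WGS` marks every panel record (the panel itself is whole-genome); `AFFY6`
#' and `OMNI5` mark records present on the Affymetrix SNP 6.0 and Illumina
#' Omni 5M ID lists; `SYNTH` marks records retained by the synthetic
#' small-discovery-panel array ascertainment.
#'
#' @export
ASC_PLATFORMS <- c("WGS", "AFFY6", "OMNI5", "SYNTH")

.daf_cols <- paste0("daf_", ASC_POPULATIONS)
.panel_cols <- c("id", "chrom", "pos", "aa", "da", .daf_cols, "platforms")
.bases <- c("A", "C", "G", "T")

#' Construct a multi-population allele-frequency panel
#'
#' A panel is a data frame with one row per biallelic SNP carrying its
#' ancestral (`aa`) and derived (`da`) allele, the derived-allele frequency
#' (DAF) in each of the five continental populations, and a comma-joined set
#' of platform flags. Row order is preserved by every operation.
#'
#' @param df data frame with columns `id`, `chrom`, `pos`, `aa`, `da`,
#'   `daf_AFR` ... `daf_SAS`, `platforms`.
#' @param provenance free-text description of where the records came from.
#' @return an object of class `asc_panel` (a data frame).
#' @export
as_panel <- function(df, provenance = "") {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(.panel_cols, names(df))
  if (length(missing_cols) > 0) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, .panel_cols]
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$aa <- toupper(as.character(df$aa))
  df$da <- toupper(as.character(df$da))
  df$platforms <- as.character(df$platforms)
  if (anyDuplicated(df$id)) {
    stop("panel ids must be unique")
  }
  if (nrow(df) > 0) {
    if (any(df$aa == df$da)) stop("ancestral and derived alleles must differ")
    if (!all(df$aa %in% .bases) || !all(df$da %in% .bases)) {
      stop("alleles must be one of A, C, G, T")
    }
    daf <- as.matrix(df[, .daf_cols])
    if (anyNA(daf) || any(daf < 0) || any(daf > 1)) {
      stop("all derived-allele frequencies must be in [0, 1]")
    }
    if (!all(grepl("WGS", df$platforms))) {
      stop("every panel record must carry the WGS platform flag")
    }
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("asc_panel", "data.frame"))
}

#' @export
print.asc_panel <- function(x, ...) {
  cat(sprintf("<asc_panel> %d SNPs\n", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("provenance:", prov, "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Derived-allele frequencies of a panel as a matrix
#'
#' @param panel an `asc_panel`.
#' @return numeric matrix, one row per SNP, columns `AFR` ... `SAS`.
#' @export
panel_daf <- function(panel) {
  m <- as.matrix(as.data.frame(panel)[, .daf_cols])
  dimnames(m) <- list(NULL, ASC_POPULATIONS)
  m
}

## per-population frequency accessor; also understands the pooled
## "nonAFR" pseudo-population (unweighted mean of AMR/EAS/EUR/SAS)
.pop_freq <- function(panel, pop, weights = NULL) {
  if (pop == "nonAFR") return(pooled_nonafrican_daf(panel, weights))
  if (!pop %in% ASC_POPULATIONS) stop("unknown population: ", pop)
  as.data.frame(panel)[[paste0("daf_", pop)]]
}

#' Pooled non-African derived-allele frequency
#'
#' By default the unweighted mean of the AMR, EAS, EUR, and SAS frequencies;
#' supplying chromosome counts per population gives a count-weighted pool
#' instead.
#'
#' @param panel an `asc_panel` (or data frame with the `daf_*` columns).
#' @param weights optional named numeric vector of chromosome counts for the
#'   four non-African populations.
#' @return numeric vector, one value per SNP.
#' @export
pooled_nonafrican_daf <- function(panel, weights = NULL) {
  m <- as.matrix(as.data.frame(panel)[, paste0("daf_", ASC_NONAFR)])
  rownames(m) <- NULL
  if (is.null(weights)) {
    return(rowMeans(m))
  }
  if (!all(ASC_NONAFR %in% names(weights))) {
    stop("weights must be named with the four non-African populations")
  }
  w <- as.numeric(weights[ASC_NONAFR])
  as.numeric(m %*% w) / sum(w)
}

#' Genomic region mask
#'
#' 1-based inclusive interval on one chromosome. [chr8_mask()] is the default
#' mask for the hg19 region with misidentified ancestral states.
#'
#' @param chrom chromosome name (matched as a string).
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @export
region_mask <- function(chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("mask start must be <= end")
  structure(list(chrom = as.character(chrom), start = start, end = end),
            class = "asc_region_mask")
}

#' @rdname region_mask
#' @export
chr8_mask <- function() region_mask("8", 89000000, 146364022)

## chromosome names are compared with and without a "chr" prefix
.norm_chrom <- function(x) sub("^chr", "", x)

#' Remove SNPs inside a masked region
#'
#' @param panel an `asc_panel`.
#' @param mask a [region_mask()]; defaults to the chr8 ancestral-state mask.
#' @return the panel without records inside the mask, order preserved. The
#'   number of removed records is attached as attribute `n_masked`.
#' @export
apply_region_mask <- function(panel, mask = chr8_mask()) {
  stopifnot(inherits(mask, "asc_region_mask"))
  hit <- .norm_chrom(panel$chrom) == .norm_chrom(mask$chrom) &
    panel$pos >= mask$start & panel$pos <= mask$end
  out <- as_panel(as.data.frame(panel)[!hit, , drop = FALSE],
                  provenance = paste0(attr(panel, "provenance"),
                                      sprintf(" | masked %s:%.0f-%.0f (%d removed)",
                                              mask$chrom, mask$start, mask$end,
                                              sum(hit))))
  attr(out, "n_masked") <- sum(hit)
  out
}

.split_platforms <- function(x) strsplit(x, ",", fixed = TRUE)

.join_platforms <- function(sets) {
  vapply(sets, function(s) {
    s <- intersect(ASC_PLATFORMS, unique(s))  # canonical order, set semantics
    paste(s, collapse = ",")
  }, character(1))
}

#' Which panel records carry a platform flag
#'
#' @param panel an `asc_panel`.
#' @param platform one of `r paste(ASC_PLATFORMS, collapse = ", ")`.
#' @return logical vector over records.
#' @export
has_platform <- function(panel, platform) {
  platform <- match.arg(platform, ASC_PLATFORMS)
  vapply(.split_platforms(panel$platforms), function(s) platform %in% s,
         logical(1))
}

#' Subset a panel to one genotyping platform
#'
#' @inheritParams has_platform
#' @export
filter_platform <- function(panel, platform) {
  keep <- has_platform(panel, platform)
  as_panel(as.data.frame(panel)[keep, , drop = FALSE],
           provenance = paste0(attr(panel, "provenance"),
                               " | platform=", platform))
}

#' Flag panel records present on an array SNP-ID list
#'
#' Reads a plain-text file with one SNP ID per line and sets the given
#' platform flag on matching panel records. Flagging is idempotent. IDs in
#' the list but absent from the panel are counted and reported.
#'
#' @param path path to the ID list.
#' @param platform `"AFFY6"` or `"OMNI5"`.
#' @param panel an `asc_panel`.
#' @return the flagged panel, with attribute `n_unmatched` giving the number
#'   of list IDs not found in the panel.
#' @export
load_array_snp_ids <- function(path, platform = c("AFFY6", "OMNI5"), panel) {
  platform <- match.arg(platform)
  ids <- readLines(path, warn = FALSE)
  ids <- unique(ids[nzchar(trimws(ids))])
  if (length(ids) == 0) stop("empty SNP-ID list: ", path)
  hit <- panel$id %in% ids
  sets <- .split_platforms(panel$platforms)
  sets[hit] <- lapply(sets[hit], function(s) c(s, platform))
  df <- as.data.frame(panel)
  df$platforms <- .join_platforms(sets)
  n_unmatched <- sum(!ids %in% panel$id)
  tag <- paste0(" | ", platform, "=", basename(path))
  prov <- attr(panel, "provenance")
  if (!grepl(tag, prov, fixed = TRUE)) prov <- paste0(prov, tag)
  out <- as_panel(df, provenance = prov)
  attr(out, "n_unmatched") <- n_unmatched
  if (n_unmatched > 0) {
    message(n_unmatched, " ", platform, " list IDs not present in the panel")
  }
  out
}

#' Joint site frequency spectrum of two populations
#'
#' Bins every record by its derived-allele frequency in two populations.
#' A record falls in cell `(floor(daf_x * bins), floor(daf_y * bins))`
#' (0-based), with frequency 1 assigned to the top bin.
#'
#' @param panel an `asc_panel`.
#' @param pop_x,pop_y population codes (rows index `pop_x`); `"nonAFR"` gives
#'   the pooled non-African frequency.
#' @param bins number of equal-width frequency bins (>= 1).
#' @return `bins` x `bins` integer matrix of counts; the total equals the
#'   number of records.
#' @export
joint_sfs_counts <- function(panel, pop_x, pop_y, bins = 10L) {
  bins <- as.integer(bins)
  if (bins < 1) stop("bins must be >= 1")
  fx <- .pop_freq(panel, pop_x)
  fy <- .pop_freq(panel, pop_y)
  ix <- pmin(floor(fx * bins), bins - 1L) + 1L
  iy <- pmin(floor(fy * bins), bins - 1L) + 1L
  counts <- tabulate((iy - 1L) * bins + ix, nbins = bins * bins)
  m <- matrix(as.integer(counts), nrow = bins, ncol = bins)
  lab <- sprintf("[%.3g,%.3g)", (seq_len(bins) - 1) / bins, seq_len(bins) / bins)
  lab[bins] <- sprintf("[%.3g,1]", (bins - 1) / bins)
  dimnames(m) <- list(lab, lab)
  m
}

#' Write / read a panel as tab-separated text
#'
#' The dialect is a header line
#' `id chrom pos aa da daf_AFR daf_AMR daf_EAS daf_EUR daf_SAS platforms`
#' with tab separators. Frequencies are written with 17 significant digits so
#' the file round-trips bit-exactly.
#'
#' @param panel an `asc_panel`.
#' @param path output / input file path.
#' @export
write_panel_tsv <- function(panel, path) {
  df <- as.data.frame(panel)
  for (cc in .daf_cols) df[[cc]] <- sprintf("%.17g", df[[cc]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = c(
    id = "character", chrom = "character", pos = "integer",
    aa = "character", da = "character", platforms = "character"))
  as_panel(df, provenance = paste0("read from ", path))
}

#' Build a panel from a VCF with per-population allele frequencies
#'
#' Retains biallelic SNPs whose ancestral allele (the `AA` INFO tag, or a
#' companion table) matches REF or ALT, and computes the derived-allele
#' frequency in each continental population as derived-allele count over
#' non-missing chromosomes. Low-confidence lowercase ancestral calls are
#' accepted case-insensitively; ambiguous or mismatching states cause the
#' site to be dropped and counted.
#'
#' @param vcf_path path to a VCF file (plain text or gzipped).
#' @param population_assignment named character vector mapping every VCF
#'   sample to one of `AFR, AMR, EAS, EUR, SAS`. A sample without an
#'   assignment is an error; all five populations must be represented.
#' @param ancestral_states optional named character vector (by variant ID)
#'   of ancestral alleles, used where the `AA` tag is absent.
#' @return an `asc_panel` with attribute `n_dropped_ancestral`, the count of
#'   biallelic SNPs dropped for unknown or mismatching ancestral state.
#' @export
read_vcf_frequencies <- function(vcf_path, population_assignment,
                                 ancestral_states = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  unassigned <- setdiff(samples, names(population_assignment))
  if (length(unassigned) > 0) {
    stop("samples without a population assignment: ",
         paste(unassigned, collapse = ", "))
  }
  pops <- population_assignment[samples]
  if (!all(pops %in% ASC_POPULATIONS)) {
    stop("population assignments must be one of ",
         paste(ASC_POPULATIONS, collapse = ", "))
  }
  if (!all(ASC_POPULATIONS %in% pops)) {
    stop("all five populations must be represented among the samples")
  }

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ref <- toupper(fix$REF)
  alt <- toupper(fix$ALT)
  id <- fix$ID
  biallelic <- ref %in% .bases & alt %in% .bases
  aa_raw <- vcfR::extract.info(vcf, element = "AA")
  ## EPO-style AA tags can look like "a|||"; take the leading base
  aa <- toupper(substr(ifelse(is.na(aa_raw), "", aa_raw), 1, 1))
  if (!is.null(ancestral_states)) {
    fill <- !nzchar(aa) & id %in% names(ancestral_states)
    aa[fill] <- toupper(ancestral_states[id[fill]])
  }
  known <- aa %in% .bases & (aa == ref | aa == alt)
  keep <- biallelic & known
  n_dropped <- sum(biallelic & !known)

  ## per-sample ALT allele counts; NA for missing genotypes
  gtk <- gt[keep, , drop = FALSE]
  alt_count <- matrix(NA_real_, nrow(gtk), ncol(gtk), dimnames = dimnames(gtk))
  clean <- gsub("[|/]", "", gtk)
  ok <- !is.na(clean) & grepl("^[01]{2}$", clean)
  alt_count[ok] <- as.numeric(substr(clean[ok], 1, 1)) +
    as.numeric(substr(clean[ok], 2, 2))

  daf <- matrix(NA_real_, sum(keep), length(ASC_POPULATIONS),
                dimnames = list(NULL, ASC_POPULATIONS))
  for (pop in ASC_POPULATIONS) {
    cols <- which(pops == pop)
    cnt <- alt_count[, cols, drop = FALSE]
    n_chrom <- 2 * rowSums(!is.na(cnt))
    if (any(n_chrom == 0)) {
      stop("population ", pop, " has no called genotypes at some sites")
    }
    daf[, pop] <- rowSums(cnt, na.rm = TRUE) / n_chrom
  }
  ## where AA == ALT the derived allele is REF: flip the frequency
  flip <- aa[keep] == alt[keep]
  daf[flip, ] <- 1 - daf[flip, ]

  df <- data.frame(
    id = id[keep], chrom = .norm_chrom(fix$CHROM[keep]),
    pos = as.integer(fix$POS[keep]),
    aa = aa[keep],
    da = ifelse(flip, ref[keep], alt[keep]),
    stringsAsFactors = FALSE)
  df[.daf_cols] <- as.data.frame(daf)
  df$platforms <- "WGS"
  ## fall back to coordinate IDs where the VCF has "."
  noid <- is.na(df$id) | df$id == "."
  df$id[noid] <- paste0(df$chrom[noid], ":", df$pos[noid])
  out <- as_panel(df, provenance = paste0(
    "VCF ", basename(vcf_path), "; ", n_dropped,
    " sites dropped for unknown/mismatching ancestral allele"))
  attr(out, "n_dropped_ancestral") <- n_dropped
  if (n_dropped > 0) {
    message(n_dropped, " sites dropped for unknown or mismatching ancestral allele")
  }
  out
}
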