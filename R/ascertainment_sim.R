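#' Effect-size model parameters
#'
#' Locus-specific genotype relative risks are drawn from a gamma
#' distribution (shape 1.24, scale 0.85, matching the spread of effect
#' sizes at known disease loci); population-specific variation adds
#' independent normal noise (SD 0.5) per population; the shifted models add
#' 0.5 to one population's GRR. Any resulting GRR below 1 is truncated to 1.
#'
#' @param gamma_shape,gamma_scale gamma distribution of the base GRR.
#' @param pop_noise_sd SD of per-population normal noise.
#' @param shift amount added to the shifted population's GRR.
#' @param fixed_grr GRR used by the `"fixed"` effect model.
#' @export
effect_model_params <- function(gamma_shape = 1.24, gamma_scale = 0.85,
                                pop_noise_sd = 0.5, shift = 0.5,
                                fixed_grr = 1.211) {
  stopifnot(gamma_shape > 0, gamma_scale > 0, pop_noise_sd >= 0)
  structure(list(gamma_shape = gamma_shape, gamma_scale = gamma_scale,
                 pop_noise_sd = pop_noise_sd, shift = shift,
                 fixed_grr = fixed_grr),
            class = "asc_effect_params")
}

.effect_models <- c("fixed", "gamma", "gamma_pop_noise",
                    "gamma_shift_eur", "gamma_shift_afr")

#' Configuration of one GWAS discovery simulation
#'
#' Defaults follow the reference study design: Affymetrix SNP 6.0 platform,
#' European study cohort, 3500 cases and 3500 controls, additive model,
#' p-value threshold 1e-5, prevalence 0.1, fixed genotype relative risk
#' 1.211, and 3036 accepted disease associations.
#'
#' @param platform pool to draw test SNPs from: `"WGS"`, `"AFFY6"`,
#'   `"OMNI5"`, or `"SYNTH"` (the synthetic EUR-ascertained array).
#' @param study_pop study-cohort ancestry, one of the five continental
#'   populations or `"MIX"` (equal mixture of all five).
#' @param risk_state whether risk alleles are `"ancestral"` or `"derived"`.
#' @param n_cases,n_controls study sample sizes.
#' @param alpha genome-wide significance threshold.
#' @param model inheritance model.
#' @param prevalence disease prevalence.
#' @param effect_model one of `"fixed"`, `"gamma"`, `"gamma_pop_noise"`,
#'   `"gamma_shift_eur"`, `"gamma_shift_afr"`.
#' @param effect_params an [effect_model_params()] object.
#' @param n_target number of accepted disease associations per replicate.
#' @param seed integer seed.
#' @param draw_cap maximum number of draws before aborting (guards pools
#'   with vanishing acceptance probability).
#' @return an object of class `asc_sim_config`.
#' @export
sim_config <- function(platform = "AFFY6", study_pop = "EUR",
                       risk_state = c("derived", "ancestral"),
                       n_cases = 3500L, n_controls = n_cases,
                       alpha = 1e-5,
                       model = c("additive", "dominant", "recessive"),
                       prevalence = 0.1,
                       effect_model = "fixed",
                       effect_params = effect_model_params(),
                       n_target = 3036L, seed = 1L, draw_cap = 1e8) {
  platform <- match.arg(platform, ASC_PLATFORMS)
  study_pop <- match.arg(study_pop, c(ASC_POPULATIONS, "MIX"))
  risk_state <- match.arg(risk_state)
  model <- match.arg(model)
  effect_model <- match.arg(effect_model, .effect_models)
  stopifnot(n_target >= 1, n_cases >= 1, n_controls >= 1,
            alpha > 0, alpha < 1, prevalence > 0, prevalence < 1,
            draw_cap >= 1)
  structure(list(platform = platform, study_pop = study_pop,
                 risk_state = risk_state,
                 n_cases = as.numeric(n_cases),
                 n_controls = as.numeric(n_controls),
                 alpha = alpha, model = model, prevalence = prevalence,
                 effect_model = effect_model, effect_params = effect_params,
                 n_target = as.integer(n_target), seed = as.integer(seed),
                 draw_cap = draw_cap),
            class = "asc_sim_config")
}

#' Risk-allele frequency matrix of a panel
#'
#' For derived risk alleles the risk frequency is the DAF; for ancestral
#' risk alleles it is `1 - DAF`.
#'
#' @param panel an `asc_panel`.
#' @param risk_state `"ancestral"` or `"derived"`.
#' @return matrix, one row per SNP, columns `AFR` ... `SAS`.
#' @export
risk_frequencies <- function(panel, risk_state = c("derived", "ancestral")) {
  risk_state <- match.arg(risk_state)
  daf <- panel_daf(panel)
  if (risk_state == "ancestral") 1 - daf else daf
}

#' Risk-allele frequency in the study population
#'
#' `MIX` cohorts use the unweighted mean over the five populations.
#'
#' @param panel an `asc_panel`.
#' @param config an [sim_config()] object (uses `study_pop`, `risk_state`).
#' @return numeric vector over panel records.
#' @export
study_population_risk_frequency <- function(panel, config) {
  rf <- risk_frequencies(panel, config$risk_state)
  unname(if (config$study_pop == "MIX") rowMeans(rf) else rf[, config$study_pop])
}

#' Draw per-population genotype relative risks
#'
#' @param n number of loci.
#' @param effect_model one of `"fixed"`, `"gamma"`, `"gamma_pop_noise"`,
#'   `"gamma_shift_eur"`, `"gamma_shift_afr"` (shifted models include the
#'   per-population noise).
#' @param params an [effect_model_params()] object.
#' @return `n` x 5 matrix of GRRs (columns `AFR` ... `SAS`), truncated at 1.
#' @export
sample_genotype_relative_risk <- function(n, effect_model = "fixed",
                                          params = effect_model_params()) {
  effect_model <- match.arg(effect_model, .effect_models)
  if (effect_model == "fixed") {
    g <- matrix(params$fixed_grr, n, 5)
  } else {
    base <- stats::rgamma(n, shape = params$gamma_shape,
                          scale = params$gamma_scale)
    g <- matrix(base, n, 5)
    if (effect_model != "gamma") {
      g <- g + matrix(stats::rnorm(n * 5, 0, params$pop_noise_sd), n, 5)
    }
    if (effect_model == "gamma_shift_eur") g[, 4] <- g[, 4] + params$shift
    if (effect_model == "gamma_shift_afr") g[, 1] <- g[, 1] + params$shift
  }
  g <- pmax(g, 1)
  colnames(g) <- ASC_POPULATIONS
  g
}

#' Rejection-sampling simulation of GWAS locus discovery
#'
#' Repeatedly draws a uniform-random test SNP from the platform-filtered
#' pool, finds its risk-allele frequency in the study population, draws
#' locus-specific genotype relative risks, computes the analytic detection
#' power, and accepts the SNP if a uniform random number falls below the
#' power. Drawing continues until `n_target` distinct loci are accepted.
#' Power uses the study population's GRR (`MIX` uses the mean GRR across
#' populations); an already-accepted SNP is never accepted twice.
#'
#' @param panel an `asc_panel`.
#' @param config an [sim_config()] object. `config$seed` seeds the run.
#' @return an object of class `asc_sim_replicate`: list with `loci` (data
#'   frame of accepted loci: `id`, `risk_state`, risk-allele frequencies
#'   `rf_AFR` ... `rf_SAS`, GRRs `grr_AFR` ... `grr_SAS`, `power`),
#'   `attempts` (draws up to and including the last acceptance), and
#'   `config`.
#' @export
rejection_sample_associations <- function(panel, config) {
  stopifnot(inherits(config, "asc_sim_config"))
  pool <- filter_platform(panel, config$platform)
  npool <- nrow(pool)
  if (npool == 0) stop("empty SNP pool after platform filtering")
  if (npool < config$n_target) {
    stop("pool smaller than n_target (", npool, " < ", config$n_target, ")")
  }
  rf <- risk_frequencies(pool, config$risk_state)
  f_study <- if (config$study_pop == "MIX") rowMeans(rf) else rf[, config$study_pop]

  set.seed(config$seed)
  taken <- logical(npool)
  acc_idx <- integer(0)
  acc_grr <- vector("list", 0)
  acc_pow <- numeric(0)
  attempts <- 0
  batch <- max(2000L, 4L * config$n_target)
  repeat {
    idx <- sample.int(npool, batch, replace = TRUE)
    g <- sample_genotype_relative_risk(batch, config$effect_model,
                                       config$effect_params)
    g_study <- if (config$study_pop == "MIX") rowMeans(g) else g[, config$study_pop]
    pow <- .power_vec(f_study[idx], g_study, config$n_cases,
                      config$n_controls, config$alpha, config$prevalence,
                      config$model, clamp = TRUE)
    ok <- stats::runif(batch) < pow
    hits <- which(ok)
    done <- FALSE
    last_pos <- batch
    for (j in hits) {
      if (!taken[idx[j]]) {
        taken[idx[j]] <- TRUE
        acc_idx <- c(acc_idx, idx[j])
        acc_grr[[length(acc_grr) + 1L]] <- g[j, ]
        acc_pow <- c(acc_pow, pow[j])
        if (length(acc_idx) == config$n_target) {
          done <- TRUE
          last_pos <- j
          break
        }
      }
    }
    attempts <- attempts + last_pos
    if (done) break
    if (attempts >= config$draw_cap) {
      stop(sprintf(
        "draw cap (%g) exceeded: %d of %d loci accepted (acceptance rate %.3g)",
        config$draw_cap, length(acc_idx), config$n_target,
        length(acc_idx) / attempts))
    }
  }
  grr_m <- do.call(rbind, acc_grr)
  loci <- data.frame(id = pool$id[acc_idx],
                     risk_state = config$risk_state,
                     stringsAsFactors = FALSE)
  loci[paste0("rf_", ASC_POPULATIONS)] <- as.data.frame(rf[acc_idx, , drop = FALSE])
  loci[paste0("grr_", ASC_POPULATIONS)] <- as.data.frame(grr_m)
  loci$power <- acc_pow
  rownames(loci) <- NULL
  structure(list(loci = loci, attempts = attempts, config = config),
            class = "asc_sim_replicate")
}

#' @export
print.asc_sim_replicate <- function(x, ...) {
  cat(sprintf(
    "<asc_sim_replicate> %d accepted loci (%s risk, %s cohort, %s) in %d draws\n",
    nrow(x$loci), x$config$risk_state, x$config$study_pop,
    x$config$platform, x$attempts))
  invisible(x)
}

#' Population summaries of one simulated GWAS catalog
#'
#' @param rep an `asc_sim_replicate`.
#' @return one-row data frame: `risk_state`, `n_loci`, mean risk-allele
#'   frequency per population (`mean_AFR` ...), `delta_afr_eur`
#'   (mean AFR minus mean EUR), and `delta_afr_nonafr` (mean AFR minus
#'   mean per-locus pooled non-African frequency).
#' @export
summarize_population_differences <- function(rep) {
  stopifnot(inherits(rep, "asc_sim_replicate"))
  rf <- as.matrix(rep$loci[, paste0("rf_", ASC_POPULATIONS)])
  colnames(rf) <- ASC_POPULATIONS
  mns <- colMeans(rf)
  nonafr <- rowMeans(rf[, ASC_NONAFR, drop = FALSE])
  out <- data.frame(risk_state = rep$config$risk_state,
                    n_loci = nrow(rf), stringsAsFactors = FALSE)
  out[paste0("mean_", ASC_POPULATIONS)] <- as.list(mns)
  out$delta_afr_eur <- mns[["AFR"]] - mns[["EUR"]]
  out$delta_afr_nonafr <- mean(rf[, "AFR"] - nonafr)
  out
}

#' Run independent simulation replicates
#'
#' Replicate `i` runs [rejection_sample_associations()] under a
#' deterministic child seed derived from `config$seed`, so any single
#' replicate can be reproduced bit-for-bit.
#'
#' @param panel an `asc_panel`.
#' @param config an [sim_config()] object.
#' @param n_reps number of replicates.
#' @return an object of class `asc_sim_summary`: list with `replicates`
#'   (data frame, one row per replicate with its summary and attempts),
#'   `mean` and `sd` (named numeric summaries across replicates), and
#'   `config`.
#' @export
run_replicates <- function(panel, config, n_reps = 10L) {
  stopifnot(n_reps >= 1)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- .child_seed(config$seed, i)
    rep_i <- rejection_sample_associations(panel, cfg_i)
    row <- summarize_population_differences(rep_i)
    row$replicate <- i
    row$attempts <- rep_i$attempts
    rows[[i]] <- row
  }
  reps <- do.call(rbind, rows)
  num_cols <- c(paste0("mean_", ASC_POPULATIONS),
                "delta_afr_eur", "delta_afr_nonafr")
  structure(list(replicates = reps,
                 mean = colMeans(reps[, num_cols, drop = FALSE]),
                 sd = apply(reps[, num_cols, drop = FALSE], 2, stats::sd),
                 config = config),
            class = "asc_sim_summary")
}

#' @export
print.asc_sim_summary <- function(x, ...) {
  cat(sprintf("<asc_sim_summary> %d replicates (%s risk, %s cohort, %s)\n",
              nrow(x$replicates), x$config$risk_state, x$config$study_pop,
              x$config$platform))
  print(round(x$mean, 4))
  invisible(x)
}

#' Sweep study sample sizes on a log10 grid
#'
#' For each grid point `x`, sets `n_cases = n_controls = round(10^x)` and
#' runs [run_replicates()]; tabulates the across-replicate mean and SD of
#' the African/non-African frequency difference.
#'
#' @param panel an `asc_panel`.
#' @param config base [sim_config()] (platform, cohort, risk state, ...).
#' @param log10_min,log10_max,step grid of `log10(n)` values.
#' @param n_reps replicates per grid point.
#' @return data frame with one row per grid point: `log10_n`, `n`,
#'   `platform`, `risk_state`, `delta_afr_nonafr`, `delta_sd`,
#'   `delta_afr_eur`.
#' @export
sweep_sample_sizes <- function(panel, config, log10_min = 3, log10_max = 6,
                               step = 0.1, n_reps = 10L) {
  if (log10_min > log10_max) stop("log10_min must be <= log10_max")
  grid <- seq(log10_min, log10_max, by = step)
  rows <- lapply(seq_along(grid), function(k) {
    x <- grid[k]
    cfg <- config
    cfg$n_cases <- cfg$n_controls <- round(10^x)
    cfg$seed <- .child_seed(config$seed, 100000L + k)
    s <- run_replicates(panel, cfg, n_reps)
    data.frame(log10_n = x, n = round(10^x),
               platform = config$platform, risk_state = config$risk_state,
               delta_afr_nonafr = s$mean[["delta_afr_nonafr"]],
               delta_sd = s$sd[["delta_afr_nonafr"]],
               delta_afr_eur = s$mean[["delta_afr_eur"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
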