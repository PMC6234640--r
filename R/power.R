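#' Parameters of one case-control power evaluation
#'
#' Bundles everything needed to compute the power to detect a disease
#' association at one SNP: sample sizes, the genome-wide significance
#' threshold, disease prevalence `K`, genotype relative risk `grr`
#' (penetrance ratio per the inheritance model), the inheritance model, and
#' the risk-allele frequency `p` in the study population.
#'
#' @param n_cases,n_controls numbers of cases and controls.
#' @param alpha two-sided significance threshold in (0, 1).
#' @param prevalence disease prevalence `K` in (0, 1).
#' @param grr genotype relative risk, >= 1.
#' @param model inheritance model: `"additive"`, `"dominant"`, or
#'   `"recessive"`.
#' @param p risk-allele frequency in [0, 1].
#' @return an object of class `power_params`.
#' @export
power_params <- function(n_cases = 3500L, n_controls = n_cases, alpha = 1e-5,
                         prevalence = 0.1, grr = 1.211,
                         model = c("additive", "dominant", "recessive"),
                         p = 0.3) {
  model <- match.arg(model)
  stopifnot(n_cases >= 1, n_controls >= 1,
            alpha > 0, alpha < 1,
            prevalence > 0, prevalence < 1,
            grr >= 1, p >= 0, p <= 1)
  structure(list(n_cases = as.numeric(n_cases),
                 n_controls = as.numeric(n_controls),
                 alpha = alpha, prevalence = prevalence, grr = grr,
                 model = model, p = p),
            class = "power_params")
}

## relative risks (r1, r2) of the 1- and 2-copy genotypes under each model
.genotype_relative_risks <- function(model, grr) {
  switch(model,
         additive  = list(r1 = grr, r2 = 2 * grr - 1),
         dominant  = list(r1 = grr, r2 = grr),
         recessive = list(r1 = rep(1, length(grr)), r2 = grr),
         stop("unknown model: ", model))
}

## vectorized penetrances (f0, f1, f2) solving the prevalence identity
## K = (1-p)^2 f0 + 2 p (1-p) f1 + p^2 f2 under Hardy-Weinberg.
## clamp = TRUE caps penetrances into [0, 1] instead of flagging them,
## for use inside large vectorized simulations.
.penetrances <- function(p, grr, K, model, clamp = FALSE) {
  rr <- .genotype_relative_risks(model, grr)
  denom <- (1 - p)^2 + 2 * p * (1 - p) * rr$r1 + p^2 * rr$r2
  f0 <- K / denom
  f1 <- rr$r1 * f0
  f2 <- rr$r2 * f0
  bad <- f0 < 0 | f0 > 1 | f1 < 0 | f1 > 1 | f2 < 0 | f2 > 1
  if (clamp) {
    f0 <- pmin(pmax(f0, 0), 1)
    f1 <- pmin(pmax(f1, 0), 1)
    f2 <- pmin(pmax(f2, 0), 1)
  } else if (any(bad)) {
    stop("penetrances fall outside [0, 1]; ",
         "prevalence, GRR, and frequency are inconsistent")
  }
  list(f0 = f0, f1 = f1, f2 = f2)
}

#' Genotype penetrances implied by prevalence, GRR, and inheritance model
#'
#' Relative risks by risk-allele count are `f1 = grr * f0`,
#' `f2 = (2 grr - 1) * f0` (additive), `f1 = f2 = grr * f0` (dominant), or
#' `f1 = f0`, `f2 = grr * f0` (recessive); `f0` is solved from the
#' population prevalence under Hardy-Weinberg:
#' `K = (1-p)^2 f0 + 2 p (1-p) f1 + p^2 f2`.
#'
#' @param params a [power_params()] object.
#' @return named numeric vector `c(f0, f1, f2)`, all in [0, 1].
#' @export
penetrances_from_model <- function(params) {
  stopifnot(inherits(params, "power_params"))
  f <- .penetrances(params$p, params$grr, params$prevalence, params$model)
  c(f0 = f$f0, f1 = f$f1, f2 = f$f2)
}

## vectorized case/control risk-allele frequencies
.cc_freqs <- function(p, grr, K, model, clamp = FALSE) {
  f <- .penetrances(p, grr, K, model, clamp = clamp)
  p_case <- (p^2 * f$f2 + p * (1 - p) * f$f1) / K
  p_control <- (p^2 * (1 - f$f2) + p * (1 - p) * (1 - f$f1)) / (1 - K)
  list(p_case = pmin(pmax(p_case, 0), 1),
       p_control = pmin(pmax(p_control, 0), 1))
}

#' Expected risk-allele frequencies among cases and controls
#'
#' `p_case = (p^2 f2 + p (1-p) f1) / K` and
#' `p_control = (p^2 (1-f2) + p (1-p) (1-f1)) / (1-K)`.
#'
#' @param params a [power_params()] object.
#' @return named numeric vector `c(p_case, p_control)`.
#' @export
case_control_allele_frequencies <- function(params) {
  stopifnot(inherits(params, "power_params"))
  f <- .cc_freqs(params$p, params$grr, params$prevalence, params$model)
  c(p_case = f$p_case, p_control = f$p_control)
}

## Vectorized analytic power of the two-sided 1-df allelic test.
## Normal approximation: the case/control allele-frequency contrast has
## alternative SD from the two binomials and null SD from the pooled
## frequency; power is the probability the contrast exceeds the null
## critical value in either direction. Monomorphic sites have power 0.
.power_vec <- function(p, grr, n_cases, n_controls, alpha, K, model,
                       clamp = TRUE) {
  out <- numeric(length(p))
  live <- p > 0 & p < 1
  if (!any(live)) return(out)
  g <- if (length(grr) == 1) rep(grr, length(p)) else grr
  f <- .cc_freqs(p[live], g[live], K, model, clamp = clamp)
  n1 <- 2 * n_cases
  n2 <- 2 * n_controls
  d <- f$p_case - f$p_control
  pbar <- (n1 * f$p_case + n2 * f$p_control) / (n1 + n2)
  sd0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  sd1 <- sqrt(f$p_case * (1 - f$p_case) / n1 +
                f$p_control * (1 - f$p_control) / n2)
  crit <- stats::qnorm(1 - alpha / 2)
  pow <- ifelse(sd1 > 0,
                stats::pnorm((d - crit * sd0) / sd1) +
                  stats::pnorm((-d - crit * sd0) / sd1),
                0)
  out[live] <- pmin(pmax(pow, 0), 1)
  out
}

#' Analytic power of the case-control allelic association test
#'
#' Power of the two-sided one-degree-of-freedom allele-frequency-contrast
#' (allelic chi-square) test at level `alpha`, using `2 n_cases` and
#' `2 n_controls` allele counts and a normal approximation with the null
#' variance at the pooled frequency and the alternative variance from the
#' case and control binomials. Monomorphic sites (`p = 0` or `p = 1`)
#' have power exactly 0.
#'
#' @param params a [power_params()] object.
#' @return detection probability in [0, 1].
#' @seealso [monte_carlo_power()] for the simulation oracle.
#' @export
analytic_power <- function(params) {
  stopifnot(inherits(params, "power_params"))
  if (params$p <= 0 || params$p >= 1) return(0)
  .power_vec(params$p, params$grr, params$n_cases, params$n_controls,
             params$alpha, params$prevalence, params$model, clamp = FALSE)
}

#' Monte-Carlo power of the allelic association test
#'
#' Simulates case and control allele counts as binomial draws at the
#' expected case/control allele frequencies and reports the fraction of
#' replicates whose allelic chi-square test (no continuity correction)
#' rejects at level `alpha`.
#'
#' @param params a [power_params()] object.
#' @param n_reps number of simulated datasets.
#' @param seed optional integer seed.
#' @return estimated power, with attribute `se` (binomial standard error).
#' @export
monte_carlo_power <- function(params, n_reps = 1e5, seed = NULL) {
  stopifnot(inherits(params, "power_params"), n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (params$p <= 0 || params$p >= 1) {
    return(structure(0, se = 0))
  }
  f <- .cc_freqs(params$p, params$grr, params$prevalence, params$model)
  n1 <- 2 * params$n_cases
  n2 <- 2 * params$n_controls
  x1 <- stats::rbinom(n_reps, n1, f$p_case)
  x2 <- stats::rbinom(n_reps, n2, f$p_control)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  v0 <- pbar * (1 - pbar) * (1 / n1 + 1 / n2)
  chisq <- ifelse(v0 > 0, (p1 - p2)^2 / v0, 0)
  pval <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  pow <- mean(pval < params$alpha)
  structure(pow, se = sqrt(pow * (1 - pow) / n_reps))
}
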