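# Seeded generator of two-sample GWAS summary statistics with known
# causal structure.

# Two-sided normal p-value, floored at the smallest positive double so a
# very strong association never underflows to an (invalid) exact zero.
z_pvalue <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
}

#' Define a simulation scenario for two-sample summary statistics
#'
#' Describes the generative model: for SNP j, an effect-allele frequency
#' is drawn uniformly from `eaf_range`, a true instrument effect
#' `gamma_j` uniformly from `gamma_range`, and a direct (pleiotropic)
#' effect `alpha_j` from a normal law with mean `pleio_mean` and sd
#' `pleio_sd`, optionally correlated with `gamma_j` (`inside_violation`
#' is that correlation; 0 means the InSiDE assumption holds). Sampling
#' noise follows the quantitative-trait approximation with unit
#' phenotypic variance: the standard error of an observed per-allele
#' effect at frequency p in a GWAS of N samples is
#' `1 / sqrt(2 N p (1 - p))`, the same frequency/sample-size law that
#' underlies the per-SNP variance-explained formula.
#'
#' Default sample sizes mirror the two cohorts the design emulates: a
#' microbiome-scale exposure GWAS (18,340 samples) and a food-allergy
#' outcome GWAS of 169,716 samples.
#'
#' @param n_snp Number of instruments.
#' @param beta_causal True causal effect on the ln(OR) scale.
#' @param gamma_range Range of true instrument-exposure effects
#'   (positive magnitudes, drawn uniformly).
#' @param pleio_mean,pleio_sd Direct-effect law; `pleio_mean = 0` is
#'   balanced pleiotropy, nonzero is directional.
#' @param inside_violation Correlation between pleiotropic and instrument
#'   effects in `[-1, 1]`; 0 preserves InSiDE.
#' @param n_exposure,n_outcome GWAS sample sizes (>= 3).
#' @param eaf_range Allele-frequency range within (0, 1).
#' @param palindromic Assign palindromic (A/T) allele pairs instead of
#'   the default non-palindromic A/G.
#' @param noise_scale Multiplier on the sampling noise; 0 yields
#'   noiseless observations (reported standard errors keep the analytic
#'   value so weights remain defined).
#' @param seed Mandatory integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_snp = 10, beta_causal = 0,
                         gamma_range = c(0.05, 0.2),
                         pleio_mean = 0, pleio_sd = 0,
                         inside_violation = 0,
                         n_exposure = 18340, n_outcome = 169716,
                         eaf_range = c(0.1, 0.9),
                         palindromic = FALSE, noise_scale = 1,
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory in a scenario", call. = FALSE)
  stopifnot(n_snp >= 1, n_exposure >= 3, n_outcome >= 3,
            length(gamma_range) == 2L, gamma_range[1] <= gamma_range[2],
            length(eaf_range) == 2L,
            eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] <= eaf_range[2],
            pleio_sd >= 0, abs(inside_violation) <= 1,
            noise_scale >= 0)
  structure(list(n_snp = as.integer(n_snp), beta_causal = beta_causal,
                 gamma_range = gamma_range, pleio_mean = pleio_mean,
                 pleio_sd = pleio_sd, inside_violation = inside_violation,
                 n_exposure = n_exposure, n_outcome = n_outcome,
                 eaf_range = eaf_range, palindromic = palindromic,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate one exposure/outcome pair of summary-statistic tables
#'
#' Draws the latent per-SNP quantities of the scenario, adds sampling
#' noise, and packages observed effects, analytic standard errors, and
#' z-test p-values as two validated trait tables. SNPs are laid out more
#' than 10,000 kb apart (cycling through 22 chromosomes) so that
#' distance-based clumping keeps all of them, and carry non-palindromic
#' A/G alleles unless the scenario requests palindromes.
#'
#' @param scenario A [sim_scenario()].
#' @return A list of class `sim_pair`: `exposure` and `outcome`
#'   `trait_table`s and `truth`, a record of every latent quantity
#'   (`gamma`, `alpha`, `Gamma`, `eaf`, `sigma_gamma`, `sigma_Gamma`,
#'   `beta_causal`, and the scenario itself).
#' @export
#' @examples
#' pair <- simulate_pair(sim_scenario(n_snp = 5, beta_causal = 0.2, seed = 1))
#' pair$truth$beta_causal
simulate_pair <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    J <- sc$n_snp
    eaf <- stats::runif(J, sc$eaf_range[1], sc$eaf_range[2])
    gamma <- stats::runif(J, sc$gamma_range[1], sc$gamma_range[2])
    # Pleiotropic effects, optionally correlated with instrument strength.
    z <- stats::rnorm(J)
    if (sc$inside_violation != 0 && sc$pleio_sd > 0) {
      sd_gamma <- stats::sd(gamma)
      gamma_std <- if (sd_gamma > 0) (gamma - mean(gamma)) / sd_gamma else
        rep(0, J)
      alpha <- sc$pleio_mean + sc$pleio_sd *
        (sc$inside_violation * gamma_std +
           sqrt(1 - sc$inside_violation^2) * z)
    } else {
      alpha <- sc$pleio_mean + sc$pleio_sd * z
    }
    sigma_gamma <- 1 / sqrt(2 * sc$n_exposure * eaf * (1 - eaf))
    sigma_Gamma <- 1 / sqrt(2 * sc$n_outcome * eaf * (1 - eaf))
    beta_exp <- stats::rnorm(J, gamma, sc$noise_scale * sigma_gamma)
    Gamma <- sc$beta_causal * gamma + alpha
    beta_out <- stats::rnorm(J, Gamma, sc$noise_scale * sigma_Gamma)

    chrom <- as.character(rep_len(1:22, J))
    pos <- 1e6 + 2e7 * (ceiling(seq_len(J) / 22) - 1)
    ea <- "A"
    oa <- if (sc$palindromic) "T" else "G"
    base <- data.frame(
      snp_id = sprintf("rs%05d", seq_len(J)),
      chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa,
      eaf = eaf, stringsAsFactors = FALSE)

    exposure <- base
    exposure$beta <- beta_exp
    exposure$se <- sigma_gamma
    exposure$pvalue <- z_pvalue(beta_exp / sigma_gamma)
    exposure$n <- sc$n_exposure
    outcome <- base
    outcome$beta <- beta_out
    outcome$se <- sigma_Gamma
    outcome$pvalue <- z_pvalue(beta_out / sigma_Gamma)
    outcome$n <- sc$n_outcome

    truth <- list(gamma = gamma, alpha = alpha, Gamma = Gamma, eaf = eaf,
                  sigma_gamma = sigma_gamma, sigma_Gamma = sigma_Gamma,
                  beta_causal = sc$beta_causal, scenario = sc)
    structure(list(
      exposure = trait_table(exposure, trait_id = "sim_exposure",
                             trait_type = "quantitative"),
      outcome = trait_table(outcome, trait_id = "sim_outcome",
                            trait_type = "binary"),
      truth = truth), class = "sim_pair")
  })
}

#' Simulate a pair with one pleiotropy-contaminated instrument
#'
#' Runs [simulate_pair()] and then shifts the observed outcome effect of
#' one SNP by `spike_size_in_se` outcome standard errors, the canonical
#' stress case for outlier detection.
#'
#' @param scenario A [sim_scenario()].
#' @param spike_index 1-based index of the contaminated instrument.
#' @param spike_size_in_se Size of the shift in units of that SNP's
#'   outcome standard error.
#' @return A `sim_pair`; `truth$spike` records the contamination.
#' @export
simulate_outlier_spike <- function(scenario, spike_index, spike_size_in_se) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (spike_index < 1L || spike_index > scenario$n_snp) {
    stop("spike_index out of range 1..", scenario$n_snp, call. = FALSE)
  }
  pair <- simulate_pair(scenario)
  i <- as.integer(spike_index)
  shift <- spike_size_in_se * pair$truth$sigma_Gamma[i]
  pair$outcome$beta[i] <- pair$outcome$beta[i] + shift
  pair$outcome$pvalue[i] <- z_pvalue(pair$outcome$beta[i] / pair$outcome$se[i])
  pair$truth$spike <- list(index = i, size_in_se = spike_size_in_se,
                           shift = shift)
  pair
}
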