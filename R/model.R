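#' Specification of the maternal sex-ratio model
#'
#' The model for the sex composition of dam `d`'s sexed adult offspring is
#' binomial with logit mean
#' `logit(pi_d) = mu + x_d' beta + m[matriline(d)] + e_d`,
#' where `m` is the maternally inherited effect shared by every dam of a
#' matriline (variance `sigma2_m`) and `e_d` is a dam-level residual
#' (variance `sigma2_e`). Priors: `mu` and each `beta` are
#' `N(0, prior_var_fixed)`; the precisions `1/sigma2_m` and `1/sigma2_e`
#' carry `Gamma(shape, rate)` priors (the WinBUGS convention), by default
#' `Gamma(0.1, 0.1)`. A `prior_on = "sd"` switch instead places the
#' `Gamma(shape, rate)` prior on the standard deviations `sigma_m`,
#' `sigma_e`, for sensitivity analysis of this ambiguous convention.
#'
#' @param covariates Character vector of dam-record column names to enter
#'   as fixed effects (converted to 0/1 indicators of the second sorted
#'   level for two-level character columns; numeric columns used as-is).
#' @param prior_var_fixed Prior variance of `mu` and each `beta`.
#' @param prior_shape,prior_rate Gamma prior parameters for the two
#'   variance components.
#' @param prior_on `"precision"` (default) or `"sd"`.
#' @param dam_effect Include the dam-level residual effect `e`? Setting
#'   FALSE drops `e` and `sigma2_e` (used by the quadrature oracle).
#' @return A list of class `maternal_model_spec`.
#' @export
maternal_model_spec <- function(covariates = character(),
                                prior_var_fixed = 1000,
                                prior_shape = 0.1,
                                prior_rate = 0.1,
                                prior_on = c("precision", "sd"),
                                dam_effect = TRUE) {
  prior_on <- match.arg(prior_on)
  stopifnot(prior_var_fixed > 0, prior_shape > 0, prior_rate > 0)
  structure(
    list(covariates = as.character(covariates),
         prior_var_fixed = prior_var_fixed,
         prior_shape = prior_shape, prior_rate = prior_rate,
         prior_on = prior_on, dam_effect = isTRUE(dam_effect)),
    class = "maternal_model_spec"
  )
}

#' MCMC configuration
#'
#' Defaults follow the sampling plan the model was designed around: two
#' independent chains of 12,000 iterations with the first 2,000 discarded
#' as burn-in. Random-walk proposal scales are adapted during burn-in
#' toward a 20–50% acceptance rate and frozen afterwards so the
#' post-burn-in kernel satisfies detailed balance.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iterations Iterations per chain (burn-in included).
#' @param burn_in Iterations discarded by [posterior_summary()] /
#'   [psrf()].
#' @param thin Keep every `thin`-th iteration in the stored draws.
#' @param seed Master seed; per-chain seeds are derived from it.
#' @param proposal_scales Named list of initial random-walk standard
#'   deviations for blocks `m`, `e`, `mu`, `beta` (and `log_sigma` when the
#'   prior is placed on standard deviations).
#' @param adapt Adapt proposal scales during burn-in?
#' @param keep_effects Store draws of every `m` and `e` effect (only
#'   sensible for small problems)?
#' @param fix_tau_m,fix_tau_e Optional fixed precision values; when given,
#'   the corresponding precision is not sampled (used when validating the
#'   sampler against quadrature).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2,
                        n_iterations = 12000,
                        burn_in = 2000,
                        thin = 1,
                        seed = 1L,
                        proposal_scales = list(m = 0.5, e = 0.5,
                                               mu = 0.15, beta = 0.25,
                                               log_sigma = 0.3),
                        adapt = TRUE,
                        keep_effects = FALSE,
                        fix_tau_m = NULL,
                        fix_tau_e = NULL) {
  cfg <- list(
    n_chains = as.integer(n_chains),
    n_iterations = as.integer(n_iterations),
    burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    seed = as.integer(seed),
    proposal_scales = proposal_scales,
    adapt = isTRUE(adapt),
    keep_effects = isTRUE(keep_effects),
    fix_tau_m = fix_tau_m, fix_tau_e = fix_tau_e
  )
  if (cfg$burn_in >= cfg$n_iterations) {
    abort("burn_in must be smaller than n_iterations",
          class = "matriline_config_error")
  }
  if (cfg$n_chains < 1) abort("need at least one chain",
                              class = "matriline_config_error")
  stopifnot(cfg$thin >= 1)
  structure(cfg, class = "mcmc_config")
}
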