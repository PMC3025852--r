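#' Fit the maternal sex-ratio model by Metropolis-within-Gibbs
#'
#' Runs independent MCMC chains on the hierarchical logit-binomial model.
#' Each iteration updates, in fixed order: (1) all matriline effects `m`
#' by vectorized random-walk Metropolis (every matriline's acceptance uses
#' the binomial likelihood of all dam records in that matriline); (2) all
#' dam effects `e` by vectorized random-walk Metropolis; (3) `mu` and each
#' fixed-effect coefficient by scalar random-walk Metropolis; (4) the
#' precisions `tau_m = 1/sigma2_m` and `tau_e = 1/sigma2_e` from their
#' conjugate full conditionals `Gamma(a + k/2, b + sum(effects^2)/2)`
#' (when the prior is placed on standard deviations, step 4 becomes a
#' random-walk Metropolis update on `log sigma`). Matriline and dam
#' effects are simultaneously proposed and accepted element-wise, which is
#' valid because they are conditionally independent blocks given the rest
#' of the state.
#'
#' Chains start from over-dispersed values: `mu` at the empirical logit of
#' the pooled sex ratio plus chain-specific jitter, effects at jittered
#' zero, precisions at 1. Proposal scales adapt during burn-in only.
#'
#' @param records Dam records from [aggregate_dams()]; rows flagged
#'   `excluded` (no sexed adults) are dropped.
#' @param spec A [maternal_model_spec()].
#' @param config An [mcmc_config()].
#' @return An object of class `maternal_fit` with elements `draws` (list
#'   of per-chain matrices, one row per stored iteration; columns `mu`,
#'   fixed effects, `tau_m`, `tau_e`, `sigma2_m`, `sigma2_e`, and the
#'   individual effects when `keep_effects = TRUE`), `spec`, `config`,
#'   `acceptance` (per-chain mean acceptance rates per block), and `data`
#'   (prepared records).
#' @seealso [posterior_summary()], [psrf()], [tidy.maternal_fit()]
#' @export
fit_maternal_model <- function(records, spec = maternal_model_spec(),
                               config = mcmc_config()) {
  stopifnot(inherits(spec, "maternal_model_spec"),
            inherits(config, "mcmc_config"))
  prep <- prepare_records(records, spec)

  set.seed(config$seed)
  chain_seeds <- sample.int(2147483646L, config$n_chains)
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    run_one_chain(prep, spec, config, chain_seeds[ch], ch)
  })

  structure(
    list(
      draws = lapply(chains, `[[`, "draws"),
      acceptance = lapply(chains, `[[`, "acceptance"),
      scales = lapply(chains, `[[`, "scales"),
      spec = spec, config = config,
      data = prep
    ),
    class = "maternal_fit"
  )
}

#' @export
print.maternal_fit <- function(x, ...) {
  cat("<maternal_fit> ", length(x$draws), " chain(s) x ",
      x$config$n_iterations, " iterations (burn-in ", x$config$burn_in,
      ")\n", sep = "")
  cat("  ", length(x$data$y), " dam records, ",
      length(x$data$mat_ids), " matrilines\n", sep = "")
  print(posterior_summary(x))
  invisible(x)
}

run_one_chain <- function(prep, spec, config, chain_seed, chain_index) {
  set.seed(chain_seed)
  y <- prep$y; n <- prep$n; mi <- prep$mi; X <- prep$X
  K <- length(prep$mat_ids)
  D <- length(y)
  P <- ncol(X)
  use_e <- isTRUE(spec$dam_effect)
  a <- spec$prior_shape; b <- spec$prior_rate
  v0 <- spec$prior_var_fixed

  # over-dispersed start: jitter grows with the chain index
  pooled <- sum(y) / sum(n)
  pooled <- min(max(pooled, 0.02), 0.98)
  jit <- 0.25 * chain_index
  mu <- qlogis(pooled) + rnorm(1, 0, jit)
  beta <- rnorm(P, 0, jit)
  m <- rnorm(K, 0, jit)
  e <- if (use_e) rnorm(D, 0, jit) else numeric(D)
  tau_m <- config$fix_tau_m %||% 1
  tau_e <- config$fix_tau_e %||% 1

  eta_fixed <- function() {
    if (P) mu + drop(X %*% beta) else rep(mu, D)
  }
  base <- eta_fixed()

  init_ll <- sum(binom_loglik_kernel(base + m[mi] + e, y, n))
  if (!is.finite(init_ll)) {
    abort(paste0("non-finite log posterior at the initial state ",
                 "(mu = ", format(mu), ", chain ", chain_index, ")"),
          class = "matriline_init_error")
  }

  sc <- config$proposal_scales
  s_m <- sc$m %||% 0.5
  s_e <- sc$e %||% 0.5
  s_mu <- sc$mu %||% 0.15
  s_beta <- rep(sc$beta %||% 0.25, P)
  s_ls_m <- sc$log_sigma %||% 0.3
  s_ls_e <- sc$log_sigma %||% 0.3

  n_iter <- config$n_iterations
  keep <- seq(config$thin, n_iter, by = config$thin)
  par_names <- c("mu", colnames(X), "tau_m", "tau_e", "sigma2_m", "sigma2_e")
  if (config$keep_effects) {
    par_names <- c(par_names, paste0("m[", prep$mat_ids, "]"),
                   if (use_e) paste0("e[", prep$dam_ids, "]"))
  }
  draws <- matrix(NA_real_, length(keep), length(par_names),
                  dimnames = list(NULL, par_names))
  store_row <- 0L

  acc <- c(m = 0, e = 0, mu = 0, beta = 0)
  tries <- c(m = 0, e = 0, mu = 0, beta = 0)
  win <- c(m = 0, e = 0, mu = 0, beta = 0)     # windowed acceptance counts
  win_n <- c(m = 0, e = 0, mu = 0, beta = 0)
  adapt_every <- 50L

  for (it in seq_len(n_iter)) {
    adapting <- config$adapt && it <= config$burn_in

    ## (1) matriline effects, all K at once
    prop <- m + s_m * rnorm(K)
    cur_eta <- base + m[mi] + e
    new_eta <- base + prop[mi] + e
    d_rec <- binom_loglik_kernel(new_eta, y, n) -
      binom_loglik_kernel(cur_eta, y, n)
    delta <- rowsum(d_rec, mi, reorder = TRUE)[, 1] +
      0.5 * tau_m * (m^2 - prop^2)
    ok <- log(runif(K)) < delta
    m[ok] <- prop[ok]
    rate_m <- mean(ok)

    ## (2) dam effects, all D at once
    if (use_e) {
      prop <- e + s_e * rnorm(D)
      me <- base + m[mi]
      delta <- binom_loglik_kernel(me + prop, y, n) -
        binom_loglik_kernel(me + e, y, n) +
        0.5 * tau_e * (e^2 - prop^2)
      ok <- log(runif(D)) < delta
      e[ok] <- prop[ok]
      rate_e <- mean(ok)
    } else rate_e <- NA_real_

    ## (3) mu, then each beta, scalar random walks
    offs <- m[mi] + e
    prop_mu <- mu + s_mu * rnorm(1)
    lin <- if (P) drop(X %*% beta) else 0
    delta <- sum(binom_loglik_kernel(prop_mu + lin + offs, y, n)) -
      sum(binom_loglik_kernel(mu + lin + offs, y, n)) +
      (mu^2 - prop_mu^2) / (2 * v0)
    ok_mu <- log(runif(1)) < delta
    if (ok_mu) mu <- prop_mu
    rate_beta <- NA_real_
    if (P) {
      ok_b <- logical(P)
      for (j in seq_len(P)) {
        prop_b <- beta
        prop_b[j] <- beta[j] + s_beta[j] * rnorm(1)
        delta <- sum(binom_loglik_kernel(mu + drop(X %*% prop_b) + offs, y, n)) -
          sum(binom_loglik_kernel(mu + drop(X %*% beta) + offs, y, n)) +
          (beta[j]^2 - prop_b[j]^2) / (2 * v0)
        if (log(runif(1)) < delta) { beta <- prop_b; ok_b[j] <- TRUE }
      }
      rate_beta <- mean(ok_b)
    }
    base <- eta_fixed()

    ## (4) precisions
    if (is.null(config$fix_tau_m)) {
      if (spec$prior_on == "precision") {
        tau_m <- rgamma(1, shape = a + K / 2, rate = b + sum(m^2) / 2)
      } else {
        tau_m <- update_tau_sd_prior(tau_m, m, a, b, s_ls_m)
      }
    }
    if (use_e && is.null(config$fix_tau_e)) {
      if (spec$prior_on == "precision") {
        tau_e <- rgamma(1, shape = a + D / 2, rate = b + sum(e^2) / 2)
      } else {
        tau_e <- update_tau_sd_prior(tau_e, e, a, b, s_ls_e)
      }
    }

    ## bookkeeping
    acc <- acc + c(rate_m, rate_e, ok_mu, rate_beta)
    tries <- tries + c(1, !is.na(rate_e), 1, P > 0)
    if (adapting) {
      win <- win + c(rate_m, if (is.na(rate_e)) 0 else rate_e, ok_mu,
                     if (is.na(rate_beta)) 0 else rate_beta)
      win_n <- win_n + c(1, use_e, 1, P > 0)
      if (it %% adapt_every == 0L) {
        tune <- function(s, rate) {
          if (rate < 0.20) s * 0.8 else if (rate > 0.50) s * 1.25 else s
        }
        s_m <- tune(s_m, win["m"] / max(win_n["m"], 1))
        if (use_e) s_e <- tune(s_e, win["e"] / max(win_n["e"], 1))
        s_mu <- tune(s_mu, win["mu"] / max(win_n["mu"], 1))
        if (P) s_beta <- vapply(s_beta, tune, numeric(1),
                                rate = win["beta"] / max(win_n["beta"], 1))
        win[] <- 0; win_n[] <- 0
      }
    }

    if (it %% config$thin == 0L) {
      store_row <- store_row + 1L
      row <- c(mu, beta, tau_m, tau_e, 1 / tau_m, 1 / tau_e)
      if (config$keep_effects) row <- c(row, m, if (use_e) e)
      draws[store_row, ] <- row
    }
  }

  list(draws = draws,
       acceptance = acc / pmax(tries, 1),
       scales = list(m = s_m, e = s_e, mu = s_mu, beta = s_beta))
}

# Metropolis update of a precision whose gamma prior sits on the standard
# deviation; random walk on log(sigma) with the jacobian of both changes
# of variable folded in.
update_tau_sd_prior <- function(tau, effects, a, b, scale) {
  sigma <- 1 / sqrt(tau)
  ls <- log(sigma)
  ls_new <- ls + scale * rnorm(1)
  sigma_new <- exp(ls_new)
  k <- length(effects)
  ssq <- sum(effects^2)
  logtarget <- function(s) {
    -k * log(s) - ssq / (2 * s^2) +           # effect likelihood
      dgamma(s, shape = a, rate = b, log = TRUE) +
      log(s)                                   # jacobian for log-sigma walk
  }
  if (log(runif(1)) < logtarget(sigma_new) - logtarget(sigma)) {
    sigma <- sigma_new
  }
  1 / sigma^2
}
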