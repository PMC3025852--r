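test_that("identical data, config and seed give identical draws", {
  rec <- tiny_record_sets()[[4]]
  cfg <- mcmc_config(n_iterations = 500, burn_in = 100, seed = 5,
                     keep_effects = TRUE)
  f1 <- fit_maternal_model(rec, maternal_model_spec(), cfg)
  f2 <- fit_maternal_model(rec, maternal_model_spec(), cfg)
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_maternal_model(rec, maternal_model_spec(),
                           mcmc_config(n_iterations = 500, burn_in = 100,
                                       seed = 6, keep_effects = TRUE))
  expect_false(identical(f1$draws[[1]], f3$draws[[1]]))
})

test_that("null-variance data concentrate the posterior at zero", {
  sim <- simulate_pedigree(sim_params(
    n_founders = 200, n_generations = 1, mu = 0, sigma2_m = 0, sigma2_e = 0,
    clutch_mean = 20, founder_infection_prevalence = 0, seed = 31
  ))
  rec <- aggregate_dams(sim$pedigree)
  fit <- fit_maternal_model(rec, maternal_model_spec(),
                            quick_config(seed = 2))
  s <- posterior_summary(fit)
  expect_lt(abs(s$mean[s$parameter == "mu"]), 0.1)
  # both variance posteriors pile up near zero
  expect_lt(s$mean[s$parameter == "sigma2_m"], 0.05)
  expect_lt(s$ci_upper[s$parameter == "sigma2_m"], 0.15)
  expect_lt(s$mean[s$parameter == "sigma2_e"], 0.05)
})

test_that("acceptance rates land in the adapted 20-50% band", {
  sim <- simulate_pedigree(sim_params(n_founders = 50, n_generations = 2,
                                      clutch_mean = 12, seed = 9))
  rec <- aggregate_dams(sim$pedigree)
  fit <- fit_maternal_model(rec, maternal_model_spec(),
                            quick_config(seed = 3))
  for (acc in fit$acceptance) {
    expect_gt(acc[["m"]], 0.15)
    expect_lt(acc[["m"]], 0.6)
    expect_gt(acc[["e"]], 0.15)
    expect_lt(acc[["e"]], 0.6)
  }
})

test_that("the posterior of mu plus the mean matriline effect is stable across chains", {
  rec <- tiny_record_sets()[[4]]
  fit <- fit_maternal_model(
    rec, maternal_model_spec(prior_var_fixed = 10),
    mcmc_config(n_iterations = 8000, burn_in = 2000, seed = 11,
                keep_effects = TRUE)
  )
  per_chain <- vapply(fit$draws, function(d) {
    post <- d[2001:nrow(d), ]
    mean(post[, "mu"] + rowMeans(post[, grep("^m\\[", colnames(d))]))
  }, numeric(1))
  # the identifiable combination agrees across chains within MC error
  mcse <- max(vapply(fit$draws, function(d) {
    post <- d[2001:nrow(d), ]
    matriline:::mcse_mean(post[, "mu"] +
                            rowMeans(post[, grep("^m\\[", colnames(d))]))
  }, numeric(1)))
  expect_lt(abs(diff(per_chain)), 6 * mcse)
})

test_that("a long chain is stationary under the conjugate precision updates", {
  sim <- simulate_pedigree(sim_params(n_founders = 60, n_generations = 2,
                                      clutch_mean = 14, seed = 77))
  rec <- aggregate_dams(sim$pedigree)
  fit <- fit_maternal_model(rec, maternal_model_spec(),
                            mcmc_config(n_iterations = 8000, burn_in = 2000,
                                        seed = 13))
  # Geweke-style check: early vs late post-burn-in segment means
  for (par in c("sigma2_m", "sigma2_e", "mu")) {
    x <- pooled_chain <- fit$draws[[1]][2001:8000, par]
    n <- length(x)
    a <- x[1:floor(0.4 * n)]
    b <- x[(n - floor(0.4 * n) + 1):n]
    se <- sqrt(matriline:::mcse_mean(a)^2 + matriline:::mcse_mean(b)^2)
    expect_lt(abs(mean(a) - mean(b)) / se, 5)
  }
})

test_that("the gamma prior can sit on standard deviations instead of precisions", {
  rec <- tiny_record_sets()[[4]]
  fit <- fit_maternal_model(
    rec, maternal_model_spec(prior_on = "sd"),
    mcmc_config(n_iterations = 3000, burn_in = 500, seed = 4)
  )
  s <- posterior_summary(fit)
  expect_true(all(is.finite(s$mean)))
  expect_true(all(s$ci_lower <= s$ci_upper))
})

test_that("initialization fails loudly on degenerate input", {
  rec <- tibble::tibble(dam_id = "d1", matriline_id = "m1",
                        total_male = 0, total_female = 0)
  expect_error(fit_maternal_model(rec), class = "matriline_domain_error")
})

test_that("posterior summaries follow their definitions", {
  const <- list(matrix(2.5, 100, 1, dimnames = list(NULL, "x")),
                matrix(2.5, 100, 1, dimnames = list(NULL, "x")))
  s <- posterior_summary(const, burn_in = 0)
  expect_equal(s$mean, 2.5)
  expect_equal(s$ci_lower, 2.5)
  expect_equal(s$ci_upper, 2.5)

  d <- list(matrix(as.numeric(1:100), 100, 1, dimnames = list(NULL, "x")))
  s <- posterior_summary(d, burn_in = 0)
  expect_equal(s$mean, 50.5)
  # type-7 quantiles computed by hand: 1 + 99p interpolated
  expect_equal(s$ci_lower, 1 + 99 * 0.025)
  expect_equal(s$ci_upper, 1 + 99 * 0.975)

  expect_error(posterior_summary(d, burn_in = 100),
               class = "matriline_config_error")
})

test_that("variance summaries transform draws, not means", {
  rec <- tiny_record_sets()[[2]]
  fit <- fit_maternal_model(rec, maternal_model_spec(),
                            mcmc_config(n_iterations = 1500, burn_in = 500,
                                        seed = 21))
  s <- posterior_summary(fit)
  tau_draws <- matriline:::pooled_draws(fit, "tau_m")
  expect_equal(s$mean[s$parameter == "sigma2_m"], mean(1 / tau_draws))
  # Jensen gap: draw-wise mean exceeds the reciprocal of the mean precision
  expect_gt(mean(1 / tau_draws), 1 / mean(tau_draws))
})

test_that("PSRF follows the textbook between/within formula", {
  # identical chains: PSRF = sqrt((N-1)/N) -> 1 as chains lengthen
  x <- matrix(rnorm(1e6), ncol = 1, dimnames = list(NULL, "p"))
  expect_lt(abs(psrf(list(x, x), burn_in = 0) - 1), 1e-6)
  # chains stuck at different constants diverge
  c1 <- matrix(0, 100, 1, dimnames = list(NULL, "p"))
  c2 <- matrix(5, 100, 1, dimnames = list(NULL, "p"))
  expect_gt(psrf(list(c1, c2), burn_in = 0), 1.1)
  # hand-computed 2-chain x 5-draw example
  a <- c(1, 2, 3, 4, 5); b <- c(2, 4, 6, 8, 10)
  W <- (var(a) + var(b)) / 2
  B <- 5 * var(c(mean(a), mean(b)))
  expected <- sqrt(((5 - 1) / 5 * W + B / 5) / W)
  got <- psrf(list(matrix(a, 5, 1, dimnames = list(NULL, "p")),
                   matrix(b, 5, 1, dimnames = list(NULL, "p"))),
              burn_in = 0)
  expect_equal(unname(got), expected)
  expect_error(psrf(list(c1), burn_in = 0),
               class = "matriline_capability_error")
})

test_that("credibility intervals for sigma2_m cover the generating value", {
  # moderate-size replicates; wide-but-finite prior influence tolerated
  n_rep <- 100
  covered <- vapply(seq_len(n_rep), function(r) {
    sim <- simulate_pedigree(sim_params(
      n_founders = 50, n_generations = 2, clutch_mean = 12,
      sigma2_m = 0.64, sigma2_e = 0.27, seed = 5000 + r
    ))
    rec <- aggregate_dams(sim$pedigree)
    fit <- fit_maternal_model(rec, maternal_model_spec(),
                              mcmc_config(n_iterations = 2500, burn_in = 500,
                                          n_chains = 2, seed = r))
    s <- posterior_summary(fit)
    i <- s$parameter == "sigma2_m"
    s$ci_lower[i] <= 0.64 && s$ci_upper[i] >= 0.64
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("tidy, glance and draw export expose the fit consistently", {
  rec <- tiny_record_sets()[[3]]
  fit <- fit_maternal_model(rec, maternal_model_spec(),
                            mcmc_config(n_iterations = 1000, burn_in = 200,
                                        seed = 2))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_records, 2L)
  expect_equal(gl$n_matrilines, 2L)
  long <- tidy_draws(fit)
  expect_equal(nrow(long), 2 * 1000 * 5)  # mu, tau_m/e, sigma2_m/e
  p <- autoplot(fit, type = "trace")
  expect_s3_class(p, "ggplot")
})
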