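#' Clutch-size-weighted Pearson correlation
#'
#' Pearson correlation computed with weighted means, variances and
#' covariance. Weighting the clutch sex ratio by clutch size down-weights
#' the noisy ratio estimates of small clutches; a positive correlation
#' between clutch size and proportion of sons (smaller clutches more
#' female-biased) is the signature of male killing rather than
#' feminization.
#'
#' @param data Data frame holding the two variables (and optional weight
#'   column); clutch-level records in practice.
#' @param x,y Column names (strings) of the two variables, e.g. clutch
#'   size and clutch sex ratio.
#' @param weights Optional column name of the weights; defaults to the
#'   `x` column (clutch size), per the weighting rationale above.
#' @return Weighted correlation coefficient in \[-1, 1\].
#' @export
weighted_pearson <- function(data, x = "n_hatched", y = "sex_ratio",
                             weights = x) {
  stopifnot(is.data.frame(data), x %in% names(data), y %in% names(data),
            weights %in% names(data))
  xv <- as.numeric(data[[x]])
  yv <- as.numeric(data[[y]])
  wv <- as.numeric(data[[weights]])
  if (length(xv) < 3) {
    abort("need at least 3 observations", class = "matriline_domain_error")
  }
  if (any(wv <= 0) || anyNA(c(xv, yv, wv))) {
    abort("weights must be positive and values non-missing",
          class = "matriline_domain_error")
  }
  cw <- cov.wt(cbind(xv, yv), wt = wv / sum(wv), cor = TRUE,
               method = "ML")
  if (any(diag(cw$cov) == 0)) {
    abort("weighted variance of a variable is zero; correlation undefined",
          class = "matriline_undefined_value_error")
  }
  unname(cw$cor[1, 2])
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional test of association with both margins fixed
#' (hypergeometric null). The two-sided p-value follows the
#' minimum-likelihood rule: the probabilities of all tables whose point
#' probability does not exceed that of the observed table are summed.
#' Used here for sex-by-infection and population-by-infection contrasts.
#'
#' @param table 2x2 matrix of counts, or a length-4 vector
#'   `c(a, b, c, d)` filled row-wise (rows = sex, columns =
#'   infected/uninfected).
#' @return Two-sided p-value in (0, 1\]. A table with a zero margin
#'   carries no information about association; p = 1 is returned with a
#'   warning.
#' @export
fisher_exact <- function(table) {
  if (!is.matrix(table)) table <- matrix(as.numeric(table), 2, byrow = TRUE)
  stopifnot(identical(dim(table), c(2L, 2L)) || identical(dim(table), c(2, 2)))
  if (any(table < 0) || sum(table) == 0) {
    abort("counts must be non-negative with a positive total",
          class = "matriline_domain_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warn("a margin of the 2x2 table is zero; returning p = 1")
    return(1)
  }
  fisher.test(table, alternative = "two.sided")$p.value
}

#' Exact binomial test
#'
#' Exact tail-sum test of `k` successes in `n` Bernoulli(p0) trials. The
#' two-sided p-value defaults to the minimum-likelihood rule (sum of all
#' outcome probabilities not exceeding that of `k`); the
#' double-the-smaller-tail rule is available via `two_sided_rule` since
#' published two-sided exact p-values do not always state their
#' convention.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @param two_sided_rule `"min.likelihood"` (default) or `"double.tail"`.
#' @return p-value in (0, 1\].
#' @export
exact_binomial_test <- function(k, n, p0,
                                alternative = c("two.sided", "less", "greater"),
                                two_sided_rule = c("min.likelihood",
                                                   "double.tail")) {
  alternative <- match.arg(alternative)
  two_sided_rule <- match.arg(two_sided_rule)
  stopifnot(k >= 0, k <= n, p0 >= 0, p0 <= 1)
  if (alternative != "two.sided" || two_sided_rule == "min.likelihood") {
    # binom.test yields a logical at the degenerate nulls p0 = 0 or 1
    return(as.numeric(binom.test(k, n, p0, alternative = alternative)$p.value))
  }
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Expected infected-male fractions from prevalence and group sex ratios
#'
#' With maternal transmission, a male is infected exactly when his mother
#' was. If a fraction `prevalence` of females is infected and infected and
#' uninfected females produce sex ratios `sr_infected` and `sr_uninfected`
#' respectively, then the fraction of offspring that are male *and*
#' infected is `prevalence * sr_infected`, the fraction male *and*
#' uninfected is `(1 - prevalence) * sr_uninfected`, and the proportion of
#' males expected to test positive is the first over their sum.
#'
#' @param prevalence Probability that a female is infected.
#' @param sr_infected,sr_uninfected Sex ratios (proportion male) of
#'   infected and uninfected females.
#' @return One-row tibble with columns `frac_male_infected`,
#'   `frac_male_uninfected`, `prop_males_infected`.
#' @examples
#' expected_male_infection(0.45, 0.36, 0.5)  # 0.162, 0.275, 0.37
#' @export
expected_male_infection <- function(prevalence, sr_infected, sr_uninfected) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            sr_infected >= 0, sr_infected <= 1,
            sr_uninfected >= 0, sr_uninfected <= 1)
  a <- prevalence * sr_infected
  b <- (1 - prevalence) * sr_uninfected
  if (a + b == 0) {
    abort("no males expected in either group; proportion undefined",
          class = "matriline_undefined_value_error")
  }
  tibble::tibble(
    frac_male_infected = a,
    frac_male_uninfected = b,
    prop_males_infected = a / (a + b)
  )
}

#' Posterior group contrast of sex ratios
#'
#' Fits the maternal model with a binary fixed-effect covariate (e.g.
#' infection status or antibiotic treatment) and reports the posterior of
#' the coefficient together with each group's expected sex ratio
#' `plogis(mu)` and `plogis(mu + beta)` with equal-tailed 95% intervals.
#' A group's ratio "differs from 0.5" when its interval excludes 0.5.
#' This Bayesian contrast is the package's analogue of a mixed-model
#' F-test on the group factor.
#'
#' @param records Dam records containing the covariate column with exactly
#'   two observed levels.
#' @param covariate Column name of the grouping covariate.
#' @param spec Optional [maternal_model_spec()]; its covariate list is
#'   replaced by `covariate`.
#' @param config An [mcmc_config()].
#' @return A list of class `group_contrast` with elements `effect`
#'   (one-row tibble for the coefficient), `groups` (tibble of per-group
#'   posterior sex ratios and `differs_from_half`), and `fit`.
#' @export
group_sexratio_contrast <- function(records, covariate,
                                    spec = maternal_model_spec(),
                                    config = mcmc_config()) {
  vals <- records[[covariate]]
  lev <- sort(unique(as.character(vals[!is.na(vals)])))
  if (length(lev) != 2) {
    abort(paste0("covariate `", covariate, "` must have exactly two levels; found ",
                 length(lev)),
          class = "matriline_design_error")
  }
  records <- records[!is.na(vals), , drop = FALSE]
  spec$covariates <- covariate
  fit <- fit_maternal_model(records, spec, config)

  beta_name <- colnames(fit$data$X)[1]
  mu_d <- pooled_draws(fit, "mu")
  beta_d <- pooled_draws(fit, beta_name)
  qs <- function(v) quantile(v, c(0.025, 0.975), names = FALSE)
  g1 <- plogis(mu_d)          # reference level (first sorted)
  g2 <- plogis(mu_d + beta_d) # second level
  ci1 <- qs(g1); ci2 <- qs(g2); cib <- qs(beta_d)

  structure(list(
    effect = tibble::tibble(
      term = beta_name, estimate = mean(beta_d),
      conf.low = cib[1], conf.high = cib[2],
      excludes_zero = cib[1] > 0 | cib[2] < 0
    ),
    groups = tibble::tibble(
      group = lev,
      mean_sex_ratio = c(mean(g1), mean(g2)),
      conf.low = c(ci1[1], ci2[1]),
      conf.high = c(ci1[2], ci2[2]),
      differs_from_half = c(ci1[1] > 0.5 | ci1[2] < 0.5,
                            ci2[1] > 0.5 | ci2[2] < 0.5)
    ),
    fit = fit
  ), class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("<group_contrast>\n")
  print(x$effect)
  print(x$groups)
  invisible(x)
}

#' Clutch-size ratio diagnostic for the distortion mechanism
#'
#' Male killing removes infected females' sons as embryos, so their broods
#' hatch at roughly half the size of uninfected broods (exactly half under
#' complete killing of an even primary sex ratio); feminization leaves
#' brood size untouched. The point estimate is the ratio of mean hatched
#' counts (infected / uninfected) with a seeded clutch-level percentile
#' bootstrap interval.
#'
#' @param clutch_data Data frame with one row per clutch, columns
#'   `n_hatched` and `infected` (logical, or `"pos"`/`"neg"`).
#' @param n_boot Bootstrap resamples.
#' @param conf Interval mass.
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `ratio`, `conf.low`, `conf.high`,
#'   `n_infected`, `n_uninfected`.
#' @export
clutch_size_mechanism_diagnostic <- function(clutch_data, n_boot = 10000,
                                             conf = 0.95, seed = 1L) {
  stopifnot(is.data.frame(clutch_data),
            all(c("n_hatched", "infected") %in% names(clutch_data)))
  inf <- clutch_data$infected
  if (!is.logical(inf)) inf <- as.character(inf) == "pos"
  sz_i <- clutch_data$n_hatched[inf]
  sz_u <- clutch_data$n_hatched[!inf]
  if (length(sz_i) < 2 || length(sz_u) < 2) {
    abort("need at least two clutches in each infection group",
          class = "matriline_domain_error")
  }
  ratio <- mean(sz_i) / mean(sz_u)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    mean(sample(sz_i, replace = TRUE)) / mean(sample(sz_u, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(ratio = ratio, conf.low = ci[1], conf.high = ci[2],
                 n_infected = length(sz_i), n_uninfected = length(sz_u))
}
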