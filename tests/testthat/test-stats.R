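test_that("weighted Pearson reduces to the unweighted correlation and hits 1 on a line", {
  set.seed(10)
  d <- tibble::tibble(x = rnorm(12), y = rnorm(12), w = 1)
  expect_equal(weighted_pearson(d, "x", "y", "w"), cor(d$x, d$y))
  d2 <- tibble::tibble(x = 1:8, y = 0.2 + 3 * (1:8), w = 1)
  expect_equal(weighted_pearson(d2, "x", "y", "w"), 1)
})

test_that("weighted Pearson matches the moment-formula oracle and its invariances", {
  set.seed(11)
  d <- tibble::tibble(size = rpois(10, 15) + 1, ratio = runif(10))
  r <- weighted_pearson(d, "size", "ratio", "size")
  expect_equal(r, weighted_pearson_formula(d$size, d$ratio, d$size))

  # invariant to positive rescaling of weights
  d$w2 <- d$size * 13.7
  expect_equal(weighted_pearson(d, "size", "ratio", "w2"), r)
  # sign-preserving affine transforms of either variable
  d$size2 <- 2 * d$size + 5
  d$ratio2 <- 0.1 * d$ratio - 3
  expect_equal(weighted_pearson(d, "size2", "ratio2", "w2"), r)
  # sign flip negates
  d$neg <- -d$size
  expect_equal(weighted_pearson(d, "neg", "ratio", "w2"), -r)

  expect_error(weighted_pearson(tibble::tibble(x = c(1, 1, 1), y = 1:3, w = 1),
                                "x", "y", "w"),
               class = "matriline_undefined_value_error")
  expect_error(weighted_pearson(d[1:2, ], "size", "ratio"),
               class = "matriline_domain_error")
})

test_that("Fisher's exact test matches field observations and conventions", {
  # Damvallei: 17/22 infected/uninfected females vs 4/3 males
  expect_gt(fisher_exact(matrix(c(17, 22, 4, 3), 2, byrow = TRUE)), 0.2)
  # identical row proportions carry no evidence of association
  expect_equal(fisher_exact(c(5, 5, 10, 10)), 1)
  # zero margin: warn and return 1
  expect_warning(p <- fisher_exact(c(0, 0, 5, 7)), "margin")
  expect_equal(p, 1)
})

test_that("Fisher p-values equal exhaustive hypergeometric enumeration", {
  set.seed(12)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 3), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab), fisher_enum_p(tab), tolerance = 1e-10)
  }
})

test_that("exact binomial test handles edge cases and both two-sided rules", {
  expect_equal(exact_binomial_test(0, 10, 0), 1)
  expect_equal(exact_binomial_test(2, 5, 0.5), binom_enum_p(2, 5, 0.5))
  # 11 infected of 18 males against an expected 37%: the double-tail rule
  # reproduces the conventionally reported 0.07
  p_dt <- exact_binomial_test(11, 18, 0.37, two_sided_rule = "double.tail")
  expect_equal(round(p_dt, 2), 0.07, tolerance = 1e-8)
  expect_gt(p_dt, 0.05)
  # the min-likelihood rule gives a different (smaller) value here
  p_ml <- exact_binomial_test(11, 18, 0.37)
  expect_lt(p_ml, p_dt)
  # one-sided tails agree with enumeration
  expect_equal(exact_binomial_test(3, 9, 0.4, alternative = "less"),
               binom_enum_p(3, 9, 0.4, "less"))
  expect_equal(exact_binomial_test(3, 9, 0.4, alternative = "greater"),
               binom_enum_p(3, 9, 0.4, "greater"))
})

test_that("expected infected-male algebra reproduces the maternal-transmission identity", {
  got <- expected_male_infection(0.45, 0.36, 0.5)
  expect_equal(got$frac_male_infected, 0.162)
  expect_equal(got$frac_male_uninfected, 0.275)
  expect_equal(round(got$prop_males_infected, 2), 0.37)

  sym <- expected_male_infection(0.5, 0.5, 0.5)
  expect_equal(unlist(sym), c(frac_male_infected = 0.25,
                              frac_male_uninfected = 0.25,
                              prop_males_infected = 0.5))
  expect_equal(expected_male_infection(1, 0.36, 0.9)$prop_males_infected, 1)
  expect_error(expected_male_infection(0, 0.4, 0),
               class = "matriline_undefined_value_error")

  # monotone in prevalence when infected females produce any sons
  ps <- seq(0.1, 0.9, by = 0.1)
  vals <- vapply(ps, function(p) {
    expected_male_infection(p, 0.36, 0.5)$prop_males_infected
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the group contrast runs on minimal and null data", {
  rec <- tibble::tibble(
    dam_id = c("d1", "d2"), matriline_id = c("m1", "m2"),
    total_male = c(1, 0), total_female = c(0, 1),
    wolbachia = c("pos", "neg")
  )
  gc <- group_sexratio_contrast(rec, "wolbachia",
                                config = mcmc_config(n_iterations = 1500,
                                                     burn_in = 500, seed = 3))
  # one offspring per group: the interval spans almost everything
  expect_gt(gc$groups$conf.high[1] - gc$groups$conf.low[1], 0.7)
  expect_error(
    group_sexratio_contrast(dplyr::mutate(rec, wolbachia = "pos"), "wolbachia"),
    class = "matriline_design_error"
  )
})

test_that("a null group difference is rarely declared significant", {
  hits <- vapply(1:20, function(r) {
    sim <- simulate_pedigree(sim_params(
      n_founders = 40, n_generations = 1, mu = 0, sigma2_m = 0,
      sigma2_e = 0, clutch_mean = 12, founder_infection_prevalence = 0.5,
      seed = 300 + r
    ))
    rec <- aggregate_dams(sim$pedigree)
    gc <- group_sexratio_contrast(
      rec, "wolbachia",
      config = mcmc_config(n_iterations = 2500, burn_in = 500, seed = r)
    )
    gc$effect$excludes_zero
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})

test_that("the clutch-size diagnostic separates male killing from no effect", {
  toy <- tibble::tibble(n_hatched = c(8L, 12L, 20L, 20L),
                        infected = c(TRUE, TRUE, FALSE, FALSE))
  d <- clutch_size_mechanism_diagnostic(toy, n_boot = 4000, seed = 9)
  expect_equal(d$ratio, 0.5)
  # enumeration of the resample space: infected mean in {8,10,12} with
  # probs {1/4,1/2,1/4}, uninfected mean always 20
  set.seed(9)
  boots <- vapply(1:4000, function(i) {
    mean(sample(c(8L, 12L), 2, replace = TRUE)) / 20
  }, numeric(1))
  expect_true(all(abs(sort(unique(boots)) - c(0.4, 0.5, 0.6)) < 1e-12))
  expect_lt(abs(mean(boots == 0.5) - 0.5), 0.05)
  expect_true(d$conf.low %in% c(0.4, 0.5) && d$conf.high %in% c(0.5, 0.6))

  expect_error(
    clutch_size_mechanism_diagnostic(toy[toy$infected, ]),
    class = "matriline_domain_error"
  )
})
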