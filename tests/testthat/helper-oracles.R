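# Independent oracles and fixture builders, deliberately coded without
# reusing the package's internals.

# toy three-generation pedigree used across files
make_toy_pedigree <- function() {
  pedigree(
    tibble::tibble(
      id = c("F1", "F2", "D1", "G1", "S1"),
      dam_id = c(NA, NA, "F1", "D1", "F1"),
      sex = c("F", "F", "F", "F", "M"),
      wolbachia = c("pos", "neg", "pos", "pos", NA)
    ),
    tibble::tibble(
      dam_id = c("F1", "F1", "D1", "G1"),
      clutch_index = c(1L, 2L, 1L, 1L),
      n_adult_male = c(2L, 1L, 0L, 5L),
      n_adult_female = c(3L, 4L, 0L, 5L),
      n_hatched = c(6L, 5L, 5L, 10L)
    )
  )
}

# random pedigree built by naive sequential attachment (not via the
# package simulator)
random_pedigree_tbl <- function(n_individuals, n_founders, seed) {
  set.seed(seed)
  id <- sprintf("X%03d", seq_len(n_individuals))
  dam_id <- rep(NA_character_, n_individuals)
  sex <- c(rep("F", n_founders),
           sample(c("F", "M"), n_individuals - n_founders, replace = TRUE,
                  prob = c(0.7, 0.3)))
  for (i in (n_founders + 1):n_individuals) {
    females <- which(sex[seq_len(i - 1)] == "F")
    dam_id[i] <- id[sample(females, 1)]
  }
  tibble::tibble(id = id, dam_id = dam_id, sex = sex)
}

# brute-force matriline: follow dam links one individual at a time
brute_force_matrilines <- function(ind) {
  vapply(ind$id, function(start) {
    cur <- start
    repeat {
      dam <- ind$dam_id[ind$id == cur]
      if (is.na(dam)) return(cur)
      cur <- dam
    }
  }, character(1))
}

# weighted Pearson correlation from the raw moment formula
weighted_pearson_formula <- function(x, y, w) {
  mx <- sum(w * x) / sum(w)
  my <- sum(w * y) / sum(w)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  sxy / sqrt(sxx * syy)
}

# two-sided Fisher p by exhaustive enumeration of the hypergeometric
# support (minimum-likelihood rule)
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact binomial p by enumeration over 0:n
binom_enum_p <- function(k, n, p0,
                         alternative = "two.sided") {
  probs <- dbinom(0:n, n, p0)
  if (alternative == "less") return(sum(probs[0:k + 1]))
  if (alternative == "greater") return(sum(probs[(k + 1):(n + 1)]))
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# small fixed dam-record tables for sampler-vs-quadrature checks;
# each has <= 2 matrilines so mu + m stays within 3 free parameters
tiny_record_sets <- function() {
  list(
    tibble::tibble(dam_id = "d1", matriline_id = "m1",
                   total_male = 8, total_female = 2),
    tibble::tibble(dam_id = c("d1", "d2"), matriline_id = c("m1", "m1"),
                   total_male = c(3, 4), total_female = c(7, 6)),
    tibble::tibble(dam_id = c("d1", "d2"), matriline_id = c("m1", "m2"),
                   total_male = c(2, 9), total_female = c(8, 3)),
    tibble::tibble(dam_id = paste0("d", 1:4),
                   matriline_id = c("m1", "m1", "m2", "m2"),
                   total_male = c(1, 2, 6, 7), total_female = c(9, 8, 4, 3)),
    tibble::tibble(dam_id = paste0("d", 1:4),
                   matriline_id = c("m1", "m1", "m2", "m2"),
                   total_male = c(5, 6, 5, 4), total_female = c(5, 4, 5, 6))
  )
}

# short MCMC settings shared by the small-fit tests
quick_config <- function(...) {
  mcmc_config(n_iterations = 4000, burn_in = 1000, ...)
}
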