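#' Posterior means by dense-grid quadrature (validation oracle)
#'
#' Independent check on the sampler for problems small enough to
#' integrate numerically: the dam-effect term is dropped
#' (`dam_effect = FALSE` model) and the matriline precision is fixed, so
#' the free parameters are `mu` plus one `m` per matriline — at most three
#' in total. The unnormalised posterior (binomial likelihood x normal
#' effect density x normal prior on `mu`) is evaluated on a regular tensor
#' grid and posterior means are the weight-normalised grid averages. For
#' these smooth, rapidly decaying integrands the regular-grid (trapezoid)
#' rule converges extremely fast, so modest grids already give means
#' stable far below Monte-Carlo resolution.
#'
#' @param records Dam records (as for [fit_maternal_model()]); at most
#'   three free parameters, i.e. at most two distinct matrilines when
#'   `include_mu = TRUE`.
#' @param spec A [maternal_model_spec()]; its `prior_var_fixed` sets the
#'   `mu` prior and hence the default `mu` grid span.
#' @param tau_m Fixed matriline precision (`1/sigma2_m`).
#' @param include_mu Integrate over `mu` (TRUE) or fix it at `mu_fixed`?
#' @param mu_fixed Value of `mu` when `include_mu = FALSE`.
#' @param m_fixed Optional named vector pinning matriline effects at fixed
#'   values (they are then excluded from the integration); useful for
#'   one-dimensional checks where only `mu` is free.
#' @param n_points Grid points per dimension.
#' @param width Half-width of each grid in prior standard deviations
#'   (default 6, so the grid spans +/- 6 prior sd around 0).
#' @return Tibble with columns `parameter` (`"mu"`, `"m[<id>]"`) and
#'   `mean`.
#' @export
posterior_oracle_small <- function(records,
                                   spec = maternal_model_spec(dam_effect = FALSE),
                                   tau_m = 1,
                                   include_mu = TRUE,
                                   mu_fixed = 0,
                                   m_fixed = NULL,
                                   n_points = 161,
                                   width = 6) {
  prep <- prepare_records(records, spec)
  if (ncol(prep$X)) {
    abort("the quadrature oracle does not support fixed-effect covariates",
          class = "matriline_capability_error")
  }
  K <- length(prep$mat_ids)
  free_m <- is.null(m_fixed)
  n_free <- as.integer(include_mu) + if (free_m) K else 0L
  if (n_free > 3) {
    abort(paste0("too many free location parameters for quadrature (",
                 n_free, " > 3)"),
          class = "matriline_capability_error")
  }
  if (n_free == 0) {
    abort("nothing to integrate: all parameters fixed",
          class = "matriline_capability_error")
  }

  sd_m <- 1 / sqrt(tau_m)
  sd_mu <- sqrt(spec$prior_var_fixed)
  grids <- c(
    if (include_mu) list(mu = seq(-width * sd_mu, width * sd_mu,
                                  length.out = n_points)),
    if (free_m) setNames(
      lapply(seq_len(K), function(k) {
        seq(-width * sd_m, width * sd_m, length.out = n_points)
      }),
      paste0("m[", prep$mat_ids, "]")
    )
  )

  theta <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  mu_col <- if (include_mu) theta[, 1] else rep(mu_fixed, nrow(theta))
  m_cols <- if (free_m) {
    theta[, (1 + include_mu):ncol(theta), drop = FALSE]
  } else {
    mf <- rep_len(m_fixed, K)
    if (!is.null(names(m_fixed))) mf <- m_fixed[prep$mat_ids]
    matrix(mf, nrow(theta), K, byrow = TRUE)
  }

  lp <- dnorm(mu_col, 0, sd_mu, log = TRUE) * as.integer(include_mu)
  if (free_m) {
    for (k in seq_len(K)) {
      lp <- lp + dnorm(m_cols[, k], 0, sd_m, log = TRUE)
    }
  }
  for (r in seq_along(prep$y)) {
    eta <- mu_col + m_cols[, prep$mi[r]]
    lp <- lp + binom_loglik_kernel(eta, prep$y[r], prep$n[r])
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  tibble::tibble(
    parameter = colnames(theta),
    mean = unname(drop(crossprod(theta, w)))
  )
}
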