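#' Summarise posterior draws
#'
#' Pools post-burn-in draws across chains and reports, per parameter, the
#' posterior mean, standard deviation and the equal-tailed 95% credibility
#' interval (2.5% and 97.5% quantiles, R's default type-7 rule), plus the
#' Gelman–Rubin potential scale reduction factor when at least two chains
#' are available. Variance components are summarised from the draw-wise
#' transformed `sigma2 = 1/tau` samples stored alongside the precisions —
#' never as `1/mean(tau)`, which Jensen's inequality would bias downward.
#'
#' @param fit A `maternal_fit`, or a list of per-chain draw matrices.
#' @param burn_in Iterations (in stored-draw units) to discard from the
#'   start of each chain; defaults to the fit's configured burn-in.
#' @param prob Total mass of the equal-tailed interval.
#' @return A tibble with columns `parameter`, `mean`, `sd`, `ci_lower`,
#'   `ci_upper`, `psrf`.
#' @export
posterior_summary <- function(fit, burn_in = NULL, prob = 0.95) {
  draws <- if (inherits(fit, "maternal_fit")) fit$draws else fit
  stopifnot(is.list(draws), length(draws) >= 1)
  if (is.null(burn_in)) {
    burn_in <- if (inherits(fit, "maternal_fit")) {
      fit$config$burn_in %/% fit$config$thin
    } else 0L
  }
  len <- nrow(draws[[1]])
  if (burn_in >= len) {
    abort("burn_in leaves no post-burn-in draws",
          class = "matriline_config_error")
  }
  post <- lapply(draws, function(d) d[(burn_in + 1):len, , drop = FALSE])
  pooled <- do.call(rbind, post)
  alpha <- (1 - prob) / 2
  qs <- apply(pooled, 2, quantile, probs = c(alpha, 1 - alpha),
              names = FALSE, type = 7)
  r <- if (length(post) >= 2) psrf(post, burn_in = 0) else
    rep(NA_real_, ncol(pooled))
  tibble::tibble(
    parameter = colnames(pooled),
    mean = unname(colMeans(pooled)),
    sd = unname(apply(pooled, 2, sd)),
    ci_lower = unname(qs[1, ]),
    ci_upper = unname(qs[2, ]),
    psrf = unname(r)
  )
}

#' Gelman–Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF: with `M` chains of length `N`, within-chain
#' variance `W` = mean of the chain variances, between-chain variance
#' `B` = `N` times the variance of the chain means, pooled posterior
#' variance estimate `V = (N-1)/N W + B/N`, and `PSRF = sqrt(V / W)`.
#' Values near 1 indicate the chains are sampling the same distribution.
#'
#' @param draws A `maternal_fit` or list of per-chain draw matrices (equal
#'   dimensions).
#' @param burn_in Draws to discard from the start of each chain.
#' @return Named numeric vector of PSRF values, one per parameter.
#' @export
psrf <- function(draws, burn_in = NULL) {
  if (inherits(draws, "maternal_fit")) {
    if (is.null(burn_in)) burn_in <- draws$config$burn_in %/% draws$config$thin
    draws <- draws$draws
  }
  burn_in <- burn_in %||% 0L
  if (length(draws) < 2) {
    abort("PSRF needs at least two chains", class = "matriline_capability_error")
  }
  len <- unique(vapply(draws, nrow, integer(1)))
  if (length(len) != 1) {
    abort("chains must have equal length", class = "matriline_capability_error")
  }
  post <- lapply(draws, function(d) d[(burn_in + 1):len, , drop = FALSE])
  N <- nrow(post[[1]])
  means <- vapply(post, colMeans, numeric(ncol(post[[1]])))
  vars <- vapply(post, function(d) apply(d, 2, var), numeric(ncol(post[[1]])))
  if (is.null(dim(means))) {  # single-parameter edge
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- N * apply(means, 1, var)
  V <- (N - 1) / N * W + B / N
  out <- sqrt(V / W)
  out[W == 0 & B == 0] <- 1   # degenerate constant chains
  setNames(out, colnames(post[[1]]))
}

# Monte-Carlo standard error of a chain mean by non-overlapping batch
# means; robust to autocorrelation for reasonably long chains.
mcse_mean <- function(x, n_batches = 25) {
  n <- length(x)
  n_batches <- min(n_batches, max(2, n %/% 10))
  bsize <- n %/% n_batches
  bm <- vapply(seq_len(n_batches), function(i) {
    mean(x[((i - 1) * bsize + 1):(i * bsize)])
  }, numeric(1))
  sd(bm) / sqrt(n_batches)
}

# pooled post-burn-in draws of one parameter across chains
pooled_draws <- function(fit, parameter, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- fit$config$burn_in %/% fit$config$thin
  len <- nrow(fit$draws[[1]])
  unlist(lapply(fit$draws, function(d) d[(burn_in + 1):len, parameter]))
}

#' @describeIn fit_maternal_model Tidy posterior summary (one row per
#'   parameter) in broom convention: `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `psrf`.
#' @param x A `maternal_fit`.
#' @param ... Passed to [posterior_summary()].
#' @export
tidy.maternal_fit <- function(x, ...) {
  posterior_summary(x, ...) |>
    dplyr::rename(term = "parameter", estimate = "mean",
                  std.error = "sd", conf.low = "ci_lower",
                  conf.high = "ci_upper")
}

#' @describeIn fit_maternal_model One-row model overview: chain and
#'   iteration counts, data size, worst PSRF and mean block acceptance.
#' @export
glance.maternal_fit <- function(x, ...) {
  s <- posterior_summary(x)
  tibble::tibble(
    n_chains = length(x$draws),
    n_iterations = x$config$n_iterations,
    burn_in = x$config$burn_in,
    n_records = length(x$data$y),
    n_matrilines = length(x$data$mat_ids),
    max_psrf = max(s$psrf, na.rm = TRUE),
    sigma2_m = s$mean[s$parameter == "sigma2_m"],
    sigma2_e = s$mean[s$parameter == "sigma2_e"]
  )
}

#' Draws in long format
#'
#' @param fit A `maternal_fit`.
#' @param parameters Optional subset of parameter names.
#' @param include_burn_in Keep the burn-in draws?
#' @return Tibble with columns `chain`, `iteration`, `parameter`, `value`.
#' @export
tidy_draws <- function(fit, parameters = NULL, include_burn_in = TRUE) {
  stopifnot(inherits(fit, "maternal_fit"))
  start <- if (include_burn_in) 1L else
    fit$config$burn_in %/% fit$config$thin + 1L
  purrr::imap_dfr(fit$draws, function(d, ch) {
    d <- d[start:nrow(d), , drop = FALSE]
    if (!is.null(parameters)) d <- d[, parameters, drop = FALSE]
    tibble::as_tibble(d) |>
      dplyr::mutate(chain = ch,
                    iteration = start - 1L + dplyr::row_number()) |>
      tidyr::pivot_longer(cols = -c("chain", "iteration"),
                          names_to = "parameter", values_to = "value")
  })
}

#' @describeIn fit_maternal_model Trace or density plot of selected
#'   parameters (one panel per parameter, colour per chain).
#' @param object A `maternal_fit`.
#' @param parameters Parameters to plot (default: the variance components
#'   and `mu`).
#' @param type `"trace"` or `"density"`.
#' @export
autoplot.maternal_fit <- function(object,
                                  parameters = c("mu", "sigma2_m", "sigma2_e"),
                                  type = c("trace", "density"), ...) {
  type <- match.arg(type)
  long <- tidy_draws(object, parameters = parameters,
                     include_burn_in = (type == "trace")) |>
    dplyr::mutate(chain = factor(.data$chain))
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                       colour = .data$chain)) +
      ggplot2::geom_line(linewidth = 0.2, alpha = 0.8) +
      ggplot2::geom_vline(xintercept = object$config$burn_in %/%
                            object$config$thin,
                          linetype = "dashed") +
      ggplot2::facet_wrap(~parameter, scales = "free_y") +
      ggplot2::labs(x = "iteration", y = NULL)
  } else {
    ggplot2::ggplot(long, ggplot2::aes(x = .data$value, colour = .data$chain)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~parameter, scales = "free") +
      ggplot2::labs(x = NULL, y = "posterior density")
  }
}
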