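# --- model internals shared by the sampler, the log posterior and the
# --- quadrature oracle

# Build the fixed-effect design matrix (no intercept; mu is separate).
# Two-level character/factor columns become a 0/1 indicator of the second
# sorted level, named "<col><level>"; numeric columns pass through.
build_design <- function(records, covariates) {
  if (!length(covariates)) {
    return(matrix(numeric(0), nrow = nrow(records), ncol = 0))
  }
  cols <- lapply(covariates, function(cv) {
    if (!cv %in% names(records)) {
      abort(paste0("covariate column not found: ", cv),
            class = "matriline_design_error")
    }
    x <- records[[cv]]
    if (is.numeric(x)) {
      out <- matrix(as.numeric(x), ncol = 1,
                    dimnames = list(NULL, cv))
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2) {
        abort(paste0("covariate `", cv, "` is constant across records"),
              class = "matriline_design_error")
      }
      if (length(lev) > 2) {
        abort(paste0("covariate `", cv, "` has more than two levels; ",
                     "recode to indicators first"),
              class = "matriline_design_error")
      }
      out <- matrix(as.numeric(x == lev[2]), ncol = 1,
                    dimnames = list(NULL, paste0(cv, lev[2])))
    }
    out
  })
  do.call(cbind, cols)
}

# records prepared for fitting: validated, excluded rows dropped, indices
prepare_records <- function(records, spec) {
  stopifnot(is.data.frame(records))
  needed <- c("dam_id", "matriline_id", "total_male", "total_female")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    abort(paste0("dam records lack column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "matriline_schema_error")
  }
  if ("excluded" %in% names(records)) {
    n_drop <- sum(records$excluded)
    if (n_drop) inform(paste0("dropping ", n_drop,
                              " dam record(s) with no sexed adults"))
    records <- records[!records$excluded, , drop = FALSE]
  }
  records <- records[records$total_male + records$total_female > 0, ,
                     drop = FALSE]
  if (!nrow(records)) {
    abort("no dam records with sexed adult offspring",
          class = "matriline_domain_error")
  }
  if (anyDuplicated(records$dam_id)) {
    abort("dam records must be one row per dam (pool clutches first)",
          class = "matriline_domain_error")
  }
  mat_ids <- sort(unique(records$matriline_id))   # id-sorted for reproducibility
  dam_ids <- records$dam_id
  ord <- order(dam_ids)
  records <- records[ord, , drop = FALSE]
  list(
    y = as.numeric(records$total_male),
    n = as.numeric(records$total_male + records$total_female),
    mi = match(records$matriline_id, mat_ids),
    mat_ids = mat_ids,
    dam_ids = records$dam_id,
    X = build_design(records, spec$covariates),
    records = records
  )
}

#' Dam-level expected sex ratio under a parameter state
#'
#' Evaluates the inverse-logit model mean
#' `plogis(mu + x' beta + m[matriline] + e[dam])` for each dam record.
#'
#' @param state A named list with elements `mu`, `beta` (named numeric,
#'   may be empty), `m` (named by matriline id), `e` (named by dam id; may
#'   be omitted for a model without dam effects), `tau_m`, `tau_e`.
#' @param records A dam-record data frame (see [aggregate_dams()]).
#' @param spec A [maternal_model_spec()].
#' @return The records tibble with a `pi` column of expected sex ratios,
#'   each strictly inside (0, 1).
#' @export
logit_sexratio <- function(state, records, spec = maternal_model_spec()) {
  eta <- linear_predictor(state, records, spec)
  dplyr::mutate(tibble::as_tibble(records), pi = plogis(eta))
}

linear_predictor <- function(state, records, spec) {
  stopifnot(is.data.frame(records))
  m_miss <- setdiff(unique(records$matriline_id), names(state$m))
  if (length(m_miss)) {
    abort(paste0("state has no matriline effect for: ",
                 paste(m_miss, collapse = ", ")),
          class = "matriline_state_error")
  }
  eta <- state$mu + unname(state$m[records$matriline_id])
  if (isTRUE(spec$dam_effect)) {
    e_miss <- setdiff(unique(records$dam_id), names(state$e))
    if (length(e_miss)) {
      abort(paste0("state has no dam effect for: ",
                   paste(e_miss, collapse = ", ")),
            class = "matriline_state_error")
    }
    eta <- eta + unname(state$e[records$dam_id])
  }
  X <- build_design(records, spec$covariates)
  if (ncol(X)) eta <- eta + drop(X %*% state$beta)
  eta
}

#' Joint log posterior of the maternal model
#'
#' Sum of the dam-level binomial log likelihood (`total_male` successes in
#' `total_male + total_female` trials at the model mean), the
#' `N(0, 1/tau_m)` log density of every matriline effect, the
#' `N(0, 1/tau_e)` log density of every dam effect, normal priors on `mu`
#' and `beta`, and the gamma priors on the precisions (or standard
#' deviations, per the spec). The dam-level binomial formulation differs
#' from a per-offspring Bernoulli likelihood only by the data-dependent
#' `log choose(n, y)` constant, which is included here via `dbinom()`.
#'
#' @inheritParams logit_sexratio
#' @return A finite scalar log posterior (up to normalising constants of
#'   the model evidence).
#' @export
log_posterior <- function(state, records, spec = maternal_model_spec()) {
  eta <- linear_predictor(state, records, spec)
  y <- records$total_male
  n <- records$total_male + records$total_female
  # stable kernel + exact choose term (avoids dbinom at pi ~ 0/1)
  ll <- sum(lchoose(n, y) + binom_loglik_kernel(eta, y, n))

  lp <- ll +
    dnorm(state$mu, 0, sqrt(spec$prior_var_fixed), log = TRUE) +
    sum(dnorm(state$m, 0, 1 / sqrt(state$tau_m), log = TRUE))
  if (length(state$beta)) {
    lp <- lp + sum(dnorm(state$beta, 0, sqrt(spec$prior_var_fixed), log = TRUE))
  }
  if (isTRUE(spec$dam_effect)) {
    lp <- lp + sum(dnorm(state$e, 0, 1 / sqrt(state$tau_e), log = TRUE))
  }
  lp <- lp + precision_log_prior(state$tau_m, spec)
  if (isTRUE(spec$dam_effect)) {
    lp <- lp + precision_log_prior(state$tau_e, spec)
  }
  lp
}

# gamma prior evaluated on the precision or, via change of variable, on
# the standard deviation sigma = tau^(-1/2)
precision_log_prior <- function(tau, spec) {
  if (spec$prior_on == "precision") {
    dgamma(tau, shape = spec$prior_shape, rate = spec$prior_rate, log = TRUE)
  } else {
    sigma <- 1 / sqrt(tau)
    # |d sigma / d tau| = sigma / (2 tau)
    dgamma(sigma, shape = spec$prior_shape, rate = spec$prior_rate, log = TRUE) +
      log(sigma / (2 * tau))
  }
}
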