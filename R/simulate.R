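#' Endosymbiont sex-ratio mechanisms
#'
#' Constructors for the mechanism argument of [sim_params()] /
#' [apply_mechanism()].
#'
#' * `mechanism_none()` leaves broods untouched.
#' * `male_killing(strength)` kills each male embryo of an infected dam
#'   with probability `strength`; killed embryos never hatch, so broods
#'   shrink and the hatched count drops.
#' * `feminization(rate)` converts each genetic male of an infected dam
#'   into a phenotypic female with probability `rate`; brood size is
#'   unchanged.
#'
#' @param strength,rate Per-male probability of the manipulation, in
#'   \[0, 1\].
#' @return A list of class `sr_mechanism`.
#' @export
mechanism_none <- function() {
  structure(list(type = "none"), class = "sr_mechanism")
}

#' @rdname mechanism_none
#' @export
male_killing <- function(strength = 1) {
  stopifnot(is.numeric(strength), strength >= 0, strength <= 1)
  structure(list(type = "male_killing", strength = strength),
            class = "sr_mechanism")
}

#' @rdname mechanism_none
#' @export
feminization <- function(rate = 1) {
  stopifnot(is.numeric(rate), rate >= 0, rate <= 1)
  structure(list(type = "feminization", rate = rate), class = "sr_mechanism")
}

#' Simulation parameters for the pedigree generator
#'
#' Defaults reproduce the structure of the breeding study the model was
#' designed for: 200 founding females each opening a matriline, one
#' breeding daughter recruited per dam for one further generation
#' (about 400 breeding dams in total), Poisson clutch sizes with mean 17
#' (the observed control-group mean hatched count was 16.8), a population
#' mean sex ratio of 0.34 on the probability scale, and matriline and
#' dam-level logit-scale variances of 0.64 and 0.27.
#'
#' @param n_founders Number of founding females (each founds a matriline).
#' @param n_generations Number of breeding generations including the
#'   founders; `2` means founders breed and one daughter generation breeds.
#' @param daughters_bred_per_dam Breeding daughters recruited per dam for
#'   the next generation (capped by daughters available in her brood).
#' @param mu Mean logit sex ratio (male = 1).
#' @param sigma2_m Matriline variance of the maternally inherited logit
#'   effect (logit^2 units).
#' @param sigma2_e Dam-level residual variance (logit^2 units).
#' @param clutch_mean Mean of the Poisson clutch-size distribution.
#' @param founder_infection_prevalence Probability that a founder is
#'   infected with the endosymbiont.
#' @param transmission_efficiency Probability that an infected dam's
#'   offspring inherits the infection.
#' @param mechanism An `sr_mechanism` (see [mechanism_none()]).
#' @param couple_infection If TRUE, only infected matrilines receive a
#'   nonzero maternal effect (endosymbiont-caused distortion); default
#'   FALSE so the generator matches the fitted model exactly.
#' @param seed Master seed; generation-level sub-seeds are derived from it
#'   deterministically.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(n_founders = 200,
                       n_generations = 2,
                       daughters_bred_per_dam = 1,
                       mu = qlogis(0.34),
                       sigma2_m = 0.64,
                       sigma2_e = 0.27,
                       clutch_mean = 17,
                       founder_infection_prevalence = 0.45,
                       transmission_efficiency = 1,
                       mechanism = mechanism_none(),
                       couple_infection = FALSE,
                       seed = 1L) {
  p <- list(
    n_founders = as.integer(n_founders),
    n_generations = as.integer(n_generations),
    daughters_bred_per_dam = as.integer(daughters_bred_per_dam),
    mu = mu, sigma2_m = sigma2_m, sigma2_e = sigma2_e,
    clutch_mean = clutch_mean,
    founder_infection_prevalence = founder_infection_prevalence,
    transmission_efficiency = transmission_efficiency,
    mechanism = mechanism,
    couple_infection = isTRUE(couple_infection),
    seed = as.integer(seed)
  )
  if (p$n_founders < 1 || p$n_generations < 1) {
    abort("n_founders and n_generations must be >= 1 (an empty pedigree is not simulable)",
          class = "matriline_config_error")
  }
  stopifnot(
    p$daughters_bred_per_dam >= 0,
    p$sigma2_m >= 0, p$sigma2_e >= 0, p$clutch_mean > 0,
    p$founder_infection_prevalence >= 0, p$founder_infection_prevalence <= 1,
    p$transmission_efficiency >= 0, p$transmission_efficiency <= 1,
    inherits(p$mechanism, "sr_mechanism")
  )
  structure(p, class = "sim_params")
}

# deterministic per-generation sub-seed below 2^31
derive_seed <- function(seed, g) {
  as.integer((as.double(seed) + 77003 * g) %% 2147483646) + 1L
}

#' Apply an endosymbiont mechanism to a brood
#'
#' Operates on the sex vector of a single clutch as drawn before any
#' manipulation (the primary brood). Uninfected dams and
#' [mechanism_none()] pass the brood through unchanged. Male killing
#' removes males (they die as embryos and are dropped from the vector);
#' feminization relabels males `"F"`.
#'
#' @param sexes Character vector of offspring sexes, `"M"`/`"F"`.
#' @param infected Is the dam infected?
#' @param mechanism An `sr_mechanism`.
#' @return Character vector of surviving offspring sexes (shorter than the
#'   input only under male killing).
#' @export
apply_mechanism <- function(sexes, infected, mechanism) {
  stopifnot(inherits(mechanism, "sr_mechanism"))
  if (!isTRUE(infected) || mechanism$type == "none" || !length(sexes)) {
    return(sexes)
  }
  male <- sexes == "M"
  if (mechanism$type == "male_killing") {
    killed <- male & runif(length(sexes)) < mechanism$strength
    sexes[!killed]
  } else if (mechanism$type == "feminization") {
    flipped <- male & runif(length(sexes)) < mechanism$rate
    sexes[flipped] <- "F"
    sexes
  } else {
    abort(paste0("unknown mechanism type: ", mechanism$type),
          class = "matriline_config_error")
  }
}

#' Maternal transmission of an endosymbiont
#'
#' Offspring of an infected dam are infected independently with
#' probability `efficiency`; offspring of uninfected dams are never
#' infected (no paternal or horizontal transmission).
#'
#' @param dam_infected Is the dam infected?
#' @param n_offspring Number of offspring.
#' @param efficiency Per-offspring transmission probability in \[0, 1\].
#' @return Logical vector of offspring infection states.
#' @export
simulate_transmission <- function(dam_infected, n_offspring, efficiency) {
  stopifnot(efficiency >= 0, efficiency <= 1, n_offspring >= 0)
  if (!isTRUE(dam_infected)) return(rep(FALSE, n_offspring))
  runif(n_offspring) < efficiency
}

#' Simulate a pedigree under the maternal sex-ratio model
#'
#' Forward-time generator that realises the maternal model read
#' generatively: each founding female receives a matriline effect
#' `m ~ N(0, sigma2_m)` that is copied unchanged down her maternal line;
#' each breeding dam receives a residual effect `e ~ N(0, sigma2_e)`; each
#' of her offspring is male independently with probability
#' `plogis(mu + m + e)` before any endosymbiont manipulation. Infection is
#' transmitted maternally with the configured efficiency, and the chosen
#' mechanism (male killing or feminization) then distorts infected dams'
#' broods. One clutch is produced per breeding dam; all hatched offspring
#' are assumed to reach adulthood and be sexed, so adult counts equal the
#' post-mechanism brood.
#'
#' @param params A [sim_params()] object.
#' @return A list with elements `pedigree` (a [pedigree()]) and `truth`, a
#'   list recording the generating parameters and every latent value:
#'   `$m` (tibble matriline_id, m), `$e` (tibble dam_id, generation, e) and
#'   `$mu`.
#' @export
simulate_pedigree <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 0L))

  nf <- params$n_founders
  founder_ids <- sprintf("F%05d", seq_len(nf))
  infected <- runif(nf) < params$founder_infection_prevalence
  m <- rnorm(nf, 0, sqrt(params$sigma2_m))
  if (params$couple_infection) m[!infected] <- 0

  individuals <- tibble::tibble(
    id = founder_ids, dam_id = NA_character_, sex = "F",
    population = "P1",
    wolbachia = ifelse(infected, "pos", "neg"),
    rickettsia = NA_character_, cardinium = NA_character_,
    treatment = NA_character_, generation = 0L
  )

  # the current breeding cohort, with its latent state
  breeders <- tibble::tibble(
    dam_id = founder_ids, matriline_id = founder_ids,
    m = m, infected = infected
  )

  clutch_rows <- list()
  e_rows <- list()
  offspring_counter <- 0L

  for (g in seq_len(params$n_generations)) {
    if (!nrow(breeders)) break
    set.seed(derive_seed(params$seed, g))
    nd <- nrow(breeders)
    e <- rnorm(nd, 0, sqrt(params$sigma2_e))
    sizes <- rpois(nd, params$clutch_mean)
    p_male <- plogis(params$mu + breeders$m + e)
    e_rows[[g]] <- tibble::tibble(dam_id = breeders$dam_id, generation = g, e = e)

    kids <- vector("list", nd)
    for (d in seq_len(nd)) {
      n_off <- sizes[d]
      if (n_off == 0L) next
      sexes <- ifelse(runif(n_off) < p_male[d], "M", "F")
      survivors <- apply_mechanism(sexes, breeders$infected[d], params$mechanism)
      n_surv <- length(survivors)
      inf_off <- simulate_transmission(breeders$infected[d], n_surv,
                                       params$transmission_efficiency)
      ids <- sprintf("I%07d", offspring_counter + seq_len(n_surv))
      offspring_counter <- offspring_counter + n_surv
      kids[[d]] <- tibble::tibble(
        id = ids, dam_id = breeders$dam_id[d], sex = survivors,
        population = "P1",
        wolbachia = ifelse(inf_off, "pos", "neg"),
        rickettsia = NA_character_, cardinium = NA_character_,
        treatment = NA_character_, generation = g,
        matriline_id = breeders$matriline_id[d],
        m = breeders$m[d]
      )
      clutch_rows[[length(clutch_rows) + 1L]] <- tibble::tibble(
        dam_id = breeders$dam_id[d], clutch_index = 1L,
        n_adult_male = sum(survivors == "M"),
        n_adult_female = sum(survivors == "F"),
        n_hatched = n_surv
      )
    }
    kids <- dplyr::bind_rows(kids)
    if (nrow(kids)) {
      individuals <- dplyr::bind_rows(
        individuals,
        dplyr::select(kids, -"matriline_id", -"m")
      )
    }

    if (g < params$n_generations && nrow(kids) &&
        params$daughters_bred_per_dam > 0) {
      breeders <- kids |>
        dplyr::filter(.data$sex == "F") |>
        dplyr::group_by(.data$dam_id) |>
        dplyr::slice_head(n = params$daughters_bred_per_dam) |>
        dplyr::ungroup() |>
        dplyr::transmute(
          dam_id = .data$id, matriline_id = .data$matriline_id,
          m = .data$m, infected = .data$wolbachia == "pos"
        )
    } else if (g < params$n_generations) {
      breeders <- breeders[0, ]
    }
  }

  ped <- pedigree(individuals, dplyr::bind_rows(clutch_rows))
  truth <- list(
    params = unclass(params)[setdiff(names(params), "mechanism")],
    mechanism = unclass(params$mechanism),
    mu = params$mu,
    m = tibble::tibble(matriline_id = founder_ids, m = m,
                       infected = infected),
    e = dplyr::bind_rows(e_rows)
  )
  list(pedigree = ped, truth = truth)
}

#' Expected population tertiary sex ratio under male killing
#'
#' Closed-form accounting for a population with infected-female fraction
#' `prevalence`, primary (pre-manipulation) male probability `primary`,
#' and per-male killing probability `strength`: surviving males per
#' offspring conceived are `primary * (1 - prevalence * strength)` and
#' survivors total `1 - prevalence * primary * strength`, so the expected
#' proportion of males among surviving adults is their ratio.
#'
#' @param prevalence Fraction of dams infected.
#' @param strength Per-male killing probability.
#' @param primary Primary sex ratio (probability male at conception).
#' @return Expected tertiary sex ratio.
#' @export
expected_sexratio_male_killing <- function(prevalence, strength = 1,
                                           primary = 0.5) {
  stopifnot(prevalence >= 0, prevalence <= 1, strength >= 0, strength <= 1,
            primary >= 0, primary <= 1)
  primary * (1 - prevalence * strength) /
    (1 - prevalence * primary * strength)
}
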