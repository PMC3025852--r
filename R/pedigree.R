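#' Construct and validate a pedigree
#'
#' A pedigree bundles an individual table (maternal links plus sex,
#' population, endosymbiont-infection and treatment labels) with a clutch
#' table (per-cocoon counts of adult males, adult females and hatched
#' offspring). All downstream analyses — matriline resolution, dam-level
#' aggregation and the maternal model — consume this object.
#'
#' Validation enforces: unique non-empty ids; every `dam_id` refers to an
#' existing female; the maternal-link graph is acyclic; clutch counts are
#' non-negative with adults never exceeding hatched; every clutch's dam
#' exists.
#'
#' @param individuals Data frame with columns `id`, `dam_id` (NA for a
#'   founder), `sex` (`"M"`, `"F"` or `"U"`), and optionally `population`,
#'   `wolbachia`, `rickettsia`, `cardinium` (`"pos"`, `"neg"` or NA),
#'   `treatment` and `sire_id` (pass-through only). Missing optional
#'   columns are filled with NA (population defaults to `"P1"`).
#' @param clutches Data frame with columns `dam_id`, `clutch_index`,
#'   `n_adult_male`, `n_adult_female`, `n_hatched`, or NULL for a pedigree
#'   without clutch records.
#' @return An object of class `pedigree`: a list with tibbles
#'   `$individuals` and `$clutches`.
#' @examples
#' ped <- pedigree(
#'   tibble::tibble(
#'     id = c("F1", "D1", "S1"),
#'     dam_id = c(NA, "F1", "F1"),
#'     sex = c("F", "F", "M")
#'   ),
#'   tibble::tibble(
#'     dam_id = "F1", clutch_index = 1L,
#'     n_adult_male = 1L, n_adult_female = 1L, n_hatched = 3L
#'   )
#' )
#' resolve_matrilines(ped)
#' @export
pedigree <- function(individuals, clutches = NULL) {
  individuals <- tibble::as_tibble(individuals)
  if (!"id" %in% names(individuals)) {
    abort("individual table must have an `id` column", class = "matriline_schema_error")
  }
  defaults <- list(
    dam_id = NA_character_, sex = "U", population = "P1",
    wolbachia = NA_character_, rickettsia = NA_character_,
    cardinium = NA_character_, treatment = NA_character_
  )
  for (col in names(defaults)) {
    if (!col %in% names(individuals)) individuals[[col]] <- defaults[[col]]
  }
  individuals <- dplyr::mutate(
    individuals,
    dplyr::across(c("id", "dam_id", "sex", "population", "wolbachia",
                    "rickettsia", "cardinium", "treatment"), as.character)
  )

  if (anyNA(individuals$id) || any(!nzchar(individuals$id))) {
    abort("individual ids must be non-empty", class = "matriline_validation_error")
  }
  if (anyDuplicated(individuals$id)) {
    dup <- unique(individuals$id[duplicated(individuals$id)])
    abort(paste0("duplicated individual id(s): ", paste(dup, collapse = ", ")),
          class = "matriline_validation_error")
  }
  bad_sex <- setdiff(unique(individuals$sex), c("M", "F", "U"))
  if (length(bad_sex)) {
    abort(paste0("sex must be one of M, F, U; found: ", paste(bad_sex, collapse = ", ")),
          class = "matriline_validation_error")
  }

  has_dam <- !is.na(individuals$dam_id) & nzchar(individuals$dam_id)
  dam_row <- match(individuals$dam_id, individuals$id)
  missing_ref <- has_dam & is.na(dam_row)
  if (any(missing_ref)) {
    rows <- which(missing_ref)
    abort(
      paste0("dam_id refers to unknown individual(s) at row(s) ",
             paste(rows, collapse = ", "), ": ",
             paste(unique(individuals$dam_id[rows]), collapse = ", ")),
      class = "matriline_reference_error"
    )
  }
  male_dam <- has_dam & individuals$sex[dam_row] != "F"
  if (any(male_dam, na.rm = TRUE)) {
    rows <- which(male_dam)
    abort(
      paste0("dam_id refers to a non-female individual at row(s) ",
             paste(rows, collapse = ", "), ": ",
             paste(unique(individuals$dam_id[rows]), collapse = ", ")),
      class = "matriline_validation_error"
    )
  }
  # cycle check happens inside the matriline walk
  check_acyclic(individuals$id, individuals$dam_id)

  if (is.null(clutches)) {
    clutches <- tibble::tibble(
      dam_id = character(), clutch_index = integer(),
      n_adult_male = integer(), n_adult_female = integer(),
      n_hatched = integer()
    )
  }
  clutches <- tibble::as_tibble(clutches)
  needed <- c("dam_id", "n_adult_male", "n_adult_female", "n_hatched")
  missing_cols <- setdiff(needed, names(clutches))
  if (length(missing_cols)) {
    abort(paste0("clutch table lacks column(s): ", paste(missing_cols, collapse = ", ")),
          class = "matriline_schema_error")
  }
  if (!"clutch_index" %in% names(clutches)) {
    clutches$clutch_index <- seq_len(nrow(clutches))
  }
  clutches <- dplyr::mutate(
    clutches,
    dam_id = as.character(.data$dam_id),
    dplyr::across(c("clutch_index", "n_adult_male", "n_adult_female", "n_hatched"),
                  ~ as.integer(.x))
  )
  counts <- clutches[c("n_adult_male", "n_adult_female", "n_hatched")]
  if (anyNA(counts) || any(as.matrix(counts) < 0)) {
    abort("clutch counts must be non-negative integers",
          class = "matriline_validation_error")
  }
  over <- clutches$n_adult_male + clutches$n_adult_female > clutches$n_hatched
  if (any(over)) {
    abort(paste0("adult counts exceed hatched count at clutch row(s) ",
                 paste(which(over), collapse = ", ")),
          class = "matriline_validation_error")
  }
  unknown_dam <- !clutches$dam_id %in% individuals$id
  if (any(unknown_dam)) {
    abort(paste0("clutch dam_id not in individual table at row(s) ",
                 paste(which(unknown_dam), collapse = ", "), ": ",
                 paste(unique(clutches$dam_id[unknown_dam]), collapse = ", ")),
          class = "matriline_reference_error")
  }

  structure(list(individuals = individuals, clutches = clutches),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(is.na(x$individuals$dam_id) | !nzchar(x$individuals$dam_id))
  cat("<pedigree> ", nrow(x$individuals), " individuals (", founders,
      " founders), ", nrow(x$clutches), " clutches\n", sep = "")
  invisible(x)
}

# Follows dam links with pointer jumping; errors (naming the cycle) if the
# graph is not a forest.
check_acyclic <- function(ids, dam_ids) {
  parent <- match(dam_ids, ids)
  cur <- parent
  for (step in seq_len(length(ids) + 1L)) {
    if (all(is.na(cur))) return(invisible(TRUE))
    nxt <- parent[cur]
    nxt[is.na(cur)] <- NA_integer_
    if (identical(nxt, cur)) break
    # self-loop guard: a node that maps to itself is a cycle
    cur <- nxt
    if (step > length(ids)) break
  }
  stuck <- which(!is.na(cur))
  start <- stuck[1]
  # walk from the stuck node collecting the cycle members
  seen <- integer(0)
  node <- start
  while (!node %in% seen) {
    seen <- c(seen, node)
    node <- parent[node]
  }
  cycle <- seen[which(seen == node)[1]:length(seen)]
  abort(paste0("cyclic dam links involving: ", paste(ids[cycle], collapse = " -> ")),
        class = "matriline_structural_error")
}

#' Resolve every individual to its founding matriline
#'
#' Follows mother links until an individual without a recorded dam (a
#' founding female, or a founder of unknown ancestry) is reached. Because a
#' maternally transmitted effect is copied unchanged from mother to
#' daughter, all members of a matriline share the effect of its founder;
#' this mapping is what lets the model pool information down a maternal
#' lineage. Males inherit the matriline label of their dam for bookkeeping.
#'
#' @param ped A [pedigree()].
#' @return A tibble with columns `id` and `matriline_id`, one row per
#'   individual, in the input order. Founders map to themselves.
#' @export
resolve_matrilines <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- ped$individuals$id
  parent <- match(ped$individuals$dam_id, ids)
  root <- seq_along(ids)
  # pointer jumping: O(n log n) worst case, acyclicity already verified
  repeat {
    p <- parent[root]
    done <- is.na(p)
    if (all(done)) break
    root[!done] <- p[!done]
  }
  tibble::tibble(id = ids, matriline_id = ids[root])
}

#' Pool each dam's clutches into one binomial record
#'
#' Sums adult male and female counts over all of a dam's clutches to give
#' the binomial observation unit of the maternal model: `total_male`
#' successes out of `total_male + total_female` sexed adults. Dams whose
#' clutches contain no sexed adults are kept but flagged `excluded` and
#' must not enter a model fit. Covariates (population, infection status,
#' treatment) are copied from the dam's individual record.
#'
#' @param ped A [pedigree()].
#' @param per_clutch If TRUE, return one row per clutch instead of pooling
#'   (used for the clutch-size/sex-ratio correlation); `total_*` columns
#'   then refer to the single clutch and `clutch_index`/`n_hatched` are
#'   retained.
#' @return A tibble of dam records with columns `dam_id`, `matriline_id`,
#'   `total_male`, `total_female`, `total_hatched`, `n_clutches` (or
#'   `clutch_index`, `n_hatched`), `excluded`, plus covariates
#'   `population`, `wolbachia`, `rickettsia`, `cardinium`, `treatment`.
#' @export
aggregate_dams <- function(ped, per_clutch = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  cl <- ped$clutches
  ind <- ped$individuals
  dam_sex <- ind$sex[match(cl$dam_id, ind$id)]
  if (any(dam_sex != "F")) {
    bad <- unique(cl$dam_id[dam_sex != "F"])
    abort(paste0("clutch dam(s) not recorded as female: ",
                 paste(bad, collapse = ", ")),
          class = "matriline_domain_error")
  }
  mat <- resolve_matrilines(ped)

  if (per_clutch) {
    out <- dplyr::transmute(
      cl,
      dam_id = .data$dam_id,
      clutch_index = .data$clutch_index,
      total_male = .data$n_adult_male,
      total_female = .data$n_adult_female,
      n_hatched = .data$n_hatched
    )
  } else {
    out <- cl |>
      dplyr::group_by(.data$dam_id) |>
      dplyr::summarise(
        total_male = sum(.data$n_adult_male),
        total_female = sum(.data$n_adult_female),
        total_hatched = sum(.data$n_hatched),
        n_clutches = dplyr::n(),
        .groups = "drop"
      )
  }
  out$matriline_id <- mat$matriline_id[match(out$dam_id, mat$id)]
  idx <- match(out$dam_id, ind$id)
  out$population <- ind$population[idx]
  out$wolbachia <- ind$wolbachia[idx]
  out$rickettsia <- ind$rickettsia[idx]
  out$cardinium <- ind$cardinium[idx]
  out$treatment <- ind$treatment[idx]
  out$excluded <- out$total_male + out$total_female == 0L
  dplyr::relocate(out, "dam_id", "matriline_id")
}

#' Tertiary sex ratio of dam records
#'
#' The tertiary sex ratio is the number of male offspring divided by the
#' total number of adult offspring — the proportion of sons among offspring
#' surviving to adulthood (as opposed to primary, at conception, or
#' secondary, at hatching). Males are coded 1 so a "ratio" is always a
#' proportion of males.
#'
#' @param records A dam-record tibble from [aggregate_dams()] (or any data
#'   frame with `total_male` and `total_female` columns).
#' @return The input with a `sex_ratio` column appended.
#' @export
tertiary_sex_ratio <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("total_male", "total_female") %in% names(records)))
  tot <- records$total_male + records$total_female
  if (any(tot == 0)) {
    abort(paste0("sex ratio undefined for record(s) with zero sexed adults: row(s) ",
                 paste(which(tot == 0), collapse = ", ")),
          class = "matriline_undefined_value_error")
  }
  dplyr::mutate(records, sex_ratio = .data$total_male / tot)
}
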