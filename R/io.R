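# CSV dialect: comma-separated, UTF-8, mandatory header, empty string =
# missing, no index column.

ped_cols <- c("individual_id", "dam_id", "sex", "population", "wolbachia",
              "rickettsia", "cardinium", "treatment")
clutch_cols <- c("dam_id", "clutch_index", "n_adult_male", "n_adult_female",
                 "n_hatched")

#' Read a pedigree CSV
#'
#' Expected columns: `individual_id`, `dam_id` (empty = founder), `sex`
#' (`M`/`F`/`U`), `population`, `wolbachia`, `rickettsia`, `cardinium`
#' (`pos`/`neg`/empty), `treatment`. The file is validated as a
#' [pedigree()]; validation errors name the offending individuals.
#'
#' @param path CSV file path.
#' @param clutch_path Optional clutch CSV to attach (see
#'   [read_clutch_csv()]).
#' @return A [pedigree()].
#' @export
read_pedigree_csv <- function(path, clutch_path = NULL) {
  if (!file.exists(path)) {
    abort(paste0("pedigree file not found: ", path),
          class = "matriline_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  missing_cols <- setdiff(c("individual_id", "dam_id", "sex"), names(df))
  if (length(missing_cols)) {
    abort(paste0("pedigree CSV lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "matriline_schema_error")
  }
  for (col in setdiff(ped_cols, names(df))) df[[col]] <- NA_character_
  individuals <- dplyr::transmute(
    df,
    id = .data$individual_id,
    dam_id = dplyr::if_else(is.na(.data$dam_id) | .data$dam_id == "",
                            NA_character_, .data$dam_id),
    sex = .data$sex,
    population = dplyr::coalesce(.data$population, "P1"),
    wolbachia = .data$wolbachia, rickettsia = .data$rickettsia,
    cardinium = .data$cardinium, treatment = .data$treatment
  )
  clutches <- if (!is.null(clutch_path)) read_clutch_csv(clutch_path)
  pedigree(individuals, clutches)
}

#' Write a pedigree to CSV
#'
#' @param ped A [pedigree()].
#' @param path Output CSV path for the individual table.
#' @return `path`, invisibly.
#' @export
write_pedigree_csv <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- dplyr::transmute(
    ped$individuals,
    individual_id = .data$id, dam_id = .data$dam_id, sex = .data$sex,
    population = .data$population, wolbachia = .data$wolbachia,
    rickettsia = .data$rickettsia, cardinium = .data$cardinium,
    treatment = .data$treatment
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read a clutch CSV
#'
#' Columns: `dam_id`, `clutch_index`, `n_adult_male`, `n_adult_female`,
#' `n_hatched`. Counts are validated as non-negative integers with adults
#' never exceeding hatched.
#'
#' @param path CSV file path.
#' @return A validated clutch tibble.
#' @export
read_clutch_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("clutch file not found: ", path),
          class = "matriline_io_error")
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      dam_id = readr::col_character(),
      clutch_index = readr::col_integer(),
      n_adult_male = readr::col_integer(),
      n_adult_female = readr::col_integer(),
      n_hatched = readr::col_integer()
    ),
    progress = FALSE
  )
  missing_cols <- setdiff(clutch_cols, names(df))
  if (length(missing_cols)) {
    abort(paste0("clutch CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "matriline_schema_error")
  }
  counts <- df[c("n_adult_male", "n_adult_female", "n_hatched")]
  if (anyNA(counts) || any(as.matrix(counts) < 0)) {
    abort("clutch counts must be non-negative integers",
          class = "matriline_validation_error")
  }
  over <- which(df$n_adult_male + df$n_adult_female > df$n_hatched)
  if (length(over)) {
    abort(paste0("adult counts exceed hatched at row(s): ",
                 paste(over, collapse = ", ")),
          class = "matriline_validation_error")
  }
  df
}

#' Write a clutch table to CSV
#'
#' @param clutches Clutch tibble (e.g. `ped$clutches`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clutch_csv <- function(clutches, path) {
  readr::write_csv(clutches[clutch_cols], path, na = "")
  invisible(path)
}

#' Write posterior draws in long format
#'
#' One row per (chain, iteration, parameter) for tool-agnostic
#' post-processing.
#'
#' @param fit A `maternal_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path) {
  readr::write_csv(tidy_draws(fit), path)
  invisible(path)
}

#' Read a long-format draws CSV
#'
#' @param path Path written by [write_draws_csv()].
#' @return Tibble with `chain`, `iteration`, `parameter`, `value`.
#' @export
read_draws_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    chain = readr::col_integer(), iteration = readr::col_integer(),
    parameter = readr::col_character(), value = readr::col_double()
  ), progress = FALSE)
}

#' Write a JSON report
#'
#' Generic JSON writer used for posterior summaries, simulation truth and
#' stats reports; scalars are unboxed.
#'
#' @param x A list or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON report
#'
#' @param path Path written by [write_json_report()].
#' @return The parsed list.
#' @export
read_json_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
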