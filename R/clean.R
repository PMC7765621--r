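#' Keep only suspected-drug rows
#'
#' Spontaneous-report databases classify each drug on a report as suspected,
#' concomitant or an interaction; disproportionality analysis uses only the
#' drugs the reporter judged causally involved.
#'
#' @param drug Tibble of DRUG rows (`case_id`, `drug_name`, `involvement`).
#' @return The rows with `involvement == "suspected"`, in their original order.
#' @export
filter_suspected <- function(drug) {
  dplyr::filter(drug, .data$involvement == "suspected")
}

#' Remove duplicate report rows
#'
#' Collapses exact duplicate rows, and within a case collapses repeated drug
#' names (DRUG) or repeated preferred terms (REAC) to one row, keeping the
#' first occurrence. Idempotent and order-stable.
#'
#' @param rows Tibble of DRUG or REAC rows.
#' @return Deduplicated tibble of the same type.
#' @export
deduplicate <- function(rows) {
  key <- if ("drug_name" %in% names(rows)) "drug_name" else if ("pt_name" %in% names(rows)) "pt_name" else NULL
  if (is.null(key)) {
    return(dplyr::distinct(rows))
  }
  dplyr::distinct(rows, .data$case_id, .data[[key]], .keep_all = TRUE)
}

#' Recode reported weight to kilograms
#'
#' Open-ended weight bands are recoded to fixed values: anything over 60 kg
#' (the band label `">60 kg"` or a number above 60) becomes 65 kg, anything
#' under 10 kg becomes 5 kg; in-range numbers pass through; unparseable
#' entries become `NA`.
#'
#' @param raw Character or numeric vector of raw weight entries.
#' @return Numeric vector of weights in kg.
#' @export
recode_weight <- function(raw) {
  x <- as.character(raw)
  x <- trimws(x)
  out <- quiet_numeric(x)
  over <- grepl("^>\\s*60", x)
  under <- grepl("^<\\s*10", x)
  out[over] <- 65
  out[under] <- 5
  out[!is.na(out) & out > 60] <- 65
  out[!is.na(out) & out < 10] <- 5
  out
}

#' Convert an age band to years
#'
#' Decade bands like `"70s"` map to their midpoint (75); exact numeric strings
#' pass through; anything else becomes `NA`.
#'
#' @param band Character vector of age entries.
#' @return Numeric vector of ages in years.
#' @export
recode_age_band <- function(band) {
  x <- trimws(as.character(band))
  out <- quiet_numeric(x)
  dec <- grepl("^[0-9]+s$", x)
  out[dec] <- quiet_numeric(sub("s$", "", x[dec])) + 5
  out
}

#' Merge DRUG, REAC and DEMO tables into case records
#'
#' Joins the three tables on the case identifier into one row per case: the
#' demographics (with weight recoding, age-band conversion and BMI), the set
#' of suspected drugs and the set of reported preferred terms. Cases present
#' in DEMO but absent from DRUG or REAC get empty sets.
#'
#' @param drug Deduplicated, suspected-only DRUG tibble.
#' @param reac Deduplicated REAC tibble.
#' @param demo Deduplicated DEMO tibble (one row per case).
#' @return A case tibble with columns `case_id`, `sex`, `age_years`,
#'   `height_cm`, `weight_kg`, `bmi`, and list-columns `drugs` and `events`.
#' @export
merge_cases <- function(drug, reac, demo) {
  if (anyDuplicated(demo$case_id)) {
    abort("DEMO contains duplicate case_id values after deduplication.")
  }
  if ("involvement" %in% names(drug)) {
    drug <- dplyr::filter(drug, .data$involvement %in% "suspected")
  }
  drug_sets <- drug |>
    dplyr::filter(!is.na(.data$drug_name)) |>
    dplyr::summarise(drugs = list(unique(.data$drug_name)), .by = "case_id")
  event_sets <- reac |>
    dplyr::filter(!is.na(.data$pt_name)) |>
    dplyr::summarise(events = list(unique(.data$pt_name)), .by = "case_id")

  cases <- demo |>
    dplyr::mutate(
      age_years = recode_age_band(.data$age_band),
      weight_kg = recode_weight(.data$weight_raw),
      bmi = .data$weight_kg / (.data$height_cm / 100)^2
    ) |>
    dplyr::select("case_id", "sex", "age_years", "height_cm", "weight_kg", "bmi") |>
    dplyr::left_join(drug_sets, by = "case_id") |>
    dplyr::left_join(event_sets, by = "case_id")
  empty <- list(character())
  cases$drugs[vapply(cases$drugs, is.null, logical(1L))] <- empty
  cases$events[vapply(cases$events, is.null, logical(1L))] <- empty
  cases
}

#' Remove BMI outliers from the case table
#'
#' Reports with an implausible body-mass index (below `low` or at/above
#' `high`) are treated as data-entry artefacts and removed. Cases whose BMI
#' cannot be computed (missing height or weight) are kept: the cleaning rule
#' only targets computable outliers, so each downstream analysis applies its
#' own complete-case restriction.
#'
#' @param cases Case tibble from [merge_cases()].
#' @param low Lower BMI bound (exclusive removal: `bmi < low`).
#' @param high Upper BMI bound (inclusive removal: `bmi >= high`).
#' @return The cleaned case tibble, with a `cleaning_report` attribute
#'   (retrievable with [cleaning_report()]) recording `n_input`,
#'   `n_removed_low_bmi`, `n_removed_high_bmi` and `n_output`.
#' @export
clean_bmi <- function(cases, low = 5, high = 100) {
  if (low >= high) {
    abort("`low` must be smaller than `high`.")
  }
  bmi <- cases$bmi
  low_out <- !is.na(bmi) & bmi < low
  high_out <- !is.na(bmi) & bmi >= high
  out <- cases[!(low_out | high_out), , drop = FALSE]
  report <- list(
    n_input = nrow(cases),
    n_removed_low_bmi = sum(low_out),
    n_removed_high_bmi = sum(high_out),
    n_output = nrow(out)
  )
  attr(out, "cleaning_report") <- report
  out
}

#' Retrieve the cleaning report attached by [clean_bmi()]
#'
#' @param cases A case tibble returned by [clean_bmi()].
#' @return A list with `n_input`, `n_removed_low_bmi`, `n_removed_high_bmi`,
#'   `n_output`.
#' @export
cleaning_report <- function(cases) {
  rep <- attr(cases, "cleaning_report", exact = TRUE)
  if (is.null(rep)) {
    abort("No cleaning report attached; did this tibble come from clean_bmi()?")
  }
  rep
}

#' Write a case table to CSV
#'
#' Drug and event sets are serialised as semicolon-joined strings.
#'
#' @param cases Case tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path) {
  flat <- cases |>
    dplyr::mutate(
      drugs = vapply(.data$drugs, paste, character(1L), collapse = ";"),
      events = vapply(.data$events, paste, character(1L), collapse = ";")
    )
  readr::write_csv(flat, path, na = "")
  invisible(path)
}
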