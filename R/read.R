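#' Default column map for JADER-layout tables
#'
#' The reader matches file headers against this map, so the same code reads
#' the synthetic fixtures shipped with the package and a real JADER extract
#' (whose headers differ) once the user supplies a translated map, e.g. loaded
#' from a JSON file with [jsonlite::read_json()].
#'
#' @return A named list with one character vector per table kind
#'   (`DRUG`, `REAC`, `DEMO`); names are canonical column names, values are the
#'   header strings expected in the file.
#' @export
default_column_map <- function() {
  list(
    DRUG = c(case_id = "case_id", drug_name = "drug_name", involvement = "involvement"),
    REAC = c(case_id = "case_id", pt_name = "pt_name"),
    DEMO = c(
      case_id = "case_id", sex = "sex", age_band = "age_band",
      height_cm = "height_cm", weight_raw = "weight_raw"
    )
  )
}

involvement_levels <- c("suspected", "concomitant", "interaction")

#' Read one JADER-layout table
#'
#' Reads a delimited DRUG, REAC or DEMO table into a typed tibble. Numeric
#' fields that fail to parse become `NA` rather than errors, mirroring the
#' blank and malformed cells of real spontaneous-report extracts; row order is
#' preserved.
#'
#' @param path Path to a delimited text file with a header row.
#' @param kind One of `"DRUG"`, `"REAC"`, `"DEMO"`.
#' @param encoding File encoding (real JADER distributions are Shift-JIS;
#'   synthetic fixtures are UTF-8).
#' @param col_map Column map in the shape of [default_column_map()].
#' @param delim Field delimiter.
#' @return A tibble: `DRUG` has `case_id`, `drug_name`, `involvement`
#'   (factor-free character restricted to suspected/concomitant/interaction);
#'   `REAC` has `case_id`, `pt_name`; `DEMO` has `case_id`, `sex`, `age_band`,
#'   `height_cm` (numeric), `weight_raw` (character).
#' @export
read_jader_table <- function(path, kind = c("DRUG", "REAC", "DEMO"),
                             encoding = "UTF-8",
                             col_map = default_column_map(),
                             delim = ",") {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort(sprintf("File not found: '%s'", path))
  }
  map <- col_map[[kind]]
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(encoding = encoding),
    na = character(),
    progress = FALSE
  )
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s table at '%s' lacks expected column(s): %s",
      kind, path, paste(missing_cols, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(raw[, unname(map)])
  names(out) <- names(map)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(),
                                          ~ dplyr::na_if(.x, "")))
  if (kind == "DRUG") {
    bad <- !is.na(out$involvement) & !(out$involvement %in% involvement_levels)
    if (any(bad)) {
      warn(sprintf(
        "%d DRUG row(s) with unrecognised involvement set to NA (e.g. '%s')",
        sum(bad), out$involvement[which(bad)[1]]
      ))
      out$involvement[bad] <- NA_character_
    }
  }
  if (kind == "DEMO") {
    out$height_cm <- quiet_numeric(out$height_cm)
    out$height_cm[!is.na(out$height_cm) & out$height_cm < 0] <- NA_real_
  }
  out
}

#' Write one JADER-layout table
#'
#' Inverse of [read_jader_table()]: writes the canonical columns under the
#' header names of `col_map`, with `NA` as empty fields.
#'
#' @param x Tibble as returned by [read_jader_table()].
#' @param path Output file path.
#' @param kind One of `"DRUG"`, `"REAC"`, `"DEMO"`.
#' @inheritParams read_jader_table
#' @return `path`, invisibly.
#' @export
write_jader_table <- function(x, path, kind = c("DRUG", "REAC", "DEMO"),
                              col_map = default_column_map(), delim = ",") {
  kind <- match.arg(kind)
  map <- col_map[[kind]]
  out <- x[, names(map)]
  names(out) <- unname(map)
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
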