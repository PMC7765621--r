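#' Disproportionality signal detection across drugs
#'
#' For each drug, cross-tabulates the case table against the event definition,
#' computes the half-corrected reporting odds ratio with its 95% interval, the
#' two-sided Fisher exact p-value on the raw cells, the reporting ratio (the
#' drug's share of all reports of the event, in percent), volcano-plot
#' coordinates, and the signal flag `ror >= ror_threshold & p < alpha`.
#'
#' @param cases Case tibble from [merge_cases()] / [clean_bmi()].
#' @param drugs Character vector of drug names to screen; `NULL` screens every
#'   suspected drug present in the data.
#' @param event_terms Character vector of preferred terms defining the event.
#' @param ror_threshold,alpha Signal criterion: `ror >= ror_threshold` and
#'   `p_fisher < alpha`.
#' @param p_floor Smallest p-value used for the volcano ordinate; p-values
#'   below it are floored before taking `-log10` so coordinates stay finite.
#' @return A tibble (class `srs_signals`) with one row per drug, sorted by
#'   descending `n_reports`, then descending `ror`, then drug name: columns
#'   `drug`, `n_reports` (= a), `reporting_ratio` (%), `ror`, `ci_low`,
#'   `ci_high`, `p_fisher`, `ln_or`, `neg_log10_p`, `is_signal`.
#' @export
detect_signals <- function(cases, drugs = NULL, event_terms,
                           ror_threshold = 1, alpha = 0.05,
                           p_floor = 1e-300) {
  if (nrow(cases) == 0L) {
    warn("Empty case table: returning zero signals.")
    return(empty_signals())
  }
  has_event <- has_any_term(cases$events, event_terms)
  n_total <- nrow(cases)
  n_event <- sum(has_event)

  drug_long <- tibble::tibble(
    row = rep.int(seq_len(n_total), lengths(cases$drugs)),
    drug = unlist(cases$drugs, use.names = FALSE)
  )
  if (is.null(drugs)) drugs <- sort(unique(drug_long$drug))
  counts <- drug_long |>
    dplyr::filter(.data$drug %in% drugs) |>
    dplyr::summarise(
      n_drug = dplyr::n(),
      a = sum(has_event[.data$row]),
      .by = "drug"
    )
  counts <- tibble::tibble(drug = drugs) |>
    dplyr::left_join(counts, by = "drug") |>
    dplyr::mutate(
      n_drug = dplyr::coalesce(.data$n_drug, 0L),
      a = dplyr::coalesce(.data$a, 0L),
      b = .data$n_drug - .data$a,
      c = n_event - .data$a,
      d = n_total - .data$n_drug - .data$c
    )

  res <- dplyr::bind_cols(
    counts,
    ror_cells(counts$a, counts$b, counts$c, counts$d)
  ) |>
    dplyr::mutate(
      p_fisher = purrr::pmap_dbl(
        list(.data$a, .data$b, .data$c, .data$d), fisher_p_one
      ),
      n_reports = .data$a,
      reporting_ratio = if (n_event > 0) 100 * .data$a / n_event else NA_real_,
      ln_or = log(.data$ror),
      neg_log10_p = -log10(pmax(.data$p_fisher, p_floor)),
      is_signal = .data$ror >= ror_threshold & .data$p_fisher < alpha
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_reports), dplyr::desc(.data$ror),
                   .data$drug) |>
    dplyr::select("drug", "n_reports", "reporting_ratio", "ror", "ci_low",
                  "ci_high", "p_fisher", "ln_or", "neg_log10_p", "is_signal")
  class(res) <- c("srs_signals", class(res))
  attr(res, "n_event_total") <- n_event
  attr(res, "alpha") <- alpha
  res
}

empty_signals <- function() {
  res <- tibble::tibble(
    drug = character(), n_reports = integer(), reporting_ratio = double(),
    ror = double(), ci_low = double(), ci_high = double(),
    p_fisher = double(), ln_or = double(), neg_log10_p = double(),
    is_signal = logical()
  )
  class(res) <- c("srs_signals", class(res))
  res
}

#' Volcano-plot coordinates for a signal table
#'
#' @param results An `srs_signals` tibble from [detect_signals()].
#' @return Tibble with `drug`, `ln_or`, `neg_log10_p`, `n_reports`; the
#'   `threshold` attribute holds the `-log10(alpha)` reference line value.
#' @export
volcano_table <- function(results) {
  alpha <- attr(results, "alpha", exact = TRUE) %||% 0.05
  out <- dplyr::select(tibble::as_tibble(results),
                       "drug", "ln_or", "neg_log10_p", "n_reports")
  attr(out, "threshold") <- -log10(alpha)
  out
}

#' Volcano plot of disproportionality signals
#'
#' Scatter of ln(OR) against -log10(p) with a dotted line at the significance
#' threshold; point size reflects the number of reports, mirroring the usual
#' presentation of drug-safety volcano plots.
#'
#' @param object An `srs_signals` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srs_signals
#' @export
autoplot.srs_signals <- function(object, ...) {
  alpha <- attr(object, "alpha", exact = TRUE) %||% 0.05
  ggplot2::ggplot(object, ggplot2::aes(.data$ln_or, .data$neg_log10_p)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_reports,
                                     colour = .data$is_signal),
                        alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dotted") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "ln(OR)", y = expression(-log[10](italic(p))),
                  size = "Reports", colour = "Signal") +
    ggplot2::theme_minimal()
}
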