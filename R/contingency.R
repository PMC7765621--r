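#' Build a 2x2 drug-by-event contingency table
#'
#' Cross-tabulates all case records by exposure to one suspected drug and
#' occurrence of an event (a single preferred term or a term set such as an
#' SMQ): `a` = drug and event, `b` = drug without event, `c` = event without
#' drug, `d` = neither. Counting is case-level: a case contributes once no
#' matter how many rows mentioned the drug or term.
#'
#' @param cases Case tibble from [merge_cases()] / [clean_bmi()].
#' @param drug Drug name.
#' @param event_terms Character vector of preferred terms defining the event.
#' @return A `contingency` object (fields `a`, `b`, `c`, `d`, `n`).
#' @export
build_contingency <- function(cases, drug, event_terms) {
  has_drug <- has_any_term(cases$drugs, drug)
  has_event <- has_any_term(cases$events, event_terms)
  contingency_table(
    a = sum(has_drug & has_event),
    b = sum(has_drug & !has_event),
    c = sum(!has_drug & has_event),
    d = sum(!has_drug & !has_event)
  )
}

#' Construct a contingency table from its four cells
#'
#' @param a,b,c,d Non-negative cell counts (drug+event, drug only, event only,
#'   neither).
#' @return A `contingency` object.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    abort("All contingency cells must be finite and non-negative.")
  }
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(c("drug", "no drug"), c("event", "no event")))
  print(m)
  invisible(x)
}

#' Haldane-Anscombe half correction
#'
#' Adds 0.5 to all four cells unconditionally (not only when a cell is zero),
#' so odds-ratio estimates and their Woolf intervals are always finite.
#'
#' @param ct A `contingency` object.
#' @return Named numeric vector `(a, b, c, d)` of corrected cells.
#' @export
half_correct <- function(ct) {
  c(a = ct$a + 0.5, b = ct$b + 0.5, c = ct$c + 0.5, d = ct$d + 0.5)
}

# Vectorised ROR point estimate and Woolf 95% CI on half-corrected cells.
ror_cells <- function(a, b, c, d, conf_level = 0.95) {
  a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    ror = est,
    ci_low = exp(log(est) - z * se),
    ci_high = exp(log(est) + z * se)
  )
}

#' Reporting odds ratio with confidence interval
#'
#' Point estimate `(a d)/(b c)` on half-corrected cells with the Woolf
#' (log-normal) interval `exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`,
#' also on corrected cells. Always finite and positive.
#'
#' @param ct A `contingency` object.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble with `ror`, `ci_low`, `ci_high`.
#' @export
ror <- function(ct, conf_level = 0.95) {
  ror_cells(ct$a, ct$b, ct$c, ct$d, conf_level)
}

# Two-sided Fisher exact p for one table, by summation over the
# hypergeometric support: all tables with the observed margins whose
# probability does not exceed the observed table's (ties at floating-point
# precision are included via a 1e-7 relative tolerance, the usual convention).
fisher_p_one <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  drawn <- a + c
  support <- max(0L, drawn - n):min(m, drawn)
  probs <- dhyper(support, m, n, drawn)
  p_obs <- dhyper(a, m, n, drawn)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value with fixed margins, summing the probabilities of all tables
#' at most as probable as the one observed. The test is defined on the raw
#' integer cells; the half correction applies only to the odds-ratio scale.
#'
#' @param ct A `contingency` object with integer cells.
#' @return The two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(ct) {
  cells <- c(ct$a, ct$b, ct$c, ct$d)
  if (any(cells != round(cells))) {
    abort("Fisher's exact test requires integer cell counts.")
  }
  fisher_p_one(ct$a, ct$b, ct$c, ct$d)
}
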