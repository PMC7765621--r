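#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two independent samples. For combined sample sizes of at most
#' `exact_max` the two-sided p-value is computed by exhaustive enumeration of
#' all group assignments of the pooled mid-ranks (valid under ties); larger
#' samples use the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param x,y Numeric samples; `NA`s are dropped.
#' @param exact_max Combined-size cutoff for the exact enumeration path.
#' @return Two-sided p-value.
#' @export
rank_sum_test <- function(x, y, exact_max = 20) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort("rank_sum_test requires both samples to be non-empty after removing missing values.")
  }
  if (length(x) + length(y) <= exact_max) {
    rank_sum_exact(x, y)
  } else {
    stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  }
}

# Exact two-sided p by enumerating all C(n, nx) assignments of the pooled
# mid-ranks; p = min(1, 2 * min(P(W <= w), P(W >= w))).
rank_sum_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(length(pooled), nx)
  w_all <- colSums(matrix(r[combos], nrow = nx))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Exact test of association between sex and an outcome
#'
#' Fisher's exact test on the 2x2 sex-by-outcome table, delegating to
#' [fisher_exact()].
#'
#' @param ct A `contingency` object (e.g. males/females by event presence).
#' @return Two-sided p-value.
#' @export
sex_association_test <- function(ct) {
  fisher_exact(ct)
}

#' Patient-background comparison between event and non-event cases
#'
#' Splits the case table into the group whose events intersect `outcome_terms`
#' and the rest, then summarises each background variable with complete-case
#' counts, means and SDs per group, and a two-group test: the rank-sum test
#' for continuous variables and Fisher's exact test for sex (summarised as
#' the proportion female).
#'
#' @param cases Case tibble.
#' @param outcome_terms Preferred terms defining the outcome group.
#' @param variables Variables to summarise, among `"female"`, `"age_years"`,
#'   `"height_cm"`, `"weight_kg"`, `"bmi"`.
#' @return Tibble with one row per variable: `variable`, `n_outcome`,
#'   `mean_outcome`, `sd_outcome`, `n_other`, `mean_other`, `sd_other`,
#'   `test`, `p_value`. All-missing variables get `n = 0` and `NA` summaries.
#' @export
summarize_groups <- function(cases, outcome_terms,
                             variables = c("female", "age_years", "height_cm",
                                           "weight_kg", "bmi")) {
  variables <- match.arg(variables, several.ok = TRUE)
  in_group <- has_any_term(cases$events, outcome_terms)
  get_var <- function(v) {
    if (v == "female") {
      ifelse(is.na(cases$sex), NA_real_, as.numeric(cases$sex == "female"))
    } else {
      cases[[v]]
    }
  }
  purrr::map_dfr(variables, function(v) {
    vals <- get_var(v)
    g1 <- vals[in_group & !is.na(vals)]
    g0 <- vals[!in_group & !is.na(vals)]
    test <- if (v == "female") "fisher_exact" else "rank_sum"
    p <- if (length(g1) == 0L || length(g0) == 0L) {
      NA_real_
    } else if (v == "female") {
      ct <- contingency_table(
        a = sum(g1 == 1), b = sum(g1 == 0),
        c = sum(g0 == 1), d = sum(g0 == 0)
      )
      fisher_exact(ct)
    } else {
      rank_sum_test(g1, g0)
    }
    tibble::tibble(
      variable = v,
      n_outcome = length(g1),
      mean_outcome = if (length(g1)) mean(g1) else NA_real_,
      sd_outcome = if (length(g1) > 1) sd(g1) else NA_real_,
      n_other = length(g0),
      mean_other = if (length(g0)) mean(g0) else NA_real_,
      sd_other = if (length(g0) > 1) sd(g0) else NA_real_,
      test = test,
      p_value = p
    )
  })
}
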