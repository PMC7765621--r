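#' Build the design matrix for the multivariate risk model
#'
#' One row per case with complete covariate information: 0/1 indicators for
#' membership of each drug in the case's suspected-drug set, `female` coded
#' 1/0, and continuous covariates in natural units (years, cm, kg). The
#' outcome is 1 when the case's events intersect `outcome_terms`. Cases with a
#' missing covariate are dropped (complete-case analysis) and counted.
#'
#' @param cases Case tibble.
#' @param outcome_terms Preferred terms defining the outcome.
#' @param drug_terms Drug names entering as indicator variables.
#' @param covariates Subset of `c("female", "age_years", "height_cm",
#'   "weight_kg")`.
#' @return List with `x` (numeric matrix, no intercept column), `y` (0/1
#'   vector) and `n_dropped_missing`.
#' @export
build_design <- function(cases, outcome_terms, drug_terms,
                         covariates = c("female", "age_years", "height_cm",
                                        "weight_kg")) {
  if (length(drug_terms) + length(covariates) == 0L) {
    abort("At least one predictor is required.")
  }
  if (length(covariates)) {
    covariates <- match.arg(covariates, several.ok = TRUE)
  } else {
    covariates <- character(0)
  }
  cov_cols <- lapply(covariates, function(v) {
    if (v == "female") {
      ifelse(is.na(cases$sex), NA_real_, as.numeric(cases$sex == "female"))
    } else {
      cases[[v]]
    }
  })
  names(cov_cols) <- covariates
  complete <- if (length(cov_cols)) {
    complete.cases(as.data.frame(cov_cols))
  } else {
    rep(TRUE, nrow(cases))
  }
  n_dropped <- sum(!complete)
  kept <- cases[complete, , drop = FALSE]

  drug_cols <- lapply(drug_terms, function(d) {
    as.numeric(has_any_term(kept$drugs, d))
  })
  names(drug_cols) <- drug_terms
  x <- cbind(
    if (length(drug_cols)) do.call(cbind, drug_cols),
    if (length(cov_cols)) do.call(cbind, lapply(cov_cols, function(v) v[complete]))
  )
  colnames(x) <- c(drug_terms, covariates)
  y <- as.numeric(has_any_term(kept$events, outcome_terms))

  const <- apply(x, 2L, function(col) length(unique(col)) < 2L)
  if (any(const)) {
    abort(sprintf("Degenerate design: constant predictor(s): %s",
                  paste(colnames(x)[const], collapse = ", ")))
  }
  list(x = x, y = y, n_dropped_missing = n_dropped)
}

#' Fit the multivariate logistic risk model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares) of the outcome on the design matrix, reporting per-term
#' coefficients, Wald standard errors and p-values, unit odds ratios
#' `exp(beta)` with 95% Wald intervals, range odds ratios `exp(beta * (max -
#' min))` over each continuous term's observed span, and McFadden's pseudo-R2
#' against the intercept-only model. Complete or quasi-complete separation is
#' surfaced as a warning and `converged = FALSE`, never silently penalised.
#'
#' @param design List from [build_design()] (or any list with `x`, `y`).
#' @param tol Convergence tolerance passed to the IRLS loop.
#' @param max_iter Maximum IRLS iterations.
#' @param continuous Names of terms treated as continuous for range odds
#'   ratios; defaults to every non-binary column of `x`.
#' @return An `srs_logit` object; see [tidy.srs_logit()] and
#'   [glance.srs_logit()].
#' @export
fit_risk_model <- function(design, tol = 1e-8, max_iter = 25,
                           continuous = NULL) {
  x <- design$x
  y <- design$y
  if (length(unique(y)) < 2L) {
    abort("Outcome is constant; the logistic model is undefined.")
  }
  xmat <- cbind(`(Intercept)` = 1, x)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(xmat, y, family = binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- coef(fit)
  p <- length(beta)
  rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  rmat[lower.tri(rmat)] <- 0
  se <- sqrt(diag(chol2inv(rmat)))
  zval <- beta / se
  pval <- 2 * pnorm(-abs(zval))
  # quasi/complete separation: essentially-degenerate fitted probabilities
  # together with a diverging coefficient
  mu <- fit$fitted.values
  separation <- separation ||
    (any(mu < 1e-8 | mu > 1 - 1e-8) && any(abs(beta) > 15))
  converged <- fit$converged && !separation
  if (separation) {
    warn("Possible separation: fitted probabilities of 0 or 1 occurred; estimates may be unstable.")
  }

  if (is.null(continuous)) {
    continuous <- colnames(x)[apply(x, 2L, function(col) {
      !all(col %in% c(0, 1))
    })]
  }
  spans <- setNames(rep(NA_real_, ncol(x)), colnames(x))
  spans[continuous] <- apply(x[, continuous, drop = FALSE], 2L,
                             function(col) diff(range(col)))

  terms <- names(beta)
  res <- tibble::tibble(
    term = terms,
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(zval),
    p.value = unname(pval),
    odds.ratio = exp(unname(beta)),
    conf.low = exp(unname(beta - 1.96 * se)),
    conf.high = exp(unname(beta + 1.96 * se)),
    span = c(NA_real_, unname(spans))[match(terms, c("(Intercept)", names(spans)))]
  )
  structure(
    list(
      coefficients = res,
      # McFadden: 1 - logLik/logLik0; for a 0/1 outcome the saturated
      # log-likelihood is 0, so this equals 1 - deviance/null deviance.
      pseudo_r2 = 1 - fit$deviance / fit$null.deviance,
      n_used = length(y),
      n_dropped_missing = design$n_dropped_missing %||% 0L,
      converged = converged,
      separation = separation,
      iterations = fit$iter,
      deviance = fit$deviance,
      null_deviance = fit$null.deviance
    ),
    class = "srs_logit"
  )
}

#' Range odds ratios over each continuous term's observed span
#'
#' For a continuous covariate with coefficient `beta` and observed span
#' `max - min`, the range odds ratio `exp(beta * span)` expresses the odds
#' multiplier across the whole observed range, with the Wald interval
#' endpoints transformed identically. Zero-span terms are reported as `NA`.
#'
#' @param fit An `srs_logit` object.
#' @return Tibble with `term`, `span`, `range.or`, `range.conf.low`,
#'   `range.conf.high`.
#' @export
range_odds_ratios <- function(fit) {
  fit$coefficients |>
    dplyr::filter(!is.na(.data$span)) |>
    dplyr::mutate(
      span = dplyr::if_else(.data$span == 0, NA_real_, .data$span),
      range.or = exp(.data$estimate * .data$span),
      range.conf.low = exp((.data$estimate - 1.96 * .data$std.error) * .data$span),
      range.conf.high = exp((.data$estimate + 1.96 * .data$std.error) * .data$span)
    ) |>
    dplyr::select("term", "span", "range.or", "range.conf.low",
                  "range.conf.high")
}

#' Tidy a fitted risk model
#'
#' @param x An `srs_logit` object.
#' @param ... Unused.
#' @return Per-term tibble with estimates, Wald standard errors and p-values,
#'   unit odds ratios with 95% intervals, and range odds ratios for
#'   continuous terms.
#' @method tidy srs_logit
#' @export
tidy.srs_logit <- function(x, ...) {
  dplyr::left_join(x$coefficients,
                   range_odds_ratios(x),
                   by = c("term", "span"))
}

#' One-row model summary
#'
#' @param x An `srs_logit` object.
#' @param ... Unused.
#' @return Tibble with `pseudo.r.squared` (McFadden), `n_used`,
#'   `n_dropped_missing`, `converged`, `iterations`, `deviance`,
#'   `null.deviance`.
#' @method glance srs_logit
#' @export
glance.srs_logit <- function(x, ...) {
  tibble::tibble(
    pseudo.r.squared = x$pseudo_r2,
    n_used = x$n_used,
    n_dropped_missing = x$n_dropped_missing,
    converged = x$converged,
    iterations = x$iterations,
    deviance = x$deviance,
    null.deviance = x$null_deviance
  )
}

#' @export
print.srs_logit <- function(x, ...) {
  cat(sprintf("Logistic risk model: %d cases, McFadden R2 = %.3f%s\n",
              x$n_used, x$pseudo_r2,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}
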