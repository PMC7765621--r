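#' Filter events by total report count
#'
#' Keeps the preferred terms reported in at least `min_reports` cases, the
#' usual stabilisation step before profiling rare events.
#'
#' @param cases Case tibble.
#' @param events Candidate preferred terms.
#' @param min_reports Minimum number of reporting cases.
#' @return The subset of `events` meeting the threshold, in input order.
#' @export
filter_events_by_reports <- function(cases, events, min_reports = 20) {
  counts <- vapply(events, function(e) sum(has_any_term(cases$events, e)),
                   numeric(1L))
  events[counts >= min_reports]
}

#' Drug-by-event ln(ROR) profile matrix
#'
#' Builds the matrix whose cell (i, j) is the natural log of the
#' half-corrected reporting odds ratio of drug i for event j. The correction
#' keeps every cell finite even for never-co-reported pairs, so the matrix is
#' rectangular with no missing values: drugs are the observations, events the
#' variables.
#'
#' @param cases Case tibble.
#' @param drugs Drug names (rows).
#' @param events Preferred terms (columns), typically pre-filtered with
#'   [filter_events_by_reports()].
#' @param min_reports If not `NULL`, events are filtered to those with at
#'   least this many reporting cases before the matrix is built.
#' @return Numeric matrix with drug rownames and event colnames.
#' @export
build_ror_matrix <- function(cases, drugs, events, min_reports = 20) {
  if (!is.null(min_reports)) {
    events <- filter_events_by_reports(cases, events, min_reports)
  }
  if (length(drugs) < 2L || length(events) < 2L) {
    abort("At least 2 drugs and 2 events (after the report-count filter) are required.")
  }
  has_drug <- vapply(drugs, function(d) has_any_term(cases$drugs, d),
                     logical(nrow(cases)))
  has_event <- vapply(events, function(e) has_any_term(cases$events, e),
                      logical(nrow(cases)))
  n <- nrow(cases)
  n_drug <- colSums(has_drug)
  n_event <- colSums(has_event)
  a <- crossprod(has_drug, has_event)           # drugs x events
  b <- n_drug - a
  cc <- matrix(n_event, nrow = length(drugs), ncol = length(events),
               byrow = TRUE) - a
  d <- n - n_drug - cc
  m <- log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)))
  dimnames(m) <- list(drugs, events)
  m
}

#' Correlation-matrix principal component analysis of an ln(ROR) profile
#'
#' Standardises each event column over drugs, eigendecomposes the correlation
#' matrix, and reports loadings as variable-component correlations
#' (eigenvector times sqrt(eigenvalue)), drug scores, and contribution ratios
#' (percent of total variance per component). Eigenvector signs are
#' arbitrary, so each component is oriented so that its largest-|loading|
#' entry is positive, making outputs reproducible.
#'
#' @param mat Drug-by-event matrix from [build_ror_matrix()].
#' @return An `srs_pca` list with `loadings` (event x component), `scores`
#'   (drug x component), `contribution` (percent per component, summing to
#'   100), and `eigenvalues`.
#' @export
profile_pca <- function(mat) {
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    abort("PCA requires at least 2 drugs and 2 events.")
  }
  sds <- apply(mat, 2L, sd)
  if (any(sds == 0)) {
    abort(sprintf("Constant event column(s): %s",
                  paste(colnames(mat)[sds == 0], collapse = ", ")))
  }
  z <- scale(mat)
  r <- cor(mat)
  eig <- eigen(r, symmetric = TRUE)
  ncomp <- min(nrow(mat) - 1L, ncol(mat))
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  loadings <- vectors %*% diag(sqrt(values), nrow = length(values))
  scores <- z %*% vectors
  # Orient each component: largest-|loading| event positive.
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      vectors[, k] <- -vectors[, k]
      scores[, k] <- -scores[, k]
    }
  }
  comp_names <- paste0("PC", seq_len(ncol(loadings)))
  dimnames(loadings) <- list(colnames(mat), comp_names)
  dimnames(scores) <- list(rownames(mat), comp_names)
  structure(
    list(
      loadings = loadings[, seq_len(ncomp), drop = FALSE],
      scores = scores[, seq_len(ncomp), drop = FALSE],
      contribution = setNames(100 * values / sum(values), comp_names),
      eigenvalues = setNames(values, comp_names),
      rotation = vectors,
      center = attr(z, "scaled:center"),
      scale = attr(z, "scaled:scale")
    ),
    class = "srs_pca"
  )
}

#' @export
print.srs_pca <- function(x, ...) {
  cat("Correlation-matrix PCA:",
      sprintf("%d events x %d components\n", nrow(x$loadings), ncol(x$loadings)))
  cat("Contribution ratios (%):\n")
  print(round(x$contribution[seq_len(min(5, length(x$contribution)))], 1))
  invisible(x)
}

#' Score plot of the drug profiles
#'
#' @param object An `srs_pca` object.
#' @param ... Unused.
#' @return A ggplot object: drugs in the plane of the first two components.
#' @method autoplot srs_pca
#' @export
autoplot.srs_pca <- function(object, ...) {
  df <- tibble::tibble(
    drug = rownames(object$scores),
    PC1 = object$scores[, 1L],
    PC2 = object$scores[, 2L]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                   label = .data$drug)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", object$contribution[1L]),
      y = sprintf("PC2 (%.1f%%)", object$contribution[2L])
    ) +
    ggplot2::theme_minimal()
}

#' Ward clustering of events on their leading principal-component loadings
#'
#' Agglomerative hierarchical clustering (Ward's minimum-variance criterion on
#' Euclidean distances, the `ward.D2` dialect) of the events described by
#' their loadings on the first `n_components` components.
#'
#' @param pca An `srs_pca` object, or a numeric matrix of loadings.
#' @param n_components Number of leading components to use.
#' @return An `srs_clust` list with the `hclust` merge history (`tree`), the
#'   input `loadings`, and the cumulative contribution of the components used
#'   (when available).
#' @export
ward_cluster <- function(pca, n_components = 3) {
  if (inherits(pca, "srs_pca")) {
    load <- pca$loadings[, seq_len(min(n_components, ncol(pca$loadings))),
                         drop = FALSE]
    cumcontrib <- sum(pca$contribution[seq_len(ncol(load))])
  } else {
    load <- as.matrix(pca)
    cumcontrib <- NA_real_
  }
  if (nrow(load) < 2L) {
    abort("Clustering requires at least 2 events.")
  }
  tree <- hclust(dist(load), method = "ward.D2")
  structure(list(tree = tree, loadings = load, cum_contribution = cumcontrib),
            class = "srs_clust")
}

#' Cut the event dendrogram into k clusters
#'
#' @param clust An `srs_clust` object from [ward_cluster()].
#' @param k Number of clusters.
#' @return Named integer vector of cluster labels (one per event).
#' @export
cut_clusters <- function(clust, k = 2) {
  n <- length(clust$tree$order)
  if (k < 1 || k > n) {
    abort(sprintf("`k` must be between 1 and %d.", n))
  }
  cutree(clust$tree, k = k)
}

#' @export
print.srs_clust <- function(x, ...) {
  cat(sprintf("Ward (ward.D2) clustering of %d events on %d components",
              length(x$tree$order), ncol(x$loadings)))
  if (!is.na(x$cum_contribution)) {
    cat(sprintf(" (cumulative contribution %.1f%%)", x$cum_contribution))
  }
  cat("\n")
  invisible(x)
}

#' Plot the event dendrogram
#'
#' @param x An `srs_clust` object.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.srs_clust <- function(x, ...) {
  plot(x$tree, xlab = "", sub = "", main = "Ward clustering of events", ...)
}
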