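#' Assemble a full-pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either a [synth_config()] to
#' simulate input tables or paths to existing DRUG/REAC/DEMO files, the
#' outcome term set, the drug list (optionally with class labels for the
#' signal table), thresholds, and the output directory. All randomness flows
#' from the single `seed` via the simulate config.
#'
#' @param simulate A [synth_config()], or `NULL` when `paths` is given.
#' @param paths Named list/vector with `drug`, `reac`, `demo` file paths
#'   (ignored when `simulate` is given).
#' @param outcome_terms Preferred terms defining the primary event.
#' @param profile_terms Preferred terms profiled in the PCA/clustering stage.
#' @param drug_list Tibble with `name` (and optionally `class`) of drugs to
#'   screen and model; `NULL` screens all observed drugs and skips the
#'   logistic/profile stages.
#' @param bmi_low,bmi_high BMI cleaning bounds.
#' @param ror_threshold,alpha Signal criterion.
#' @param min_reports Report-count filter for profiled events.
#' @param k Number of clusters cut from the event dendrogram.
#' @param covariates Covariates for the logistic stage.
#' @param encoding Input file encoding when reading from `paths`.
#' @return A `run_config` list.
#' @export
run_config <- function(simulate = synth_config(), paths = NULL,
                       outcome_terms = "osteonecrosis of the jaw",
                       profile_terms = NULL,
                       drug_list = NULL,
                       bmi_low = 5, bmi_high = 100,
                       ror_threshold = 1, alpha = 0.05,
                       min_reports = 20, k = 2,
                       covariates = c("female", "age_years", "height_cm",
                                      "weight_kg"),
                       encoding = "UTF-8") {
  structure(
    list(
      simulate = simulate, paths = paths,
      outcome_terms = outcome_terms,
      profile_terms = profile_terms,
      drug_list = drug_list,
      bmi_low = bmi_low, bmi_high = bmi_high,
      ror_threshold = ror_threshold, alpha = alpha,
      min_reports = min_reports, k = k,
      covariates = covariates, encoding = encoding
    ),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' @param config A `run_config` list.
#' @return Character vector of human-readable issues; empty when valid. Never
#'   mutates the config.
#' @export
validate_config <- function(config) {
  issues <- character()
  if (is.null(config$simulate) && is.null(config$paths)) {
    issues <- c(issues, "Neither a simulate config nor input paths were given.")
  }
  if (!is.null(config$paths)) {
    need <- c("drug", "reac", "demo")
    miss <- setdiff(need, names(config$paths))
    if (length(miss)) {
      issues <- c(issues, sprintf("Input paths missing entries: %s",
                                  paste(miss, collapse = ", ")))
    } else {
      absent <- unlist(config$paths[need])
      absent <- absent[!file.exists(absent)]
      if (length(absent)) {
        issues <- c(issues, sprintf("Input file(s) not found: %s",
                                    paste(absent, collapse = ", ")))
      }
    }
  }
  if (!is.null(config$simulate)) {
    ok <- tryCatch({
      validate_synth_config(config$simulate)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) issues <- c(issues, paste("simulate:", ok))
  }
  if (config$bmi_low >= config$bmi_high) {
    issues <- c(issues, "bmi_low must be smaller than bmi_high.")
  }
  if (config$alpha <= 0 || config$alpha >= 1) {
    issues <- c(issues, "alpha must be in (0, 1).")
  }
  if (length(config$outcome_terms) == 0) {
    issues <- c(issues, "outcome_terms must not be empty.")
  }
  if (!is.null(config$drug_list)) {
    if (!"name" %in% names(config$drug_list)) {
      issues <- c(issues, "drug_list must have a `name` column.")
    } else if (!is.null(config$simulate)) {
      unknown <- setdiff(config$drug_list$name, config$simulate$drugs$name)
      if (length(unknown)) {
        issues <- c(issues, sprintf("drug_list names not in simulate config: %s",
                                    paste(unknown, collapse = ", ")))
      }
    }
  }
  issues
}

#' Run the whole analysis pipeline
#'
#' Executes simulate (or read) -> suspected filter -> deduplication -> merge
#' -> BMI cleaning -> demographics comparison -> disproportionality signals
#' -> multivariate logistic model -> ln(ROR) PCA/Ward profiling, writing each
#' stage's table under `out_dir` together with a run manifest. Identical
#' config and seed produce byte-identical outputs.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_all <- function(config, out_dir) {
  issues <- validate_config(config)
  if (length(issues)) {
    abort(paste0("Invalid run config:\n", paste("-", issues, collapse = "\n")))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline failed in stage '%s': %s", name,
                    conditionMessage(e)))
    })
  }

  # -- ingest ----------------------------------------------------------------
  tables <- stage("ingest", {
    if (!is.null(config$simulate)) {
      sim <- simulate_reports(config$simulate)
      list(drug = sim$drug, reac = sim$reac, demo = sim$demo)
    } else {
      list(
        drug = read_jader_table(config$paths[["drug"]], "DRUG",
                                encoding = config$encoding),
        reac = read_jader_table(config$paths[["reac"]], "REAC",
                                encoding = config$encoding),
        demo = read_jader_table(config$paths[["demo"]], "DEMO",
                                encoding = config$encoding)
      )
    }
  })
  input_counts <- vapply(tables, nrow, integer(1L))

  # -- clean -----------------------------------------------------------------
  cases <- stage("clean", {
    drug <- deduplicate(filter_suspected(tables$drug))
    reac <- deduplicate(tables$reac)
    demo <- dplyr::distinct(tables$demo, .data$case_id, .keep_all = TRUE)
    merged <- merge_cases(drug, reac, demo)
    clean_bmi(merged, low = config$bmi_low, high = config$bmi_high)
  })
  creport <- cleaning_report(cases)
  write_cases(cases, file.path(out_dir, "cases.csv"))

  # -- demographics ----------------------------------------------------------
  demo_tbl <- stage("demographics",
                  summarize_groups(cases, config$outcome_terms))
  readr::write_csv(demo_tbl, file.path(out_dir, "demographics.csv"), na = "")

  # -- signals ---------------------------------------------------------------
  drug_names <- if (is.null(config$drug_list)) NULL else config$drug_list$name
  signals <- stage("signals", detect_signals(
    cases, drugs = drug_names, event_terms = config$outcome_terms,
    ror_threshold = config$ror_threshold, alpha = config$alpha
  ))
  signals_out <- signals
  if (!is.null(config$drug_list) && "class" %in% names(config$drug_list)) {
    signals_out <- dplyr::left_join(
      signals, dplyr::select(config$drug_list, "name", "class"),
      by = c(drug = "name")
    ) |>
      dplyr::relocate("class", .after = "drug")
  }
  readr::write_csv(signals_out, file.path(out_dir, "signals.csv"), na = "")
  readr::write_tsv(volcano_table(signals), file.path(out_dir, "volcano.tsv"),
                   na = "")

  # -- logistic --------------------------------------------------------------
  fit <- NULL
  if (!is.null(config$drug_list)) {
    fit <- stage("logistic", {
      design <- build_design(cases, config$outcome_terms,
                             drug_terms = config$drug_list$name,
                             covariates = config$covariates)
      fit_risk_model(design)
    })
    readr::write_csv(tidy(fit), file.path(out_dir, "risk_model.csv"),
                     na = "")
    jsonlite::write_json(as.list(glance(fit)),
                         file.path(out_dir, "logistic_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # -- profile ---------------------------------------------------------------
  profile <- NULL
  if (!is.null(config$drug_list) && !is.null(config$profile_terms)) {
    profile <- stage("profile", {
      mat <- build_ror_matrix(cases, config$drug_list$name,
                              config$profile_terms,
                              min_reports = config$min_reports)
      pca <- profile_pca(mat)
      clust <- ward_cluster(pca, n_components = 3)
      labels <- cut_clusters(clust, k = config$k)
      list(matrix = mat, pca = pca, clust = clust, labels = labels)
    })
    write_mat <- function(m, file) {
      readr::write_csv(
        tibble::as_tibble(m, rownames = "name"),
        file.path(out_dir, file), na = ""
      )
    }
    write_mat(profile$matrix, "ror_matrix.csv")
    write_mat(profile$pca$loadings, "loadings.csv")
    write_mat(profile$pca$scores, "scores.csv")
    readr::write_csv(
      tibble::tibble(component = names(profile$pca$contribution),
                     contribution_pct = unname(profile$pca$contribution)),
      file.path(out_dir, "contributions.csv"), na = ""
    )
    readr::write_csv(
      tibble::tibble(event = names(profile$labels),
                     cluster = unname(profile$labels)),
      file.path(out_dir, "labels.csv"), na = ""
    )
    merges <- profile$clust$tree
    readr::write_csv(
      tibble::tibble(step = seq_len(nrow(merges$merge)),
                     left = merges$merge[, 1L], right = merges$merge[, 2L],
                     height = merges$height),
      file.path(out_dir, "merges.csv"), na = ""
    )
  }

  # -- manifest --------------------------------------------------------------
  cfg_hash <- rlang::hash(config)
  manifest <- list(
    package_version = as.character(utils::packageVersion("srssignal")),
    config_hash = cfg_hash,
    seed = if (!is.null(config$simulate)) config$simulate$seed else NA,
    input_rows = as.list(input_counts),
    cleaning = creport,
    n_cases = nrow(cases),
    n_signals = sum(signals$is_signal),
    logistic = if (!is.null(fit)) as.list(glance(fit)),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
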