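#' Configuration for the synthetic report generator
#'
#' Describes a spontaneous-reporting population with known structure: marginal
#' drug exposure probabilities, per-(drug, event) log odds ratios, demographic
#' effects on each event, per-field missingness and an exact-duplicate rate.
#' Defaults emulate an osteoporosis/oncology reporting population: mostly
#' female, elderly, with antiresorptive agents strongly associated with jaw
#' osteonecrosis and atypical femoral fracture.
#'
#' @param n_cases Number of cases to simulate.
#' @param drugs Tibble with columns `name` and `p_exposure` (marginal
#'   probability that a case lists the drug as suspected).
#' @param events Character vector of MedDRA-style preferred terms.
#' @param baseline_event_logit Log-odds of each event for an unexposed male at
#'   the reference age/height.
#' @param drug_effects Tibble with columns `drug`, `event`, `log_or`; pairs not
#'   listed have log odds ratio 0.
#' @param covariate_effects Named list with elements `female`, `age_per_year`,
#'   `height_per_cm`: log odds ratios applied to every event (age and height
#'   enter centred at `age_ref` / `height_ref`).
#' @param age_ref,height_ref Reference age (years) and height (cm) at which
#'   `baseline_event_logit` applies.
#' @param p_female Probability a case is female.
#' @param age_mean,age_sd Mean/SD of the age distribution, truncated to
#'   \[0, 100\] years.
#' @param height_mean,height_sd Named vectors (`female`, `male`) of height
#'   means/SDs in cm.
#' @param weight_mean,weight_sd Named vectors (`female`, `male`) of weight
#'   means/SDs in kg; weight is drawn conditionally on height with correlation
#'   `hw_cor`.
#' @param hw_cor Height-weight correlation within sex.
#' @param missingness Named list of per-field missingness probabilities for
#'   the DEMO fields `sex`, `age`, `height`, `weight`.
#' @param duplicate_rate Fraction of DRUG and REAC rows duplicated verbatim.
#' @param concomitant_rate Probability that a case carries one extra
#'   non-suspected (concomitant) drug row, exercising the suspected-only
#'   filter downstream.
#' @param exposure_corr Optional drug-by-drug correlation matrix for a
#'   Gaussian-copula co-prescription structure; `NULL` means independent
#'   exposures.
#' @param age_as_band If `TRUE` (the JADER convention) ages are emitted as
#'   decade bands like `"70s"`; otherwise as exact years.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_cases = 20000,
                         drugs = tibble::tibble(
                           name = c("zoledronate", "alendronate", "denosumab",
                                    "prednisolone", "sunitinib", "amoxicillin"),
                           p_exposure = c(0.010, 0.015, 0.008, 0.050, 0.004, 0.030)
                         ),
                         events = c("osteonecrosis of the jaw",
                                    "atypical femoral fracture",
                                    "osteomyelitis", "nausea"),
                         baseline_event_logit = -6.5,
                         drug_effects = tibble::tibble(
                           drug = c("zoledronate", "alendronate", "denosumab",
                                    "prednisolone", "zoledronate", "alendronate",
                                    "denosumab", "zoledronate"),
                           event = c(rep("osteonecrosis of the jaw", 4),
                                     rep("atypical femoral fracture", 3),
                                     "osteomyelitis"),
                           log_or = c(log(50), log(40), log(45), log(1.5),
                                      log(30), log(30), log(30), log(10))
                         ),
                         covariate_effects = list(female = log(1.3),
                                                  age_per_year = log(1.02),
                                                  height_per_cm = log(0.99)),
                         age_ref = 60, height_ref = 156,
                         p_female = 0.485,
                         age_mean = 59, age_sd = 21.7,
                         height_mean = c(female = 153, male = 165),
                         height_sd = c(female = 7, male = 7),
                         weight_mean = c(female = 52, male = 62),
                         weight_sd = c(female = 10, male = 11),
                         hw_cor = 0.4,
                         missingness = list(sex = 0.02, age = 0.07,
                                            height = 0.35, weight = 0.30),
                         duplicate_rate = 0.05,
                         concomitant_rate = 0,
                         exposure_corr = NULL,
                         age_as_band = TRUE,
                         seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), drugs = tibble::as_tibble(drugs),
    events = events, baseline_event_logit = baseline_event_logit,
    drug_effects = tibble::as_tibble(drug_effects),
    covariate_effects = covariate_effects,
    age_ref = age_ref, height_ref = height_ref,
    p_female = p_female, age_mean = age_mean, age_sd = age_sd,
    height_mean = height_mean, height_sd = height_sd,
    weight_mean = weight_mean, weight_sd = weight_sd, hw_cor = hw_cor,
    missingness = missingness, duplicate_rate = duplicate_rate,
    concomitant_rate = concomitant_rate, exposure_corr = exposure_corr,
    age_as_band = isTRUE(age_as_band), seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_cases < 1L) abort("`n_cases` must be at least 1.")
  stopifnot_prob(cfg$drugs$p_exposure, "drugs$p_exposure")
  stopifnot_prob(cfg$p_female, "p_female")
  stopifnot_prob(unlist(cfg$missingness), "missingness")
  stopifnot_prob(cfg$duplicate_rate, "duplicate_rate")
  stopifnot_prob(cfg$concomitant_rate, "concomitant_rate")
  if (nrow(cfg$drug_effects) > 0) {
    bad_drug <- setdiff(cfg$drug_effects$drug, cfg$drugs$name)
    bad_event <- setdiff(cfg$drug_effects$event, cfg$events)
    if (length(bad_drug) || length(bad_event)) {
      abort(sprintf(
        "drug_effects references undeclared drugs/events: %s",
        paste(c(bad_drug, bad_event), collapse = ", ")
      ))
    }
  }
  if (!is.null(cfg$exposure_corr)) {
    k <- nrow(cfg$drugs)
    if (!is.matrix(cfg$exposure_corr) || any(dim(cfg$exposure_corr) != k)) {
      abort("`exposure_corr` must be a square matrix matching the drug list.")
    }
  }
  invisible(cfg)
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Generate synthetic JADER-layout tables with known ground truth
#'
#' Simulates demographics, independent (or copula-correlated) drug exposures,
#' and events whose log-odds are `baseline + sum(drug effects) + covariate
#' effects`, then emits DRUG/REAC/DEMO tibbles in the layout that
#' [read_jader_table()] produces, with configured missingness and exact
#' duplicate rows. Fully reproducible from the config's seed.
#'
#' @param config A [synth_config()].
#' @return A `synth_reports` list with elements `drug`, `reac`, `demo`
#'   (tibbles) and `truth` (per-case latent exposure/event indicator matrices,
#'   the true demographics, and the designed odds ratios).
#' @export
simulate_reports <- function(config) {
  validate_synth_config(config)
  set.seed(config$seed)
  n <- config$n_cases
  drug_names <- config$drugs$name
  k <- length(drug_names)
  m <- length(config$events)
  case_id <- sprintf("C%08d", seq_len(n))

  female <- rbinom(n, 1L, config$p_female)
  sex_chr <- ifelse(female == 1L, "female", "male")
  age <- rnorm_trunc(n, config$age_mean, config$age_sd, 0, 100)
  hm <- config$height_mean[sex_chr]
  hs <- config$height_sd[sex_chr]
  height <- rnorm(n, hm, hs)
  wm <- config$weight_mean[sex_chr] +
    config$hw_cor * (config$weight_sd[sex_chr] / hs) * (height - hm)
  ws <- sqrt(1 - config$hw_cor^2) * config$weight_sd[sex_chr]
  weight <- pmax(rnorm(n, wm, ws), 2)

  if (is.null(config$exposure_corr)) {
    expo <- matrix(rbinom(n * k, 1L, rep(config$drugs$p_exposure, each = n)),
                   nrow = n, ncol = k)
  } else {
    z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = config$exposure_corr)
    expo <- 1L * (z < matrix(qnorm(config$drugs$p_exposure),
                             nrow = n, ncol = k, byrow = TRUE))
  }
  colnames(expo) <- drug_names

  eff <- matrix(0, nrow = k, ncol = m, dimnames = list(drug_names, config$events))
  if (nrow(config$drug_effects) > 0) {
    eff[cbind(config$drug_effects$drug, config$drug_effects$event)] <-
      config$drug_effects$log_or
  }
  ce <- config$covariate_effects
  eta_cov <- ce$female * female +
    ce$age_per_year * (age - config$age_ref) +
    ce$height_per_cm * (height - config$height_ref)
  eta <- expo %*% eff + config$baseline_event_logit + eta_cov
  ev <- matrix(rbinom(n * m, 1L, plogis(eta)), nrow = n, ncol = m)
  colnames(ev) <- config$events

  idx <- which(expo == 1L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  drug_tbl <- tibble::tibble(
    case_id = case_id[idx[, 1L]],
    drug_name = drug_names[idx[, 2L]],
    involvement = "suspected"
  )
  if (config$concomitant_rate > 0) {
    con <- which(rbinom(n, 1L, config$concomitant_rate) == 1L)
    if (length(con) > 0) {
      drug_tbl <- dplyr::bind_rows(drug_tbl, tibble::tibble(
        case_id = case_id[con],
        drug_name = sample(drug_names, length(con), replace = TRUE),
        involvement = "concomitant"
      ))
      drug_tbl <- dplyr::arrange(drug_tbl, .data$case_id)
    }
  }
  ridx <- which(ev == 1L, arr.ind = TRUE)
  ridx <- ridx[order(ridx[, 1L], ridx[, 2L]), , drop = FALSE]
  reac_tbl <- tibble::tibble(
    case_id = case_id[ridx[, 1L]],
    pt_name = config$events[ridx[, 2L]]
  )

  dup_rows <- function(tbl, rate) {
    ndup <- floor(rate * nrow(tbl))
    if (ndup < 1L || nrow(tbl) == 0L) return(tbl)
    dplyr::bind_rows(tbl, tbl[sample.int(nrow(tbl), ndup, replace = TRUE), ])
  }
  drug_tbl <- dup_rows(drug_tbl, config$duplicate_rate)
  reac_tbl <- dup_rows(reac_tbl, config$duplicate_rate)

  miss <- function(x, p) {
    if (p <= 0) return(x)
    x[rbinom(length(x), 1L, p) == 1L] <- NA
    x
  }
  age_out <- if (config$age_as_band) {
    paste0(10 * floor(age / 10), "s")
  } else {
    formatC(age, digits = 1, format = "f")
  }
  weight_out <- dplyr::case_when(
    weight > 60 ~ ">60 kg",
    weight < 10 ~ "<10 kg",
    .default = as.character(round(weight))
  )
  demo_tbl <- tibble::tibble(
    case_id = case_id,
    sex = miss(sex_chr, config$missingness$sex),
    age_band = miss(age_out, config$missingness$age),
    height_cm = miss(round(height), config$missingness$height),
    weight_raw = miss(weight_out, config$missingness$weight)
  )

  designed <- tidyr::expand_grid(drug = drug_names, event = config$events) |>
    dplyr::left_join(config$drug_effects, by = c("drug", "event")) |>
    dplyr::mutate(odds_ratio = exp(dplyr::coalesce(.data$log_or, 0)),
                  log_or = dplyr::coalesce(.data$log_or, 0))

  structure(
    list(
      drug = drug_tbl, reac = reac_tbl, demo = demo_tbl,
      truth = list(
        exposure = expo, event = ev,
        demographics = tibble::tibble(case_id = case_id, female = female,
                                      age = age, height = height,
                                      weight = weight),
        designed_or = designed,
        config = config
      )
    ),
    class = "synth_reports"
  )
}

#' Write simulated tables to disk
#'
#' Emits `drug.csv`, `reac.csv`, `demo.csv` in the dialect that
#' [read_jader_table()] reads with the default column map, plus
#' `ground_truth.json` with the designed odds ratios and the full seedable
#' configuration summary.
#'
#' @param sim A `synth_reports` object from [simulate_reports()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths.
#' @export
write_tables <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory '%s'.", out_dir))
  }
  paths <- c(
    drug = file.path(out_dir, "drug.csv"),
    reac = file.path(out_dir, "reac.csv"),
    demo = file.path(out_dir, "demo.csv"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_jader_table(sim$drug, paths[["drug"]], "DRUG")
  write_jader_table(sim$reac, paths[["reac"]], "REAC")
  write_jader_table(sim$demo, paths[["demo"]], "DEMO")
  truth <- list(
    n_cases = sim$truth$config$n_cases,
    seed = sim$truth$config$seed,
    designed_or = sim$truth$designed_or
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
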