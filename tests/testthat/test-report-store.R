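test_that("read_jader_table parses the three table kinds and tolerates bad numerics", {
  dir <- withr::local_tempdir()
  drug_path <- file.path(dir, "drug.csv")
  writeLines(c(
    "case_id,drug_name,involvement",
    "A1,zoledronate,suspected",
    "A1,aspirin,concomitant",
    "A2,warfarin,interaction"
  ), drug_path)
  drug <- read_jader_table(drug_path, "DRUG")
  expect_equal(nrow(drug), 3L)
  expect_equal(drug$involvement, c("suspected", "concomitant", "interaction"))

  demo_path <- file.path(dir, "demo.csv")
  writeLines(c(
    "case_id,sex,age_band,height_cm,weight_raw",
    "A1,female,70s,,52",
    "A2,male,40s,not-a-number,>60 kg"
  ), demo_path)
  demo <- read_jader_table(demo_path, "DEMO")
  expect_true(is.na(demo$height_cm[1]))
  expect_true(is.na(demo$height_cm[2]))
  expect_equal(demo$weight_raw[2], ">60 kg")

  expect_error(read_jader_table(file.path(dir, "nope.csv"), "DRUG"),
               "not found")
  bad <- file.path(dir, "bad.csv")
  writeLines(c("case_id,drug", "A1,x"), bad)
  expect_error(read_jader_table(bad, "DRUG"), "drug_name")
})

test_that("generator tables survive a write/read round trip field-for-field", {
  sim <- simulate_reports(synth_config(n_cases = 9000, seed = 303,
                                       duplicate_rate = 0.1))
  expect_gt(nrow(sim$drug), 1000)
  dir <- withr::local_tempdir()
  paths <- write_tables(sim, dir)
  expect_equal(read_jader_table(paths[["drug"]], "DRUG"), sim$drug)
  expect_equal(read_jader_table(paths[["reac"]], "REAC"), sim$reac)
  demo_rt <- read_jader_table(paths[["demo"]], "DEMO")
  expect_equal(demo_rt$height_cm, sim$demo$height_cm)
  expect_equal(demo_rt[c("case_id", "sex", "age_band", "weight_raw")],
               sim$demo[c("case_id", "sex", "age_band", "weight_raw")])
})

test_that("filter_suspected keeps exactly the suspected rows, in order", {
  rows <- tibble::tibble(
    case_id = c("A", "A", "B"),
    drug_name = c("d1", "d2", "d3"),
    involvement = c("suspected", "concomitant", "interaction")
  )
  expect_equal(filter_suspected(rows)$drug_name, "d1")
  expect_equal(nrow(filter_suspected(rows[0, ])), 0L)

  set.seed(5)
  inv <- sample(c("suspected", "concomitant", "interaction"), 100,
                replace = TRUE, prob = c(0.4, 0.4, 0.2))
  big <- tibble::tibble(case_id = as.character(1:100),
                        drug_name = "x", involvement = inv)
  kept <- filter_suspected(big)
  expect_equal(nrow(kept), sum(inv == "suspected"))
  expect_true(all(kept$case_id %in% big$case_id))
  expect_equal(kept$case_id, big$case_id[big$involvement == "suspected"])
})

test_that("deduplicate collapses exact and within-case duplicates and is idempotent", {
  drug <- tibble::tibble(
    case_id = c("A", "A", "A", "B"),
    drug_name = c("d1", "d1", "d1", "d1"),
    involvement = c("suspected", "suspected", "concomitant", "suspected")
  )
  out <- deduplicate(drug)
  expect_equal(nrow(out), 2L)   # one (A, d1), one (B, d1)

  reac <- tibble::tibble(case_id = c("A", "A"), pt_name = c("pt1", "pt1"))
  expect_equal(nrow(deduplicate(reac)), 1L)

  set.seed(6)
  rnd <- tibble::tibble(
    case_id = sample(LETTERS[1:5], 60, TRUE),
    pt_name = sample(c("p", "q", "r"), 60, TRUE)
  )
  once <- deduplicate(rnd)
  expect_identical(deduplicate(once), once)
  expect_true(all(vapply(split(once$pt_name, once$case_id),
                         anyDuplicated, integer(1L)) == 0L))
})

test_that("merge_cases aggregates drug/event sets, outer-joins on DEMO, and flags bad DEMO", {
  drug <- tibble::tibble(case_id = c("A", "A"), drug_name = c("d1", "d2"),
                         involvement = "suspected")
  reac <- tibble::tibble(case_id = c("A", "A", "A"),
                         pt_name = c("p1", "p2", "p3"))
  demo <- tibble::tibble(case_id = c("A", "B"), sex = "female",
                         age_band = "70s", height_cm = c(150, 160),
                         weight_raw = c("52", "48"))
  cases <- merge_cases(drug, reac, demo)
  expect_equal(nrow(cases), 2L)
  expect_equal(lengths(cases$drugs), c(2L, 0L))
  expect_equal(lengths(cases$events), c(3L, 0L))
  expect_equal(cases$age_years, c(75, 75))
  expect_equal(cases$bmi, c(52 / 1.5^2, 48 / 1.6^2))

  expect_error(merge_cases(drug, reac, demo[c(1, 1), ]), "duplicate case_id")
})

test_that("merge then split: the (case, drug) pairs equal the suspected input pairs", {
  sim <- simulate_reports(synth_config(n_cases = 500, seed = 99,
                                       duplicate_rate = 0.15,
                                       concomitant_rate = 0.2))
  drug <- deduplicate(filter_suspected(sim$drug))
  reac <- deduplicate(sim$reac)
  cases <- merge_cases(drug, reac, sim$demo)

  out_pairs <- tidyr::unnest(cases[c("case_id", "drugs")], "drugs")
  expect_setequal(
    paste(out_pairs$case_id, out_pairs$drugs),
    paste(drug$case_id, drug$drug_name)
  )
  # per-case set sizes match the generator's latent indicators
  truth_sizes <- rowSums(sim$truth$exposure)
  names(truth_sizes) <- sim$truth$demographics$case_id
  expect_equal(unname(truth_sizes[cases$case_id]),
               as.double(lengths(cases$drugs)))
  expect_equal(unname(rowSums(sim$truth$event)[match(cases$case_id,
                                                     sim$truth$demographics$case_id)]),
               as.double(lengths(cases$events)))
})

test_that("weight and age recoding follow the band rules", {
  expect_equal(recode_weight(">60 kg"), 65)
  expect_equal(recode_weight("<10 kg"), 5)
  expect_equal(recode_weight(52), 52)
  expect_equal(recode_weight("70"), 65)
  expect_equal(recode_weight(c("8", "junk")), c(5, NA_real_))

  expect_equal(recode_age_band(c("70s", "0s", "42", "unknown")),
               c(75, 5, 42, NA_real_))
})

test_that("clean_bmi removes only computable outliers and conserves counts", {
  n <- c(low = 8, high = 1164, ok = 10, missing = 4)
  heights <- c(rep(160, n["low"]), rep(10, n["high"]), rep(160, n["ok"]),
               rep(NA_real_, n["missing"]))
  weights <- c(rep(12, n["low"]), rep(50, n["high"]), rep(55, n["ok"]),
               rep(50, n["missing"]))
  cases <- make_cases(rep(list(character()), sum(n)),
                      rep(list(character()), sum(n)),
                      height = heights, weight = weights)
  cleaned <- clean_bmi(cases)
  rep <- cleaning_report(cleaned)
  expect_equal(rep$n_removed_low_bmi, 8L)
  expect_equal(rep$n_removed_high_bmi, 1164L)
  expect_equal(rep$n_removed_low_bmi + rep$n_removed_high_bmi, 1172L)
  expect_equal(rep$n_output, 14L)  # valid + missing-BMI kept
  expect_equal(rep$n_input, rep$n_output + rep$n_removed_low_bmi +
                 rep$n_removed_high_bmi)

  # boundary: bmi = 100.0 exactly is removed, bmi = 4.999 is removed
  edge <- make_cases(list(character()), list(character()),
                     height = c(70, 200), weight = c(49, 19.99))
  expect_equal(cleaning_report(clean_bmi(edge))$n_output, 0L)
  expect_error(clean_bmi(cases, low = 50, high = 50), "smaller")
})
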