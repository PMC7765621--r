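test_that("build_contingency partitions the cases correctly", {
  cases <- make_cases(
    drugs = list("D", "D", character(), character()),
    events = list("E", character(), "E", character())
  )
  ct <- build_contingency(cases, "D", "E")
  expect_equal(unlist(ct[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(ct$n, nrow(cases))

  ct0 <- build_contingency(cases, "never-reported", "E")
  expect_equal(ct0$a, 0)
  expect_equal(ct0$b, 0)

  # independent brute-force recount on generator output
  sim <- simulate_reports(synth_config(n_cases = 400, seed = 17))
  cs <- merge_cases(deduplicate(filter_suspected(sim$drug)),
                    deduplicate(sim$reac), sim$demo)
  ct2 <- build_contingency(cs, "zoledronate", "osteonecrosis of the jaw")
  hd <- sapply(cs$drugs, function(s) "zoledronate" %in% s)
  he <- sapply(cs$events, function(s) "osteonecrosis of the jaw" %in% s)
  expect_equal(ct2$a, sum(hd & he))
  expect_equal(ct2$b, sum(hd & !he))
  expect_equal(ct2$c, sum(!hd & he))
  expect_equal(ct2$d, sum(!hd & !he))
})

test_that("the half correction adds 0.5 to every cell unconditionally", {
  expect_equal(half_correct(contingency_table(0, 0, 0, 0)),
               c(a = 0.5, b = 0.5, c = 0.5, d = 0.5))
  expect_equal(half_correct(contingency_table(1, 2, 3, 4)),
               c(a = 1.5, b = 2.5, c = 3.5, d = 4.5))
  # corrected OR converges to the raw OR as cells scale up
  raw_or <- (3 * 40) / (7 * 11)
  scaled <- contingency_table(3e4, 7e4, 11e4, 40e4)
  expect_equal(ror(scaled)$ror, raw_or, tolerance = 1e-4)
})

test_that("ror matches direct arithmetic and its CI behaves", {
  expect_equal(ror(contingency_table(10, 10, 10, 10))$ror, 1.0)
  r <- ror(contingency_table(5, 10, 2, 100))
  expect_equal(r$ror, (5.5 * 100.5) / (10.5 * 2.5), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:50) {
    cells <- sample(0:30, 4, replace = TRUE)
    r1 <- ror(do.call(contingency_table, as.list(cells)))
    expect_true(r1$ci_low <= r1$ror && r1$ror <= r1$ci_high)
    r10 <- ror(do.call(contingency_table, as.list(cells * 10)))
    expect_lt(log(r10$ci_high / r10$ci_low), log(r1$ci_high / r1$ci_low))
  }
})

test_that("ror is monotone in the expected cell directions", {
  base <- c(a = 5, b = 7, c = 6, d = 9)
  r0 <- ror(do.call(contingency_table, as.list(base)))$ror
  bump <- function(cell) {
    cells <- base
    cells[cell] <- cells[cell] + 1
    ror(do.call(contingency_table, as.list(cells)))$ror
  }
  expect_gt(bump("a"), r0)
  expect_gt(bump("d"), r0)
  expect_lt(bump("b"), r0)
  expect_lt(bump("c"), r0)
})

test_that("fisher_exact reproduces exact enumeration and known values", {
  expect_equal(fisher_exact(contingency_table(3, 1, 1, 3)), 34 / 70,
               tolerance = 1e-12)
  # most probable table with proportional rows: p = 1
  expect_equal(fisher_exact(contingency_table(2, 2, 2, 2)), 1.0)
  expect_error(fisher_exact(contingency_table(1.5, 2, 3, 4)), "integer")

  set.seed(77)
  for (i in 1:100) {
    cells <- as.list(sample(0:25, 4, replace = TRUE))
    ct <- do.call(contingency_table, cells)
    p <- fisher_exact(ct)
    expect_equal(p, do.call(fisher_oracle, cells), tolerance = 1e-12)
    # independent library cross-check
    m <- matrix(unlist(cells), 2, byrow = TRUE)
    expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("fisher p is invariant under transpose and row/column swaps", {
  set.seed(78)
  for (i in 1:25) {
    cells <- sample(0:20, 4, replace = TRUE)
    p0 <- fisher_exact(contingency_table(cells[1], cells[2], cells[3], cells[4]))
    pt <- fisher_exact(contingency_table(cells[1], cells[3], cells[2], cells[4]))
    ps <- fisher_exact(contingency_table(cells[4], cells[3], cells[2], cells[1]))
    expect_equal(p0, pt, tolerance = 1e-12)
    expect_equal(p0, ps, tolerance = 1e-12)
  }
})

test_that("detect_signals recovers a planted association and orders output", {
  cfg <- synth_config(
    n_cases = 30000, seed = 88,
    drugs = tibble::tibble(name = c("planted", "inert"),
                           p_exposure = c(0.05, 0.05)),
    events = "target event",
    baseline_event_logit = qlogis(0.01),
    drug_effects = tibble::tibble(drug = "planted", event = "target event",
                                  log_or = log(20)),
    covariate_effects = list(female = 0, age_per_year = 0, height_per_cm = 0)
  )
  sim <- simulate_reports(cfg)
  cases <- merge_cases(deduplicate(filter_suspected(sim$drug)),
                       deduplicate(sim$reac), sim$demo)
  sig <- detect_signals(cases, event_terms = "target event")
  expect_true(sig$is_signal[sig$drug == "planted"])
  expect_equal(sig$drug[1], "planted")
  expect_equal(order(sig$n_reports, decreasing = TRUE), seq_len(nrow(sig)))
  expect_equal(sig$reporting_ratio,
               100 * sig$n_reports / attr(sig, "n_event_total"))
})

test_that("under the null the signal fraction stays near the test size", {
  cfg <- synth_config(
    n_cases = 20000, seed = 1234,
    drugs = tibble::tibble(name = sprintf("d%03d", 1:100), p_exposure = 0.03),
    events = "ev",
    baseline_event_logit = qlogis(0.05),
    drug_effects = tibble::tibble(drug = character(), event = character(),
                                  log_or = double()),
    covariate_effects = list(female = 0, age_per_year = 0, height_per_cm = 0),
    duplicate_rate = 0,
    missingness = list(sex = 0, age = 0, height = 0, weight = 0)
  )
  sim <- simulate_reports(cfg)
  cases <- merge_cases(deduplicate(filter_suspected(sim$drug)),
                       deduplicate(sim$reac), sim$demo)
  sig <- detect_signals(cases, event_terms = "ev")
  # two-sided test + one-sided ROR criterion: expect roughly alpha/2 flags
  expect_lte(mean(sig$is_signal), 0.10)
})

test_that("the signal criterion follows the Fisher p, not the Woolf CI", {
  # near the boundary the two can disagree: here the CI excludes 1 yet
  # p >= 0.05, so the pair is not flagged
  ct <- contingency_table(8, 8, 13, 44)
  r <- ror(ct)
  p <- fisher_exact(ct)
  expect_gt(r$ci_low, 1)
  expect_gte(p, 0.05)

  cases <- make_2x2_cases(8, 8, 13, 44)
  sig <- detect_signals(cases, event_terms = "eventY")
  expect_false(sig$is_signal[sig$drug == "drugX"])
})

test_that("volcano coordinates are exact transforms of the signal fields", {
  cases <- make_2x2_cases(6, 4, 10, 30)
  sig <- detect_signals(cases, event_terms = "eventY")
  expect_equal(exp(sig$ln_or), sig$ror, tolerance = 1e-12)
  expect_equal(sig$neg_log10_p, -log10(sig$p_fisher), tolerance = 1e-12)
  v <- volcano_table(sig)
  expect_named(v, c("drug", "ln_or", "neg_log10_p", "n_reports"))
  expect_equal(attr(v, "threshold"), -log10(0.05), tolerance = 1e-12)
  expect_equal(-log10(0.05), 1.30103, tolerance = 1e-5)

  expect_warning(out <- detect_signals(make_cases(list(), list())[0, ],
                                       event_terms = "x"), "Empty")
  expect_equal(nrow(out), 0L)
})
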