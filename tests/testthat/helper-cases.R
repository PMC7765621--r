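# Build a case tibble directly, bypassing the file layer: `drugs` and
# `events` are lists of character vectors, recycled demographics fill in.
make_cases <- function(drugs, events, sex = "female", age = 60,
                       height = 155, weight = 52) {
  n <- max(length(drugs), length(events))
  weight_kg <- recode_weight(rep_len(weight, n))
  height_cm <- rep_len(height, n)
  tibble::tibble(
    case_id = sprintf("T%04d", seq_len(n)),
    sex = rep_len(sex, n),
    age_years = rep_len(age, n),
    height_cm = height_cm,
    weight_kg = weight_kg,
    bmi = weight_kg / (height_cm / 100)^2,
    drugs = rep_len(drugs, n),
    events = rep_len(events, n)
  )
}

# A compact case table where `n_both` cases carry drug and event, then
# `n_drug_only`, `n_event_only`, `n_neither` fill the other cells.
make_2x2_cases <- function(n_both, n_drug_only, n_event_only, n_neither,
                           drug = "drugX", event = "eventY") {
  drugs <- c(rep(list(drug), n_both + n_drug_only),
             rep(list(character()), n_event_only + n_neither))
  events <- c(rep(list(event), n_both), rep(list(character()), n_drug_only),
              rep(list(event), n_event_only), rep(list(character()), n_neither))
  make_cases(drugs, events)
}

# Independent brute-force Fisher oracle: enumerate the whole hypergeometric
# support with lchoose-based probabilities (no dhyper), two-sided by the
# probability-mass rule with the conventional 1e-7 relative tie tolerance.
fisher_oracle <- function(a, b, c, d) {
  row1 <- a + b
  row2 <- c + d
  col1 <- a + c
  n <- row1 + row2
  support <- max(0, col1 - row2):min(row1, col1)
  logp <- lchoose(row1, support) + lchoose(row2, col1 - support) -
    lchoose(n, col1)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# deterministic pair of unit-variance columns with an exact sample correlation
make_corr_pair <- function(n = 12, r = 0.5) {
  x <- scale(seq_len(n))[, 1]
  e <- stats::resid(stats::lm(rnorm(n) ~ x))
  e <- e / sd(e) * sqrt(1 - r^2)
  y <- r * x + e
  cbind(v1 = x, v2 = y)
}
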