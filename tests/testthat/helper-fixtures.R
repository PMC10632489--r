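# Shared fixtures: exact F-18 constants and small constructors used across
# the suite. All expected values in tests were derived from these constants
# (lambda = ln2 * 60 / 109.77 per hour), not from rounded literature figures.

f18 <- isotope_f18()
lambda_f18 <- f18$lambda_per_h          # 0.3788744 /h
total_tau_f18 <- f18$total_residence_h  # 2.6394 h

# a flat decay-corrected TAC turned into the decay-uncorrected curve the
# residence-time stage expects
make_exponential_tac <- function(organ = "liver", a0 = 100, n = 7,
                                 t_end_min = 120, lambda = lambda_f18) {
  sched <- schedule_uniform(n, t_end_min)
  t_h <- (sched$start_min + sched$end_min) / 2 / 60
  tac(organ, sched, a0 * exp(-lambda * t_h), decay_corrected = FALSE)
}

# long-format residence values for compare_tables tests
make_long <- function(subjects, organs, values, sexes = "male") {
  grid <- expand.grid(organ = organs, subject = subjects,
                      stringsAsFactors = FALSE)
  grid$sex <- rep(sexes, length.out = length(subjects))[
    match(grid$subject, subjects)]
  grid$value <- values
  grid[c("subject", "sex", "organ", "value")]
}
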