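test_that("organ activity has the right boundary behaviour", {
  kin0 <- organ_kinetics(0, 3, 0.3, "washout")
  expect_equal(organ_activity(kin0, c(0, 0.5, 2), 100, f18), rep(0, 3))
  kin <- organ_kinetics(0.4, 3, 0.3, "washout")
  expect_equal(organ_activity(kin, 0, 100, f18), 0)   # no instantaneous uptake
  acc <- organ_kinetics(0.5, 1e6, mode = "accumulation")
  # saturating uptake: activity approaches ID * f * e^(-lambda t)
  t <- c(0.5, 1, 2)
  expect_equal(organ_activity(acc, t, 100, f18),
               100 * 0.5 * exp(-lambda_f18 * t), tolerance = 1e-6)
  expect_true(all(organ_activity(kin, seq(0, 3, 0.1), 100, f18) >= 0))
})

test_that("degenerate and invalid kinetics are rejected", {
  expect_error(organ_kinetics(0.5, 2, 2, "washout"), "degenerate")
  expect_error(organ_kinetics(0.5, 2, 3, "washout"), "k_u > k_c")
  expect_error(organ_kinetics(1.2, 2), "f")
  expect_error(organ_kinetics(0.5, -1), "k_u")
})

test_that("analytic tau equals the numeric integral of organ activity", {
  cases <- list(
    organ_kinetics(0.4, 3, 0.3, "washout"),
    organ_kinetics(0.2, 3.0, 0, "washout"),
    organ_kinetics(0.072, 8, 4, "washout"),
    organ_kinetics(0.4, 2.5, mode = "accumulation"),
    organ_kinetics(0.3, 20, mode = "accumulation")
  )
  for (kin in cases) {
    numeric_tau <- stats::integrate(
      function(t) organ_activity(kin, t, 1, f18), 0, Inf,
      rel.tol = 1e-11)$value
    expect_equal(analytic_tau(kin, f18), numeric_tau, tolerance = 1e-8)
  }
  # frozen spot values from the numeric-integration oracle above
  expect_equal(analytic_tau(organ_kinetics(0.4, 3, 0.3, "washout"), f18),
               0.52316, tolerance = 1e-4)
  expect_equal(analytic_tau(organ_kinetics(0.5, 1e6, mode = "accumulation"), f18),
               0.5 / lambda_f18, tolerance = 1e-5)
  expect_equal(0.5 / lambda_f18, 1.31971, tolerance = 1e-5)
  expect_equal(analytic_tau(organ_kinetics(0, 3), f18), 0)
})

test_that("noiseless simulation equals the kinetic model exactly at midpoints", {
  sim <- simulate_subject("hepatobiliary", schedule_t807(), 246.3,
                          noise_model(cv = 0, seed = 99))
  kin <- preset_kinetics("hepatobiliary")
  t_h <- frame_midpoints(schedule_t807()) / 60
  for (org in names(kin)) {
    expect_equal(sim$subject$tacs[[org]]$activity,
                 organ_activity(kin[[org]], t_h, 246.3, f18),
                 tolerance = 1e-12)
    expect_false(sim$subject$tacs[[org]]$decay_corrected)
  }
})

test_that("identical seeds reproduce identical subjects bit for bit", {
  s1 <- simulate_subject("renal", schedule_mefway(), 226,
                         noise_model(cv = 0.1, seed = 7))
  s2 <- simulate_subject("renal", schedule_mefway(), 226,
                         noise_model(cv = 0.1, seed = 7))
  expect_identical(s1, s2)
  s3 <- simulate_subject("renal", schedule_mefway(), 226,
                         noise_model(cv = 0.1, seed = 8))
  expect_false(identical(s1$subject$tacs$liver$activity,
                         s3$subject$tacs$liver$activity))
})

test_that("the bladder fills monotonically in the renal preset", {
  sim <- simulate_subject("renal", schedule_mefway(), 226,
                          noise_model(cv = 0, seed = 1))
  bl <- sim$subject$tacs$urinary_bladder
  corrected <- decay_correct(bl, f18)
  expect_true(all(diff(corrected$activity) > 0))
})

test_that("preset fractions leave a positive remainder and the expected ranking", {
  for (preset in c("hepatobiliary", "renal")) {
    kin <- preset_kinetics(preset)
    f_sum <- sum(vapply(kin, `[[`, numeric(1), "f"))
    expect_lte(f_sum, 1)
    tau <- vapply(kin, analytic_tau, numeric(1), isotope = f18)
    expect_gte(remainder_of_body(tau, f18), 0)
    if (preset == "hepatobiliary") {
      expect_gt(tau[["liver"]], 5 * tau[["lungs"]])   # liver >> lungs
      expect_gt(tau[["lungs"]], tau[["brain"]])
    } else {
      expect_gt(tau[["urinary_bladder"]], 2 * tau[["liver"]])  # bladder >> liver
    }
  }
})

test_that("across-seed mean of noisy tau estimates matches the noiseless estimate", {
  sched <- schedule_mefway()
  noiseless <- residence_table(
    simulate_subject("renal", sched, 226, noise_model(cv = 0, seed = 1))$subject)
  liver_ref <- noiseless$tau_h[noiseless$organ == "liver"]
  taus <- vapply(1:100, function(s) {
    rt <- residence_table(
      simulate_subject("renal", sched, 226,
                       noise_model(cv = 0.05, seed = s))$subject)
    rt$tau_h[rt$organ == "liver"]
  }, numeric(1))
  se <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - liver_ref), 2 * se + 1e-12)
})
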