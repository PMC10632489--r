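test_that("trapezoid matches hand-computed areas and validates input", {
  expect_equal(trapezoid_auc(c(0, 1), c(10, 10)), 10)
  expect_equal(trapezoid_auc(c(0, 2), c(0, 4)), 4)
  expect_equal(trapezoid_auc(c(0, 1), c(100, 68.466)), 84.233)
  # additivity over a split interval
  t <- c(0, 0.5, 1, 2); a <- c(3, 7, 2, 9)
  expect_equal(trapezoid_auc(t, a),
               trapezoid_auc(t[1:2], a[1:2]) + trapezoid_auc(t[2:4], a[2:4]))
  expect_error(trapezoid_auc(1, 5), "at least 2")
  expect_error(trapezoid_auc(c(0, 1, 1), c(1, 2, 3)), "strictly increasing")
  expect_error(trapezoid_auc(c(0, 2, 1), c(1, 2, 3)), "strictly increasing")
})

test_that("physical-decay tail is A/lambda and zero for zero activity", {
  expect_equal(tail_area(2, 50, f18, tail_method("physical")),
               50 / lambda_f18)
  expect_equal(50 / lambda_f18, 131.9706, tolerance = 1e-6)
  expect_equal(tail_area(5, 0, f18, tail_method("physical")), 0)
  expect_equal(tail_area(5, 0, f18, tail_method("expfit")), 0)
})

test_that("exponential tail fit recovers the rate of a noiseless exponential", {
  # samples exactly on 100 e^(-2 lambda t): fitted rate 2*lambda (above the
  # physical floor), so the tail is A_last / (2 lambda)
  t <- c(1.0, 1.5, 2.0)
  a <- 100 * exp(-2 * lambda_f18 * t)
  got <- tail_area(2, a[3], f18, tail_method("expfit", 3),
                   recent_samples = list(times = t, activities = a))
  expect_equal(got, a[3] / (2 * lambda_f18), tolerance = 1e-10)
})

test_that("tail fit floors at physical decay and falls back on bad fits", {
  t <- c(1.0, 1.5, 2.0)
  # clearance slower than physical: floor to physical lambda
  a_slow <- 100 * exp(-0.1 * t)
  got <- tail_area(2, a_slow[3], f18, tail_method("expfit", 3),
                   recent_samples = list(times = t, activities = a_slow))
  expect_equal(got, a_slow[3] / lambda_f18)
  # rising activity: non-positive fitted rate, fallback with a warning
  a_rise <- c(10, 20, 40)
  expect_warning(
    got <- tail_area(2, 40, f18, tail_method("expfit", 3),
                     recent_samples = list(times = t, activities = a_rise)),
    "non-positive")
  expect_equal(got, 40 / lambda_f18)
  expect_error(tail_area(2, 40, f18, tail_method("expfit", 3),
                         recent_samples = list(times = t[1:2],
                                               activities = a_rise[1:2])),
               "last 3 samples")
  expect_error(tail_method("expfit", 1), "k_points >= 2")
})

test_that("residence time of the full injected dose is the theoretical total", {
  # all injected activity in one organ, decaying physically: tau = T1/2 / ln2
  tiny <- frame_schedule(0, 1e-6)
  x <- tac("body", tiny, 100, decay_corrected = FALSE)
  tau <- residence_time(x, 100, f18, leading_ramp = FALSE)
  expect_equal(as.numeric(tau), total_tau_f18, tolerance = 1e-6)
  expect_equal(round(as.numeric(tau), 2), 2.64)
})

test_that("residence time is zero for an empty organ and scale-invariant", {
  sched <- schedule_mefway()
  zero <- tac("gallbladder", sched, rep(0, 5), decay_corrected = FALSE)
  expect_equal(as.numeric(residence_time(zero, 200, f18)), 0)
  x <- make_exponential_tac(n = 5)
  t1 <- residence_time(x, 100, f18)
  x2 <- tac(x$organ, x$schedule, x$activity * 3.7, decay_corrected = FALSE)
  t2 <- residence_time(x2, 370, f18)
  expect_equal(as.numeric(t1), as.numeric(t2), tolerance = 1e-12)
})

test_that("decay-corrected input is refused by the residence stage", {
  x <- tac("liver", schedule_mefway(), rep(10, 5), decay_corrected = TRUE)
  expect_error(residence_time(x, 100, f18), "decay_uncorrect")
})

test_that("increasing any activity sample never decreases tau", {
  x <- make_exponential_tac(n = 7)
  base <- as.numeric(residence_time(x, 100, f18))
  for (i in seq_along(x$activity)) {
    a <- x$activity
    a[i] <- a[i] * 1.25
    bumped <- as.numeric(residence_time(
      tac(x$organ, x$schedule, a, FALSE), 100, f18))
    expect_gte(bumped, base)
  }
})

test_that("trapezoid + physical tail converges to the analytic integral at second order", {
  # noiseless mono-exponential at the physical rate, point samples from t=0:
  # the only numerical error is the trapezoid's, O(h^2)
  tau_hat <- function(n) {
    t <- seq(0, 2, length.out = n)
    a <- 100 * exp(-lambda_f18 * t)
    (trapezoid_auc(t, a) +
       tail_area(2, a[n], f18, tail_method("physical"))) / 100
  }
  err <- abs(c(tau_hat(50), tau_hat(100)) - total_tau_f18) / total_tau_f18
  expect_lt(err[1], 0.001)
  expect_gt(err[1] / err[2], 3.5)   # halving h divides the error by ~4
  expect_lt(err[1] / err[2], 4.7)
})

test_that("physical tail bounds the true remaining integral for cleared organs", {
  # organs with genuine biological clearance (washout, k_c > 0) clear at
  # least as fast as physical decay beyond the last frame, so
  # A_last / lambda >= integral of the true curve beyond T. (k_c = 0
  # trapping still approaches saturation there and is excluded.)
  for (kc in c(0.25, 0.5, 2, 4)) {
    kin <- organ_kinetics(0.3, k_u = 6, k_c = kc, mode = "washout")
    T_last <- 1.7
    a_last <- organ_activity(kin, T_last, 100, f18)
    tail_phys <- tail_area(T_last, a_last, f18, tail_method("physical"))
    true_remaining <- stats::integrate(
      function(t) organ_activity(kin, t, 100, f18),
      T_last, Inf, rel.tol = 1e-10)$value
    expect_gte(tail_phys, true_remaining - 1e-9)
  }
})

test_that("remainder of body closes against the theoretical total", {
  expect_equal(remainder_of_body(numeric(0), f18), total_tau_f18)
  expect_equal(round(remainder_of_body(numeric(0), f18), 2), 2.64)
  expect_equal(remainder_of_body(total_tau_f18, f18), 0)
  # summed source-organ residence times of a hepatobiliary study: 1.048 h
  taus <- c(0.052, 0.015, 0.191, 0.518, 0.001, 0.130, 0.027, 0.114)
  expect_equal(sum(taus), 1.048)
  expect_equal(remainder_of_body(taus, f18), total_tau_f18 - 1.048,
               tolerance = 1e-12)
  expect_equal(round(remainder_of_body(taus, f18), 4), 1.5914)
  expect_error(remainder_of_body(c(2, 1), f18), "exceeding")
  expect_error(remainder_of_body(c(-0.1, 0.5), f18), "non-negative")
})

test_that("residence tables satisfy the closure invariant by construction", {
  sims <- list(
    simulate_subject("hepatobiliary", schedule_t807(), 246.3,
                     noise_model(cv = 0.05, seed = 11)),
    simulate_subject("renal", schedule_mefway(), 226,
                     noise_model(cv = 0.1, seed = 12))
  )
  for (sim in sims) {
    for (ramp in c(TRUE, FALSE)) {
      rt <- residence_table(sim$subject, leading_ramp = ramp)
      expect_equal(sum(rt$tau_h), total_tau_f18, tolerance = 1e-9)
      expect_true(all(rt$tau_h >= 0))
      expect_identical(rt$organ[nrow(rt)], "remainder")
    }
  }
})

test_that("a no-organ subject yields a remainder-only table", {
  s <- subject("empty", "male", 100, f18, list())
  rt <- residence_table(s)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$tau_h, total_tau_f18)
})
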