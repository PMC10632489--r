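make_rt <- function(organ, tau_h, sex = "male", id = "s1",
                    injected = 100) {
  out <- data.frame(organ = organ, tau_h = tau_h, stringsAsFactors = FALSE)
  attr(out, "isotope") <- f18
  attr(out, "injected_MBq") <- injected
  attr(out, "subject_id") <- id
  attr(out, "sex") <- sex
  class(out) <- c("residence_table", "data.frame")
  out
}

test_that("S values assemble from absorbed fractions, dose constants and mass", {
  expect_equal(s_from_components(0.5, 2.0, 100), 0.01)
  expect_equal(s_from_components(c(0, 0), c(1, 2), 50), 0)
  expect_equal(s_from_components(c(0.3, 0.2), c(1, 2), 1), 0.7)
  expect_error(s_from_components(0.5, 2, 0), "positive")
  expect_error(s_from_components(1.2, 2, 10), "\\[0, 1\\]")
  expect_error(s_from_components(c(0.1, 0.2), 1, 10), "per emission type")
})

test_that("absorbed doses are tau-weighted sums of S values", {
  S <- svalue_table(matrix(0.003, 1, 1, dimnames = list("liver", "liver")))
  d <- absorbed_doses(make_rt("liver", 2), S)
  expect_equal(d$dose_uGy_per_MBq, 6)  # 2 h * 3 uGy/(MBq h)

  S2 <- svalue_table(matrix(c(0.003, 0.004), 1, 2,
                            dimnames = list("liver", c("liver", "lungs"))))
  d2 <- absorbed_doses(make_rt(c("liver", "lungs"), c(1, 2)), S2)
  expect_equal(d2$dose_uGy_per_MBq, 11)  # 1*3 + 2*4

  d0 <- absorbed_doses(make_rt(c("liver", "lungs"), c(0, 0)), S2)
  expect_equal(d0$dose_uGy_per_MBq, 0)
})

test_that("a residence organ missing from the S sources is a named error", {
  S <- svalue_table(matrix(0.01, 1, 1, dimnames = list("liver", "liver")))
  expect_error(absorbed_doses(make_rt(c("liver", "spleen"), c(1, 1)), S),
               "spleen")
})

test_that("the dose engine is linear and additive in residence times", {
  organs <- c("liver", "lungs", "brain", "remainder")
  S <- synthetic_svalue_table(organs, seed = 7)
  rt1 <- make_rt(organs, c(0.5, 0.2, 0.05, 1.8))
  rt2 <- make_rt(organs, c(0.1, 0.4, 0.02, 0.9))
  d1 <- absorbed_doses(rt1, S)$dose_uGy_per_MBq
  d2 <- absorbed_doses(rt2, S)$dose_uGy_per_MBq
  alpha <- 0.37
  d_scaled <- absorbed_doses(make_rt(organs, alpha * rt1$tau_h), S)
  expect_equal(d_scaled$dose_uGy_per_MBq, alpha * d1, tolerance = 1e-12)
  d_sum <- absorbed_doses(make_rt(organs, rt1$tau_h + rt2$tau_h), S)
  expect_equal(d_sum$dose_uGy_per_MBq, d1 + d2, tolerance = 1e-12)
})

test_that("synthetic S tables are reproducible and self-dose dominant", {
  organs <- c("liver", "lungs", "urinary_bladder")
  S1 <- synthetic_svalue_table(organs, seed = 42)
  S2 <- synthetic_svalue_table(organs, seed = 42)
  expect_identical(S1, S2)
  M <- unclass(S1)
  for (k in rownames(M)) {
    expect_gte(M[k, k], 10 * max(M[k, setdiff(colnames(M), k)]))
  }
  expect_true(all(M > 0))
  expect_true("remainder" %in% colnames(M))
})

test_that("built-in weighting schemes are normalised and carry published values", {
  for (nm in c("icrp103", "icrp60")) {
    sch <- weighting_scheme(nm)
    expect_equal(sum(sch$w_T), 1, tolerance = 1e-6)
    expect_true(all(sch$w_T >= 0))
    expect_equal(sch$w_R, 1)
  }
  w103 <- weighting_scheme("icrp103")$w_T
  expect_equal(w103[["urinary_bladder"]], 0.04)
  expect_equal(w103[["brain"]], 0.01)
  expect_equal(w103[["lungs"]], 0.12)
  expect_equal(weighting_scheme("icrp60")$w_T[["urinary_bladder"]], 0.05)
  expect_error(weighting_scheme_custom("bad", c(liver = 0.5, lungs = 0.4)),
               "sum to 1")
})

test_that("effective dose weights organ doses and handles partial coverage", {
  # bladder-only dose table: E = 0.04 * 100 under the default scheme
  d <- data.frame(organ = "urinary_bladder", dose_uGy_per_MBq = 100)
  expect_warning(e <- effective_dose(d), "contributing 0")
  expect_equal(e, 4.0)

  # uniform dose over every weighted tissue: normalisation gives E = d
  w <- weighting_scheme("icrp103")
  du <- data.frame(organ = names(w$w_T), dose_uGy_per_MBq = 7.3)
  expect_equal(effective_dose(du, w), 7.3, tolerance = 1e-12)

  d0 <- data.frame(organ = names(w$w_T), dose_uGy_per_MBq = 0)
  expect_equal(effective_dose(d0, w), 0)
})

test_that("effective dose is invariant under permuting tissue labels", {
  w <- weighting_scheme("icrp103")
  set.seed(3)
  d <- data.frame(organ = names(w$w_T),
                  dose_uGy_per_MBq = runif(length(w$w_T), 0, 50))
  perm <- sample(nrow(d))
  expect_equal(effective_dose(d, w), effective_dose(d[perm, ], w),
               tolerance = 1e-12)
})

test_that("organ-label synonyms resolve to weighted tissues", {
  w <- weighting_scheme("icrp103")
  d1 <- data.frame(organ = "lungs", dose_uGy_per_MBq = 10)
  d2 <- data.frame(organ = "Lung", dose_uGy_per_MBq = 10)
  expect_equal(suppressWarnings(effective_dose(d1, w)),
               suppressWarnings(effective_dose(d2, w)))
  d3 <- data.frame(organ = "Urinary bladder wall", dose_uGy_per_MBq = 100)
  expect_equal(suppressWarnings(effective_dose(d3, w)), 4.0)
})

test_that("compliance converts to mSv and fails only on strict excess", {
  chk <- compliance_check(22.47, 262.5)
  expect_equal(chk$total_mSv, 5.898, tolerance = 1e-3)
  expect_true(chk$pass_per_administration)
  expect_true(chk$pass_per_year)

  # exactly at the limit passes (strict-exceed convention)
  at_limit <- compliance_check(30, 1000)
  expect_equal(at_limit$total_mSv, 30)
  expect_true(at_limit$pass_per_administration)

  over <- compliance_check(200, 200)   # 40 mSv
  expect_equal(over$total_mSv, 40)
  expect_false(over$pass_per_administration)
  expect_true(over$pass_per_year)

  expect_error(dose_limits(60, 50), "per_year")
  expect_error(dose_limits(0, 50), "per_year|positive")
})
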