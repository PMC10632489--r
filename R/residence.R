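#' Trapezoidal area under a sampled curve
#'
#' Composite trapezoid rule over strictly increasing sample times. This is
#' the observed-window part of the cumulated activity: the integral of
#' decay-uncorrected organ activity over the imaging window.
#'
#' @param times Sample times in hours, strictly increasing, at least two.
#' @param activities Activities in MBq at those times, non-negative.
#' @return Area in MBq·h.
#' @examples
#' trapezoid_auc(c(0, 1), c(10, 10))  # 10
#' trapezoid_auc(c(0, 2), c(0, 4))    # 4 (triangle)
#' @export
trapezoid_auc <- function(times, activities) {
  if (length(times) < 2L) stop("trapezoid needs at least 2 samples")
  if (length(times) != length(activities)) {
    stop("times and activities must have equal length")
  }
  if (any(diff(times) <= 0)) stop("sample times must be strictly increasing")
  if (any(activities < 0)) stop("activities must be non-negative")
  dt <- diff(times)
  sum(dt * (activities[-length(activities)] + activities[-1L]) / 2)
}

#' Tail-extrapolation method for cumulated activity
#'
#' After the last image the curve is extrapolated to infinity either by pure
#' physical decay of the isotope (area \eqn{A_{last}/\lambda}) or by a
#' single exponential fitted by log-linear least squares to the last
#' `k_points` samples (area \eqn{A_{last}/\lambda_{fit}}). The fitted rate
#' is floored at the physical decay constant: measured (decay-uncorrected)
#' activity cannot clear slower than physical decay, and an unfloored slow
#' fit would inflate the tail without bound.
#'
#' @param method `"physical"` or `"expfit"`.
#' @param k_points Number of trailing samples used by the exponential fit;
#'   at least 2.
#' @return An object of class `tail_method`.
#' @export
tail_method <- function(method = c("physical", "expfit"), k_points = 3L) {
  method <- match.arg(method)
  k_points <- as.integer(k_points)
  if (method == "expfit" && k_points < 2L) {
    stop("exponential tail fit needs k_points >= 2")
  }
  structure(list(method = method, k_points = k_points), class = "tail_method")
}

#' Cumulated-activity tail from the last image to infinity
#'
#' @param last_time Time of the last sample, hours.
#' @param last_activity Activity at the last sample, MBq (>= 0).
#' @param isotope An [isotope()].
#' @param method A [tail_method()].
#' @param recent_samples For `"expfit"`: a list with `times` (hours) and
#'   `activities` (MBq) holding at least the trailing samples to fit;
#'   the last `k_points` are used. Ignored for `"physical"`.
#' @return Tail area in MBq·h.
#' @examples
#' tail_area(2, 50, isotope_f18(), tail_method("physical"))  # 50 / lambda
#' @export
tail_area <- function(last_time, last_activity, isotope,
                      method = tail_method("physical"),
                      recent_samples = NULL) {
  stopifnot(is_isotope(isotope), inherits(method, "tail_method"))
  if (!is.finite(last_activity) || last_activity < 0) {
    stop("last activity must be non-negative")
  }
  if (last_activity == 0) return(0)
  lambda_phys <- isotope$lambda_per_h
  if (method$method == "physical") {
    return(last_activity / lambda_phys)
  }
  # log-linear least squares on the last k samples
  k <- method$k_points
  if (is.null(recent_samples) || length(recent_samples$times) < k) {
    stop(sprintf("exponential tail fit needs the last %d samples", k))
  }
  n <- length(recent_samples$times)
  idx <- seq.int(n - k + 1L, n)
  t_fit <- recent_samples$times[idx]
  a_fit <- recent_samples$activities[idx]
  if (any(a_fit <= 0)) {
    warning("non-positive activities in tail-fit window; using physical decay")
    return(last_activity / lambda_phys)
  }
  slope <- stats::coef(stats::lm(log(a_fit) ~ t_fit))[[2L]]
  lambda_fit <- -slope
  if (!is.finite(lambda_fit) || lambda_fit <= 0) {
    warning("fitted tail clearance is non-positive; using physical decay")
    return(last_activity / lambda_phys)
  }
  # no slower-than-physical clearance
  lambda_fit <- max(lambda_fit, lambda_phys)
  last_activity / lambda_fit
}

#' Residence time of one organ
#'
#' The residence time \eqn{\tau} is the cumulated activity (number of
#' decays) per unit injected activity: the trapezoidal area over the
#' observed window plus the extrapolated tail, divided by the injected
#' dose. The input curve must be decay-uncorrected; passing a corrected
#' curve is an error rather than an implicit conversion, because the two
#' differ by the very decay factor the integral must contain.
#'
#' With `leading_ramp = TRUE` (default) the observed window is extended
#' from the first frame midpoint back to injection by a linear ramp from
#' `(0, 0)`: no tracer has reached any organ at the moment of injection.
#' Turning it off starts the integral at the first midpoint.
#'
#' @param x A decay-uncorrected [tac()].
#' @param injected_MBq Injected activity, MBq, positive.
#' @param isotope An [isotope()].
#' @param method A [tail_method()].
#' @param leading_ramp Include the zero-anchored leading segment?
#' @return Residence time in hours (a `cumulated_activity` attribute
#'   carries the window/tail decomposition in MBq·h).
#' @export
residence_time <- function(x, injected_MBq, isotope,
                           method = tail_method("physical"),
                           leading_ramp = TRUE) {
  stopifnot(inherits(x, "tac"), is_isotope(isotope))
  if (x$decay_corrected) {
    stop(sprintf("TAC for '%s' is decay-corrected; apply decay_uncorrect() first",
                 x$organ))
  }
  if (!is.numeric(injected_MBq) || injected_MBq <= 0) {
    stop("injected activity must be positive")
  }
  t_h <- min_to_h(frame_midpoints(x$schedule))
  a <- x$activity
  if (leading_ramp && t_h[1L] > 0) {
    t_h <- c(0, t_h)
    a <- c(0, a)
  }
  window <- if (length(t_h) >= 2L) trapezoid_auc(t_h, a) else 0
  n <- length(t_h)
  tail_a <- tail_area(t_h[n], a[n], isotope, method,
                      recent_samples = list(times = t_h, activities = a))
  tau <- (window + tail_a) / injected_MBq
  attr(tau, "cumulated_activity") <- c(window = window, tail = tail_a,
                                       total = window + tail_a)
  tau
}

#' Remainder-of-body residence time by closure
#'
#' For a non-excreting system every decay happens somewhere in the body, so
#' residence times over all compartments must sum to the theoretical total
#' \eqn{T_{1/2}/\ln 2} (2.6394 h for F-18). The remainder of body is that
#' total minus the summed source-organ residence times. A source-organ sum
#' exceeding the total is unphysical and raises an error.
#'
#' @param taus Numeric vector of source-organ residence times, hours,
#'   non-negative; may be empty.
#' @param isotope An [isotope()].
#' @return Remainder residence time in hours, >= 0.
#' @examples
#' remainder_of_body(numeric(0), isotope_f18())  # 2.6394
#' @export
remainder_of_body <- function(taus, isotope) {
  stopifnot(is_isotope(isotope))
  if (length(taus) && (any(!is.finite(taus)) || any(taus < 0))) {
    stop("residence times must be non-negative")
  }
  total <- isotope$total_residence_h
  s <- sum(taus)
  if (s > total + 1e-9) {
    stop(sprintf(
      "source-organ residence times sum to %.4f h, exceeding the theoretical total %.4f h",
      s, total))
  }
  max(total - s, 0)
}

#' Per-subject residence-time table with remainder closure
#'
#' Runs [residence_time()] for every organ TAC of a subject and appends the
#' remainder-of-body row, so the table satisfies
#' \eqn{\sum\tau + \tau_{remainder} = T_{1/2}/\ln 2} by construction.
#'
#' @param subj A [subject()] whose TACs are decay-uncorrected.
#' @param method A [tail_method()].
#' @param leading_ramp Passed to [residence_time()].
#' @return A data.frame of class `residence_table` with columns `organ`
#'   and `tau_h` (the last row is `"remainder"`), and attributes
#'   `isotope`, `injected_MBq`, `subject_id`, `sex`.
#' @export
residence_table <- function(subj, method = tail_method("physical"),
                            leading_ramp = TRUE) {
  stopifnot(inherits(subj, "subject"))
  taus <- vapply(subj$tacs, function(x) {
    as.numeric(residence_time(x, subj$injected_MBq, subj$isotope,
                              method = method, leading_ramp = leading_ramp))
  }, numeric(1L))
  rem <- remainder_of_body(taus, subj$isotope)
  out <- data.frame(
    organ = c(names(taus), "remainder"),
    tau_h = c(unname(taus), rem),
    stringsAsFactors = FALSE
  )
  attr(out, "isotope") <- subj$isotope
  attr(out, "injected_MBq") <- subj$injected_MBq
  attr(out, "subject_id") <- subj$id
  attr(out, "sex") <- subj$sex
  class(out) <- c("residence_table", "data.frame")
  out
}

#' Dosimetry pipeline presets
#'
#' The two pipeline variants compared in this package differ only in
#' stated implementation details of the residence-time stage: the
#' `"conventional"` preset anchors the observed window at injection with a
#' zero ramp and uses the physical-decay tail; the `"pmod"` preset starts
#' the trapezoid at the first frame midpoint with the same physical-decay
#' ("isotope toolbox") tail. An exponential-fit tail can be swapped into
#' either via [tail_method()].
#'
#' @param name `"conventional"` or `"pmod"`.
#' @param tail Optional [tail_method()] override.
#' @return A list with `name`, `leading_ramp`, `tail`.
#' @export
pipeline_preset <- function(name = c("conventional", "pmod"), tail = NULL) {
  name <- match.arg(name)
  if (is.null(tail)) tail <- tail_method("physical")
  stopifnot(inherits(tail, "tail_method"))
  list(name = name,
       leading_ramp = (name == "conventional"),
       tail = tail)
}
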