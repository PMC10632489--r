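#' Organ time-activity curve
#'
#' One organ's sampled radioactivity on a frame schedule. Dosimetry
#' integrates decay-UNcorrected activity (the activity a detector would see,
#' including physical decay); scanners usually export decay-corrected
#' curves, so the correction status is carried as an explicit flag and
#' conversions are flag-checked.
#'
#' @param organ Organ label (free text; canonicalised to lower-case
#'   underscore form for matching).
#' @param schedule A [frame_schedule()].
#' @param activity Numeric vector of activities in MBq, one per frame;
#'   all must be non-negative. Negative values are rejected, not clamped:
#'   they indicate VOI errors upstream.
#' @param decay_corrected Logical flag: has physical decay been divided out?
#'
#' @return An object of class `tac`.
#' @export
tac <- function(organ, schedule, activity, decay_corrected) {
  stopifnot(is.character(organ), length(organ) == 1L)
  if (!inherits(schedule, "frame_schedule")) {
    stop("schedule must be a frame_schedule")
  }
  if (length(activity) != nrow(schedule)) {
    stop(sprintf("activity has %d values for %d frames",
                 length(activity), nrow(schedule)))
  }
  if (any(!is.finite(activity)) || any(activity < 0)) {
    stop(sprintf("negative or non-finite activity for organ '%s'", organ))
  }
  stopifnot(is.logical(decay_corrected), length(decay_corrected) == 1L)
  obj <- list(
    organ = organ,
    schedule = schedule,
    activity = as.numeric(activity),
    decay_corrected = decay_corrected
  )
  class(obj) <- "tac"
  obj
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s: %d frames, %s, peak %.3g MBq\n",
              x$organ, nrow(x$schedule),
              if (x$decay_corrected) "decay-corrected" else "decay-uncorrected",
              if (length(x$activity)) max(x$activity) else NA_real_))
  invisible(x)
}

#' Remove or restore physical decay in a time-activity curve
#'
#' `decay_uncorrect()` converts a decay-corrected curve to measured
#' (decay-uncorrected) activity by multiplying each frame-midpoint sample by
#' \eqn{e^{-\lambda t}}, with \eqn{t} the midpoint time since injection.
#' `decay_correct()` is the inverse. Both refuse a curve already in the
#' requested state rather than silently double-applying the factor.
#'
#' @param x A [tac()].
#' @param isotope An [isotope()] supplying the decay constant.
#' @return A [tac()] with converted activities and the flag flipped.
#' @examples
#' f18 <- isotope_f18()
#' sched <- frame_schedule(104.77, 114.77)        # midpoint = one half-life
#' decay_uncorrect(tac("liver", sched, 100, TRUE), f18)$activity  # 50
#' @export
decay_uncorrect <- function(x, isotope) {
  stopifnot(inherits(x, "tac"), is_isotope(isotope))
  if (!x$decay_corrected) {
    stop(sprintf("TAC for '%s' is already decay-uncorrected", x$organ))
  }
  t_h <- min_to_h(frame_midpoints(x$schedule))
  tac(x$organ, x$schedule, x$activity * exp(-isotope$lambda_per_h * t_h),
      decay_corrected = FALSE)
}

#' @rdname decay_uncorrect
#' @export
decay_correct <- function(x, isotope) {
  stopifnot(inherits(x, "tac"), is_isotope(isotope))
  if (x$decay_corrected) {
    stop(sprintf("TAC for '%s' is already decay-corrected", x$organ))
  }
  t_h <- min_to_h(frame_midpoints(x$schedule))
  tac(x$organ, x$schedule, x$activity * exp(isotope$lambda_per_h * t_h),
      decay_corrected = TRUE)
}

#' A scanned subject: injected activity plus per-organ curves
#'
#' @param id Subject identifier.
#' @param sex `"male"` or `"female"`.
#' @param injected_MBq Injected activity in MBq, positive.
#' @param isotope An [isotope()]; all TACs share this decay context.
#' @param tacs Named list of [tac()] objects, one per source organ.
#'
#' @return An object of class `subject`.
#' @export
subject <- function(id, sex, injected_MBq, isotope, tacs) {
  stopifnot(is.character(id), length(id) == 1L)
  sex <- match.arg(sex, c("male", "female"))
  if (!is.numeric(injected_MBq) || length(injected_MBq) != 1L ||
      !is.finite(injected_MBq) || injected_MBq <= 0) {
    stop("injected activity must be a single positive number of MBq")
  }
  stopifnot(is_isotope(isotope), is.list(tacs))
  if (length(tacs)) {
    if (!all(vapply(tacs, inherits, logical(1L), "tac"))) {
      stop("tacs must be a list of tac objects")
    }
    names(tacs) <- vapply(tacs, `[[`, character(1L), "organ")
  }
  obj <- list(id = id, sex = sex, injected_MBq = injected_MBq,
              isotope = isotope, tacs = tacs)
  class(obj) <- "subject"
  obj
}

#' @export
print.subject <- function(x, ...) {
  cat(sprintf("<subject> %s (%s): %.1f MBq %s, %d organ TACs\n",
              x$id, x$sex, x$injected_MBq, x$isotope$name, length(x$tacs)))
  invisible(x)
}

# lower-case, underscores, no punctuation: "Urinary bladder wall" -> "urinary_bladder_wall"
canonical_organ <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}
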