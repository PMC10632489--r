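#' Radioisotope physical-decay parameters
#'
#' An isotope is described by its physical half-life. The decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}} and the theoretical total residence time
#' \eqn{T_{1/2}/\ln 2} (the integral of \eqn{e^{-\lambda t}} from 0 to
#' infinity, in hours) are derived from it. Internal convention: half-lives
#' are stated in minutes (the scale on which PET frame schedules are quoted),
#' decay constants in per-hour, residence times in hours.
#'
#' @param name Isotope label, e.g. `"F-18"`.
#' @param half_life_min Physical half-life in minutes; must be positive.
#'
#' @return An object of class `isotope`: a list with `name`,
#'   `half_life_min`, `lambda_per_h` (decay constant, 1/h) and
#'   `total_residence_h` (\eqn{T_{1/2}/\ln 2} in hours).
#'
#' @examples
#' f18 <- isotope_f18()
#' f18$total_residence_h  # 2.6394 h
#' @export
isotope <- function(name, half_life_min) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(half_life_min) || length(half_life_min) != 1L ||
      !is.finite(half_life_min) || half_life_min <= 0) {
    stop("isotope half-life must be a single positive number of minutes")
  }
  half_life_h <- half_life_min / 60
  obj <- list(
    name = name,
    half_life_min = half_life_min,
    lambda_per_h = log(2) / half_life_h,
    total_residence_h = half_life_h / log(2)
  )
  class(obj) <- "isotope"
  obj
}

#' @describeIn isotope Fluorine-18 with the conventional 109.77 min
#'   half-life, giving a theoretical total residence time of 2.6394 h
#'   (the "2.64" closure constant).
#' @export
isotope_f18 <- function() isotope("F-18", 109.77)

#' @export
print.isotope <- function(x, ...) {
  cat(sprintf("<isotope> %s: T1/2 = %.4g min, lambda = %.6g /h, T1/2/ln2 = %.6g h\n",
              x$name, x$half_life_min, x$lambda_per_h, x$total_residence_h))
  invisible(x)
}

is_isotope <- function(x) inherits(x, "isotope")

# minutes -> hours; the only unit conversion in the package
min_to_h <- function(t_min) t_min / 60
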