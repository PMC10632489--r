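#' S-value matrix: dose to a target per unit cumulated activity in a source
#'
#' The MIRD schema factorises the absorbed dose as
#' \eqn{D_k = \sum_h \tilde A_h \, S(k \leftarrow h)} with
#' \eqn{S(k \leftarrow h) = \sum_i \phi_i(k \leftarrow h)\,\Delta_i / m_k}:
#' absorbed fractions \eqn{\phi_i}, equilibrium dose constants
#' \eqn{\Delta_i} and target mass \eqn{m_k} folded into a single dose rate
#' per unit cumulated activity. Units here: mGy/(MBq·h).
#'
#' @param S Numeric matrix, rows = target organs, columns = source organs,
#'   dimnames required, all entries >= 0.
#' @return An object of class `svalue_table` (the matrix with a class).
#' @export
svalue_table <- function(S) {
  if (!is.matrix(S) || is.null(rownames(S)) || is.null(colnames(S))) {
    stop("S must be a matrix with target rownames and source colnames")
  }
  if (any(!is.finite(S)) || any(S < 0)) stop("S values must be non-negative")
  rownames(S) <- canonical_organ(rownames(S))
  colnames(S) <- canonical_organ(colnames(S))
  class(S) <- c("svalue_table", class(S))
  S
}

#' Assemble one S value from MIRD components
#'
#' @param phi Absorbed fractions per emission type, each in \[0, 1\].
#' @param delta Equilibrium dose constants per emission type, in
#'   g·mGy/(MBq·h), same length as `phi`, non-negative.
#' @param target_mass_g Target organ mass in grams, positive.
#' @return S in mGy/(MBq·h): \eqn{\sum_i \phi_i \Delta_i / m_t}.
#' @examples
#' s_from_components(0.5, 2.0, 100)  # 0.01
#' @export
s_from_components <- function(phi, delta, target_mass_g) {
  if (length(phi) != length(delta)) {
    stop("phi and delta must have one entry per emission type")
  }
  if (any(phi < 0 | phi > 1)) stop("absorbed fractions must lie in [0, 1]")
  if (any(delta < 0)) stop("equilibrium dose constants must be non-negative")
  if (!is.numeric(target_mass_g) || length(target_mass_g) != 1L ||
      !is.finite(target_mass_g) || target_mass_g <= 0) {
    stop("target mass must be a single positive number of grams")
  }
  sum(phi * delta) / target_mass_g
}

#' Absorbed dose per injected activity for every target organ
#'
#' \eqn{D_k = \sum_h \tau_h \, S(k \leftarrow h)}: residence times in hours
#' times S values in mGy/(MBq·h) give mGy per injected MBq, reported
#' \eqn{\times 1000} as \eqn{\mu}Gy/MBq (numerically \eqn{\mu}Sv/MBq at
#' \eqn{w_R = 1}). The remainder-of-body row is treated as a source organ
#' named `"remainder"` and must have its own column in the S table.
#'
#' @param residence A [residence_table()].
#' @param s An [svalue_table()] whose sources cover every residence organ.
#' @return A data.frame of class `dose_table` with columns `organ` and
#'   `dose_uGy_per_MBq`; `sex` attribute copied from the residence table.
#' @export
absorbed_doses <- function(residence, s) {
  stopifnot(inherits(residence, "residence_table"), inherits(s, "svalue_table"))
  src <- canonical_organ(residence$organ)
  missing_src <- setdiff(src, colnames(s))
  if (length(missing_src)) {
    stop(sprintf("S table has no source column for: %s (targets: %s)",
                 paste(missing_src, collapse = ", "),
                 paste(rownames(s), collapse = ", ")))
  }
  tau <- residence$tau_h
  names(tau) <- src
  d_mGy <- as.numeric(unclass(s)[, src, drop = FALSE] %*% tau[src])
  out <- data.frame(
    organ = rownames(s),
    dose_uGy_per_MBq = 1000 * d_mGy,
    stringsAsFactors = FALSE
  )
  attr(out, "sex") <- attr(residence, "sex")
  attr(out, "subject_id") <- attr(residence, "subject_id")
  class(out) <- c("dose_table", "data.frame")
  out
}

#' ICRP tissue-weighting schemes
#'
#' Tissue weighting factors \eqn{w_T} sum to 1 and express each organ's
#' share of stochastic radiation risk; \eqn{w_R} is the radiation weighting
#' factor (1 for the photons and positrons of F-18, so \eqn{\mu}Gy and
#' \eqn{\mu}Sv coincide). Two published sets are built in: `"icrp103"`
#' (urinary bladder 0.04, brain 0.01, 14 named tissues + remainder 0.12)
#' and the older `"icrp60"`.
#'
#' @param name `"icrp103"` or `"icrp60"`, or use `weighting_scheme_custom()`.
#' @return An object of class `weighting_scheme`: list with `name`,
#'   `w_T` (named numeric, sums to 1), `w_R`.
#' @examples
#' weighting_scheme("icrp103")$w_T[["urinary_bladder"]]  # 0.04
#' @export
weighting_scheme <- function(name = c("icrp103", "icrp60")) {
  name <- match.arg(name)
  w_T <- switch(name,
    icrp103 = c(
      gonads = 0.08,
      red_bone_marrow = 0.12, colon = 0.12, lungs = 0.12, stomach = 0.12,
      breasts = 0.12,
      urinary_bladder = 0.04, liver = 0.04, oesophagus = 0.04, thyroid = 0.04,
      bone_surfaces = 0.01, brain = 0.01, salivary_glands = 0.01, skin = 0.01,
      remainder = 0.12
    ),
    icrp60 = c(
      gonads = 0.20,
      red_bone_marrow = 0.12, colon = 0.12, lungs = 0.12, stomach = 0.12,
      urinary_bladder = 0.05, breasts = 0.05, liver = 0.05, oesophagus = 0.05,
      thyroid = 0.05,
      bone_surfaces = 0.01, skin = 0.01,
      remainder = 0.05
    )
  )
  weighting_scheme_custom(name, w_T, w_R = 1)
}

#' @rdname weighting_scheme
#' @param w_T Named numeric vector of tissue weights, non-negative,
#'   summing to 1 within 1e-6.
#' @param w_R Radiation weighting factor, positive.
#' @export
weighting_scheme_custom <- function(name, w_T, w_R = 1) {
  if (is.null(names(w_T)) || any(!nzchar(names(w_T)))) {
    stop("tissue weights must be named")
  }
  if (any(w_T < 0)) stop("tissue weights must be non-negative")
  if (abs(sum(w_T) - 1) > 1e-6) {
    stop(sprintf("tissue weights must sum to 1 (got %.8f)", sum(w_T)))
  }
  if (!is.numeric(w_R) || length(w_R) != 1L || w_R <= 0) {
    stop("w_R must be a single positive number")
  }
  names(w_T) <- canonical_organ(names(w_T))
  structure(list(name = name, w_T = w_T, w_R = w_R),
            class = "weighting_scheme")
}

# common synonyms between dose-table organ labels and tissue-weight names
.tissue_aliases <- c(
  lung = "lungs", kidney = "kidneys", breast = "breasts",
  urinary_bladder_wall = "urinary_bladder", bladder = "urinary_bladder",
  heart_wall = "heart", bone_marrow = "red_bone_marrow",
  esophagus = "oesophagus", testes = "gonads", ovaries = "gonads",
  reminder_of_body = "remainder", remainder_of_body = "remainder"
)

resolve_tissue <- function(x) {
  x <- canonical_organ(x)
  hit <- .tissue_aliases[x]
  ifelse(is.na(hit), x, hit)
}

#' Effective dose from a table of organ absorbed doses
#'
#' \eqn{E = \sum_T w_T \, D_T \, w_R}. Organ labels are canonicalised and
#' matched against the scheme's tissue names (with common synonyms such as
#' lung/lungs resolved); weighted tissues absent from the dose table
#' contribute zero with a warning, so a partial organ list yields a lower
#' bound rather than an error.
#'
#' @param doses A [dose_table()] (or data.frame with `organ`,
#'   `dose_uGy_per_MBq`).
#' @param weights A [weighting_scheme()].
#' @return Effective dose per injected activity, \eqn{\mu}Sv/MBq.
#' @export
effective_dose <- function(doses, weights = weighting_scheme("icrp103")) {
  stopifnot(is.data.frame(doses), inherits(weights, "weighting_scheme"))
  organ <- resolve_tissue(doses$organ)
  d <- doses$dose_uGy_per_MBq
  if (any(d < 0)) stop("absorbed doses must be non-negative")
  # a tissue may resolve from several dose rows (e.g. testes+ovaries -> gonads):
  # take the mean dose over contributing rows
  d_by_tissue <- tapply(d, organ, mean)
  matched <- names(weights$w_T) %in% names(d_by_tissue)
  if (!all(matched)) {
    warning(sprintf("no dose entry for weighted tissue(s): %s; contributing 0",
                    paste(names(weights$w_T)[!matched], collapse = ", ")))
  }
  d_T <- ifelse(matched, d_by_tissue[names(weights$w_T)], 0)
  sum(weights$w_T * d_T) * weights$w_R
}

#' Regulatory effective-dose limits
#'
#' US federal limits for research subjects: 30 mSv per administration and
#' 50 mSv per year.
#'
#' @param per_administration_mSv,per_year_mSv Limits in mSv;
#'   `0 < per_administration <= per_year`.
#' @return An object of class `dose_limits`.
#' @export
dose_limits <- function(per_administration_mSv = 30, per_year_mSv = 50) {
  if (per_administration_mSv <= 0 || per_administration_mSv > per_year_mSv) {
    stop("limits must satisfy 0 < per_administration <= per_year")
  }
  structure(list(per_administration_mSv = per_administration_mSv,
                 per_year_mSv = per_year_mSv),
            class = "dose_limits")
}

#' Check a planned administration against dose limits
#'
#' Total effective dose is `e_uSv_per_MBq * injected_MBq / 1000` mSv; a
#' limit fails only when strictly exceeded (a total exactly at the limit
#' passes).
#'
#' @param e_uSv_per_MBq Effective dose per injected activity.
#' @param injected_MBq Planned injected activity, MBq.
#' @param limits A [dose_limits()].
#' @return List with `total_mSv`, `pass_per_administration`,
#'   `pass_per_year`, `limits`.
#' @examples
#' compliance_check(22.47, 262.5)  # 5.9 mSv, passes both
#' @export
compliance_check <- function(e_uSv_per_MBq, injected_MBq,
                             limits = dose_limits()) {
  stopifnot(e_uSv_per_MBq >= 0, injected_MBq >= 0,
            inherits(limits, "dose_limits"))
  total <- e_uSv_per_MBq * injected_MBq / 1000
  list(
    total_mSv = total,
    pass_per_administration = !(total > limits$per_administration_mSv),
    pass_per_year = !(total > limits$per_year_mSv),
    limits = limits
  )
}
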