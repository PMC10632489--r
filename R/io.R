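#' Read and write subject TAC files
#'
#' The interchange format is a comma-delimited UTF-8 table with columns
#' `organ, frame_start_min, frame_end_min, activity_MBq, decay_corrected`
#' (0/1), preceded by a header block of `# key: value` lines carrying the
#' subject metadata: `subject_id`, `sex`, `injected_MBq`, `isotope` and
#' (for isotopes other than F-18) `half_life_min`.
#'
#' @param path File path.
#' @return `read_tac_file()`: a validated [subject()].
#' @export
read_tac_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such TAC file: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- grep("^#", lines)
  hdr_idx <- hdr_idx[hdr_idx == seq_along(hdr_idx)]   # leading block only
  meta <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  for (key in c("subject_id", "sex", "injected_MBq", "isotope")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("TAC file %s: missing required header field '%s'", path, key))
    }
  }
  iso <- if (!is.null(meta$half_life_min)) {
    isotope(meta$isotope, as.numeric(meta$half_life_min))
  } else if (canonical_organ(meta$isotope) %in% c("f_18", "f18", "18f")) {
    isotope_f18()
  } else {
    stop(sprintf("TAC file %s: unknown isotope '%s' and no half_life_min given",
                 path, meta$isotope))
  }

  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("organ", "frame_start_min", "frame_end_min", "activity_MBq",
           "decay_corrected")
  if (!all(req %in% names(tab))) {
    stop(sprintf("TAC file %s: columns must be %s", path,
                 paste(req, collapse = ", ")))
  }
  neg <- which(tab$activity_MBq < 0)
  if (length(neg)) {
    stop(sprintf("TAC file %s: negative activity in data row %d (organ %s)",
                 path, neg[1L], tab$organ[neg[1L]]))
  }
  tacs <- lapply(split(tab, tab$organ), function(d) {
    d <- d[order(d$frame_start_min), ]
    if (length(unique(d$decay_corrected)) != 1L) {
      stop(sprintf("TAC file %s: mixed decay_corrected flags for organ %s",
                   path, d$organ[1L]))
    }
    sched <- tryCatch(
      frame_schedule(d$frame_start_min, d$frame_end_min),
      error = function(e) stop(sprintf("TAC file %s, organ %s: %s",
                                       path, d$organ[1L], conditionMessage(e))))
    tac(d$organ[1L], sched, d$activity_MBq,
        decay_corrected = as.logical(d$decay_corrected[1L]))
  })
  subject(meta$subject_id, meta$sex, as.numeric(meta$injected_MBq), iso, tacs)
}

#' @rdname read_tac_file
#' @param subj A [subject()].
#' @return `write_tac_file()`: `path`, invisibly.
#' @export
write_tac_file <- function(subj, path) {
  stopifnot(inherits(subj, "subject"))
  hdr <- c(
    sprintf("# subject_id: %s", subj$id),
    sprintf("# sex: %s", subj$sex),
    sprintf("# injected_MBq: %s", format(subj$injected_MBq, digits = 15)),
    sprintf("# isotope: %s", subj$isotope$name),
    sprintf("# half_life_min: %s", format(subj$isotope$half_life_min, digits = 15))
  )
  rows <- do.call(rbind, lapply(subj$tacs, function(x) {
    data.frame(organ = x$organ,
               frame_start_min = x$schedule$start_min,
               frame_end_min = x$schedule$end_min,
               activity_MBq = x$activity,
               decay_corrected = as.integer(x$decay_corrected),
               stringsAsFactors = FALSE)
  }))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(rows, digits = 15, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write S-value tables
#'
#' Long-format comma-delimited file with columns
#' `target, source, S_mGy_per_MBq_h` and optional provenance columns
#' `phi`, `delta`, `mass_g` (semicolon-separated lists for `phi`/`delta`);
#' when provenance is present each S entry is validated against
#' [s_from_components()] to 1e-9 relative.
#'
#' @param path File path.
#' @return `read_svalue_file()`: an [svalue_table()].
#' @export
read_svalue_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such S-value file: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("target", "source", "S_mGy_per_MBq_h")
  if (!all(req %in% names(tab))) {
    stop(sprintf("S-value file %s: columns must include %s", path,
                 paste(req, collapse = ", ")))
  }
  if (all(c("phi", "delta", "mass_g") %in% names(tab))) {
    for (i in seq_len(nrow(tab))) {
      phi_raw <- as.character(tab$phi[i])
      if (is.na(phi_raw) || !nzchar(phi_raw)) next
      phi <- as.numeric(strsplit(phi_raw, ";")[[1L]])
      delta <- as.numeric(strsplit(as.character(tab$delta[i]), ";")[[1L]])
      s_chk <- s_from_components(phi, delta, tab$mass_g[i])
      if (abs(s_chk - tab$S_mGy_per_MBq_h[i]) >
          1e-9 * max(abs(s_chk), .Machine$double.eps)) {
        stop(sprintf(
          "S-value file %s row %d: S=%.9g inconsistent with phi/delta/mass (%.9g)",
          path, i, tab$S_mGy_per_MBq_h[i], s_chk))
      }
    }
  }
  targets <- unique(tab$target)
  sources <- unique(tab$source)
  S <- matrix(NA_real_, length(targets), length(sources),
              dimnames = list(targets, sources))
  S[cbind(match(tab$target, targets), match(tab$source, sources))] <-
    tab$S_mGy_per_MBq_h
  if (anyNA(S)) stop(sprintf("S-value file %s: incomplete target x source grid", path))
  svalue_table(S)
}

#' @rdname read_svalue_file
#' @param s An [svalue_table()].
#' @return `write_svalue_file()`: `path`, invisibly.
#' @export
write_svalue_file <- function(s, path) {
  stopifnot(inherits(s, "svalue_table"))
  grid <- expand.grid(target = rownames(s), source = colnames(s),
                      stringsAsFactors = FALSE)
  grid$S_mGy_per_MBq_h <- unclass(s)[cbind(grid$target, grid$source)]
  utils::write.csv(format(grid, digits = 15, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a residence table
#'
#' `write_residence_table()` writes the full CSV (organ, tau_h; remainder
#' row included). `write_residence_olinda()` writes the flat text layout
#' dose software imports: one `organ<space>tau_hours` pair per line.
#'
#' @param residence A [residence_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residence_table <- function(residence, path) {
  stopifnot(inherits(residence, "residence_table"))
  utils::write.csv(
    data.frame(organ = residence$organ,
               tau_h = format(residence$tau_h, digits = 15, trim = TRUE)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_residence_table
#' @export
write_residence_olinda <- function(residence, path) {
  stopifnot(inherits(residence, "residence_table"))
  writeLines(sprintf("%s %.6f", residence$organ, residence$tau_h), path)
  invisible(path)
}

#' Pipeline run configuration
#'
#' A serialisable bag of every switch the pipeline takes: tail method,
#' leading-ramp flag, weighting scheme, percent-difference convention,
#' isotope, dose limits, seed and paths. Round-trips through YAML
#' unchanged.
#'
#' @param tail `"physical"` or `"expfit"`.
#' @param k_points Tail-fit sample count (expfit only).
#' @param leading_ramp Zero-anchored leading segment?
#' @param weights `"icrp103"` or `"icrp60"`.
#' @param convention `"rel_first"` or `"rel_mean"`.
#' @param isotope_name,half_life_min Isotope description.
#' @param per_administration_mSv,per_year_mSv Dose limits.
#' @param seed Integer seed for any stochastic stage.
#' @param input_paths,out_dir File locations (may be empty).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(tail = "physical", k_points = 3L, leading_ramp = TRUE,
                       weights = "icrp103", convention = "rel_first",
                       isotope_name = "F-18", half_life_min = 109.77,
                       per_administration_mSv = 30, per_year_mSv = 50,
                       seed = 1L, input_paths = character(0), out_dir = "") {
  cfg <- list(
    tail = match.arg(tail, c("physical", "expfit")),
    k_points = as.integer(k_points),
    leading_ramp = isTRUE(leading_ramp),
    weights = match.arg(weights, c("icrp103", "icrp60")),
    convention = match.arg(convention, c("rel_first", "rel_mean")),
    isotope_name = isotope_name,
    half_life_min = half_life_min,
    per_administration_mSv = per_administration_mSv,
    per_year_mSv = per_year_mSv,
    seed = as.integer(seed),
    input_paths = as.character(input_paths),
    out_dir = out_dir
  )
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}
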