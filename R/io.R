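#' Read a trajectory CSV
#'
#' Expects a header `time,<place_1>,<place_2>,...` and numeric cells; times
#' must be strictly increasing. Malformed content is reported with the file
#' line number (header = line 1).
#'
#' @param path CSV file.
#' @return an `hfpn_trajectory` data.frame.
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L || names(raw)[1L] != "time")
    stop("missing or malformed header: first column must be 'time' ",
         "followed by at least one place column (", path, ")")
  num <- suppressWarnings(
    as.data.frame(lapply(raw, as.numeric), check.names = FALSE))
  names(num) <- names(raw)
  bad <- which(is.na(as.matrix(num)) & as.matrix(raw) != "NA", arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("nonnumeric cell at line %d, column '%s' in %s",
                 bad[1L, 1L] + 1L, names(raw)[bad[1L, 2L]], path))
  dtime <- diff(num$time)
  if (length(dtime) && any(dtime <= 0)) {
    i <- which(dtime <= 0)[1L]
    stop(sprintf("time not strictly increasing at line %d in %s",
                 i + 2L, path))
  }
  structure(num, class = c("hfpn_trajectory", "data.frame"))
}

#' Write a trajectory CSV
#'
#' Writes `time,<place columns>` with full double precision (15 significant
#' digits) so that a write/read round-trip reproduces the values.
#'
#' @param traj `hfpn_trajectory` or data.frame with a `time` column.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 15, format = "g") else col
  }), check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a dose--response CSV
#'
#' Columns `concentration_M,F,replicate`; one zero-concentration (Fmax) row
#' per replicate by convention.
#'
#' @param path CSV file.
#' @return data.frame with the three columns.
#' @export
read_doseresponse_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path)
  need <- c("concentration_M", "F", "replicate")
  if (!all(need %in% names(d)))
    stop("dose-response CSV must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(d$concentration_M)) || any(d$concentration_M < 0))
    stop("concentrations must be finite and nonnegative in ", path)
  d
}

#' @rdname read_doseresponse_csv
#' @param data dose--response data.frame.
#' @export
write_doseresponse_csv <- function(data, path) {
  out <- data
  out$concentration_M <- formatC(out$concentration_M, digits = 15, format = "g")
  out$F <- formatC(out$F, digits = 15, format = "g")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Combined control / C-1193 analysis report
#'
#' Tabulates, per observable and condition, the reference (model) coefficients
#' against the recovered fit coefficients with their R-squared; appends the
#' initial-velocity table and, when supplied, the Hill Ki estimate. Missing
#' pieces are listed and the report is still emitted.
#'
#' @param fits named list per condition (`control`, `c1193`); each element a
#'   named list of fitted models (`poly_fit` or `two_component_fit`) keyed by
#'   observable name.
#' @param velocities optional named list of [initial_velocities()] reports per
#'   condition.
#' @param ki optional [estimate_ki()] result.
#' @return object of class `mito_report` with a `table` data.frame,
#'   `velocities`, `ki` and `missing`.
#' @export
run_report <- function(fits, velocities = NULL, ki = NULL) {
  conditions <- intersect(c("control", "c1193"), names(fits))
  missing <- setdiff(c("control", "c1193"), names(fits))
  rows <- list()
  for (cond in conditions) {
    ref <- .dynamics[[cond]]
    for (obs in names(fits[[cond]])) {
      f <- fits[[cond]][[obs]]
      if (inherits(f, "two_component_fit")) {
        co <- sprintf("early: %s / late: %s",
                      paste(signif(coef(f$early), 6), collapse = ", "),
                      paste(signif(coef(f$late), 6), collapse = ", "))
        r2 <- min(f$early$r_squared, f$late$r_squared)
      } else {
        co <- paste(signif(coef(f), 6), collapse = ", ")
        r2 <- f$r_squared %||% NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        observable = obs, condition = cond,
        reference_coefficients = if (obs %in% names(ref))
          paste(ref[[obs]], collapse = ", ") else NA_character_,
        fitted_coefficients = co,
        r_squared = r2)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 velocities = velocities,
                 ki = ki,
                 missing = missing),
            class = "mito_report")
}

#' @export
print.mito_report <- function(x, ...) {
  cat("Mitochondrial model analysis report\n")
  cat("===================================\n")
  if (length(x$missing))
    cat("missing condition(s):", paste(x$missing, collapse = ", "), "\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$velocities)) {
    cat("\nInitial velocities:\n")
    for (v in x$velocities) print(v)
  }
  if (!is.null(x$ki)) {
    cat("\n")
    print(x$ki)
  } else {
    cat("\nKi section: absent (no dose-response data supplied)\n")
  }
  invisible(x)
}
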