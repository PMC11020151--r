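#' Hill-coordinate transform of a dose--response row
#'
#' Maps fluorescence at inhibitor concentration `conc` into Hill coordinates
#' `{x, y} = {-log10(conc), -log10((Fmax - F)/F)}`, under which the ideal
#' inhibition law `F = Fmax / (1 + (C/Ki)^n)` becomes the straight line
#' `y = n x + n log10(Ki)` with x-intercept `-log10(Ki)`. Rows with `F`
#' outside `(0, Fmax)` or `conc <= 0` are untransformable and are dropped with
#' a message (batch input is not interrupted by an exception).
#'
#' @param F fluorescence at each concentration (relative units).
#' @param Fmax fluorescence in the absence of inhibitor (scalar or vector).
#' @param conc inhibitor concentration, molar.
#' @return data.frame with columns `x`, `y` for the transformable rows;
#'   attribute `n_dropped` counts rejected rows.
#' @export
hill_transform <- function(F, Fmax, conc) {
  n <- length(F)
  stopifnot(length(conc) == n, length(Fmax) %in% c(1L, n))
  Fmax <- rep_len(Fmax, n)
  ok <- is.finite(F) & is.finite(conc) & F > 0 & F < Fmax & conc > 0
  if (any(!ok))
    message(sum(!ok), " dose-response row(s) dropped: F outside (0, Fmax) ",
            "or nonpositive concentration")
  out <- data.frame(x = -log10(conc[ok]),
                    y = -log10((Fmax[ok] - F[ok]) / F[ok]))
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Apparent inhibition constant from dose--response data (Hill plot)
#'
#' Per replicate: the zero-inhibitor row supplies that replicate's `Fmax`, the
#' remaining rows are transformed with [hill_transform()] and a least-squares
#' line is fitted in Hill coordinates. The Hill coefficient is the line's
#' slope and `Ki = 10^(-x-intercept)` (the concentration of half-maximal
#' suppression; exact for the ideal law). Replicates whose line has
#' `R-squared <= r2_min` (default 0.9) are excluded; the surviving Ki values
#' are aggregated as mean +/- SE.
#'
#' The line is fitted by weighted least squares with delta-method weights
#' `w = ((Fmax - F)/Fmax)^2` by default: under multiplicative measurement
#' noise the variance of the transformed ordinate grows as
#' `(Fmax/(Fmax - F))^2` when `F` approaches `Fmax`, and inverse-variance
#' weighting removes the strong small-sample bias this induces near the
#' weak-inhibition end of the curve. Weights have no effect on noiseless data
#' (the linearization is exact there). Set `weights = "none"` for an ordinary
#' unweighted fit.
#'
#' @param data data.frame with columns `concentration_M`, `F`, `replicate`;
#'   each replicate needs a `concentration_M == 0` row (its Fmax) unless
#'   `Fmax` is supplied.
#' @param r2_min acceptance threshold on the per-replicate R-squared.
#' @param Fmax optional fixed Fmax (overrides the zero-concentration rows).
#' @param weights `"delta"` (inverse-variance, default) or `"none"`.
#' @return object of class `ki_estimate`: `Ki` (molar, mean over surviving
#'   replicates), `se` (molar), `hill_slope` (mean), `n_replicates`
#'   (surviving), and the per-replicate table `replicates`.
#' @export
estimate_ki <- function(data, r2_min = 0.9, Fmax = NULL,
                        weights = c("delta", "none")) {
  weights <- match.arg(weights)
  stopifnot(all(c("concentration_M", "F", "replicate") %in% names(data)))
  reps <- split(data, data$replicate)
  per <- lapply(names(reps), function(rid) {
    d <- reps[[rid]]
    fmax <- if (!is.null(Fmax)) Fmax else {
      z <- d$F[d$concentration_M == 0]
      if (!length(z))
        stop("replicate '", rid, "' has no zero-inhibitor (Fmax) row")
      mean(z)
    }
    d <- d[d$concentration_M > 0, , drop = FALSE]
    keepF <- is.finite(d$F) & d$F > 0 & d$F < fmax
    h <- suppressMessages(hill_transform(d$F, fmax, d$concentration_M))
    if (nrow(h) < 3L)
      stop("replicate '", rid, "' has fewer than 3 transformable rows")
    w <- if (weights == "delta") ((fmax - d$F[keepF]) / fmax)^2
         else rep(1, nrow(h))
    fit <- stats::lm.wfit(cbind(1, h$x), h$y, w)
    b <- unname(fit$coefficients[1]); a <- unname(fit$coefficients[2])
    if (!is.finite(a) || a == 0)
      stop("replicate '", rid, "': degenerate Hill-plot line (zero slope)")
    ybar <- sum(w * h$y) / sum(w)
    ss_tot <- sum(w * (h$y - ybar)^2)
    ss_res <- sum(w * fit$residuals^2)
    r2 <- if (ss_tot == 0) as.numeric(ss_res <= 1e-20) else 1 - ss_res / ss_tot
    data.frame(replicate = rid, ki = 10^(b / a), hill_slope = a,
               r_squared = r2, n_points = nrow(h),
               n_dropped = attr(h, "n_dropped"))
  })
  per <- do.call(rbind, per)
  keep <- per$r_squared > r2_min
  if (!any(keep))
    stop("all replicates filtered out by the R-squared > ", r2_min,
         " rule; per-replicate R-squared: ",
         paste(sprintf("%s=%.3f", per$replicate, per$r_squared),
               collapse = ", "))
  kis <- per$ki[keep]
  structure(list(
    Ki = mean(kis),
    se = if (length(kis) > 1L) stats::sd(kis) / sqrt(length(kis)) else NA_real_,
    hill_slope = mean(per$hill_slope[keep]),
    n_replicates = sum(keep),
    r2_min = r2_min,
    replicates = per),
    class = "ki_estimate")
}

#' @export
print.ki_estimate <- function(x, ...) {
  cat(sprintf("Apparent inhibition constant (Hill plot): %.3g +/- %.2g nM (n = %d)\n",
              x$Ki * 1e9, x$se * 1e9, x$n_replicates))
  cat(sprintf("  mean Hill slope: %.4g; replicates kept: R-squared > %.2f\n",
              x$hill_slope, x$r2_min))
  if (any(x$replicates$r_squared <= x$r2_min))
    cat(sprintf("  excluded replicates: %s\n",
                paste(x$replicates$replicate[x$replicates$r_squared <= x$r2_min],
                      collapse = ", ")))
  invisible(x)
}

#' @export
coef.ki_estimate <- function(object, ...) {
  c(Ki_M = object$Ki, hill_slope = object$hill_slope)
}

#' @export
summary.ki_estimate <- function(object, ...) {
  print(object)
  cat("per-replicate estimates:\n")
  print(transform(object$replicates, ki_nM = ki * 1e9)[,
        c("replicate", "ki_nM", "hill_slope", "r_squared", "n_points")],
        row.names = FALSE)
  invisible(object)
}
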