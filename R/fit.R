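#' Polynomial model of a fluorescence time course
#'
#' A plain (unfitted) polynomial in time with ascending coefficients; fitted
#' models ([fit_polynomial()]) inherit from this class and additionally carry
#' an R-squared.
#'
#' @param coefficients numeric vector `c0..cd` (intercept first), degree <= 4.
#' @param valid_interval validity window, minutes.
#' @return object of class `poly_model`.
#' @export
poly_model <- function(coefficients, valid_interval = c(0, 15)) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            length(coefficients) <= 5L)
  structure(list(coefficients = stats::setNames(
                   as.numeric(coefficients),
                   paste0("c", seq_along(coefficients) - 1L)),
                 degree = length(coefficients) - 1L,
                 valid_interval = valid_interval),
            class = "poly_model")
}

#' @export
coef.poly_model <- function(object, ...) object$coefficients

#' @export
print.poly_model <- function(x, ...) {
  d <- x$degree
  terms <- vapply(seq_along(x$coefficients), function(i) {
    p <- i - 1L
    v <- x$coefficients[i]
    if (p == 0) sprintf("%.6g", v)
    else if (p == 1) sprintf("%+.6g t", v)
    else sprintf("%+.6g t^%d", v, p)
  }, "")
  cat(sprintf("polynomial model (degree %d): %s\n", d,
              paste(terms, collapse = " ")))
  if (!is.null(x$r_squared))
    cat(sprintf("  R-squared: %.6f  (n = %d)\n", x$r_squared, x$n))
  invisible(x)
}

#' @export
predict.poly_model <- function(object, times, ...) {
  unname(poly_eval(unname(object$coefficients), times))
}

as_time_value <- function(traj) {
  if (is.data.frame(traj)) {
    if (all(c("time", "value") %in% names(traj)))
      return(data.frame(time = traj$time, value = traj$value))
    if (ncol(traj) == 2L)
      return(stats::setNames(as.data.frame(traj), c("time", "value")))
  }
  stop("trajectory must be a data.frame with columns time and value")
}

#' Least-squares polynomial fit to a trajectory
#'
#' Ordinary (unweighted) least squares of a degree-1..4 polynomial in time,
#' the model family used to describe all the fluorometric time courses.
#'
#' @param traj data.frame with columns `time` (minutes) and `value`, e.g. from
#'   [observable_trajectory()] or [gen_timeseries()].
#' @param degree polynomial degree, 1 to 4.
#' @return a fitted `poly_fit` (inherits `poly_model`) with elements
#'   `coefficients` (ascending), `r_squared`, `n`, `residuals`, `fitted`.
#' @export
fit_polynomial <- function(traj, degree) {
  stopifnot(degree %in% 1:4)
  traj <- as_time_value(traj)
  n <- nrow(traj)
  if (n < degree + 2L)
    stop("degree-", degree, " fit needs at least ", degree + 2L,
         " samples; got ", n)
  X <- outer(traj$time, 0:degree, `^`)
  fit <- stats::lm.fit(X, traj$value)
  co <- fit$coefficients
  if (anyNA(co)) stop("singular design: times do not support degree ", degree)
  fitted <- drop(X %*% co)
  res <- traj$value - fitted
  ss_res <- sum(res^2)
  ss_tot <- sum((traj$value - mean(traj$value))^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res <= 1e-20) else 1 - ss_res / ss_tot
  out <- poly_model(unname(co), valid_interval = range(traj$time))
  out$r_squared <- r2
  out$n <- n
  out$residuals <- res
  out$fitted <- fitted
  out$data <- traj
  class(out) <- c("poly_fit", class(out))
  out
}

#' @export
residuals.poly_fit <- function(object, ...) object$residuals

#' @export
summary.poly_fit <- function(object, ...) {
  cat("Polynomial least-squares fit\n")
  print(object)
  cat(sprintf("  residual SD: %.6g over t in [%g, %g] min\n",
              stats::sd(object$residuals), object$valid_interval[1],
              object$valid_interval[2]))
  invisible(object)
}

#' Analytic derivative of a polynomial model
#'
#' The activation speed of the transition producing an observable is the first
#' derivative of the observable's dynamics model; this maps the control NADH
#' cubic onto the printed quadratic speed.
#'
#' @param model a [poly_model()] (degree >= 1) or coefficient vector.
#' @return a `poly_model` of degree d - 1.
#' @export
differentiate <- function(model) {
  co <- if (inherits(model, "poly_model")) coef(model) else model
  vi <- if (inherits(model, "poly_model")) model$valid_interval else c(0, 15)
  poly_model(poly_deriv_coef(unname(co)), valid_interval = vi)
}

#' Antiderivative of a polynomial model
#'
#' @param model a [poly_model()] or coefficient vector.
#' @param constant integration constant (value at t = 0).
#' @return a `poly_model` of degree d + 1.
#' @export
antiderivative <- function(model, constant = 0) {
  co <- if (inherits(model, "poly_model")) coef(model) else model
  poly_model(c(constant, unname(co) / seq_along(co)))
}

#' Two-component linearization of a trajectory
#'
#' Fits two independent least-squares lines on either side of a breakpoint
#' (default 2.5 min): samples with `time <= breakpoint` form the early
#' component, samples with `time > breakpoint` the late component. No
#' continuity is imposed at the breakpoint.
#'
#' @param traj data.frame with columns `time`, `value`.
#' @param breakpoint split time, minutes.
#' @return object of class `two_component_fit`: list with `early` and `late`
#'   degree-1 `poly_fit`s and the `breakpoint`.
#' @export
two_component_fit <- function(traj, breakpoint = 2.5) {
  traj <- as_time_value(traj)
  early <- traj[traj$time <= breakpoint, , drop = FALSE]
  late <- traj[traj$time > breakpoint, , drop = FALSE]
  if (nrow(early) < 3L)
    stop("fewer than 3 samples in the early interval [0, ", breakpoint, "]")
  if (nrow(late) < 3L)
    stop("fewer than 3 samples in the late interval (", breakpoint, ", ...]")
  structure(list(early = fit_polynomial(early, 1L),
                 late = fit_polynomial(late, 1L),
                 breakpoint = breakpoint),
            class = "two_component_fit")
}

#' @export
coef.two_component_fit <- function(object, ...) {
  rbind(early = coef(object$early), late = coef(object$late))
}

#' @export
print.two_component_fit <- function(x, ...) {
  cat(sprintf("two-component linear fit, breakpoint %.2f min\n", x$breakpoint))
  cat(sprintf("  early [<= %.2f]: slope %.6g, intercept %.6g, R2 %.4f\n",
              x$breakpoint, coef(x$early)[2], coef(x$early)[1],
              x$early$r_squared))
  cat(sprintf("  late  [>  %.2f]: slope %.6g, intercept %.6g, R2 %.4f\n",
              x$breakpoint, coef(x$late)[2], coef(x$late)[1],
              x$late$r_squared))
  invisible(x)
}

#' @export
predict.two_component_fit <- function(object, times, ...) {
  ifelse(times <= object$breakpoint,
         predict(object$early, times), predict(object$late, times))
}

#' Initial velocities of NO synthesis, Ca2+ accumulation and energization
#'
#' Extracts, for one condition, the initial velocity of NO synthesis (slope of
#' the DAF-FM linear model), of matrix Ca2+ accumulation (slope of the early,
#' 0--2.5 min, component of the Fluo-4 two-component fit) and of membrane
#' energization (derivative of the EP model at t = 0). The report is
#' descriptive: the model's qualitative reading is that NO synthesis is driven
#' by both Ca2+ entry and energization, but no arithmetic identity between the
#' three slopes is asserted (the printed slopes do not satisfy one).
#'
#' @param no_model degree-1 `poly_model`/`poly_fit` of the DAF-FM trajectory.
#' @param ca_model a `two_component_fit` of the Fluo-4 trajectory, or a
#'   degree-1 model of its early interval.
#' @param ep_model `poly_model` of the EP trajectory (any degree >= 1).
#' @param condition label carried into the report.
#' @return object of class `velocity_report` with fields `V0_NO`, `V0_Ca`,
#'   `V0_EP` (units per minute) and provenance strings.
#' @export
initial_velocities <- function(no_model, ca_model, ep_model,
                               condition = "control") {
  if (missing(no_model) || is.null(no_model)) stop("missing NO (DAF-FM) model")
  if (missing(ca_model) || is.null(ca_model)) stop("missing Ca2+ (Fluo-4) model")
  if (missing(ep_model) || is.null(ep_model)) stop("missing EP model")
  if (inherits(ca_model, "two_component_fit")) {
    v_ca <- unname(coef(ca_model$early)[2])
    prov_ca <- sprintf("early-interval (0-%g min) linear slope", ca_model$breakpoint)
  } else {
    stopifnot(inherits(ca_model, "poly_model"), ca_model$degree == 1L)
    v_ca <- unname(coef(ca_model)[2])
    prov_ca <- "early-interval linear slope"
  }
  stopifnot(inherits(no_model, "poly_model"), no_model$degree == 1L)
  structure(list(
    condition = condition,
    V0_NO = unname(coef(no_model)[2]),
    V0_Ca = v_ca,
    V0_EP = unname(coef(differentiate(ep_model))[1]),
    provenance = c(NO = "DAF-FM linear-model slope",
                   Ca = prov_ca,
                   EP = "EP model derivative at t = 0")),
    class = "velocity_report")
}

#' @export
print.velocity_report <- function(x, ...) {
  cat(sprintf("Initial velocities (%s), units/min:\n", x$condition))
  cat(sprintf("  V0_NO = %8.4g  (%s)\n", x$V0_NO, x$provenance["NO"]))
  cat(sprintf("  V0_Ca = %8.4g  (%s)\n", x$V0_Ca, x$provenance["Ca"]))
  cat(sprintf("  V0_EP = %8.4g  (%s)\n", x$V0_EP, x$provenance["EP"]))
  cat("  (descriptive report; no identity between the three is asserted)\n")
  invisible(x)
}

#' Pointwise mean and standard error across replicate trajectories
#'
#' @param trajs list of >= 2 replicate data.frames (`time`, `value`) sharing
#'   one time grid.
#' @return data.frame with columns `time`, `mean`, `se`, `n`.
#' @export
aggregate_replicates <- function(trajs) {
  stopifnot(is.list(trajs), length(trajs) >= 2L)
  trajs <- lapply(trajs, as_time_value)
  grid <- trajs[[1L]]$time
  for (i in seq_along(trajs))
    if (!isTRUE(all.equal(trajs[[i]]$time, grid)))
      stop("replicate ", i, " is not on the common time grid")
  vals <- vapply(trajs, `[[`, numeric(length(grid)), "value")
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L)
  n <- length(trajs)
  data.frame(time = grid,
             mean = rowMeans(vals),
             se = apply(vals, 1L, stats::sd) / sqrt(n),
             n = n)
}
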