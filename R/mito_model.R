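# The printed trajectory models of the fluorometric observables, 0-15 min,
# relative fluorescence x1000 (EP in mV). Coefficients stored ascending
# (c0, c1, ...), i.e. intercept first.

.dynamics <- list(
  control = list(
    NADH     = c(0, -49.20, 7.44, -0.38),
    EP       = c(-40.00, -49.20, 7.44, -0.38),
    Ca_Fluo4 = c(1.57, 106.15, -28.68, 4.06, -0.20),
    NO_DAFFM = c(16.91, 17.39),
    ROS_DCF  = c(1000, 13.9)
  ),
  c1193 = list(
    NADH     = c(0, -30.80, 3.81, -0.16),
    EP       = c(-40.00, -30.80, 3.81, -0.16),
    Ca_Fluo4 = c(3.26, 61.15, -19.58, 2.80, -0.14),
    NO_DAFFM = c(-8.23, 13.12),
    ROS_DCF  = c(1000, 1.3)
  )
)

.ca_piecewise <- list(
  control = list(early = c(-11.41, 27.68), late = c(116.03, 20.44)),
  c1193   = list(early = c(1.01, 12.86),   late = c(66.43, 4.17))
)

match_condition <- function(condition) match.arg(condition, c("control", "c1193"))

#' Fluorescence dynamics models for one condition
#'
#' Returns the polynomial time-dependence of each observable (relative
#' fluorescence x1000; EP in mV) for the control suspension or under 10 uM
#' C-1193: a cubic for NADH autofluorescence change, the same cubic shifted by
#' -40 mV for the inner-membrane electric potential, a quartic for matrix
#' Ca2+ (Fluo-4), and first-degree models for NO (DAF-FM) and ROS (DCF).
#'
#' @param condition `"control"` or `"c1193"`.
#' @return named list of [poly_model()] objects
#'   (`NADH`, `EP`, `Ca_Fluo4`, `NO_DAFFM`, `ROS_DCF`).
#' @export
dynamics_polynomials <- function(condition = c("control", "c1193")) {
  condition <- match_condition(condition)
  lapply(.dynamics[[condition]], poly_model)
}

#' Two-component (piecewise linear) Ca2+ model
#'
#' The alternative representation of the Fluo-4 time course as two straight
#' lines joined at the 2.5-min breakpoint: a fast accumulation phase on
#' 0--2.5 min and a slower phase on 2.5--15 min. It is fitted to the data
#' independently of the quartic and is numerically inconsistent with it at
#' late times; both parameterizations are kept as printed.
#'
#' @param condition `"control"` or `"c1193"`.
#' @return object of class `piecewise_model`: list with `early` and `late`
#'   [poly_model()]s (degree 1) and `breakpoint` (minutes).
#' @export
ca_piecewise_model <- function(condition = c("control", "c1193")) {
  condition <- match_condition(condition)
  pw <- .ca_piecewise[[condition]]
  structure(list(early = poly_model(pw$early), late = poly_model(pw$late),
                 breakpoint = 2.5),
            class = "piecewise_model")
}

#' @export
print.piecewise_model <- function(x, ...) {
  cat(sprintf("piecewise linear model, breakpoint %.2f min\n", x$breakpoint))
  cat(sprintf("  early: %.4g t %+.4g\n", coef(x$early)[2], coef(x$early)[1]))
  cat(sprintf("  late:  %.4g t %+.4g\n", coef(x$late)[2], coef(x$late)[1]))
  invisible(x)
}

#' @export
predict.piecewise_model <- function(object, times, ...) {
  unname(ifelse(times <= object$breakpoint,
                poly_eval(unname(coef(object$early)), times),
                poly_eval(unname(coef(object$late)), times)))
}

#' Transition activation speed from a dynamics model
#'
#' The firing speed of the Petri-net transition producing an observable is the
#' analytic first derivative of that observable's fluorescence-vs-time model;
#' applied to the control NADH cubic this reproduces the quadratic speed
#' -1.14 t^2 + 14.88 t - 49.20.
#'
#' @param dynamics a [poly_model()] (degree <= 4) or its coefficient vector
#'   (ascending).
#' @param valid_interval validity window of the resulting [rate_law()].
#' @return a [rate_law()].
#' @export
rate_from_dynamics <- function(dynamics, valid_interval = c(0, 15)) {
  co <- if (inherits(dynamics, "poly_model")) coef(dynamics) else dynamics
  stopifnot(length(co) <= 5L)
  rate_law(poly_deriv_coef(co), valid_interval)
}

poly_deriv_coef <- function(co) {
  if (length(co) == 1L) return(0)
  co[-1L] * seq_len(length(co) - 1L)
}

#' Electric potential from the NADH dynamics value
#'
#' The model's calculated inner-membrane electric potential is the NADH
#' fluorescence-change dynamics shifted by the constant -40.00 mV (the printed
#' EP equations equal the NADH cubics minus 40); the implied 1 fluorescence
#' unit = 1 mV identification is adopted as printed.
#'
#' @param nadh_dynamics_value NADH fluorescence change (relative units x1000).
#' @return EP in mV.
#' @export
ep_from_nadh <- function(nadh_dynamics_value) nadh_dynamics_value - 40.00

#' Build the mitochondrial HFPN for one condition
#'
#' Constructs the network of isolated myometrial mitochondria: substrate
#' places (succinate `Sc`, pyruvate `Pyr`; test-arc sources), generic places
#' for electron-transport-chain complexes I--IV and the NO-synthase, the five
#' continuous observable places (`NADH` and `EP` flagged `allow_negative`),
#' a `C1193` place holding the inhibitor concentration (M), a cyclosporin-A
#' place keeping the permeability transition pore (`MPTP`, a discrete
#' transition) silent, and per observable a pair of continuous transitions:
#' the control-rate transition gated by an inhibitory arc from `C1193`
#' (threshold 1 nM) and the inhibited-rate transition gated by a test arc at
#' the same threshold, so that exactly one of the pair is enabled at any
#' inhibitor concentration. Rates are the analytic derivatives of the
#' condition dynamics ([rate_from_dynamics()]); each observable place starts
#' at its model intercept. Negative intercepts of non-negative observables
#' (the C-1193 DAF-FM intercept -8.23) are raised to 0 with a message, the
#' analytic model being retained for fitting comparisons.
#'
#' @param condition `"control"` or `"c1193"`.
#' @param c1193_concentration inhibitor concentration in molar; defaults to 0
#'   (control) or 10 uM (c1193). Must be consistent with the condition.
#' @param ca_model `"quartic"` (default) or `"piecewise"`: which printed Ca2+
#'   parameterization drives the Fluo-4 transitions.
#' @return a validated `hfpn` whose `metadata` carries `condition` and the
#'   observable -> place map `observables`.
#' @export
build_mito_model <- function(condition = c("control", "c1193"),
                             c1193_concentration = NULL,
                             ca_model = c("quartic", "piecewise")) {
  condition <- match_condition(condition)
  ca_model <- match.arg(ca_model)
  if (is.null(c1193_concentration))
    c1193_concentration <- if (condition == "control") 0 else 1e-5
  stopifnot(c1193_concentration >= 0)
  if ((condition == "control") != (c1193_concentration == 0))
    stop("condition '", condition, "' is inconsistent with a C-1193 ",
         "concentration of ", c1193_concentration, " M")

  thr <- 1e-9  # gating threshold, 1 nM, well below the 10 uM dose
  dyn <- .dynamics[[condition]]

  intercept0 <- function(obs) {
    i0 <- dyn[[obs]][1]
    if (obs %in% c("NADH", "EP")) return(i0)
    if (i0 < 0) {
      message("initial marking of ", obs, " raised from ", i0,
              " to 0 (fluorescence cannot be negative; fit artifact)")
      i0 <- 0
    }
    i0
  }
  ca0 <- if (ca_model == "quartic") intercept0("Ca_Fluo4") else {
    i0 <- .ca_piecewise[[condition]]$early[1]
    if (i0 < 0) {
      message("initial marking of Ca_Fluo4 raised from ", i0,
              " to 0 (fluorescence cannot be negative; fit artifact)")
      i0 <- 0
    }
    i0
  }

  places <- list(
    place("Sc", "continuous", 5, "sodium succinate (mM)"),
    place("Pyr", "continuous", 5, "sodium pyruvate (mM)"),
    place("CxI", "generic", 1, "ETC complex I"),
    place("CxII", "generic", 1, "ETC complex II"),
    place("CxIII", "generic", 1, "ETC complex III"),
    place("CxIV", "generic", 1, "ETC complex IV"),
    place("NOS", "generic", 1, "mitochondrial NO-synthase"),
    place("CsA", "continuous", 0.005, "cyclosporin A (mM)"),
    place("C1193", "continuous", c1193_concentration,
          "thiacalix[4]arene C-1193 (M)"),
    place("NADH", "continuous", intercept0("NADH"),
          "NADH autofluorescence change (rel. units x1000)",
          allow_negative = TRUE),
    place("EP", "continuous", -40.00,
          "inner-membrane electric potential (mV)", allow_negative = TRUE),
    place("Ca_Fluo4", "continuous", ca0,
          "matrix Ca2+, Fluo-4 fluorescence (rel. units x1000)"),
    place("NO_DAFFM", "continuous", intercept0("NO_DAFFM"),
          "NO, DAF-FM fluorescence (rel. units x1000)"),
    place("ROS_DCF", "continuous", intercept0("ROS_DCF"),
          "ROS, DCF fluorescence (rel. units x1000)")
  )

  # per-observable rate laws for both gating branches; the active branch is
  # the one matching `condition` (the other branch carries the other
  # condition's printed rate so the gate, not the file, selects the dynamics)
  branch_rates <- function(obs) {
    if (obs == "Ca_Fluo4" && ca_model == "piecewise") {
      lapply(.ca_piecewise, function(pw) list(
        rate_law(poly_deriv_coef(pw$early), c(0, 2.5)),
        rate_law(poly_deriv_coef(pw$late), c(2.5, 15))
      ))
    } else {
      lapply(.dynamics, function(d) list(rate_from_dynamics(d[[obs]])))
    }
  }

  observables <- c("NADH", "EP", "Ca_Fluo4", "NO_DAFFM", "ROS_DCF")
  transitions <- list()
  arcs <- list()
  add_arc <- function(...) arcs[[length(arcs) + 1L]] <<- arc(...)

  # catalytic (test-arc) context of each observable's production
  context <- list(
    NADH = c("Sc", "Pyr", "CxI"),
    EP = c("Sc", "Pyr", "CxI", "CxII", "CxIII", "CxIV"),
    Ca_Fluo4 = c("Sc", "Pyr"),
    NO_DAFFM = c("Sc", "Pyr", "NOS"),
    ROS_DCF = c("Sc", "Pyr", "CxIII")
  )

  for (obs in observables) {
    rates <- branch_rates(obs)
    for (branch in c("control", "c1193")) {
      segs <- rates[[branch]]
      for (s in seq_along(segs)) {
        tag <- if (length(segs) > 1L) c("_early", "_late")[s] else ""
        tid <- sprintf("T_%s_%s%s", obs, if (branch == "control") "ctrl" else "c1193", tag)
        transitions[[length(transitions) + 1L]] <-
          transition(tid, "continuous", rate = segs[[s]],
                     label = sprintf("%s production, %s branch", obs, branch))
        add_arc(tid, obs, "normal", 1)
        if (branch == "control") add_arc("C1193", tid, "inhibitory", thr)
        else add_arc("C1193", tid, "test", thr)
        for (ctx in context[[obs]]) add_arc(ctx, tid, "test", 0.1)
      }
    }
  }

  # permeability transition pore: discrete, structurally present, never fires
  # (cyclosporin A in the medium inhibits it; the Ca2+-overload test threshold
  # is far above any reachable marking)
  transitions[[length(transitions) + 1L]] <-
    transition("MPTP", "discrete", delay = 0,
               label = "cyclosporin-sensitive permeability transition pore")
  add_arc("Ca_Fluo4", "MPTP", "test", 1e6)
  add_arc("CsA", "MPTP", "inhibitory", 0.001)
  add_arc("Ca_Fluo4", "MPTP", "normal", 1)

  net <- hfpn(places, transitions, arcs,
              metadata = list(
                condition = condition,
                c1193_concentration = c1193_concentration,
                ca_model = ca_model,
                observables = list(NADH = "NADH", EP = "EP",
                                   Ca_Fluo4 = "Ca_Fluo4",
                                   NO_DAFFM = "NO_DAFFM",
                                   ROS_DCF = "ROS_DCF", C1193 = "C1193")))
  stop_if_invalid(net)
}

#' Extract one observable's (time, value) trajectory
#'
#' @param traj an `hfpn_trajectory` from [simulate_hfpn()].
#' @param observable observable name; resolved through the net's observable
#'   map when present, otherwise used as a column name.
#' @return data.frame with columns `time` and `value`.
#' @export
observable_trajectory <- function(traj, observable) {
  map <- attr(traj, "metadata")$observables
  col <- if (!is.null(map) && observable %in% names(map)) map[[observable]]
         else observable
  if (!col %in% names(traj))
    stop("no place column '", col, "' in trajectory")
  data.frame(time = traj$time, value = traj[[col]])
}
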