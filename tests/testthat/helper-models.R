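# Canonical coefficient sets (ascending: intercept first) used across tests.
COEF <- list(
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

SPEED <- list(control = c(-49.20, 14.88, -1.14),
              c1193 = c(-30.80, 7.62, -0.48))

CA_PIECEWISE <- list(
  control = list(early = c(-11.41, 27.68), late = c(116.03, 20.44)),
  c1193   = list(early = c(1.01, 12.86),   late = c(66.43, 4.17))
)

# horner evaluation, independent of the package internals
peval <- function(co, t) {
  out <- rep(0, length(t))
  for (i in rev(seq_along(co))) out <- out * t + co[i]
  out
}

# exact antiderivative coefficients of a rate polynomial (oracle for the
# integrator): value at t of integral from 0, plus initial marking
integral_oracle <- function(rate_co, t, init = 0) {
  anti <- c(0, rate_co / seq_along(rate_co))
  init + peval(anti, t)
}

# documented integrator error contract: composite midpoint quadrature of a
# time-only rate p has |error(t)| <= dt^2/24 * |p'(t) - p'(0)| (+ rounding);
# used as the comparison bound wherever the simulated marking is checked
# against the exact antiderivative
midpoint_err_bound <- function(rate_co, t, dt) {
  dco <- if (length(rate_co) > 1) rate_co[-1] * seq_len(length(rate_co) - 1) else 0
  2 * dt^2 / 24 * abs(peval(dco, t) - peval(dco, 0)) + 1e-8
}

# minimal net: one continuous transition filling place X at a polynomial rate
single_transition_net <- function(rate_co, init = 0, allow_negative = TRUE,
                                  extra_places = list(), extra_arcs = list()) {
  hfpn(
    places = c(list(place("X", "continuous", init,
                          allow_negative = allow_negative)), extra_places),
    transitions = list(transition("T1", "continuous",
                                  rate = rate_law(rate_co))),
    arcs = c(list(arc("T1", "X", "normal", 1)), extra_arcs)
  )
}

# a state with one place's marking overridden (for enabling sweeps)
with_marking <- function(net, place_id, value) {
  st <- init_state(net)
  st$marking[[place_id]] <- value
  st
}
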