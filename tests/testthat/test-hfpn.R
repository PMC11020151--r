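test_that("validator reports structural violations, one per offending element", {
  # place -> place arc (bipartite violation)
  net <- hfpn(list(place("A"), place("B")),
              list(transition("T", "continuous", rate = rate_law(1))),
              list(arc("T", "A"), arc("A", "B")))
  d <- validate_hfpn(net)
  expect_length(d, 1L)
  expect_match(d, "A->B")
  expect_match(d, "bipartite")

  # duplicate place id
  net <- hfpn(list(place("NADH"), place("NADH")),
              list(transition("T", "continuous", rate = rate_law(1))),
              list(arc("T", "NADH")))
  d <- validate_hfpn(net)
  expect_length(d, 1L)
  expect_match(d, "NADH")

  # one diagnostic per violation across kinds
  net <- hfpn(
    list(place("P", "discrete", initial_marking = 1.5),
         place("Q", "continuous", initial_marking = -1)),
    list(transition("Tc", "continuous"),                      # missing rate
         transition("Td", "discrete", rate = rate_law(1)),    # rate, no delay
         transition("Te", "continuous",
                    rate = rate_law(c(1, 1, 1, 1, 1), c(0, 20)))),
    list(arc("P", "Tc"), arc("ghost", "Tc"),
         arc("Tc", "P", kind = "normal"),
         arc("Td", "P", kind = "normal"))
  )
  d <- validate_hfpn(net)
  expect_true(any(grepl("'P'.*nonnegative integer", d)))
  expect_true(any(grepl("'Q'.*allow_negative", d)))
  expect_true(any(grepl("'Tc'.*lacks a rate", d)))
  expect_true(any(grepl("'Td'.*delay", d)))
  expect_true(any(grepl("'Td'.*rate", d)))
  expect_true(any(grepl("'Te'.*\\[0, 15\\]", d)))
  expect_true(any(grepl("ghost", d)))
})

test_that("property: random malformed nets are rejected exactly when invariants break", {
  set.seed(42)
  base <- function() single_transition_net(c(1, 2))
  breakers <- list(
    function(n) { n$arcs[[2]] <- arc("X", "X"); n },          # place->place
    function(n) { n$places[[2]] <- place("X"); n },           # duplicate id
    function(n) { n$transitions[[1]]$rate <- NULL; n },       # continuous, no rate
    function(n) { n$arcs[[1]] <- arc("X", "T1", "inhibitory", -1); n },
    function(n) { n$transitions <- list(); n }                # no transitions
  )
  for (rep in 1:10) {
    n <- base()
    expect_length(validate_hfpn(n), 0L)
    broken <- breakers[[sample.int(length(breakers), 1)]](n)
    expect_gt(length(validate_hfpn(broken)), 0L)
  }
})

test_that("shipped mitochondrial model files validate cleanly", {
  for (f in c("mito_control.yaml", "mito_c1193.yaml")) {
    net <- read_hfpn_yaml(system.file("extdata", f, package = "mitohfpn"))
    expect_length(validate_hfpn(net), 0L)
  }
})

test_that("test and inhibitory arc enabling semantics", {
  mk <- function(kind, thr) single_transition_net(
    13.9, extra_places = list(place("G", "continuous", 0)),
    extra_arcs = list(arc("G", "T1", kind, thr)))

  net <- mk("inhibitory", 0.001)
  expect_true(is_enabled(net, with_marking(net, "G", 0), "T1"))        # below
  expect_false(is_enabled(net, with_marking(net, "G", 10), "T1"))      # above
  expect_false(is_enabled(net, with_marking(net, "G", 0.001), "T1"))   # at: disabled

  net <- mk("test", 1)
  expect_true(is_enabled(net, with_marking(net, "G", 5), "T1"))
  expect_true(is_enabled(net, with_marking(net, "G", 1), "T1"))        # at: enabled
  expect_false(is_enabled(net, with_marking(net, "G", 0.5), "T1"))

  expect_error(is_enabled(net, init_state(net), "nope"), "nope")
})

test_that("step advances markings by rate(t)*dt and respects gating and clamping", {
  # constant rate 13.9 into a place holding 1000
  net <- single_transition_net(13.9, init = 1000)
  st <- hfpn_step(net, init_state(net), 0.1)
  expect_equal(st$marking[["X"]], 1001.39)
  expect_equal(st$time, 0.1)

  # zero rate: identity
  net0 <- single_transition_net(0, init = 7)
  expect_equal(hfpn_step(net0, init_state(net0), 0.5)$marking[["X"]], 7)

  # transition disabled by an inhibitory arc leaves outputs unchanged
  net_i <- single_transition_net(
    13.9, init = 1000,
    extra_places = list(place("I", "continuous", 1)),
    extra_arcs = list(arc("I", "T1", "inhibitory", 0.5)))
  expect_equal(hfpn_step(net_i, init_state(net_i), 0.1)$marking[["X"]], 1000)

  # normal input arcs consume weight * rate * dt
  net_c <- hfpn(
    list(place("S", "continuous", 10), place("P", "continuous", 0)),
    list(transition("T", "continuous", rate = rate_law(2))),
    list(arc("S", "T", "normal", 3), arc("T", "P", "normal", 1)))
  st <- hfpn_step(net_c, init_state(net_c), 0.1)
  expect_equal(st$marking[["S"]], 10 - 3 * 2 * 0.1)
  expect_equal(st$marking[["P"]], 0.2)

  # negative flow clamps non-allow_negative places at 0 and logs it
  net_n <- single_transition_net(-100, init = 1, allow_negative = FALSE)
  st <- hfpn_step(net_n, init_state(net_n), 0.1)
  expect_equal(st$marking[["X"]], 0)
  expect_equal(nrow(st$clamp_log), 1L)
  expect_equal(st$clamp_log$place, "X")

  # allow_negative places are not clamped
  net_s <- single_transition_net(-100, init = 1, allow_negative = TRUE)
  expect_lt(hfpn_step(net_s, init_state(net_s), 0.1)$marking[["X"]], 0)

  # nonfinite rate names the transition and the time
  net_o <- single_transition_net(c(0, 1e308))
  expect_error(hfpn_step(net_o, init_state(net_o), 10), "T1")
})

test_that("integrator matches closed-form antiderivatives for degree <= 4 rates", {
  set.seed(7)
  for (rep in 1:8) {
    deg <- sample(0:4, 1)
    co <- round(stats::runif(deg + 1, -10, 10), 2)
    net <- single_transition_net(co)
    traj <- simulate_hfpn(net, 15, dt = 0.005, sample_every = 1)
    for (t in c(1, 5, 10, 15)) {
      expect_lt(abs(traj$X[traj$time == t] - integral_oracle(co, t)),
                midpoint_err_bound(co, t, 0.005))
    }
  }
})

test_that("halving dt at least halves the integration error", {
  co <- c(3, -2, 5, -1, 0.2)               # degree-4 rate: nonzero midpoint error
  net <- single_transition_net(co)
  err <- function(dt) {
    traj <- simulate_hfpn(net, 15, dt = dt, sample_every = 15,
                          engine = "stepwise")
    abs(traj$X[traj$time == 15] - integral_oracle(co, 15))
  }
  e1 <- err(0.25); e2 <- err(0.125)
  expect_gt(e1, 1e-8)                       # above numerical noise
  expect_lt(e2, 0.5 * e1 + 1e-10)
})

test_that("spec'd simulation examples hold", {
  # quadratic NADH speed from marking 0: exact integral at t = 2 is -71.68
  net <- single_transition_net(c(-49.20, 14.88, -1.14))
  traj <- simulate_hfpn(net, 2, dt = 0.001, sample_every = 2)
  expect_equal(traj$X[traj$time == 2], -71.68, tolerance = 1e-6)

  # constant 13.9 from 1000 reaches 1208.5 at t = 15
  net <- single_transition_net(13.9, init = 1000)
  traj <- simulate_hfpn(net, 15, dt = 0.001, sample_every = 15)
  expect_equal(traj$X[traj$time == 15], 1208.5, tolerance = 1e-9)

  # t_end = 0: single sample equal to the initial marking
  traj0 <- simulate_hfpn(net, 0)
  expect_equal(nrow(traj0), 1L)
  expect_equal(traj0$X, 1000)
})

test_that("simulate preconditions and the 15-min validity cap", {
  net <- single_transition_net(1)
  expect_error(simulate_hfpn(net, 20), "15-min")
  expect_warning(simulate_hfpn(net, 20, dt = 0.5, sample_every = 10,
                               allow_beyond_validity = TRUE), "validity")
  expect_error(simulate_hfpn(net, 10, dt = 0.3, sample_every = 0.5),
               "multiple")
  expect_error(simulate_hfpn(net, 1, dt = 0.5, sample_every = 2), "sample_every")
})

test_that("test/inhibitory arcs never mutate markings; engine is deterministic", {
  net <- hfpn(
    list(place("A", "continuous", 4), place("B", "continuous", 2),
         place("X", "continuous", 0)),
    list(transition("T", "continuous", rate = rate_law(c(1, 2)))),
    list(arc("A", "T", "test", 1), arc("B", "T", "inhibitory", 10),
         arc("T", "X", "normal", 1)))
  traj <- simulate_hfpn(net, 10, dt = 0.01, sample_every = 1)
  expect_true(all(traj$A == 4))
  expect_true(all(traj$B == 2))
  expect_gt(traj$X[traj$time == 10], 0)

  traj2 <- simulate_hfpn(net, 10, dt = 0.01, sample_every = 1)
  expect_identical(as.data.frame(traj), as.data.frame(traj2))
})

test_that("vectorized and stepwise engines agree on the full model", {
  net <- build_mito_model("control")
  a <- simulate_hfpn(net, 15, dt = 0.01, sample_every = 0.5)
  b <- simulate_hfpn(net, 15, dt = 0.01, sample_every = 0.5,
                     engine = "stepwise")
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-10)
  expect_equal(nrow(attr(a, "clamp_log")), nrow(attr(b, "clamp_log")))
})

test_that("YAML serialization round-trips nets losslessly", {
  net <- build_mito_model("c1193")
  path <- tempfile(fileext = ".yaml")
  on.exit(unlink(path))
  write_hfpn_yaml(net, path)
  net2 <- read_hfpn_yaml(path)
  expect_length(validate_hfpn(net2), 0L)
  expect_equal(length(net2$places), length(net$places))
  expect_equal(length(net2$transitions), length(net$transitions))
  expect_equal(length(net2$arcs), length(net$arcs))
  for (i in seq_along(net$places))
    expect_equal(net2$places[[i]], net$places[[i]], tolerance = 1e-10)
  for (i in seq_along(net$transitions))
    expect_equal(net2$transitions[[i]], net$transitions[[i]], tolerance = 1e-10)
  for (i in seq_along(net$arcs))
    expect_equal(net2$arcs[[i]], net$arcs[[i]], tolerance = 1e-10)
  # and the round-tripped net simulates identically
  a <- simulate_hfpn(net, 5, dt = 0.01, sample_every = 1)
  b <- simulate_hfpn(net2, 5, dt = 0.01, sample_every = 1)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-9)
})
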