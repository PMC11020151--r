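test_that("dynamics polynomials carry the documented coefficient sets", {
  for (cond in c("control", "c1193")) {
    dyn <- dynamics_polynomials(cond)
    for (obs in names(COEF[[cond]]))
      expect_equal(unname(coef(dyn[[obs]])), COEF[[cond]][[obs]],
                   info = paste(cond, obs))
  }
  expect_error(dynamics_polynomials("mystery"))

  # spot values
  dyn <- dynamics_polynomials("control")
  expect_equal(predict(dyn$NADH, 5), -107.5)
  expect_equal(predict(dyn$Ca_Fluo4, 0), 1.57)
  dyn2 <- dynamics_polynomials("c1193")
  expect_equal(predict(dyn2$NADH, 5), -78.75)
})

test_that("transition speeds are the analytic derivatives of the dynamics", {
  for (cond in c("control", "c1193")) {
    rl <- rate_from_dynamics(dynamics_polynomials(cond)$NADH)
    expect_equal(unname(rl$coefficients), SPEED[[cond]], info = cond)
  }
  expect_equal(rate_from_dynamics(poly_model(5))$coefficients, 0)
})

test_that("electric potential is the NADH dynamics shifted by -40 mV", {
  expect_equal(ep_from_nadh(0), -40.00)
  expect_equal(ep_from_nadh(-107.5), -147.5)
  for (cond in c("control", "c1193"))
    expect_equal(predict(dynamics_polynomials(cond)$EP, 0), -40.00)
})

test_that("built nets validate and reach the analytic endpoint values", {
  net <- build_mito_model("control")
  expect_length(validate_hfpn(net), 0L)
  traj <- simulate_hfpn(net, 15, dt = 0.005, sample_every = 0.5)
  expect_equal(traj$ROS_DCF[traj$time == 15], 1208.5, tolerance = 1e-8)
  expect_equal(traj$NO_DAFFM[traj$time == 10], 190.81, tolerance = 1e-8)

  netc <- suppressMessages(build_mito_model("c1193"))
  trajc <- simulate_hfpn(netc, 15, dt = 0.005, sample_every = 0.5)
  expect_equal(trajc$ROS_DCF[trajc$time == 15], 1019.5, tolerance = 1e-8)
})

test_that("condition gating: exactly one transition of each pair is enabled at any dose", {
  net <- suppressMessages(build_mito_model("c1193"))
  pairs <- list(c("T_NADH_ctrl", "T_NADH_c1193"),
                c("T_EP_ctrl", "T_EP_c1193"),
                c("T_Ca_Fluo4_ctrl", "T_Ca_Fluo4_c1193"),
                c("T_NO_DAFFM_ctrl", "T_NO_DAFFM_c1193"),
                c("T_ROS_DCF_ctrl", "T_ROS_DCF_c1193"))
  for (conc in c(0, 1e-10, 0.999e-9, 1e-9, 1e-8, 1e-7, 1e-6, 1e-5, 1e-4)) {
    st <- with_marking(net, "C1193", conc)
    for (p in pairs) {
      en <- c(is_enabled(net, st, p[1]), is_enabled(net, st, p[2]))
      expect_equal(sum(en), 1L,
                   info = sprintf("%s at %g M", p[1], conc))
      expect_equal(en[2], conc >= 1e-9)
    }
  }
})

test_that("the permeability transition pore never fires", {
  for (cond in c("control", "c1193")) {
    net <- suppressMessages(build_mito_model(cond))
    for (eng in c("auto", "stepwise")) {
      traj <- simulate_hfpn(net, 15, dt = 0.05, sample_every = 1, engine = eng)
      expect_equal(nrow(attr(traj, "event_log")), 0L,
                   info = paste(cond, eng))
    }
  }
})

test_that("EP trajectory equals NADH trajectory minus 40 at every sample", {
  for (cond in c("control", "c1193")) {
    net <- suppressMessages(build_mito_model(cond))
    traj <- simulate_hfpn(net, 15, dt = 0.01, sample_every = 0.5)
    expect_equal(traj$EP, traj$NADH - 40.00, tolerance = 1e-12, info = cond)
  }
})

test_that("simulate -> fit round-trip recovers the model coefficients", {
  # moderate dt here; the full-precision dt = 0.001 contract is exercised by
  # the acceptance suite
  for (cond in c("control", "c1193")) {
    net <- suppressMessages(build_mito_model(cond))
    traj <- simulate_hfpn(net, 15, dt = 0.005, sample_every = 0.5)
    co <- COEF[[cond]]

    nadh <- fit_polynomial(observable_trajectory(traj, "NADH"), 3)
    expect_equal(unname(coef(nadh))[2:4], co$NADH[2:4], tolerance = 1e-5)
    expect_lt(abs(coef(nadh)[1]), 1e-4)

    dcf <- fit_polynomial(observable_trajectory(traj, "ROS_DCF"), 1)
    expect_equal(unname(coef(dcf)), co$ROS_DCF, tolerance = 1e-7)

    daf <- fit_polynomial(observable_trajectory(traj, "NO_DAFFM"), 1)
    expect_equal(unname(coef(daf))[2], co$NO_DAFFM[2], tolerance = 1e-7)
    if (cond == "control")
      expect_equal(unname(coef(daf))[1], co$NO_DAFFM[1], tolerance = 1e-6)

    # the quartic is recovered on the interval before the Ca2+ place clamps
    # at zero (the printed quartic goes negative past ~12 min and fluorescence
    # places are clamped)
    ca <- observable_trajectory(traj, "Ca_Fluo4")
    ca_fit <- fit_polynomial(ca[ca$time <= 10.5, ], 4)
    expect_equal(unname(coef(ca_fit)), co$Ca_Fluo4, tolerance = 1e-4)
  }
})

test_that("negative fluorescence intercepts are raised to zero with a message", {
  expect_message(build_mito_model("c1193"), "NO_DAFFM")
  net <- suppressMessages(build_mito_model("c1193"))
  expect_equal(init_state(net)$marking[["NO_DAFFM"]], 0)
  # the analytic model keeps the printed negative intercept for fitting
  expect_equal(unname(coef(dynamics_polynomials("c1193")$NO_DAFFM))[1], -8.23)
})

test_that("piecewise Ca2+ parameterization is selectable and simulates", {
  expect_message(net <- build_mito_model("control", ca_model = "piecewise"),
                 "Ca_Fluo4")
  expect_length(validate_hfpn(net), 0L)
  traj <- simulate_hfpn(net, 15, dt = 0.005, sample_every = 0.5)
  # early phase integrates the 27.68/min line from a zero floor
  early <- observable_trajectory(traj, "Ca_Fluo4")
  early <- early[early$time > 0 & early$time <= 2.5, ]
  expect_equal(fit_polynomial(early, 1)$coefficients[["c1"]],
               CA_PIECEWISE$control$early[2], tolerance = 1e-6)
  # late phase advances at the late slope
  late <- observable_trajectory(traj, "Ca_Fluo4")
  late <- late[late$time >= 3, ]
  expect_equal(fit_polynomial(late, 1)$coefficients[["c1"]],
               CA_PIECEWISE$control$late[2], tolerance = 1e-6)
})

test_that("condition/concentration consistency is enforced", {
  expect_error(build_mito_model("control", c1193_concentration = 1e-5),
               "inconsistent")
  expect_error(suppressMessages(build_mito_model("c1193", c1193_concentration = 0)),
               "inconsistent")
  net <- suppressMessages(build_mito_model("c1193", c1193_concentration = 1e-6))
  expect_equal(init_state(net)$marking[["C1193"]], 1e-6)
})
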