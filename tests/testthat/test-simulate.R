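# Trajectory integration, equilibration detection, dominance.

test_that("unsupplemented informed dynamics approach the 0.6 equilibrium", {
  tr <- cf_simulate(informed, cf_init(0.2), t_end = 300)
  fr <- fractions(tr)
  expect_equal(fr$frac_ADE[1], 0.2, tolerance = 1e-12)
  final <- fr$frac_ADE[nrow(fr)]
  expect_lt(abs(final - 0.6), 0.05)
  expect_gt(final, 0.5) # ADE-up rises from the 0.2 start
  # strain fractions sum to 1 on the whole grid
  expect_equal(fr$frac_LYS + fr$frac_ADE + fr$frac_O, rep(1, nrow(fr)),
               tolerance = 1e-12)
})

test_that("symmetric parameters give equal strain and metabolite fractions", {
  tr <- cf_simulate(neutral, cf_init(0.2), t_end = 300)
  fr <- fractions(tr)
  n <- nrow(fr)
  expect_equal(fr$frac_ADE[n], 0.5, tolerance = 0.02)
  expect_equal(fr$frac_cA[n], 0.5, tolerance = 0.02)
})

test_that("a missing partner is an absorbing boundary", {
  tr <- cf_simulate(informed, cf_state(xL = 0.2, xA = 0), t_end = 50)
  expect_true(all(tr$states[, "xA"] == 0))
  # no adenine source -> LYS-up cannot grow either
  expect_equal(unname(tr$states[nrow(tr$states), "xL"]), 0.2,
               tolerance = 1e-9)
})

test_that("trajectories stay non-negative and bounded by K", {
  regs <- list(cf_regime("none"),
               cf_regime("initial", doseA = 10, doseL = 5),
               cf_regime("intermittent", doseA = 2, doseL = 1, period = 10,
                         start = 10),
               cf_regime("continuous", doseA = 0.3, doseL = 0.3))
  set.seed(11)
  for (reg in regs) {
    init <- cf_init(runif(1, 0.05, 0.95), total = runif(1, 0.05, 0.9))
    tr <- cf_simulate(informed, init, reg, t_end = 100)
    expect_true(all(tr$states >= 0))
    expect_true(all(rowSums(tr$states[, 1:3]) <= informed$K + 1e-9))
  }
})

test_that("compiled integrator agrees with the pure-R reference path", {
  tr_c <- cf_simulate(informed, cf_init(0.2), t_end = 50)
  tr_r <- cf_simulate(informed, cf_init(0.2), t_end = 50, method = "r")
  expect_equal(tr_r$states, tr_c$states, tolerance = 1e-6)
})

test_that("fixed-step Euler oracle brackets the production integrator", {
  # independent oracle: explicit Euler, step 1e-4, on [0, 50]
  pv <- c(informed$r1, informed$r2, informed$K, informed$beta1,
          informed$beta2, informed$gamma1, informed$gamma2, informed$kcA,
          informed$kcL, informed$ro, 0, 0)
  f <- function(t, y, pv) {
    crowd <- 1 - (y[1] + y[2] + y[3]) / pv[3]
    mA <- if (y[4] <= 0) 0 else y[4] / (y[4] + pv[8])
    mL <- if (y[5] <= 0) 0 else y[5] / (y[5] + pv[9])
    c(y[1] * pv[1] * mA * crowd, y[2] * pv[2] * mL * crowd,
      y[3] * pv[10] * crowd,
      pv[4] * (y[2] + y[3]) - pv[6] * mA * y[1],
      pv[5] * (y[1] + y[3]) - pv[7] * mL * y[2])
  }
  init <- cf_init(0.2)
  eu <- euler(f, c(init$xL, init$xA, init$xO, init$cA, init$cL), 0:50,
              pv = pv, h = 1e-4)
  tr <- cf_simulate(informed, init, t_end = 50)
  expect_lt(max(abs(eu - tr$states)), 1e-3)
})

test_that("equilibration detection implements the 1e-4 step criterion", {
  # constant trajectory: equilibrated from the second reporting point
  const <- fake_trajectory(state_mat(c(0.3, 0.3, 0, 1, 1),
                                     c(0.3, 0.3, 0, 1, 1),
                                     c(0.3, 0.3, 0, 1, 1)))
  eq <- detect_equilibration(const)
  expect_true(eq$equilibrated)
  expect_equal(eq$first_time, 1)
  expect_equal(eq$max_step_change, 0)

  # linear growth with slope 1 per step never equilibrates at 1e-4
  lin <- fake_trajectory(state_mat(c(0, 0.1, 0, 0, 0), c(1, 0.1, 0, 0, 0),
                                   c(2, 0.1, 0, 0, 0)))
  expect_false(detect_equilibration(lin)$equilibrated)
  expect_true(is.na(detect_equilibration(lin)$first_time))

  # metabolite drift is ignored unless all_components = TRUE
  met <- fake_trajectory(state_mat(c(0.3, 0.3, 0, 0, 0),
                                   c(0.3, 0.3, 0, 1, 0),
                                   c(0.3, 0.3, 0, 2, 0)))
  expect_true(detect_equilibration(met)$equilibrated)
  expect_false(detect_equilibration(met, all_components = TRUE)$equilibrated)

  # real run: unsupplemented informed culture equilibrates well before 300
  tr <- cf_simulate(informed, cf_init(0.5), t_end = 300)
  eq <- detect_equilibration(tr)
  expect_true(eq$equilibrated)
  expect_lt(eq$first_time, 300)

  expect_error(
    detect_equilibration(fake_trajectory(state_mat(c(1, 1, 0, 0, 0)))),
    "at least 2")
})

test_that("dominant_strain picks the strictly largest fraction", {
  expect_equal(dominant_strain(cf_state(0.2, 0.5, xO = 0.1)), "ADE")
  expect_equal(dominant_strain(cf_state(0.5, 0.2, xO = 0.1)), "LYS")
  expect_equal(dominant_strain(cf_state(0.1, 0.2, xO = 0.5)),
               "overproducer")
  expect_equal(dominant_strain(cf_state(0.3, 0.3, xO = 0)), "tie")
  expect_error(dominant_strain(cf_state(0, 0, xO = 0)), "extinct")
  # trajectory method uses the final state
  tr <- cf_simulate(informed, cf_init(0.2), t_end = 300)
  expect_equal(dominant_strain(tr), "ADE")
})

test_that("trajectory CSV round-trips and carries fractions", {
  tr <- cf_simulate(informed, cf_init(0.3),
                    cf_regime("initial", doseA = 1), t_end = 20)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read_trajectory(f)
  expect_equal(names(back),
               c("t", "xL", "xA", "xO", "cA", "cL", "frac_LYS", "frac_ADE",
                 "frac_O"))
  expect_equal(back$xL, unname(tr$states[, "xL"]), tolerance = 1e-15)
  expect_equal(back$cA, unname(tr$states[, "cA"]), tolerance = 1e-15)
  expect_equal(back$frac_ADE, fractions(tr)$frac_ADE, tolerance = 1e-15)
})

test_that("t_end must sit on the unit reporting grid", {
  expect_error(cf_simulate(informed, cf_init(0.5), t_end = 10.5),
               "reporting step")
  expect_error(cf_simulate(informed, cf_init(0.5), t_end = 0),
               "reporting step")
})
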