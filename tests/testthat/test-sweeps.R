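# Phase diagrams, coexistence zone, timing sweeps, dominance grids.
# Grids are kept small; each cell is a full 300-step integration.

doses3 <- c(0.1, 1, 10)
ratios3 <- c(0.5, 1, 2)

test_that("coexistence zone counts cells inside the band", {
  allmid <- structure(list(grid = data.frame(frac_ADE = rep(0.5, 9))),
                      class = "cf_phase_diagram")
  expect_equal(coexistence_zone(allmid), 1)
  allhi <- structure(list(grid = data.frame(frac_ADE = rep(0.95, 9))),
                     class = "cf_phase_diagram")
  expect_equal(coexistence_zone(allhi), 0)
  v <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  expect_equal(coexistence_zone(v), 3 / 5)
  # widening the band never decreases the zone
  expect_gte(coexistence_zone(v, 0.1, 0.9), coexistence_zone(v, 0.2, 0.8))
  expect_error(coexistence_zone(numeric(0)), "empty")
  expect_error(coexistence_zone(v, 0.8, 0.2))
})

test_that("initial-supplementation snapshot is monotone in adenine dose", {
  fr <- vapply(c(0.1, 1, 10), function(d)
    final_ade_fraction(cf_simulate(informed, cf_init(0.5),
                                   cf_regime("initial", doseA = d),
                                   t_end = 300)), numeric(1))
  unsupp <- final_ade_fraction(cf_simulate(informed, cf_init(0.5),
                                           t_end = 300))
  expect_true(all(diff(c(unsupp, fr)) < 0))
  # a very large adenine-only dose hands the culture to LYS-up
  big <- final_ade_fraction(cf_simulate(informed, cf_init(0.5),
                                        cf_regime("initial", doseA = 100),
                                        t_end = 300))
  expect_lt(big, fr[3]) # below the dose-10 snapshot (~0.13)
  expect_lt(big, 0.15)
})

test_that("phase diagrams are deterministic and ordered across regimes", {
  pd_ini <- phase_diagram(informed, cf_regime("initial"), doses3, ratios3)
  expect_true(all(pd_ini$grid$frac_ADE >= 0 & pd_ini$grid$frac_ADE <= 1))
  expect_equal(pd_ini$grid$doseL, pd_ini$grid$doseA * pd_ini$grid$ratioL)

  # bit-identical on rerun: no hidden randomness
  pd_ini2 <- phase_diagram(informed, cf_regime("initial"), doses3, ratios3)
  expect_identical(pd_ini$grid, pd_ini2$grid)

  pd_int <- phase_diagram(informed,
                          cf_regime("intermittent", period = 25,
                                    start = 25), doses3, ratios3)
  pd_cont <- phase_diagram(informed, cf_regime("continuous"), doses3,
                           ratios3)
  z <- vapply(list(pd_ini, pd_int, pd_cont), coexistence_zone, numeric(1))
  expect_gte(z[1], z[2])
  expect_gte(z[2], z[3])

  # dose 0 collapses every cell to the unsupplemented snapshot
  pd0 <- phase_diagram(informed, cf_regime("initial"), 0, ratios3)
  unsupp <- final_ade_fraction(cf_simulate(informed, cf_init(0.5),
                                           t_end = 300))
  expect_equal(pd0$grid$frac_ADE, rep(unsupp, 3), tolerance = 1e-9)

  # continuous lysine excess hands the culture to ADE-up
  lys <- cf_simulate(informed, cf_init(0.5),
                     cf_regime("continuous", doseA = 0, doseL = 0.3),
                     t_end = 300)
  expect_gt(final_ade_fraction(lys), 0.8)
})

test_that("timing sweep: longer periods stay closer to the baseline", {
  eq <- final_ade_fraction(cf_simulate(informed, cf_init(0.5), t_end = 300))
  tw <- timing_sweep(informed, periods = c(10, 30, 60), doses = 1)
  expect_equal(nrow(tw), 3)
  dev <- abs(tw$frac_ADE[order(tw$period)] - eq)
  expect_true(all(diff(dev) <= 0))

  # dose 0 reproduces the unsupplemented snapshot for every period
  tw0 <- timing_sweep(informed, periods = c(10, 60), doses = 0)
  expect_equal(tw0$frac_ADE, rep(eq, 2), tolerance = 1e-9)
})

test_that("start time of a high dose controls initial-condition ordering", {
  # early start preserves the ordering of outcomes by initial fraction;
  # a late start (after the transient) scrambles or inverts it
  sw <- timing_sweep(informed, periods = 5, doses = 10,
                     init_fractions = c(0.2, 0.8),
                     start_times = c(5, 25),
                     include_initial_dose = FALSE)
  f <- function(st, init) sw$frac_ADE[sw$start == st &
                                        sw$init_fraction == init]
  expect_gt(f(5, 0.8), f(5, 0.2))      # order preserved
  expect_lt(f(25, 0.8), f(25, 0.2))    # order lost after the transient
})

test_that("dominance grid reproduces the baseline and high-ro flips", {
  g <- overproducer_grid(informed, ro_values = c(0.1, 0.7),
                         intervention_times = c(1, 10),
                         lysine_doses = c(0, 0.1))
  expect_s3_class(g, "cf_dominance_grid")
  expect_true(all(g$dominant %in% c("LYS", "ADE", "overproducer", "tie")))

  base01 <- g$dominant[g$ro == 0.1 & g$dose == 0]
  expect_true(all(base01 == "ADE")) # no intervention: ADE-up dominates
  base07 <- g$dominant[g$ro == 0.7]
  expect_true(all(base07 == "overproducer")) # high ro: overproducer wins
  # small lysine dose at every time step does not destabilize ADE dominance
  expect_equal(g$dominant[g$ro == 0.1 & g$dose == 0.1 & g$tau == 1], "ADE")
})

test_that("grids serialize as long CSV with JSON metadata", {
  pd <- phase_diagram(informed, cf_regime("initial"), c(0.1, 1), c(1, 2),
                      snapshot_time = 100)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_grid(pd, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), 4)
  expect_equal(back$frac_ADE, pd$grid$frac_ADE, tolerance = 1e-12)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$regime$mode, "initial")
  expect_equal(meta$snapshot_time, 100)
})
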