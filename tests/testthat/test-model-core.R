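# Right-hand sides of the two- and three-strain systems.

test_that("strain growth terms match hand-evaluated values", {
  # zero metabolites abolish growth
  d0 <- strain_rhs(cf_state(0.2, 0.2, cA = 0, cL = 0), informed)
  expect_identical(d0$dxL, 0)
  expect_identical(d0$dxA, 0)

  # logistic factor vanishes at carrying capacity
  dK <- strain_rhs(cf_state(0.5, 0.5, cA = 3, cL = 7), informed)
  expect_equal(dK$dxL, 0)
  expect_equal(dK$dxA, 0)

  # frozen values from manual substitution:
  # dxL = 0.2 * 1 * (0.1/2.1) * 0.6, dxA = 0.2 * 2 * (0.1/1.1) * 0.6
  d <- strain_rhs(cf_state(0.2, 0.2, cA = 0.1, cL = 0.1), informed)
  expect_equal(d$dxL, 0.00571428571428571, tolerance = 1e-12)
  expect_equal(d$dxA, 0.02181818181818182, tolerance = 1e-12)
})

test_that("metabolite production/uptake terms match hand-evaluated values", {
  # no producers, no consumers
  d0 <- metabolite_rhs(cf_state(0, 0, cA = 0.7, cL = 0.3), informed)
  expect_identical(d0$dcA, 0)
  expect_identical(d0$dcL, 0)

  # uptake vanishes at zero concentration even with beta = 0
  p0 <- cf_params(beta1 = 0, beta2 = 0, kcA = 2)
  dz <- metabolite_rhs(cf_state(0.3, 0.4, cA = 0, cL = 0), p0)
  expect_identical(dz$dcA, 0)
  expect_identical(dz$dcL, 0)

  # frozen: dcA = 0.1*0.2 - (0.1/2.1)*0.2, dcL = 0.1*0.2 - (0.1/1.1)*0.2
  d <- metabolite_rhs(cf_state(0.2, 0.2, cA = 0.1, cL = 0.1), informed)
  expect_equal(d$dcA, 0.01047619047619048, tolerance = 1e-12)
  expect_equal(d$dcL, 0.00181818181818182, tolerance = 1e-11)
})

test_that("overproducer growth is metabolite-independent and logistic", {
  p <- cf_preset("informed", ro = 0.5)
  expect_identical(overproducer_rhs(cf_state(0.2, 0.2, xO = 0), p)$dxO, 0)
  expect_equal(overproducer_rhs(cf_state(0.4, 0.5, xO = 0.1), p)$dxO, 0)
  # frozen: 0.1 * 0.5 * (1 - 0.5)
  d <- overproducer_rhs(cf_state(0.2, 0.2, xO = 0.1, cA = 9, cL = 9), p)
  expect_equal(d$dxO, 0.025, tolerance = 1e-14)
  # independent of concentrations
  d2 <- overproducer_rhs(cf_state(0.2, 0.2, xO = 0.1), p)
  expect_identical(d$dxO, d2$dxO)
})

test_that("three-strain RHS reduces to the two-strain RHS when xO = 0", {
  for (s in random_states(10)) {
    s$xO <- 0
    full <- cf_rhs(s, informed)
    two_s <- strain_rhs(s, informed)
    two_m <- metabolite_rhs(s, informed)
    expect_identical(unname(full[["dxL"]]), two_s$dxL)
    expect_identical(unname(full[["dxA"]]), two_s$dxA)
    expect_identical(unname(full[["dxO"]]), 0)
    expect_identical(unname(full[["dcA"]]), two_m$dcA)
    expect_identical(unname(full[["dcL"]]), two_m$dcL)
  }
})

test_that("RHS respects non-negativity and boundedness at the boundaries", {
  p <- cf_preset("informed", ro = 0.3)
  for (s in random_states(20, seed = 7)) {
    # any component at 0 has non-negative derivative there
    for (comp in c("xL", "xA", "xO", "cA", "cL")) {
      sz <- s
      sz[[comp]] <- 0
      d <- cf_rhs(sz, p)
      expect_gte(d[[paste0("d", comp)]], 0)
    }
    # the strain-sum derivative vanishes at the carrying capacity
    tot <- s$xL + s$xA + s$xO
    sK <- s
    sK$xL <- s$xL / tot * p$K
    sK$xA <- s$xA / tot * p$K
    sK$xO <- s$xO / tot * p$K
    d <- cf_rhs(sK, p)
    expect_equal(unname(d[["dxL"]] + d[["dxA"]] + d[["dxO"]]), 0,
                 tolerance = 1e-12)
  }
})

test_that("with zero uptake the metabolite derivatives are non-negative", {
  p <- cf_params(gamma1 = 0, gamma2 = 0)
  for (s in random_states(10, seed = 3)) {
    d <- metabolite_rhs(s, p)
    expect_gte(d$dcA, 0)
    expect_gte(d$dcL, 0)
  }
})

test_that("invalid states and parameters are rejected", {
  expect_error(cf_state(-0.1, 0.2), "non-negative")
  expect_error(strain_rhs(structure(list(xL = -1, xA = 0, xO = 0, cA = 0,
                                         cL = 0, t = 0),
                                    class = "cf_state"), informed),
               "invalid state")
  expect_error(cf_params(K = 0), "carrying capacity")
  expect_error(cf_params(kcA = 0), "strictly positive")
  expect_error(cf_params(r1 = -1), "non-negative")
  expect_error(monod(0.5, 0), "> 0")
  expect_identical(monod(0, 2), 0)
})

test_that("presets and YAML configs round-trip", {
  expect_equal(informed[c("r1", "r2", "kcA", "kcL")],
               list(r1 = 1, r2 = 2, kcA = 2, kcL = 1))
  expect_equal(neutral[c("r1", "r2", "kcA", "kcL")],
               list(r1 = 1, r2 = 1, kcA = 1, kcL = 1))
  expect_equal(informed$beta1, 0.1)
  expect_equal(informed$gamma2, 1)

  f <- tempfile(fileext = ".yaml")
  write_params(cf_preset("informed", ro = 0.4), f)
  expect_equal(read_params(f), cf_preset("informed", ro = 0.4))

  shipped <- system.file("extdata", "params_informed.yaml",
                         package = "crossfeedr")
  expect_equal(read_params(shipped), informed)

  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(r1 = 1, bogus = 2), bad)
  expect_error(read_params(bad), "unknown parameter")
})
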