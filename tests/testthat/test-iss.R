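test_that("intracellular 25OHD balances influx against enzymatic flux", {
  pars <- cell_params()
  act <- activated_state()
  # trivial ends
  expect_equal(solve_v1c(0, pars, act)$v1c, 0)
  expect_equal(solve_v1c(0, pars, act)$conversion_flux, 0)
  no_enzyme <- update_cell_params(pars, v_max = 0)
  expect_equal(solve_v1c(3e-5, no_enzyme)$v1c, 3e-5)
  # flux balance at the root, across magnitudes
  for (v1o in c(1e-6, 7.4e-5, 1e-3, 0.5, 10)) {
    st <- solve_v1c(v1o, pars, act)
    vm <- pars$v_max * act$cyp_fold
    expect_equal(pars$d * (v1o - st$v1c),
                 vm * st$v1c / (pars$K_m + st$v1c), tolerance = 1e-12)
    expect_true(st$v1c >= 0 && st$v1c <= v1o)
  }
})

test_that("linear regime matches d/(d + v_max/K_m) scaling", {
  pars <- cell_params()
  act <- activated_state() # v_max 1 uM/hr, d 6, K_m 1
  v1o <- 7.4e-5 # free 25OHD at high sufficiency, lowest-affinity genotype
  st <- solve_v1c(v1o, pars, act)
  expect_equal(st$v1c, 6 / 7 * v1o, tolerance = 1e-4)
  # and the ratio approaches the closed form as v1o shrinks
  ratio <- solve_v1c(1e-9, pars, act)$v1c / 1e-9
  expect_equal(ratio, 6 / 7, tolerance = 1e-8)
})

test_that("intracellular 1,25D adds endocrine and intracrine terms", {
  pars <- cell_params()
  st0 <- compute_v2c(solve_v1c(0, pars), 5e-7)
  expect_equal(st0$v2c, 5e-7) # no conversion flux: endocrine only
  st1 <- compute_v2c(solve_v1c(3.7e-5, pars, activated_state()), 0)
  expect_equal(st1$v2c, st1$conversion_flux / pars$d) # intracrine only
  st2 <- compute_v2c(solve_v1c(3.7e-5, pars, activated_state()), 1.3e-6)
  expect_equal(st2$v2c, 1.3e-6 + st1$v2c)
  expect_gte(st2$v2c, st2$v2o)
})

test_that("receptor occupancy is competitive, cooperative and half-saturating", {
  pars <- cell_params()
  act <- activation_state()
  mk <- function(v1c, v2c) {
    st <- solve_v1c(0, pars, act)
    st$v1c <- v1c; st$v2c <- v2c; st$v2o <- 0
    st
  }
  expect_equal(unname(vdr_occupancy(mk(0, 0), pars, act)), c(0, 0))
  # v2c = K_r2 with no 25OHD: half of total receptor, any pp
  half <- vdr_occupancy(mk(0, pars$K_r2), pars, act)
  expect_equal(unname(half["r2"]), pars$R_T / 2)
  # r1 + r2 never exceeds (scaled) R_T
  r <- vdr_occupancy(mk(1, 1), pars, activated_state())
  expect_lte(sum(r), pars$R_T * 5)
})

test_that("VDRE activation saturates and respects the unit interval", {
  pars <- cell_params()
  expect_equal(unname(vdre_activation(0, 0, pars)), c(0, 0))
  expect_equal(unname(vdre_activation(0, pars$K_cc2, pars)["o2"]), 0.5)
  big <- vdre_activation(10, 10, pars)
  expect_equal(sum(big), 1, tolerance = 1e-4)
  expect_true(all(big >= 0 & big <= 1))
})

test_that("CAMP output is bounded by basal and basal-plus-maximal levels", {
  pars <- cell_params()
  expect_equal(camp_output(0, 0, pars), 0.010)
  expect_equal(camp_output(0.4, 0.6, pars), 1.010)
  expect_error(camp_output(0.7, 0.6, pars), "o1 \\+ o2")
  set.seed(7)
  for (i in 1:20) {
    o <- stats::runif(2); o <- o / max(1, sum(o))
    cv <- camp_output(o[1], o[2], pars)
    expect_true(cv >= pars$camp0 && cv <= pars$camp0 + pars$eta)
  }
})

test_that("CAMP is monotone in totals and activation folds", {
  cal <- the_calibration()
  camp_at <- function(t25, t125, vdr = 5, cyp = 10) {
    sc <- scenario_context(t25, t125, genotype = "GC2/2",
                           activation = activation_state(vdr, cyp),
                           calibration = cal)
    predict_camp(sc)$camp
  }
  c25 <- vapply(c(0, 25, 50, 100, 200), camp_at, numeric(1), t125 = 0.1)
  expect_true(all(diff(c25) >= 0))
  c125 <- vapply(c(0, 0.05, 0.1, 0.5), function(t) camp_at(50, t), numeric(1))
  expect_true(all(diff(c125) >= 0))
  expect_lte(camp_at(50, 0.1, vdr = 1, cyp = 1), camp_at(50, 0.1, vdr = 5, cyp = 1))
  expect_lte(camp_at(50, 0.1, vdr = 5, cyp = 1), camp_at(50, 0.1, vdr = 5, cyp = 10))
})

test_that("end-to-end chain keeps the genotype ordering under activation", {
  cal <- the_calibration()
  camp <- vapply(GC_GENOTYPES, function(g) {
    predict_camp(scenario_context(50, 0.1, genotype = g,
                                  activation = activated_state(),
                                  calibration = cal))$camp
  }, numeric(1))
  expect_true(all(diff(camp) > 0)) # same order as free 25OHD
})

test_that("receptor counts convert to concentrations geometrically", {
  expect_equal(vdr_concentration_from_count(3000, 10) * 1e3, 1.2,
               tolerance = 0.01)
  expect_equal(vdr_concentration_from_count(0, 10), 0)
  expect_equal(vdr_concentration_from_count(3000, 20),
               vdr_concentration_from_count(3000, 10) / 8)
})

test_that("activation folds below one are rejected", {
  expect_error(activation_state(0.5, 1), ">= 1")
  expect_error(cell_params(K_m = -1), "> 0")
  expect_error(cell_params(pp = 0.5), ">= 1")
})
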