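test_that("ddCt transforms and inverts consistently", {
  expect_equal(response_transform(0), 1)
  expect_equal(response_transform(3), 8)
  pars <- cell_params()
  y <- response_transform(2.5, mode = "camp", params = pars, plateau_fold = 64)
  expect_equal(response_untransform(y, "camp", pars, plateau_fold = 64), 2.5)
  expect_equal(response_untransform(response_transform(1.7), "fold"), 1.7)
  # vehicle maps to basal, the plateau fold to basal + maximal
  expect_equal(response_transform(0, "camp", pars, plateau_fold = 64), pars$camp0)
  expect_equal(response_transform(6, "camp", pars, plateau_fold = 64),
               pars$camp0 + pars$eta)
  expect_error(response_transform(1, "camp"), "plateau_fold")
})

test_that("stage 1 recovers 1,25D-pathway parameters from noiseless data", {
  cal <- the_calibration()
  truth <- update_cell_params(cell_params(), K_r2 = 2.5e-4, K_cc2 = 4e-5)
  d <- generate_dose_response(synthetic_spec(params = truth, ligand = "125D",
                                             sd = 0, calibration = cal))
  fit <- fit_stage_125d(d, fixed = cell_params(), calibration = cal)
  expect_true(fit$converged)
  expect_lt(abs(fit$par[["K_r2"]] - 2.5e-4) / 2.5e-4, 0.01)
  expect_lt(abs(fit$par[["K_cc2"]] - 4e-5) / 4e-5, 0.01)
  expect_error(fit_stage_125d(generate_dose_response(
    synthetic_spec(ligand = "25OHD", sd = 0, calibration = cal))), "1,25")
})

test_that("the pp exponent is found on its discrete grid", {
  cal <- the_calibration()
  truth <- update_cell_params(cell_params(), pp = 3, K_r2 = 2e-4)
  d <- generate_dose_response(synthetic_spec(params = truth, ligand = "125D",
                                             sd = 0, calibration = cal))
  fit <- fit_stage_125d(d, free_params = c("K_r2", "pp"),
                        fixed = cell_params(), calibration = cal)
  expect_identical(fit$pp, 3)
  expect_lt(abs(fit$par[["K_r2"]] - 2e-4) / 2e-4, 0.01)
})

test_that("stage 2 fits only the enzymatic capacity and lowers the loss", {
  cal <- the_calibration()
  truth <- update_cell_params(cell_params(), v_max = 0.3)
  d <- generate_dose_response(synthetic_spec(params = truth, ligand = "25OHD",
                                             sd = 0, calibration = cal))
  fit <- fit_stage_25ohd(d, fixed = cell_params(), calibration = cal)
  expect_true(fit$converged)
  expect_lt(abs(fit$par[["v_max"]] - 0.3) / 0.3, 0.01)
  expect_lte(fit$loss, wls_loss(cell_params(), d, calibration = cal))
  expect_error(fit_stage_25ohd(d, free_params = c("k_cat", "Y_T")),
               "confounded")
  # identifiability: splitting the capacity differently changes nothing
  a <- camp_dose_curve(d, params = cell_params(k_cat = 10, Y_T = 0.03),
                       calibration = cal)
  b <- camp_dose_curve(d, params = cell_params(k_cat = 20, Y_T = 0.015),
                       calibration = cal)
  expect_identical(a, b)
})

test_that("lower 1,25D sensitivity is expressed as a reduced K_r2 affinity", {
  # osteoblast-like cells respond much less to 1,25D; fitting such a curve
  # from monocyte defaults must raise the K_r2 dissociation constant
  cal <- the_calibration()
  insensitive <- update_cell_params(cell_params(), K_r2 = 1e-3)
  d <- generate_dose_response(synthetic_spec(params = insensitive,
                                             ligand = "125D", sd = 0,
                                             serum_fraction = 0.02,
                                             calibration = cal))
  fit <- fit_stage_125d(d, free_params = "K_r2", fixed = cell_params(),
                        calibration = cal)
  expect_gt(fit$par[["K_r2"]], cell_params()$K_r2)
})

test_that("flat data at basal drive parameters to the bound and flag it", {
  cal <- the_calibration()
  pars <- cell_params()
  d <- dose_response_set("125D", c(0.1, 0.5, 1, 3, 6),
                         rep(pars$camp0, 5), sd = 0.01)
  fit <- fit_stage_125d(d, free_params = "K_r2", fixed = pars,
                        calibration = cal)
  expect_true(fit$at_boundary)
  expect_false(fit$converged)
})
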