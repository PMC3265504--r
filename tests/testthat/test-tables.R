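test_that("the free-25OHD reference grid reproduces at printed precision", {
  tab <- reproduce_table("free25ohd", calibration = the_calibration())
  expect_true(attr(tab, "all_match"))
  expect_equal(attr(tab, "tol"), 0.001)
  # ordering across genotypes holds in every column
  for (tot in unique(tab$total_25ohd_nM)) {
    col <- tab[tab$total_25ohd_nM == tot, ]
    col <- col[match(GC_GENOTYPES, col$genotype), ]
    expect_true(all(diff(col$free_25ohd_nM) > 0))
  }
})

test_that("the CAMP grids reproduce within documented tolerances", {
  # mechanism grid (endocrine term exact or absent): every cell matches
  mech <- reproduce_table("camp-mechanism", calibration = the_calibration())
  expect_true(attr(mech, "all_match"))
  # status grid: all cells within 0.005 except at most one middle-genotype
  # activated cell whose endocrine input is interpolated (within 0.01);
  # see the methods vignette on the free-1,25D interpolation
  stat <- reproduce_table("camp-status", calibration = the_calibration())
  dev <- abs(stat$camp - stat$expected)
  expect_lte(sum(!stat$matches), 1L)
  expect_lt(max(dev), 0.01)
  keyed <- stat[stat$genotype %in% c("GC1F/1F", "GC2/2"), ]
  expect_true(all(keyed$matches))
})

test_that("sweep tables scale linearly in the unsaturated regime", {
  cal <- the_calibration()
  sw <- sweep_curves("25OHD", c(10, 20, 40), genotype = "GC2/2",
                     serum_fraction = 1, calibration = cal)
  # linear to within the sub-0.1% albumin-occupancy effect
  expect_equal(sw$free_nM[2] / sw$free_nM[1], 2, tolerance = 1e-4)
  expect_equal(sw$free_nM[3] / sw$free_nM[1], 4, tolerance = 1e-4)
  empty <- sweep_curves("125D", numeric(0), genotype = "GC1F/1F",
                        calibration = cal)
  expect_identical(nrow(empty), 0L)
  # in vitro sweep holds the co-metabolite at its fixed culture level
  sw5 <- sweep_curves("25OHD", 2.5, genotype = "GC1F/1F",
                      serum_fraction = 0.05, calibration = cal)
  expect_equal(sw5$total_nM, 2.5)
  expect_gt(sw5$percent_free, 0.4)
})

test_that("config files round-trip and reject malformed content", {
  cfg <- list("binder.X.concentration" = "5 uM",
              "binder.X.ka_25ohd" = "7e8 /M",
              "binder.X.ka_125d" = "4e7 /M")
  f <- withr::local_tempfile(fileext = ".txt")
  write_kv_config(cfg, f)
  expect_identical(read_kv_config(f), cfg)
  binders <- load_binders_config(f)
  expect_length(binders, 1L)
  expect_equal(binders[[1]]$concentration, 5)
  expect_equal(binders[[1]]$kd_25ohd, ka_to_kd_uM(7e8))
  writeLines("no equals sign here", f)
  expect_error(read_kv_config(f), "malformed")
})

test_that("the shipped standard serum config matches the constructors", {
  binders <- load_binders_config()
  labs <- vapply(binders, `[[`, "", "label")
  dbp <- binders[[which(labs == "DBP")]]
  alb <- binders[[which(labs == "Albumin")]]
  ref_dbp <- mixed_dbp_binder()
  ref_alb <- albumin_binder()
  expect_equal(dbp$concentration, ref_dbp$concentration)
  expect_equal(dbp$kd_25ohd, ref_dbp$kd_25ohd)
  expect_equal(alb$kd_125d, ref_alb$kd_125d)
})

test_that("cell parameter configs load into cell_params", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_kv_config(list("cell.d" = "6", "cell.K_m" = "1",
                       "cell.v_max" = "0.1", "cell.pp" = "2"), f)
  pars <- load_cell_config(f)
  expect_s3_class(pars, "cell_params")
  expect_equal(pars$v_max, 0.1)
  expect_equal(pars$R_T, cell_params()$R_T)
})
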