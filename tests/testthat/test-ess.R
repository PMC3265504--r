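test_that("with no binders the free levels equal the totals", {
  tot <- ligand_totals(50, 0.1, unit = "nM")
  sol <- solve_ess(tot, serum_context(list(), genotype = NA))
  expect_equal(sol$v1_free, tot$v1)
  expect_equal(sol$v2_free, tot$v2)
  z <- solve_ess(tot, serum_context(list(
    binding_species("empty", 0, 1, 1))))
  expect_equal(z$v1_free, tot$v1)
})

test_that("mass is conserved for ligands and binders on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    inst <- random_equilibrium_instance()
    sol <- solve_equilibrium(inst$V, inst$B, inst$K, tol = 1e-12)
    # ligand balance: free + sum of complexes
    expect_lt(max(abs(sol$free + rowSums(sol$bound) - inst$V)), 1e-12)
    # binder balance: free binder + complexes equals B
    D <- 1 + colSums(sol$free / inst$K)
    free_binder <- inst$B / D
    expect_lt(max(abs(free_binder + colSums(sol$bound) - inst$B)), 1e-9)
    expect_true(all(sol$free >= 0 & sol$free <= inst$V))
  }
})

test_that("free 25OHD rises with total and falls with binder capacity", {
  ctx <- standard_serum()
  f <- function(tot_nM) {
    solve_ess(ligand_totals(tot_nM, 0.1, unit = "nM"), ctx)$v1_free
  }
  frees <- vapply(c(10, 25, 50, 100, 200), f, numeric(1))
  expect_true(all(diff(frees) > 0))

  richer <- serum_context(list(mixed_dbp_binder(concentration = 7),
                               albumin_binder()))
  expect_lt(solve_ess(ligand_totals(50, 0.1, unit = "nM"), richer)$v1_free,
            f(50))
  tighter <- serum_context(list(mixed_dbp_binder(ka_25ohd = 1.4e9),
                                albumin_binder()))
  expect_lt(solve_ess(ligand_totals(50, 0.1, unit = "nM"), tighter)$v1_free,
            f(50))
})

test_that("unsaturated limit matches the closed-form free fraction", {
  # totals far below capacity: fraction = 1/(1 + sum B/K), within 0.1%
  ctx <- standard_serum()
  sol <- solve_ess(ligand_totals(0.05, 1e-4, unit = "nM"), ctx)
  cap1 <- 5 / ka_to_kd_uM(7e8) + 650 / ka_to_kd_uM(6e5)
  cap2 <- 5 / ka_to_kd_uM(4e7) + 650 / ka_to_kd_uM(5.4e4)
  ff <- free_fraction(sol)
  expect_equal(ff$fraction[1], 1 / (1 + cap1), tolerance = 1e-3)
  expect_equal(ff$fraction[2], 1 / (1 + cap2), tolerance = 1e-3)
})

test_that("free fractions report as fraction and percent, guarding zero totals", {
  ctx <- calibrated_context("GC1F/1F", calibration = the_calibration())
  sol <- solve_ess(ligand_totals(50, 0.1, unit = "nM"), ctx)
  ff <- free_fraction(sol)
  # 0.013 nM free of 50 nM total prints as 0.026%
  expect_equal(round(ff$percent[1], 3), 0.026)
  # identity case: no binders means 100% free
  id <- solve_ess(ligand_totals(50, 0.1, unit = "nM"), serum_context(list()))
  expect_equal(free_fraction(id)$percent, c(100, 100))
  z <- solve_ess(ligand_totals(0, 0.1, unit = "nM"), ctx)
  expect_error(free_fraction(z), "undefined")
})

test_that("dilution scales binder concentrations only", {
  ctx <- dilute_serum(list(mixed_dbp_binder(), albumin_binder()), 0.05)
  expect_equal(ctx$binders[[1]]$concentration, 0.25)
  expect_equal(ctx$binders[[2]]$concentration, 32.5)
  expect_equal(ctx$binders[[1]]$kd_25ohd, ka_to_kd_uM(7e8))
  full <- dilute_serum(list(mixed_dbp_binder()), 1)
  expect_equal(full$binders[[1]]$concentration, 5)
  expect_equal(dilute_serum(list(albumin_binder()), 0.02)$binders[[1]]$concentration,
               13)
  expect_error(dilute_serum(list(albumin_binder()), 0), "serum_fraction")
  expect_error(dilute_serum(list(albumin_binder()), 1.2), "serum_fraction")
})

test_that("free fraction at a serum fraction is total-independent when unsaturated", {
  cal <- the_calibration()
  ctx5 <- calibrated_context("GC2/2", serum_fraction = 0.05, calibration = cal)
  pct <- vapply(c(1, 2.5, 10), function(tot) {
    free_fraction(solve_ess(ligand_totals(tot, 0.005, unit = "nM"), ctx5))$percent[1]
  }, numeric(1))
  expect_lt(max(abs(pct - pct[1])) / pct[1], 1e-3)
})

test_that("solver rejects invalid inputs", {
  expect_error(solve_equilibrium(c(-1, 0.1), 1, matrix(1, 2, 1)), ">= 0")
  expect_error(solve_equilibrium(c(1, 0.1), 1, matrix(1, 2, 1), tol = 0), "tol")
  expect_error(binding_species("x", 5, -1, 1), "> 0")
  expect_error(binding_species("x", -5, 1, 1), ">= 0")
})
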