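# Shared fixtures, built in code.

# standard full-serum binder set (genotype-averaged DBP + albumin)
standard_serum <- function() {
  serum_context(list(mixed_dbp_binder(), albumin_binder()))
}

# the shipped genotype calibration, computed once per test run
the_calibration <- local({
  cal <- NULL
  function() {
    if (is.null(cal)) cal <<- reference_calibration()
    cal
  }
})

# random saturable equilibrium instance with totals comparable to capacities
random_equilibrium_instance <- function(n_lig = 2, n_bind = 3) {
  B <- 10^stats::runif(n_bind, -1, 1)
  K <- matrix(10^stats::runif(n_lig * n_bind, -2, 1), n_lig, n_bind)
  V <- stats::runif(n_lig, 0.1, 2) * sum(B)
  list(V = V, B = B, K = K)
}

# generic kinetic realization of an n-ligand, m-binder equilibrium
# (k+ = 1, k- = K), independent of the package's 2-ligand builder
kinetic_system_generic <- function(V, B, K) {
  n <- length(V); m <- length(B)
  init <- stats::setNames(V, paste0("L", seq_len(n)))
  init <- c(init, stats::setNames(B, paste0("P", seq_len(m))))
  rxs <- list()
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cn <- paste0("C", i, "_", j)
    init[cn] <- 0
    rxs <- c(rxs, list(
      reaction(1, stats::setNames(c(1, 1), c(paste0("L", i), paste0("P", j))),
               stats::setNames(1, cn)),
      reaction(K[i, j], stats::setNames(1, cn),
               stats::setNames(c(1, 1), c(paste0("L", i), paste0("P", j))))
    ))
  }
  mass_action_system(init, rxs)
}
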