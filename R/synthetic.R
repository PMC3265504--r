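#' Describe one mass-action reaction
#'
#' @param rate rate constant (> 0 or 0); units consistent with the order.
#' @param reactants,products named numeric vectors of stoichiometries; an
#'   empty reactants vector gives a zeroth-order (constant) source.
#' @return object of class `reaction`.
#' @export
reaction <- function(rate, reactants = numeric(0), products = numeric(0)) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (length(reactants) && is.null(names(reactants))) {
    stop("reactants must be a named vector")
  }
  if (length(products) && is.null(names(products))) {
    stop("products must be a named vector")
  }
  structure(list(rate = rate, reactants = reactants, products = products),
            class = "reaction")
}

#' Assemble a mass-action system
#'
#' @param init named numeric vector of initial concentrations (all species
#'   must be named here, including those only produced).
#' @param reactions list of [reaction()]s.
#' @return object of class `mass_action_system`.
#' @export
mass_action_system <- function(init, reactions) {
  stopifnot(is.numeric(init), !is.null(names(init)))
  if (inherits(reactions, "reaction")) reactions <- list(reactions)
  stopifnot(all(vapply(reactions, inherits, logical(1), "reaction")))
  for (rx in reactions) {
    sp <- c(names(rx$reactants), names(rx$products))
    if (!all(sp %in% names(init))) {
      stop("reaction references species not in init: ",
           paste(setdiff(sp, names(init)), collapse = ", "))
    }
  }
  structure(list(init = init, reactions = reactions),
            class = "mass_action_system")
}

#' @keywords internal
.mass_action_derivs <- function(t, y, sys) {
  dy <- numeric(length(y))
  names(dy) <- names(y)
  for (rx in sys$reactions) {
    flux <- rx$rate
    if (length(rx$reactants)) {
      flux <- flux * prod(y[names(rx$reactants)]^rx$reactants)
    }
    if (length(rx$reactants)) {
      dy[names(rx$reactants)] <- dy[names(rx$reactants)] - rx$reactants * flux
    }
    if (length(rx$products)) {
      dy[names(rx$products)] <- dy[names(rx$products)] + rx$products * flux
    }
  }
  list(dy)
}

#' Relax a mass-action system to steady state (kinetic oracle)
#'
#' Integrates the kinetic ODEs with [deSolve::lsoda] over doubling time
#' horizons until the relative rate of change per unit time falls below
#' `rel_tol` for every species. This oracle validates the algebraic
#' steady-state solvers by an independent route: only the dissociation
#' constants are shared (rates are chosen as `k+ = 1`, `k- = K`, since the
#' individual rates are irrelevant at steady state).
#'
#' @param sys a [mass_action_system()].
#' @param rel_tol steady-state criterion on `|dy/dt| / (|y| + atol)`.
#' @param max_time failure horizon (integration time units).
#' @param atol,rtol integrator tolerances.
#' @return named numeric vector of steady-state concentrations.
#' @export
ode_oracle <- function(sys, rel_tol = 1e-10, max_time = 1e8,
                       atol = 1e-16, rtol = 1e-10) {
  stopifnot(inherits(sys, "mass_action_system"))
  y <- sys$init
  t_end <- 1
  repeat {
    # an early return within a chunk is harmless: the loop resumes from the
    # returned state and convergence is judged on the derivative criterion
    sol <- withCallingHandlers(
      deSolve::lsoda(y, times = c(0, t_end), func = .mass_action_derivs,
                     parms = sys, atol = atol, rtol = rtol,
                     maxsteps = 5e5),
      warning = function(w) {
        if (grepl("maxsteps|Returning early|excessive", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    y <- sol[nrow(sol), -1]
    dy <- .mass_action_derivs(0, y, sys)[[1]]
    if (max(abs(dy) / (abs(y) + 1e-12)) < rel_tol) {
      return(y)
    }
    if (t_end >= max_time) {
      stop("kinetic oracle did not reach steady state by t = ", t_end)
    }
    t_end <- t_end * 4
  }
}

#' Kinetic system realizing an extracellular binding equilibrium
#'
#' Builds the mass-action network (free ligands, free binders, complexes)
#' whose steady state is the eSS solution, with `k+ = 1 /uM/hr` and
#' `k- = K_ij /hr`. Linear (non-saturable) binders are realized as
#' pseudo-first-order exchange with an unoccupied reservoir so that the
#' bound level satisfies `c = v * B/K` at steady state.
#'
#' @param totals a [ligand_totals()].
#' @param context a [serum_context()].
#' @return a [mass_action_system()]; free ligand species are named `v1`,
#'   `v2`, complexes `c<i>_<j>`.
#' @export
ess_kinetic_system <- function(totals, context) {
  stopifnot(inherits(totals, "ligand_totals"), inherits(context, "serum_context"))
  binders <- context$binders
  V <- c(totals$v1, totals$v2)
  init <- c(v1 = V[1], v2 = V[2])
  rxs <- list()
  for (j in seq_along(binders)) {
    b <- binders[[j]]
    Kj <- c(b$kd_25ohd, b$kd_125d)
    if (b$saturable) {
      bn <- paste0("b", j)
      init[bn] <- b$concentration
      for (i in 1:2) {
        cn <- paste0("c", i, "_", j)
        init[cn] <- 0
        vi <- paste0("v", i)
        rxs <- c(rxs, list(
          reaction(1, stats::setNames(c(1, 1), c(vi, bn)),
                   stats::setNames(1, cn)),
          reaction(Kj[i], stats::setNames(1, cn),
                   stats::setNames(c(1, 1), c(vi, bn)))
        ))
      }
    } else {
      for (i in 1:2) {
        cn <- paste0("c", i, "_", j)
        init[cn] <- 0
        vi <- paste0("v", i)
        P <- b$concentration / Kj[i]
        rxs <- c(rxs, list(
          reaction(P, stats::setNames(1, vi), stats::setNames(1, cn)),
          reaction(1, stats::setNames(1, cn), stats::setNames(1, vi))
        ))
      }
    }
  }
  mass_action_system(init, rxs)
}

#' Kinetic system realizing the intracellular steady state
#'
#' Diffusive exchange with fixed extracellular free levels plus an explicit
#' enzyme species pair (free CYP27B1 and its 25OHD complex) whose
#' Michaelis constant matches the algebraic model: `k_on = 2 k_cat / K_m`,
#' `k_off = k_cat`, so `K_m = (k_off + k_cat)/k_on`.
#'
#' @param v1o,v2o fixed free extracellular levels (uM).
#' @param params a [cell_params()].
#' @param activation an [activation_state()].
#' @param k_cat catalytic rate used by the oracle (only the capacity
#'   `v_max` is meaningful; the split is arbitrary).
#' @return a [mass_action_system()] with species `v1c`, `v2c`, `Y`, `Y1`.
#' @export
iss_kinetic_system <- function(v1o, v2o, params = cell_params(),
                               activation = activation_state(),
                               k_cat = 1e3) {
  d <- params$d
  vm <- params$v_max * activation$cyp_fold
  YT <- vm / k_cat
  k_on <- 2 * k_cat / params$K_m
  k_off <- k_cat
  init <- c(v1c = 0, v2c = 0, Y = YT, Y1 = 0)
  rxs <- list(
    reaction(d * v1o, products = c(v1c = 1)),
    reaction(d, reactants = c(v1c = 1)),
    reaction(d * v2o, products = c(v2c = 1)),
    reaction(d, reactants = c(v2c = 1)),
    reaction(k_on, reactants = c(v1c = 1, Y = 1), products = c(Y1 = 1)),
    reaction(k_off, reactants = c(Y1 = 1), products = c(v1c = 1, Y = 1)),
    reaction(k_cat, reactants = c(Y1 = 1), products = c(v2c = 1, Y = 1))
  )
  if (vm == 0) {
    rxs <- rxs[1:4]
    init <- init[c("v1c", "v2c")]
  }
  mass_action_system(init, rxs)
}

#' Specification of a synthetic dose-response experiment
#'
#' Defines the ground truth and noise model for generated dose-response
#' data: the treated metabolite, its dose grid, the cell parameters, the
#' genotype/serum context, activation, Gaussian noise on the normalized
#' response scale (scalar or per-dose sd), replicate count and seed.
#' Output is a pure function of the `synthetic_spec` object (bit-reproducible
#' per seed).
#'
#' @param params true [cell_params()].
#' @param ligand `"25OHD"` or `"125D"` (the dosed metabolite).
#' @param doses_nM strictly increasing non-negative totals of the dosed
#'   metabolite (nM).
#' @param sd Gaussian noise sd on the response scale (scalar or per-dose).
#' @param replicates number of replicate data sets.
#' @param seed integer RNG seed.
#' @param genotype,serum_fraction context of the culture (defaults mirror
#'   the monocyte in vitro setting: GC1F/1F at 5% serum).
#' @param co_total_nM total of the non-dosed metabolite (nM).
#' @param activation an [activation_state()].
#' @param calibration genotype calibration used to build the context.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(params = cell_params(),
                           ligand = c("125D", "25OHD"),
                           doses_nM = NULL, sd = 0, replicates = 1L,
                           seed = 1L, genotype = "GC1F/1F",
                           serum_fraction = 0.05, co_total_nM = 0,
                           activation = activation_state(),
                           calibration = reference_calibration()) {
  ligand <- match.arg(ligand)
  if (is.null(doses_nM)) {
    doses_nM <- if (ligand == "25OHD") {
      c(1, 3, 10, 30, 100, 200, 300)
    } else {
      c(0.1, 0.2, 0.5, 1, 2, 4, 6)
    }
  }
  if (any(doses_nM < 0) || is.unsorted(doses_nM, strictly = TRUE)) {
    stop("doses must be non-negative and strictly increasing")
  }
  if (any(sd < 0)) stop("noise sd must be >= 0")
  if (!(length(sd) %in% c(1L, length(doses_nM)))) {
    stop("sd must be a scalar or one value per dose")
  }
  structure(list(params = params, ligand = ligand, doses_nM = doses_nM,
                 sd = sd, replicates = as.integer(replicates),
                 seed = as.integer(seed), genotype = genotype,
                 serum_fraction = serum_fraction, co_total_nM = co_total_nM,
                 activation = activation, calibration = calibration),
            class = "synthetic_spec")
}

#' A dose-response data set
#'
#' @param ligand `"25OHD"` or `"125D"`.
#' @param doses_nM strictly increasing non-negative doses (nM).
#' @param response normalized responses (model CAMP scale), finite.
#' @param sd per-point spread (same length, >= 0), optional.
#' @param serum_fraction,genotype culture context metadata.
#' @param co_total_nM total of the non-dosed metabolite (nM).
#' @return object of class `dose_response_set`.
#' @export
dose_response_set <- function(ligand, doses_nM, response, sd = NULL,
                              serum_fraction = 0.05, genotype = "GC1F/1F",
                              co_total_nM = 0) {
  ligand <- match.arg(ligand, c("25OHD", "125D"))
  if (any(doses_nM < 0) || is.unsorted(doses_nM, strictly = TRUE)) {
    stop("doses must be non-negative and strictly increasing")
  }
  if (length(response) != length(doses_nM) || any(!is.finite(response))) {
    stop("responses must be finite and match the dose grid")
  }
  if (is.null(sd)) sd <- rep(0, length(doses_nM))
  if (length(sd) == 1L) sd <- rep(sd, length(doses_nM))
  if (length(sd) != length(doses_nM) || any(sd < 0)) {
    stop("sd must be non-negative, one per dose")
  }
  structure(list(ligand = ligand, doses_nM = doses_nM, response = response,
                 sd = sd, serum_fraction = serum_fraction,
                 genotype = genotype, co_total_nM = co_total_nM),
            class = "dose_response_set")
}

#' @export
print.dose_response_set <- function(x, ...) {
  cat(sprintf("<dose_response_set> %s, %d doses (%g-%g nM), %s at %g%% serum\n",
              x$ligand, length(x$doses_nM), min(x$doses_nM), max(x$doses_nM),
              x$genotype, 100 * x$serum_fraction))
  print(data.frame(dose_nM = x$doses_nM, response = x$response, sd = x$sd))
  invisible(x)
}

#' Model dose-response curve for a data set's design
#'
#' Runs the full eSS+iSS chain at every dose of the design and returns the
#' noiseless normalized CAMP responses.
#'
#' @param data a [dose_response_set()] (responses ignored) or
#'   [synthetic_spec()].
#' @param params a [cell_params()].
#' @param activation an [activation_state()].
#' @param calibration genotype calibration for the serum context.
#' @return numeric vector of model responses.
#' @export
camp_dose_curve <- function(data, params = cell_params(),
                            activation = activation_state(),
                            calibration = reference_calibration()) {
  ctx <- calibrated_context(data$genotype,
                            serum_fraction = data$serum_fraction,
                            calibration = calibration)
  vapply(data$doses_nM, function(D) {
    tot <- if (data$ligand == "25OHD") {
      ligand_totals(D, data$co_total_nM, unit = "nM")
    } else {
      ligand_totals(data$co_total_nM, D, unit = "nM")
    }
    ess <- solve_ess(tot, ctx)
    iss_chain(ess$v1_free, ess$v2_free, params, activation)$camp
  }, numeric(1))
}

#' Generate synthetic dose-response data from a known model
#'
#' Responses are the model curve ([camp_dose_curve()]) plus Gaussian noise
#' on the normalized response scale. Deterministic per seed; the RNG state
#' of the session is restored afterwards.
#'
#' @param spec a [synthetic_spec()].
#' @return a [dose_response_set()] (`replicates = 1`) or a list of them.
#' @export
generate_dose_response <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mu <- camp_dose_curve(spec, params = spec$params,
                        activation = spec$activation,
                        calibration = spec$calibration)
  sd <- if (length(spec$sd) == 1L) rep(spec$sd, length(mu)) else spec$sd
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  reps <- lapply(seq_len(spec$replicates), function(r) {
    dose_response_set(spec$ligand, spec$doses_nM,
                      mu + stats::rnorm(length(mu), 0, sd), sd = sd,
                      serum_fraction = spec$serum_fraction,
                      genotype = spec$genotype,
                      co_total_nM = spec$co_total_nM)
  })
  if (spec$replicates == 1L) reps[[1]] else reps
}

#' Per-dose noise spreads shipped as a fixture
#'
#' Representative per-dose standard deviations on the normalized response
#' scale for the default dose grids, mirroring the spread of replicate
#' qPCR-derived expression measurements.
#'
#' @param ligand `"25OHD"` or `"125D"`.
#' @return data frame with `dose_nM` and `sd`.
#' @export
reference_noise_sd <- function(ligand = c("125D", "25OHD")) {
  ligand <- match.arg(ligand)
  f <- system.file("extdata", "dose_response_noise.tsv", package = "vitdfree")
  tab <- utils::read.delim(f, stringsAsFactors = FALSE)
  tab[tab$ligand == ligand, c("dose_nM", "sd")]
}
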