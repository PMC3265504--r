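#' Intracellular steady-state (iSS) model parameters
#'
#' All constants of the intracellular model in internal units (uM, hr).
#' Defaults are the monocyte parameter set:
#' \itemize{
#'   \item `d = 6` /hr: membrane permeability to free 25OHD and 1,25(OH)2D.
#'   \item `K_m = 1` uM: Michaelis constant of CYP27B1 for 25OHD.
#'   \item `v_max = 0.1` uM/hr: basal enzymatic capacity `k_cat * Y_T` of
#'     CYP27B1. Only this product enters the model; individual `k_cat` and
#'     `Y_T` may be supplied for provenance and, if both are given and
#'     `v_max` is not, their product is used.
#'   \item `R_T = 1.2e-3` uM: total VDR (3000 molecules in a 10 um-radius
#'     sphere, see [vdr_concentration_from_count()]).
#'   \item `K_r1 = 5e-2`, `K_r2 = 1e-4` uM: VDR binding constants for 25OHD
#'     and 1,25(OH)2D (25OHD binds 500-fold more weakly).
#'   \item `K_cc1 = 1e-3`, `K_cc2 = 1e-4` uM: VDR:ligand complex binding to
#'     the CAMP VDRE (the 25OHD complex is 10-fold weaker).
#'   \item `mm = 1`, `pp = 2`: cooperativity of 25OHD / 1,25(OH)2D binding
#'     to VDR; `m = 2`, `p = 2`: cooperativity of the complexes on the VDRE.
#'   \item `eta = 1`: net CAMP production scale (normalized maximal
#'     induction); `camp0 = 0.010`: basal CAMP level on the same scale.
#' }
#'
#' @param d,K_m,v_max,R_T,K_r1,K_r2,K_cc1,K_cc2,mm,pp,m,p,eta,camp0 numeric
#'   scalars as described above; rates and constants must be > 0, exponents
#'   >= 1, `camp0 >= 0`.
#' @param k_cat,Y_T optional provenance values (per hr; uM).
#' @return object of class `cell_params`.
#' @export
cell_params <- function(d = 6, K_m = 1, v_max = NULL, R_T = 1.2e-3,
                        K_r1 = 5e-2, K_r2 = 1e-4,
                        K_cc1 = 1e-3, K_cc2 = 1e-4,
                        mm = 1, pp = 2, m = 2, p = 2,
                        eta = 1, camp0 = 0.010,
                        k_cat = NULL, Y_T = NULL) {
  if (is.null(v_max)) {
    v_max <- if (!is.null(k_cat) && !is.null(Y_T)) k_cat * Y_T else 0.1
  }
  pars <- list(d = d, K_m = K_m, v_max = v_max, R_T = R_T,
               K_r1 = K_r1, K_r2 = K_r2, K_cc1 = K_cc1, K_cc2 = K_cc2,
               mm = mm, pp = pp, m = m, p = p, eta = eta, camp0 = camp0,
               k_cat = k_cat, Y_T = Y_T)
  pos <- c("d", "K_m", "R_T", "K_r1", "K_r2", "K_cc1", "K_cc2", "eta")
  for (nm in pos) {
    if (!(is.numeric(pars[[nm]]) && pars[[nm]] > 0)) {
      stop("parameter ", nm, " must be > 0")
    }
  }
  if (!(v_max >= 0)) stop("v_max must be >= 0")
  for (nm in c("mm", "pp", "m", "p")) {
    if (!(is.numeric(pars[[nm]]) && pars[[nm]] >= 1)) {
      stop("cooperativity exponent ", nm, " must be >= 1")
    }
  }
  if (camp0 < 0) stop("camp0 must be >= 0")
  structure(pars, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> (uM, hr)\n")
  cat(sprintf("  d = %g /hr, K_m = %g, v_max = %g uM/hr\n", x$d, x$K_m, x$v_max))
  cat(sprintf("  R_T = %g, K_r1 = %g, K_r2 = %g, K_cc1 = %g, K_cc2 = %g\n",
              x$R_T, x$K_r1, x$K_r2, x$K_cc1, x$K_cc2))
  cat(sprintf("  mm = %g, pp = %g, m = %g, p = %g, eta = %g, camp0 = %g\n",
              x$mm, x$pp, x$m, x$p, x$eta, x$camp0))
  invisible(x)
}

#' Update cell parameters by name
#' @param params a [cell_params()].
#' @param ... named replacements (natural scale).
#' @return a validated `cell_params`.
#' @export
update_cell_params <- function(params, ...) {
  stopifnot(inherits(params, "cell_params"))
  repl <- list(...)
  if (length(repl) == 1L && is.list(repl[[1]]) && is.null(names(repl)[1])) {
    repl <- repl[[1]]
  }
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown cell parameter(s): ", paste(bad, collapse = ", "))
  pars <- unclass(params)
  pars[names(repl)] <- repl
  pars$v_max <- pars$v_max # keep explicit v_max even if k_cat/Y_T present
  do.call(cell_params, pars)
}

#' Immune activation state
#'
#' Activation is modelled as expression folds on total VDR and on the
#' CYP27B1 capacity; affinity constants are unchanged. The default
#' activated state is a 5-fold VDR and 10-fold CYP27B1 induction, as seen
#' after TLR stimulation of monocytes.
#'
#' @param vdr_fold multiplier on `R_T`, >= 1.
#' @param cyp_fold multiplier on `v_max`, >= 1.
#' @return object of class `activation_state`.
#' @export
activation_state <- function(vdr_fold = 1, cyp_fold = 1) {
  if (!(vdr_fold >= 1 && cyp_fold >= 1)) stop("activation folds must be >= 1")
  structure(list(vdr_fold = vdr_fold, cyp_fold = cyp_fold),
            class = "activation_state")
}

#' @rdname activation_state
#' @export
activated_state <- function(vdr_fold = 5, cyp_fold = 10) {
  activation_state(vdr_fold, cyp_fold)
}

#' @export
print.activation_state <- function(x, ...) {
  cat(sprintf("<activation_state> VDR x%g, CYP27B1 x%g\n",
              x$vdr_fold, x$cyp_fold))
  invisible(x)
}

#' Intracellular free 25OHD from permeation/conversion balance
#'
#' Solves the steady-state balance between diffusive influx and
#' Michaelis-Menten consumption by CYP27B1,
#' \deqn{d\,(v_1^o - v_1^c) = \frac{v_{max}\, v_1^c}{K_m + v_1^c},}
#' via the closed-form positive root of the equivalent quadratic (which
#' always lies in `[0, v1o]`).
#'
#' @param v1o free extracellular 25OHD (uM), >= 0.
#' @param params a [cell_params()].
#' @param activation an [activation_state()]; `cyp_fold` scales `v_max`.
#' @return object of class `intracellular_state` with `v1c`, the conversion
#'   flux (uM/hr), and a `v2c` slot filled by [compute_v2c()].
#' @export
solve_v1c <- function(v1o, params = cell_params(),
                      activation = activation_state()) {
  stopifnot(inherits(params, "cell_params"),
            inherits(activation, "activation_state"))
  if (!(is.numeric(v1o) && v1o >= 0)) stop("v1o must be >= 0")
  d <- params$d
  Km <- params$K_m
  vm <- params$v_max * activation$cyp_fold
  # d*v1c^2 + (d*Km + vm - d*v1o)*v1c - d*Km*v1o = 0
  b <- d * (Km - v1o) + vm
  cc <- -d * Km * v1o
  disc <- b^2 - 4 * d * cc
  v1c <- if (b >= 0) -2 * cc / (b + sqrt(disc)) else (-b + sqrt(disc)) / (2 * d)
  v1c <- min(max(v1c, 0), v1o)
  flux <- if (v1c > 0) vm * v1c / (Km + v1c) else 0
  structure(list(v1c = v1c, v2c = NA_real_, conversion_flux = flux,
                 v1o = v1o, v2o = NA_real_,
                 params = params, activation = activation),
            class = "intracellular_state")
}

#' Intracellular free 1,25(OH)2D: endocrine plus intracrine sources
#'
#' Adds the endocrine term (free extracellular 1,25(OH)2D, which
#' equilibrates across the membrane) and the intracrine term (CYP27B1
#' conversion flux divided by the permeability):
#' \deqn{v_2^c = v_2^o + \frac{v_{max}}{d}\,\frac{v_1^c}{K_m + v_1^c}.}
#'
#' @param v1c_state an [solve_v1c()] result.
#' @param v2o free extracellular 1,25(OH)2D (uM), >= 0.
#' @return the completed `intracellular_state`.
#' @export
compute_v2c <- function(v1c_state, v2o) {
  stopifnot(inherits(v1c_state, "intracellular_state"))
  if (!(is.numeric(v2o) && v2o >= 0)) stop("v2o must be >= 0")
  st <- v1c_state
  st$v2o <- v2o
  st$v2c <- v2o + st$conversion_flux / st$params$d
  st
}

#' @export
print.intracellular_state <- function(x, ...) {
  cat(sprintf("<intracellular_state> v1c = %.4g nM (of v1o = %.4g nM), flux = %.4g uM/hr",
              x$v1c * 1e3, x$v1o * 1e3, x$conversion_flux))
  if (!is.na(x$v2c)) {
    cat(sprintf(", v2c = %.4g pM (v2o = %.4g pM)", x$v2c * 1e6, x$v2o * 1e6))
  }
  cat("\n")
  invisible(x)
}

#' Cooperative competitive VDR occupancy
#'
#' The two metabolites compete for total receptor `R_T` (scaled by the
#' activation fold) with cooperativity exponents `mm` (25OHD) and `pp`
#' (1,25(OH)2D): with \eqn{u_1 = (v_1^c/K_{r1})^{mm}} and
#' \eqn{u_2 = (v_2^c/K_{r2})^{pp}},
#' \deqn{r_1 = R_T' \frac{u_1}{1+u_1+u_2}, \qquad r_2 = R_T' \frac{u_2}{1+u_1+u_2}.}
#'
#' @param state a completed [compute_v2c()] state.
#' @param params,activation model parameters and activation (defaults taken
#'   from the state).
#' @return named numeric vector `c(r1 = , r2 = )` in uM.
#' @export
vdr_occupancy <- function(state, params = state$params,
                          activation = state$activation) {
  stopifnot(inherits(state, "intracellular_state"))
  if (is.na(state$v2c)) stop("state is incomplete: run compute_v2c() first")
  RT <- params$R_T * activation$vdr_fold
  u1 <- (state$v1c / params$K_r1)^params$mm
  u2 <- (state$v2c / params$K_r2)^params$pp
  den <- 1 + u1 + u2
  c(r1 = RT * u1 / den, r2 = RT * u2 / den)
}

#' Active VDRE fractions from the liganded-VDR complexes
#'
#' The two complexes compete for the CAMP promoter VDRE with cooperativity
#' `m` and `p`: with \eqn{w_1 = (r_1/K_{cc1})^m} and
#' \eqn{w_2 = (r_2/K_{cc2})^p},
#' \deqn{o_1 = \frac{w_1}{1+w_1+w_2}, \qquad o_2 = \frac{w_2}{1+w_1+w_2}.}
#'
#' @param r1,r2 VDR:25OHD and VDR:1,25(OH)2D complex levels (uM), >= 0.
#' @param params a [cell_params()].
#' @return named numeric vector `c(o1 = , o2 = )`, each in `[0, 1]` with
#'   `o1 + o2 <= 1`.
#' @export
vdre_activation <- function(r1, r2, params = cell_params()) {
  if (!(r1 >= 0 && r2 >= 0)) stop("complex levels must be >= 0")
  w1 <- (r1 / params$K_cc1)^params$m
  w2 <- (r2 / params$K_cc2)^params$p
  den <- 1 + w1 + w2
  c(o1 = w1 / den, o2 = w2 / den)
}

#' CAMP transcriptional output
#'
#' `camp = eta * (o1 + o2) + camp0`; bounded in `[camp0, camp0 + eta]`.
#'
#' @param o1,o2 active VDRE fractions with `0 <= o1 + o2 <= 1`.
#' @param params a [cell_params()].
#' @return normalized CAMP score.
#' @export
camp_output <- function(o1, o2, params = cell_params()) {
  if (o1 < 0 || o2 < 0 || o1 + o2 > 1 + 1e-12) {
    stop("active fractions must satisfy 0 <= o1 + o2 <= 1")
  }
  params$eta * (o1 + o2) + params$camp0
}

#' VDR concentration from a molecules-per-cell count
#'
#' Converts a per-cell receptor count to a concentration assuming a
#' spherical cell: `conc = n / (N_A * 4/3 pi r^3)`. 3000 molecules in a
#' 10 um-radius monocyte give approximately 1.2 nM.
#'
#' @param molecules_per_cell number of molecules (>= 0).
#' @param cell_radius_um cell radius in micrometres (> 0).
#' @return concentration in uM.
#' @examples
#' vdr_concentration_from_count(3000, 10) * 1e3  # ~1.2 nM
#' @export
vdr_concentration_from_count <- function(molecules_per_cell, cell_radius_um) {
  if (!(molecules_per_cell >= 0)) stop("molecule count must be >= 0")
  if (!(cell_radius_um > 0)) stop("cell radius must be > 0")
  avogadro <- 6.02214076e23
  vol_L <- (4 / 3) * pi * (cell_radius_um * 1e-5)^3 # um -> dm, dm^3 = L
  (molecules_per_cell / (avogadro * vol_L)) * 1e6
}

#' A prediction scenario: totals, genotype/serum context and activation
#'
#' The full input of one end-to-end prediction. Supply either an explicit
#' [serum_context()] or a genotype (resolved through the calibration).
#'
#' @param total_25ohd,total_125d total extracellular metabolite levels.
#' @param unit unit of the totals (default `"nM"`, the scale of serum
#'   measurements).
#' @param genotype one of [GC_GENOTYPES]; ignored when `context` is given.
#' @param serum_fraction fraction of full serum in (0, 1].
#' @param activation an [activation_state()].
#' @param context optional explicit [serum_context()].
#' @param calibration a `genotype_calibration` used to resolve `genotype`.
#' @return object of class `scenario_context`.
#' @export
scenario_context <- function(total_25ohd, total_125d, unit = "nM",
                             genotype = "GC1F/1F", serum_fraction = 1,
                             activation = activation_state(),
                             context = NULL,
                             calibration = reference_calibration()) {
  totals <- ligand_totals(total_25ohd, total_125d, unit = unit)
  if (is.null(context)) {
    context <- calibrated_context(genotype, serum_fraction = serum_fraction,
                                  calibration = calibration)
  }
  stopifnot(inherits(context, "serum_context"),
            inherits(activation, "activation_state"))
  structure(list(totals = totals, context = context, activation = activation),
            class = "scenario_context")
}

#' @keywords internal
iss_chain <- function(v1o, v2o, params, activation) {
  st <- solve_v1c(v1o, params, activation)
  st <- compute_v2c(st, v2o)
  r <- vdr_occupancy(st, params, activation)
  o <- vdre_activation(r[["r1"]], r[["r2"]], params)
  camp <- camp_output(o[["o1"]], o[["o2"]], params)
  structure(list(v1o = v1o, v2o = v2o, v1c = st$v1c, v2c = st$v2c,
                 conversion_flux = st$conversion_flux,
                 r1 = r[["r1"]], r2 = r[["r2"]],
                 o1 = o[["o1"]], o2 = o[["o2"]], camp = camp,
                 params = params, activation = activation),
            class = "transactivation_output")
}

#' Predict CAMP induction for a scenario (full eSS to iSS chain)
#'
#' Solves the extracellular equilibrium for the scenario's totals and
#' binder set, feeds the free levels through the intracellular model
#' (permeation, CYP27B1 conversion, VDR occupancy, VDRE activation) and
#' returns the transactivation output. Deterministic for fixed inputs.
#'
#' @param scenario a [scenario_context()].
#' @param cell a [cell_params()].
#' @param tol equilibrium mass-balance tolerance (uM).
#' @return object of class `transactivation_output`: extracellular and
#'   intracellular free levels, complexes `r1`, `r2`, active fractions
#'   `o1`, `o2` and the `camp` score; the eSS solution is attached as
#'   attribute `ess`.
#' @examples
#' sc <- scenario_context(50, 0.1, genotype = "GC2/2",
#'                        activation = activated_state())
#' predict_camp(sc)$camp
#' @export
predict_camp <- function(scenario, cell = cell_params(), tol = 1e-12) {
  stopifnot(inherits(scenario, "scenario_context"),
            inherits(cell, "cell_params"))
  ess <- solve_ess(scenario$totals, scenario$context, tol = tol)
  out <- iss_chain(ess$v1_free, ess$v2_free, cell, scenario$activation)
  attr(out, "ess") <- ess
  out
}

#' @export
print.transactivation_output <- function(x, ...) {
  cat(sprintf("<transactivation_output> CAMP = %.3f\n", x$camp))
  cat(sprintf("  free: v1o = %.4g nM, v2o = %.4g pM | v1c = %.4g nM, v2c = %.4g pM\n",
              x$v1o * 1e3, x$v2o * 1e6, x$v1c * 1e3, x$v2c * 1e6))
  cat(sprintf("  VDR complexes: r1 = %.3g uM, r2 = %.3g uM; active VDRE: o1 = %.3g, o2 = %.3g\n",
              x$r1, x$r2, x$o1, x$o2))
  invisible(x)
}
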