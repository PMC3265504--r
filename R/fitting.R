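#' Transform qPCR expression measures to the normalized response scale
#'
#' Relative expression from qPCR arrives as ddCt values (control dCt minus
#' treated dCt), i.e. log2 fold change. Two modes are provided:
#' \itemize{
#'   \item `"fold"`: plain fold change `2^ddCt`.
#'   \item `"camp"`: fold change rescaled to the model's normalized CAMP
#'     axis so that vehicle (fold 1) maps to `camp0` and a stated plateau
#'     fold maps to `camp0 + eta`:
#'     `camp0 + eta * (2^ddCt - 1) / (plateau_fold - 1)`.
#' }
#' The mapping between assay units and the model scale is a convention, not
#' a measured quantity; the plateau fold is therefore an explicit argument.
#'
#' @param ddct finite ddCt values.
#' @param mode `"fold"` or `"camp"`.
#' @param params a [cell_params()] (for `camp0`, `eta`).
#' @param plateau_fold fold change corresponding to maximal induction
#'   (required for `mode = "camp"`).
#' @return transformed values.
#' @examples
#' response_transform(3)              # fold 8
#' response_untransform(response_transform(1.7), "fold")  # 1.7
#' @export
response_transform <- function(ddct, mode = c("fold", "camp"),
                               params = cell_params(), plateau_fold = NULL) {
  mode <- match.arg(mode)
  if (any(!is.finite(ddct))) stop("ddCt values must be finite")
  fold <- 2^ddct
  if (mode == "fold") return(fold)
  if (is.null(plateau_fold) || !(plateau_fold > 1)) {
    stop("mode 'camp' needs a plateau_fold > 1")
  }
  params$camp0 + params$eta * (fold - 1) / (plateau_fold - 1)
}

#' @rdname response_transform
#' @param y transformed values to invert back to ddCt.
#' @export
response_untransform <- function(y, mode = c("fold", "camp"),
                                 params = cell_params(), plateau_fold = NULL) {
  mode <- match.arg(mode)
  fold <- if (mode == "fold") {
    y
  } else {
    if (is.null(plateau_fold) || !(plateau_fold > 1)) {
      stop("mode 'camp' needs a plateau_fold > 1")
    }
    1 + (y - params$camp0) * (plateau_fold - 1) / params$eta
  }
  log2(fold)
}

#' @keywords internal
.fit_wls <- function(data, free_params, fixed, activation, calibration,
                     pp_grid = NULL, stage, span_log10 = 3,
                     control = list(factr = 1e2, maxit = 500L)) {
  stopifnot(inherits(data, "dose_response_set"), inherits(fixed, "cell_params"))
  cont_free <- setdiff(free_params, "pp")
  if (!length(cont_free)) stop("no continuous free parameters")
  bad <- setdiff(cont_free, names(unclass(fixed)))
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  w <- ifelse(data$sd > 0, 1 / data$sd^2, 1)
  start <- vapply(cont_free, function(nm) fixed[[nm]], numeric(1))
  if (any(start <= 0)) stop("free parameters must start > 0")
  lp0 <- log10(start)
  lower <- lp0 - span_log10
  upper <- lp0 + span_log10

  objective <- function(lp, pp_val) {
    pars <- as.list(10^lp)
    names(pars) <- cont_free
    if (!is.null(pp_val)) pars$pp <- pp_val
    cand <- do.call(update_cell_params, c(list(fixed), pars))
    mu <- camp_dose_curve(data, params = cand, activation = activation,
                          calibration = calibration)
    sum(w * (data$response - mu)^2)
  }

  run_one <- function(pp_val) {
    fit <- stats::optim(lp0, objective, pp_val = pp_val, method = "L-BFGS-B",
                        lower = lower, upper = upper, control = control)
    list(fit = fit, pp = pp_val)
  }

  cands <- if ("pp" %in% free_params) {
    grid <- if (is.null(pp_grid)) c(1, 2, 3) else pp_grid
    lapply(grid, run_one)
  } else {
    list(run_one(NULL))
  }
  best <- cands[[which.min(vapply(cands, function(z) z$fit$value, numeric(1)))]]
  par <- stats::setNames(10^best$fit$par, cont_free)
  at_boundary <- any(abs(best$fit$par - lower) < 1e-6) ||
    any(abs(best$fit$par - upper) < 1e-6)
  all_par <- as.list(par)
  if (!is.null(best$pp)) all_par$pp <- best$pp
  params <- do.call(update_cell_params, c(list(fixed), all_par))
  structure(list(par = par, pp = best$pp, loss = best$fit$value,
                 stage = stage,
                 converged = best$fit$convergence == 0 && !at_boundary,
                 at_boundary = at_boundary,
                 optim = best$fit, params = params, data = data),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> stage %s: loss = %.4g, converged = %s%s\n",
              x$stage, x$loss, x$converged,
              if (x$at_boundary) " (parameter at bound)" else ""))
  est <- x$par
  if (!is.null(x$pp)) est <- c(est, pp = x$pp)
  print(est)
  invisible(x)
}

#' Stage 1: fit 1,25(OH)2D-pathway parameters to a 1,25(OH)2D dose-response
#'
#' The staged recipe fits the mechanistically most direct pathway first:
#' parameters governing 1,25(OH)2D action (`K_r2`, `K_cc2`, optionally the
#' cooperativity `pp` over a discrete grid and the VDR level `R_T`) are
#' adjusted by bounded weighted least squares (weights `1/sd^2`) on a
#' 1,25(OH)2D dose-response set, with all other parameters fixed. The
#' optimizer is L-BFGS-B on log10-parameters starting from the supplied
#' `fixed` values; `pp` is searched over `{1, 2, 3}` with a continuous
#' refit per grid point. Note that when the dosed metabolite is the only
#' VDR ligand, `R_T` and `K_cc2` enter the curve only through `R_T/K_cc2`
#' and should not both be freed.
#'
#' @param data a [dose_response_set()] with `ligand == "125D"`.
#' @param free_params character subset of `c("K_r2", "K_cc2", "pp", "R_T")`.
#' @param fixed a [cell_params()] giving the fixed values and the starting
#'   point of the free ones.
#' @param activation an [activation_state()].
#' @param calibration genotype calibration for the serum context.
#' @param pp_grid integer grid searched when `"pp"` is free.
#' @param span_log10 half-width of the log10 search box around the start.
#' @param control passed to [stats::optim].
#' @return object of class `fit_result`: fitted values (`par`, natural
#'   scale), `loss`, `stage`, `converged` flag (FALSE when the optimizer
#'   failed or a parameter sits at its bound), and `params`, the updated
#'   [cell_params()].
#' @export
fit_stage_125d <- function(data, free_params = c("K_r2", "K_cc2"),
                           fixed = cell_params(),
                           activation = activation_state(),
                           calibration = reference_calibration(),
                           pp_grid = NULL, span_log10 = 3,
                           control = list(factr = 1e2, maxit = 500L)) {
  if (data$ligand != "125D") {
    stop("stage 1 fits a 1,25(OH)2D dose-response set")
  }
  allowed <- c("K_r2", "K_cc2", "pp", "R_T")
  bad <- setdiff(free_params, allowed)
  if (length(bad)) {
    stop("stage 1 frees only ", paste(allowed, collapse = ", "))
  }
  .fit_wls(data, free_params, fixed, activation, calibration,
           pp_grid = pp_grid, stage = "125d", span_log10 = span_log10,
           control = control)
}

#' Stage 2: fit the CYP27B1 capacity to a 25OHD dose-response
#'
#' With the 1,25(OH)2D-pathway parameters frozen (typically at the stage-1
#' result), the 25OHD response identifies only the enzymatic capacity
#' `v_max = k_cat * Y_T`: enzyme level and catalytic rate are confounded,
#' so their product is the single fitted quantity.
#'
#' @param data a [dose_response_set()] with `ligand == "25OHD"`.
#' @param fixed a [cell_params()], e.g. `stage1$params`.
#' @param free_params fixed to `"v_max"`.
#' @inheritParams fit_stage_125d
#' @return a `fit_result` (stage `"25ohd"`).
#' @export
fit_stage_25ohd <- function(data, fixed = cell_params(),
                            free_params = "v_max",
                            activation = activation_state(),
                            calibration = reference_calibration(),
                            span_log10 = 3,
                            control = list(factr = 1e2, maxit = 500L)) {
  if (data$ligand != "25OHD") {
    stop("stage 2 fits a 25OHD dose-response set")
  }
  if (!identical(free_params, "v_max")) {
    stop("stage 2 fits the capacity v_max only (k_cat and Y_T are confounded)")
  }
  .fit_wls(data, free_params, fixed, activation, calibration,
           stage = "25ohd", span_log10 = span_log10, control = control)
}

#' Weighted least-squares loss of a parameter set on a data set
#'
#' @param params a [cell_params()].
#' @param data a [dose_response_set()].
#' @param activation,calibration as in [fit_stage_125d()].
#' @return the WLS loss.
#' @export
wls_loss <- function(params, data, activation = activation_state(),
                     calibration = reference_calibration()) {
  w <- ifelse(data$sd > 0, 1 / data$sd^2, 1)
  mu <- camp_dose_curve(data, params = params, activation = activation,
                        calibration = calibration)
  sum(w * (data$response - mu)^2)
}
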