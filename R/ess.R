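#' Solve a general multi-ligand, multi-binder binding equilibrium
#'
#' Low-level solver for the coupled mass-balance system
#' \deqn{V_i = v_i \left(1 + \sum_j \frac{B_j}{K_{ij}\,(1 + \sum_l v_l/K_{lj})}\right)}
#' where `v_i` is the free level of ligand `i`, `B_j` the total concentration
#' of binder `j` and `K_ij` the dissociation constant. Binders flagged
#' non-saturable contribute a fixed capacity `B_j/K_ij` (linear regime).
#'
#' The solution is unique and bracketed (each free level lies in
#' `[0, V_i]`). Damped fixed-point iteration is polished by Newton steps on
#' the full system; if Newton leaves the bracket, per-ligand bisection
#' ([stats::uniroot]) is used as a fallback.
#'
#' @param V numeric vector of total ligand levels (uM).
#' @param B numeric vector of binder concentrations (uM).
#' @param K matrix (`length(V)` x `length(B)`) of dissociation constants (uM).
#' @param saturable logical vector per binder.
#' @param tol maximum absolute mass-balance defect (uM), > 0.
#' @param max_iter iteration cap before a solver-failure error.
#' @return list with `free` (uM), `bound` (ligand x binder matrix, uM),
#'   `residual` (max abs defect) and `iterations`.
#' @export
solve_equilibrium <- function(V, B, K, saturable = rep(TRUE, length(B)),
                              tol = 1e-12, max_iter = 1000L) {
  n <- length(V)
  if (any(V < 0)) stop("total ligand levels must be >= 0")
  if (!(tol > 0)) stop("tol must be > 0")
  if (length(B) == 0L || all(B == 0)) {
    return(list(free = V, bound = matrix(0, n, length(B)), residual = 0,
                iterations = 0L))
  }
  stopifnot(is.matrix(K), nrow(K) == n, ncol(K) == length(B),
            length(saturable) == length(B))
  if (any(B < 0)) stop("binder concentrations must be >= 0")
  if (any(K <= 0)) stop("dissociation constants must be > 0")
  m <- length(B)
  C <- sweep(1 / K, 2, B, "*") # C[i, j] = B_j / K_ij, capacity products

  denom <- function(v) {
    # per-binder competitive occupancy denominator D_j
    D <- 1 + colSums(v / K)
    D[!saturable] <- 1
    D
  }
  capacity <- function(v) sweep(C, 2, denom(v), "/")
  resid <- function(v) v * (1 + rowSums(capacity(v))) - V

  v <- V / (1 + rowSums(C)) # start from the fully-unsaturated guess
  iter <- 0L
  # damped fixed point: contraction in the binder-excess regime
  repeat {
    iter <- iter + 1L
    vn <- V / (1 + rowSums(capacity(v)))
    v <- 0.5 * v + 0.5 * vn
    r <- resid(v)
    if (max(abs(r)) <= tol || iter >= 60L) break
  }
  # Newton polish on f(v) = v*(1 + sum_j C_ij/D_j(v)) - V
  while (max(abs(resid(v))) > tol && iter < max_iter) {
    iter <- iter + 1L
    D <- denom(v)
    capD <- sweep(C, 2, D, "/")
    J <- diag(1 + rowSums(capD), n, n)
    for (k in seq_len(n)) {
      sat <- which(saturable & B > 0)
      if (length(sat)) {
        # d f_i / d v_k from the occupancy denominators
        J[, k] <- J[, k] - rowSums(
          sweep(capD[, sat, drop = FALSE] / matrix(D[sat], n, length(sat), byrow = TRUE),
                2, 1 / K[k, sat], "*")) * v
      }
    }
    step <- tryCatch(solve(J, resid(v)), error = function(e) NULL)
    ok <- !is.null(step)
    if (ok) {
      vn <- v - step
      ok <- all(is.finite(vn)) && all(vn >= 0) && all(vn <= V + tol)
    }
    if (ok) {
      v <- pmin(pmax(vn, 0), V)
    } else {
      # bracketed per-ligand fallback: f_i is increasing in v_i
      for (i in seq_len(n)) {
        if (V[i] == 0) { v[i] <- 0; next }
        fi <- function(x) { vv <- v; vv[i] <- x; resid(vv)[i] }
        v[i] <- stats::uniroot(fi, c(0, V[i]), tol = .Machine$double.eps)$root
      }
    }
  }
  r <- resid(v)
  if (max(abs(r)) > tol) {
    stop(sprintf(
      "equilibrium solver did not converge: residual %.3e uM after %d iterations",
      max(abs(r)), iter))
  }
  bound <- sweep(capacity(v), 1, v, "*")
  list(free = v, bound = bound, residual = max(abs(r)), iterations = iter)
}

#' Solve the extracellular steady state (eSS) for free 25OHD and 1,25(OH)2D
#'
#' Computes the free extracellular levels of both vitamin D metabolites at
#' binding equilibrium with the serum binder set (DBP species and albumin),
#' with full competitive coupling: both ligands occupy each binder, reducing
#' its free capacity.
#'
#' @param totals a [ligand_totals()].
#' @param context a [serum_context()].
#' @param tol maximum absolute mass-balance defect (uM).
#' @param max_iter iteration cap.
#' @return object of class `ess_solution`: free levels `v1_free`, `v2_free`
#'   (uM), `bound_per_binder` (data frame: binder, bound 25OHD, bound
#'   1,25(OH)2D, all uM), `residual`, plus the inputs.
#' @examples
#' ctx <- serum_context(list(mixed_dbp_binder(), albumin_binder()))
#' sol <- solve_ess(ligand_totals(50, 0.1, unit = "nM"), ctx)
#' free_fraction(sol)
#' @export
solve_ess <- function(totals, context, tol = 1e-12, max_iter = 1000L) {
  stopifnot(inherits(totals, "ligand_totals"), inherits(context, "serum_context"))
  binders <- context$binders
  B <- vapply(binders, `[[`, numeric(1), "concentration")
  K <- rbind(vapply(binders, `[[`, numeric(1), "kd_25ohd"),
             vapply(binders, `[[`, numeric(1), "kd_125d"))
  saturable <- vapply(binders, `[[`, logical(1), "saturable")
  sol <- solve_equilibrium(c(totals$v1, totals$v2), B, K, saturable,
                           tol = tol, max_iter = max_iter)
  bpb <- data.frame(
    binder = vapply(binders, `[[`, character(1), "label"),
    bound_25ohd = if (ncol(sol$bound)) sol$bound[1, ] else numeric(0),
    bound_125d = if (ncol(sol$bound)) sol$bound[2, ] else numeric(0),
    stringsAsFactors = FALSE
  )
  structure(list(v1_free = sol$free[1], v2_free = sol$free[2],
                 bound_per_binder = bpb, residual = sol$residual,
                 iterations = sol$iterations,
                 totals = totals, context = context),
            class = "ess_solution")
}

#' @export
print.ess_solution <- function(x, ...) {
  cat(sprintf(
    "<ess_solution> free 25OHD = %.4g nM (%.4g%% of total), free 1,25(OH)2D = %.4g pM (%.4g%% of total)\n",
    x$v1_free * 1e3,
    if (x$totals$v1 > 0) 100 * x$v1_free / x$totals$v1 else NA_real_,
    x$v2_free * 1e6,
    if (x$totals$v2 > 0) 100 * x$v2_free / x$totals$v2 else NA_real_))
  cat(sprintf("  mass-balance residual %.2e uM in %d iterations\n",
              x$residual, x$iterations))
  invisible(x)
}

#' Free fraction and percentage of each metabolite
#'
#' @param sol an [solve_ess()] solution.
#' @param totals optionally override the totals stored in `sol`.
#' @return data frame with one row per metabolite: `free_uM`, `total_uM`,
#'   `fraction`, `percent`.
#' @export
free_fraction <- function(sol, totals = sol$totals) {
  stopifnot(inherits(sol, "ess_solution"), inherits(totals, "ligand_totals"))
  tot <- c(totals$v1, totals$v2)
  if (any(tot <= 0)) {
    stop("free fraction undefined: total level is zero for ",
         paste(c("25OHD", "1,25(OH)2D")[tot <= 0], collapse = ", "))
  }
  free <- c(sol$v1_free, sol$v2_free)
  data.frame(ligand = c("25OHD", "1,25(OH)2D"),
             free_uM = free, total_uM = tot,
             fraction = free / tot, percent = 100 * free / tot,
             stringsAsFactors = FALSE)
}
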