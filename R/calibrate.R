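#' Published free-25OHD reference values by genotype
#'
#' Reads the shipped reference table of predicted free 25OHD by DBP genotype
#' at three vitamin D status levels (25, 50 and 100 nM total 25OHD, full
#' serum). Values are printed to 0.001 nM precision.
#'
#' @param file optional path to a TSV with columns `genotype`,
#'   `total_25ohd_nM`, `free_25ohd_nM`.
#' @return data frame in long format.
#' @export
reference_free25ohd <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "free_25ohd_reference.tsv",
                        package = "vitdfree")
  }
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("genotype", "total_25ohd_nM", "free_25ohd_nM")
  if (!all(need %in% names(tab))) {
    stop("calibration table must have columns ", paste(need, collapse = ", "))
  }
  tab
}

#' Calibrate effective DBP binding products per genotype
#'
#' Per-allele DBP affinities and plasma concentrations are literature
#' quantities; only the dimensionless product \eqn{P_g = B_g/K_g} is
#' identifiable from free/total reference values. With albumin fixed at its
#' standard parameters, the binder-excess mass balance gives, per genotype,
#' \deqn{P_g = \mathrm{total}/\mathrm{free} - 1 - B_{alb}/K_{1,alb}}
#' from the anchor column (default 50 nM total 25OHD).
#'
#' The corresponding 1,25(OH)2D products are anchored to the in vivo free
#' 1,25(OH)2D percentage range (default 0.4%-1.3% at 100 pM total): the
#' lowest-free genotype (largest 25OHD product) takes the lower endpoint,
#' the highest-free genotype the upper, and intermediate genotypes have
#' their free percentage interpolated linearly in their 25OHD product.
#'
#' The products are corrected for the (sub-printed-precision) albumin
#' occupancy at the anchor condition, so that solving the full competitive
#' model at the anchor reproduces the reference free values exactly.
#'
#' @param tab reference table as from [reference_free25ohd()]; rows with
#'   `free >= total` are invalid and raise an error.
#' @param albumin albumin [binding_species()] at full serum.
#' @param anchor_total_nM which total-25OHD column anchors the calibration.
#' @param anchor_total_125d_nM total 1,25(OH)2D at the anchor condition (nM).
#' @param free_125d_pct_range length-2 percentage range (low-free, high-free
#'   endpoints) for the 1,25(OH)2D side.
#' @return object of class `genotype_calibration`: data frame with columns
#'   `genotype`, `product_25ohd`, `free_pct_125d`, `product_125d`. A
#'   calibration warning (class `vitdfree_calibration_warning`) is signalled
#'   if the products are not monotone across the affinity ordering of
#'   [GC_GENOTYPES].
#' @export
calibrate_genotype_products <- function(tab = reference_free25ohd(),
                                        albumin = albumin_binder(),
                                        anchor_total_nM = 50,
                                        anchor_total_125d_nM = 0.1,
                                        free_125d_pct_range = c(0.4, 1.3)) {
  stopifnot(inherits(albumin, "binding_species"))
  if (any(tab$free_25ohd_nM >= tab$total_25ohd_nM)) {
    stop("invalid calibration row: free 25OHD must be smaller than total")
  }
  if (any(tab$free_25ohd_nM <= 0)) stop("free 25OHD must be > 0")
  anchor <- tab[tab$total_25ohd_nM == anchor_total_nM, , drop = FALSE]
  if (nrow(anchor) == 0L) {
    stop("no calibration rows at anchor total ", anchor_total_nM, " nM")
  }
  alb1 <- albumin$concentration / albumin$kd_25ohd
  alb2 <- albumin$concentration / albumin$kd_125d
  P <- anchor$total_25ohd_nM / anchor$free_25ohd_nM - 1 - alb1
  if (any(P <= 0)) {
    stop("calibrated product is non-positive: free value exceeds the level ",
         "implied by albumin binding alone")
  }
  out <- data.frame(genotype = anchor$genotype, product_25ohd = P,
                    stringsAsFactors = FALSE)
  known <- intersect(GC_GENOTYPES, out$genotype)
  out <- out[match(known, out$genotype), , drop = FALSE]
  if (is.unsorted(rev(out$product_25ohd), strictly = TRUE)) {
    warning(warningCondition(
      "calibrated 25OHD products are not strictly decreasing across the DBP affinity ordering",
      class = "vitdfree_calibration_warning"))
  }
  # free-1,25D percentage linear in the 25OHD product between the endpoints
  rng <- range(out$product_25ohd)
  span <- diff(rng)
  s <- if (span > 0) (out$product_25ohd - rng[1]) / span else rep(0, nrow(out))
  out$free_pct_125d <- free_125d_pct_range[2] +
    (free_125d_pct_range[1] - free_125d_pct_range[2]) * s
  # exact inversion: both anchor free levels are known, so the albumin
  # capacity at the anchor (competitive occupancy included) is known too
  v1 <- out$free_25ohd_nM <- anchor$free_25ohd_nM[match(out$genotype,
                                                        anchor$genotype)]
  v1 <- v1 * 1e-3 # nM -> uM
  v2 <- out$free_pct_125d / 100 * anchor_total_125d_nM * 1e-3
  D_alb <- 1 + v1 / albumin$kd_25ohd + v2 / albumin$kd_125d
  out$product_25ohd <- anchor_total_nM / (v1 * 1e3) - 1 - alb1 / D_alb
  Q <- anchor_total_125d_nM / (v2 * 1e3) - 1 - alb2 / D_alb
  if (any(Q <= 0)) stop("1,25(OH)2D product calibration is non-positive")
  out$product_125d <- Q
  out$free_25ohd_nM <- NULL
  rownames(out) <- NULL
  structure(out, class = c("genotype_calibration", "data.frame"),
            albumin = albumin, anchor_total_nM = anchor_total_nM,
            anchor_total_125d_nM = anchor_total_125d_nM)
}

#' The default genotype calibration shipped with the package
#'
#' @return a `genotype_calibration` from the shipped reference table with
#'   standard albumin and the 50 nM anchor.
#' @export
reference_calibration <- function() {
  calibrate_genotype_products()
}

#' Serum context for a calibrated genotype
#'
#' Builds the binder set used by the eSS model for one genotype: a linear
#' effective DBP species carrying the calibrated products for both ligands,
#' plus albumin with full competitive (saturable) treatment, optionally
#' diluted to a serum fraction.
#'
#' @param genotype one of [GC_GENOTYPES].
#' @param serum_fraction fraction of full serum in (0, 1].
#' @param calibration a `genotype_calibration`.
#' @param albumin albumin species at full serum.
#' @return a [serum_context()].
#' @examples
#' ctx <- calibrated_context("GC2/2")
#' solve_ess(ligand_totals(50, 0.1, unit = "nM"), ctx)
#' @export
calibrated_context <- function(genotype, serum_fraction = 1,
                               calibration = reference_calibration(),
                               albumin = albumin_binder()) {
  stopifnot(inherits(calibration, "genotype_calibration"))
  genotype <- match.arg(genotype, GC_GENOTYPES)
  row <- calibration[calibration$genotype == genotype, , drop = FALSE]
  if (nrow(row) != 1L) stop("genotype ", genotype, " not present in calibration")
  # concentration 1 with Kd = 1/product: bound = v * product in the linear form
  dbp <- binding_species(paste0("DBP (", genotype, ", calibrated)"),
                         concentration = 1,
                         kd_25ohd = 1 / row$product_25ohd,
                         kd_125d = 1 / row$product_125d,
                         saturable = FALSE)
  ctx <- serum_context(list(dbp, albumin), serum_fraction = 1,
                       genotype = genotype)
  if (serum_fraction < 1) ctx <- dilute_serum(ctx, serum_fraction)
  ctx
}
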