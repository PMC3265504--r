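#' Canonical DBP (GC) allele and genotype labels
#'
#' The group-specific component (GC) gene has three common alleles whose
#' products differ in plasma concentration and binding affinity for the
#' vitamin D metabolites. The six diploid combinations are ordered by
#' decreasing 25OHD affinity of the genotype (highest-affinity first), which
#' is also the order of increasing free 25OHD at fixed total.
#'
#' @format Character vectors.
#' @export
GC_ALLELES <- c("GC1F", "GC1S", "GC2")

#' @rdname GC_ALLELES
#' @export
GC_GENOTYPES <- c("GC1F/1F", "GC1F/1S", "GC1F/2",
                  "GC1S/1S", "GC1S/2", "GC2/2")

#' One GC allele product: affinities and plasma contribution
#'
#' Holds the per-allele dissociation constants for 25OHD and 1,25(OH)2D and
#' the allele's contribution to total plasma DBP. 25OHD is always the
#' higher-affinity ligand of DBP, so `k_25ohd < k_125d` is enforced.
#'
#' @param name allele name, one of [GC_ALLELES].
#' @param k_25ohd dissociation constant vs 25OHD (uM), > 0.
#' @param k_125d dissociation constant vs 1,25(OH)2D (uM), > k_25ohd.
#' @param plasma_level per-allele contribution to plasma DBP (uM), > 0.
#' @return an object of class `gc_allele`.
#' @seealso [default_gc_alleles()] for reference-derived defaults.
#' @export
gc_allele <- function(name, k_25ohd, k_125d, plasma_level) {
  name <- match.arg(name, GC_ALLELES)
  stopifnot(is.numeric(k_25ohd), is.numeric(k_125d), is.numeric(plasma_level))
  if (!(k_25ohd > 0 && k_125d > 0 && plasma_level > 0)) {
    stop("allele constants must be strictly positive")
  }
  if (!(k_25ohd < k_125d)) {
    stop("k_25ohd must be smaller than k_125d: ",
         "25OHD is the higher-affinity DBP ligand")
  }
  structure(list(name = name, k_25ohd = k_25ohd, k_125d = k_125d,
                 plasma_level = plasma_level),
            class = "gc_allele")
}

#' Reference-derived default GC allele parameters
#'
#' Per-allele affinities and plasma contributions assembled from the
#' biochemical literature on DBP variants. They are convenience defaults
#' only and are user-overridable; all quantitative claims in the test suite
#' go through the calibration route ([calibrate_genotype_products()]), which
#' depends only on the published free-25OHD reference table, because only
#' the product concentration/Kd is identifiable from those data.
#'
#' @param file optional path to a key-value config overriding the defaults
#'   (same schema as `inst/extdata/gc_alleles.txt`).
#' @return a named list of [gc_allele()] objects.
#' @export
default_gc_alleles <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "gc_alleles.txt", package = "vitdfree")
  }
  cfg <- read_kv_config(file)
  out <- lapply(GC_ALLELES, function(al) {
    key <- function(f) paste0("allele.", al, ".", f)
    gc_allele(
      name = al,
      k_25ohd = parse_affinity(cfg[[key("ka_25ohd")]]),
      k_125d = parse_affinity(cfg[[key("ka_125d")]]),
      plasma_level = parse_concentration(cfg[[key("plasma_level")]])
    )
  })
  names(out) <- GC_ALLELES
  out
}

#' An extracellular binding species
#'
#' One binder (a DBP allele product, albumin, or a calibrated effective
#' DBP species) with its concentration and per-ligand dissociation
#' constants. A `saturable = FALSE` species is treated in the linear
#' (binder-excess) regime: bound ligand is `v * concentration / Kd` with no
#' occupancy of the binder. That form is used for genotype species
#' calibrated from published free values, where only the dimensionless
#' product concentration/Kd is identifiable.
#'
#' @param label text label.
#' @param concentration binder concentration (uM), >= 0.
#' @param kd_25ohd dissociation constant vs 25OHD (uM), > 0.
#' @param kd_125d dissociation constant vs 1,25(OH)2D (uM), > 0.
#' @param saturable logical; `FALSE` selects the linear effective-product
#'   representation.
#' @return an object of class `binding_species`.
#' @export
binding_species <- function(label, concentration, kd_25ohd, kd_125d,
                            saturable = TRUE) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.numeric(concentration) || concentration < 0) {
    stop("binder concentration must be >= 0")
  }
  if (!(kd_25ohd > 0 && kd_125d > 0)) {
    stop("dissociation constants must be > 0")
  }
  structure(list(label = label, concentration = concentration,
                 kd_25ohd = kd_25ohd, kd_125d = kd_125d,
                 saturable = isTRUE(saturable)),
            class = "binding_species")
}

#' @export
print.binding_species <- function(x, ...) {
  cat(sprintf("<binding_species> %s: B = %.4g uM, Kd(25OHD) = %.4g uM, Kd(1,25D) = %.4g uM%s\n",
              x$label, x$concentration, x$kd_25ohd, x$kd_125d,
              if (x$saturable) "" else " [linear effective product]"))
  invisible(x)
}

#' Serum albumin as a binding species
#'
#' Default concentration 650 uM with association constants 6e5 /M (25OHD)
#' and 5.4e4 /M (1,25(OH)2D), inverted to dissociation constants on
#' construction.
#'
#' @param concentration albumin concentration in uM.
#' @param ka_25ohd,ka_125d association constants in 1/M.
#' @return a `binding_species`.
#' @export
albumin_binder <- function(concentration = 650, ka_25ohd = 6e5, ka_125d = 5.4e4) {
  binding_species("Albumin", concentration,
                  kd_25ohd = ka_to_kd_uM(ka_25ohd),
                  kd_125d = ka_to_kd_uM(ka_125d))
}

#' Genotype-averaged ("mixed") DBP as a single binding species
#'
#' Average serum DBP at 5 uM with association constants 7e8 /M (25OHD) and
#' 4e7 /M (1,25(OH)2D); the single-coefficient representation used when
#' genotype is unknown.
#'
#' @param concentration DBP concentration in uM.
#' @param ka_25ohd,ka_125d association constants in 1/M.
#' @return a `binding_species`.
#' @export
mixed_dbp_binder <- function(concentration = 5, ka_25ohd = 7e8, ka_125d = 4e7) {
  binding_species("DBP (mixed)", concentration,
                  kd_25ohd = ka_to_kd_uM(ka_25ohd),
                  kd_125d = ka_to_kd_uM(ka_125d))
}

#' Split a genotype label into its two alleles
#' @keywords internal
parse_genotype <- function(genotype) {
  genotype <- match.arg(genotype, GC_GENOTYPES)
  parts <- strsplit(sub("^GC", "", genotype), "/", fixed = TRUE)[[1]]
  paste0("GC", parts)
}

#' Binding species for a DBP genotype from per-allele parameters
#'
#' Heterozygous genotypes yield two DBP species, one per allele at that
#' allele's plasma contribution; homozygous genotypes yield a single species
#' at the combined (doubled) concentration.
#'
#' @param genotype one of [GC_GENOTYPES].
#' @param alleles named list of [gc_allele()] objects (defaults to
#'   [default_gc_alleles()]).
#' @return list of `binding_species` (length 1 or 2).
#' @export
genotype_binders <- function(genotype, alleles = default_gc_alleles()) {
  als <- parse_genotype(genotype)
  if (als[1] == als[2]) {
    a <- alleles[[als[1]]]
    list(binding_species(paste0("DBP (", a$name, ", x2)"),
                         2 * a$plasma_level, a$k_25ohd, a$k_125d))
  } else {
    lapply(als, function(nm) {
      a <- alleles[[nm]]
      binding_species(paste0("DBP (", a$name, ")"),
                      a$plasma_level, a$k_25ohd, a$k_125d)
    })
  }
}

#' Total metabolite levels
#'
#' Total (free + bound) extracellular 25OHD and 1,25(OH)2D.
#'
#' @param total_25ohd,total_125d totals, >= 0.
#' @param unit unit of the supplied values (default `"uM"`).
#' @return object of class `ligand_totals` with elements `v1` (25OHD) and
#'   `v2` (1,25(OH)2D) in uM.
#' @examples
#' ligand_totals(50, 0.1, unit = "nM")
#' @export
ligand_totals <- function(total_25ohd, total_125d, unit = "uM") {
  v1 <- convert_conc(total_25ohd, unit, "uM")
  v2 <- convert_conc(total_125d, unit, "uM")
  if (v1 < 0 || v2 < 0) stop("total metabolite levels must be >= 0")
  structure(list(v1 = v1, v2 = v2), class = "ligand_totals")
}

#' @export
print.ligand_totals <- function(x, ...) {
  cat(sprintf("<ligand_totals> 25OHD = %.4g nM, 1,25(OH)2D = %.4g nM\n",
              x$v1 * 1e3, x$v2 * 1e3))
  invisible(x)
}

#' A serum context: binder set at a serum fraction
#'
#' @param binders list of [binding_species()] (or a single one).
#' @param serum_fraction dimensionless fraction of full serum in (0, 1];
#'   binder concentrations are stored already scaled.
#' @param genotype optional genotype label for provenance.
#' @return object of class `serum_context`.
#' @export
serum_context <- function(binders, serum_fraction = 1, genotype = NA_character_) {
  if (inherits(binders, "binding_species")) binders <- list(binders)
  stopifnot(is.list(binders),
            all(vapply(binders, inherits, logical(1), "binding_species")))
  if (!(is.numeric(serum_fraction) && serum_fraction > 0 && serum_fraction <= 1)) {
    stop("serum_fraction must lie in (0, 1]")
  }
  structure(list(binders = binders, serum_fraction = serum_fraction,
                 genotype = genotype),
            class = "serum_context")
}

#' @export
print.serum_context <- function(x, ...) {
  cat(sprintf("<serum_context> %d binder(s), serum fraction %.3g%s\n",
              length(x$binders), x$serum_fraction,
              if (is.na(x$genotype)) "" else paste0(", genotype ", x$genotype)))
  for (b in x$binders) print(b)
  invisible(x)
}

#' Dilute a full-serum binder set to a serum fraction
#'
#' Scales every binder concentration linearly by `serum_fraction`;
#' affinities are unchanged. Models in vitro culture conditions (e.g. 5%
#' serum gives 0.25 uM DBP from the 5 uM full-serum level).
#'
#' @param binders_at_100pct list of [binding_species()] at full serum, or a
#'   [serum_context()] assembled at full serum.
#' @param serum_fraction fraction in (0, 1].
#' @return a [serum_context()] with scaled binders.
#' @export
dilute_serum <- function(binders_at_100pct, serum_fraction) {
  if (!(is.numeric(serum_fraction) && length(serum_fraction) == 1L &&
        serum_fraction > 0 && serum_fraction <= 1)) {
    stop("serum_fraction must lie in (0, 1]")
  }
  genotype <- NA_character_
  if (inherits(binders_at_100pct, "serum_context")) {
    genotype <- binders_at_100pct$genotype
    binders_at_100pct <- binders_at_100pct$binders
  }
  if (inherits(binders_at_100pct, "binding_species")) {
    binders_at_100pct <- list(binders_at_100pct)
  }
  scaled <- lapply(binders_at_100pct, function(b) {
    b$concentration <- b$concentration * serum_fraction
    b
  })
  serum_context(scaled, serum_fraction = serum_fraction, genotype = genotype)
}
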