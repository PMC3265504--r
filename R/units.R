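#' @keywords internal
".conc_units" <- c(pM = 1e-6, nM = 1e-3, uM = 1, "µM" = 1, mM = 1e3, M = 1e6)

#' Convert between concentration units
#'
#' All model internals work in micromolar. These helpers convert tagged
#' quantities on the way in and out. Bare numbers without a unit are rejected
#' by [parse_concentration()] because the source tables mix pM, nM and uM.
#'
#' @param x numeric vector of values.
#' @param from,to unit names: one of `"pM"`, `"nM"`, `"uM"` (alias `"µM"`),
#'   `"mM"`, `"M"`.
#' @return numeric vector in the target unit.
#' @examples
#' convert_conc(50, "nM", "uM")   # 0.05
#' convert_conc(0.25, "uM", "nM") # 250
#' @export
convert_conc <- function(x, from, to = "uM") {
  sf <- .conc_units[from]
  st <- .conc_units[to]
  if (anyNA(sf) || anyNA(st)) {
    stop("unknown concentration unit; use one of ",
         paste(unique(names(.conc_units)), collapse = ", "))
  }
  x * unname(sf) / unname(st)
}

#' Parse a unit-tagged concentration string
#'
#' Accepts strings like `"650 uM"`, `"0.1 nM"`, `"5e3 pM"`. The unit suffix is
#' mandatory; a bare number is an error (strict-parsing rule for config files).
#'
#' @param x character vector of `"<value> <unit>"` strings.
#' @return numeric vector in uM.
#' @examples
#' parse_concentration("50 nM")  # 0.05 uM
#' @export
parse_concentration <- function(x) {
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*(pM|nM|uM|µM|mM|M)\\s*$", x))
  vapply(seq_along(x), function(i) {
    g <- m[[i]]
    if (length(g) != 3L) {
      stop("cannot parse concentration '", x[i],
           "': expected '<value> <unit>' with an explicit unit suffix")
    }
    val <- suppressWarnings(as.numeric(g[2]))
    if (is.na(val)) stop("cannot parse numeric value in '", x[i], "'")
    convert_conc(val, g[3], "uM")
  }, numeric(1))
}

#' Convert an association constant to a dissociation constant
#'
#' Binding tables report association constants Ka in 1/M; the equilibrium
#' solver uses dissociation constants Kd = 1/Ka in uM.
#'
#' @param ka_per_M association constant in 1/M (strictly positive).
#' @return dissociation constant in uM.
#' @examples
#' ka_to_kd_uM(7e8)   # DBP vs 25OHD: ~1.43e-3 uM
#' ka_to_kd_uM(6e5)   # albumin vs 25OHD: ~1.67 uM
#' @export
ka_to_kd_uM <- function(ka_per_M) {
  if (any(!is.finite(ka_per_M)) || any(ka_per_M <= 0)) {
    stop("association constants must be finite and > 0")
  }
  1e6 / ka_per_M
}

#' Parse an affinity given either as Ka ("7e8 /M") or Kd ("1.4e-3 uM")
#'
#' @param x character vector; association constants are tagged `/M` (or
#'   `1/M`, `M-1`), dissociation constants carry a concentration unit.
#' @return dissociation constant(s) in uM.
#' @export
parse_affinity <- function(x) {
  vapply(x, function(s) {
    ma <- regexec("^\\s*([-+0-9.eE]+)\\s*(/M|1/M|M-1|M\\^-1)\\s*$", s)
    g <- regmatches(s, ma)[[1]]
    if (length(g) == 3L) {
      return(ka_to_kd_uM(as.numeric(g[2])))
    }
    parse_concentration(s)
  }, numeric(1), USE.NAMES = FALSE)
}
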