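#' Read a flat key-value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; blank lines ignored.
#' Values stay character so unit-tagged quantities can be parsed strictly
#' by [parse_concentration()] / [parse_affinity()].
#'
#' @param path file path.
#' @return named list of character values.
#' @export
read_kv_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line (expected 'key = value'): ", ln)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!nzchar(key) || !nzchar(val)) stop("malformed config line: ", ln)
    out[[key]] <- val
  }
  out
}

#' Write a flat key-value configuration file
#'
#' @param config named list or vector of scalar values.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_kv_config <- function(config, path) {
  stopifnot(!is.null(names(config)), all(nzchar(names(config))))
  writeLines(paste(names(config), "=", vapply(config, as.character, "")), path)
  invisible(path)
}

#' Load a binder set from a config file
#'
#' Expects, per binder `<name>`: `binder.<name>.concentration` (unit-tagged
#' concentration), `binder.<name>.ka_25ohd` and `binder.<name>.ka_125d`
#' (association constants tagged `/M`, or dissociation constants tagged
#' with a concentration unit), and optionally `binder.<name>.saturable`
#' (`true`/`false`).
#'
#' @param path config file; defaults to the shipped standard serum set
#'   (mixed DBP + albumin).
#' @return list of [binding_species()].
#' @export
load_binders_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "serum_binders.txt", package = "vitdfree")
  }
  cfg <- read_kv_config(path)
  keys <- grep("^binder\\.", names(cfg), value = TRUE)
  names_ <- unique(vapply(strsplit(keys, ".", fixed = TRUE), `[[`, "", 2))
  lapply(names_, function(nm) {
    g <- function(f, required = TRUE) {
      k <- paste0("binder.", nm, ".", f)
      if (is.null(cfg[[k]])) {
        if (required) stop("missing config key: ", k)
        return(NULL)
      }
      cfg[[k]]
    }
    sat <- g("saturable", required = FALSE)
    binding_species(
      label = nm,
      concentration = parse_concentration(g("concentration")),
      kd_25ohd = parse_affinity(g("ka_25ohd")),
      kd_125d = parse_affinity(g("ka_125d")),
      saturable = is.null(sat) || tolower(sat) %in% c("true", "yes", "1")
    )
  })
}

#' Load intracellular model parameters from a config file
#'
#' Keys `cell.<name>` for every [cell_params()] field; rate/affinity values
#' are plain numbers in the internal units (uM, hr), exponents and scales
#' dimensionless.
#'
#' @param path config file; `NULL` returns the defaults.
#' @return a [cell_params()].
#' @export
load_cell_config <- function(path = NULL) {
  if (is.null(path)) return(cell_params())
  cfg <- read_kv_config(path)
  keys <- grep("^cell\\.", names(cfg), value = TRUE)
  vals <- lapply(cfg[keys], function(v) as.numeric(v))
  names(vals) <- sub("^cell\\.", "", keys)
  if (anyNA(unlist(vals))) stop("non-numeric cell parameter value")
  do.call(cell_params, vals)
}
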