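# Provenance-annotated constant tables shipped as plain-text files under
# inst/extdata.  Loaded lazily and cached per session; every numeric constant
# used by the models lives in one of these files, never inline in code.

.qb_cache <- new.env(parent = emptyenv())

qb_extdata <- function(file) {
  path <- system.file("extdata", file, package = "quakebiogeo")
  if (!nzchar(path)) {
    # during development (pkgload) fall back to the source tree
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) {
    stop("constant table not found: ", file, call. = FALSE)
  }
  path
}

qb_table <- function(file) {
  key <- paste0("tbl:", file)
  if (!is.null(.qb_cache[[key]])) {
    return(.qb_cache[[key]])
  }
  tbl <- utils::read.delim(qb_extdata(file), stringsAsFactors = FALSE,
                           check.names = FALSE)
  .qb_cache[[key]] <- tbl
  tbl
}

qb_constant <- function(key) {
  tbl <- qb_table("thermo_constants.tsv")
  i <- match(key, tbl$key)
  if (is.na(i)) stop("unknown constant: ", key, call. = FALSE)
  tbl$value[i]
}

#' Seawater reference composition
#'
#' Ion concentrations (mM), water isotopes and sulfate sulfur isotopes of the
#' seawater endmember used for contamination correction and sulfur mixing.
#' Values are shipped with per-entry provenance in
#' \code{inst/extdata/seawater_reference.tsv}; any entry can be overridden.
#'
#' @param ... named overrides, e.g. \code{SO4 = 28.9}.
#' @return A named list with elements \code{ions} (named numeric vector, mM),
#'   \code{dD_H2O}, \code{d18O_H2O} (permil VSMOW), \code{d34S_SO4},
#'   \code{D33S_SO4} (permil VCDT).
#' @examples
#' seawater_reference()$ions[["Cl"]]
#' seawater_reference(SO4 = 28.9)$ions[["SO4"]]
#' @export
seawater_reference <- function(...) {
  tbl <- qb_table("seawater_reference.tsv")
  vals <- stats::setNames(tbl$value, tbl$key)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(vals))
    if (length(bad)) stop("unknown seawater entries: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    vals[names(over)] <- unlist(over)
  }
  if (any(vals[c("Cl", "SO4", "K", "Ca", "Mg")] <= 0)) {
    stop("major seawater ion concentrations must be positive", call. = FALSE)
  }
  iso <- c("dD_H2O", "d18O_H2O", "d34S_SO4", "D33S_SO4")
  list(ions = vals[setdiff(names(vals), iso)],
       dD_H2O = unname(vals[["dD_H2O"]]),
       d18O_H2O = unname(vals[["d18O_H2O"]]),
       d34S_SO4 = unname(vals[["d34S_SO4"]]),
       D33S_SO4 = unname(vals[["D33S_SO4"]]))
}

#' Lithological unit depth table
#'
#' Depth intervals (mbsf) of the core's lithological units.  Intervals are
#' checked for overlap at load time; uncovered depths are reported as
#' \code{"gap"} by [assign_unit()].
#'
#' @return Data frame with columns \code{unit}, \code{top_mbsf},
#'   \code{bottom_mbsf}, \code{cores}, \code{note}.
#' @export
lithologic_units <- function() {
  tbl <- qb_table("lithologic_units.tsv")
  tbl <- tbl[order(tbl$top_mbsf), ]
  if (any(tbl$bottom_mbsf <= tbl$top_mbsf)) {
    stop("degenerate unit interval in lithologic_units.tsv", call. = FALSE)
  }
  n <- nrow(tbl)
  if (any(tbl$top_mbsf[-1] < tbl$bottom_mbsf[-n])) {
    stop("overlapping unit intervals in lithologic_units.tsv", call. = FALSE)
  }
  tbl
}

qb_reaction_table <- function() {
  qb_table("reactions.tsv")
}

qb_bdot_ion_table <- function() {
  qb_table("bdot_ion_sizes.tsv")
}
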