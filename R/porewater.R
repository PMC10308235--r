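# Pore-water depth profiles: lithological unit assignment and correction of
# seawater contamination introduced during core recovery, traced by sulfate.
# In the prism units the indigenous pore water is sulfate-free (microbial
# sulfate reduction exhausted it over geological time), so any measured
# sulfate is attributed to admixed seawater and the measured sulfate
# concentration fixes the volumetric contamination fraction.

QB_ION_COLS <- c("Cl", "K", "Ca", "Mg", "Mn", "NH4")
QB_ISO_COLS <- c("dD_H2O", "d18O_H2O")

#' Lithological unit containing a depth
#'
#' Looks a depth (mbsf) up in the shipped unit interval table.  Intervals are
#' treated as closed at the top and open at the bottom, except the deepest
#' interval which is closed on both ends; depths in the uncovered intervals
#' between units return `"gap"`.
#'
#' @param depth_mbsf depth(s) in metres below seafloor (>= 0).
#' @return character vector of unit labels (`"U1"` ... or `"gap"`).
#' @examples
#' assign_unit(c(180, 700, 822))  # U1, U3, U4
#' @export
assign_unit <- function(depth_mbsf) {
  if (any(depth_mbsf < 0)) stop("depth must be >= 0", call. = FALSE)
  tbl <- lithologic_units()
  deepest <- which.max(tbl$bottom_mbsf)
  vapply(depth_mbsf, function(d) {
    hit <- which(d >= tbl$top_mbsf &
                   (d < tbl$bottom_mbsf |
                      (d == tbl$bottom_mbsf & seq_len(nrow(tbl)) == deepest)))
    if (length(hit)) tbl$unit[hit[1]] else "gap"
  }, character(1))
}

#' Volumetric seawater-contamination fraction from the sulfate tracer
#'
#' Assuming indigenous sulfate is zero (valid for the prism units), the
#' fraction of admixed seawater is `f = SO4_observed / SO4_seawater`.
#' Fractions above 1 are reported clipped to 1 with a warning; they indicate
#' either an unusually sulfate-rich sample or a violated assumption.
#'
#' @param so4_mM observed sulfate (mM, >= 0); vectorised.
#' @param ref seawater reference, see [seawater_reference()].
#' @return contamination fraction(s) in `[0, 1]`.
#' @examples
#' contamination_fraction(11)  # about 0.39
#' @export
contamination_fraction <- function(so4_mM, ref = seawater_reference()) {
  if (any(so4_mM < 0)) stop("sulfate concentration must be >= 0", call. = FALSE)
  f <- so4_mM / ref$ions[["SO4"]]
  if (any(f > 1)) {
    warning("observed sulfate exceeds the seawater reference; fraction clipped to 1")
    f <- pmin(f, 1)
  }
  f
}

#' Endmember concentration by extrapolating sulfate to zero
#'
#' Draws the line through the seawater point `(SO4_sw, c_sw)` and the sample
#' point `(SO4_obs, c_obs)` and evaluates it at zero sulfate.  Algebraically
#' identical to [unmix_conservative()] with `f = SO4_obs / SO4_sw`, which is
#' asserted by test.
#'
#' @param so4_obs observed sulfate (mM), strictly less than the seawater
#'   reference value.
#' @param c_obs observed concentration of the species of interest (mM).
#' @param species name of the species in the seawater reference table.
#' @param ref seawater reference, see [seawater_reference()].
#' @return extrapolated endmember concentration (mM); may be negative, which
#'   flags a violated zero-sulfate assumption rather than being clamped.
#' @examples
#' extrapolate_zero_sulfate(5, 9.5, "K", seawater_reference(K = 10.2))  # 9.35
#' @export
extrapolate_zero_sulfate <- function(so4_obs, c_obs, species,
                                     ref = seawater_reference()) {
  so4_sw <- ref$ions[["SO4"]]
  if (any(so4_obs >= so4_sw)) {
    stop("sample sulfate must be below the seawater reference (pure seawater is degenerate)",
         call. = FALSE)
  }
  c_sw <- ref$ions[[species]]
  if (is.null(c_sw)) stop("species '", species, "' not in the seawater reference",
                          call. = FALSE)
  slope <- (c_sw - c_obs) / (so4_sw - so4_obs)
  c_obs - so4_obs * slope
}

#' Correct a pore-water profile for seawater contamination
#'
#' For every row the sulfate tracer fixes the volumetric seawater fraction
#' ([contamination_fraction()]); all ion concentrations are extrapolated to
#' zero sulfate and the water isotope columns unmixed with the same fraction.
#' The correction is only meaningful where indigenous sulfate is zero, so a
#' per-unit applicability mask is applied (default: the prism units U1-U4;
#' the underthrust units retain indigenous sulfate and are flagged
#' not-applicable).  Rows where the correction fails (e.g. sulfate at the
#' seawater value) are flagged, not fatal.  Negative corrected
#' concentrations are reported as-is with a flag: they diagnose a violated
#' zero-sulfate assumption.
#'
#' @param profile data frame with columns `depth_mbsf`, `SO4`, any of
#'   `Cl, K, Ca, Mg, Mn, NH4` (mM) and `dD_H2O`, `d18O_H2O` (permil).
#' @param ref seawater reference, see [seawater_reference()].
#' @param applicable_units unit labels for which the zero-sulfate assumption
#'   holds.
#' @return data frame of the same shape plus columns `unit`, `f_contam`,
#'   `corrected` (logical) and `flag` (`""`, `"not_applicable"`,
#'   `"pure_seawater"`, or `"negative_concentration"`); ion and isotope
#'   columns hold corrected values where `corrected` is `TRUE`.
#' @export
correct_profile <- function(profile, ref = seawater_reference(),
                            applicable_units = c("U1", "U2", "U3", "U4")) {
  if (!nrow(profile)) stop("profile is empty", call. = FALSE)
  if (!all(c("depth_mbsf", "SO4") %in% names(profile))) {
    stop("profile needs columns depth_mbsf and SO4", call. = FALSE)
  }
  ions <- intersect(QB_ION_COLS, names(profile))
  isos <- intersect(QB_ISO_COLS, names(profile))
  out <- profile
  out$unit <- assign_unit(profile$depth_mbsf)
  out$f_contam <- NA_real_
  out$corrected <- FALSE
  out$flag <- ""
  sw_iso <- c(dD_H2O = ref$dD_H2O, d18O_H2O = ref$d18O_H2O)
  for (i in seq_len(nrow(out))) {
    if (!(out$unit[i] %in% applicable_units)) {
      out$flag[i] <- "not_applicable"
      next
    }
    so4 <- profile$SO4[i]
    if (!is.finite(so4)) next
    if (so4 >= ref$ions[["SO4"]]) {
      out$flag[i] <- "pure_seawater"
      next
    }
    f <- so4 / ref$ions[["SO4"]]
    out$f_contam[i] <- f
    for (ion in ions) {
      v <- profile[[ion]][i]
      if (is.finite(v)) {
        out[[ion]][i] <- extrapolate_zero_sulfate(so4, v, ion, ref)
      }
    }
    for (iso in isos) {
      v <- profile[[iso]][i]
      if (is.finite(v)) {
        out[[iso]][i] <- unmix_conservative(v, f, sw_iso[[iso]])
      }
    }
    out$SO4[i] <- 0
    out$corrected[i] <- TRUE
    if (any(unlist(out[i, ions]) < 0, na.rm = TRUE)) {
      out$flag[i] <- "negative_concentration"
    }
  }
  out
}
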