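# Core delta/ratio/alpha algebra.  All delta values are permil deviations
# from the conventional reference standard of their isotope system (VSMOW for
# D/H and 18O/16O, VPDB for 13C/12C, VCDT for sulfur).  A delta of -1000
# would imply a zero or negative isotope ratio, so every entry point rejects
# deltas at or below that bound.

.check_delta <- function(delta, what = "delta") {
  if (any(!is.finite(delta)) || any(delta <= -1000)) {
    stop(what, " must be finite and > -1000 permil (isotope ratio must stay positive)",
         call. = FALSE)
  }
  invisible(delta)
}

#' Fractionation factor object
#'
#' Light container for an isotope fractionation factor alpha relating species
#' A over species B.
#'
#' @param alpha dimensionless factor, must satisfy 0 < alpha < 2 for the
#'   systems handled here.
#' @param pair character label "A-B" naming the ordered species pair.
#' @param kind one of `"kinetic"`, `"equilibrium"`, `"apparent"`.
#' @param stderr optional standard error of a fitted alpha.
#' @return Object of class `"fractionation_factor"`.
#' @export
fractionation_factor <- function(alpha, pair = "A-B",
                                 kind = c("apparent", "kinetic", "equilibrium"),
                                 stderr = NA_real_) {
  kind <- match.arg(kind)
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 2)) {
    stop("alpha must lie in (0, 2)", call. = FALSE)
  }
  structure(list(alpha = alpha, pair = pair, kind = kind, stderr = stderr),
            class = "fractionation_factor")
}

#' @export
print.fractionation_factor <- function(x, ...) {
  a <- paste(sprintf("%.4f", utils::head(x$alpha, 5)), collapse = ", ")
  if (length(x$alpha) > 5) a <- paste0(a, ", ...")
  cat(sprintf("alpha(%s) = %s  [%s]%s\n", x$pair, a, x$kind,
              if (is.finite(x$stderr[1])) sprintf("  se = %.4f", x$stderr[1]) else ""))
  invisible(x)
}

as_alpha <- function(x) {
  if (inherits(x, "fractionation_factor")) x$alpha else as.numeric(x)
}

#' Convert a delta value to an isotope ratio (relative to the standard)
#'
#' Returns (1 + delta/1000), the sample/standard ratio quotient.  Multiplying
#' by the standard's absolute ratio (see the constants table) gives the
#' absolute isotope ratio; most algebra in this package only needs the
#' quotient, in which the absolute scale cancels.
#'
#' @param delta permil value(s), > -1000.
#' @return numeric ratio quotient(s).
#' @export
delta_to_ratio <- function(delta) {
  .check_delta(delta)
  1 + delta / 1000
}

#' Convert a ratio quotient back to a delta value
#'
#' @param ratio sample/standard ratio quotient(s), > 0.
#' @return permil delta value(s).
#' @export
ratio_to_delta <- function(ratio) {
  if (any(ratio <= 0)) stop("ratio must be positive", call. = FALSE)
  (ratio - 1) * 1000
}

#' Apparent fractionation factor from two delta values
#'
#' alpha(A-B) = (1000 + delta_A) / (1000 + delta_B).  The chain rule
#' alpha(A-C) = alpha(A-B) * alpha(B-C) holds exactly.
#'
#' @param delta_a,delta_b permil values of species A and B (> -1000).
#' @param pair label for the ordered pair, used only for display.
#' @return A [fractionation_factor()] of kind `"apparent"`.
#' @examples
#' alpha_from_deltas(-850, 0)$alpha        # 0.15
#' alpha_from_deltas(-64, -4)$alpha        # ~0.94 (CH4 vs CO2 carbon)
#' @export
alpha_from_deltas <- function(delta_a, delta_b, pair = "A-B") {
  .check_delta(delta_a, "delta_a")
  .check_delta(delta_b, "delta_b")
  fractionation_factor((1000 + delta_a) / (1000 + delta_b), pair = pair,
                       kind = "apparent")
}

#' Delta of species A implied by the delta of B and a fractionation factor
#'
#' Inverse of [alpha_from_deltas()]:
#' delta_A = alpha * (1000 + delta_B) - 1000.
#'
#' @param delta_b permil value of species B (> -1000).
#' @param alpha fractionation factor (numeric or [fractionation_factor()]),
#'   must be positive.
#' @return permil value of species A.
#' @examples
#' delta_via_alpha(0, 0.15)   # -850
#' @export
delta_via_alpha <- function(delta_b, alpha) {
  .check_delta(delta_b, "delta_b")
  a <- as_alpha(alpha)
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("alpha must be positive", call. = FALSE)
  }
  a * (1000 + delta_b) - 1000
}

# ---- equilibrium calibrations -------------------------------------------

qb_calibration <- function(pair) {
  tbl <- qb_table("equilibrium_calibrations.tsv")
  i <- match(pair, tbl$pair)
  if (is.na(i)) {
    stop("no equilibrium calibration for pair '", pair, "'; available: ",
         paste(tbl$pair, collapse = ", "), call. = FALSE)
  }
  as.list(tbl[i, ])
}

#' Equilibrium isotope fractionation factor at a given temperature
#'
#' Evaluates the shipped equilibrium calibration
#' ln(alpha) = a + b*(1000/T) + c*(1000/T)^2 (T in kelvin) for the requested
#' species pair.  The H2-H2O(l) hydrogen-isotope curve is anchored at
#' alpha = 0.23, 0.26, 0.31 for 4, 25, 55 degC; the CH4-H2O(l) curve is the
#' thermometer used to interpret aged biogenic methane.  Both curves are
#' strictly increasing in temperature over their validity range.
#'
#' @param pair `"H2-H2O"` or `"CH4-H2O"`.
#' @param temperature_C temperature in degC; must lie within the
#'   calibration's validity range (an error is raised otherwise).
#' @return A [fractionation_factor()] of kind `"equilibrium"`.
#' @examples
#' equilibrium_alpha("H2-H2O", 25)$alpha   # 0.26
#' equilibrium_alpha("H2-H2O", 0)$alpha    # about 0.22 (never below 0.2)
#' @export
equilibrium_alpha <- function(pair = c("H2-H2O", "CH4-H2O"), temperature_C) {
  pair <- match.arg(pair)
  cal <- qb_calibration(pair)
  if (any(temperature_C < cal$t_min_C | temperature_C > cal$t_max_C)) {
    stop(sprintf("temperature %.6g degC outside calibration range [%g, %g] for %s",
                 temperature_C[1], cal$t_min_C, cal$t_max_C, pair), call. = FALSE)
  }
  u <- 1000 / (temperature_C + 273.15)
  alpha <- exp(cal$a + cal$b * u + cal$c * u^2)
  fractionation_factor(alpha, pair = pair, kind = "equilibrium")
}

#' Invert an equilibrium calibration: temperature from alpha
#'
#' Finds the temperature at which the equilibrium calibration attains the
#' given alpha, by monotone root bracketing over the calibration's validity
#' range.  Because the calibration is strictly increasing, the root is
#' unique when it exists.
#'
#' @param pair `"H2-H2O"` or `"CH4-H2O"`.
#' @param alpha fractionation factor (numeric or [fractionation_factor()]).
#' @return temperature in degC.
#' @examples
#' temperature_from_alpha("H2-H2O", 0.26)  # 25
#' @export
temperature_from_alpha <- function(pair = c("H2-H2O", "CH4-H2O"), alpha) {
  pair <- match.arg(pair)
  a <- as_alpha(alpha)
  cal <- qb_calibration(pair)
  lo <- equilibrium_alpha(pair, cal$t_min_C)$alpha
  hi <- equilibrium_alpha(pair, cal$t_max_C)$alpha
  if (a < lo || a > hi) {
    stop(sprintf("alpha = %.4g not attainable on the %s calibration (range %.4g-%.4g)",
                 a, pair, lo, hi), call. = FALSE)
  }
  f <- function(tc) equilibrium_alpha(pair, tc)$alpha - a
  stats::uniroot(f, c(cal$t_min_C, cal$t_max_C), tol = 1e-9)$root
}

# ---- conservative-tracer unmixing ---------------------------------------

#' Linear two-component mixing of a conservative quantity
#'
#' @param value indigenous (uncontaminated) value.
#' @param f_contam volumetric contaminant fraction in `[0, 1]`.
#' @param contaminant_value value carried by the contaminant.
#' @return mixed value `(1 - f) * value + f * contaminant_value`.
#' @seealso [unmix_conservative()] for the inverse.
#' @export
mix_conservative <- function(value, f_contam, contaminant_value) {
  if (any(f_contam < 0 | f_contam > 1)) {
    stop("f_contam must lie in [0, 1]", call. = FALSE)
  }
  (1 - f_contam) * value + f_contam * contaminant_value
}

#' Remove a known contaminant fraction from a conservative quantity
#'
#' Inverts linear volumetric mixing:
#' indigenous = (measured - f * contaminant) / (1 - f).  Exact for any
#' conservative quantity (ion concentration, water isotope value) under the
#' two-component mixing model.
#'
#' @param measured measured (mixed) value.
#' @param f_contam volumetric contaminant fraction, `0 <= f < 1`.
#' @param contaminant_value value carried by the contaminant.
#' @return the indigenous value.
#' @examples
#' unmix_conservative(3.82, 0.40, 0)  # +6.37 permil
#' @export
unmix_conservative <- function(measured, f_contam, contaminant_value) {
  if (any(f_contam < 0) || any(f_contam >= 1)) {
    stop("f_contam must lie in [0, 1); at f = 1 there is no indigenous fraction",
         call. = FALSE)
  }
  (measured - f_contam * contaminant_value) / (1 - f_contam)
}

#' Isotopic trajectory of residual methane under microbial oxidation
#'
#' Microbial methane consumption enriches the residual CH4 in both 13C and D
#' with a characteristic deltaD/delta13C slope of about 10.  Given a starting
#' composition and an extent of 13C enrichment, returns the displaced
#' composition along that trajectory.
#'
#' @param delta13C_0,deltaD_0 starting composition (permil).
#' @param shift13C nonnegative 13C enrichment (permil).
#' @param slope deltaD per delta13C; default 10.
#' @return named numeric vector `c(delta13C, deltaD)`.
#' @examples
#' methanotrophy_trajectory(-84, -200, 2)  # c(-82, -180)
#' @export
methanotrophy_trajectory <- function(delta13C_0, deltaD_0, shift13C, slope = 10) {
  if (any(shift13C < 0)) stop("shift13C must be >= 0", call. = FALSE)
  c(delta13C = delta13C_0 + shift13C,
    deltaD = deltaD_0 + slope * shift13C)
}
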