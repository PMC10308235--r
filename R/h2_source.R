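# Source attribution for headspace H2: Keeling-plot endmember regression,
# kinetic fractionation fitting of Fe-H2O batch experiments, and the
# alpha-temperature classification of H2 origin.

#' Forward two-endmember Keeling mixtures
#'
#' Builds the observed headspace series produced when H2 from a source with
#' fixed isotope composition is added on top of a constant background (for
#' headspace work, air H2: about 0.5 ppmv with deltaD +150 permil).  Each
#' observation obeys isotope mass balance
#' `delta_obs = (c_bg * delta_bg + c_add * delta_src) / (c_bg + c_add)` and is
#' exactly linear in the reciprocal total mixing ratio, which is what the
#' Keeling regression exploits.
#'
#' @param c_background background mixing ratio (ppmv, >= 0).
#' @param delta_background background isotope value (permil).
#' @param added_concentrations vector of source-derived mixing ratios
#'   (ppmv, >= 0).
#' @param delta_source source isotope value (permil).
#' @return data frame with columns `mixing_ratio_ppmv` and `dD_h2_permil`.
#' @export
keeling_forward <- function(c_background, delta_background,
                            added_concentrations, delta_source) {
  if (c_background < 0 || any(added_concentrations < 0)) {
    stop("mixing ratios must be nonnegative", call. = FALSE)
  }
  total <- c_background + added_concentrations
  if (any(total == 0)) {
    stop("background plus added H2 must be positive for every sample",
         call. = FALSE)
  }
  delta <- (c_background * delta_background +
              added_concentrations * delta_source) / total
  data.frame(mixing_ratio_ppmv = total, dD_h2_permil = delta)
}

#' Keeling-plot regression: isotope value on reciprocal mixing ratio
#'
#' Regresses the isotope value on 1/mixing ratio.  On the two-endmember
#' mixing model the intercept estimates the isotope composition of the
#' high-concentration source endmember and the slope equals
#' `c_background * (delta_background - delta_source)`.  Ordinary least
#' squares is the conventional Keeling estimator and is exact on noise-free
#' mixtures; a geometric-mean (model II) variant is available for data with
#' comparable error in both coordinates.
#'
#' @param samples data frame with columns `mixing_ratio_ppmv` and
#'   `dD_h2_permil` (as produced by [keeling_forward()] or read from file);
#'   alternatively a numeric vector of mixing ratios.
#' @param delta isotope values, required when `samples` is a numeric vector.
#' @param method `"ols"` (default) or `"gmr"` (geometric-mean regression).
#' @return object of class `"keeling_fit"`: list with `intercept_delta`,
#'   `slope`, `stderr_intercept`, `r2`, `n`, `method`.
#' @examples
#' s <- keeling_forward(0.5, 150, c(1, 2, 5, 20, 100), -850)
#' keeling_fit(s)$intercept_delta   # -850 exactly
#' @export
keeling_fit <- function(samples, delta = NULL, method = c("ols", "gmr")) {
  method <- match.arg(method)
  if (is.data.frame(samples)) {
    x <- samples$mixing_ratio_ppmv
    y <- samples$dD_h2_permil
  } else {
    x <- as.numeric(samples)
    y <- delta
  }
  keep <- is.finite(x) & is.finite(y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("keeling_fit: dropped ", n_dropped, " sample(s) with missing values")
  }
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete samples", call. = FALSE)
  if (any(x <= 0)) stop("mixing ratios must be positive", call. = FALSE)
  inv <- 1 / x
  if (diff(range(inv)) == 0) {
    stop("degenerate design: all mixing ratios equal", call. = FALSE)
  }
  fit <- stats::lm(y ~ inv)
  cf <- stats::coef(fit)
  # noise-free forward mixtures fit exactly; the perfect-fit note is expected
  sm <- suppressWarnings(summary(fit))
  slope <- unname(cf[2])
  intercept <- unname(cf[1])
  if (method == "gmr") {
    # model II: slope sign from OLS, magnitude sd(y)/sd(x)
    slope <- sign(slope) * stats::sd(y) / stats::sd(inv)
    intercept <- mean(y) - slope * mean(inv)
  }
  se_int <- if (length(x) >= 3) unname(sm$coefficients[1, 2]) else NA_real_
  structure(list(intercept_delta = intercept,
                 slope = slope,
                 stderr_intercept = se_int,
                 r2 = sm$r.squared,
                 n = length(x),
                 method = method),
            class = "keeling_fit")
}

#' @export
print.keeling_fit <- function(x, ...) {
  cat(sprintf("Keeling fit (%s, n = %d): intercept %.1f permil (se %.2f), slope %.2f, r2 = %.4f\n",
              x$method, x$n, x$intercept_delta, x$stderr_intercept, x$slope, x$r2))
  invisible(x)
}

#' Kinetic fractionation factor from a water-manipulation batch experiment
#'
#' In low-temperature Fe-H2O batch experiments the water's deltaD is varied
#' (up to about +3000 permil by D2O spiking) and the generated H2 measured.
#' Under a constant kinetic fractionation factor the points
#' `(1000 + dD_H2O, 1000 + dD_H2)` fall on a line through the origin with
#' slope alpha; that slope is estimated by least squares through the origin,
#' which weights all batches equally and is exact on the linear
#' fractionation model.
#'
#' @param dD_h2o,dD_h2 paired water and H2 isotope values (permil, > -1000).
#' @param pair label for the returned factor.
#' @return [fractionation_factor()] of kind `"kinetic"`, with the regression
#'   standard error in `$stderr`.
#' @examples
#' dw <- c(0, 1000, 3000)
#' fit_alpha_origin(dw, 0.19 * (1000 + dw) - 1000)$alpha  # 0.19
#' @export
fit_alpha_origin <- function(dD_h2o, dD_h2, pair = "H2-H2O") {
  .check_delta(dD_h2o, "dD_h2o")
  .check_delta(dD_h2, "dD_h2")
  if (length(dD_h2o) != length(dD_h2)) stop("inputs must be paired", call. = FALSE)
  if (length(unique(dD_h2o)) < 2) {
    stop("degenerate design: need at least two distinct dD_h2o values",
         call. = FALSE)
  }
  x <- 1000 + dD_h2o
  y <- 1000 + dD_h2
  fit <- stats::lm(y ~ 0 + x)
  se <- unname(suppressWarnings(summary(fit))$coefficients[1, 2])
  fractionation_factor(unname(stats::coef(fit)[1]), pair = pair,
                       kind = "kinetic", stderr = se)
}

#' Classify the origin of H2 from its apparent alpha and temperature
#'
#' Compares an apparent H2-H2O hydrogen-isotope fractionation factor with the
#' equilibrium curve at the ambient temperature.  Strongly D-depleted H2
#' (alpha well below equilibrium) indicates generation by a low-temperature
#' water-rock process; alpha within a band of the equilibrium value indicates
#' isotopically equilibrated H2 (e.g. microbially cycled); D-rich H2 with
#' alpha at or above 0.6 carries the signature of high-temperature processes
#' (hydrothermal fluids at 300-400 degC show 0.6-0.7; frictional melting
#' about 0.8).
#'
#' @param alpha apparent fractionation factor in (0, 1).
#' @param temperature_C ambient temperature, 0-400 degC.  Above the
#'   equilibrium calibration's range (100 degC) only the high-temperature
#'   cutoff can discriminate, and alpha below it is reported as
#'   low-temperature water-rock.
#' @param band half-width of the equilibrium band (default 0.02).
#' @param high_t_cutoff alpha at or above which H2 is classified as
#'   high-temperature kinetic (default 0.6).
#' @return one of `"low_T_water_rock"`, `"equilibrated"`, `"high_T_kinetic"`.
#' @examples
#' classify_h2_origin(0.15, 4)    # low_T_water_rock
#' classify_h2_origin(0.26, 25)   # equilibrated
#' classify_h2_origin(0.80, 25)   # high_T_kinetic
#' @export
classify_h2_origin <- function(alpha, temperature_C, band = 0.02,
                               high_t_cutoff = 0.6) {
  a <- as_alpha(alpha)
  if (a <= 0 || a >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (temperature_C < 0 || temperature_C > 400) {
    stop("temperature must lie in 0-400 degC", call. = FALSE)
  }
  cal <- qb_calibration("H2-H2O")
  if (temperature_C <= cal$t_max_C) {
    a_eq <- equilibrium_alpha("H2-H2O", temperature_C)$alpha
    if (abs(a - a_eq) <= band) return("equilibrated")
    if (a < a_eq - band) return("low_T_water_rock")
    return("high_T_kinetic")
  }
  if (a >= high_t_cutoff) "high_T_kinetic" else "low_T_water_rock"
}
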