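# Multiple-sulfur-isotope statistics.  The mass-dependent reference exponent
# linking 33S to 34S fractionation is fixed at 0.515; observed mass-dependent
# processes (e.g. microbial sulfate reduction) may express a slightly
# different exponent lambda33 (0.514 is typical), which is why cap_delta33
# and lambda33 are kept distinct.

#' Capital-delta-33S: deviation from the mass-dependent reference line
#'
#' Delta33S = delta33S - ((1 + delta34S/1000)^0.515 - 1) * 1000, evaluated
#' exactly (no linearised approximation).  Near-zero for mass-dependently
#' fractionated sulfur; juvenile mantle sulfur sits at (0, 0).
#'
#' @param delta33S,delta34S permil VCDT values (> -1000).
#' @param exponent mass-dependent reference exponent (default 0.515).
#' @return Delta33S in permil.
#' @examples
#' cap_delta33(10.963, 21.3)   # about +0.050 (seawater sulfate)
#' @export
cap_delta33 <- function(delta33S, delta34S, exponent = 0.515) {
  .check_delta(delta33S, "delta33S")
  .check_delta(delta34S, "delta34S")
  delta33S - ((1 + delta34S / 1000)^exponent - 1) * 1000
}

#' 34S fractionation magnitude of sulfate reduction (epsilon-34)
#'
#' eps34 = 1000 * (1 - (1000 + delta34_sulfide) / (1000 + delta34_sulfate)).
#' Positive values mean the product sulfide is depleted in 34S relative to
#' the reactant sulfate, as in microbial sulfate reduction.
#'
#' @param delta34_sulfide,delta34_sulfate permil VCDT values (> -1000).
#' @return eps34 in permil.
#' @examples
#' epsilon34(-47.95, 21.3)  # 67.8
#' @export
epsilon34 <- function(delta34_sulfide, delta34_sulfate) {
  .check_delta(delta34_sulfide, "delta34_sulfide")
  .check_delta(delta34_sulfate, "delta34_sulfate")
  1000 * (1 - (1000 + delta34_sulfide) / (1000 + delta34_sulfate))
}

#' Mass-law exponent of sulfate reduction (lambda-33)
#'
#' lambda33 = ln(R33_sulfide / R33_sulfate) / ln(R34_sulfide / R34_sulfate),
#' with R the isotope ratio quotients implied by the delta values.  Recovers
#' the exponent exactly when the sulfide was constructed from the sulfate by
#' a single mass-dependent fractionation.
#'
#' @param delta33_sulfide,delta34_sulfide,delta33_sulfate,delta34_sulfate
#'   permil VCDT values (> -1000).
#' @return dimensionless exponent.
#' @export
lambda33 <- function(delta33_sulfide, delta34_sulfide,
                     delta33_sulfate, delta34_sulfate) {
  .check_delta(c(delta33_sulfide, delta34_sulfide,
                 delta33_sulfate, delta34_sulfate), "delta")
  if (any(delta34_sulfide == delta34_sulfate)) {
    stop("degenerate: sulfide and sulfate coincide in delta34S (zero denominator)",
         call. = FALSE)
  }
  log((1000 + delta33_sulfide) / (1000 + delta33_sulfate)) /
    log((1000 + delta34_sulfide) / (1000 + delta34_sulfate))
}

#' Forward model of microbial sulfate reduction fractionation
#'
#' Produces the sulfide composition generated from a sulfate reservoir by a
#' fractionation of magnitude eps34 and mass-law exponent lambda33:
#' the 34S ratio is scaled by (1 - eps34/1000) and the 33S ratio by that
#' factor raised to lambda33.  [epsilon34()] and [lambda33()] applied to the
#' input/output pair recover the parameters exactly.
#'
#' @param delta33_sulfate,delta34_sulfate sulfate composition (permil VCDT).
#' @param eps34 fractionation magnitude (permil).
#' @param lambda mass-law exponent (default 0.515).
#' @return named numeric vector `c(delta33S, delta34S, cap_delta33)` of the
#'   product sulfide.
#' @examples
#' msr_forward(10.963, 21.3, eps34 = 67.8, lambda = 0.514)
#' @export
msr_forward <- function(delta33_sulfate, delta34_sulfate, eps34,
                        lambda = 0.515) {
  .check_delta(delta33_sulfate, "delta33_sulfate")
  .check_delta(delta34_sulfate, "delta34_sulfate")
  r34 <- 1 - eps34 / 1000
  if (r34 <= 0) stop("eps34 must be < 1000 permil", call. = FALSE)
  d34 <- (1000 + delta34_sulfate) * r34 - 1000
  d33 <- (1000 + delta33_sulfate) * r34^lambda - 1000
  c(delta33S = d33, delta34S = d34,
    cap_delta33 = cap_delta33(d33, d34))
}

#' Two-endmember sulfur mixing curve in (delta34S, Delta33S) space
#'
#' Mixes two sulfur reservoirs by mass balance on isotopologue abundances:
#' each endmember's delta values are converted to absolute 33S/32S and
#' 34S/32S ratios on the VCDT scale, the molar fractions of 32S, 33S and 34S
#' are combined linearly in the mixing fraction (equal total sulfur per unit
#' of fraction unless weights are supplied), and the mixture is converted
#' back to deltas with Delta33S recomputed.  Because Delta33S is a nonlinear
#' function of delta34S, mixtures between isotopically distant endmembers
#' bow away from the straight line in (delta34S, Delta33S) coordinates -
#' the signature used to recognise juvenile/biogenic sulfide mixtures.
#'
#' @param end1,end2 numeric vectors `c(delta33S, delta34S)` (named or
#'   positional), e.g. `c(delta33S = 0, delta34S = 0)` for juvenile sulfur.
#' @param fractions vector of mixing fractions f in `[0, 1]`; f = 0 returns
#'   `end1`, f = 1 returns `end2`.
#' @param weight2 relative total sulfur of endmember 2 per unit of mixing
#'   fraction (default 1: composition-only mixing).
#' @return data frame with columns `f`, `delta33S`, `delta34S`,
#'   `cap_delta33`.
#' @export
sulfur_mixing_curve <- function(end1, end2, fractions, weight2 = 1) {
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  r33 <- qb_constant("ratio_33S_32S_VCDT")
  r34 <- qb_constant("ratio_34S_32S_VCDT")
  dd <- function(e) {
    e <- as.numeric(e)
    .check_delta(e)
    c(R33 = r33 * (1 + e[1] / 1000), R34 = r34 * (1 + e[2] / 1000))
  }
  ab <- function(R) {
    tot <- 1 + R[["R33"]] + R[["R34"]]
    c(x32 = 1 / tot, x33 = R[["R33"]] / tot, x34 = R[["R34"]] / tot)
  }
  a1 <- ab(dd(end1))
  a2 <- ab(dd(end2))
  out <- vapply(fractions, function(f) {
    w1 <- (1 - f); w2 <- f * weight2
    m <- (w1 * a1 + w2 * a2) / (w1 + w2)
    d33 <- (m[["x33"]] / m[["x32"]] / r33 - 1) * 1000
    d34 <- (m[["x34"]] / m[["x32"]] / r34 - 1) * 1000
    c(d33, d34)
  }, numeric(2))
  data.frame(f = fractions,
             delta33S = out[1, ],
             delta34S = out[2, ],
             cap_delta33 = cap_delta33(out[1, ], out[2, ]))
}
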