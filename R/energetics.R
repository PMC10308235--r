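# Catabolic energetics of the competing hydrogenotrophic metabolisms:
# hydrogenotrophic methanogenesis, homoacetogenesis, and (via the reverse of
# the shipped acetate-exchange reaction) acetoclastic methanogenesis.
# Activities of charged species use the B-dot extended Debye-Huckel model;
# neutral dissolved species (H2, CO2, CH4, CH3COOH) default to unit activity
# coefficients, and water activity is fixed at 1.  pH is interpreted on the
# activity scale (a_H = 10^-pH).

qb_species_elements <- function() {
  # element counts and charge used only for stoichiometry validation
  list(
    H2      = c(H = 2, C = 0, O = 0, z = 0),
    CO2     = c(H = 0, C = 1, O = 2, z = 0),
    CH4     = c(H = 4, C = 1, O = 0, z = 0),
    H2O     = c(H = 2, C = 0, O = 1, z = 0),
    CH3COOH = c(H = 4, C = 2, O = 2, z = 0)
  )
}

parse_stoichiometry <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  stats::setNames(vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(kv, function(p) p[1], character(1)))
}

validate_reaction <- function(stoich, name = "reaction") {
  el <- qb_species_elements()
  unknown <- setdiff(names(stoich), names(el))
  if (length(unknown)) {
    stop(name, ": unknown species ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bal <- Reduce(`+`, Map(function(sp, nu) nu * el[[sp]],
                         names(stoich), stoich))
  if (any(abs(bal) > 1e-9)) {
    stop(name, ": element or charge imbalance (",
         paste(names(bal), bal, sep = "=", collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(stoich)
}

#' Reaction specification
#'
#' @param name reaction label.
#' @param stoichiometry named numeric vector of signed coefficients
#'   (products positive).
#' @param dG0_kJ standard Gibbs energy of reaction (kJ/mol) at 25 degC.
#' @return object of class `"reaction_spec"`.
#' @export
reaction_spec <- function(name, stoichiometry, dG0_kJ) {
  validate_reaction(stoichiometry, name)
  structure(list(name = name, stoichiometry = stoichiometry, dG0_kJ = dG0_kJ),
            class = "reaction_spec")
}

#' @export
print.reaction_spec <- function(x, ...) {
  lhs <- x$stoichiometry[x$stoichiometry < 0]
  rhs <- x$stoichiometry[x$stoichiometry > 0]
  term <- function(v) paste(ifelse(abs(v) == 1, "", abs(v)), names(v),
                            sep = "", collapse = " + ")
  cat(sprintf("%s: %s = %s   dG0 = %.2f kJ/mol\n", x$name, term(lhs), term(rhs),
              x$dG0_kJ))
  invisible(x)
}

#' Shipped metabolic reactions
#'
#' The three reactions of the energy landscape: hydrogenotrophic
#' methanogenesis, homoacetogenesis, and the acetate-exchange reaction
#' (CH4 + CO2 = CH3COOH), whose reverse is acetoclastic methanogenesis.
#' Standard Gibbs energies are shipped with provenance in
#' \code{inst/extdata/reactions.tsv}; the trio is Hess-closed
#' (acetate exchange = homoacetogenesis - methanogenesis) exactly.
#'
#' @param name optional single reaction name.
#' @return a named list of [reaction_spec()] objects, or a single one.
#' @export
qb_reactions <- function(name = NULL) {
  tbl <- qb_reaction_table()
  rx <- lapply(seq_len(nrow(tbl)), function(i) {
    reaction_spec(tbl$name[i], parse_stoichiometry(tbl$stoichiometry[i]),
                  tbl$dG0_kJ_mol[i])
  })
  names(rx) <- tbl$name
  # enforce exact Hess closure of the trio; the stored value is the rounded
  # documentation copy and must agree with the combination it represents
  hess <- rx$homoacetogenesis$dG0_kJ - rx$hydrogenotrophic_methanogenesis$dG0_kJ
  if (abs(hess - rx$acetate_exchange$dG0_kJ) > 0.01) {
    stop("reactions.tsv: acetate_exchange dG0 inconsistent with Hess closure",
         call. = FALSE)
  }
  rx$acetate_exchange$dG0_kJ <- hess
  if (is.null(name)) return(rx)
  if (!name %in% names(rx)) {
    stop("unknown reaction '", name, "'; available: ",
         paste(names(rx), collapse = ", "), call. = FALSE)
  }
  rx[[name]]
}

#' Reverse a reaction
#'
#' Negates stoichiometry and standard Gibbs energy, e.g. turning the
#' acetate-exchange reaction into acetoclastic methanogenesis.
#'
#' @param reaction a [reaction_spec()].
#' @return the reversed [reaction_spec()].
#' @export
reverse_reaction <- function(reaction) {
  reaction_spec(paste0(reaction$name, "_reversed"),
                -reaction$stoichiometry, -reaction$dG0_kJ)
}

# ---- activity model ------------------------------------------------------

#' Ionic strength of a solution composition
#'
#' I = 1/2 * sum(m_i * z_i^2).  Charges are looked up from the shipped ion
#' table when not supplied.
#'
#' @param molality named numeric vector of molalities (mol/kg, >= 0), names
#'   as in \code{inst/extdata/bdot_ion_sizes.tsv} (e.g. `"Na+"`, `"Cl-"`).
#' @param charges optional named integer vector overriding the lookup.
#' @return ionic strength (mol/kg).
#' @examples
#' ionic_strength(c("Na+" = 0.5, "Cl-" = 0.5))  # 0.5
#' @export
ionic_strength <- function(molality, charges = NULL) {
  if (!length(molality)) return(0)
  if (any(molality < 0)) stop("molalities must be >= 0", call. = FALSE)
  if (is.null(charges)) {
    tbl <- qb_bdot_ion_table()
    idx <- match(names(molality), tbl$species)
    if (anyNA(idx)) {
      stop("no charge known for species: ",
           paste(names(molality)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    charges <- tbl$charge[idx]
  } else {
    charges <- charges[names(molality)]
  }
  sum(molality * charges^2) / 2
}

#' B-dot extended Debye-Huckel single-ion activity coefficient
#'
#' log10(gamma) = -A z^2 sqrt(I) / (1 + B a sqrt(I)) + Bdot * I for charged
#' species; neutral species return log10(gamma) = 0 under the default
#' neutral rule (unit activity coefficient).
#'
#' @param z signed charge number.
#' @param ion_size effective ion diameter a (Angstrom).
#' @param I ionic strength (mol/kg, >= 0).
#' @return log10 of the activity coefficient.
#' @export
bdot_log_gamma <- function(z, ion_size, I) {
  if (I < 0) stop("ionic strength must be >= 0", call. = FALSE)
  if (z == 0) return(0)
  A <- qb_constant("A_gamma")
  B <- qb_constant("B_gamma")
  bdot <- qb_constant("bdot")
  -A * z^2 * sqrt(I) / (1 + B * ion_size * sqrt(I)) + bdot * I
}

qb_gamma <- function(species, I) {
  tbl <- qb_bdot_ion_table()
  i <- match(species, tbl$species)
  if (is.na(i)) stop("species '", species, "' not in the B-dot ion table",
                     call. = FALSE)
  10^bdot_log_gamma(tbl$charge[i], tbl$a_angstrom[i], I)
}

#' Weak monoprotic acid speciation at fixed pH
#'
#' Mass balance on total acid with HA = H+ + A-:
#' `m_A = total / (1 + a_H * gamma_A / Ka)` and
#' `a_HA = a_H * gamma_A * m_A / Ka` (unit activity coefficient for the
#' neutral form).  At fixed pH the neutral-species activity is exactly
#' linear in the total concentration.
#'
#' @param total_mM total acid (mM, >= 0).
#' @param pKa dissociation constant at the conditions of interest; defaults
#'   to the shipped acetic-acid value at 25 degC and 500 bar.
#' @param pH activity-scale pH.
#' @param I ionic strength (mol/kg).
#' @param anion species name of the deprotonated form in the ion table.
#' @return list with `a_HA`, `a_A`, `m_HA`, `m_A` (activities and molalities;
#'   molality is taken as molarity at these conditions).
#' @examples
#' speciate_weak_acid(1, pH = 7.9)$a_HA  # about 4e-7
#' @export
speciate_weak_acid <- function(total_mM, pKa = qb_constant("pKa_acetic"),
                               pH = 7.9, I = 0.66, anion = "CH3COO-") {
  if (total_mM < 0) stop("total must be >= 0", call. = FALSE)
  total <- total_mM / 1000
  aH <- 10^(-pH)
  Ka <- 10^(-pKa)
  gA <- qb_gamma(anion, I)
  m_A <- total / (1 + aH * gA / Ka)
  m_HA <- total - m_A
  a_A <- gA * m_A
  a_HA <- aH * a_A / Ka
  list(a_HA = a_HA, a_A = a_A, m_HA = m_HA, m_A = m_A)
}

#' Carbonate speciation: CO2(aq) activity from total dissolved CO2
#'
#' Three-species mass balance (CO2(aq), HCO3-, CO3--) at fixed pH with
#' activity coefficients from the B-dot model:
#' `m_CO2 = total / (1 + r1 + r1 * r2)` with
#' `r1 = K1 / (a_H * gamma_HCO3)` and `r2 = K2 * gamma_HCO3 /
#' (a_H * gamma_CO3)`; `a_CO2 = m_CO2` under the unit neutral rule.
#'
#' @param total_mM total dissolved CO2 (mM, >= 0).
#' @param pH activity-scale pH.
#' @param I ionic strength (mol/kg).
#' @param pK1,pK2 dissociation constants; default to the shipped values at
#'   25 degC and 500 bar.
#' @return list with `a_CO2`, `m_CO2`, `m_HCO3`, `m_CO3`.
#' @export
speciate_carbonate <- function(total_mM, pH = 7.9, I = 0.66,
                               pK1 = qb_constant("pK1_CO2"),
                               pK2 = qb_constant("pK2_CO2")) {
  if (total_mM < 0) stop("total must be >= 0", call. = FALSE)
  total <- total_mM / 1000
  aH <- 10^(-pH)
  g1 <- qb_gamma("HCO3-", I)
  g2 <- qb_gamma("CO3-2", I)
  r1 <- 10^(-pK1) / (aH * g1)
  r2 <- 10^(-pK2) * g1 / (aH * g2)
  m_CO2 <- total / (1 + r1 + r1 * r2)
  list(a_CO2 = m_CO2, m_CO2 = m_CO2,
       m_HCO3 = m_CO2 * r1, m_CO3 = m_CO2 * r1 * r2)
}

# ---- conditions and free energy -----------------------------------------

#' Solution condition for the energy landscape
#'
#' Bundles the geochemical context held fixed while sweeping a substrate
#' activity: 25 degC, 500 bar, pH 7.9, total CO2 50 mM, CH4 5 mM (the
#' deep-prism values) and a configurable total acetate; the ionic strength
#' default (0.66 mol/kg) is seawater-like, consistent with 560 mM chloride.
#'
#' @param temperature_C temperature (degC).
#' @param pressure_bar pressure (bar); recorded for provenance (the shipped
#'   constants are evaluated at these conditions).
#' @param pH activity-scale pH.
#' @param sum_co2_mM total dissolved CO2 (mM).
#' @param sum_acetate_mM total acetate (mM).
#' @param ch4_mM dissolved methane (mM).
#' @param ionic_strength ionic strength (mol/kg).
#' @return object of class `"solution_condition"` (a list).
#' @export
solution_condition <- function(temperature_C = 25, pressure_bar = 500,
                               pH = 7.9, sum_co2_mM = 50, sum_acetate_mM = 1,
                               ch4_mM = 5, ionic_strength = 0.66) {
  stopifnot(sum_co2_mM >= 0, sum_acetate_mM >= 0, ch4_mM >= 0,
            ionic_strength >= 0)
  structure(list(temperature_C = temperature_C, pressure_bar = pressure_bar,
                 pH = pH, sum_co2_mM = sum_co2_mM,
                 sum_acetate_mM = sum_acetate_mM, ch4_mM = ch4_mM,
                 ionic_strength = ionic_strength),
            class = "solution_condition")
}

#' Species activities implied by a solution condition
#'
#' Speciates total CO2 and total acetate and applies the unit neutral rule
#' to CH4; water activity is 1.  The H2 activity is left for the caller
#' (it is the swept variable of the landscape).
#'
#' @param condition a [solution_condition()].
#' @param a_H2 optional H2 activity to include.
#' @return named numeric vector of activities.
#' @export
condition_activities <- function(condition, a_H2 = NULL) {
  act <- c(
    CO2 = speciate_carbonate(condition$sum_co2_mM, pH = condition$pH,
                             I = condition$ionic_strength)$a_CO2,
    CH3COOH = speciate_weak_acid(condition$sum_acetate_mM, pH = condition$pH,
                                 I = condition$ionic_strength)$a_HA,
    CH4 = condition$ch4_mM / 1000,
    H2O = 1
  )
  if (!is.null(a_H2)) act <- c(act, H2 = a_H2)
  act
}

#' Gibbs free energy of reaction at given activities
#'
#' dGr = dG0 + R T ln(Q) with Q the stoichiometric activity product and T
#' the absolute temperature.  Missing activities are an error, except water
#' which defaults to 1.
#'
#' @param reaction a [reaction_spec()] or reaction name.
#' @param activities named numeric activities covering the reaction species.
#' @param temperature_C temperature (degC).
#' @return dGr in kJ/mol (negative = exergonic).
#' @examples
#' rx <- qb_reactions("hydrogenotrophic_methanogenesis")
#' delta_g(rx, c(H2 = 1, CO2 = 1, CH4 = 1, H2O = 1))  # equals dG0
#' @export
delta_g <- function(reaction, activities, temperature_C = 25) {
  if (is.character(reaction)) reaction <- qb_reactions(reaction)
  sp <- names(reaction$stoichiometry)
  if (!"H2O" %in% names(activities) && "H2O" %in% sp) {
    activities <- c(activities, H2O = 1)
  }
  missing <- setdiff(sp, names(activities))
  if (length(missing)) {
    stop("missing activities for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(activities[sp] <= 0)) stop("activities must be positive", call. = FALSE)
  R <- qb_constant("R_J_mol_K")
  TK <- temperature_C + 273.15
  lnQ <- sum(reaction$stoichiometry * log(activities[sp]))
  reaction$dG0_kJ + R * TK * lnQ / 1000
}

#' Threshold activity at which a reaction reaches dGr = 0
#'
#' Bisection on the log10 activity of one species over `[-12, 0]` to a
#' free-energy tolerance of 0.01 kJ/mol.  The reaction quotient is monotone
#' in the log activity of any single species, so the root is unique when the
#' sign changes over the bracket.
#'
#' @param reaction a [reaction_spec()] or name.
#' @param condition a [solution_condition()] fixing all other activities.
#' @param free_species the species whose activity is solved for
#'   (default `"H2"`).
#' @param lower,upper log10 activity bracket.
#' @param tol_kJ free-energy tolerance (kJ/mol).
#' @return list with `activity`, `log10_activity`, `dG_at_root_kJ`.
#' @examples
#' cond <- solution_condition(sum_acetate_mM = 1)
#' threshold_activity("homoacetogenesis", cond)$log10_activity  # about -7
#' @export
threshold_activity <- function(reaction, condition = solution_condition(),
                               free_species = "H2", lower = -12, upper = 0,
                               tol_kJ = 0.01) {
  if (is.character(reaction)) reaction <- qb_reactions(reaction)
  base <- condition_activities(condition)
  g <- function(lg) {
    act <- base
    act[free_species] <- 10^lg
    delta_g(reaction, act, condition$temperature_C)
  }
  glo <- g(lower); ghi <- g(upper)
  if (sign(glo) == sign(ghi)) {
    stop("dGr does not change sign over the bracket [", lower, ", ", upper,
         "]; no threshold", call. = FALSE)
  }
  lo <- lower; hi <- upper
  repeat {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (abs(gm) < tol_kJ) break
    if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    if (hi - lo < 1e-14) break
  }
  list(activity = 10^mid, log10_activity = mid, dG_at_root_kJ = gm)
}

#' Free-energy landscape over a substrate activity sweep
#'
#' Evaluates dGr of a reaction while one species' activity sweeps a log10
#' grid, all other activities fixed by the solution condition.  Reactions
#' not involving the swept species return a constant profile.
#'
#' @param reaction a [reaction_spec()] or name.
#' @param condition a [solution_condition()].
#' @param species swept species (default `"H2"`).
#' @param log10_grid sorted finite grid of log10 activities.
#' @return data frame with columns `log10_activity`, `activity`, `dG_kJ`.
#' @export
energy_landscape <- function(reaction, condition = solution_condition(),
                             species = "H2",
                             log10_grid = seq(-12, 0, by = 0.1)) {
  if (any(!is.finite(log10_grid)) || is.unsorted(log10_grid)) {
    stop("log10_grid must be finite and sorted", call. = FALSE)
  }
  if (is.character(reaction)) reaction <- qb_reactions(reaction)
  base <- condition_activities(condition)
  dg <- vapply(log10_grid, function(lg) {
    act <- base
    act[species] <- 10^lg
    delta_g(reaction, act, condition$temperature_C)
  }, numeric(1))
  data.frame(log10_activity = log10_grid, activity = 10^log10_grid,
             dG_kJ = dg)
}
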