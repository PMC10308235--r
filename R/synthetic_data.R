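# Seeded generators producing tables with the statistical structure the
# pipeline assumes: background-plus-peak H2 depth profiles, two-endmember
# Keeling mixtures contaminated by air H2, D-spiked Fe-H2O batch
# experiments, seawater-contaminated pore-water profiles, sulfide sulfur
# isotope records from microbial sulfate reduction mixed with juvenile
# sulfur, and endpoint dilution series.  A single integer seed drives a
# named substream per generator, so adding a generator never perturbs the
# streams of the existing ones; every generator returns its hidden truth
# alongside the table.

substream_seed <- function(seed, name) {
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 31 + b) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  force(expr)
}

#' Synthetic depth profile of gas concentrations and isotopes
#'
#' Emulates a core gas record: a sub-quantification H2 background (limit
#' 3 uM) with Gaussian-shaped enrichment peaks near fault depths, methane in
#' the 1-20 mM band that drops below 5 mM past the decollement, a methane
#' carbon-isotope drift from -64 to -84 permil with depth at a constant
#' CH4-CO2 fractionation of 0.94, and headspace H2 isotope values drawn from
#' two-endmember mixing between the subsurface source and air H2 (0.5 ppmv,
#' +150 permil).
#'
#' @param seed integer seed.
#' @param n number of sampled depths (default 52).
#' @param peak_centers_mbsf,peak_amplitudes_uM Gaussian peak positions and
#'   heights (defaults: 209 uM at 695 mbsf and 26 uM at 818.5 mbsf).
#' @param peak_width_m Gaussian standard deviation of the peaks (m).
#' @param quantification_limit_uM H2 quantification limit (default 3).
#' @param delta_source_dD deltaD of the subsurface H2 endmember (permil).
#' @return data frame with columns `depth_mbsf`, `unit`, `h2_uM`,
#'   `below_quantification`, `h2_ppmv`, `dD_h2_permil`, `ch4_mM`,
#'   `d13C_ch4_permil`, `d13C_co2_permil`, `dD_ch4_permil`.
#' @export
gen_gas_profile <- function(seed = 1, n = 52,
                            peak_centers_mbsf = c(695, 818.5),
                            peak_amplitudes_uM = c(209, 26),
                            peak_width_m = 2,
                            quantification_limit_uM = 3,
                            delta_source_dD = -850) {
  with_substream(seed, "gas_profile", {
    n_shallow <- 3
    depths <- sort(unique(c(seq(176.5, 185.2, length.out = n_shallow),
                            seq(648, 836.8, length.out = n - n_shallow -
                                  length(peak_centers_mbsf)),
                            peak_centers_mbsf)))
    bg <- pmin(exp(rnorm(length(depths), log(0.4), 0.6)),
               0.97 * quantification_limit_uM)
    peak <- rep(0, length(depths))
    for (i in seq_along(peak_centers_mbsf)) {
      peak <- pmax(peak, peak_amplitudes_uM[i] *
                     exp(-0.5 * ((depths - peak_centers_mbsf[i]) / peak_width_m)^2))
    }
    h2 <- pmax(bg, peak)
    ch4 <- ifelse(depths <= 820.1, runif(length(depths), 1, 20),
                  runif(length(depths), 0.5, 5))
    d13c_ch4 <- approx(x = c(176.5, 754, 837), y = c(-64, -64, -84),
                       xout = depths, rule = 2)$y +
      rnorm(length(depths), 0, 0.3)
    d13c_co2 <- delta_via_alpha(d13c_ch4, 1 / 0.94)
    dd_ch4 <- -200 + rnorm(length(depths), 0, 5) +
      ifelse(depths > 800, (depths - 800) * 0.5, 0)
    # headspace: source-derived H2 on top of the 0.5 ppmv air background
    c_add <- 2 * h2
    mix <- keeling_forward(0.5, 150, c_add, delta_source_dD)
    data.frame(depth_mbsf = depths,
               unit = assign_unit(depths),
               h2_uM = h2,
               below_quantification = h2 < quantification_limit_uM,
               h2_ppmv = mix$mixing_ratio_ppmv,
               dD_h2_permil = mix$dD_h2_permil,
               ch4_mM = ch4,
               d13C_ch4_permil = d13c_ch4,
               d13C_co2_permil = d13c_co2,
               dD_ch4_permil = dd_ch4)
  })
}

#' Synthetic seawater-contaminated pore-water table with hidden truth
#'
#' Each row is a convex combination of a configured indigenous endmember
#' (sulfate-free, as in the prism units) and the seawater reference, with a
#' per-row contamination fraction drawn uniformly from `[0, f_max]`.
#' Optional relative Gaussian noise can be applied to the ion columns; the
#' default is noise-free so that [correct_profile()] recovers the endmember
#' exactly.
#'
#' @param seed integer seed.
#' @param n number of rows (default 12).
#' @param f_max maximum contamination fraction (default 0.4).
#' @param endmember named list/vector of the indigenous composition; any of
#'   `Cl, K, Ca, Mg, Mn, NH4, SO4` (mM) and `dD_H2O`, `d18O_H2O` (permil).
#' @param sigma_rel relative noise on ion concentrations (default 0).
#' @param ref seawater reference, see [seawater_reference()].
#' @return list with `table` (data frame with `depth_mbsf` and composition
#'   columns) and `truth` (list: `endmember`, `f` per row).
#' @export
gen_porewater_table <- function(seed = 1, n = 12, f_max = 0.4,
                                endmember = list(Cl = 559, K = 9.8, Ca = 9.5,
                                                 Mg = 51, Mn = 0.05,
                                                 NH4 = 1.5, SO4 = 0,
                                                 dD_H2O = 2.5,
                                                 d18O_H2O = 0.25),
                                sigma_rel = 0, ref = seawater_reference()) {
  stopifnot(f_max >= 0, f_max <= 1)
  with_substream(seed, "porewater", {
    depths <- sort(c(runif(2, 176.5, 185.2), runif(n - 2, 689, 820)))
    f <- runif(n, 0, f_max)
    sw <- c(ref$ions, dD_H2O = ref$dD_H2O, d18O_H2O = ref$d18O_H2O)
    em <- unlist(endmember)
    cols <- names(em)
    tab <- data.frame(depth_mbsf = depths)
    for (cl in cols) {
      v <- mix_conservative(em[[cl]], f, sw[[cl]])
      if (sigma_rel > 0 && !cl %in% c("dD_H2O", "d18O_H2O")) {
        v <- v * (1 + rnorm(n, 0, sigma_rel))
      }
      tab[[cl]] <- v
    }
    list(table = tab, truth = list(endmember = em, f = f))
  })
}

#' Synthetic Keeling mixture series with hidden truth
#'
#' Forward two-endmember mixtures of a subsurface H2 source over the air
#' background (0.5 ppmv, +150 permil), with Gaussian measurement noise on
#' the observed deltaD.
#'
#' @param seed integer seed.
#' @param n number of samples (default 20).
#' @param delta_source source deltaD (permil, default -850).
#' @param c_background,delta_background air background (ppmv, permil).
#' @param c_added_range range of source-derived mixing ratios (ppmv),
#'   sampled log-uniformly.
#' @param sigma measurement noise on deltaD (permil, default 15).
#' @return list with `table` (columns `mixing_ratio_ppmv`, `dD_h2_permil`)
#'   and `truth` (list: `delta_source`, `c_background`, `delta_background`).
#' @export
gen_keeling_dataset <- function(seed = 1, n = 20, delta_source = -850,
                                c_background = 0.5, delta_background = 150,
                                c_added_range = c(0.5, 200), sigma = 15) {
  stopifnot(n >= 3)
  with_substream(seed, "keeling", {
    c_add <- 10^runif(n, log10(c_added_range[1]), log10(c_added_range[2]))
    tab <- keeling_forward(c_background, delta_background, c_add, delta_source)
    tab$dD_h2_permil <- tab$dD_h2_permil + rnorm(n, 0, sigma)
    list(table = tab,
         truth = list(delta_source = delta_source,
                      c_background = c_background,
                      delta_background = delta_background))
  })
}

#' Synthetic Fe-H2O batch experiments with hidden truth
#'
#' For each temperature, paired (deltaD_H2O, deltaD_H2) observations with
#' water deltaD levels spanning 0 to about +3000 permil (D2O spiking), H2
#' generated at the configured kinetic fractionation factor, and Gaussian
#' noise on the measured deltaD_H2.
#'
#' @param seed integer seed.
#' @param temperatures_C reaction temperatures (default 4, 25, 55 degC).
#' @param alphas kinetic fractionation factors per temperature (defaults
#'   0.13, 0.19, 0.23).
#' @param n_levels water-spike levels per temperature (default 8).
#' @param dD_h2o_max highest spiked water deltaD (permil, default 3000).
#' @param sigma noise on deltaD_H2 (permil, default 10).
#' @return list with `table` (columns `T_C`, `dD_h2o_permil`,
#'   `dD_h2_permil`) and `truth` (named alpha vector).
#' @export
gen_fe_h2o_batches <- function(seed = 1, temperatures_C = c(4, 25, 55),
                               alphas = c(0.13, 0.19, 0.23), n_levels = 8,
                               dD_h2o_max = 3000, sigma = 10) {
  stopifnot(length(temperatures_C) == length(alphas))
  with_substream(seed, "fe_h2o", {
    out <- do.call(rbind, lapply(seq_along(temperatures_C), function(i) {
      dw <- seq(0, dD_h2o_max, length.out = n_levels)
      dh <- delta_via_alpha(dw, alphas[i]) + rnorm(n_levels, 0, sigma)
      data.frame(T_C = temperatures_C[i], dD_h2o_permil = dw,
                 dD_h2_permil = dh)
    }))
    list(table = out,
         truth = stats::setNames(alphas, paste0("T", temperatures_C)))
  })
}

#' Synthetic sulfide sulfur-isotope records with hidden truth
#'
#' Sulfide produced from seawater sulfate by microbial sulfate reduction
#' (per-row eps34 sampled from `eps_range`, fixed mass-law exponent), mixed
#' with juvenile mantle sulfur (0, 0) at a per-row fraction via abundance
#' mass balance.
#'
#' @param seed integer seed.
#' @param n number of records (default 20).
#' @param eps_range range of eps34 values (permil, default 10-68).
#' @param lambda mass-law exponent of the reduction (default 0.514).
#' @param f_range range of juvenile mixing fractions (default 0-1).
#' @param ref seawater reference supplying the sulfate composition.
#' @return list with `table` (columns `sample_id`, `d33S_permil`,
#'   `d34S_permil`, `cap_delta33`, `role`) and `truth` (data frame with
#'   per-row `eps34`, `lambda`, `f_juvenile`).
#' @export
gen_sulfur_records <- function(seed = 1, n = 20, eps_range = c(10, 68),
                               lambda = 0.514, f_range = c(0, 1),
                               ref = seawater_reference()) {
  with_substream(seed, "sulfur", {
    d34_sw <- ref$d34S_SO4
    d33_sw <- ref$D33S_SO4 + ((1 + d34_sw / 1000)^0.515 - 1) * 1000
    eps <- runif(n, eps_range[1], eps_range[2])
    f <- runif(n, f_range[1], f_range[2])
    rows <- t(vapply(seq_len(n), function(i) {
      bio <- msr_forward(d33_sw, d34_sw, eps[i], lambda)
      mx <- sulfur_mixing_curve(bio[c("delta33S", "delta34S")],
                                c(0, 0), f[i])
      c(mx$delta33S, mx$delta34S, mx$cap_delta33)
    }, numeric(3)))
    list(table = data.frame(sample_id = sprintf("syn%02d", seq_len(n)),
                            d33S_permil = rows[, 1],
                            d34S_permil = rows[, 2],
                            cap_delta33 = rows[, 3],
                            role = "sulfide_CRS"),
         truth = data.frame(eps34 = eps, lambda = lambda, f_juvenile = f))
  })
}

#' Synthetic endpoint dilution series with hidden truth
#'
#' Positivity at step k is Poisson presence: the tube is positive when at
#' least one organism entered its inoculum volume, whose expected count is
#' `density * v_inoculum / slurry_dilution / step_factor^k` under the same
#' convention as [endpoint_dilution_density()].
#'
#' @param seed integer seed.
#' @param density true cultivable density (cells per mL sediment, > 0);
#'   vectorised over densities.
#' @param n_steps dilution steps per series (default 8).
#' @param step_factor,v_inoculum_mL,slurry_dilution as in
#'   [endpoint_dilution_density()].
#' @return list with `series` (list of logical vectors) and `truth`
#'   (numeric densities).
#' @export
gen_dilution_series <- function(seed = 1, density = 1e5, n_steps = 8,
                                step_factor = 11, v_inoculum_mL = 0.5,
                                slurry_dilution = 10) {
  stopifnot(all(density >= 0))
  with_substream(seed, "dilution", {
    series <- lapply(density, function(d) {
      lam <- d * v_inoculum_mL / slurry_dilution / step_factor^seq_len(n_steps)
      rpois(n_steps, lam) >= 1
    })
    list(series = series, truth = density)
  })
}
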