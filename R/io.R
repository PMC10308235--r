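# Tabular IO and the end-to-end pipeline.  One TSV dialect everywhere:
# UTF-8, "." decimal, "NA" missing marker, tab separated, so that a
# write-read round trip is lossless and reruns are byte-identical.

#' Read a typed profile table
#'
#' Reads a TSV, checks that all required columns are present (extra columns
#' are preserved), coerces the named numeric columns, and reports parse
#' problems with their line numbers.  `"NA"` cells become missing values.
#'
#' @param path file path.
#' @param required character vector of required column names.
#' @param numeric_cols columns to coerce to numeric (default: the required
#'   ones).
#' @return data frame.
#' @export
read_profile_table <- function(path, required = character(),
                               numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cl in intersect(numeric_cols, names(tab))) {
    raw <- tab[[cl]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' of %s at data line %d: '%s'",
                   cl, basename(path), bad[1], raw[bad[1]]), call. = FALSE)
    }
    tab[[cl]] <- val
  }
  tab
}

#' Write a table in the package's TSV dialect
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Generates every synthetic scenario at the given seed and pushes each
#' through its analysis stage: pore-water contamination correction, methane
#' isotope systematics, Keeling endmember fit, Fe-H2O fractionation-factor
#' fits, sulfur isotope statistics with the juvenile mixing curve, and the
#' free-energy landscapes of the three metabolic reactions.  Each stage
#' writes a TSV into `out_dir` and the run manifest (inputs, seed, file
#' checksums) is written last, so that equal manifests imply equal outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving all generators.
#' @param sum_acetate_mM total acetate for the energetics stage (mM).
#' @param correct_units units for which the pore-water correction applies.
#' @return the manifest data frame, invisibly.
#' @export
run_pipeline <- function(out_dir, seed = 1, sum_acetate_mM = 1,
                         correct_units = c("U1", "U2", "U3", "U4")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message("[quakebiogeo] ", ...)
  files <- character()
  put <- function(x, name) {
    p <- file.path(out_dir, name)
    write_profile_table(x, p)
    files <<- c(files, p)
    p
  }

  log_stage("stage porewater: contamination correction")
  pw <- gen_porewater_table(seed)
  corrected <- correct_profile(pw$table, applicable_units = correct_units)
  put(corrected, "porewater_corrected.tsv")

  log_stage("stage gas: methane isotope systematics")
  gas <- gen_gas_profile(seed)
  gas$alpha13C_ch4_co2 <- alpha_from_deltas(gas$d13C_ch4_permil,
                                            gas$d13C_co2_permil)$alpha
  gas$alphaD_ch4_h2o <- alpha_from_deltas(gas$dD_ch4_permil, 0)$alpha
  put(gas, "gas_systematics.tsv")

  log_stage("stage keeling: H2 endmember regression")
  ke <- gen_keeling_dataset(seed)
  kf <- keeling_fit(ke$table)
  put(data.frame(intercept_delta = kf$intercept_delta, slope = kf$slope,
                 stderr_intercept = kf$stderr_intercept, r2 = kf$r2,
                 n = kf$n, truth_delta_source = ke$truth$delta_source),
      "keeling_fit.tsv")

  log_stage("stage alphafit: Fe-H2O kinetic factors")
  fb <- gen_fe_h2o_batches(seed)
  fits <- do.call(rbind, lapply(split(fb$table, fb$table$T_C), function(d) {
    ff <- fit_alpha_origin(d$dD_h2o_permil, d$dD_h2_permil)
    data.frame(T_C = d$T_C[1], alpha = ff$alpha, stderr = ff$stderr)
  }))
  fits$truth_alpha <- fb$truth[paste0("T", fits$T_C)]
  put(fits, "fe_h2o_alpha.tsv")

  log_stage("stage sulfur: isotope statistics and mixing curve")
  su <- gen_sulfur_records(seed)
  ref <- seawater_reference()
  d34_sw <- ref$d34S_SO4
  d33_sw <- ref$D33S_SO4 + ((1 + d34_sw / 1000)^0.515 - 1) * 1000
  stats_tab <- su$table
  stats_tab$eps34_vs_seawater <- epsilon34(stats_tab$d34S_permil, d34_sw)
  put(stats_tab, "sulfur_statistics.tsv")
  top <- stats_tab[which.max(stats_tab$cap_delta33), ]
  curve <- sulfur_mixing_curve(c(0, 0),
                               c(top$d33S_permil, top$d34S_permil),
                               seq(0, 1, by = 0.05))
  put(curve, "sulfur_mixing_curve.tsv")

  log_stage("stage energetics: free-energy landscapes")
  cond <- solution_condition(sum_acetate_mM = sum_acetate_mM)
  grid <- seq(-12, 0, by = 0.1)
  rx <- qb_reactions()
  land <- do.call(rbind, lapply(names(rx), function(nm) {
    r <- if (nm == "acetate_exchange") reverse_reaction(rx[[nm]]) else rx[[nm]]
    lbl <- if (nm == "acetate_exchange") "acetoclastic_methanogenesis" else nm
    cbind(reaction = lbl, energy_landscape(r, cond, log10_grid = grid))
  }))
  put(land, "energy_landscape.tsv")

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  attr(manifest, "seed") <- seed
  header <- data.frame(file = c("(seed)", "(acetate_mM)"),
                       md5 = c(as.character(seed),
                               as.character(sum_acetate_mM)))
  write_profile_table(rbind(header, manifest),
                      file.path(out_dir, "manifest.tsv"))
  log_stage("done: ", length(files), " stage outputs + manifest")
  invisible(manifest)
}
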