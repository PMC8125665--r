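# CSV/JSON boundary. Files carry the units experimentalists print (wt%,
# hours, percent); everything internal is fractions and minutes. Numeric
# columns are written with 17 significant digits so write -> read round
# trips are exact in double precision.

csv_schema_check <- function(df, required, where) {
  have <- tolower(names(df))
  required_l <- tolower(required)
  missing <- required[!(required_l %in% have)]
  if (length(missing)) {
    extra <- names(df)[!(have %in% required_l)]
    stop(sprintf(
      "%s: missing column(s): %s%s", where,
      paste(missing, collapse = ", "),
      if (length(extra)) paste0("; unrecognized column(s): ",
                                paste(extra, collapse = ", ")) else ""),
      call. = FALSE)
  }
  # return df with canonical names, canonical columns first
  idx <- match(required_l, have)
  rest <- setdiff(seq_along(df), idx)
  out <- df[, c(idx, rest), drop = FALSE]
  names(out) <- c(required, names(df)[rest])
  out
}

write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write fractionation condition tables
#'
#' Conditions CSVs have columns `run_id, temperature_C, fa_wt_percent,
#' time_h` (case-insensitive, any order). FA is in wt% and time in hours on
#' file; the returned object stores fractions and minutes.
#'
#' @param path File path.
#' @return `read_conditions_csv()`: a [fractionation_conditions()] object.
#' @export
read_conditions_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- csv_schema_check(df, c("run_id", "temperature_C", "fa_wt_percent",
                               "time_h"), path)
  fractionation_conditions(temperature = df$temperature_C,
                           fa_wt_percent = df$fa_wt_percent,
                           time_h = df$time_h, run_id = df$run_id)
}

#' @rdname read_conditions_csv
#' @param conditions A [fractionation_conditions()] object.
#' @export
write_conditions_csv <- function(conditions, path) {
  conditions <- as_conditions(conditions)
  write_table_csv(data.frame(
    run_id = conditions$run_id,
    temperature_C = conditions$temperature_C,
    fa_wt_percent = conditions$fa_weight_fraction * 100,
    time_h = conditions$time_min / 60), path)
}

#' Read and write solubilization tables
#'
#' Alpha CSVs have columns `run_id, component, alpha` with alpha as a
#' fraction in \[0, 1\].
#'
#' @param path File path.
#' @return `read_alpha_csv()`: a data frame with those three columns.
#' @export
read_alpha_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  csv_schema_check(df, c("run_id", "component", "alpha"), path)
}

#' @rdname read_alpha_csv
#' @param dataset A [solubilization_dataset()] or a data frame with
#'   `run_id`, `component`, `alpha`.
#' @export
write_alpha_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)[, c("run_id", "component", "alpha")]
  write_table_csv(df, path)
}

#' Read a density table from JSON
#'
#' The JSON maps wt% keys to densities in g/mL, e.g.
#' `{"60": 1.131, "70": 1.153}`.
#'
#' @param path File path; defaults to the packaged formic-acid table.
#' @return An [fa_density_table()].
#' @export
read_density_json <- function(path = system.file("extdata",
                                                 "fa_density.json",
                                                 package = "csfext")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fa_density_table(as.numeric(names(x)), as.numeric(x))
}

#' Read a feedstock composition from JSON
#'
#' @param path File path; defaults to the packaged sugarcane bagasse
#'   composition.
#' @return A [feedstock_composition()].
#' @export
read_feedstock_json <- function(path = system.file(
                                  "extdata", "feedstock_sugarcane_bagasse.json",
                                  package = "csfext")) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(feedstock_composition, as.list(x))
}

#' The packaged 16-run orthogonal fractionation design
#'
#' `load_table2()` returns the published results of the L16 orthogonal
#' design of FA fractionation of sugarcane bagasse as printed: operating
#' conditions, both published severity columns (`A_CSF_ext`, `L_CSF_ext`)
#' and the measured outcomes in percent (solid yield SY, glucan/xylan/lignin
#' contents GC/XC/LC, xylan removal XR, delignification DD, formyl content
#' FC, enzymatic glucan conversion EGC at 6 and 72 h). `load_table3()`
#' returns the two lime-deformylated follow-up solids.
#'
#' @return A data frame (16 rows for `load_table2()`, 2 for
#'   `load_table3()`).
#' @export
load_table2 <- function() {
  path <- system.file("extdata", "table2.csv", package = "csfext")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  csv_schema_check(df, c("run", "temperature_C", "fa_wt_percent", "time_h",
                         "A_CSF_ext", "L_CSF_ext", "SY_pct", "GC_pct",
                         "XC_pct", "LC_pct", "XR_pct", "DD_pct", "FC_pct",
                         "EGC6_pct", "EGC72_pct"), path)
}

#' @rdname load_table2
#' @export
load_table3 <- function() {
  path <- system.file("extdata", "table3.csv", package = "csfext")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname load_table2
#' @return `table2_conditions()`: the 16 operating points as a
#'   [fractionation_conditions()] object.
#' @export
table2_conditions <- function() {
  t2 <- load_table2()
  fractionation_conditions(temperature = t2$temperature_C,
                           fa_wt_percent = t2$fa_wt_percent,
                           time_h = t2$time_h, run_id = t2$run)
}

#' Solubilization datasets from the packaged design
#'
#' Builds per-variant [solubilization_dataset()] objects from the packaged
#' 16-run design, for refitting or demonstration. Xylan and lignin use the
#' printed removal percentages (`source = "printed"`) or the mass-balance
#' derivation from solid yield and contents (`source = "derived"`); the
#' pooled xylan-plus-lignin response is always computed by mass-balance
#' pooling, and total biomass is `1 - SY`.
#'
#' @param source `"printed"` or `"derived"` for the single-component
#'   responses.
#' @param feedstock A [feedstock_composition()].
#' @inheritParams component_initial
#' @return Named list of datasets: `xylan`, `lignin`, `xylan_plus_lignin`,
#'   `total_biomass`.
#' @export
table2_datasets <- function(source = c("printed", "derived"),
                            feedstock = feedstock_composition(),
                            lignin_basis = c("klason", "total"),
                            xylan_basis = c("xylan", "xylan_plus_arabinan")) {
  source <- match.arg(source)
  lignin_basis <- match.arg(lignin_basis)
  xylan_basis <- match.arg(xylan_basis)
  t2 <- load_table2()
  cond <- table2_conditions()
  comp <- data.frame(run_id = t2$run,
                     solid_yield = t2$SY_pct / 100,
                     xylan_content = t2$XC_pct / 100,
                     lignin_content = t2$LC_pct / 100)
  derived <- derive_solubilization(comp, feedstock,
                                   lignin_basis = lignin_basis,
                                   xylan_basis = xylan_basis)
  xylan_alpha <- if (source == "printed") t2$XR_pct / 100 else derived$xylan
  lignin_alpha <- if (source == "printed") t2$DD_pct / 100 else derived$lignin
  list(
    xylan = solubilization_dataset(cond, "xylan", xylan_alpha),
    lignin = solubilization_dataset(cond, "lignin", lignin_alpha),
    xylan_plus_lignin = solubilization_dataset(cond, "xylan_plus_lignin",
                                               derived$xylan_plus_lignin),
    total_biomass = solubilization_dataset(cond, "total_biomass",
                                           derived$total_biomass)
  )
}

#' Recompute the published per-run severity values
#'
#' Recomputes both severity columns of the packaged 16-run design from the
#' operating conditions under given constant presets and density table, and
#' compares them with the printed values. Run 12's printed Arrhenius value
#' (32.28) disagrees with every constant convention by ~11 units and is
#' flagged as an outlier (suspected misprint) rather than counted as a
#' mismatch.
#'
#' @param constants_arrhenius,constants_logistic [severity_constants()] for
#'   the two columns; default the table-consistent presets.
#' @param density_table An [fa_density_table()].
#' @param tol Agreement tolerance (default 0.02, the rounding precision of
#'   the printed values).
#' @return Data frame of class `table2_reproduction` with printed, computed
#'   and delta columns plus logical `match_A`/`match_L` and an `outlier_A`
#'   flag; attribute `n_matched` counts matches among non-outlier entries.
#' @export
reproduce_table2 <- function(constants_arrhenius = csf_presets("arrhenius-table1"),
                             constants_logistic = csf_presets("logistic-table1"),
                             density_table = fa_density_default(),
                             tol = 0.02) {
  t2 <- load_table2()
  cond <- table2_conditions()
  a <- csf_ext_fa(cond, constants_arrhenius, density_table)
  l <- csf_ext_fa(cond, constants_logistic, density_table)
  out <- data.frame(
    run = t2$run,
    printed_A = t2$A_CSF_ext, computed_A = a, delta_A = a - t2$A_CSF_ext,
    printed_L = t2$L_CSF_ext, computed_L = l, delta_L = l - t2$L_CSF_ext)
  out$match_A <- abs(out$delta_A) <= tol
  out$match_L <- abs(out$delta_L) <= tol
  # an entry that is off by orders of magnitude more than rounding is a
  # misprint in the source, not a model mismatch
  out$outlier_A <- abs(out$delta_A) > 50 * tol
  attr(out, "n_matched") <- sum(out$match_A[!out$outlier_A]) + sum(out$match_L)
  attr(out, "n_compared") <- sum(!out$outlier_A) + nrow(out)
  class(out) <- c("table2_reproduction", "data.frame")
  out
}

#' @export
print.table2_reproduction <- function(x, ...) {
  cat(sprintf(
    "Severity reproduction: %d/%d printed values within tolerance;%s\n",
    attr(x, "n_matched"), attr(x, "n_compared"),
    if (any(x$outlier_A)) sprintf(
      " run(s) %s flagged as Arrhenius-column outliers (suspected misprint)",
      paste(x$run[x$outlier_A], collapse = ", ")) else " no outliers"))
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Run the full simulation-fit-reproduction pipeline
#'
#' End-to-end orchestration: generates a seeded synthetic dataset, inverts
#' it into a composition table, rebuilds the four data-processing variants
#' (single components, mass-balance pooled xylan-plus-lignin, total
#' biomass), fits every variant under both model families, and recomputes
#' the packaged design's severity values. When `out_dir` is given, writes
#' `conditions.csv`, `alpha.csv`, `composition.csv`, `fits.json`,
#' `reproduction.csv` and `log.json` (the log records seed, presets,
#' density table, clipping epsilon and bases, enough to re-run
#' bit-identically).
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param clip_eps Clipping margin for the transforms.
#' @return Invisibly, a list with `dataset`, `composition`, `fits` (per
#'   family), `reproduction` and `log`.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         clip_eps = 1e-4) {
  dataset <- simulate_alpha(config)
  composition <- simulate_composition_table(dataset, config)
  derived <- derive_solubilization(composition, config$feedstock)
  cond <- generate_design(config)
  datasets <- list()
  for (comp in intersect(c("xylan", "lignin"), names(derived))) {
    datasets[[comp]] <- solubilization_dataset(
      cond, comp, derived[[comp]], config$density_table)
  }
  if ("xylan_plus_lignin" %in% names(derived)) {
    datasets$xylan_plus_lignin <- solubilization_dataset(
      cond, "xylan_plus_lignin", derived$xylan_plus_lignin,
      config$density_table)
  }
  datasets$total_biomass <- solubilization_dataset(
    cond, "total_biomass", derived$total_biomass, config$density_table)
  fits <- lapply(c(arrhenius = "arrhenius", logistic = "logistic"),
                 function(fam) {
                   suppressWarnings(fit_all_variants(datasets, family = fam,
                                                     clip_eps = clip_eps))
                 })
  reproduction <- reproduce_table2(density_table = config$density_table)
  log <- list(
    seed = config$seed,
    noise_sigma = config$noise_sigma,
    noise_scale = config$noise_scale,
    clip_eps = clip_eps,
    severity_presets = c("arrhenius-table1", "logistic-table1"),
    density_table = stats::setNames(config$density_table$density_g_per_ml,
                                    config$density_table$wt_percent),
    lignin_basis = "klason", xylan_basis = "xylan",
    grids = list(temperature_C = config$t_grid, fa_wt_percent = config$fa_grid,
                 time_h = config$time_grid))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_conditions_csv(cond, file.path(out_dir, "conditions.csv"))
    write_alpha_csv(dataset, file.path(out_dir, "alpha.csv"))
    write_table_csv(as.data.frame(composition),
                    file.path(out_dir, "composition.csv"))
    write_table_csv(as.data.frame(reproduction)[
      , c("run", "printed_A", "computed_A", "delta_A",
          "printed_L", "computed_L", "delta_L")],
      file.path(out_dir, "reproduction.csv"))
    fit_json <- lapply(fits, function(f) f$summary)
    jsonlite::write_json(fit_json, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(dataset = dataset, composition = composition, fits = fits,
                 reproduction = reproduction, log = log))
}
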