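#' Default ground truth for the synthetic-data generator
#'
#' Per-component generating parameters on the Arrhenius transform: xylan and
#' lignin use the published single-component fits; glucan uses a shallow
#' monotone curve (slope 0.03, intercept -2.8 with the pooled-fit severity
#' constants), a deliberate simplification of its small, noisy and weakly
#' non-monotone solubilization.
#'
#' @return Named list, one entry per component, each with elements
#'   `constants` and `model`.
#' @export
default_truth <- function() {
  list(
    xylan = solubilization_presets("arrhenius", "xylan"),
    lignin = solubilization_presets("arrhenius", "lignin"),
    glucan = list(
      constants = csf_presets("arrhenius-table1"),
      model = solubilization_model("arrhenius", slope = 0.03,
                                   intercept = -2.8)
    )
  )
}

#' Configuration of a synthetic fractionation study
#'
#' Defines the factorial operating grid, the per-component generating
#' parameters, the noise model and the seed of a simulated fractionation
#' dataset. Default grids mirror the experimental design space of FA
#' fractionation of bagasse: T in \{80, 90, 99, 105\} degC, FA in
#' \{60, 70, 80, 90\} wt%, t in \{0.25, 0.5, 1, 1.5\} h.
#'
#' @param t_grid Temperature levels, degrees C (>= 2 levels).
#' @param fa_grid FA concentration levels, wt% (>= 2 levels; every level
#'   must have a density entry).
#' @param time_grid Time levels, hours (>= 2 levels).
#' @param truth Named list of per-component ground truth, each entry a list
#'   with `constants` ([severity_constants()]) and `model`
#'   ([solubilization_model()]); see [default_truth()].
#' @param noise_sigma Noise standard deviation (>= 0).
#' @param noise_scale `"transformed"` (Gaussian noise on the linearized
#'   response, the error model the regression assumes) or `"alpha"`
#'   (additive noise on the fraction scale, clamped to \[0, 1\]).
#' @param seed Integer seed; a fixed seed makes every generated artifact
#'   reproducible byte for byte.
#' @param density_table Density table for wt% to mol/L conversion.
#' @param feedstock [feedstock_composition()] used when inverting the mass
#'   balance into composition tables.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(t_grid = c(80, 90, 99, 105),
                              fa_grid = c(60, 70, 80, 90),
                              time_grid = c(0.25, 0.5, 1, 1.5),
                              truth = default_truth(),
                              noise_sigma = 0.15,
                              noise_scale = c("transformed", "alpha"),
                              seed = 1L,
                              density_table = fa_density_default(),
                              feedstock = feedstock_composition()) {
  noise_scale <- match.arg(noise_scale)
  for (g in list(t_grid, fa_grid, time_grid)) {
    if (length(g) < 2L || anyDuplicated(g)) {
      stop("each factor grid needs at least two distinct levels",
           call. = FALSE)
    }
  }
  if (!is.numeric(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  if (is.null(names(truth)) || !all(nzchar(names(truth)))) {
    stop("truth must be a named list of per-component parameters",
         call. = FALSE)
  }
  for (comp in names(truth)) {
    tr <- truth[[comp]]
    if (!inherits(tr$constants, "severity_constants") ||
        !inherits(tr$model, "solubilization_model")) {
      stop(sprintf(
        "truth entry '%s' must have severity_constants and a solubilization_model",
        comp), call. = FALSE)
    }
  }
  structure(list(t_grid = sort(t_grid), fa_grid = sort(fa_grid),
                 time_grid = sort(time_grid), truth = truth,
                 noise_sigma = noise_sigma, noise_scale = noise_scale,
                 seed = as.integer(seed), density_table = density_table,
                 feedstock = feedstock),
            class = "simulation_config")
}

#' Full-factorial fractionation design from a simulation config
#'
#' Cartesian product of the three factor grids with deterministic row order:
#' sorted by temperature, then FA concentration, then time, all ascending
#' (time varies fastest).
#'
#' @param config A [simulation_config()].
#' @return A [fractionation_conditions()] object with
#'   `length(t_grid) * length(fa_grid) * length(time_grid)` rows.
#' @export
generate_design <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- expand.grid(time_h = config$time_grid, fa_wt_percent = config$fa_grid,
                   temperature = config$t_grid, KEEP.OUT.ATTRS = FALSE)
  fractionation_conditions(temperature = g$temperature,
                           fa_wt_percent = g$fa_wt_percent,
                           time_h = g$time_h)
}

#' Simulate solubilization observations
#'
#' For each condition and component, computes the true severity ordinate
#' under the component's generating constants, adds Gaussian noise on the
#' configured scale, and back-transforms to a degree of solubilization.
#' On the transformed scale the generated alpha always lies strictly inside
#' (0, 1); on the alpha scale, values are clamped to \[0, 1\].
#'
#' @param config A [simulation_config()].
#' @param conditions Optional [fractionation_conditions()]; defaults to
#'   [generate_design()] of the config.
#' @return A [solubilization_dataset()] stacking all components, with the
#'   generating config attached as attribute `config`.
#' @export
simulate_alpha <- function(config, conditions = generate_design(config)) {
  stopifnot(inherits(config, "simulation_config"))
  conditions <- as_conditions(conditions)
  set.seed(config$seed)
  parts <- lapply(names(config$truth), function(comp) {
    tr <- config$truth[[comp]]
    x <- csf_ext_fa(conditions, tr$constants, config$density_table)
    if (config$noise_scale == "transformed") {
      y <- tr$model$slope * x + tr$model$intercept +
        rnorm(length(x), 0, config$noise_sigma)
      alpha <- inverse_transform(tr$model$family, y)
    } else {
      alpha <- predict_alpha(tr$model, x) +
        rnorm(length(x), 0, config$noise_sigma)
      alpha <- pmin(pmax(alpha, 0), 1)
    }
    data.frame(as.data.frame(conditions), component = comp, alpha = alpha,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  out <- solubilization_dataset(
    fractionation_conditions(
      temperature = all$temperature_C,
      fa_wt_percent = all$fa_weight_fraction * 100,
      time_h = all$time_min / 60,
      run_id = all$run_id),
    component = all$component, alpha = all$alpha,
    density_table = config$density_table)
  attr(out, "config") <- config
  out
}

#' Invert simulated solubilization into a composition table
#'
#' Constructs per-run solid yield and solid-phase contents consistent with
#' the simulated degrees of solubilization, so that pushing the table back
#' through the mass-balance relations recovers each alpha exactly:
#' \deqn{SY = 1 - \sum_c \alpha_c c_0, \qquad
#'   c = (1 - \alpha_c) c_0 / SY.}
#' Only the modeled components (those present in the dataset among glucan,
#' xylan, lignin) enter the balance; the remaining feedstock mass is treated
#' as insoluble.
#'
#' @param dataset A [solubilization_dataset()] containing glucan, xylan and
#'   lignin rows per run (as produced by [simulate_alpha()] with the default
#'   truth).
#' @param config The [simulation_config()] (for the feedstock); defaults to
#'   the config attached to `dataset`.
#' @return Data frame of class `composition_table` with columns `run_id`,
#'   `solid_yield` and `<component>_content`.
#' @export
simulate_composition_table <- function(dataset,
                                       config = attr(dataset, "config")) {
  stopifnot(inherits(dataset, "solubilization_dataset"))
  if (is.null(config)) {
    stop("no simulation config available; pass `config`", call. = FALSE)
  }
  feed <- config$feedstock
  comps <- intersect(c("glucan", "xylan", "lignin"),
                     unique(dataset$component))
  if (length(comps) == 0L) {
    stop("dataset contains none of glucan/xylan/lignin", call. = FALSE)
  }
  c0 <- vapply(comps, function(comp) {
    component_initial(feed, comp)
  }, numeric(1))
  wide <- stats::reshape(
    as.data.frame(dataset)[, c("run_id", "component", "alpha")],
    direction = "wide", idvar = "run_id", timevar = "component")
  alpha_mat <- as.matrix(wide[, paste0("alpha.", comps), drop = FALSE])
  if (anyNA(alpha_mat)) {
    stop("every run needs an alpha for each of: ",
         paste(comps, collapse = ", "), call. = FALSE)
  }
  sy <- 1 - as.numeric(alpha_mat %*% c0)
  if (any(sy <= 0)) {
    stop("inconsistent alphas: implied solid yield <= 0", call. = FALSE)
  }
  contents <- sweep(1 - alpha_mat, 2, c0, `*`) / sy
  out <- data.frame(run_id = wide$run_id, solid_yield = sy)
  for (j in seq_along(comps)) {
    out[[paste0(comps[j], "_content")]] <- contents[, j]
  }
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Calibrate the noise level to a target goodness of fit
#'
#' Fixes the noise realization under the config's seed and scales its
#' standard deviation by root-finding until the linearized fit of the
#' simulated dataset reaches a target transformed-scale R^2. Used to study
#' diagnostic behavior at a prescribed fit quality when the raw data behind
#' a published fit are unavailable.
#'
#' @param config A [simulation_config()]; its `truth` entry named by
#'   `component` provides the generating curve.
#' @param target_r2 Target transformed-scale R^2, in (0, 1).
#' @param component Which truth component to simulate (default the first).
#' @param interval Search interval for sigma.
#' @return List with elements `sigma`, `dataset` (the calibrated
#'   [solubilization_dataset()]), `fit` (its [fit_linearized()] result) and
#'   `r_squared`.
#' @export
calibrate_noise <- function(config, target_r2,
                            component = names(config$truth)[1L],
                            interval = c(1e-4, 2)) {
  stopifnot(inherits(config, "simulation_config"),
            target_r2 > 0, target_r2 < 1)
  tr <- config$truth[[component]]
  if (is.null(tr)) stop("no truth entry for component ", component,
                        call. = FALSE)
  conditions <- generate_design(config)
  x <- csf_ext_fa(conditions, tr$constants, config$density_table)
  y0 <- tr$model$slope * x + tr$model$intercept
  set.seed(config$seed)
  z <- rnorm(length(x))
  make_dataset <- function(sigma) {
    solubilization_dataset(
      conditions, component = component,
      alpha = inverse_transform(tr$model$family, y0 + sigma * z),
      density_table = config$density_table)
  }
  r2_at <- function(sigma) {
    # transient clipping at extreme trial sigmas is part of the search,
    # not a user-facing condition
    suppressWarnings(
      fit_linearized(make_dataset(sigma), family = tr$model$family,
                     t_ref = tr$constants$t_ref)$r_squared)
  }
  root <- uniroot(function(s) r2_at(s) - target_r2, interval = interval,
                  tol = 1e-10)
  ds <- make_dataset(root$root)
  fit <- fit_linearized(ds, family = tr$model$family,
                        t_ref = tr$constants$t_ref)
  list(sigma = root$root, dataset = ds, fit = fit,
       r_squared = fit$r_squared)
}
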