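#' Assemble a solubilization dataset for fitting
#'
#' Bundles fractionation conditions with observed degrees of solubilization
#' of one (or more) biomass components into the tidy table the fitting
#' routines consume. Identifiability requires variation in every operating
#' factor: at least two distinct levels each of temperature, FA
#' concentration and time.
#'
#' @param conditions A [fractionation_conditions()] object, one row per
#'   observation (repeat rows for multiple components).
#' @param component Component label(s): `"xylan"`, `"lignin"`,
#'   `"xylan_plus_lignin"`, `"glucan"` or `"total_biomass"`.
#' @param alpha Observed degrees of solubilization, each in \[0, 1\].
#' @param density_table Density table used for wt% to mol/L conversion
#'   during fitting.
#' @return A data frame of class `solubilization_dataset`.
#' @export
solubilization_dataset <- function(conditions, component, alpha,
                                   density_table = fa_density_default()) {
  conditions <- as_conditions(conditions)
  n <- nrow(conditions)
  component <- rep_len(as.character(component), n)
  alpha <- rep_len(as.numeric(alpha), n)
  valid_components <- c("xylan", "lignin", "xylan_plus_lignin", "glucan",
                        "total_biomass")
  if (!all(component %in% valid_components)) {
    stop("component must be one of: ",
         paste(valid_components, collapse = ", "), call. = FALSE)
  }
  if (n < 5L) {
    stop("a solubilization dataset needs at least 5 observations",
         call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha < 0 | alpha > 1)) {
    stop("alpha must lie in [0, 1]", call. = FALSE)
  }
  for (f in c("temperature_C", "fa_weight_fraction", "time_min")) {
    if (length(unique(conditions[[f]])) < 2L) {
      stop(sprintf(
        "factor '%s' has a single level; severity constants are not identifiable",
        f), call. = FALSE)
    }
  }
  out <- cbind(as.data.frame(conditions),
               data.frame(component = component, alpha = alpha,
                          stringsAsFactors = FALSE))
  attr(out, "density_table") <- density_table
  class(out) <- c("solubilization_dataset", "data.frame")
  out
}

dataset_density_table <- function(dataset) {
  dt <- attr(dataset, "density_table")
  if (is.null(dt)) fa_density_default() else dt
}

#' Build the linearized design for joint severity-constant fitting
#'
#' Substituting the severity definition into the linear transformed-scale
#' relation gives
#' \deqn{y = \beta_0 + \beta_1 (T - T_{ref}) + \beta_2 \ln C_{FA}
#'   + \beta_3 \ln t}
#' with \eqn{y} the transformed solubilization, so severity constants and
#' model parameters can be estimated in a single ordinary least-squares fit
#' and recovered as \eqn{\omega = \beta_3/\beta_1}, \eqn{m = \beta_2/\beta_3},
#' slope \eqn{= \beta_3}, intercept \eqn{= \beta_0}.
#'
#' @param dataset A [solubilization_dataset()].
#' @param family Model family, determining the transform of `alpha`.
#' @param t_ref Reference temperature, degrees C.
#' @param clip_eps,clip_action Clipping policy applied to `alpha` before
#'   transformation; see [clip_alpha()].
#' @return A list with the response `y`, the 3-column predictor matrix `X`
#'   (`delta_T`, `ln_C`, `ln_t`) and `n`.
#' @export
build_design <- function(dataset, family = c("arrhenius", "logistic"),
                         t_ref = 70, clip_eps = 1e-4,
                         clip_action = c("clip", "drop")) {
  family <- match.arg(family)
  clip_action <- match.arg(clip_action)
  stopifnot(inherits(dataset, "solubilization_dataset"))
  alpha <- clip_alpha(dataset$alpha, eps = clip_eps, action = clip_action)
  keep <- seq_len(nrow(dataset))
  if (clip_action == "drop") keep <- setdiff(keep, attr(alpha, "dropped"))
  d <- dataset[keep, , drop = FALSE]
  y <- transform_alpha(family, as.numeric(alpha))
  c_fa <- wtpct_to_molarity(d$fa_weight_fraction, dataset_density_table(dataset))
  X <- cbind(delta_T = d$temperature_C - t_ref,
             ln_C = log(c_fa),
             ln_t = log(d$time_min))
  check_design_rank(X)
  list(y = y, X = X, n = length(y))
}

check_design_rank <- function(X) {
  full <- cbind(intercept = 1, X)
  if (qr(full)$rank < ncol(full)) {
    sds <- apply(X, 2, sd)
    constant <- colnames(X)[sds < 1e-12]
    msg <- if (length(constant)) {
      sprintf("constant predictor column(s): %s",
              paste(constant, collapse = ", "))
    } else {
      collinear <- character(0)
      for (j in seq_len(ncol(X))) {
        if (qr(cbind(1, X[, -j, drop = FALSE]))$rank ==
            qr(full)$rank) collinear <- c(collinear, colnames(X)[j])
      }
      sprintf("collinear predictor column(s): %s",
              paste(collinear, collapse = ", "))
    }
    stop("design matrix is rank deficient; severity constants are not ",
         "identifiable (", msg, ")", call. = FALSE)
  }
  invisible(X)
}

#' Jointly fit severity constants and model parameters by linearized OLS
#'
#' Fits the transformed solubilization response against
#' `(T - T_ref, ln C_FA, ln t)` by ordinary least squares and extracts the
#' severity constants and model parameters from the regression coefficients
#' (see [build_design()]). Diagnostics are computed on the transformed
#' (linear) scale, where the regression is performed; an alpha-scale R^2 is
#' reported alongside for transparency.
#'
#' @inheritParams build_design
#' @param variant Optional label recorded in the result (e.g. which
#'   component's data were fitted).
#' @return An object of class `csf_fit`: severity `constants`, the fitted
#'   `model`, raw `coefficients` (beta0..beta3), `r_squared` (transformed
#'   scale), `r_squared_alpha`, `f_statistic`, `p_value`, `n`, `residuals`.
#' @examples
#' cfg <- simulation_config(noise_sigma = 0)
#' ds <- simulate_alpha(cfg)
#' fit <- fit_linearized(ds[ds$component == "xylan", ], "arrhenius")
#' fit
#' @export
fit_linearized <- function(dataset, family = c("arrhenius", "logistic"),
                           t_ref = 70, clip_eps = 1e-4,
                           clip_action = c("clip", "drop"),
                           variant = NULL) {
  family <- match.arg(family)
  clip_action <- match.arg(clip_action)
  if (inherits(dataset, "solubilization_dataset") &&
      is.null(variant) && length(unique(dataset$component)) == 1L) {
    variant <- dataset$component[1L]
  }
  d <- build_design(dataset, family, t_ref, clip_eps, clip_action)
  df <- data.frame(y = d$y, d$X)
  ols <- lm(y ~ delta_T + ln_C + ln_t, data = df)
  beta <- coef(ols)
  names(beta) <- c("beta0", "beta1_delta_T", "beta2_ln_C", "beta3_ln_t")
  if (abs(beta[["beta1_delta_T"]]) < 1e-10) {
    stop("temperature coefficient is numerically zero; omega is undefined",
         call. = FALSE)
  }
  if (abs(beta[["beta3_ln_t"]]) < 1e-10) {
    stop("time coefficient is numerically zero; m and the model slope are ",
         "undefined", call. = FALSE)
  }
  omega <- beta[["beta3_ln_t"]] / beta[["beta1_delta_T"]]
  m <- beta[["beta2_ln_C"]] / beta[["beta3_ln_t"]]
  slope <- beta[["beta3_ln_t"]]
  intercept <- beta[["beta0"]]
  n <- d$n
  k <- 3L
  # R^2 from the residuals directly (summary.lm warns on perfect fits)
  r2 <- 1 - sum(stats::residuals(ols)^2) / sum((d$y - mean(d$y))^2)
  f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1L))
  p_val <- pf(f_stat, k, n - k - 1L, lower.tail = FALSE)
  model <- solubilization_model(family, slope, intercept)
  constants <- new_severity_constants(omega, m, t_ref = t_ref)
  # alpha-scale R^2 of the back-transformed predictions
  alpha_hat <- predict_alpha(model, csf_ext_fa(
    structure(dataset, class = c("fractionation_conditions", "data.frame")),
    constants, dataset_density_table(dataset)))
  alpha_obs <- dataset$alpha
  r2_alpha <- 1 - sum((alpha_obs - alpha_hat)^2) /
    sum((alpha_obs - mean(alpha_obs))^2)
  structure(list(
    family = family, variant = variant, t_ref = t_ref,
    constants = constants, model = model,
    coefficients = beta,
    r_squared = r2, r_squared_alpha = r2_alpha,
    f_statistic = f_stat, p_value = p_val,
    n = n, df_residual = n - k - 1L,
    residuals = unname(stats::residuals(ols)),
    method = "linearized-ols"
  ), class = "csf_fit")
}

#' @export
print.csf_fit <- function(x, ...) {
  lab <- if (x$family == "arrhenius") c("a", "b") else c("q", "c")
  cat(sprintf("Joint severity fit (%s)%s\n", x$method,
              if (!is.null(x$variant)) paste0(" - variant: ", x$variant) else ""))
  cat(sprintf("  family: %s   n = %d   T_ref = %g degC\n",
              x$family, x$n, x$t_ref))
  cat(sprintf("  omega = %.4f degC   m = %.4f   %s = %.4f   %s = %.4f\n",
              x$constants$omega, x$constants$m,
              lab[1], x$model$slope, lab[2], x$model$intercept))
  cat(sprintf(
    "  R2 = %.4f (transformed)   R2 = %.4f (alpha)   F = %.2f   p = %.3g\n",
    x$r_squared, x$r_squared_alpha, x$f_statistic, x$p_value))
  invisible(x)
}

#' @export
coef.csf_fit <- function(object, ...) {
  c(omega = object$constants$omega, m = object$constants$m,
    slope = object$model$slope, intercept = object$model$intercept)
}

#' Fit every data-processing variant and rank by goodness of fit
#'
#' Runs [fit_linearized()] on each dataset in a named list (one per
#' data-processing variant, e.g. xylan, lignin, pooled xylan-plus-lignin,
#' total biomass) and returns the fits plus a summary table ranked by
#' transformed-scale R^2, the criterion by which the pooled variant is
#' conventionally preferred. A variant whose fit fails is reported in the
#' summary with its error message, not raised.
#'
#' @param datasets Named list of [solubilization_dataset()] objects.
#' @param family Model family (a single one).
#' @param ... Passed to [fit_linearized()].
#' @return A list of class `csf_fit_comparison` with elements `fits` (named
#'   list; failed variants are `NULL`) and `summary` (data frame ranked by
#'   descending R^2).
#' @export
fit_all_variants <- function(datasets, family = c("arrhenius", "logistic"),
                             ...) {
  family <- match.arg(family)
  stopifnot(is.list(datasets), length(datasets) >= 1L,
            !is.null(names(datasets)), all(nzchar(names(datasets))))
  fits <- vector("list", length(datasets))
  names(fits) <- names(datasets)
  rows <- lapply(names(datasets), function(v) {
    res <- tryCatch(
      fit_linearized(datasets[[v]], family = family, variant = v, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(variant = v, family = family, omega = NA_real_,
                 m = NA_real_, slope = NA_real_, intercept = NA_real_,
                 r_squared = NA_real_, f_statistic = NA_real_,
                 p_value = NA_real_, n = NA_integer_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      fits[[v]] <<- res
      data.frame(variant = v, family = family,
                 omega = res$constants$omega, m = res$constants$m,
                 slope = res$model$slope, intercept = res$model$intercept,
                 r_squared = res$r_squared, f_statistic = res$f_statistic,
                 p_value = res$p_value, n = res$n,
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  })
  summary <- do.call(rbind, rows)
  summary <- summary[order(-xtfrm(summary$r_squared), summary$variant), ,
                     drop = FALSE]
  rownames(summary) <- NULL
  structure(list(fits = fits, summary = summary),
            class = "csf_fit_comparison")
}

#' @export
print.csf_fit_comparison <- function(x, ...) {
  cat("Severity fits by data-processing variant (ranked by R2):\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Direct nonlinear least-squares oracle
#'
#' Independently re-estimates `(omega, m, slope, intercept)` by nonlinear
#' least squares of the *untransformed* `alpha` against the model curve,
#' via Levenberg-Marquardt ([minpack.lm::nlsLM()]). On noiseless data this
#' agrees with [fit_linearized()] to high precision; on noisy data the two
#' estimators weight observations differently and are reported side by side,
#' making this a cross-check rather than a replacement.
#'
#' @inheritParams fit_linearized
#' @param init Initial values: a `csf_fit` or a named list/vector with
#'   `omega`, `m`, `slope`, `intercept`.
#' @return A `csf_fit` with `method = "nls"` (diagnostics computed on the
#'   transformed scale for comparability).
#' @export
nls_oracle <- function(dataset, family = c("arrhenius", "logistic"),
                       t_ref = 70, init, clip_eps = 1e-4) {
  family <- match.arg(family)
  stopifnot(inherits(dataset, "solubilization_dataset"))
  if (inherits(init, "csf_fit")) init <- as.list(coef(init))
  init <- init[c("omega", "m", "slope", "intercept")]
  if (anyNA(init)) stop("init must provide omega, m, slope, intercept",
                        call. = FALSE)
  c_fa <- wtpct_to_molarity(dataset$fa_weight_fraction,
                            dataset_density_table(dataset))
  df <- data.frame(alpha = dataset$alpha,
                   delta_T = dataset$temperature_C - t_ref,
                   ln_C = log(c_fa),
                   ln_t = log(dataset$time_min))
  inv <- function(y) inverse_transform(family, y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      alpha ~ inv(slope * (delta_T / omega + m * ln_C + ln_t) + intercept),
      data = df, start = init,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) {
      stop("nonlinear least squares did not converge: ",
           conditionMessage(e), call. = FALSE)
    })
  est <- coef(fit)
  model <- solubilization_model(family, est[["slope"]], est[["intercept"]])
  constants <- new_severity_constants(est[["omega"]], est[["m"]],
                                      t_ref = t_ref)
  # transformed-scale diagnostics, for comparability with the linearized fit
  alpha_clip <- suppressWarnings(clip_alpha(dataset$alpha, eps = clip_eps))
  y <- transform_alpha(family, alpha_clip)
  yhat <- model$slope * (df$delta_T / constants$omega +
                           constants$m * df$ln_C + df$ln_t) + model$intercept
  n <- length(y); k <- 3L
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  f_stat <- (r2 / k) / ((1 - r2) / (n - k - 1L))
  alpha_hat <- predict(fit)
  r2_alpha <- 1 - sum((df$alpha - alpha_hat)^2) /
    sum((df$alpha - mean(df$alpha))^2)
  structure(list(
    family = family,
    variant = if (length(unique(dataset$component)) == 1L)
      dataset$component[1L] else NULL,
    t_ref = t_ref, constants = constants, model = model,
    coefficients = c(beta0 = est[["intercept"]],
                     beta1_delta_T = est[["slope"]] / est[["omega"]],
                     beta2_ln_C = est[["slope"]] * est[["m"]],
                     beta3_ln_t = est[["slope"]]),
    r_squared = r2, r_squared_alpha = r2_alpha,
    f_statistic = f_stat,
    p_value = pf(f_stat, k, n - k - 1L, lower.tail = FALSE),
    n = n, df_residual = n - k - 1L,
    residuals = unname(y - yhat),
    convergence = fit$convInfo,
    method = "nls"
  ), class = "csf_fit")
}
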