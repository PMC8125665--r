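#' Feedstock composition of the raw biomass
#'
#' Initial mass fractions of the polymeric components of the untreated
#' feedstock, on a dry-matter basis. Defaults are the measured composition of
#' the sugarcane bagasse the packaged design was run on (glucan 43.4%, xylan
#' 24.4%, arabinan 1.2%, acetyl 2.51%, Klason lignin 24.2%, acid-soluble
#' lignin 2.88%).
#'
#' @param glucan,xylan,arabinan,acetyl,klason_lignin,acid_soluble_lignin
#'   Mass fractions in \[0, 1\].
#' @return A list of class `feedstock_composition`.
#' @export
feedstock_composition <- function(glucan = 0.434, xylan = 0.244,
                                  arabinan = 0.012, acetyl = 0.0251,
                                  klason_lignin = 0.242,
                                  acid_soluble_lignin = 0.0288) {
  x <- list(glucan = glucan, xylan = xylan, arabinan = arabinan,
            acetyl = acetyl, klason_lignin = klason_lignin,
            acid_soluble_lignin = acid_soluble_lignin)
  vals <- unlist(x)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1)) {
    stop("feedstock fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(vals) > 1 + 1e-9) {
    stop("feedstock fractions sum to more than 1", call. = FALSE)
  }
  structure(x, class = "feedstock_composition")
}

#' Initial mass fraction of a component under a basis convention
#'
#' The xylan basis controls whether arabinan is counted with xylan; the
#' lignin basis whether acid-soluble lignin is counted with Klason lignin.
#' Defaults (xylan only, Klason only) are the conventions that best track
#' the removal percentages printed alongside the packaged design.
#'
#' @param feedstock A [feedstock_composition()].
#' @param component `"glucan"`, `"xylan"`, `"lignin"` or
#'   `"xylan_plus_lignin"`.
#' @param lignin_basis `"klason"` (default) or `"total"` (Klason +
#'   acid-soluble).
#' @param xylan_basis `"xylan"` (default) or `"xylan_plus_arabinan"`.
#' @return Initial mass fraction.
#' @export
component_initial <- function(feedstock, component,
                              lignin_basis = c("klason", "total"),
                              xylan_basis = c("xylan", "xylan_plus_arabinan")) {
  stopifnot(inherits(feedstock, "feedstock_composition"))
  lignin_basis <- match.arg(lignin_basis)
  xylan_basis <- match.arg(xylan_basis)
  x0 <- feedstock$xylan +
    if (xylan_basis == "xylan_plus_arabinan") feedstock$arabinan else 0
  l0 <- feedstock$klason_lignin +
    if (lignin_basis == "total") feedstock$acid_soluble_lignin else 0
  switch(component,
         glucan = feedstock$glucan,
         xylan = x0,
         lignin = l0,
         xylan_plus_lignin = x0 + l0,
         stop("unknown component: ", component, call. = FALSE))
}

#' Degree of solubilization of one component from composition data
#'
#' The degree of solubilization is the mass of the component transferred to
#' the liquid phase relative to its initial mass:
#' \deqn{\alpha = 1 - SY \cdot c / c_0}
#' with `SY` the solid yield (fraction of dry matter retained), `c` the
#' component's content in the pretreated solid and `c0` its initial content
#' in the feedstock. Small excursions outside \[0, 1\] from measurement
#' noise are clamped; excursions beyond `tol` trigger a warning.
#'
#' @param solid_yield Fraction of initial dry mass retained, in (0, 1\].
#' @param content Component mass fraction of the pretreated solid, \[0, 1\].
#' @param initial_fraction Component mass fraction of the feedstock, > 0.
#' @param tol Clamp-warning threshold (default 0.02).
#' @return Degree of solubilization in \[0, 1\].
#' @examples
#' component_solubilization(0.687, 0.2116, 0.242) # delignification, ~0.399
#' @export
component_solubilization <- function(solid_yield, content, initial_fraction,
                                     tol = 0.02) {
  if (any(!is.finite(initial_fraction)) || any(initial_fraction <= 0)) {
    stop("initial_fraction must be > 0", call. = FALSE)
  }
  if (any(!is.finite(solid_yield)) ||
      any(solid_yield <= 0 | solid_yield > 1)) {
    stop("solid_yield must lie in (0, 1]", call. = FALSE)
  }
  if (any(!is.finite(content)) || any(content < 0 | content > 1)) {
    stop("content must lie in [0, 1]", call. = FALSE)
  }
  alpha <- 1 - solid_yield * content / initial_fraction
  excess <- pmax(alpha - 1, -alpha, 0)
  if (any(excess > tol)) {
    warning(sprintf(
      "%d solubilization value(s) outside [0, 1] by more than %g; clamped",
      sum(excess > tol), tol), call. = FALSE)
  }
  pmin(pmax(alpha, 0), 1)
}

#' Pooled xylan-plus-lignin solubilization
#'
#' Treats xylan and lignin together as one pseudo-soluble fraction:
#' \deqn{\alpha_{pool} = 1 - SY (XC + LC) / (X_0 + L_0)}
#' This pooled response is the preferred fitting variant for FA
#' fractionation, where both components are removed substantially.
#'
#' @inheritParams component_solubilization
#' @param xylan_content,lignin_content Mass fractions of the pretreated
#'   solid.
#' @param feedstock A [feedstock_composition()].
#' @inheritParams component_initial
#' @return Pooled degree of solubilization in \[0, 1\].
#' @examples
#' pooled_solubilization(0.467, 0.070, 0.067) # ~0.868
#' @export
pooled_solubilization <- function(solid_yield, xylan_content, lignin_content,
                                  feedstock = feedstock_composition(),
                                  lignin_basis = c("klason", "total"),
                                  xylan_basis = c("xylan",
                                                  "xylan_plus_arabinan"),
                                  tol = 0.02) {
  x0 <- component_initial(feedstock, "xylan", xylan_basis = xylan_basis)
  l0 <- component_initial(feedstock, "lignin", lignin_basis = lignin_basis)
  component_solubilization(solid_yield, xylan_content + lignin_content,
                           x0 + l0, tol = tol)
}

#' Total biomass solubilization
#'
#' The fraction of the initial dry matter dissolved: `1 - SY`.
#'
#' @inheritParams component_solubilization
#' @return Total degree of solubilization in \[0, 1).
#' @export
total_solubilization <- function(solid_yield) {
  if (any(!is.finite(solid_yield)) ||
      any(solid_yield <= 0 | solid_yield > 1)) {
    stop("solid_yield must lie in (0, 1]", call. = FALSE)
  }
  1 - solid_yield
}

#' Enzymatic glucan conversion
#'
#' The fraction of loaded glucan converted to glucose by cellulases,
#' corrected for the water of hydrolysis: one anhydroglucose unit (162
#' g/mol) yields one glucose (180 g/mol), so
#' \deqn{EGC = (162/180) \cdot m_{glucose} / m_{glucan} = 0.9 \, m_{glucose} / m_{glucan}.}
#'
#' @param glucose_released Glucose mass released, g, >= 0.
#' @param glucan_loaded Glucan mass loaded, g, > 0.
#' @param anhydro_factor Anhydro correction, default 162/180 = 0.9.
#' @return Conversion fraction, capped at 1 (with a warning if exceeded).
#' @export
enzymatic_glucan_conversion <- function(glucose_released, glucan_loaded,
                                        anhydro_factor = 0.9) {
  if (any(!is.finite(glucan_loaded)) || any(glucan_loaded <= 0)) {
    stop("glucan_loaded must be > 0", call. = FALSE)
  }
  if (any(!is.finite(glucose_released)) || any(glucose_released < 0)) {
    stop("glucose_released must be >= 0", call. = FALSE)
  }
  egc <- anhydro_factor * glucose_released / glucan_loaded
  if (any(egc > 1)) {
    warning("conversion above 100% capped at 1; check the glucose and ",
            "glucan masses", call. = FALSE)
  }
  pmin(egc, 1)
}

#' Derive solubilization fractions from a composition table
#'
#' Applies the mass-balance relations to a per-run composition table (solid
#' yield plus component contents of the pretreated solid, all as fractions)
#' and returns the derived degrees of solubilization for glucan, xylan,
#' lignin, the pooled xylan-plus-lignin fraction and total biomass.
#'
#' @param composition Data frame with columns `run_id`, `solid_yield`, and
#'   content columns among `glucan_content`, `xylan_content`,
#'   `lignin_content` (fractions).
#' @param feedstock A [feedstock_composition()].
#' @inheritParams component_initial
#' @param tol Clamp-warning threshold passed to
#'   [component_solubilization()].
#' @return Data frame with one row per run and one column per derived
#'   solubilization.
#' @export
derive_solubilization <- function(composition,
                                  feedstock = feedstock_composition(),
                                  lignin_basis = c("klason", "total"),
                                  xylan_basis = c("xylan",
                                                  "xylan_plus_arabinan"),
                                  tol = 0.02) {
  lignin_basis <- match.arg(lignin_basis)
  xylan_basis <- match.arg(xylan_basis)
  need <- c("run_id", "solid_yield")
  if (!all(need %in% names(composition))) {
    stop("composition must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sy <- composition$solid_yield
  out <- data.frame(run_id = composition$run_id,
                    total_biomass = total_solubilization(sy))
  for (comp in c("glucan", "xylan", "lignin")) {
    col <- paste0(comp, "_content")
    if (col %in% names(composition)) {
      c0 <- component_initial(feedstock, comp, lignin_basis = lignin_basis,
                              xylan_basis = xylan_basis)
      out[[comp]] <- component_solubilization(sy, composition[[col]], c0,
                                              tol = tol)
    }
  }
  if (all(c("xylan_content", "lignin_content") %in% names(composition))) {
    out$xylan_plus_lignin <- pooled_solubilization(
      sy, composition$xylan_content, composition$lignin_content,
      feedstock = feedstock, lignin_basis = lignin_basis,
      xylan_basis = xylan_basis, tol = tol)
  }
  out
}
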