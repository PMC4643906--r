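# Ligand depletion by serum albumin.
#
# Fatty acid-free bovine serum albumin in the assay medium binds lipophilic
# inhibitors, so the free concentration seen by the enzyme lags behind the
# added (total) concentration until the binding sites saturate. Refitting a
# logistic curve on the *total* axis then returns an apparently steep Hill
# slope -- the mechanism invoked for carprofen-like compounds whose n_H
# comes out near 3 despite simple 1:1 enzyme binding.

#' Free ligand concentration after albumin binding
#'
#' Closed-form 1:1 site-binding depletion model. With total ligand `T`,
#' total site concentration `capacity` and site dissociation constant
#' `kd`, the free concentration is the positive root of
#' `free^2 + free * (capacity - T + kd) - kd * T = 0`,
#' evaluated in a cancellation-safe form. It satisfies `0 <= free <= T`,
#' is monotone increasing in `T`, and conserves mass:
#' `free + capacity * free / (kd + free) = T`.
#'
#' @param total Added (total) ligand concentration(s), uM, >= 0.
#' @param model An [albumin_model()].
#' @return Numeric vector of free concentrations, uM.
#' @examples
#' m <- albumin_model(capacity = 10, kd = 1)
#' free_concentration(5, m)  # (-6 + sqrt(56)) / 2
#' @export
free_concentration <- function(total, model) {
  stopifnot(inherits(model, "albumin_model"))
  if (any(total < 0, na.rm = TRUE))
    stop_inhibkin("total concentrations must be >= 0", "invalid_parameter")
  if (model$capacity == 0 || is.infinite(model$kd)) return(total)
  b <- model$capacity - total + model$kd
  disc <- sqrt(b^2 + 4 * model$kd * total)
  # quadratic root without subtractive cancellation on either branch
  ifelse(b >= 0,
         2 * model$kd * total / (b + disc),
         (disc - b) / 2)
}

#' Apparent Hill slope under albumin depletion
#'
#' Simulates a noiseless concentration-response experiment in which the
#' response follows the true potency curve as a function of the *free*
#' inhibitor concentration, then refits a logistic curve against the
#' *total* (added) concentration axis and returns the apparent Hill slope.
#' With no albumin (`capacity = 0`) the true slope is recovered; as the
#' binding capacity grows past the true IC50 with tight binding
#' (`kd << capacity`), the apparent slope inflates well above the true
#' value because the free concentration switches on sharply once the sites
#' saturate.
#'
#' @param true_potency [potency_params()] describing the genuine
#'   free-concentration potency.
#' @param model An [albumin_model()].
#' @param total_conc_grid Total-concentration grid (uM) spanning the
#'   apparent transition; default 24 log-spaced points from 1e-3 to 1e4 uM.
#' @return The fitted apparent Hill slope (numeric scalar) with the full
#'   `potency_fit` attached as attribute `"fit"`.
#' @examples
#' pp <- potency_params(pIC50 = 6, hill_slope = 1)
#' apparent_hill_slope(pp, albumin_model(capacity = 0, kd = 1))
#' @export
apparent_hill_slope <- function(true_potency, model,
                                total_conc_grid = 10^seq(-3, 4, length.out = 24)) {
  stopifnot(inherits(true_potency, "potency_params"),
            inherits(model, "albumin_model"))
  free <- free_concentration(total_conc_grid, model)
  lg <- ifelse(free > 0, log10(free * 1e-6), -Inf)
  response <- four_pl_response(lg, true_potency)
  span <- true_potency$top - true_potency$bottom
  if (diff(range(response)) < 0.5 * span)
    stop_inhibkin("transition lies outside the total-concentration grid",
                  "degenerate_data")
  mode <- if (true_potency$bottom == 0) "fixed_zero" else "floating"
  fit <- fit_potency(data.frame(inhibitor_uM = total_conc_grid,
                                response = response),
                     bottom_mode = mode, top = true_potency$top)
  structure(fit$params$hill_slope, fit = fit)
}

#' Free-vs-total concentration table
#'
#' Convenience tabulation of [free_concentration()] over a grid, for export
#' or plotting.
#'
#' @param model An [albumin_model()].
#' @param total Total concentrations (uM).
#' @return Data frame with columns `total_uM`, `free_uM`, `bound_uM`.
#' @export
free_total_table <- function(model, total = 10^seq(-2, 3, length.out = 51)) {
  free <- free_concentration(total, model)
  data.frame(total_uM = total, free_uM = free, bound_uM = total - free)
}
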