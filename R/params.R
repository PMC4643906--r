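#' @keywords internal
"_PACKAGE"

# Condition helper: all package errors carry a subclass so callers can
# distinguish invalid parameters from fit failures, schema problems, etc.
stop_inhibkin <- function(msg, class, ...) {
  stop(structure(
    class = c(paste0("inhibkin_", class), "inhibkin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Michaelis-Menten parameters
#'
#' Bundle the substrate half-saturation constant and maximal velocity of a
#' Michaelis-Menten enzyme. Concentrations are in micromolar throughout the
#' package; velocity units are arbitrary but must be consistent within a
#' dataset (all fits are equivariant to rescaling the velocity axis).
#'
#' @param Km Substrate concentration at half-maximal velocity (uM), > 0.
#' @param Vmax Maximal velocity (signal units per unit time), > 0.
#' @return An object of class `mm_params`.
#' @examples
#' mm_params(Km = 1, Vmax = 10)
#' @export
mm_params <- function(Km, Vmax) {
  if (!is.numeric(Km) || length(Km) != 1L || !is.finite(Km) || Km <= 0)
    stop_inhibkin("'Km' must be a single finite positive number (uM)",
                  "invalid_parameter")
  if (!is.numeric(Vmax) || length(Vmax) != 1L || !is.finite(Vmax) || Vmax <= 0)
    stop_inhibkin("'Vmax' must be a single finite positive number",
                  "invalid_parameter")
  structure(list(Km = Km, Vmax = Vmax), class = "mm_params")
}

#' Inhibition parameters
#'
#' Equilibrium inhibition constant and cooperativity factor of a linear
#' mixed-type (or purely competitive) inhibitor. In the mixed model the
#' inhibitor binds free enzyme with dissociation constant `Ki` and the
#' enzyme-substrate complex with dissociation constant `alpha * Ki`;
#' `alpha -> Inf` recovers pure competitive inhibition and `alpha = 1` pure
#' noncompetitive inhibition.
#'
#' @param Ki Inhibition constant (uM), > 0.
#' @param alpha Cooperativity factor (dimensionless), > 0. Ignored (treated
#'   as infinite) when `mode = "competitive"`.
#' @param mode `"mixed"` or `"competitive"`.
#' @return An object of class `inhibition_params`.
#' @examples
#' inhibition_params(Ki = 0.8, alpha = 3.2)
#' inhibition_params(Ki = 0.8, mode = "competitive")
#' @export
inhibition_params <- function(Ki, alpha = Inf, mode = c("mixed", "competitive")) {
  mode <- match.arg(mode)
  if (!is.numeric(Ki) || length(Ki) != 1L || !is.finite(Ki) || Ki <= 0)
    stop_inhibkin("'Ki' must be a single finite positive number (uM)",
                  "invalid_parameter")
  if (mode == "competitive") {
    alpha <- Inf
  } else if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop_inhibkin("'alpha' must be positive for mixed-mode inhibition",
                  "invalid_parameter")
  }
  structure(list(Ki = Ki, alpha = alpha, mode = mode),
            class = "inhibition_params")
}

#' Concentration-response (potency) parameters
#'
#' Parameters of the four-parameter logistic ("log(inhibitor) vs response,
#' variable slope") curve. `pIC50` is defined on the molar scale
#' (pIC50 = -log10 of the molar IC50) even though concentrations elsewhere
#' in the package are micromolar; [pic50_to_ic50_uM()] converts between the
#' two conventions.
#'
#' @param pIC50 Negative decadic logarithm of the molar IC50.
#' @param hill_slope Hill slope n_H (dimensionless, finite and nonzero).
#'   Positive values describe curves that fall with increasing inhibitor,
#'   the usual situation for an enzyme-inhibition readout reported as
#'   percent of control activity.
#' @param top Response at zero inhibitor (percent of control), default 100.
#' @param bottom Response at saturating inhibitor, default 0. Must be
#'   strictly less than `top`.
#' @return An object of class `potency_params`.
#' @examples
#' potency_params(pIC50 = 6.13, hill_slope = 0.9)
#' @export
potency_params <- function(pIC50, hill_slope = 1, top = 100, bottom = 0) {
  for (nm in c("pIC50", "hill_slope", "top", "bottom")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_inhibkin(sprintf("'%s' must be a single finite number", nm),
                    "invalid_parameter")
  }
  if (hill_slope == 0)
    stop_inhibkin("'hill_slope' must be nonzero", "invalid_parameter")
  if (top <= bottom)
    stop_inhibkin("'top' must exceed 'bottom'", "invalid_parameter")
  structure(list(pIC50 = pIC50, hill_slope = hill_slope,
                 top = top, bottom = bottom),
            class = "potency_params")
}

#' Serum-albumin ligand-binding model
#'
#' Single-class binding-site description of inhibitor sequestration by fatty
#' acid-free serum albumin present in the assay medium. Multiple equivalent
#' sites per albumin molecule are folded into the total site concentration
#' (`capacity` = albumin concentration x sites per molecule).
#'
#' @param capacity Total binding-site concentration (uM), >= 0.
#' @param kd Site dissociation constant (uM), > 0 (may be `Inf`, meaning no
#'   binding).
#' @return An object of class `albumin_model`.
#' @examples
#' albumin_model(capacity = 10, kd = 1)
#' @export
albumin_model <- function(capacity, kd) {
  if (!is.numeric(capacity) || length(capacity) != 1L || is.na(capacity) ||
      capacity < 0 || !is.finite(capacity))
    stop_inhibkin("'capacity' must be a single finite number >= 0 (uM)",
                  "invalid_parameter")
  if (!is.numeric(kd) || length(kd) != 1L || is.na(kd) || kd <= 0)
    stop_inhibkin("'kd' must be a single positive number (uM)",
                  "invalid_parameter")
  structure(list(capacity = capacity, kd = kd), class = "albumin_model")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten parameters: Km = %g uM, Vmax = %g\n",
              x$Km, x$Vmax))
  invisible(x)
}

#' @export
print.inhibition_params <- function(x, ...) {
  cat(sprintf("Inhibition parameters (%s): Ki = %g uM, alpha = %g\n",
              x$mode, x$Ki, x$alpha))
  invisible(x)
}

#' @export
print.potency_params <- function(x, ...) {
  cat(sprintf("Potency: pIC50 = %.3g (IC50 = %.3g uM), n_H = %.3g, top = %g, bottom = %g\n",
              x$pIC50, pic50_to_ic50_uM(x$pIC50), x$hill_slope, x$top, x$bottom))
  invisible(x)
}
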