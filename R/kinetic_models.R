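# Closed-form steady-state velocity and concentration-response equations.
# Everything downstream (simulation, fitting, Dixon construction) is written
# against these functions, so they are kept pure and vectorised over the
# concentration arguments.

#' Michaelis-Menten velocity
#'
#' Uninhibited steady-state velocity `v = Vmax * S / (Km + S)`. A substrate
#' concentration of zero returns a velocity of zero so that blank wells can
#' be simulated.
#'
#' @param S Substrate concentration(s), uM, >= 0.
#' @param p [mm_params()] object.
#' @return Numeric vector of velocities, same length as `S`.
#' @examples
#' mm_velocity(1, mm_params(Km = 1, Vmax = 1))  # half-saturation: 0.5
#' @export
mm_velocity <- function(S, p) {
  stopifnot(inherits(p, "mm_params"))
  if (any(S < 0, na.rm = TRUE))
    stop_inhibkin("substrate concentrations must be >= 0", "invalid_parameter")
  p$Vmax * S / (p$Km + S)
}

#' Linear mixed-inhibition velocity
#'
#' Observed velocity in the presence of a linear mixed-type inhibitor,
#' `v = Vmax_app / (1 + Km_app / S)` with
#' `Vmax_app = Vmax / (1 + I / (alpha * Ki))` and
#' `Km_app = Km * (1 + I / Ki) / (1 + I / (alpha * Ki))`.
#' With `I = 0` this reduces to [mm_velocity()]; parameters with
#' `mode = "competitive"` delegate to [competitive_velocity()].
#'
#' @param S Substrate concentration(s), uM.
#' @param I Inhibitor concentration(s), uM, >= 0.
#' @param p [mm_params()] object.
#' @param q [inhibition_params()] object.
#' @return Numeric vector of velocities.
#' @examples
#' p <- mm_params(Km = 1, Vmax = 1)
#' q <- inhibition_params(Ki = 1, alpha = 2)
#' mixed_inhibition_velocity(1, 1, p, q)  # 2/7
#' @export
mixed_inhibition_velocity <- function(S, I, p, q) {
  stopifnot(inherits(p, "mm_params"), inherits(q, "inhibition_params"))
  if (q$mode == "competitive")
    return(competitive_velocity(S, I, p, q$Ki))
  if (any(I < 0, na.rm = TRUE))
    stop_inhibkin("inhibitor concentrations must be >= 0", "invalid_parameter")
  vmax_app <- p$Vmax / (1 + I / (q$alpha * q$Ki))
  km_app <- p$Km * (1 + I / q$Ki) / (1 + I / (q$alpha * q$Ki))
  vmax_app * S / (km_app + S)
}

#' Competitive-inhibition velocity
#'
#' The `alpha -> Inf` limit of the mixed model:
#' `v = Vmax / (1 + (Km / S) * (1 + I / Ki))`.
#'
#' @inheritParams mixed_inhibition_velocity
#' @param Ki Inhibition constant (uM), > 0.
#' @return Numeric vector of velocities.
#' @export
competitive_velocity <- function(S, I, p, Ki) {
  stopifnot(inherits(p, "mm_params"))
  if (!is.numeric(Ki) || Ki <= 0)
    stop_inhibkin("'Ki' must be positive", "invalid_parameter")
  if (any(I < 0, na.rm = TRUE))
    stop_inhibkin("inhibitor concentrations must be >= 0", "invalid_parameter")
  p$Vmax * S / (p$Km * (1 + I / Ki) + S)
}

#' Four-parameter logistic concentration-response
#'
#' "log(inhibitor) vs response, variable slope" curve on the percent-of-
#' control scale:
#' `response = bottom + (top - bottom) / (1 + 10^((pIC50 + log10(conc_M)) * n_H))`.
#' With a positive Hill slope the response falls from `top` at zero
#' inhibitor to `bottom` at saturating inhibitor and equals the midpoint
#' `(top + bottom)/2` exactly at the IC50.
#'
#' @param log10_conc_M Decadic log of the molar inhibitor concentration
#'   (vectorised; `-Inf` encodes zero inhibitor and returns `top`).
#' @param p [potency_params()] object.
#' @return Numeric vector of responses (percent of control).
#' @examples
#' pp <- potency_params(pIC50 = 6, hill_slope = 1)
#' four_pl_response(log10(1e-6), pp)  # midpoint: 50
#' @export
four_pl_response <- function(log10_conc_M, p) {
  stopifnot(inherits(p, "potency_params"))
  expo <- (p$pIC50 + log10_conc_M) * p$hill_slope
  p$bottom + (p$top - p$bottom) / (1 + 10^expo)
}

#' Convert between pIC50 and micromolar IC50
#'
#' `pIC50` is minus the decadic log of the *molar* IC50, so the micromolar
#' IC50 is `10^(6 - pIC50)`. The two functions are exact inverses.
#'
#' @param pIC50 Numeric vector of pIC50 values.
#' @param ic50_uM Numeric vector of IC50 values in uM, > 0.
#' @return Numeric vector of converted values.
#' @examples
#' pic50_to_ic50_uM(6.13)      # 0.74 to two significant figures
#' ic50_uM_to_pic50(1)         # 6
#' @export
pic50_to_ic50_uM <- function(pIC50) {
  10^(6 - pIC50)
}

#' @rdname pic50_to_ic50_uM
#' @export
ic50_uM_to_pic50 <- function(ic50_uM) {
  if (any(ic50_uM <= 0, na.rm = TRUE))
    stop_inhibkin("IC50 values must be positive", "invalid_parameter")
  6 - log10(ic50_uM)
}

#' Theoretical Dixon-line coefficients
#'
#' In a Dixon plot the reciprocal velocity at a fixed substrate
#' concentration is exactly linear in the inhibitor concentration:
#' `1/v = intercept + slope * I` with
#' `slope = (Km/S + 1/alpha) / (Vmax * Ki)` and
#' `intercept = (1 + Km/S) / Vmax`. For a competitive inhibitor the
#' `1/alpha` term is zero. Any two such lines from the same parameter set
#' intersect at `I = -Ki`, `1/v = (1 - 1/alpha) / Vmax`, which is what the
#' median-intersection estimator exploits.
#'
#' @param S Substrate concentration(s), uM, > 0 (vectorised).
#' @param p [mm_params()] object.
#' @param q [inhibition_params()] object.
#' @return A data frame with columns `substrate_uM`, `slope`, `intercept`,
#'   one row per element of `S`.
#' @export
dixon_line_coefficients <- function(S, p, q) {
  stopifnot(inherits(p, "mm_params"), inherits(q, "inhibition_params"))
  if (any(S <= 0, na.rm = TRUE))
    stop_inhibkin("Dixon lines require substrate concentrations > 0",
                  "invalid_parameter")
  inv_alpha <- if (q$mode == "competitive" || is.infinite(q$alpha)) 0 else 1 / q$alpha
  data.frame(
    substrate_uM = S,
    slope = (p$Km / S + inv_alpha) / (p$Vmax * q$Ki),
    intercept = (1 + p$Km / S) / p$Vmax
  )
}
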