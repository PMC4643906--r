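# Nonlinear least-squares estimation of potency and inhibition parameters.
#
# All nonlinear fits go through a Levenberg-Marquardt core (minpack.lm) with
# a multi-start grid over log-spaced initial values; positivity constraints
# on Km, Vmax, Ki, alpha and the Hill slope are enforced by fitting on the
# log scale. Standard errors are delta-method back-transforms of the
# curvature-based errors on the log scale.

# Run nls.lm from every start in `starts` (list of named numeric vectors)
# and keep the lowest residual sum of squares.
lm_multistart <- function(resid_fn, starts, maxiter = 200) {
  best <- NULL
  diagnostics <- character(0)
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = maxiter)),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      diagnostics <- c(diagnostics, conditionMessage(fit))
      next
    }
    if (!is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    stop_inhibkin(
      paste0("nonlinear fit failed to converge from any start",
             if (length(diagnostics))
               paste0(": ", paste(unique(diagnostics), collapse = "; "))),
      "fit_failure", diagnostics = diagnostics)
  best
}

# Standard errors from the local curvature of the objective at the optimum.
# Returns NA per parameter when the hessian is singular.
lm_se <- function(fit, n_obs) {
  k <- length(fit$par)
  sigma2 <- fit$deviance / max(n_obs - k, 1)
  covm <- tryCatch(solve(fit$hessian) * 2 * sigma2, error = function(e) NULL)
  if (is.null(covm)) return(rep(NA_real_, k))
  d <- diag(covm)
  d[d < 0] <- NA_real_
  sqrt(d)
}

#' Akaike information criterion from a residual sum of squares
#'
#' Gaussian-likelihood form `AIC = n * log(RSS / n) + 2 * (k + 1)`, where
#' `k` is the number of free model parameters and the `+ 1` accounts for
#' the estimated residual variance. `correct = TRUE` adds the small-sample
#' (AICc) correction term.
#'
#' @param rss Residual sum of squares.
#' @param n_obs Number of observations.
#' @param k_free Number of free model parameters (excluding the variance).
#' @param correct Apply the AICc small-sample correction (default `FALSE`).
#' @return The criterion value (scalar).
#' @export
aic_from_rss <- function(rss, n_obs, k_free, correct = FALSE) {
  k <- k_free + 1
  aic <- n_obs * log(rss / n_obs) + 2 * k
  if (correct) aic <- aic + 2 * k * (k + 1) / max(n_obs - k - 1, 1)
  aic
}

#' Select among candidate fits by AIC
#'
#' Compares fits of the *same* data by the Gaussian-RSS Akaike criterion
#' and returns the comparison with the winner flagged. Ties (difference
#' below 1e-9) are resolved toward the model with fewer free parameters.
#'
#' @param candidates A list of fit objects; each must carry `rss`, `n_obs`
#'   and `k_free` entries (as the fits returned by [fit_potency()] and
#'   [fit_inhibition_kinetics()] do).
#' @param correct Use the AICc small-sample correction (default `FALSE`).
#' @return An object of class `fit_comparison` with elements `candidates`,
#'   `selected` (index of the winner), `aic` and `delta_aic`.
#' @export
select_by_aic <- function(candidates, correct = FALSE) {
  if (!is.list(candidates) || length(candidates) < 2L)
    stop_inhibkin("need at least two candidate fits", "invalid_parameter")
  n <- vapply(candidates, function(f) f$n_obs, numeric(1))
  if (length(unique(n)) != 1L)
    stop_inhibkin("candidates were fit to different data (n_obs differ)",
                  "mismatch")
  rss <- vapply(candidates, function(f) f$rss, numeric(1))
  k <- vapply(candidates, function(f) f$k_free, numeric(1))
  aic <- mapply(aic_from_rss, rss, n[1], k, MoreArgs = list(correct = correct))
  # exact fits give RSS = 0 and AIC = -Inf; `<=` keeps such ties well-defined
  tied <- which(aic <= min(aic) + 1e-9)
  selected <- tied[which.min(k[tied])]
  delta <- aic - aic[selected]
  delta[is.nan(delta)] <- 0    # -Inf ties
  structure(list(candidates = candidates,
                 selected = selected,
                 aic = aic,
                 delta_aic = delta),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  labs <- vapply(seq_along(x$candidates), function(i) {
    f <- x$candidates[[i]]
    if (!is.null(f$model_label)) f$model_label
    else if (!is.null(f$bottom_mode)) f$bottom_mode
    else paste0("candidate ", i)
  }, character(1))
  cat("Model comparison by AIC:\n")
  for (i in seq_along(labs))
    cat(sprintf("  %s%-14s AIC = %10.3f  dAIC = %8.3f  (k = %d)\n",
                if (i == x$selected) "* " else "  ", labs[i],
                x$aic[i], x$delta_aic[i], x$candidates[[i]]$k_free))
  invisible(x)
}

# 4PL mean function on the uM concentration axis; conc = 0 maps to `top`.
fourpl_mean <- function(conc_uM, pIC50, hill, top, bottom) {
  log10_conc_M <- ifelse(conc_uM > 0, log10(conc_uM * 1e-6), -Inf)
  bottom + (top - bottom) / (1 + 10^((pIC50 + log10_conc_M) * hill))
}

#' Fit a concentration-response (potency) curve
#'
#' Least-squares fit of the four-parameter logistic to percent-of-control
#' responses with the top fixed at 100%. The bottom is either fixed to zero
#' or allowed to float; with `bottom_mode = "auto"` both variants are fit
#' and the winner chosen by AIC, mirroring common concentration-response
#' practice. The Hill slope is constrained positive (falling curve) via a
#' log parameterisation.
#'
#' @param data Data frame with numeric columns `inhibitor_uM` and
#'   `response` (percent of control). Zero-inhibitor control rows are
#'   allowed and enter the fit with a predicted response equal to the top.
#' @param bottom_mode `"auto"` (default), `"fixed_zero"` or `"floating"`.
#' @param top Fixed top asymptote (default 100).
#' @return An object of class `potency_fit`: `params` ([potency_params()]),
#'   `se` (named standard errors), `ic50_uM`, `bottom_mode`, `aic`, `rss`,
#'   `n_obs`, `k_free`, and for `"auto"` the full `comparison`.
#' @examples
#' pp <- potency_params(pIC50 = 6, hill_slope = 1)
#' conc <- 10^seq(-2, 2, length.out = 9)
#' d <- data.frame(inhibitor_uM = conc,
#'                 response = four_pl_response(log10(conc * 1e-6), pp))
#' fit <- fit_potency(d, bottom_mode = "fixed_zero")
#' fit$params$pIC50
#' @export
fit_potency <- function(data, bottom_mode = c("auto", "fixed_zero", "floating"),
                        top = 100) {
  bottom_mode <- match.arg(bottom_mode)
  if (!is.data.frame(data) || !all(c("inhibitor_uM", "response") %in% names(data)))
    stop_inhibkin("'data' needs columns 'inhibitor_uM' and 'response'",
                  "schema_error")
  conc <- data$inhibitor_uM
  resp <- data$response
  ok <- is.finite(conc) & is.finite(resp) & conc >= 0
  conc <- conc[ok]; resp <- resp[ok]
  n <- length(resp)
  if (n < 5L)
    stop_inhibkin("potency fitting needs at least 5 points spanning the transition",
                  "design_error")
  if (diff(range(resp)) < 1e-6 * max(abs(resp), 1))
    stop_inhibkin("all responses are flat; no transition to fit",
                  "degenerate_data")

  pos <- conc > 0
  lg <- -log10(conc[pos] * 1e-6)                   # candidate pIC50 scale
  # crossing-point start: concentration nearest the half-maximal response
  mid_fz <- (top + 0) / 2
  cross <- lg[which.min(abs(resp[pos] - mid_fz))]
  pic_starts <- unique(c(cross, stats::quantile(lg, c(0.25, 0.5, 0.75), names = FALSE)))
  hill_starts <- c(0.5, 1, 2)

  fit_one <- function(mode) {
    floating <- mode == "floating"
    resid_fn <- function(par) {
      pic <- par[["pIC50"]]
      h <- exp(par[["log_hill"]])
      b <- if (floating) par[["bottom"]] else 0
      resp - fourpl_mean(conc, pic, h, top, b)
    }
    starts <- list()
    b_starts <- if (floating) c(0, max(min(resp), 0)) else 0
    for (p0 in pic_starts) for (h0 in hill_starts) for (b0 in b_starts) {
      st <- c(pIC50 = p0, log_hill = log(h0))
      if (floating) st <- c(st, bottom = b0)
      starts[[length(starts) + 1L]] <- st
    }
    best <- lm_multistart(resid_fn, starts)
    se_log <- lm_se(best, n)
    names(se_log) <- names(best$par)
    pic <- best$par[["pIC50"]]
    h <- exp(best$par[["log_hill"]])
    b <- if (floating) best$par[["bottom"]] else 0
    se <- c(pIC50 = unname(se_log["pIC50"]),
            hill_slope = unname(h * se_log["log_hill"]),
            bottom = if (floating) unname(se_log["bottom"]) else 0)
    k_free <- if (floating) 3L else 2L
    structure(list(
      params = potency_params(pIC50 = pic, hill_slope = h, top = top, bottom = b),
      se = se,
      ic50_uM = pic50_to_ic50_uM(pic),
      bottom_mode = mode,
      rss = best$deviance,
      aic = aic_from_rss(best$deviance, n, k_free),
      n_obs = n,
      k_free = k_free
    ), class = "potency_fit")
  }

  if (bottom_mode != "auto") return(fit_one(bottom_mode))
  cmp <- select_by_aic(list(fit_one("fixed_zero"), fit_one("floating")))
  out <- cmp$candidates[[cmp$selected]]
  out$comparison <- cmp
  out
}

#' @export
print.potency_fit <- function(x, ...) {
  cat(sprintf(
    "Potency fit (bottom %s): pIC50 = %.3f +/- %.3f (IC50 = %.3g uM), n_H = %.2f +/- %.2f\n",
    x$bottom_mode, x$params$pIC50, x$se[["pIC50"]], x$ic50_uM,
    x$params$hill_slope, x$se[["hill_slope"]]))
  if (x$bottom_mode == "floating")
    cat(sprintf("  bottom = %.2f +/- %.2f %% of control\n",
                x$params$bottom, x$se[["bottom"]]))
  cat(sprintf("  RSS = %.4g, AIC = %.3f, n = %d\n", x$rss, x$aic, x$n_obs))
  invisible(x)
}

#' Global fit of mixed and competitive inhibition models
#'
#' Fits the full substrate x inhibitor velocity surface twice -- once with
#' the linear mixed-inhibition model (free Km, Vmax, Ki, alpha) and once
#' with the pure competitive model (alpha fixed at infinity) -- from a
#' multi-start grid of log-spaced initial values, and compares the two by
#' AIC. This reproduces the usual analysis sequence for deciding the mode
#' of inhibition from a steady-state design.
#'
#' @param table Velocity table: a data frame with numeric columns
#'   `substrate_uM`, `inhibitor_uM` and `velocity` (replicate rows are
#'   simply additional observations). Needs at least two distinct substrate
#'   and two distinct inhibitor concentrations (a zero-inhibitor series is
#'   expected in any real design).
#' @param correct Use AICc instead of AIC for the comparison.
#' @return A `fit_comparison` whose two candidates are objects of class
#'   `mixed_inhibition_fit` carrying `mm` ([mm_params()]), `inhib`
#'   ([inhibition_params()]), `se`, `rss`, `aic`, `n_obs`, `k_free` and
#'   `model_label` (`"mixed"` or `"competitive"`).
#' @examples
#' p <- mm_params(Km = 1, Vmax = 10)
#' q <- inhibition_params(Ki = 0.8, alpha = 3.2)
#' g <- expand.grid(substrate_uM = seq(0.5, 4, length.out = 8),
#'                  inhibitor_uM = c(0, 0.5, 1, 2))
#' g$velocity <- mixed_inhibition_velocity(g$substrate_uM, g$inhibitor_uM, p, q)
#' cmp <- fit_inhibition_kinetics(g)
#' cmp$candidates[[cmp$selected]]$inhib$Ki
#' @export
fit_inhibition_kinetics <- function(table, correct = FALSE) {
  if (!is.data.frame(table) ||
      !all(c("substrate_uM", "inhibitor_uM", "velocity") %in% names(table)))
    stop_inhibkin(
      "'table' needs columns 'substrate_uM', 'inhibitor_uM' and 'velocity'",
      "schema_error")
  ok <- is.finite(table$substrate_uM) & is.finite(table$inhibitor_uM) &
    is.finite(table$velocity)
  S <- table$substrate_uM[ok]
  I <- table$inhibitor_uM[ok]
  v <- table$velocity[ok]
  if (length(unique(S)) < 2L)
    stop_inhibkin("design has fewer than 2 distinct substrate concentrations",
                  "design_error")
  if (length(unique(I)) < 2L)
    stop_inhibkin("design has fewer than 2 distinct inhibitor concentrations",
                  "design_error")
  n <- length(v)

  km_starts <- stats::median(S) * c(0.3, 1, 3)
  i_pos <- I[I > 0]
  ki_ref <- if (length(i_pos)) stats::median(i_pos) else 1
  ki_starts <- ki_ref * c(0.3, 1, 3)
  alpha_starts <- c(0.5, 3, 20)
  vmax0 <- function(km) max(v) * (1 + km / max(S))

  fit_mixed <- function() {
    resid_fn <- function(par) {
      km <- exp(par[["lKm"]]); vm <- exp(par[["lVmax"]])
      ki <- exp(par[["lKi"]]); al <- exp(par[["lalpha"]])
      denom_app <- 1 + I / (al * ki)
      v - (vm / denom_app) * S / (km * (1 + I / ki) / denom_app + S)
    }
    starts <- list()
    for (km0 in km_starts) for (ki0 in ki_starts) for (a0 in alpha_starts)
      starts[[length(starts) + 1L]] <-
        c(lKm = log(km0), lVmax = log(vmax0(km0)), lKi = log(ki0),
          lalpha = log(a0))
    best <- lm_multistart(resid_fn, starts)
    est <- exp(best$par)
    se_log <- lm_se(best, n)
    se <- est * se_log
    names(se) <- c("Km", "Vmax", "Ki", "alpha")
    structure(list(
      mm = mm_params(Km = est[["lKm"]], Vmax = est[["lVmax"]]),
      inhib = inhibition_params(Ki = est[["lKi"]], alpha = est[["lalpha"]],
                                mode = "mixed"),
      se = se,
      rss = best$deviance,
      aic = aic_from_rss(best$deviance, n, 4L, correct),
      n_obs = n, k_free = 4L,
      model_label = "mixed"
    ), class = "mixed_inhibition_fit")
  }

  fit_competitive <- function() {
    resid_fn <- function(par) {
      km <- exp(par[["lKm"]]); vm <- exp(par[["lVmax"]])
      ki <- exp(par[["lKi"]])
      v - vm * S / (km * (1 + I / ki) + S)
    }
    starts <- list()
    for (km0 in km_starts) for (ki0 in ki_starts)
      starts[[length(starts) + 1L]] <-
        c(lKm = log(km0), lVmax = log(vmax0(km0)), lKi = log(ki0))
    best <- lm_multistart(resid_fn, starts)
    est <- exp(best$par)
    se_log <- lm_se(best, n)
    se <- est * se_log
    names(se) <- c("Km", "Vmax", "Ki")
    structure(list(
      mm = mm_params(Km = est[["lKm"]], Vmax = est[["lVmax"]]),
      inhib = inhibition_params(Ki = est[["lKi"]], mode = "competitive"),
      se = se,
      rss = best$deviance,
      aic = aic_from_rss(best$deviance, n, 3L, correct),
      n_obs = n, k_free = 3L,
      model_label = "competitive"
    ), class = "mixed_inhibition_fit")
  }

  select_by_aic(list(fit_mixed(), fit_competitive()), correct = correct)
}

#' @export
print.mixed_inhibition_fit <- function(x, ...) {
  cat(sprintf("%s-inhibition fit:\n", x$model_label))
  cat(sprintf("  Km = %.3g +/- %.2g uM, Vmax = %.3g +/- %.2g\n",
              x$mm$Km, x$se[["Km"]], x$mm$Vmax, x$se[["Vmax"]]))
  if (x$model_label == "mixed")
    cat(sprintf("  Ki = %.3g +/- %.2g uM, alpha = %.3g +/- %.2g\n",
                x$inhib$Ki, x$se[["Ki"]], x$inhib$alpha, x$se[["alpha"]]))
  else
    cat(sprintf("  Ki = %.3g +/- %.2g uM (alpha -> Inf)\n",
                x$inhib$Ki, x$se[["Ki"]]))
  cat(sprintf("  RSS = %.4g, AIC = %.3f, n = %d\n", x$rss, x$aic, x$n_obs))
  invisible(x)
}

#' Robust straight-line fit
#'
#' Straight-line fit used for Dixon plots: iteratively reweighted least
#' squares with the Tukey bisquare loss (tuning constant 4.685, scale from
#' the median absolute deviation), which bounds the influence of outlying
#' reciprocal velocities. With fewer than 4 points (or when the robust
#' scale degenerates, e.g. exactly collinear data) the fit falls back to
#' ordinary least squares; two points are interpolated exactly.
#'
#' @param x,y Numeric vectors of equal length (at least 2 points with
#'   distinct `x`).
#' @return An object of class `line_fit` with elements `slope`,
#'   `intercept`, `method` (`"robust"` or `"ols"`), `scale` (robust scale
#'   estimate, `NA` for OLS) and `n_obs`.
#' @examples
#' f <- robust_line(0:5, 1 + 2 * (0:5))
#' c(f$slope, f$intercept)
#' @export
robust_line <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2L)
    stop_inhibkin("need at least 2 finite points", "design_error")
  if (length(unique(x)) < 2L)
    stop_inhibkin("all x values identical: vertical line has no finite slope",
                  "vertical_line")
  ols <- stats::lm.fit(cbind(1, x), y)
  out <- list(slope = unname(ols$coefficients[2]),
              intercept = unname(ols$coefficients[1]),
              method = "ols", scale = NA_real_, n_obs = n)
  if (n >= 4L) {
    rfit <- tryCatch(
      MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                scale.est = "MAD", maxit = 100),
      error = function(e) NULL, warning = function(w) {
        # non-convergence warning: still use the result if coefficients finite
        tryCatch(suppressWarnings(
          MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685,
                    scale.est = "MAD", maxit = 100)),
          error = function(e) NULL)
      })
    if (!is.null(rfit) && all(is.finite(stats::coef(rfit)))) {
      out$slope <- unname(stats::coef(rfit)[2])
      out$intercept <- unname(stats::coef(rfit)[1])
      out$method <- "robust"
      out$scale <- rfit$s
    }
  }
  structure(out, class = "line_fit")
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("line fit (%s, n = %d): slope = %.4g, intercept = %.4g\n",
              x$method, x$n_obs, x$slope, x$intercept))
  invisible(x)
}
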