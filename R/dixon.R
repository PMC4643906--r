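# Dixon-plot construction and the median-intersection Ki estimator.
#
# A Dixon plot shows 1/v against inhibitor concentration at each fixed
# substrate concentration. For a linear mixed-type inhibitor all lines are
# concurrent at (-Ki, (1 - 1/alpha)/Vmax); with noisy lines the pairwise
# intersections scatter, and taking the median of their x positions (in the
# spirit of the direct linear plot of Eisenthal & Cornish-Bowden) gives a
# Ki estimate that single wild intersections cannot drag away.

#' Build a family of Dixon lines from a velocity table
#'
#' Fits one straight line of reciprocal velocity against inhibitor
#' concentration per distinct substrate concentration, using
#' [robust_line()]. Non-positive velocities cannot be reciprocated and are
#' excluded with a warning; substrate levels left with fewer than two
#' distinct inhibitor concentrations are skipped with a warning.
#'
#' @param table Data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `velocity`.
#' @return An object of class `dixon_family`: a list with `substrate_uM`
#'   (sorted vector of line labels) and `lines` (list of [robust_line()]
#'   fits in the same order).
#' @examples
#' p <- mm_params(Km = 1, Vmax = 10)
#' q <- inhibition_params(Ki = 0.8, alpha = 3.2)
#' g <- expand.grid(substrate_uM = c(0.5, 1, 2, 4),
#'                  inhibitor_uM = c(0, 0.5, 1, 2))
#' g$velocity <- mixed_inhibition_velocity(g$substrate_uM, g$inhibitor_uM, p, q)
#' fam <- build_dixon_family(g)
#' length(fam$lines)
#' @export
build_dixon_family <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("substrate_uM", "inhibitor_uM", "velocity") %in% names(table)))
    stop_inhibkin(
      "'table' needs columns 'substrate_uM', 'inhibitor_uM' and 'velocity'",
      "schema_error")
  bad <- !is.finite(table$velocity) | table$velocity <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d non-positive or non-finite velocities from Dixon plot",
                    sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  s_levels <- sort(unique(table$substrate_uM))
  lines <- list()
  kept <- numeric(0)
  for (s in s_levels) {
    sub <- table[table$substrate_uM == s, , drop = FALSE]
    if (length(unique(sub$inhibitor_uM)) < 2L) {
      warning(sprintf("substrate level %g uM has < 2 inhibitor levels; skipped", s))
      next
    }
    lines[[length(lines) + 1L]] <- robust_line(sub$inhibitor_uM, 1 / sub$velocity)
    kept <- c(kept, s)
  }
  if (length(lines) < 2L)
    stop_inhibkin("Dixon analysis needs at least 2 usable substrate levels",
                  "design_error")
  structure(list(substrate_uM = kept, lines = lines), class = "dixon_family")
}

#' @export
print.dixon_family <- function(x, ...) {
  cat(sprintf("Dixon family: %d lines (1/v vs [I])\n", length(x$lines)))
  for (i in seq_along(x$lines))
    cat(sprintf("  S = %5.3g uM: slope = %.4g, intercept = %.4g (%s)\n",
                x$substrate_uM[i], x$lines[[i]]$slope, x$lines[[i]]$intercept,
                x$lines[[i]]$method))
  invisible(x)
}

#' Plot a Dixon line family
#'
#' Base-graphics display of the reciprocal-velocity lines, optionally with
#' the pairwise-intersection cloud and the median-projection marker.
#'
#' @param x A `dixon_family`.
#' @param intersections Optional [pairwise_intersections()] result to
#'   overlay as points, with the median intersection marked.
#' @param xlim,ylim Optional axis limits.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dixon_family <- function(x, intersections = NULL,
                              xlim = NULL, ylim = NULL, ...) {
  slopes <- vapply(x$lines, `[[`, numeric(1), "slope")
  ints <- vapply(x$lines, `[[`, numeric(1), "intercept")
  if (is.null(xlim)) {
    xr <- if (!is.null(intersections) && nrow(intersections$pairs))
      range(intersections$pairs$x_intersect) else c(-1, 1)
    xlim <- range(0, xr * 1.2)
  }
  xx <- seq(xlim[1], xlim[2], length.out = 2)
  yy <- outer(xx, slopes) + rep(ints, each = 2)
  if (is.null(ylim)) ylim <- range(0, yy)
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "[I] (uM)", ylab = "1/v", ...)
  for (i in seq_along(slopes)) graphics::abline(ints[i], slopes[i], col = i)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 3)
  if (!is.null(intersections) && nrow(intersections$pairs)) {
    graphics::points(intersections$pairs$x_intersect,
                     intersections$pairs$y_intersect, pch = 4, col = "grey40")
    est <- median_intersection_ki(intersections)
    graphics::points(est$median_x, est$median_y, pch = 19, col = "red")
  }
  invisible(x)
}

#' Enumerate pairwise intersections of a Dixon family
#'
#' Every unordered pair of lines is solved for its crossing point
#' `x = (b2 - b1) / (m1 - m2)`. Pairs whose slopes differ by less than
#' `tol` relative to the larger slope magnitude are treated as parallel and
#' reported in `excluded_pairs` instead (their nominal crossing would be
#' numerically explosive). For n lines in generic position this yields
#' choose(n, 2) intersections -- 28 for the eight substrate concentrations
#' of a typical design.
#'
#' @param family A [build_dixon_family()] result.
#' @param tol Relative slope-difference tolerance for declaring two lines
#'   parallel (default 1e-6).
#' @return An object of class `intersection_set`: `pairs` (data frame
#'   `S_a`, `S_b`, `x_intersect`, `y_intersect`), `excluded_pairs` (data
#'   frame `S_a`, `S_b`, `reason`) and `n_expected` = choose(n_lines, 2).
#' @export
pairwise_intersections <- function(family, tol = 1e-6) {
  stopifnot(inherits(family, "dixon_family"))
  nl <- length(family$lines)
  if (nl < 2L)
    stop_inhibkin("need at least 2 lines", "design_error")
  idx <- utils::combn(nl, 2)
  pairs <- list()
  excluded <- list()
  for (j in seq_len(ncol(idx))) {
    a <- idx[1, j]; b <- idx[2, j]
    m1 <- family$lines[[a]]$slope; b1 <- family$lines[[a]]$intercept
    m2 <- family$lines[[b]]$slope; b2 <- family$lines[[b]]$intercept
    if (abs(m1 - m2) < tol * max(abs(m1), abs(m2))) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        S_a = family$substrate_uM[a], S_b = family$substrate_uM[b],
        reason = "near-parallel")
      next
    }
    x <- (b2 - b1) / (m1 - m2)
    pairs[[length(pairs) + 1L]] <- data.frame(
      S_a = family$substrate_uM[a], S_b = family$substrate_uM[b],
      x_intersect = x, y_intersect = m1 * x + b1)
  }
  empty_pairs <- data.frame(S_a = numeric(0), S_b = numeric(0),
                            x_intersect = numeric(0), y_intersect = numeric(0))
  empty_excl <- data.frame(S_a = numeric(0), S_b = numeric(0),
                           reason = character(0))
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else empty_pairs,
    excluded_pairs = if (length(excluded)) do.call(rbind, excluded) else empty_excl,
    n_expected = choose(nl, 2)
  ), class = "intersection_set")
}

#' Median-intersection Ki estimate
#'
#' Projects the median of the intersection x positions onto the inhibitor
#' axis: `Ki = -median(x_intersect)`. Even counts use the midpoint of the
#' two central values (the usual sample median). The median of the y
#' positions is reported alongside; for a mixed-type inhibitor it estimates
#' `(1 - 1/alpha) / Vmax`.
#'
#' @param intersections A [pairwise_intersections()] result.
#' @return An object of class `dixon_ki_estimate` with `ki`, `median_x`,
#'   `median_y` and `n_used`.
#' @export
median_intersection_ki <- function(intersections) {
  stopifnot(inherits(intersections, "intersection_set"))
  p <- intersections$pairs
  if (nrow(p) == 0L)
    stop_inhibkin("all line pairs were excluded as parallel; no Ki estimate",
                  "no_estimate")
  mx <- stats::median(p$x_intersect)
  structure(list(ki = -mx,
                 median_x = mx,
                 median_y = stats::median(p$y_intersect),
                 n_used = nrow(p)),
            class = "dixon_ki_estimate")
}

#' @export
print.dixon_ki_estimate <- function(x, ...) {
  cat(sprintf("Dixon median-intersection Ki = %.4g uM (from %d intersections; median 1/v = %.4g)\n",
              x$ki, x$n_used, x$median_y))
  invisible(x)
}

#' Two-inhibitor mutual-exclusivity analysis
#'
#' Yonetani-Theorell-style analysis of a two-inhibitor design at a fixed
#' substrate concentration. Reciprocal velocity is regressed on the
#' concentration of the primary inhibitor, one line per concentration of
#' the second inhibitor. Mutually exclusive inhibitors give parallel lines
#' (the 1/v slope in the primary inhibitor does not depend on the second);
#' cooperative binding makes the lines converge into a "V" towards the y
#' axis, i.e. the slopes grow with the second inhibitor.
#'
#' The parallel-line hypothesis is tested by comparing a shared-slope
#' linear model against one with a free slope per line, using the
#' extra-sum-of-squares F-test and the AIC difference. Because the assay
#' noise is proportional to the velocity, the reciprocal responses are
#' heteroskedastic (the standard deviation of 1/v scales with 1/v); both
#' linear models are therefore fit with inverse-variance weights
#' proportional to the squared observed velocity, which restores the
#' nominal level of the F-test. The verdict is `"mutually_exclusive"` when
#' the shared-slope model is supported (F-test p >= `f_level` and the AIC
#' difference short of the `delta_aic_min` margin for the free model),
#' `"cooperative"` when the free-slope model is clearly preferred
#' (p < `f_level`, AIC margin >= `delta_aic_min`) and the slopes increase
#' with the second inhibitor, and `"inconclusive"` otherwise.
#'
#' @param table Data frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `inhibitor2_uM`, `velocity`, at a single substrate concentration.
#' @param primary_axis Which inhibitor goes on the x axis: `"inhibitor"`
#'   (default) or `"inhibitor2"`.
#' @param f_level Significance level of the extra-sum-of-squares F-test
#'   (default 0.05).
#' @param delta_aic_min AIC margin required to call the free-slope model
#'   clearly preferred (default 2).
#' @return An object of class `exclusivity_result`: `family` (list of
#'   [robust_line()] fits per second-inhibitor level), `levels` (the
#'   second-inhibitor concentrations), `free_slope_fit` and
#'   `common_slope_fit` (per-line coefficients and RSS), `statistic`
#'   (F, df, p-value, `delta_aic` = AIC_shared - AIC_free), and `verdict`.
#' @export
exclusivity_analysis <- function(table,
                                 primary_axis = c("inhibitor", "inhibitor2"),
                                 f_level = 0.05, delta_aic_min = 2) {
  primary_axis <- match.arg(primary_axis)
  need <- c("substrate_uM", "inhibitor_uM", "inhibitor2_uM", "velocity")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop_inhibkin(paste0("'table' needs columns ",
                         paste(need, collapse = ", ")), "schema_error")
  if (length(unique(table$substrate_uM)) != 1L)
    stop_inhibkin("exclusivity analysis expects a single fixed substrate concentration",
                  "design_error")
  xcol <- if (primary_axis == "inhibitor") "inhibitor_uM" else "inhibitor2_uM"
  gcol <- if (primary_axis == "inhibitor") "inhibitor2_uM" else "inhibitor_uM"
  bad <- !is.finite(table$velocity) | table$velocity <= 0
  if (any(bad)) {
    warning(sprintf("excluding %d non-positive velocities", sum(bad)))
    table <- table[!bad, , drop = FALSE]
  }
  x <- table[[xcol]]
  g <- table[[gcol]]
  y <- 1 / table$velocity
  w <- table$velocity^2            # inverse-variance weights for 1/v
  glev <- sort(unique(g))
  if (length(glev) < 2L)
    stop_inhibkin("need at least 2 levels of the second inhibitor", "design_error")
  per_line_x <- tapply(x, g, function(z) length(unique(z)))
  if (any(per_line_x < 3L))
    stop_inhibkin("each Dixon line needs at least 3 primary-inhibitor levels",
                  "design_error")

  gf <- factor(g, levels = glev)
  free <- stats::lm(y ~ gf + gf:x, weights = w)
  shared <- stats::lm(y ~ gf + x, weights = w)
  n <- length(y)
  rss_free <- sum(w * stats::residuals(free)^2)
  rss_shared <- sum(w * stats::residuals(shared)^2)
  k_free <- 2L * length(glev)
  k_shared <- length(glev) + 1L
  aic_free <- aic_from_rss(rss_free, n, k_free)
  aic_shared <- aic_from_rss(rss_shared, n, k_shared)
  ftest <- stats::anova(shared, free)
  fstat <- ftest$F[2]
  pval <- ftest$`Pr(>F)`[2]

  # per-level slopes from separate weighted fits (equivalent to the free model)
  slopes <- vapply(glev, function(lv) {
    sel <- g == lv
    unname(stats::lm.wfit(cbind(1, x[sel]), y[sel], w[sel])$coefficients[2])
  }, numeric(1))
  tau <- suppressWarnings(stats::cor(slopes, glev, method = "kendall"))

  # dAIC margin read in the Burnham-Anderson sense: the free-slope model is
  # only "clearly preferred" when it beats the shared model by delta_aic_min
  delta_aic <- aic_shared - aic_free
  slope_spread <- diff(range(slopes)) / max(abs(slopes))
  if (!is.finite(pval)) {
    # exact data: both models interpolate and the F statistic is 0/0;
    # judge parallelism directly from the fitted slopes
    verdict <- if (slope_spread < 1e-6) "mutually_exclusive"
    else if (isTRUE(tau > 0)) "cooperative"
    else "inconclusive"
  } else {
    shared_supported <- (pval >= f_level) && (delta_aic < delta_aic_min)
    free_preferred <- (pval < f_level) && (delta_aic >= delta_aic_min)
    verdict <- if (shared_supported) "mutually_exclusive"
    else if (free_preferred && isTRUE(tau > 0)) "cooperative"
    else "inconclusive"
  }

  family <- lapply(glev, function(lv) {
    sel <- g == lv
    robust_line(x[sel], y[sel])
  })

  structure(list(
    family = family,
    levels = glev,
    primary_axis = primary_axis,
    free_slope_fit = list(slopes = slopes, rss = rss_free, k_free = k_free,
                          aic = aic_free),
    common_slope_fit = list(slope = unname(stats::coef(shared)[["x"]]),
                            rss = rss_shared, k_free = k_shared,
                            aic = aic_shared),
    statistic = list(F = fstat, df1 = ftest$Df[2], df2 = ftest$Res.Df[2],
                     p_value = pval, delta_aic = delta_aic,
                     slope_trend_tau = tau),
    verdict = verdict
  ), class = "exclusivity_result")
}

#' @export
print.exclusivity_result <- function(x, ...) {
  cat("Two-inhibitor Dixon analysis:\n")
  cat(sprintf("  %d lines; common slope = %.4g; per-line slopes %s\n",
              length(x$levels), x$common_slope_fit$slope,
              paste(signif(x$free_slope_fit$slopes, 3), collapse = ", ")))
  cat(sprintf("  F(%d, %d) = %.3g, p = %.3g; dAIC (shared - free) = %.3g\n",
              x$statistic$df1, x$statistic$df2, x$statistic$F,
              x$statistic$p_value, x$statistic$delta_aic))
  cat(sprintf("  verdict: %s\n", x$verdict))
  invisible(x)
}
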