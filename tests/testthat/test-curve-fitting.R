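# Nonlinear least-squares estimators and AIC model selection.

test_that("robust line recovers exact and outlier-contaminated lines", {
  # exact line
  f <- robust_line(0:7, 1 + 2 * (0:7))
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  # two points: exact interpolation, OLS fallback
  f2 <- robust_line(c(1, 3), c(5, 9))
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 3)
  expect_identical(f2$method, "ols")
  # one gross outlier among 8 points: bisquare stays near the truth and
  # beats OLS on the same data
  x <- 0:7
  y <- 1 + 2 * x
  y[4] <- y[4] + 40
  fr <- robust_line(x, y)
  ols <- stats::lm(y ~ x)
  expect_lt(abs(fr$slope - 2) / 2, 0.05)
  expect_lt(abs(fr$slope - 2), abs(coef(ols)[2] - 2))
  expect_identical(fr$method, "robust")
  expect_error(robust_line(rep(2, 5), 1:5), class = "inhibkin_vertical_line")
})

test_that("AIC selection prefers the simpler model on ties and checks inputs", {
  f1 <- list(rss = 1.234, n_obs = 20, k_free = 2)
  f2 <- list(rss = 1.234, n_obs = 20, k_free = 3)  # extra frozen parameter
  cmp <- select_by_aic(list(f2, f1))
  expect_identical(cmp$selected, 2L)
  expect_equal(cmp$delta_aic[cmp$selected], 0)
  expect_error(select_by_aic(list(f1, list(rss = 1, n_obs = 19, k_free = 2))),
               class = "inhibkin_mismatch")
  # exact fits (rss = 0) still produce a well-defined comparison
  cmp0 <- select_by_aic(list(list(rss = 0, n_obs = 10, k_free = 3),
                             list(rss = 0, n_obs = 10, k_free = 2)))
  expect_identical(cmp0$selected, 2L)
})

test_that("potency fit recovers exact logistic data to optimizer precision", {
  pp <- potency_params(pIC50 = 6, hill_slope = 1)
  conc <- 10^seq(-2.5, 2.5, length.out = 11)
  d <- data.frame(inhibitor_uM = conc,
                  response = four_pl_response(log10(conc * 1e-6), pp))
  fit <- fit_potency(d)
  expect_equal(fit$params$pIC50, 6, tolerance = 1e-6)
  expect_equal(fit$params$hill_slope, 1, tolerance = 1e-6)
  expect_identical(fit$bottom_mode, "fixed_zero")
  expect_equal(fit$ic50_uM, 1, tolerance = 1e-5)
  # floating-bottom data
  pp2 <- potency_params(pIC50 = 5.5, hill_slope = 1.3, bottom = 20)
  d2 <- data.frame(inhibitor_uM = conc,
                   response = four_pl_response(log10(conc * 1e-6), pp2))
  fit2 <- fit_potency(d2)
  expect_identical(fit2$bottom_mode, "floating")
  expect_equal(fit2$params$bottom, 20, tolerance = 1e-4)
})

test_that("potency fit rejects flat or underpowered designs", {
  expect_error(fit_potency(data.frame(inhibitor_uM = 1:10,
                                      response = rep(100, 10))),
               class = "inhibkin_degenerate_data")
  expect_error(fit_potency(data.frame(inhibitor_uM = 1:3,
                                      response = c(90, 50, 10))),
               class = "inhibkin_design_error")
})

test_that("pIC50 is recovered within 0.1 log units at assay-like noise", {
  # 8 log-spaced concentrations, 3 replicates, 5% CV, pIC50 = 6.13
  pp <- potency_params(pIC50 = 6.13, hill_slope = 1)
  errs <- vapply(1:60, function(s) {
    cfg <- simulation_config(seed = s,
                             inhibitor_grid = 10^seq(-2, 1.5, length.out = 8))
    d <- simulate_conc_response(cfg, pp)
    abs(fit_potency(d, bottom_mode = "fixed_zero")$params$pIC50 - 6.13)
  }, numeric(1))
  expect_lte(median(errs), 0.1)
})

test_that("bottom-mode selection prefers fixed zero when the data say zero", {
  pp <- potency_params(pIC50 = 6, hill_slope = 1)
  hits <- vapply(1:20, function(s) {
    cfg <- simulation_config(seed = 100 + s,
                             inhibitor_grid = 10^seq(-2, 2, length.out = 8))
    d <- simulate_conc_response(cfg, pp)
    fit_potency(d)$bottom_mode == "fixed_zero"
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("global kinetics fit recovers noiseless parameters exactly", {
  cmp <- fit_inhibition_kinetics(exact_mixed_table())
  sel <- cmp$candidates[[cmp$selected]]
  expect_identical(sel$model_label, "mixed")
  expect_equal(sel$inhib$Ki, 0.8, tolerance = 1e-6)
  expect_equal(sel$inhib$alpha, 3.2, tolerance = 1e-6)
  expect_equal(sel$mm$Km, 1, tolerance = 1e-6)
  expect_equal(sel$mm$Vmax, 10, tolerance = 1e-6)
  # noiseless competitive data: mixed gains nothing, competitive selected
  cmp2 <- fit_inhibition_kinetics(exact_competitive_table())
  sel2 <- cmp2$candidates[[cmp2$selected]]
  expect_identical(sel2$model_label, "competitive")
  expect_equal(sel2$inhib$Ki, 0.8, tolerance = 1e-6)
})

test_that("kinetics fits are equivariant to velocity rescaling", {
  tab <- simulate_velocity_table(simulation_config(seed = 17))
  cmp1 <- fit_inhibition_kinetics(tab)
  tab2 <- tab
  tab2$velocity <- tab2$velocity * 1000
  cmp2 <- fit_inhibition_kinetics(tab2)
  a <- cmp1$candidates[[1]]
  b <- cmp2$candidates[[1]]
  expect_equal(b$inhib$Ki, a$inhib$Ki, tolerance = 1e-5)
  expect_equal(b$inhib$alpha, a$inhib$alpha, tolerance = 1e-5)
  expect_equal(b$mm$Km, a$mm$Km, tolerance = 1e-5)
  expect_equal(b$mm$Vmax, a$mm$Vmax * 1000, tolerance = 1)
})

test_that("kinetics fit names the missing design dimension", {
  tab <- exact_mixed_table()
  expect_error(fit_inhibition_kinetics(tab[tab$substrate_uM == 0.5, ]),
               "substrate", class = "inhibkin_design_error")
  expect_error(fit_inhibition_kinetics(tab[tab$inhibitor_uM == 0, ]),
               "inhibitor", class = "inhibkin_design_error")
})

test_that("kinetics fit reports usable standard errors on noisy data", {
  cmp <- fit_inhibition_kinetics(simulate_velocity_table(simulation_config(seed = 23)))
  sel <- cmp$candidates[[cmp$selected]]
  expect_true(all(is.finite(sel$se)))
  expect_true(all(sel$se > 0))
  # SE magnitudes should be a modest fraction of the estimates at 5% CV
  expect_lt(sel$se[["Ki"]] / sel$inhib$Ki, 1)
})
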