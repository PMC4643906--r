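# Closed-form velocity and response equations.

test_that("Michaelis-Menten velocity obeys its defining identities", {
  p <- mm_params(Km = 1, Vmax = 1)
  expect_equal(mm_velocity(1, p), 0.5)                 # half-saturation
  expect_equal(mm_velocity(0, p), 0)                   # blank well
  expect_equal(mm_velocity(1e9, p), 1, tolerance = 1e-8)  # saturation limit
  expect_equal(mm_velocity(2, mm_params(Km = 2, Vmax = 7)), 3.5)
  expect_error(mm_params(Km = -1, Vmax = 1), class = "inhibkin_invalid_parameter")
  expect_error(mm_params(Km = 1, Vmax = 0), class = "inhibkin_invalid_parameter")
})

test_that("mixed-inhibition velocity matches hand substitution and limits", {
  p <- mm_params(Km = 1, Vmax = 1)
  q <- inhibition_params(Ki = 1, alpha = 2)
  # Vmax_app = 1/(1 + 1/2) = 2/3, Km_app = (1 + 1)/(1 + 1/2) = 4/3
  expect_equal(mixed_inhibition_velocity(1, 1, p, q), 2 / 7)
  # no-inhibitor limit
  S <- c(0.5, 1, 2, 4)
  expect_equal(mixed_inhibition_velocity(S, 0, p, q), mm_velocity(S, p))
  # alpha -> Inf recovers the competitive closed form
  q_big <- inhibition_params(Ki = 0.8, alpha = 1e9)
  vc <- competitive_velocity(S, 1.5, p, 0.8)
  vm <- mixed_inhibition_velocity(S, 1.5, p, q_big)
  expect_lt(max(abs(vm - vc) / vc), 1e-6)
  # competitive mode delegates
  q_comp <- inhibition_params(Ki = 0.8, mode = "competitive")
  expect_equal(mixed_inhibition_velocity(S, 1.5, p, q_comp), vc)
})

test_that("competitive velocity matches substitution and its limits", {
  p <- mm_params(Km = 1, Vmax = 1)
  expect_equal(competitive_velocity(1, 0, p, 1), mm_velocity(1, p))
  expect_equal(competitive_velocity(1, 1, p, 1), 1 / 3)  # S=Km, I=Ki
  expect_lt(competitive_velocity(1, 1e12, p, 1), 1e-10)  # I -> Inf
})

test_that("velocity is monotone: decreasing in [I], increasing in [S]", {
  set.seed(41)
  for (i in 1:20) {
    p <- mm_params(Km = runif(1, 0.2, 5), Vmax = runif(1, 1, 100))
    q <- inhibition_params(Ki = runif(1, 0.1, 10), alpha = runif(1, 0.2, 50))
    I <- sort(runif(6, 0, 10))
    S <- sort(runif(6, 0.1, 10))
    vI <- mixed_inhibition_velocity(2, I, p, q)
    vS <- mixed_inhibition_velocity(S, 1, p, q)
    expect_true(all(diff(vI) < 0))
    expect_true(all(diff(vS) > 0))
  }
})

test_that("1/v is exactly linear in [I] at fixed [S]", {
  set.seed(42)
  for (i in 1:10) {
    p <- mm_params(Km = runif(1, 0.2, 5), Vmax = runif(1, 1, 100))
    q <- inhibition_params(Ki = runif(1, 0.1, 10), alpha = runif(1, 0.2, 50))
    I <- seq(0, 8, length.out = 9)
    y <- 1 / mixed_inhibition_velocity(1.7, I, p, q)
    second_diff <- diff(diff(y))
    expect_lt(max(abs(second_diff)) / max(y), 1e-12)
  }
})

test_that("four-parameter logistic hits midpoint, asymptotes and substitution", {
  pp <- potency_params(pIC50 = 6, hill_slope = 1)
  expect_equal(four_pl_response(log10(1e-6), pp), 50)          # conc = IC50
  expect_equal(four_pl_response(log10(10e-6), pp), 100 / 11)   # 10 uM
  expect_equal(four_pl_response(-Inf, pp), 100)                # conc -> 0
  pp2 <- potency_params(pIC50 = 5, hill_slope = 2, top = 90, bottom = 10)
  expect_equal(four_pl_response(log10(1e-5), pp2), 50)         # (top+bottom)/2
  # monotone decreasing in concentration for positive Hill slope
  lg <- seq(-9, -3, length.out = 30)
  expect_true(all(diff(four_pl_response(lg, pp)) < 0))
  expect_error(potency_params(pIC50 = 6, hill_slope = 1, top = 0, bottom = 50),
               class = "inhibkin_invalid_parameter")
})

test_that("pIC50 <-> IC50 conversion round-trips at machine precision", {
  expect_equal(pic50_to_ic50_uM(6), 1)
  set.seed(43)
  pic <- runif(50, 3, 9)
  expect_lt(max(abs(ic50_uM_to_pic50(pic50_to_ic50_uM(pic)) - pic) / pic), 1e-12)
  ic <- 10^runif(50, -3, 3)
  expect_lt(max(abs(pic50_to_ic50_uM(ic50_uM_to_pic50(ic)) - ic) / ic), 1e-12)
  expect_error(ic50_uM_to_pic50(0), class = "inhibkin_invalid_parameter")
})

test_that("Dixon line coefficients match the closed form and its intersection", {
  p <- mm_params(Km = 1, Vmax = 1)
  # competitive limit: slope (Km/S)/(Vmax Ki) = 1, intercept (1 + Km/S)/Vmax = 2
  co <- dixon_line_coefficients(1, p, inhibition_params(Ki = 1, mode = "competitive"))
  expect_equal(co$slope, 1)
  expect_equal(co$intercept, 2)
  # any two lines from one parameter set are concurrent at (-Ki, (1 - 1/alpha)/Vmax)
  set.seed(44)
  for (i in 1:10) {
    pp <- mm_params(Km = runif(1, 0.2, 5), Vmax = runif(1, 1, 100))
    qq <- inhibition_params(Ki = runif(1, 0.1, 10), alpha = runif(1, 0.2, 50))
    co2 <- dixon_line_coefficients(c(0.5, 3), pp, qq)
    x <- (co2$intercept[2] - co2$intercept[1]) / (co2$slope[1] - co2$slope[2])
    y <- co2$intercept[1] + co2$slope[1] * x
    expect_equal(x, -qq$Ki, tolerance = 1e-10)
    expect_equal(y, (1 - 1 / qq$alpha) / pp$Vmax, tolerance = 1e-10)
  }
})
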