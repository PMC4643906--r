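# Dixon-plot construction, intersection census, median-Ki estimator and
# the two-inhibitor exclusivity analysis.

test_that("Dixon family reproduces the closed-form lines on exact data", {
  tab <- exact_mixed_table()
  fam <- build_dixon_family(tab)
  expect_length(fam$lines, 8)
  theo <- dixon_line_coefficients(fam$substrate_uM, ref_mm(), ref_inhib())
  for (i in seq_along(fam$lines)) {
    expect_equal(fam$lines[[i]]$slope, theo$slope[i], tolerance = 1e-9)
    expect_equal(fam$lines[[i]]$intercept, theo$intercept[i], tolerance = 1e-9)
  }
  # competitive data: slopes increase as S decreases (slope ~ Km/S)
  fam_c <- build_dixon_family(exact_competitive_table())
  slopes <- vapply(fam_c$lines, `[[`, numeric(1), "slope")
  expect_true(all(diff(slopes) < 0))  # substrate_uM is sorted ascending
})

test_that("Dixon family rejects degenerate designs and bad velocities", {
  tab <- exact_mixed_table()
  expect_error(build_dixon_family(tab[tab$substrate_uM == 0.5, ]),
               class = "inhibkin_design_error")
  tab$velocity[1] <- 0
  expect_warning(build_dixon_family(tab), "non-positive")
})

test_that("pairwise intersections: census, hand algebra and parallels", {
  # three concurrent lines: y = 1 + 2x, 2 + 4x, 3 + 6x cross at x = -0.5
  fam <- structure(list(
    substrate_uM = c(1, 2, 3),
    lines = lapply(1:3, function(i)
      structure(list(slope = 2 * i, intercept = i, method = "ols",
                     scale = NA_real_, n_obs = 2L), class = "line_fit"))),
    class = "dixon_family")
  xs <- pairwise_intersections(fam)
  expect_equal(nrow(xs$pairs), 3)
  expect_equal(xs$pairs$x_intersect, rep(-0.5, 3))
  # two parallel lines: excluded, count conserved
  fam2 <- structure(list(
    substrate_uM = c(1, 2),
    lines = list(
      structure(list(slope = 1, intercept = 0, method = "ols",
                     scale = NA_real_, n_obs = 2L), class = "line_fit"),
      structure(list(slope = 1, intercept = 1, method = "ols",
                     scale = NA_real_, n_obs = 2L), class = "line_fit"))),
    class = "dixon_family")
  xs2 <- pairwise_intersections(fam2)
  expect_equal(nrow(xs2$pairs), 0)
  expect_equal(nrow(xs2$excluded_pairs), 1)
  expect_error(median_intersection_ki(xs2), class = "inhibkin_no_estimate")
})

test_that("intersection count conservation holds across noisy families", {
  for (s in 1:10) {
    tab <- simulate_velocity_table(simulation_config(seed = 200 + s))
    xs <- pairwise_intersections(build_dixon_family(tab))
    expect_equal(nrow(xs$pairs) + nrow(xs$excluded_pairs), xs$n_expected)
    expect_equal(xs$n_expected, choose(8, 2))
  }
})

test_that("median-intersection Ki: definition, invariances and outliers", {
  mk_set <- function(x) {
    structure(list(pairs = data.frame(S_a = seq_along(x), S_b = seq_along(x) + 1,
                                      x_intersect = x, y_intersect = 0 * x),
                   excluded_pairs = data.frame(), n_expected = length(x)),
              class = "intersection_set")
  }
  expect_equal(median_intersection_ki(mk_set(c(-1, -2, -9)))$ki, 2)
  # even count: midpoint of the central pair
  expect_equal(median_intersection_ki(mk_set(c(-1, -2, -4, -9)))$ki, 3)
  # permutation invariance of line order and velocity-rescaling invariance
  tab <- simulate_velocity_table(simulation_config(seed = 31))
  ki1 <- median_intersection_ki(pairwise_intersections(build_dixon_family(tab)))$ki
  perm <- tab[sample(nrow(tab)), ]
  ki2 <- median_intersection_ki(pairwise_intersections(build_dixon_family(perm)))$ki
  expect_equal(ki2, ki1, tolerance = 1e-12)
  resc <- tab
  resc$velocity <- resc$velocity * 500
  ki3 <- median_intersection_ki(pairwise_intersections(build_dixon_family(resc)))$ki
  expect_equal(ki3, ki1, tolerance = 1e-9)
  # 28 noisy intersections with 3 wild outliers: median survives within 20%
  errs <- vapply(1:10, function(s) {
    tabn <- simulate_velocity_table(simulation_config(seed = 300 + s))
    xs <- pairwise_intersections(build_dixon_family(tabn))
    set.seed(s)
    idx <- sample(nrow(xs$pairs), 3)
    xs$pairs$x_intersect[idx] <- xs$pairs$x_intersect[idx] - runif(3, 10, 30)
    abs(median_intersection_ki(xs)$ki - 0.8) / 0.8
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("exclusivity analysis reads noiseless generators correctly", {
  # mutually exclusive: 1/v slope in I1 is (Km/S)/(Vmax K1), independent of I2
  cfg <- two_inhibitor_config("exclusive", noise_cv = 0)
  ex <- exclusivity_analysis(simulate_velocity_table(cfg))
  expect_identical(ex$verdict, "mutually_exclusive")
  expect_lt(diff(range(ex$free_slope_fit$slopes)) /
              max(abs(ex$free_slope_fit$slopes)), 1e-9)
  expect_lte(ex$free_slope_fit$rss, ex$common_slope_fit$rss + 1e-12)
  # synergistic (beta = 1): slope grows with I2, "V"-shaped family
  cfg2 <- two_inhibitor_config("synergistic", noise_cv = 0)
  ex2 <- exclusivity_analysis(simulate_velocity_table(cfg2))
  expect_identical(ex2$verdict, "cooperative")
  expect_true(all(diff(ex2$free_slope_fit$slopes) > 0))
})

test_that("exclusivity analysis enforces its design preconditions", {
  cfg <- two_inhibitor_config("exclusive")
  tab <- simulate_velocity_table(cfg)
  # fewer than 3 primary-inhibitor levels per line
  thin <- tab[tab$inhibitor_uM %in% c(0, 2), ]
  expect_error(exclusivity_analysis(thin), class = "inhibkin_design_error")
  # multiple substrate concentrations
  tab2 <- rbind(tab, transform(tab, substrate_uM = 1))
  expect_error(exclusivity_analysis(tab2), class = "inhibkin_design_error")
})
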