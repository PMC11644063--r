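test_that("the gap distance is Euclidean distance from the (0, 1) reference", {
  expect_equal(entry_distance_from_center(0, 1), 0)
  expect_equal(entry_distance_from_center(3.66, 1), 3.66)
  expect_equal(entry_distance_from_center(1.2, 2.0), sqrt(1.2^2 + 1^2))
  # lateral symmetry: (x, y) and (-x, y) close the same gap
  expect_equal(entry_distance_from_center(-1.2, 2.0),
               entry_distance_from_center(1.2, 2.0))
  # configurable reference for the adult 1.3 m midriff variant
  g13 <- goal_geometry(center = c(0, 1.3))
  expect_equal(entry_distance_from_center(0, 1.3, g13), 0)
  expect_error(entry_distance_from_center(Inf, 1), "finite")
})

test_that("required rate of closure is gap over flight time", {
  expect_equal(required_rate_of_closure(0, 0.31), 0)
  expect_equal(required_rate_of_closure(sqrt(2.44), 0.5), sqrt(2.44) / 0.5)
  expect_error(required_rate_of_closure(1, 0), "flight_duration")
  expect_error(required_rate_of_closure(-1, 1), "distance")
  # scaling: doubling the gap doubles RROC, doubling the time halves it
  d <- runif(20, 0.1, 4); tt <- runif(20, 0.3, 1.5)
  expect_equal(required_rate_of_closure(2 * d, tt),
               2 * required_rate_of_closure(d, tt))
  expect_equal(required_rate_of_closure(d, 2 * tt),
               required_rate_of_closure(d, tt) / 2)
})

test_that("tau identity: rroc times flight duration recovers the gap", {
  flights <- generate_routines(generator_config(n_routines = 200, seed = 3))
  feats <- compute_features(flights)
  gap <- entry_distance_from_center(flights$entry_x, flights$entry_y)
  expect_equal(feats$rroc * flights$flight_duration, gap,
               tolerance = 1e-9)
})

test_that("spin-free lateral entry matches uniform lateral motion", {
  fl <- data.frame(launch_x = c(2.0, 1.3), vx = c(-1.5, 0),
                   flight_duration = c(0.8, 0.9))
  expect_equal(spin_free_entry_x(fl), c(2.0 + (-1.5) * 0.8, 1.3))

  flights <- generate_routines(generator_config(n_routines = 25, seed = 8))
  closed <- spin_free_entry_x(flights)
  numeric <- mapply(integrate_lateral, flights$launch_x, flights$vx,
                    flights$flight_duration)
  expect_lt(max(abs(closed - numeric)), 1e-6)
})

test_that("spin deviation is a direction-free magnitude with a signed variant", {
  expect_equal(spin_deviation(0.3, 0.8), 0.5)
  expect_equal(spin_deviation(0.8, 0.3), 0.5)
  expect_equal(spin_deviation(0.8, 0.8), 0)
  expect_equal(spin_deviation(0.3, 0.8, signed = TRUE), -0.5)
})

test_that("shot angle runs from straight-on 0 to goal-line 90 degrees", {
  expect_equal(shot_angle(0, 11), 0)       # penalty spot
  expect_equal(shot_angle(3, 0), 90)       # on the goal line
  expect_equal(shot_angle(-3, 0), 90)
  expect_equal(shot_angle(5, 5), 45)
  expect_error(shot_angle(0, 0), "undefined")
  # monotone in |x| at fixed z, monotone decreasing in z at fixed |x|
  xs <- seq(0.5, 30, length.out = 40)
  expect_true(all(diff(shot_angle(xs, 11)) > 0))
  zs <- seq(1, 40, length.out = 40)
  expect_true(all(diff(shot_angle(7, zs)) < 0))
})

test_that("the feature table composes the three features per routine", {
  fl <- make_flights_df()
  tab <- fl
  tab$goal_proportion <- c(0.3, 0.5, 0.9)
  tab$n_plays <- c(120L, 150L, 110L)
  feats <- build_feature_table(tab)
  expect_equal(nrow(feats), 3)
  gap1 <- sqrt(0.7^2 + 0.4^2)
  expect_equal(feats$rroc[1], gap1 / 0.7)
  expect_equal(feats$curvature[2], abs(0.3 - (2 + (-1.5) * 0.8)))
  expect_equal(feats$shot_angle[1], 0)
  expect_equal(feats$goal_proportion, tab$goal_proportion)

  bad <- tab
  bad$flight_duration[2] <- 0
  expect_error(build_feature_table(bad), "R2")
  expect_error(build_feature_table(tab[0, ]), "empty")

  # synthetic scale: all invariants hold on a generated table
  sc <- default_scenario(seed = 21, n_routines = 150, plays = 120)
  f <- sc$features
  expect_true(all(is.finite(f$rroc)) && all(f$rroc >= 0))
  expect_true(all(f$curvature >= 0))
  expect_true(all(f$shot_angle >= 0 & f$shot_angle <= 90))
  expect_equal(abs(f$curvature_signed), f$curvature)
})

test_that("IQR outlier flags use interpolated quartiles and 1.5 fences", {
  expect_false(any(iqr_outlier_flags(rep(3, 10))))
  flags <- iqr_outlier_flags(c(1:9, 100))
  expect_equal(which(flags), 10L)
  expect_false(any(iqr_outlier_flags(c(1, 2, 3, 4))))
  expect_error(iqr_outlier_flags(c(1, 2, 3)), "at least 4")
})

test_that("pearson_r matches hand-computed correlations and guards input", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 3, 2)), 0.5)
  expect_error(pearson_r(c(1, 2, 3), c(5, 5, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("the OLS screen recovers signal and rejects collinearity", {
  sc <- default_scenario(seed = 31, n_routines = 120, plays = 100)
  f <- sc$features
  target <- 0.05 + 0.1 * f$rroc + rnorm(nrow(f), 0, 1e-8)
  scr <- ols_screen(f, target)
  expect_equal(scr$coefficient[scr$feature == "rroc"], 0.1,
               tolerance = 1e-4)
  expect_lt(scr$p_value[scr$feature == "rroc"], 1e-10)

  dup <- f
  dup$curvature <- dup$rroc
  expect_error(ols_screen(dup, target), "collinear")
  expect_error(ols_screen(f[1:4, ], target[1:4]), "more rows")
})

test_that("the OLS screen holds its size under a pure-noise feature", {
  sc <- default_scenario(seed = 41, n_routines = 500, plays = 50)
  f <- sc$features
  n_sims <- 1000
  set.seed(99)
  pvals <- vapply(seq_len(n_sims), function(i) {
    target <- runif(nrow(f))  # independent of every feature
    ols_screen(f, target)$p_value[1]
  }, numeric(1))
  rejection <- mean(pvals < 0.05)
  # binomial 3-sigma band around the nominal 5% level
  expect_gt(rejection, 0.05 - 3 * sqrt(0.05 * 0.95 / n_sims))
  expect_lt(rejection, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sims))
})
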