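# dry-mass conversion, time courses, increments, endpoint statistics

test_that("fov_area multiplies and validates", {
  expect_equal(fov_area(450, 338), 152100)
  expect_equal(fov_area(1, 1), 1)
  expect_error(fov_area(100, 0), class = "holomass_config_error")
})

test_that("mean_phase is the plain FOV mean", {
  expect_equal(mean_phase(matrix(0, 8, 8)), 0)
  expect_equal(mean_phase(matrix(1.3, 8, 8)), 1.3)
  m <- matrix(0, 10, 10); m[1:5, 1:4] <- 2.5   # 20% coverage
  expect_equal(mean_phase(m), 0.2 * 2.5)
  expect_error(mean_phase(matrix(numeric(0), 0, 0)), "empty")
})

test_that("dry mass follows the lambda/(2 pi alpha) conversion", {
  p <- drymass_params(s_fov_um2 = 152100)
  expect_equal(dry_mass(0, p), 0)
  # hand-derived oracle: alpha 0.19 mL/g = 0.19 um^3/pg, lambda 0.532 um
  # => dm(1 rad) = 0.532 * 152100 / (2*pi*0.19) pg = 67.78 ng
  oracle_ng <- 0.532 * 152100 / (2 * pi * 0.19) / 1000
  expect_equal(dry_mass(1, p), oracle_ng, tolerance = 1e-12)
  expect_equal(signif(dry_mass(1, p), 4), 67.78)
  expect_equal(dry_mass(2.2, p), 2.2 * dry_mass(1, p), tolerance = 1e-12)
  expect_error(dry_mass(1, drymass_params(alpha_ml_per_g = -1)),
               class = "holomass_config_error")

  # the two formulations of the same quantity agree to machine precision
  set.seed(8)
  ph <- phase_map(matrix(runif(96 * 128), 96, 128), 0.879)
  s <- length(ph$phase) * 0.879^2
  via_mean <- dry_mass(mean_phase(ph), drymass_params(s_fov_um2 = s))
  via_sum <- 0.532 / (2 * pi * 0.19) * sum(ph$phase) * 0.879^2 / 1000
  expect_equal(via_mean, via_sum, tolerance = 1e-12)
  expect_equal(dry_mass_map(ph), via_sum, tolerance = 1e-12)
})

test_that("dm_course tracks scenarios and rejects bad stacks", {
  g <- tiny_grid()
  sc <- smooth_scene(6, g, n_cells = 12)
  m0 <- analytic_dry_mass(sc)
  ts <- c(0, 6, 12, 18, 24)

  mk_maps <- function(kind) lapply(ts, function(t) {
    pm <- render_phase(evolve(sc, scenario_spec(kind), t))
    pm$time_h <- t
    pm
  })
  arrest <- dm_course(mk_maps("arrest"))
  expect_s3_class(arrest, "dry_mass_series")
  expect_true(all(abs(arrest$dry_mass_ng - m0) < 0.03 * m0))

  # empty FOV stays at ~0
  empty <- lapply(ts, function(t) {
    pm <- render_phase(scene(grid = g)); pm$time_h <- t; pm
  })
  expect_true(all(abs(dm_course(empty)$dry_mass_ng) < 1e-9))

  bad <- mk_maps("arrest")
  bad[[2]] <- phase_map(matrix(0, 10, 10), 0.879, time_h = 6)
  expect_error(dm_course(bad), "geometry")
})

test_that("an exponential course recovers its doubling time by regression", {
  spec <- scenario_spec("control-exponential", doubling_time_h = 12)
  ts <- seq(0, 24, by = 0.5)
  m <- local({
    set.seed(21)
    scenario_mass(spec, 25, ts) + rnorm(length(ts), 0, 0.5)
  })
  fit <- lm(log2(m) ~ ts)
  expect_equal(1 / unname(coef(fit)[2]), 12, tolerance = 0.1)
})

test_that("dm_increment subtracts the t = 0 mass from the t = 24 mass", {
  flat <- dry_mass_series(c(0, 12, 24), c(10, 10, 10))
  expect_equal(dm_increment(flat), 0)
  expect_equal(dm_increment(dry_mass_series(c(0, 24), c(10, 35))), 25)
  expect_error(dm_increment(dry_mass_series(c(0, 12), c(10, 20))),
               "t = 0 and t = 24")
  # negative increments are representable (lysis endpoint)
  expect_equal(dm_increment(dry_mass_series(c(0, 24), c(25, 17.1))), -7.9)
})

test_that("compare_conditions implements the two-sample t-test endpoint", {
  x <- c(24.1, 25.3, 23.8, 24.9, 25.1, 24.4, 23.9, 25.0, 24.2, 24.8,
         25.2, 24.0)
  same <- compare_conditions(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "ns")

  # independent oracle through the pooled-t tail formula
  set.seed(10)
  tr <- rnorm(12, 25, 2); ct <- rnorm(12, 0, 2)
  st <- compare_conditions(tr, ct)
  sp <- sqrt(((11) * var(tr) + (11) * var(ct)) / 22)
  t_oracle <- (mean(tr) - mean(ct)) / (sp * sqrt(2 / 12))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 22)
  expect_equal(st$t, t_oracle, tolerance = 1e-12)
  expect_equal(st$p, p_oracle, tolerance = 1e-12)
  expect_lt(st$p_adj, 0.005)
  expect_equal(st$stars, "***")

  # Bonferroni arithmetic
  st3 <- compare_conditions(tr, ct, n_comparisons = 3)
  expect_equal(st3$p_adj, min(1, 3 * st3$p))

  # both groups constant: equal means p = 1, different means p = 0
  expect_equal(compare_conditions(rep(2, 3), rep(2, 3))$p, 1)
  expect_equal(compare_conditions(rep(2, 3), rep(5, 3))$p, 0)
  expect_error(compare_conditions(1, c(1, 2)), "at least 2")
})

test_that("the printed star convention is reproduced exactly", {
  expect_equal(significance_stars(0.0049), "***")
  expect_equal(significance_stars(0.005), "**")
  expect_equal(significance_stars(0.0099), "**")
  expect_equal(significance_stars(0.01), "*")
  expect_equal(significance_stars(0.049), "*")
  expect_equal(significance_stars(0.05), "ns")
  expect_equal(significance_stars(1), "ns")
})
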