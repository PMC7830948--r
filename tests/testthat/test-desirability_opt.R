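test_that("individual desirability follows the Derringer-Suich forms", {
  g_min <- goal("particle_size", "minimize", 139, 210)
  expect_equal(individual_desirability(210, g_min), 0)
  expect_equal(individual_desirability(139, g_min), 1)
  expect_equal(individual_desirability(250, g_min), 0)   # clamped
  expect_equal(individual_desirability(100, g_min), 1)
  # (210 - 141.145) / 71 evaluated directly
  expect_equal(individual_desirability(141.145, g_min), 0.9698, tolerance = 5e-4)

  g_max <- goal("ee", "maximize", 58.7, 75.6)
  expect_equal(individual_desirability(67.15, g_max), 0.5)
  expect_equal(individual_desirability(58.7, g_max), 0)
  expect_equal(individual_desirability(75.6, g_max), 1)

  g_w <- goal("y", "minimize", 0, 1, weight = 2)
  expect_equal(individual_desirability(0.5, g_w), 0.25)

  g_r <- goal("plga", "in_range", 33.3, 100)
  expect_equal(individual_desirability(c(33.3, 50, 100, 101), g_r),
               c(1, 1, 1, 0))
})

test_that("individual desirability is monotone and bounded on random goals", {
  set.seed(19)
  for (i in 1:25) {
    lo <- stats::runif(1, -50, 50)
    hi <- lo + stats::runif(1, 0.5, 100)
    w <- stats::runif(1, 0.2, 5)
    v <- sort(stats::runif(200, lo - 20, hi + 20))
    d_min <- individual_desirability(v, goal("y", "minimize", lo, hi, weight = w))
    d_max <- individual_desirability(v, goal("y", "maximize", lo, hi, weight = w))
    expect_true(all(d_min >= 0 & d_min <= 1))
    expect_true(all(d_max >= 0 & d_max <= 1))
    expect_true(all(diff(d_min) <= 1e-12))
    expect_true(all(diff(d_max) >= -1e-12))
  }
})

test_that("overall desirability is the importance-weighted geometric mean", {
  expect_equal(overall_desirability(c(1, 1, 1)), 1)
  expect_equal(overall_desirability(c(0.9, 0, 1)), 0)
  # one goal at 0.9698 with importance 1 against a saturated goal with 5
  expect_equal(overall_desirability(c(0.9698, 1), c(1L, 5L)),
               0.9698^(1 / 6), tolerance = 1e-6)
  expect_equal(overall_desirability(c(0.9698, 1), c(1L, 5L)), 0.99491,
               tolerance = 1e-4)
  set.seed(23)
  for (i in 1:20) {
    d <- stats::runif(4)
    r <- sample(1:5, 4, replace = TRUE)
    D <- overall_desirability(d, r)
    expect_equal(overall_desirability(d, rep(2L, 4)),
                 prod(d)^(1 / 4), tolerance = 1e-12)
    # D never exceeds the weakest goal's share
    expect_lte(D, min(d)^(r[which.min(d)] / sum(r)) + 1e-12)
    expect_gte(D, 0); expect_lte(D, 1)
  }
  expect_error(overall_desirability(numeric(0)), "nonempty")
  expect_error(overall_desirability(c(0.5, 1.2)), "0, 1")
})

test_that("the optimizer finds the analytic vertex of a concave surface", {
  # interior maximum at coded (-b1/2b11, -b2/2b22, -b3/2b33)
  b_true <- c(10, 1, 0.5, -0.3, 0, 0, 0, -2, -2, -2)
  vertex <- -b_true[2:4] / (2 * b_true[8:10])
  facs <- pln_factors()
  d <- simulate_design_responses(facs, list(y = b_true), noise_sd = 0, seed = 2)
  m <- fit_quadratic(d, "y")
  sol <- optimize_desirability(list(m), list(goal("y", "maximize", 0, 20)),
                               n_starts = 16, seed = 4)
  got <- vapply(1:3, function(j)
    code_setting(facs[[j]], sol[1, factor_names(facs)[j]]), numeric(1))
  expect_equal(got, vertex, tolerance = 1e-3)
})

test_that("the formulation problem is optimized to the reported region", {
  d <- pln_design()
  models <- list(fit_quadratic(d, "particle_size"), fit_quadratic(d, "ee"))
  sol <- optimize_desirability(models, pln_goals(), n_starts = 64, seed = 1)
  top <- sol[1, ]
  expect_lt(abs(top$ee - 75.6), 0.25)
  expect_gte(top$particle_size, 139)
  expect_lte(top$particle_size, 142.5)
  expect_gte(top$poloxamer, 1.3)
  # settings stay inside the factor ranges
  facs <- attr(sol, "factors")
  for (nm in factor_names(facs)) {
    expect_gte(min(sol[[nm]]), facs[[nm]]$low - 1e-8)
    expect_lte(max(sol[[nm]]), facs[[nm]]$high + 1e-8)
  }
  # per-goal desirabilities recompute exactly from the predicted responses
  goals <- pln_goals()
  g_size <- goals[[4]]; g_ee <- goals[[5]]
  expect_equal(sol$d_particle_size,
               individual_desirability(sol$particle_size, g_size))
  expect_equal(sol$d_ee, individual_desirability(sol$ee, g_ee))
  # result is seed-stable at this start count
  sol2 <- optimize_desirability(models, pln_goals(), n_starts = 64, seed = 2)
  expect_equal(sol2$desirability[1], sol$desirability[1], tolerance = 1e-3)
})

test_that("goal bookkeeping is validated", {
  d <- pln_design()
  m <- fit_quadratic(d, "particle_size")
  expect_error(
    optimize_desirability(list(m), list(goal("zeta", "minimize", 0, 1))),
    "unknown")
  expect_error(
    optimize_desirability(list(m), list(goal("plga", "in_range", 33.3, 100))),
    "no goal references")
  expect_error(goal("y", "minimize", 2, 1), "lower < upper")
  expect_error(goal("y", "minimize", 0, 1, importance = 6), "1..5")
  expect_error(goal("y", "minimize", 0, 1, weight = 0), "positive")
})

test_that("design-space masks mark the feasible overlay region", {
  d <- pln_design()
  models <- list(fit_quadratic(d, "particle_size"), fit_quadratic(d, "ee"))
  sp <- design_space(models,
                     list(list("particle_size", "<=", 141), list("ee", ">=", 75.5)),
                     grid_resolution = 41)
  expect_gt(sp$volume_fraction, 0)
  # the first reported solution satisfies both constraints...
  at <- c(plga = 72.1, lecithin = 86.8, poloxamer = 1.5)
  expect_lte(as.numeric(predict_response(models[[1]], at)), 141)
  expect_gte(as.numeric(predict_response(models[[2]], at)), 75.5)
  # ...and sits next to a feasible grid point
  feas <- sp$grid[sp$grid$feasible, ]
  dist <- sqrt(((feas$plga - 72.1) / 33.33)^2 +
               ((feas$lecithin - 86.8) / 66.665)^2 +
               ((feas$poloxamer - 1.5) / 0.5)^2)
  expect_lt(min(dist), 0.15)

  empty <- design_space(models, list(list("particle_size", "<=", 0)), 11)
  expect_equal(empty$volume_fraction, 0)
  expect_false(any(empty$grid$feasible))

  # the feasible volume stabilizes under grid refinement
  coarse <- design_space(models,
                         list(list("particle_size", "<=", 160), list("ee", ">=", 70)),
                         grid_resolution = 21)
  fine <- design_space(models,
                       list(list("particle_size", "<=", 160), list("ee", ">=", 70)),
                       grid_resolution = 101)
  expect_lt(abs(coarse$volume_fraction - fine$volume_fraction), 0.05)

  expect_error(design_space(models, list(list("particle_size", "=<", 1))),
               "comparator")
  expect_error(design_space(models, list(list("pdi", "<=", 1))), "unfitted")
})
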