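test_that("quadratic fit to the study design matches the normal-equations oracle", {
  d <- pln_design()
  cm <- as.matrix(d[, c("plga_coded", "lecithin_coded", "poloxamer_coded")])
  for (resp in c("particle_size", "ee")) {
    m <- fit_quadratic(d, resp)
    oracle <- ne_quadratic(cm, d[[resp]])
    expect_equal(unname(coef(m)), unname(oracle), tolerance = 1e-8)
  }
  # for a Box-Behnken design the intercept is the center-run mean
  ms <- fit_quadratic(d, "particle_size")
  expect_equal(coef(ms)[["b0"]], mean(c(150, 151, 149)), tolerance = 1e-10)
  expect_gte(ms$r_squared, 0)
  expect_lte(ms$r_squared, 1)
  expect_equal(ms$df_residual, 15 - 10)
})

test_that("fitting is invariant to run order", {
  d <- pln_design()
  set.seed(7)
  shuf <- d[sample(nrow(d)), ]
  attr(shuf, "factors") <- attr(d, "factors")
  class(shuf) <- class(d)
  expect_equal(coef(fit_quadratic(shuf, "ee")),
               coef(fit_quadratic(d, "ee")), tolerance = 1e-10)
})

test_that("a noiseless synthetic surface is recovered exactly", {
  b_true <- c(150, 8, -4, 2.5, 3, -1, 0.5, 6, -2, 1.5)
  d <- simulate_design_responses(pln_factors(), list(y = b_true),
                                 noise_sd = 0, seed = 11)
  m <- fit_quadratic(d, "y")
  expect_equal(unname(coef(m)), b_true, tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
})

test_that("predictions reproduce the reported solution responses", {
  d <- pln_design()
  ms <- fit_quadratic(d, "particle_size")
  me <- fit_quadratic(d, "ee")
  sols <- reported_solutions()
  for (i in seq_len(nrow(sols))) {
    at <- c(plga = sols$plga[i], lecithin = sols$lecithin[i],
            poloxamer = sols$poloxamer[i])
    expect_equal(as.numeric(predict_response(ms, at)),
                 sols$particle_size[i], tolerance = 0.5 / sols$particle_size[i])
    expect_equal(as.numeric(predict_response(me, at)),
                 sols$ee[i], tolerance = 0.25 / sols$ee[i])
  }
  # at the all-center setting every coded term vanishes: prediction is b0
  center <- c(plga = 66.67, lecithin = 133.34, poloxamer = 1.0)
  expect_equal(as.numeric(predict_response(ms, center)), coef(ms)[["b0"]])
})

test_that("prediction flags extrapolation and validates settings", {
  m <- fit_quadratic(pln_design(), "particle_size")
  expect_error(predict_response(m, c(plga = 50, lecithin = 100)), "missing|one setting")
  expect_warning(p <- predict_response(m, c(plga = 300, lecithin = 133, poloxamer = 1)),
                 "extrapolation")
  expect_true(attr(p, "extrapolated"))
  p2 <- predict_response(m, c(plga = 66.67, lecithin = 133.34, poloxamer = 1))
  expect_false(attr(p2, "extrapolated"))
})

test_that("fit preconditions are enforced", {
  d <- pln_design()
  expect_error(fit_quadratic(d, "zeta"), "not found")
  small <- d[1:9, ]
  attr(small, "factors") <- attr(d, "factors")
  class(small) <- class(d)
  expect_error(fit_quadratic(small, "ee"), ">= 10 runs")
  # duplicate-only points cannot support 10 terms
  dup <- design_table(pln_factors(), matrix(0, 12, 3),
                      responses = data.frame(y = rnorm(12)))
  expect_error(fit_quadratic(dup, "y"), "rank deficient")
})

test_that("checkpoint analysis tabulates observed vs predicted", {
  d <- pln_design()
  m <- fit_quadratic(d, "particle_size")
  centers <- d[13:15, ]
  attr(centers, "factors") <- attr(d, "factors")
  class(centers) <- class(d)
  ck <- checkpoint_analysis(m, centers)
  expect_equal(ck$predicted, rep(coef(m)[["b0"]], 3))
  expect_equal(ck$residual, c(150, 151, 149) - coef(m)[["b0"]])
  expect_equal(ck$relative_error, abs(ck$residual) / ck$observed)
  # against the fitted design itself residuals average to zero (OLS)
  full <- checkpoint_analysis(m, d)
  expect_equal(mean(full$residual), 0, tolerance = 1e-8)
  # noiseless off-design checkpoints are predicted exactly
  b_true <- c(100, 5, -2, 1, 0.5, 0, -0.5, 3, 2, -1)
  sim <- simulate_design_responses(pln_factors(), list(y = b_true),
                                   noise_sd = 0, seed = 3)
  ms <- fit_quadratic(sim, "y")
  set.seed(5)
  coded <- matrix(stats::runif(30, -1, 1), 10, 3)
  cps <- design_table(pln_factors(), coded,
                      responses = data.frame(y = quad_eval(b_true, coded)))
  ck2 <- checkpoint_analysis(ms, cps)
  expect_lt(max(abs(ck2$residual)), 1e-8)
  expect_error(checkpoint_analysis(m, d[0, ]), "empty")
})

test_that("models round-trip through the flat text record", {
  m <- fit_quadratic(pln_design(), "ee")
  path <- withr::local_tempfile(fileext = ".txt")
  write_quadratic_model(m, path)
  back <- read_quadratic_model(path)
  expect_equal(coef(back), coef(m), tolerance = 1e-14)
  expect_identical(back$response_name, "ee")
  expect_equal(back$r_squared, m$r_squared, tolerance = 1e-14)
  at <- c(plga = 67.5, lecithin = 69.9, poloxamer = 1.5)
  expect_equal(as.numeric(predict_response(back, at)),
               as.numeric(predict_response(m, at)), tolerance = 1e-12)
})
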