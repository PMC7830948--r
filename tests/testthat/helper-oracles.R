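# Independent oracles used across the test files.

# Brute-force OLS for the 10-term quadratic model: explicit normal equations
# on the coded design matrix, independent of fit_quadratic()'s lm() path.
ne_quadratic <- function(coded, y) {
  X <- cbind(1, coded[, 1], coded[, 2], coded[, 3],
             coded[, 1] * coded[, 2], coded[, 1] * coded[, 3],
             coded[, 2] * coded[, 3],
             coded[, 1]^2, coded[, 2]^2, coded[, 3]^2)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Evaluate a 10-coefficient quadratic at coded rows.
quad_eval <- function(b, coded) {
  coded <- matrix(coded, ncol = 3)
  X <- cbind(1, coded[, 1], coded[, 2], coded[, 3],
             coded[, 1] * coded[, 2], coded[, 1] * coded[, 3],
             coded[, 2] * coded[, 3],
             coded[, 1]^2, coded[, 2]^2, coded[, 3]^2)
  drop(X %*% b)
}

# Exhaustive grid search for the overall-desirability optimum of the
# two-response formulation problem, on a regular coded grid over the
# optimizer's box (factor ranges intersected with in_range factor goals).
# Returns the best D found.  Scans one x1 slice at a time to bound memory.
grid_search_D <- function(size_model, ee_model, goals, step = 0.01) {
  factors <- size_model$factors
  fac_goals <- Filter(function(g) g$kind == "in_range" &&
                        g$name %in% names(factors), goals)
  resp_goals <- Filter(function(g) g$name %in% c(size_model$response_name,
                                                 ee_model$response_name),
                       goals)
  bounds <- lapply(factors, function(f) {
    lo <- f$low; hi <- f$high
    for (g in fac_goals) if (g$name == f$name) {
      lo <- max(lo, g$lower); hi <- min(hi, g$upper)
    }
    c(code_setting(f, lo), code_setting(f, hi))
  })
  ax <- lapply(bounds, function(b) unique(c(seq(b[1], b[2], by = step), b[2])))
  g_size <- Filter(function(g) g$name == size_model$response_name, resp_goals)[[1]]
  g_ee <- Filter(function(g) g$name == ee_model$response_name, resp_goals)[[1]]
  denom <- sum(vapply(c(resp_goals, fac_goals), `[[`, integer(1), "importance"))
  best <- 0
  slice <- expand.grid(x2 = ax[[2]], x3 = ax[[3]])
  for (x1 in ax[[1]]) {
    cm <- cbind(x1, slice$x2, slice$x3)
    ps <- quad_eval(size_model$coefficients, cm)
    pe <- quad_eval(ee_model$coefficients, cm)
    d1 <- individual_desirability(ps, g_size)
    d2 <- individual_desirability(pe, g_ee)
    ok <- d1 > 0 & d2 > 0
    if (any(ok)) {
      D <- exp((g_size$importance * log(d1[ok]) +
                g_ee$importance * log(d2[ok])) / denom)
      best <- max(best, D)
    }
  }
  best
}

# The three optimizer solutions reported by the original study's software:
# settings in actual units and the predictions printed alongside them.
reported_solutions <- function() {
  data.frame(
    plga = c(72.1, 67.5, 70.9),
    lecithin = c(86.8, 69.9, 78.6),
    poloxamer = c(1.5, 1.5, 1.4),
    particle_size = c(139.089, 141.145, 141.817),
    ee = c(75.6, 75.6002, 75.6)
  )
}
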