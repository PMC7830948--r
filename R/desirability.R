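#' Define a desirability goal
#'
#' A goal maps one predicted response (or one design factor) onto a [0, 1]
#' desirability scale in the Derringer-Suich fashion:
#' * `minimize`: d = 1 at or below `lower`, 0 at or above `upper`, and
#'   `((upper - value)/(upper - lower))^weight` in between;
#' * `maximize`: the mirror image, `((value - lower)/(upper - lower))^weight`;
#' * `in_range`: d = 1 inside `[lower, upper]`, 0 outside (a hard box
#'   constraint, typically applied to the design factors themselves).
#'
#' `importance` is the exponent the goal carries in the weighted geometric
#' mean that combines goals into the overall desirability D.
#'
#' @param name Response or factor name the goal applies to.
#' @param kind One of `"minimize"`, `"maximize"`, `"in_range"`.
#' @param lower,upper Goal limits (`lower < upper`).
#' @param weight Curvature exponent of the individual desirability (> 0).
#' @param importance Integer 1-5.
#' @return An object of class `goal`.
#' @export
goal <- function(name, kind = c("minimize", "maximize", "in_range"),
                 lower, upper, weight = 1, importance = 1) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a nonempty string", call. = FALSE)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop(sprintf("goal '%s': need finite lower < upper", name), call. = FALSE)
  if (!is.finite(weight) || weight <= 0)
    stop(sprintf("goal '%s': weight must be positive", name), call. = FALSE)
  if (!importance %in% 1:5)
    stop(sprintf("goal '%s': importance must be an integer in 1..5", name),
         call. = FALSE)
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 weight = weight, importance = as.integer(importance)),
            class = "goal")
}

#' @export
print.goal <- function(x, ...) {
  cat(sprintf("Goal: %s %s in [%g, %g], weight %g, importance %d\n",
              x$kind, x$name, x$lower, x$upper, x$weight, x$importance))
  invisible(x)
}

#' Read desirability goals from a CSV file
#'
#' Expects columns `name, goal, lower, upper, lower_weight, upper_weight,
#' importance` (mirroring the goal table of common DoE software).  For the
#' one-sided goals only one weight is active: the lower weight for
#' `maximize`, the upper weight for `minimize`; `in_range` goals use neither.
#'
#' @param path CSV file path.
#' @return List of [goal()] objects.
#' @export
read_goals <- function(path) {
  df <- utils::read.csv(path)
  lapply(seq_len(nrow(df)), function(i) {
    kind <- df$goal[i]
    wt <- switch(kind, maximize = df$lower_weight[i],
                 minimize = df$upper_weight[i], 1)
    goal(df$name[i], kind, df$lower[i], df$upper[i], weight = wt,
         importance = df$importance[i])
  })
}

#' Individual desirability of a value under a goal
#'
#' @param value Numeric vector of response (or factor) values.
#' @param goal A [goal()].
#' @return Desirabilities in [0, 1], vectorized over `value`.
#' @examples
#' g <- goal("particle_size", "minimize", 139, 210)
#' individual_desirability(c(139, 210, 141.145), g)
#' @export
individual_desirability <- function(value, goal) {
  span <- goal$upper - goal$lower
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  switch(goal$kind,
    minimize = clamp01((goal$upper - value) / span)^goal$weight,
    maximize = clamp01((value - goal$lower) / span)^goal$weight,
    in_range = as.numeric(value >= goal$lower & value <= goal$upper)
  )
}

#' Overall desirability: importance-weighted geometric mean
#'
#' \deqn{D = \left(\prod_i d_i^{r_i}\right)^{1/\sum_i r_i}}
#' With equal importances this reduces to the plain geometric mean; any zero
#' individual desirability forces D = 0.
#'
#' @param d Numeric vector of individual desirabilities in [0, 1].
#' @param importance Integer vector of importances (same length as `d`).
#' @return Overall desirability in [0, 1].
#' @export
overall_desirability <- function(d, importance = rep(1L, length(d))) {
  if (!length(d) || length(d) != length(importance))
    stop("'d' and 'importance' must be nonempty and of equal length",
         call. = FALSE)
  if (any(d < 0 | d > 1))
    stop("individual desirabilities must lie in [0, 1]", call. = FALSE)
  if (any(d == 0)) return(0)
  exp(sum(importance * log(d)) / sum(importance))
}

# Split goals into response goals (matched to models) and factor box goals.
split_goals <- function(goals, models, factors) {
  resp_names <- vapply(models, `[[`, character(1), "response_name")
  fac_names <- factor_names(factors)
  is_resp <- vapply(goals, function(g) g$name %in% resp_names, logical(1))
  is_fac <- vapply(goals, function(g) g$name %in% fac_names, logical(1))
  bad <- !(is_resp | is_fac)
  if (any(bad))
    stop("goal(s) reference unknown response/factor: ",
         paste(vapply(goals[bad], `[[`, character(1), "name"), collapse = ", "),
         call. = FALSE)
  list(response = goals[is_resp], factor = goals[is_fac])
}

#' Optimize factor settings by overall desirability
#'
#' Maximizes the overall desirability D over the factor cuboid by multi-start
#' bounded quasi-Newton (L-BFGS-B) search from Latin-hypercube start points.
#' Response goals are scored through the supplied fitted models; `in_range`
#' goals on design factors act as hard box constraints (desirability 1 inside
#' their range) and, by default, their importances still enter the geometric
#' mean denominator, matching common DoE-software behavior -- with d = 1 this
#' rescales D monotonically and cannot reorder solutions.
#'
#' Local optima closer than `dedup_radius` in coded units are merged;
#' solutions are ranked by D (descending), ties broken by the predicted value
#' of the first `minimize` goal (ascending).  Deterministic for a fixed seed.
#'
#' @param models List of `quadratic_model` objects sharing one factor set.
#' @param goals List of [goal()] objects; every response goal must name a
#'   fitted model's response.
#' @param n_starts Number of Latin-hypercube start points (>= 1; 64 or more
#'   makes the result effectively seed-independent on smooth quadratics).
#' @param seed Integer seed for the start points.
#' @param include_range_importance Count the importances of factor
#'   `in_range` goals in the D denominator (default `TRUE`).
#' @param dedup_radius Coded-distance threshold below which two local optima
#'   are considered the same solution.
#' @return A `desirability_solutions` data frame: one row per distinct local
#'   optimum with `rank`, actual factor settings, predicted responses,
#'   per-goal desirabilities (`d_<name>`), and `desirability` (D).
#' @examples
#' d <- pln_design()
#' models <- list(fit_quadratic(d, "particle_size"), fit_quadratic(d, "ee"))
#' sol <- optimize_desirability(models, pln_goals(), n_starts = 64, seed = 1)
#' sol[1, ]
#' @export
optimize_desirability <- function(models, goals, n_starts = 64, seed = 1,
                                  include_range_importance = TRUE,
                                  dedup_radius = 0.02) {
  if (!length(models)) stop("at least one model is required", call. = FALSE)
  factors <- models[[1]]$factors
  nms <- factor_names(factors)
  for (m in models[-1])
    if (!identical(factor_names(m$factors), nms))
      stop("all models must share the same factors", call. = FALSE)
  if (n_starts < 1) stop("'n_starts' must be >= 1", call. = FALSE)
  gs <- split_goals(goals, models, factors)
  if (!length(gs$response))
    stop("no goal references a fitted response", call. = FALSE)

  k <- length(factors)
  lb <- ub <- numeric(k)
  for (j in seq_len(k)) {
    f <- factors[[j]]
    lo <- f$low; hi <- f$high
    for (g in gs$factor) if (g$name == f$name) {
      lo <- max(lo, g$lower); hi <- min(hi, g$upper)
    }
    lb[j] <- code_setting(f, lo); ub[j] <- code_setting(f, hi)
  }

  resp_goal_imp <- vapply(gs$response, `[[`, integer(1), "importance")
  fac_goal_imp <- vapply(gs$factor, `[[`, integer(1), "importance")
  denom <- sum(resp_goal_imp) +
    if (include_range_importance) sum(fac_goal_imp) else 0
  model_by_resp <- stats::setNames(models,
    vapply(models, `[[`, character(1), "response_name"))

  predict_at <- function(x) {
    tm <- quad_terms(matrix(x, nrow = 1))
    vapply(model_by_resp, function(m) drop(tm %*% m$coefficients), numeric(1))
  }
  d_of <- function(preds) {
    vapply(gs$response, function(g)
      individual_desirability(preds[[g$name]], g), numeric(1))
  }
  D_of <- function(x) {
    d <- d_of(predict_at(x))
    if (any(d == 0)) return(0)
    exp(sum(resp_goal_imp * log(d)) / denom)
  }

  set.seed(seed)
  starts <- lhs::randomLHS(n_starts, k)
  starts <- sweep(sweep(starts, 2, ub - lb, `*`), 2, lb, `+`)

  opts <- lapply(seq_len(n_starts), function(i) {
    res <- stats::optim(starts[i, ], function(x) -D_of(x), method = "L-BFGS-B",
                        lower = lb, upper = ub)
    list(x = res$par, D = -res$value)
  })

  ord <- order(-vapply(opts, `[[`, numeric(1), "D"))
  kept <- list()
  for (o in opts[ord]) {
    dup <- any(vapply(kept, function(kpt)
      sqrt(sum((kpt$x - o$x)^2)) < dedup_radius, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- o
  }

  first_min <- Filter(function(g) g$kind == "minimize", gs$response)
  tiebreak_resp <- if (length(first_min)) first_min[[1]]$name else NULL

  rows <- lapply(kept, function(o) {
    preds <- predict_at(o$x)
    d <- d_of(preds)
    actual <- vapply(seq_len(k), function(j)
      decode_setting(factors[[j]], o$x[j]), numeric(1))
    row <- c(stats::setNames(as.list(actual), nms),
             as.list(preds),
             stats::setNames(as.list(d), paste0("d_", names(preds))),
             list(desirability = o$D))
    as.data.frame(row, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  o2 <- if (!is.null(tiebreak_resp))
    order(-round(out$desirability, 9), out[[tiebreak_resp]]) else
    order(-round(out$desirability, 9))
  out <- out[o2, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("desirability_solutions", "data.frame"),
            factors = factors)
}

#' Map the feasible design space (overlay region)
#'
#' Evaluates every fitted response on a regular actual-units grid over the
#' factor cuboid and marks the settings where all constraints hold -- the
#' gray region of the classical overlay plot.
#'
#' @param models List of `quadratic_model` objects sharing one factor set.
#' @param constraints List of constraints, each a list or vector of
#'   `(response, comparator, threshold)` with comparator one of
#'   `"<=", "<", ">=", ">"`, e.g. `list("particle_size", "<=", 141)`.
#' @param grid_resolution Grid points per factor axis (>= 2, default 21).
#' @return A list with `grid` (data frame of actual factor settings, the
#'   predicted responses, and logical `feasible`), `volume_fraction` (share
#'   of feasible grid points), and `resolution`.
#' @export
design_space <- function(models, constraints, grid_resolution = 21) {
  if (!length(models)) stop("at least one model is required", call. = FALSE)
  if (grid_resolution < 2) stop("'grid_resolution' must be >= 2", call. = FALSE)
  factors <- models[[1]]$factors
  nms <- factor_names(factors)
  resp_names <- vapply(models, `[[`, character(1), "response_name")
  cons <- lapply(constraints, function(cn) {
    cn <- as.list(cn)
    if (length(cn) != 3L)
      stop("each constraint is (response, comparator, threshold)", call. = FALSE)
    if (!cn[[1]] %in% resp_names)
      stop("constraint references unfitted response: ", cn[[1]], call. = FALSE)
    if (!cn[[2]] %in% c("<=", "<", ">=", ">"))
      stop("comparator must be one of <=, <, >=, >", call. = FALSE)
    list(response = cn[[1]], op = cn[[2]], threshold = as.numeric(cn[[3]]))
  })

  axes <- lapply(factors, function(f) seq(f$low, f$high, length.out = grid_resolution))
  grid <- do.call(expand.grid, stats::setNames(axes, nms))
  cm <- vapply(seq_along(nms), function(j)
    code_setting(factors[[j]], grid[[j]]), numeric(nrow(grid)))
  cm <- matrix(cm, nrow = nrow(grid))

  feasible <- rep(TRUE, nrow(grid))
  # evaluate in chunks so large grids stay memory-bounded
  chunk <- 250000L
  preds <- matrix(NA_real_, nrow(grid), length(models),
                  dimnames = list(NULL, resp_names))
  for (s in seq(1L, nrow(grid), by = chunk)) {
    idx <- s:min(s + chunk - 1L, nrow(grid))
    tm <- quad_terms(cm[idx, , drop = FALSE])
    for (m in models)
      preds[idx, m$response_name] <- drop(tm %*% m$coefficients)
  }
  for (cn in cons) {
    v <- preds[, cn$response]
    feasible <- feasible & switch(cn$op,
      "<=" = v <= cn$threshold, "<" = v < cn$threshold,
      ">=" = v >= cn$threshold, ">" = v > cn$threshold)
  }
  grid <- cbind(grid, as.data.frame(preds))
  grid$feasible <- feasible
  list(grid = grid, volume_fraction = mean(feasible),
       resolution = grid_resolution)
}
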