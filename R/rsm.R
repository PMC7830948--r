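#' Fit the full quadratic response-surface model
#'
#' Fits, by ordinary least squares on the coded factor levels, the 10-term
#' second-order polynomial
#' \deqn{Y = b_0 + b_1 x_1 + b_2 x_2 + b_3 x_3 + b_{12} x_1 x_2 +
#'   b_{13} x_1 x_3 + b_{23} x_2 x_3 + b_{11} x_1^2 + b_{22} x_2^2 +
#'   b_{33} x_3^2}
#' to one response of a three-factor design.  Responses are per-run means;
#' any `<response>_sd` column is metadata and does not weight the fit.
#' Fitting on coded levels makes coefficients directly comparable across
#' factors; predictions are unaffected by the choice of scale.
#'
#' @param design A [design_table()] with at least 10 runs carrying
#'   non-missing values of `response_name`.
#' @param response_name Name of the response column to fit.
#' @return A `quadratic_model`: the named coefficient vector (`b0`, `b1`,
#'   `b2`, `b3`, `b12`, `b13`, `b23`, `b11`, `b22`, `b33`, in response units
#'   on the coded scale), the factor specifications, and fit diagnostics
#'   (`r_squared`, `adj_r_squared`, `sigma`, `df_residual`, `f_statistic`,
#'   `p_value`).
#' @examples
#' m <- fit_quadratic(pln_design(), "particle_size")
#' coef(m)[["b0"]]  # center-run mean
#' @export
fit_quadratic <- function(design, response_name) {
  factors <- design_factors(design)
  if (length(factors) != 3L)
    stop("quadratic fit requires a 3-factor design", call. = FALSE)
  if (!response_name %in% names(design))
    stop(sprintf("response '%s' not found in design", response_name), call. = FALSE)
  y <- design[[response_name]]
  ok <- !is.na(y)
  if (sum(ok) < 10L)
    stop(sprintf("need >= 10 runs with non-missing '%s' to fit 10 terms (got %d)",
                 response_name, sum(ok)), call. = FALSE)
  cm <- coded_matrix(design)[ok, , drop = FALSE]
  dat <- data.frame(y = y[ok], x1 = cm[, 1], x2 = cm[, 2], x3 = cm[, 3])
  fit <- stats::lm(y ~ x1 + x2 + x3 + x1:x2 + x1:x3 + x2:x3 +
                     I(x1^2) + I(x2^2) + I(x3^2), data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("design is rank deficient for the quadratic model ",
         "(degenerate or duplicate-only points)", call. = FALSE)
  # lm orders main effects, squares, then interactions; reorder to the
  # conventional b0, linear, interaction, quadratic layout.
  cf <- cf[c("(Intercept)", "x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
             "I(x1^2)", "I(x2^2)", "I(x3^2)")]
  names(cf) <- c("b0", "b1", "b2", "b3", "b12", "b13", "b23",
                 "b11", "b22", "b33")
  # diagnostics computed directly (a noiseless surface fits exactly and
  # summary.lm() warns on perfect fits)
  res <- stats::residuals(fit)
  yy <- dat$y
  rss <- sum(res^2)
  tss <- sum((yy - mean(yy))^2)
  dfr <- fit$df.residual
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  p <- 10L
  fstat <- if (dfr > 0 && rss > 0)
    ((tss - rss) / (p - 1)) / (rss / dfr) else NA_real_
  structure(
    list(
      response_name = response_name,
      coefficients = cf,
      factors = factors,
      r_squared = r2,
      adj_r_squared = if (dfr > 0) 1 - (1 - r2) * (length(yy) - 1) / dfr
        else NA_real_,
      sigma = if (dfr > 0) sqrt(rss / dfr) else NA_real_,
      df_residual = dfr,
      f_statistic = fstat,
      p_value = if (is.finite(fstat))
        stats::pf(fstat, p - 1, dfr, lower.tail = FALSE) else NA_real_
    ),
    class = "quadratic_model"
  )
}

#' @export
coef.quadratic_model <- function(object, ...) object$coefficients

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Quadratic response-surface model for '%s' (coded factors: %s)\n",
              x$response_name, paste(factor_names(x$factors), collapse = ", ")))
  print(round(x$coefficients, 6))
  cat(sprintf("R2 %.4f | adj R2 %.4f | residual SD %.4g on %d df\n",
              x$r_squared, x$adj_r_squared, x$sigma, x$df_residual))
  invisible(x)
}

# Quadratic model matrix from coded levels (rows of a 3-column matrix).
quad_terms <- function(cm) {
  cbind(1, cm[, 1], cm[, 2], cm[, 3],
        cm[, 1] * cm[, 2], cm[, 1] * cm[, 3], cm[, 2] * cm[, 3],
        cm[, 1]^2, cm[, 2]^2, cm[, 3]^2)
}

# Settings (named or positional, actual units) -> coded row matrix.
settings_to_coded <- function(factors, settings) {
  nms <- factor_names(factors)
  if (is.list(settings)) settings <- unlist(settings)
  if (!is.null(names(settings)) && any(nzchar(names(settings)))) {
    miss <- setdiff(nms, names(settings))
    if (length(miss))
      stop("missing settings for factor(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    settings <- settings[nms]
  } else if (length(settings) != length(nms)) {
    stop("provide one setting per factor (", length(nms), ")", call. = FALSE)
  }
  if (!all(is.finite(settings)))
    stop("factor settings must be finite", call. = FALSE)
  matrix(vapply(seq_along(nms), function(j)
    code_setting(factors[[j]], settings[[j]]), numeric(1)), nrow = 1)
}

#' Predict a response at given factor settings
#'
#' Codes the actual-unit settings and evaluates the fitted polynomial.
#' Settings far outside the design cuboid (any coded magnitude above 2) are
#' flagged as extrapolation via the `"extrapolated"` attribute and a warning,
#' but still evaluated.
#'
#' @param model A `quadratic_model` from [fit_quadratic()].
#' @param settings Named numeric vector (or list) of actual factor settings,
#'   one per model factor.
#' @return Predicted response (scalar) with attribute `extrapolated`.
#' @examples
#' m <- fit_quadratic(pln_design(), "particle_size")
#' predict_response(m, c(plga = 67.5, lecithin = 69.9, poloxamer = 1.5))
#' @export
predict_response <- function(model, settings) {
  cm <- settings_to_coded(model$factors, settings)
  extra <- max(abs(cm)) > 2
  if (extra)
    warning("settings lie far outside the design cuboid (|coded| > 2); ",
            "prediction is an extrapolation", call. = FALSE)
  val <- drop(quad_terms(cm) %*% model$coefficients)
  attr(val, "extrapolated") <- extra
  val
}

#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  if (inherits(newdata, "design_table")) {
    drop(quad_terms(coded_matrix(newdata)) %*% object$coefficients)
  } else {
    nms <- factor_names(object$factors)
    newdata <- as.data.frame(newdata)
    cm <- vapply(seq_along(nms), function(j)
      code_setting(object$factors[[j]], newdata[[nms[j]]]),
      numeric(nrow(newdata)))
    drop(quad_terms(matrix(cm, nrow = nrow(newdata))) %*% object$coefficients)
  }
}

#' Checkpoint analysis of a fitted model
#'
#' Evaluates the fitted polynomial at extra runs carrying observed response
#' values and tabulates observed vs predicted, the residual, and the relative
#' error `|obs - pred| / |obs|` -- the standard check that the derived
#' polynomial predicts settings it was not necessarily fitted to.
#'
#' @param model A `quadratic_model`.
#' @param checkpoints A [design_table()] with observed values of the model's
#'   response.
#' @return Data frame with columns `run_id`, `observed`, `predicted`,
#'   `residual`, `relative_error`.
#' @export
checkpoint_analysis <- function(model, checkpoints) {
  if (nrow(checkpoints) == 0L)
    stop("checkpoint set is empty", call. = FALSE)
  if (!model$response_name %in% names(checkpoints))
    stop(sprintf("checkpoints carry no '%s' column", model$response_name),
         call. = FALSE)
  obs <- checkpoints[[model$response_name]]
  pred <- drop(quad_terms(coded_matrix(checkpoints)) %*% model$coefficients)
  data.frame(
    run_id = checkpoints$run_id,
    observed = obs,
    predicted = pred,
    residual = obs - pred,
    relative_error = abs(obs - pred) / abs(obs),
    stringsAsFactors = FALSE
  )
}

#' Serialize a quadratic model as a flat text record
#'
#' Key-value lines (`key: value`) covering the response name, factor
#' definitions, the 10 coefficients, and diagnostics, so fitted models are
#' diffable and round-trip exactly via full-precision formatting.
#'
#' @param model A `quadratic_model`.
#' @param path File path.
#' @return `write_quadratic_model()` returns `path` invisibly;
#'   `read_quadratic_model()` returns the model.
#' @export
write_quadratic_model <- function(model, path) {
  num <- function(x) formatC(x, digits = 17, format = "g")
  lines <- c(
    paste0("response: ", model$response_name),
    vapply(model$factors, function(f)
      sprintf("factor: %s|%s|%s|%s|%s", f$name, f$units,
              num(f$low), num(f$center), num(f$high)), character(1)),
    vapply(names(model$coefficients), function(k)
      paste0(k, ": ", num(model$coefficients[[k]])), character(1)),
    paste0("r_squared: ", num(model$r_squared)),
    paste0("adj_r_squared: ", num(model$adj_r_squared)),
    paste0("sigma: ", num(model$sigma)),
    paste0("df_residual: ", model$df_residual),
    paste0("f_statistic: ", num(model$f_statistic)),
    paste0("p_value: ", num(model$p_value))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_quadratic_model
#' @export
read_quadratic_model <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr("^[^:]+", lines))
  val <- sub("^[^:]+: ?", "", lines)
  get1 <- function(k) val[match(k, kv)]
  facs <- lapply(val[kv == "factor"], function(s) {
    p <- strsplit(s, "|", fixed = TRUE)[[1]]
    factor_spec(p[1], as.numeric(p[3]), as.numeric(p[4]), as.numeric(p[5]),
                units = p[2])
  })
  cn <- c("b0", "b1", "b2", "b3", "b12", "b13", "b23", "b11", "b22", "b33")
  cf <- vapply(cn, function(k) as.numeric(get1(k)), numeric(1))
  structure(
    list(
      response_name = get1("response"),
      coefficients = cf,
      factors = check_factor_list(facs),
      r_squared = as.numeric(get1("r_squared")),
      adj_r_squared = as.numeric(get1("adj_r_squared")),
      sigma = as.numeric(get1("sigma")),
      df_residual = as.integer(get1("df_residual")),
      f_statistic = as.numeric(get1("f_statistic")),
      p_value = as.numeric(get1("p_value"))
    ),
    class = "quadratic_model"
  )
}
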