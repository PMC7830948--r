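#' Construct a design table
#'
#' A design table is a data frame with one row per experimental run and, for
#' each factor, a `<name>_coded` and `<name>_actual` column, plus optional
#' response columns (and `<response>_sd` standard-deviation columns, carried
#' as metadata).  The factor specifications travel with the table as an
#' attribute so downstream fits know the coding.
#'
#' Coded and actual levels of every run must agree under the coding transform
#' to within `tol` coded units; coded magnitudes above `1 + tol` are rejected
#' for design runs (checkpoint runs anywhere inside the cuboid are fine).
#'
#' @param factors List of [factor_spec()] (distinct names).
#' @param coded Numeric matrix of coded levels, one column per factor.
#' @param actual Optional matrix of actual levels; derived from `coded` when
#'   omitted.
#' @param responses Optional data frame (or named list) of response columns.
#' @param run_id Optional character vector of run labels.
#' @param tol Consistency/containment tolerance in coded units.
#' @return A `design_table` (also a data frame).
#' @export
design_table <- function(factors, coded, actual = NULL, responses = NULL,
                         run_id = NULL, tol = 1e-3) {
  factors <- check_factor_list(factors)
  coded <- as.matrix(coded)
  k <- length(factors)
  if (ncol(coded) != k)
    stop("'coded' must have one column per factor", call. = FALSE)
  n <- nrow(coded)
  if (max(abs(coded)) > 1 + tol)
    stop("coded levels must lie within [-1, +1] (tolerance ", tol, ")",
         call. = FALSE)
  if (is.null(actual)) {
    actual <- vapply(seq_len(k), function(j) decode_setting(factors[[j]], coded[, j]),
                     numeric(n))
    actual <- matrix(actual, nrow = n)
  } else {
    actual <- as.matrix(actual)
    for (j in seq_len(k)) {
      back <- code_setting(factors[[j]], actual[, j])
      if (max(abs(back - coded[, j])) > tol)
        stop(sprintf("actual and coded levels disagree for factor '%s'",
                     factors[[j]]$name), call. = FALSE)
    }
  }
  if (is.null(run_id)) run_id <- sprintf("run%02d", seq_len(n))
  nms <- factor_names(factors)
  out <- data.frame(run_id = run_id, stringsAsFactors = FALSE)
  for (j in seq_len(k)) out[[paste0(nms[j], "_coded")]] <- coded[, j]
  for (j in seq_len(k)) out[[paste0(nms[j], "_actual")]] <- actual[, j]
  if (!is.null(responses)) {
    responses <- as.data.frame(responses)
    if (anyDuplicated(names(responses)))
      stop("response names must be unique", call. = FALSE)
    for (nm in names(responses)) out[[nm]] <- responses[[nm]]
  }
  structure(out, factors = factors, class = c("design_table", "data.frame"))
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Design table: %d runs x %d factors (%s)\n", nrow(x),
              length(attr(x, "factors")),
              paste(factor_names(attr(x, "factors")), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

design_factors <- function(design) {
  f <- attr(design, "factors")
  if (is.null(f)) stop("not a design_table: missing factor attribute", call. = FALSE)
  f
}

coded_matrix <- function(design) {
  nms <- factor_names(design_factors(design))
  as.matrix(design[, paste0(nms, "_coded"), drop = FALSE])
}

#' Generate a three-factor Box-Behnken design
#'
#' Builds the classical 3-factor Box-Behnken design: the 12 edge midpoints --
#' all four (+/-1, +/-1) combinations over each of the three factor pairs with
#' the remaining factor at its center -- followed by replicated center runs.
#' With 3 center replicates this gives the standard 15-run design.  Runs are
#' emitted in factor-pair order (1-2, 1-3, 2-3), then the centers; run order
#' carries no meaning for the fitted model.
#'
#' Only the 3-factor construction is supported.
#'
#' @param factors List of exactly 3 [factor_spec()] objects.
#' @param center_replicates Number of center-point runs (>= 1, default 3).
#' @return A [design_table()] with empty response columns.
#' @examples
#' facs <- pln_factors()
#' d <- bbd_design(facs)
#' nrow(d)  # 15
#' @export
bbd_design <- function(factors, center_replicates = 3) {
  factors <- check_factor_list(factors)
  if (length(factors) != 3L)
    stop("only the 3-factor Box-Behnken design is supported (got ",
         length(factors), " factors)", call. = FALSE)
  if (!is.numeric(center_replicates) || length(center_replicates) != 1L ||
      center_replicates < 1 || center_replicates != round(center_replicates))
    stop("'center_replicates' must be a positive integer", call. = FALSE)
  pm <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  edge <- function(i, j) {
    m <- matrix(0, 4, 3)
    m[, i] <- pm[, 1]
    m[, j] <- pm[, 2]
    m
  }
  coded <- rbind(edge(1, 2), edge(1, 3), edge(2, 3),
                 matrix(0, center_replicates, 3))
  design_table(factors, coded)
}

#' Attach measured responses to a design table
#'
#' @param design A [design_table()].
#' @param ... Named numeric vectors, one value per run (e.g.
#'   `particle_size = c(...)`).  Names ending in `_sd` are treated as
#'   replicate standard deviations and carried as metadata only.
#' @return The design table with the new columns.
#' @export
set_responses <- function(design, ...) {
  vals <- list(...)
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    stop("responses must be named", call. = FALSE)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != nrow(design))
      stop(sprintf("response '%s' must have one value per run", nm), call. = FALSE)
    design[[nm]] <- v
  }
  design
}

#' Names of response columns in a design table
#'
#' Everything that is not the run label, a factor column or an `_sd`
#' metadata column.
#'
#' @param design A [design_table()].
#' @return Character vector of response names.
#' @export
response_names <- function(design) {
  nms <- factor_names(design_factors(design))
  fac_cols <- c("run_id", paste0(nms, "_coded"), paste0(nms, "_actual"))
  cand <- setdiff(names(design), fac_cols)
  cand[!grepl("_sd$", cand)]
}

#' Read / write design tables as CSV
#'
#' The CSV layout is one header row with `run_id`, `<factor>_coded`,
#' `<factor>_actual`, then response (and `<response>_sd`) columns.  Factor
#' specifications are supplied separately since the CSV carries only levels.
#'
#' @param path File path.
#' @param factors List of [factor_spec()] describing the coded columns.
#' @param tol Coded/actual consistency tolerance (see [design_table()]).
#' @return `read_design()` returns a [design_table()]; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path, factors, tol = 1e-3) {
  factors <- check_factor_list(factors)
  df <- utils::read.csv(path, check.names = FALSE)
  nms <- factor_names(factors)
  need <- c("run_id", paste0(nms, "_coded"), paste0(nms, "_actual"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("design file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  resp_cols <- setdiff(names(df), need)
  design_table(
    factors,
    coded = as.matrix(df[, paste0(nms, "_coded")]),
    actual = as.matrix(df[, paste0(nms, "_actual")]),
    responses = if (length(resp_cols)) df[, resp_cols, drop = FALSE],
    run_id = as.character(df$run_id),
    tol = tol
  )
}

#' @rdname read_design
#' @param design A [design_table()] to write.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' Packaged formulation-study fixtures
#'
#' Small packaged tables describing a published three-factor PLGA-lecithin
#' nanoparticle formulation study: the factor levels (`pln_factors()`), the
#' 15-run Box-Behnken design with measured mean particle size (nm) and
#' entrapment efficiency (%) responses (`pln_design()`), the desirability
#' goals used for optimization (`pln_goals()`), and the three ranked
#' optimizer solutions reported by the original DoE software
#' (`pln_solutions()`), useful as reference points in checkpoint analyses.
#'
#' @return `pln_factors()`: a named list of three [factor_spec()] objects
#'   (PLGA mg/100 mL, lecithin mg/100 mL, poloxamer 188 % w/v).
#'   `pln_design()`: a [design_table()] with responses `particle_size` and
#'   `ee`. `pln_goals()`: a list of [goal()] objects. `pln_solutions()`:
#'   a data frame of reported solution settings and predictions.
#' @export
pln_factors <- function() {
  df <- utils::read.csv(system.file("extdata", "pln_factors.csv",
                                    package = "plnopt"))
  check_factor_list(lapply(seq_len(nrow(df)), function(i)
    factor_spec(df$name[i], df$low[i], df$center[i], df$high[i],
                units = df$units[i])))
}

#' @rdname pln_factors
#' @export
pln_design <- function() {
  read_design(system.file("extdata", "pln_design.csv", package = "plnopt"),
              pln_factors())
}

#' @rdname pln_factors
#' @export
pln_goals <- function() {
  read_goals(system.file("extdata", "pln_goals.csv", package = "plnopt"))
}

#' @rdname pln_factors
#' @export
pln_solutions <- function() {
  utils::read.csv(system.file("extdata", "pln_solutions.csv", package = "plnopt"))
}
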