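#' Simulate Box-Behnken design responses from a known quadratic surface
#'
#' Generates the 3-factor Box-Behnken design and evaluates a known 10-term
#' quadratic polynomial (on coded levels) at each run, adding i.i.d. Gaussian
#' noise per response.  Used to test parameter recovery of the fitting and
#' optimization pipeline; reproducible under a fixed seed.
#'
#' @param factors List of 3 [factor_spec()] objects.
#' @param true_coefficients Named list, one numeric vector of 10 coefficients
#'   per response, ordered `b0, b1, b2, b3, b12, b13, b23, b11, b22, b33`.
#' @param noise_sd Per-response Gaussian SD (response units); a single value
#'   is recycled.  Zero gives exact surfaces.
#' @param center_replicates Number of center runs (default 3).
#' @param seed Integer seed.
#' @return A [design_table()] with one simulated response column per entry
#'   of `true_coefficients`.
#' @examples
#' facs <- pln_factors()
#' d <- simulate_design_responses(facs,
#'        list(y = c(150, 5, -3, 2, 1, 0, 0, 4, -2, 1)),
#'        noise_sd = 0, seed = 1)
#' coef(fit_quadratic(d, "y"))
#' @export
simulate_design_responses <- function(factors, true_coefficients,
                                      noise_sd = 0, center_replicates = 3,
                                      seed = 1) {
  if (!is.list(true_coefficients) || is.null(names(true_coefficients)) ||
      any(!nzchar(names(true_coefficients))))
    stop("'true_coefficients' must be a named list of coefficient vectors",
         call. = FALSE)
  bad <- vapply(true_coefficients, function(b)
    length(b) != 10L || !all(is.finite(b)), logical(1))
  if (any(bad))
    stop("each coefficient vector must hold 10 finite values", call. = FALSE)
  noise_sd <- rep_len(noise_sd, length(true_coefficients))
  if (any(noise_sd < 0)) stop("'noise_sd' must be >= 0", call. = FALSE)

  design <- bbd_design(factors, center_replicates)
  tm <- quad_terms(coded_matrix(design))
  set.seed(seed)
  for (i in seq_along(true_coefficients)) {
    nm <- names(true_coefficients)[i]
    design[[nm]] <- drop(tm %*% true_coefficients[[i]]) +
      stats::rnorm(nrow(design), sd = noise_sd[i])
  }
  design
}

#' Simulate a dissolution run with withdrawal/replacement bookkeeping
#'
#' Simulates first-order release of a dose into a stirred vessel,
#' `M(t) = dose * plateau_fraction * (1 - exp(-k t))`, with explicit
#' bookkeeping of the mass removed by each withdrawn-and-replaced sampling
#' aliquot.  The measured concentrations carry multiplicative Gaussian noise
#' of coefficient of variation `noise_cv`; the true released-mass trajectory
#' is returned alongside so mass-balance oracles can check
#' [cumulative_release()] exactly.
#'
#' @param dose Drug mass in the bag (mg).
#' @param vessel_volume Medium volume (mL).
#' @param sample_volume Withdrawn-and-replaced volume per time point (mL).
#' @param times Strictly increasing, nonempty sampling times (h).
#' @param rate_constant First-order release rate (1/h, > 0).
#' @param plateau_fraction Fraction of the dose ultimately releasable
#'   (in (0, 1]).
#' @param noise_cv Relative SD of the concentration measurement (>= 0).
#' @param seed Integer seed.
#' @param medium_ph,saturation_solubility Passed through to the experiment
#'   record.
#' @return A list: `experiment` (a [release_experiment()] with the measured
#'   concentrations), `true_released_mass` (cumulative mass released from the
#'   bag at each time, mg), `true_percent_released`, `vessel_mass` (mass in
#'   the vessel just before each withdrawal), and `withdrawn_mass`
#'   (cumulative mass removed by sampling).
#' @export
simulate_release <- function(dose, vessel_volume, sample_volume, times,
                             rate_constant, plateau_fraction = 1,
                             noise_cv = 0, seed = 1, medium_ph = 6.8,
                             saturation_solubility = NULL) {
  if (!length(times)) stop("sampling grid is empty", call. = FALSE)
  if (any(diff(times) <= 0) || any(times <= 0))
    stop("'times' must be positive and strictly increasing", call. = FALSE)
  if (!is.finite(rate_constant) || rate_constant <= 0)
    stop("'rate_constant' must be > 0", call. = FALSE)
  if (plateau_fraction <= 0 || plateau_fraction > 1)
    stop("'plateau_fraction' must be in (0, 1]", call. = FALSE)
  if (noise_cv < 0) stop("'noise_cv' must be >= 0", call. = FALSE)

  n <- length(times)
  released <- dose * plateau_fraction * (1 - exp(-rate_constant * times))
  set.seed(seed)
  vessel <- numeric(n)      # mass in vessel just before sampling
  conc_true <- numeric(n)
  conc_meas <- numeric(n)
  withdrawn <- numeric(n)   # cumulative withdrawn mass
  in_vessel <- 0
  taken <- 0
  prev_released <- 0
  for (i in seq_len(n)) {
    in_vessel <- in_vessel + (released[i] - prev_released)
    prev_released <- released[i]
    vessel[i] <- in_vessel
    conc_true[i] <- in_vessel / vessel_volume
    conc_meas[i] <- max(0, conc_true[i] * (1 + stats::rnorm(1, sd = noise_cv)))
    aliquot <- sample_volume * conc_true[i]
    in_vessel <- in_vessel - aliquot
    taken <- taken + aliquot
    withdrawn[i] <- taken
  }
  exp <- release_experiment(dose, vessel_volume, sample_volume, times,
                            conc_meas, medium_ph = medium_ph,
                            saturation_solubility = saturation_solubility)
  list(experiment = exp,
       true_released_mass = released,
       true_percent_released = 100 * released / dose,
       vessel_mass = vessel,
       withdrawn_mass = withdrawn)
}

#' Simulate grouped qPCR Ct values with a housekeeping reference
#'
#' Draws, for each group, target-gene and reference-gene Ct values:
#' `Ct_target = base_ct - log2_shift + noise` and
#' `Ct_reference = base_reference_ct + noise`, with independent Gaussian
#' noise of SD `reference_sd` cycles on both genes.  A group's expression
#' shift of `s` on the log2 scale therefore corresponds to a true fold
#' change of `2^s` relative to the control group, which
#' [fold_change_ddct()] applied to the output recovers up to Monte-Carlo
#' error.
#'
#' @param groups Data frame with columns `label`, `n` (>= 1), `log2_shift`,
#'   one row per group.
#' @param reference_sd Gaussian Ct noise SD in cycles (>= 0).
#' @param seed Integer seed.
#' @param base_ct,base_reference_ct Baseline target and reference Ct levels
#'   (cycles).
#' @param control Control-group label; defaults to the first row of `groups`.
#' @return Long Ct data frame (`sample`, `group`, `gene`, `ct`; genes
#'   `"target"` and `"reference"`) with attributes `control_group`,
#'   `target_gene`, `reference_gene`.
#' @export
simulate_ct <- function(groups, reference_sd = 0.2, seed = 1,
                        base_ct = 25, base_reference_ct = 18,
                        control = NULL) {
  groups <- as.data.frame(groups)
  need <- c("label", "n", "log2_shift")
  miss <- setdiff(need, names(groups))
  if (length(miss))
    stop("'groups' is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(groups$n < 1)) stop("each group needs n >= 1", call. = FALSE)
  if (reference_sd < 0) stop("'reference_sd' must be >= 0", call. = FALSE)
  if (is.null(control)) control <- groups$label[1]
  if (!control %in% groups$label)
    stop(sprintf("control group '%s' not among group labels", control),
         call. = FALSE)

  set.seed(seed)
  recs <- lapply(seq_len(nrow(groups)), function(i) {
    n <- groups$n[i]
    lab <- groups$label[i]
    ids <- sprintf("%s_%02d", lab, seq_len(n))
    tgt <- base_ct - groups$log2_shift[i] + stats::rnorm(n, sd = reference_sd)
    ref <- base_reference_ct + stats::rnorm(n, sd = reference_sd)
    rbind(
      data.frame(sample = ids, group = lab, gene = "target", ct = tgt,
                 stringsAsFactors = FALSE),
      data.frame(sample = ids, group = lab, gene = "reference", ct = ref,
                 stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  attr(out, "control_group") <- control
  attr(out, "target_gene") <- "target"
  attr(out, "reference_gene") <- "reference"
  out
}
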