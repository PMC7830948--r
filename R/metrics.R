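#' Encapsulation efficiency
#'
#' The percentage of the total drug mass retained inside the nanoparticles:
#' `100 * (w_total - w_free) / w_total`, where `w_free` is the free
#' (unencapsulated) drug measured in the aqueous phase after separating the
#' particles.
#'
#' @param w_total Total drug mass in the formulation (mg, > 0).
#' @param w_free Free drug mass in the aqueous phase (mg, in `[0, w_total]`).
#' @return Encapsulation efficiency in percent, in [0, 100]. Vectorized.
#' @examples
#' ee_percent(100, 24.4)  # 75.6
#' @export
ee_percent <- function(w_total, w_free) {
  if (any(!is.finite(w_total)) || any(!is.finite(w_free)))
    stop("masses must be finite", call. = FALSE)
  if (any(w_total <= 0))
    stop("'w_total' must be positive", call. = FALSE)
  if (any(w_free < 0))
    stop("'w_free' cannot be negative", call. = FALSE)
  if (any(w_free > w_total))
    stop("'w_free' exceeds 'w_total'; check the assay or blank", call. = FALSE)
  100 * (w_total - w_free) / w_total
}

#' Describe a dissolution (release) experiment
#'
#' Records a dialysis-bag release run: the dose placed in the bag, the
#' dissolution-medium volume, the volume withdrawn (and replaced with fresh
#' medium) at each sampling time, and the measured medium concentrations.
#'
#' @param dose Total drug mass in the bag (mg, > 0).
#' @param vessel_volume Dissolution medium volume (mL, > 0).
#' @param sample_volume Withdrawn-and-replaced volume per time point (mL, in
#'   `(0, vessel_volume]`).
#' @param times Strictly increasing sampling times (h).
#' @param concentrations Measured medium concentrations at `times`
#'   (mg/mL, >= 0).
#' @param medium_ph pH of the dissolution medium (metadata).
#' @param saturation_solubility Drug saturation solubility in the medium
#'   (mg/mL); needed only by [sink_condition()].
#' @return An object of class `release_experiment`.
#' @export
release_experiment <- function(dose, vessel_volume, sample_volume,
                               times, concentrations, medium_ph = 6.8,
                               saturation_solubility = NULL) {
  if (!is.finite(dose) || dose <= 0) stop("'dose' must be > 0", call. = FALSE)
  if (!is.finite(vessel_volume) || vessel_volume <= 0)
    stop("'vessel_volume' must be > 0", call. = FALSE)
  if (!is.finite(sample_volume) || sample_volume <= 0 ||
      sample_volume > vessel_volume)
    stop("'sample_volume' must be in (0, vessel_volume]", call. = FALSE)
  if (length(times) != length(concentrations))
    stop("'times' and 'concentrations' must have equal length", call. = FALSE)
  if (length(times) && any(diff(times) <= 0))
    stop("'times' must be strictly increasing", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations cannot be negative", call. = FALSE)
  structure(
    list(dose = dose, vessel_volume = vessel_volume,
         sample_volume = sample_volume, times = times,
         concentrations = concentrations, medium_ph = medium_ph,
         saturation_solubility = saturation_solubility),
    class = "release_experiment"
  )
}

#' Cumulative release with sampling-replacement correction
#'
#' At each sampling time the withdrawn aliquot removes drug from the vessel,
#' so the raw concentration underestimates what has been released.  The
#' standard additive correction restores the withdrawn mass:
#' \deqn{M_n = C_n V + v \sum_{i<n} C_i}
#' where \eqn{C_n} is the measured concentration at the n-th time, \eqn{V}
#' the vessel volume and \eqn{v} the withdrawn-and-replaced volume.  The
#' cumulative percent released is `100 * M_n / dose`.
#'
#' Non-monotone cumulative sequences are reported as computed and flagged
#' with a warning (a data-quality signal, never clipped); a value above
#' 110 % indicates a unit or mass-balance mistake and is an error.
#'
#' @param exp A [release_experiment()].
#' @return Data frame with columns `time`, `released_mass` (mg), and
#'   `percent_released`.
#' @export
cumulative_release <- function(exp) {
  if (!inherits(exp, "release_experiment"))
    stop("expected a 'release_experiment'", call. = FALSE)
  C <- exp$concentrations
  n <- length(C)
  if (!n) stop("experiment has no sampling records", call. = FALSE)
  withdrawn_before <- exp$sample_volume * c(0, cumsum(C)[-n])
  released <- C * exp$vessel_volume + withdrawn_before
  pct <- 100 * released / exp$dose
  if (any(pct > 110))
    stop("cumulative release exceeds 110% of dose; check units/mass balance",
         call. = FALSE)
  if (n > 1 && any(diff(pct) < 0))
    warning("cumulative release is not monotone; check the measurements",
            call. = FALSE)
  data.frame(time = exp$times, released_mass = released,
             percent_released = pct)
}

#' Sink-condition check
#'
#' Dissolution is under sink conditions when the medium could dissolve the
#' entire dose many times over -- by the usual rule, when the vessel volume
#' is at least 10 times the volume needed to dissolve the dose at saturation
#' (`dose / saturation_solubility`).
#'
#' @param exp A [release_experiment()] with `saturation_solubility` set.
#' @return A list: `sink` (logical, `TRUE` iff the 10x rule holds) and
#'   `margin` (vessel volume over saturation volume; sink iff `margin >= 10`).
#' @export
sink_condition <- function(exp) {
  if (!inherits(exp, "release_experiment"))
    stop("expected a 'release_experiment'", call. = FALSE)
  s <- exp$saturation_solubility
  if (is.null(s) || !is.finite(s) || s <= 0)
    stop("saturation solubility missing; sink condition not evaluable",
         call. = FALSE)
  saturation_volume <- exp$dose / s
  margin <- exp$vessel_volume / saturation_volume
  list(sink = margin >= 10, margin = margin)
}
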