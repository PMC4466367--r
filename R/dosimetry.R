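## Dose accounting, site-hit probability and uncertainty estimation.
## All uncertainties are one standard deviation of the mean.

#' Absorbed dose in the ROI
#'
#' Sum of the energy deposits made inside the ROI annulus divided by the
#' ROI mass. Events outside the annulus contribute nothing.
#'
#' @param events Event data.frame or `event_set`.
#' @param roi A [roi_params()] object.
#' @return Dose in Gy.
#' @export
absorbed_dose <- function(events, roi = roi_params()) {
  if (inherits(events, "event_set")) events <- events$events
  if (nrow(events) == 0) return(0)
  inside <- in_roi(roi, events$x_nm, events$y_nm, events$z_nm)
  sum(events$energy_ev[inside]) * .EV_TO_J / roi_mass(roi)
}

#' Standard error of the mean over batches
#'
#' @param values Numeric vector of per-batch estimates (length >= 2).
#' @return Sample standard deviation divided by `sqrt(n)`.
#' @export
batch_sem <- function(values) {
  n <- length(values)
  if (n < 2) stop("batch_sem needs at least two values")
  stats::sd(values) / sqrt(n)
}

#' Site-hit probability
#'
#' Ratio between the total number of strand breaks and the total number of
#' in-ROI inelastic events. When per-batch counts are supplied (10 equal
#' batches in uniform mode, one batch per history in track mode) the
#' uncertainty is one standard deviation of the mean of the per-batch
#' ratios.
#'
#' @param n_tsb Strand-break count, scalar or per-batch vector.
#' @param n_events In-ROI event count, scalar or per-batch vector of the
#'   same length.
#' @return A list with `value` and `sem` (NA when fewer than two non-empty
#'   batches are available).
#' @export
site_hit_probability <- function(n_tsb, n_events) {
  stopifnot(length(n_tsb) == length(n_events))
  tot <- sum(n_events)
  if (tot == 0) stop("site-hit probability undefined for zero events")
  value <- sum(n_tsb) / tot
  keep <- n_events > 0
  sem <- if (sum(keep) >= 2)
    batch_sem(n_tsb[keep] / n_events[keep]) else NA_real_
  list(value = value, sem = sem)
}

#' Secondary-electron event and dose fractions
#'
#' Fractions of the in-ROI inelastic events and of the absorbed dose
#' carried by secondary electrons.
#'
#' @param events Event data.frame or `event_set`.
#' @param roi A [roi_params()] object.
#' @return A list with `event_fraction` and `dose_fraction`.
#' @export
electron_fractions <- function(events, roi = roi_params()) {
  if (inherits(events, "event_set")) events <- events$events
  inside <- in_roi(roi, events$x_nm, events$y_nm, events$z_nm)
  ev <- events[inside, , drop = FALSE]
  if (nrow(ev) == 0)
    return(list(event_fraction = NA_real_, dose_fraction = NA_real_))
  e <- ev$particle == "electron"
  list(event_fraction = mean(e),
       dose_fraction = sum(ev$energy_ev[e]) / sum(ev$energy_ev))
}
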