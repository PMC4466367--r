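## Synthetic energy-deposition event generators. These stand in for a full
## track-structure transport engine: they reproduce the *statistical*
## structure the damage analysis assumes (event density per unit dose,
## secondary-electron event and dose fractions, spatial clustering along
## primary trajectories) without simulating any physics.

#' Event generator configuration
#'
#' @param mode `"uniform"` (events i.i.d. uniform in the ROI annulus) or
#'   `"track"` (events clustered along vertical primary trajectories).
#' @param n_events Number of events (uniform mode).
#' @param target_dose_gy Absorbed-dose target in Gy (track mode); histories
#'   are generated until the cumulative in-ROI dose reaches it, always
#'   completing the final history.
#' @param let_kev_um Linear energy transfer of the primary (keV/um, track
#'   mode). It only sets the linear event density `LET / mean_event_energy`
#'   along the trajectory; no slowing-down is modelled.
#' @param mean_event_energy_ev Mean energy deposit per inelastic event
#'   (eV). Quasiconstant for light ions and their electrons; default 55.
#' @param min_event_energy_ev Minimum possible inelasticity (eV); default 9.
#' @param electron_event_fraction Fraction of events carried by secondary
#'   electrons; default 0.70.
#' @param electron_dose_fraction Fraction of the absorbed dose carried by
#'   secondary electrons; default 0.61. Together with the event fraction it
#'   fixes the class-specific mean event energies.
#' @param electron_radial_scale_nm Scale of the isotropic exponential
#'   lateral displacement of electron clusters from the primary trajectory
#'   (nm); default 5.
#' @param electron_cluster_size_mean Mean electron cluster size (geometric
#'   law, support >= 1); default 3.
#' @param electron_cluster_radius_nm Scale of the isotropic exponential
#'   spread of events about their cluster centre (nm); default 2,
#'   comparable to the range of ~50 eV electrons in water.
#' @param seed Optional integer seed; when given, sampling is reproducible
#'   and byte-identical.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(mode = c("uniform", "track"), n_events = 1e5,
                             target_dose_gy = 100, let_kev_um = 66.9,
                             mean_event_energy_ev = 55,
                             min_event_energy_ev = 9,
                             electron_event_fraction = 0.70,
                             electron_dose_fraction = 0.61,
                             electron_radial_scale_nm = 5,
                             electron_cluster_size_mean = 3,
                             electron_cluster_radius_nm = 2,
                             seed = NULL) {
  mode <- match.arg(mode)
  if (electron_event_fraction < 0 || electron_event_fraction > 1 ||
      electron_dose_fraction < 0 || electron_dose_fraction > 1)
    stop("fractions must lie in [0, 1]")
  if (min_event_energy_ev > mean_event_energy_ev)
    stop("min_event_energy_ev must not exceed mean_event_energy_ev")
  if (mode == "track" && let_kev_um <= 0)
    stop("let_kev_um must be positive in track mode")
  if (mode == "uniform" && n_events <= 0)
    stop("n_events must be positive in uniform mode")
  f <- electron_event_fraction; d <- electron_dose_fraction
  mean_e <- if (f == 0) mean_event_energy_ev else
    mean_event_energy_ev * d / f
  mean_p <- if (f == 1) mean_event_energy_ev else
    mean_event_energy_ev * (1 - d) / (1 - f)
  if (mean_e < min_event_energy_ev || mean_p < min_event_energy_ev)
    stop("class mean energies fall below the minimum inelasticity; ",
         "electron_dose_fraction is inconsistent with the event fraction")
  structure(list(
    mode = mode, n_events = n_events, target_dose_gy = target_dose_gy,
    let_kev_um = let_kev_um,
    mean_event_energy_ev = mean_event_energy_ev,
    min_event_energy_ev = min_event_energy_ev,
    electron_event_fraction = f, electron_dose_fraction = d,
    mean_energy_electron_ev = mean_e, mean_energy_primary_ev = mean_p,
    electron_radial_scale_nm = electron_radial_scale_nm,
    electron_cluster_size_mean = electron_cluster_size_mean,
    electron_cluster_radius_nm = electron_cluster_radius_nm,
    seed = seed
  ), class = "generator_config")
}

#' Sample event energies
#'
#' Event energies follow a shifted exponential law,
#' `min + Exp(mean - min)`, bounded below by the minimum inelasticity so
#' that every event can qualify as a strand break. With `mean == min` the
#' law degenerates to a constant.
#'
#' @param n Number of draws.
#' @param config A [generator_config()]; alternatively give `mean_ev`.
#' @param mean_ev Optional class-specific mean overriding the config mean.
#' @return Numeric vector of energies (eV).
#' @export
sample_event_energy <- function(n, config, mean_ev = NULL) {
  m <- if (is.null(mean_ev)) config$mean_event_energy_ev else mean_ev
  lo <- config$min_event_energy_ev
  if (m < lo) stop("mean energy below the minimum inelasticity")
  if (m == lo) return(rep(lo, n))
  lo + stats::rexp(n, rate = 1 / (m - lo))
}

# class labels + class-conditional energies for n events
.sample_class_energy <- function(n, config) {
  electron <- stats::runif(n) < config$electron_event_fraction
  energy <- numeric(n)
  ne <- sum(electron)
  if (ne > 0)
    energy[electron] <- sample_event_energy(ne, config,
                                            config$mean_energy_electron_ev)
  if (ne < n)
    energy[!electron] <- sample_event_energy(n - ne, config,
                                             config$mean_energy_primary_ev)
  list(particle = ifelse(electron, "electron", "primary_ion"),
       energy = energy)
}

.new_event_set <- function(events, n_histories, config) {
  structure(list(events = events, n_histories = n_histories,
                 config = config),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events, %d histories (%s mode)\n",
              nrow(x$events), x$n_histories, x$config$mode))
  invisible(x)
}

# uniform point in the annulus: uniform in z, azimuth and r^2
.runif_annulus <- function(n, roi) {
  r <- sqrt(stats::runif(n, roi$r_inner_nm^2, roi$r_outer_nm^2))
  th <- stats::runif(n, 0, 2 * pi)
  list(x = r * cos(th), y = r * sin(th),
       z = stats::runif(n, 0, roi$height_nm))
}

#' Uniform events in the ROI
#'
#' Draw events i.i.d. uniform in the ROI annulus (uniform in height,
#' azimuth and squared radius). Used for the volume-ratio consistency
#' check: the fraction of such events falling in a target estimates the
#' predicted site-hit probability.
#'
#' @param config A [generator_config()] with `mode = "uniform"`.
#' @param roi A [roi_params()] object.
#' @return An `event_set`; each event is its own history.
#' @export
sample_uniform <- function(config, roi = roi_params()) {
  stopifnot(inherits(config, "generator_config"))
  if (config$mode != "uniform") stop("config mode must be 'uniform'")
  n <- as.integer(config$n_events)
  if (n <= 0) stop("n_events must be positive")
  if (!is.null(config$seed)) set.seed(config$seed)
  pos <- .runif_annulus(n, roi)
  ce <- .sample_class_energy(n, config)
  events <- data.frame(history = 0:(n - 1L), particle = ce$particle,
                       x_nm = pos$x, y_nm = pos$y, z_nm = pos$z,
                       energy_ev = ce$energy)
  .new_event_set(events, n, config)
}

# one track history: returns kept (in-ROI) events as a data.frame
.sample_history <- function(config, roi) {
  x0y0 <- .runif_annulus(1, roi)
  density <- config$let_kev_um / config$mean_event_energy_ev  # events / nm
  n_cand <- stats::rpois(1, density * roi$height_nm)
  if (n_cand == 0)
    return(data.frame(particle = character(0), x_nm = numeric(0),
                      y_nm = numeric(0), z_nm = numeric(0),
                      energy_ev = numeric(0)))
  electron <- stats::runif(n_cand) < config$electron_event_fraction
  n_e <- sum(electron); n_p <- n_cand - n_e

  xs <- numeric(0); ys <- numeric(0); zs <- numeric(0); cls <- character(0)
  if (n_p > 0) {
    xs <- rep(x0y0$x, n_p); ys <- rep(x0y0$y, n_p)
    zs <- stats::runif(n_p, 0, roi$height_nm)
    cls <- rep("primary_ion", n_p)
  }
  if (n_e > 0) {
    # split electron events into clusters of geometric size (mean >= 1)
    sizes <- integer(0)
    while (sum(sizes) < n_e) {
      draw <- stats::rgeom(n_e, 1 / config$electron_cluster_size_mean) + 1L
      sizes <- c(sizes, draw)
    }
    cum <- cumsum(sizes)
    n_cl <- which(cum >= n_e)[1]
    sizes <- sizes[seq_len(n_cl)]
    sizes[n_cl] <- sizes[n_cl] - (cum[n_cl] - n_e)
    sizes <- sizes[sizes > 0]
    n_cl <- length(sizes)
    # cluster centres: lateral isotropic exponential displacement off the
    # trajectory, uniform in height
    dist <- stats::rexp(n_cl, 1 / config$electron_radial_scale_nm)
    ang <- stats::runif(n_cl, 0, 2 * pi)
    cx <- x0y0$x + dist * cos(ang)
    cy <- x0y0$y + dist * sin(ang)
    cz <- stats::runif(n_cl, 0, roi$height_nm)
    # members: isotropic exponential spread about the centre
    id <- rep(seq_len(n_cl), sizes)
    rr <- stats::rexp(n_e, 1 / config$electron_cluster_radius_nm)
    u <- stats::runif(n_e, -1, 1)
    ph <- stats::runif(n_e, 0, 2 * pi)
    sq <- sqrt(pmax(0, 1 - u^2))
    xs <- c(xs, cx[id] + rr * sq * cos(ph))
    ys <- c(ys, cy[id] + rr * sq * sin(ph))
    zs <- c(zs, cz[id] + rr * u)
    cls <- c(cls, rep("electron", n_e))
  }
  keep <- in_roi(roi, xs, ys, zs)
  data.frame(particle = cls[keep], x_nm = xs[keep], y_nm = ys[keep],
             z_nm = zs[keep], energy_ev = NA_real_)
}

#' Track-surrogate events
#'
#' Generate complete primary histories until the cumulative in-ROI dose
#' reaches `target_dose_gy` (the final history is always completed). Each
#' history is a vertical trajectory at a uniform position in the annulus;
#' candidate events occur along it with Poisson linear density
#' `LET / mean_event_energy`. A fraction of events (default 0.70) is
#' carried by secondary electrons, which are displaced laterally off the
#' trajectory in clusters; events landing outside the annulus are
#' discarded from the set, the dose and all later denominators.
#'
#' This is not a physics engine: no stopping-power evolution, charge
#' transfer or electron transport is simulated; `let_kev_um` only sets the
#' event density.
#'
#' @param config A [generator_config()] with `mode = "track"`.
#' @param roi A [roi_params()] object.
#' @param max_histories Safety cap on the number of histories.
#' @return An `event_set` with 0-based contiguous history indices.
#' @export
sample_tracks <- function(config, roi = roi_params(), max_histories = 1e6) {
  stopifnot(inherits(config, "generator_config"))
  if (config$mode != "track") stop("config mode must be 'track'")
  density <- config$let_kev_um / config$mean_event_energy_ev
  if (density * roi$height_nm <= 0)
    stop("event density is zero; the target dose is unreachable")
  if (!is.null(config$seed)) set.seed(config$seed)
  mass <- roi_mass(roi)
  chunks <- list()
  dose <- 0
  h <- 0L
  while (dose < config$target_dose_gy) {
    if (h >= max_histories)
      stop("target dose not reached within max_histories")
    ev <- .sample_history(config, roi)
    n <- nrow(ev)
    if (n > 0) {
      ce <- .sample_class_energy_given(ev$particle, config)
      ev$energy_ev <- ce
      ev <- cbind(history = h, ev)
      chunks[[length(chunks) + 1L]] <- ev
      dose <- dose + sum(ev$energy_ev) * .EV_TO_J / mass
    }
    h <- h + 1L
  }
  events <- do.call(rbind, chunks)
  rownames(events) <- NULL
  .new_event_set(events, h, config)
}

# energies for pre-assigned classes
.sample_class_energy_given <- function(particle, config) {
  energy <- numeric(length(particle))
  e <- particle == "electron"
  if (any(e))
    energy[e] <- sample_event_energy(sum(e), config,
                                     config$mean_energy_electron_ev)
  if (any(!e))
    energy[!e] <- sample_event_energy(sum(!e), config,
                                      config$mean_energy_primary_ev)
  energy
}
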