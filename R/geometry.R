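## Geometry of the multi-scale DNA / chromatin model.
##
## Organisation levels (innermost to outermost):
##   base pair -> double helix -> nucleosome (two toroidal loops) ->
##   30 nm chromatin fiber level (6 nucleosomes) -> fiber fragment
##   (500 levels) -> annular region of interest (900 fragments).
## Internal units: nm for length, degrees for angle, eV for energy.

# unit conversions, isolated here on purpose
.EV_TO_J <- 1.602176634e-19
.NM3_TO_CM3 <- 1e-21

#' DNA conformation parameters
#'
#' Construct the geometric parameter set describing one double-helix
#' conformation. The canonical A-, B- and Z-DNA parameter sets are returned
#' by [dna_conformation_params()]; this low-level constructor accepts
#' arbitrary values (used e.g. for mirror-symmetry checks).
#'
#' @param label Short label for the conformation ("A", "B", "Z" or custom).
#' @param handedness "right" or "left"; sets the sign of the helical twist.
#' @param dna_diameter Outer diameter of the double helix (nm).
#' @param bp_diameter Diameter of the base-pair (nitrogenous base) core (nm);
#'   its radius is the inner radius of the sugar-phosphate target sector.
#' @param bp_axial_step Rise per base pair along the helix axis (nm).
#' @param bp_per_turn Base pairs per helical turn (may be fractional).
#' @param helix_pitch Helical pitch (nm).
#' @param bp_per_nucleosome Base pairs accommodated by the two nucleosome
#'   loops (must be even).
#' @param helix_axial_shift Axial offset between the two strands (nm).
#' @param target_aperture Angular aperture of the sugar-phosphate sector
#'   (degrees, in (0, 360]).
#' @param target_height Height of the target sector along the helix axis
#'   (nm); must be smaller than `bp_axial_step` so that consecutive targets
#'   never overlap when the helix bends around the histone.
#' @param helix_phase Angular position (degrees) of the strand-1 target of
#'   base pair 0; a free phase that does not affect any volume.
#'
#' @return An object of class `conformation_params` (a named list).
#' @seealso [dna_conformation_params()], [build_conformation()]
#' @export
conformation_params <- function(label, handedness = c("right", "left"),
                                dna_diameter, bp_diameter, bp_axial_step,
                                bp_per_turn, helix_pitch, bp_per_nucleosome,
                                helix_axial_shift, target_aperture,
                                target_height, helix_phase = 0) {
  handedness <- match.arg(handedness)
  lens <- c(dna_diameter = dna_diameter, bp_diameter = bp_diameter,
            bp_axial_step = bp_axial_step, helix_pitch = helix_pitch,
            target_height = target_height)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths must be positive and finite")
  if (bp_diameter >= dna_diameter)
    stop("bp_diameter must be smaller than dna_diameter")
  if (target_height >= bp_axial_step)
    stop("target_height must be smaller than bp_axial_step ",
         "(adjacent targets would overlap axially)")
  if (target_aperture <= 0 || target_aperture > 360)
    stop("target_aperture must lie in (0, 360] degrees")
  if (bp_per_turn <= 0 || bp_per_nucleosome <= 0)
    stop("bp_per_turn and bp_per_nucleosome must be positive")
  if (bp_per_nucleosome %% 2 != 0)
    stop("bp_per_nucleosome must be even (two loops per nucleosome)")
  structure(list(
    label = as.character(label), handedness = handedness,
    dna_diameter = dna_diameter, bp_diameter = bp_diameter,
    bp_axial_step = bp_axial_step, bp_per_turn = bp_per_turn,
    helix_pitch = helix_pitch, bp_per_nucleosome = bp_per_nucleosome,
    helix_axial_shift = helix_axial_shift,
    target_aperture = target_aperture, target_height = target_height,
    helix_phase = helix_phase %% 360
  ), class = "conformation_params")
}

# canonical dimensions of the three DNA forms (nm / degrees)
.DNA_TABLE <- list(
  A = list(handedness = "right", dna_diameter = 2.55, bp_diameter = 1.0,
           bp_axial_step = 0.23, bp_per_turn = 10.7, helix_pitch = 2.46,
           bp_per_nucleosome = 286, helix_axial_shift = 0.76,
           target_aperture = 87, target_height = 0.119),
  B = list(handedness = "right", dna_diameter = 2.37, bp_diameter = 1.0,
           bp_axial_step = 0.33, bp_per_turn = 10, helix_pitch = 3.2,
           bp_per_nucleosome = 198, helix_axial_shift = 1.2,
           target_aperture = 73, target_height = 0.183),
  Z = list(handedness = "left", dna_diameter = 1.84, bp_diameter = 0.6,
           bp_axial_step = 0.38, bp_per_turn = 12, helix_pitch = 3.0,
           bp_per_nucleosome = 172, helix_axial_shift = 0.77,
           target_aperture = 60, target_height = 0.249)
)

#' Canonical A-, B- and Z-DNA parameters
#'
#' Dimensions of the double helix and of the sugar-phosphate target sector
#' for the three main DNA conformations. A- and B-DNA are right-handed,
#' Z-DNA is left-handed.
#'
#' @param label One of "A", "B", "Z".
#' @return A [conformation_params()] object.
#' @examples
#' p <- dna_conformation_params("B")
#' p$bp_per_nucleosome  # 198
#' @export
dna_conformation_params <- function(label = c("A", "B", "Z")) {
  label <- match.arg(label)
  do.call(conformation_params, c(list(label = label), .DNA_TABLE[[label]]))
}

#' Region-of-interest parameters
#'
#' The region of interest (ROI) is a thin annulus of chromatin: 900
#' fragments of 30 nm fiber stand vertically around a circle of 10 um
#' central diameter, each fragment holding 500 axial levels of 6
#' nucleosomes. The annulus is 5.25 um high and its radial thickness equals
#' the fiber diameter (30 nm). All regions contain water at 1.06 g/cm3.
#'
#' @param central_diameter_um Central diameter of the annulus (um).
#' @param radial_thickness_nm Radial thickness of the annulus (nm).
#' @param height_um Height of the annulus (um).
#' @param n_fragments Number of chromatin-fiber fragments.
#' @param levels_per_fragment Axial nucleosome levels per fragment.
#' @param nucleosomes_per_level Nucleosomes per level.
#' @param nucleosome_external_diameter_nm Nominal external nucleosome
#'   diameter (nm); equals the level height.
#' @param density_g_cm3 Mass density (g/cm3).
#' @return An object of class `roi_params`.
#' @export
roi_params <- function(central_diameter_um = 10, radial_thickness_nm = 30,
                       height_um = 5.25, n_fragments = 900,
                       levels_per_fragment = 500, nucleosomes_per_level = 6,
                       nucleosome_external_diameter_nm = 10.5,
                       density_g_cm3 = 1.06) {
  if (central_diameter_um <= 0 || radial_thickness_nm < 0 || height_um <= 0)
    stop("ROI dimensions must be positive")
  if (n_fragments < 1 || levels_per_fragment < 1 || nucleosomes_per_level < 1)
    stop("ROI counts must be positive integers")
  r_central <- central_diameter_um * 1000 / 2
  structure(list(
    central_radius_nm = r_central,
    radial_thickness_nm = radial_thickness_nm,
    height_nm = height_um * 1000,
    r_inner_nm = r_central - radial_thickness_nm / 2,
    r_outer_nm = r_central + radial_thickness_nm / 2,
    n_fragments = as.integer(n_fragments),
    levels_per_fragment = as.integer(levels_per_fragment),
    nucleosomes_per_level = as.integer(nucleosomes_per_level),
    nucleosome_external_diameter_nm = nucleosome_external_diameter_nm,
    density_g_cm3 = density_g_cm3
  ), class = "roi_params")
}

#' Volume of an angular sector of a hollow cylinder
#'
#' The sugar-phosphate target is an angular sector of a hollow cylinder
#' coaxial with the double helix: inner radius at the base-pair core, outer
#' radius at the helix surface. Its volume is
#' \deqn{V = \frac{\alpha}{360^\circ}\,\pi\,(r_\max^2 - r_\min^2)\,h.}
#'
#' @param aperture_deg Angular aperture (degrees, in (0, 360]).
#' @param r_max Outer radius (nm).
#' @param r_min Inner radius (nm), `0 <= r_min < r_max`.
#' @param height Sector height (nm).
#' @return Volume in nm^3 (vectorised over the arguments).
#' @examples
#' # B-DNA sugar-phosphate group: 73 deg, radii 1.185 / 0.5 nm, 0.183 nm high
#' sector_volume(73, 1.185, 0.5, 0.183)  # ~0.1346 nm^3
#' @export
sector_volume <- function(aperture_deg, r_max, r_min, height) {
  if (any(!is.finite(c(aperture_deg, r_max, r_min, height))))
    stop("sector dimensions must be finite")
  if (any(aperture_deg <= 0 | aperture_deg > 360))
    stop("aperture must lie in (0, 360] degrees")
  if (any(height <= 0) || any(r_max <= 0) || any(r_min < 0))
    stop("sector dimensions must be positive (r_min may be zero)")
  if (any(r_min >= r_max)) stop("r_min must be smaller than r_max")
  (aperture_deg / 360) * pi * (r_max^2 - r_min^2) * height
}

#' Build a full conformation model
#'
#' Assemble the hierarchical geometry for one DNA conformation inside the
#' ROI and pre-compute every derived quantity the locator and the analytic
#' predictions need: signed twist per base pair, nucleosome loop radius
#' (from the requirement that the two loops accommodate exactly
#' `bp_per_nucleosome` base pairs at the conformation's axial step),
#' nucleosome slot placement, strand-2 offsets, per-target volume and
#' totals.
#'
#' Within a level the 6 nucleosomes sit on a circle about the fiber axis at
#' a radius chosen so the outermost target point just reaches the fiber
#' surface, and alternate between two axial tiers 2.625 nm apart; this
#' arrangement keeps all targets pairwise disjoint and fully inside the
#' fiber (and hence the ROI annulus) for all three conformations.
#'
#' @param conformation A label ("A", "B", "Z") or a [conformation_params()]
#'   object.
#' @param roi A [roi_params()] object.
#' @param slot_level_offset_deg Additional rotation of the nucleosome slot
#'   pattern per level (degrees).
#' @return An object of class `conformation_model`.
#' @examples
#' m <- build_conformation("B")
#' m$total_bp            # 5.346e8
#' m$twist_per_bp_deg    # 36
#' @export
build_conformation <- function(conformation, roi = roi_params(),
                               slot_level_offset_deg = 30) {
  params <- if (inherits(conformation, "conformation_params")) conformation
            else dna_conformation_params(conformation)
  stopifnot(inherits(roi, "roi_params"))

  sign_twist <- if (params$handedness == "left") -1 else 1
  twist <- sign_twist * 360 / params$bp_per_turn

  per_loop <- params$bp_per_nucleosome / 2
  loop_circ <- per_loop * params$bp_axial_step     # arc length of one loop
  loop_radius <- loop_circ / (2 * pi)

  r_min <- params$bp_diameter / 2
  r_max <- params$dna_diameter / 2

  fiber_radius <- roi$radial_thickness_nm / 2
  slot_radius <- fiber_radius - loop_radius - r_max
  if (slot_radius <= 0)
    stop("helix does not fit inside the fiber radius")

  level_height <- roi$height_nm / roi$levels_per_fragment
  # nucleosome centre heights: even slots low tier, odd slots high tier
  tier_z <- c(3, 5) * level_height / 8
  loop_dz <- level_height / 4                      # loop planes at centre +/- dz
  # worst-case containment: centre +/- (loop_dz + r_max) must stay in level
  if (min(tier_z) - loop_dz - r_max < 0 ||
      max(tier_z) + loop_dz + r_max > level_height)
    warning("nucleosome assembly exceeds its level slab; ",
            "targets may leak between levels")
  # adjacent-tier loop planes are 2.625 nm apart; tubes of radius r_max must
  # clear each other where loop circles cross in plan view
  if (diff(tier_z) <= 2 * r_max)
    warning("axial tier separation does not clear the helix diameter; ",
            "adjacent nucleosome targets may overlap")
  if (sqrt(3) * slot_radius <= 2 * (loop_radius + r_max))
    warning("same-tier nucleosomes too close; targets may overlap")

  n_nucleosomes <- as.numeric(roi$n_fragments) * roi$levels_per_fragment *
    roi$nucleosomes_per_level
  total_bp <- n_nucleosomes * params$bp_per_nucleosome
  n_targets <- 2 * total_bp
  target_volume <- sector_volume(params$target_aperture, r_max, r_min,
                                 params$target_height)

  # strand 2: rotated 180 deg about the helix axis and translated along it;
  # the twist advances with arc length, so the translation also rotates
  strand_arc_shift <- params$helix_axial_shift %% loop_circ

  structure(list(
    params = params, roi = roi,
    twist_per_bp_deg = twist,
    per_loop = per_loop, loop_circumference = loop_circ,
    nucleosome_path_radius = loop_radius,
    r_min = r_min, r_max = r_max,
    fiber_radius = fiber_radius, slot_radius = slot_radius,
    level_height = level_height, tier_z = tier_z, loop_dz = loop_dz,
    slot_level_offset_deg = slot_level_offset_deg,
    fragment_width_deg = 360 / roi$n_fragments,
    strand_arc_shift = strand_arc_shift,
    n_nucleosomes = n_nucleosomes, total_bp = total_bp,
    n_targets = n_targets, target_volume = target_volume,
    total_target_volume = n_targets * target_volume
  ), class = "conformation_model")
}

#' @export
print.conformation_model <- function(x, ...) {
  cat(sprintf("<conformation_model> %s-DNA (%s-handed)\n",
              x$params$label, x$params$handedness))
  cat(sprintf("  twist/bp: %+.3f deg, loop radius: %.3f nm\n",
              x$twist_per_bp_deg, x$nucleosome_path_radius))
  cat(sprintf("  targets: %.4g (volume %.4f nm^3 each)\n",
              x$n_targets, x$target_volume))
  cat(sprintf("  predicted site-hit probability: %.4f\n",
              predicted_hit_probability(x)))
  invisible(x)
}

#' ROI annulus volume
#'
#' Exact volume of the annular ROI, `pi * (R_out^2 - R_in^2) * H`, which for
#' a thin annulus equals `pi * central_diameter * thickness * H`.
#'
#' @param roi A [roi_params()] object.
#' @return Volume in nm^3.
#' @export
roi_volume <- function(roi = roi_params()) {
  pi * (roi$r_outer_nm^2 - roi$r_inner_nm^2) * roi$height_nm
}

#' ROI mass
#'
#' Mass of the water contained in the ROI annulus, used to convert deposited
#' energy into absorbed dose.
#'
#' @param roi A [roi_params()] object.
#' @return Mass in kg.
#' @export
roi_mass <- function(roi = roi_params()) {
  roi_volume(roi) * .NM3_TO_CM3 * roi$density_g_cm3 * 1e-3
}

#' Energy corresponding to a dose in the ROI
#'
#' @param dose_gy Absorbed dose (Gy).
#' @param roi A [roi_params()] object.
#' @return Energy in eV that must be deposited in the ROI.
#' @export
dose_to_energy_ev <- function(dose_gy, roi = roi_params()) {
  dose_gy * roi_mass(roi) / .EV_TO_J
}

#' Predicted site-hit probability
#'
#' Under spatially uniform energy-deposition events the probability that an
#' event falls inside any sugar-phosphate target equals the fraction of the
#' ROI volume occupied by targets:
#' `(2 * total_bp * target_volume) / roi_volume`.
#'
#' @param model A [build_conformation()] model.
#' @return A fraction.
#' @export
predicted_hit_probability <- function(model) {
  stopifnot(inherits(model, "conformation_model"))
  model$total_target_volume / roi_volume(model$roi)
}

#' Per-conformation geometry report
#'
#' One row per DNA conformation with the analytic quantities of the model:
#' per-target volume, total base pairs, total target volume, ROI volume and
#' the predicted (volume-ratio) site-hit probability.
#'
#' @param roi A [roi_params()] object.
#' @param conformations Character vector of conformation labels.
#' @return A data.frame.
#' @export
geometry_report <- function(roi = roi_params(),
                            conformations = c("A", "B", "Z")) {
  rows <- lapply(conformations, function(lbl) {
    m <- build_conformation(lbl, roi)
    data.frame(conformation = lbl,
               target_volume_nm3 = m$target_volume,
               total_bp = m$total_bp,
               total_target_volume_nm3 = m$total_target_volume,
               roi_volume_nm3 = roi_volume(roi),
               predicted_hit_probability = predicted_hit_probability(m))
  })
  do.call(rbind, rows)
}
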