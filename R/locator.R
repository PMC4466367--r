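## Target placement (address -> lab frame) and the inverse event locator
## (lab frame -> address). Both are fully vectorised; the locator never
## iterates over targets but inverts the transform chain analytically:
## annulus azimuth -> fragment, z -> level, then the 6 nucleosome slots x
## 2 loops x 2 strands are tested in index order (24 vectorised passes).
##
## All membership tests use half-open intervals [low, high) in radius,
## angle and arc height so that points on a shared boundary resolve
## deterministically to the lower-indexed target and the 0/360 degree seam
## is exact.

# signed angular difference a - b mapped to [-180, 180)
.ang_diff <- function(a, b) {
  ((a - b + 180) %% 360) - 180
}

.check_address <- function(model, fragment, level, nucleosome, bp, strand) {
  roi <- model$roi
  bad <- fragment < 0 | fragment >= roi$n_fragments |
    level < 0 | level >= roi$levels_per_fragment |
    nucleosome < 0 | nucleosome >= roi$nucleosomes_per_level |
    bp < 0 | bp >= model$params$bp_per_nucleosome |
    !strand %in% c(0, 1)
  if (any(bad)) stop("target address out of range for this model")
}

# Helix angle as a single-valued function of arc position around the
# closed loop: both strands share it (strand 2 is +180 deg), so wherever
# two targets of opposite strands overlap in arc height their sector
# centres are ~180 deg apart and the sectors cannot intersect. The
# loop-closure twist defect (per_loop * twist mod 360 != 0) is thereby
# confined to the arc origin for both strands consistently.
.helix_angle <- function(model, arc, strand) {
  p <- model$params
  (p$helix_phase + (arc / p$bp_axial_step) * model$twist_per_bp_deg +
     strand * 180) %% 360
}

# per-address local frame pieces shared by placement
.address_frame <- function(model, level, nucleosome, bp, strand) {
  p <- model$params
  loop <- as.numeric(bp >= model$per_loop)
  i_loc <- bp - loop * model$per_loop
  s_center <- (i_loc + 0.5) * p$bp_axial_step
  s1 <- strand == 1
  s_center[s1] <- (s_center[s1] + model$strand_arc_shift) %%
    model$loop_circumference
  theta <- .helix_angle(model, s_center, strand)
  # nucleosome centre: even slots on the low tier, odd on the high tier
  zc <- ifelse(nucleosome %% 2 == 0, model$tier_z[1], model$tier_z[2])
  z_ring <- level * model$level_height + zc + (2 * loop - 1) * model$loop_dz
  alpha <- (nucleosome * 360 / model$roi$nucleosomes_per_level +
              level * model$slot_level_offset_deg) %% 360
  list(s_center = s_center, theta = theta, z_ring = z_ring, alpha = alpha)
}

#' Place a target in the lab frame
#'
#' Map hierarchical target addresses to lab-frame coordinates. By default
#' the reference interior point of each target is returned (mid radius,
#' sector centre angle, arc centre); the `*_frac` arguments select any other
#' interior point, with `r_frac` uniform in the annular area so that
#' uniformly drawn fractions sample the sector volume uniformly.
#'
#' @param model A [build_conformation()] model.
#' @param fragment,level,nucleosome,bp,strand Integer address vectors
#'   (0-based), recycled to a common length.
#' @param r_frac,ang_frac,s_frac Fractions in `[0, 1)` placing the point
#'   within the sector in radius (area-uniform), aperture angle and arc
#'   height; default 0.5 (the reference point).
#' @return A data.frame with lab-frame coordinates `x_nm`, `y_nm`, `z_nm`.
#' @examples
#' m <- build_conformation("B")
#' target_placement(m, 0, 0, 0, 0, 0)
#' @export
target_placement <- function(model, fragment, level, nucleosome, bp, strand,
                             r_frac = 0.5, ang_frac = 0.5, s_frac = 0.5) {
  stopifnot(inherits(model, "conformation_model"))
  n <- max(lengths(list(fragment, level, nucleosome, bp, strand)))
  fragment <- rep_len(fragment, n); level <- rep_len(level, n)
  nucleosome <- rep_len(nucleosome, n); bp <- rep_len(bp, n)
  strand <- rep_len(strand, n)
  r_frac <- rep_len(r_frac, n); ang_frac <- rep_len(ang_frac, n)
  s_frac <- rep_len(s_frac, n)
  .check_address(model, fragment, level, nucleosome, bp, strand)

  p <- model$params
  fr <- .address_frame(model, level, nucleosome, bp, strand)
  s <- (fr$s_center + (s_frac - 0.5) * p$target_height) %%
    model$loop_circumference
  psi <- fr$theta + (ang_frac - 0.5) * p$target_aperture
  rho <- sqrt(model$r_min^2 + r_frac * (model$r_max^2 - model$r_min^2))

  beta <- fr$alpha * pi / 180 + s / model$nucleosome_path_radius
  alpha_rad <- fr$alpha * pi / 180
  cx <- model$slot_radius * cos(alpha_rad)
  cy <- model$slot_radius * sin(alpha_rad)
  psi_rad <- psi * pi / 180
  d_xy <- model$nucleosome_path_radius + rho * cos(psi_rad)
  lx <- cx + d_xy * cos(beta)
  ly <- cy + d_xy * sin(beta)
  lz <- fr$z_ring + rho * sin(psi_rad)

  gamma <- (fragment + 0.5) * model$fragment_width_deg * pi / 180
  X <- model$roi$central_radius_nm + lx
  data.frame(x_nm = cos(gamma) * X - sin(gamma) * ly,
             y_nm = sin(gamma) * X + cos(gamma) * ly,
             z_nm = lz)
}

#' Annulus membership
#'
#' @param roi A [roi_params()] object.
#' @param x,y,z Lab-frame coordinates (nm).
#' @return Logical vector; `TRUE` for points inside the ROI annulus
#'   (half-open in radius squared and height).
#' @export
in_roi <- function(roi, x, y, z) {
  r2 <- x^2 + y^2
  r2 >= roi$r_inner_nm^2 & r2 < roi$r_outer_nm^2 & z >= 0 & z < roi$height_nm
}

#' Locate energy-deposition points
#'
#' Map lab-frame points to the sugar-phosphate target containing them, if
#' any. The locator is the exact inverse of [target_placement()] on target
#' interiors; points outside every target (including everything outside the
#' ROI annulus) yield `NA` addresses.
#'
#' @param model A [build_conformation()] model.
#' @param x,y,z Lab-frame coordinates (nm), equal-length vectors.
#' @return A data.frame with columns `fragment`, `level`, `nucleosome`,
#'   `bp`, `strand` (0-based integers, `NA` for misses) and logical `hit`.
#' @examples
#' m <- build_conformation("B")
#' pt <- target_placement(m, 10, 3, 2, 50, 1)
#' locate_events(m, pt$x_nm, pt$y_nm, pt$z_nm)
#' @export
locate_events <- function(model, x, y, z) {
  stopifnot(inherits(model, "conformation_model"))
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("event coordinates must be finite")
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  roi <- model$roi
  p <- model$params

  out_frag <- rep(NA_integer_, n); out_lvl <- rep(NA_integer_, n)
  out_nuc <- rep(NA_integer_, n); out_bp <- rep(NA_integer_, n)
  out_str <- rep(NA_integer_, n)

  inside <- in_roi(roi, x, y, z)
  if (any(inside)) {
    xi <- x[inside]; yi <- y[inside]; zi <- z[inside]
    az <- atan2(yi, xi) %% (2 * pi)
    frag <- pmin(floor(az / (2 * pi) * roi$n_fragments), roi$n_fragments - 1)
    gamma <- (frag + 0.5) * model$fragment_width_deg * pi / 180
    cg <- cos(gamma); sg <- sin(gamma)
    lx <- cg * xi + sg * yi - roi$central_radius_nm
    ly <- -sg * xi + cg * yi
    lvl <- pmin(floor(zi / model$level_height), roi$levels_per_fragment - 1)
    zl <- zi - lvl * model$level_height

    m <- length(xi)
    hit_nuc <- rep(NA_integer_, m); hit_bp <- rep(NA_integer_, m)
    hit_str <- rep(NA_integer_, m)
    # only points inside the fiber disk can be hits
    open <- lx^2 + ly^2 <= model$fiber_radius^2

    half_h <- p$target_height / 2
    half_ap <- p$target_aperture / 2
    step <- p$bp_axial_step
    for (k in 0:(roi$nucleosomes_per_level - 1)) {
      if (!any(open)) break
      alpha <- (k * 360 / roi$nucleosomes_per_level +
                  lvl * model$slot_level_offset_deg) %% 360
      a_rad <- alpha * pi / 180
      dx <- lx - model$slot_radius * cos(a_rad)
      dy <- ly - model$slot_radius * sin(a_rad)
      d_xy <- sqrt(dx^2 + dy^2)
      zc <- if (k %% 2 == 0) model$tier_z[1] else model$tier_z[2]
      for (loop in 0:1) {
        z_ring <- zc + (2 * loop - 1) * model$loop_dz
        dz <- zl - z_ring
        dr <- d_xy - model$nucleosome_path_radius
        r_hel <- sqrt(dr^2 + dz^2)
        cand <- open & r_hel >= model$r_min & r_hel < model$r_max
        if (!any(cand)) next
        phi <- (atan2(dy[cand], dx[cand]) - a_rad[cand]) %% (2 * pi)
        s <- model$nucleosome_path_radius * phi
        psi <- (atan2(dz[cand], dr[cand]) * 180 / pi) %% 360
        idx <- which(cand)
        for (strand in 0:1) {
          s_eff <- if (strand == 0) s else
            (s - model$strand_arc_shift) %% model$loop_circumference
          i_loc <- pmin(floor(s_eff / step), model$per_loop - 1)
          s_center <- (i_loc + 0.5) * step
          ds <- s_eff - s_center
          ok_h <- ds >= -half_h & ds < half_h
          g <- loop * model$per_loop + i_loc
          if (strand == 1)
            s_center <- (s_center + model$strand_arc_shift) %%
              model$loop_circumference
          theta <- .helix_angle(model, s_center, strand)
          da <- .ang_diff(psi, theta)
          ok <- ok_h & da >= -half_ap & da < half_ap
          if (any(ok)) {
            sel <- idx[ok]
            hit_nuc[sel] <- k
            hit_bp[sel] <- g[ok]
            hit_str[sel] <- strand
            open[sel] <- FALSE
            # refresh candidate view for the second strand
            if (strand == 0) {
              cand <- cand & open
              if (!any(cand)) break
              keep <- open[idx]
              idx <- idx[keep]; s <- s[keep]; psi <- psi[keep]
            }
          }
        }
      }
    }
    got <- !is.na(hit_nuc)
    w <- which(inside)
    out_frag[w[got]] <- as.integer(frag[got])
    out_lvl[w[got]] <- as.integer(lvl[got])
    out_nuc[w[got]] <- hit_nuc[got]
    out_bp[w[got]] <- hit_bp[got]
    out_str[w[got]] <- hit_str[got]
  }
  data.frame(fragment = out_frag, level = out_lvl, nucleosome = out_nuc,
             bp = out_bp, strand = out_str, hit = !is.na(out_nuc))
}

#' Base-pair separation between two strand-break sites
#'
#' Genomic distance used by the double-strand-break pairing rule. It is
#' defined only for targets on the same nucleosome of the same fragment and
#' level (no linker DNA is modelled, so cross-nucleosome pairs are never
#' formed); otherwise `NA` is returned.
#'
#' @param a,b Data.frames (or single-row lists) with `fragment`, `level`,
#'   `nucleosome`, `bp` columns.
#' @return Integer bp separation, or `NA` when undefined.
#' @export
bp_separation <- function(a, b) {
  same <- a$fragment == b$fragment & a$level == b$level &
    a$nucleosome == b$nucleosome
  ifelse(same, abs(a$bp - b$bp), NA_integer_)
}

#' Read / write the event CSV schema
#'
#' Events are exchanged as plain CSV with header
#' `history,particle,x_nm,y_nm,z_nm,energy_ev` (UTF-8, "." decimal).
#'
#' @param path File path.
#' @return `read_event_csv()` returns a data.frame in the schema above.
#' @export
read_event_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("history", "particle", "x_nm", "y_nm", "z_nm", "energy_ev")
  if (!all(need %in% names(df)))
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  df[need]
}

#' @rdname read_event_csv
#' @param events Event data.frame (or an `event_set`).
#' @export
write_event_csv <- function(events, path) {
  if (inherits(events, "event_set")) events <- events$events
  need <- c("history", "particle", "x_nm", "y_nm", "z_nm", "energy_ev")
  utils::write.csv(events[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
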