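# Seeded synthetic confocal stacks of the fly retina with known ground truth.
#
# Geometry: ommatidia sit on a hexagonal lattice draped over a spherical cap
# (the dissected retina mounted concave toward the objective), long axes
# pointing at the cap center, so central ommatidia are z-aligned and
# peripheral ones tilt.  Each ommatidium carries 7 rhabdomeres (R1-R6 plus
# the central R7/8) in the stereotyped trapezoid.  Optics: depth- and
# curvature-dependent exponential attenuation, Gaussian scatter halos around
# bright cells, additive sensor noise, 8-bit quantization.  Expression:
# per-cell reporter levels drawn from a two-state shifted-gamma mixture, in
# the same relative-intensity units the quantification pipeline reports.

# Canonical rhabdomere layout (units of half the PR center spacing; x right,
# y up, looking distally).  R3 sits at the apex of the trapezoid, R7/8 near
# the middle; R6 is closer to R5 than to R1, which breaks mirror symmetry.
.pr_layout <- function(chirality = c("standard", "mirrored")) {
  chirality <- match.arg(chirality)
  xy <- rbind(
    R1 = c(-2.0, 0.0),
    R2 = c(-1.7, 1.7),
    R3 = c(0.0, 2.8),
    R4 = c(1.7, 1.7),
    R5 = c(2.0, 0.0),
    R6 = c(1.0, -1.6),
    `R7/8` = c(0.0, 0.3))
  if (chirality == "mirrored") xy[, 1] <- -xy[, 1]
  xy
}

.pr_labels <- c("R1", "R2", "R3", "R4", "R5", "R6", "R7/8")

# hexagonal spiral positions (axial coords -> cartesian, unit spacing)
.hex_positions <- function(n) {
  pts <- matrix(0, nrow = 1, ncol = 2)
  ring <- 1
  dirs <- rbind(c(0, -1), c(-1, 0), c(-1, 1), c(0, 1), c(1, 0), c(1, -1))
  while (nrow(pts) < n) {
    ax <- c(ring, 0)
    for (d in seq_len(6)) {
      for (s in seq_len(ring)) {
        pts <- rbind(pts, ax)
        ax <- ax + dirs[d, ]
      }
    }
    ring <- ring + 1
  }
  q <- pts[seq_len(n), 1]; r <- pts[seq_len(n), 2]
  cbind(x = q + r / 2, y = r * sqrt(3) / 2)
}

#' Configuration of the synthetic retina generator
#'
#' Defaults emulate the acquisition conditions the pipeline assumes: 250 nm
#' optical sections, 160 nm pixels, 8-bit depth; ommatidial center spacing
#' 13 um and radius 4 um; PR centers about 2 um apart with rhabdomere radius
#' 0.85 um (PR spacing of ~2 um with sub-250 nm gaps implies ~1.7 um
#' rhabdomere diameters).
#'
#' @param n_ommatidia Number of ommatidia (hexagonal spiral from the center).
#' @param lattice_spacing_um Center-to-center ommatidial spacing (12-15 um).
#' @param ommatidium_radius_um Ommatidium radius (3-5 um).
#' @param pr_center_spacing_um Spacing between neighboring PR centers.
#' @param rhabdomere_radius_um Rhabdomere radius.
#' @param voxel_size_um Voxel size as `c(z, y, x)` in microns.
#' @param n_slices Number of optical sections (slice 1 is the deepest).
#' @param curvature_radius_um Radius of the spherical cap; `Inf` for a flat
#'   retina.  The cap is concave toward the objective, so light reaching
#'   peripheral ommatidia crosses more tissue.
#' @param attenuation_coeff Attenuation per micron of overlying tissue.
#' @param scatter_fraction Fraction of a bright cell's intensity scattered
#'   into a Gaussian halo (in `[0, 1)`).
#' @param scatter_sigma_um Width of the scatter halo.
#' @param noise_sd Additive Gaussian sensor noise SD (intensity units).
#' @param bit_depth Sensor bit depth (8).
#' @param cytoplasm_level Cytoplasm intensity inside the ommatidium; kept
#'   off the contour-level grid so plateau-level contours are never
#'   degenerate.
#' @param edge_ramp_um Width of the linear intensity falloff at the
#'   ommatidium boundary (gives the background contour set its support).
#' @param structural_peak Rhabdomere peak intensity in the structural
#'   (phalloidin-like) channel.
#' @param chirality `"standard"` or `"mirrored"` trapezoid.
#' @param orientation_deg Global in-plane rotation of the PR trapezoid.
#' @param orientation_jitter_deg Per-ommatidium uniform orientation jitter.
#' @param helix_deg_per_um Helical twist of the PR bundle along z.
#' @param n_levels_quant Contour quantization the renderer calibrates
#'   against (integer intensity levels by default; see the quantification
#'   module).
#' @param seed Integer seed; the generated stack is bit-identical given the
#'   seed.
#' @return An object of class `retina_sim_config`.
#' @export
retina_sim_config <- function(n_ommatidia = 37,
                              lattice_spacing_um = 13,
                              ommatidium_radius_um = 4,
                              pr_center_spacing_um = 2,
                              rhabdomere_radius_um = 0.85,
                              voxel_size_um = c(0.25, 0.16, 0.16),
                              n_slices = 60,
                              curvature_radius_um = 250,
                              attenuation_coeff = 0.01,
                              scatter_fraction = 0.05,
                              scatter_sigma_um = 1.0,
                              noise_sd = 2,
                              bit_depth = 8,
                              cytoplasm_level = 12.3,
                              edge_ramp_um = 0.8,
                              structural_peak = 230,
                              chirality = c("standard", "mirrored"),
                              orientation_deg = 0,
                              orientation_jitter_deg = 8,
                              helix_deg_per_um = 0,
                              n_levels_quant = 255,
                              seed = 1) {
  chirality <- match.arg(chirality)
  lens <- c(lattice_spacing_um, ommatidium_radius_um, pr_center_spacing_um,
            rhabdomere_radius_um, voxel_size_um, edge_ramp_um)
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("retina_sim_config: all lengths must be positive and finite")
  }
  if (n_ommatidia < 1 || n_slices < 5) {
    stop("retina_sim_config: need n_ommatidia >= 1 and n_slices >= 5")
  }
  if (scatter_fraction < 0 || scatter_fraction >= 1) {
    stop("retina_sim_config: scatter_fraction must lie in [0, 1)")
  }
  if (lattice_spacing_um <= 2 * ommatidium_radius_um) {
    stop("retina_sim_config: lattice_spacing must exceed twice the ",
         "ommatidium radius")
  }
  if (curvature_radius_um <= 0) stop("curvature_radius_um must be positive")
  structure(list(
    n_ommatidia = as.integer(n_ommatidia),
    lattice_spacing_um = lattice_spacing_um,
    ommatidium_radius_um = ommatidium_radius_um,
    pr_center_spacing_um = pr_center_spacing_um,
    rhabdomere_radius_um = rhabdomere_radius_um,
    voxel_size_um = voxel_size_um,
    n_slices = as.integer(n_slices),
    curvature_radius_um = curvature_radius_um,
    attenuation_coeff = attenuation_coeff,
    scatter_fraction = scatter_fraction,
    scatter_sigma_um = scatter_sigma_um,
    noise_sd = noise_sd,
    bit_depth = as.integer(bit_depth),
    cytoplasm_level = cytoplasm_level,
    edge_ramp_um = edge_ramp_um,
    structural_peak = structural_peak,
    chirality = chirality,
    orientation_deg = orientation_deg,
    orientation_jitter_deg = orientation_jitter_deg,
    helix_deg_per_um = helix_deg_per_um,
    n_levels_quant = as.integer(n_levels_quant),
    seed = as.integer(seed)), class = "retina_sim_config")
}

#' @export
print.retina_sim_config <- function(x, ...) {
  cat(sprintf(paste0("synthetic retina: %d ommatidia, %d slices, voxel ",
                     "%.2f x %.2f x %.2f um, curvature R = %s um\n"),
              x$n_ommatidia, x$n_slices, x$voxel_size_um[1],
              x$voxel_size_um[2], x$voxel_size_um[3],
              format(x$curvature_radius_um)))
  invisible(x)
}

# quantization grid used by the contour quantifier: n equally spaced levels
# spanning (0, max]; with n = 255 on 8-bit data these are the integer levels
.quant_levels <- function(n_levels, max_val = 255) {
  seq(max_val / n_levels, max_val, length.out = n_levels)
}

#' Expected ommatidial background reference of a simulated stack
#'
#' The closed-form length-weighted mean of the quantized contour levels that
#' cross the ommatidium's linear edge ramp — the value the contour
#' quantifier's reference level I_omma estimates on a clean stack.  This is
#' computed from the rendering equations, independently of any contour
#' extraction.
#'
#' @param cfg A `retina_sim_config`.
#' @return Expected reference intensity (scalar).
#' @export
expected_background_level <- function(cfg) {
  stopifnot(inherits(cfg, "retina_sim_config"))
  px <- cfg$voxel_size_um[3]
  r0 <- cfg$ommatidium_radius_um / px
  w <- cfg$edge_ramp_um / px
  cyt <- cfg$cytoplasm_level
  lv <- .quant_levels(cfg$n_levels_quant)
  lv <- lv[lv < cyt & lv > 0]
  if (length(lv) == 0) stop("no quantization level crosses the edge ramp")
  radii <- r0 + w * (1 - lv / cyt)   # ring radius at each level
  sum(lv * radii) / sum(radii)
}

# Gradient-weighted contour readout of a linear radial profile running from
# base level `cyt` at radius R to peak `v` at the center (a dip when
# v < cyt): the length-weighted mean over the quantized levels crossed.
# Continuous and monotone in v (a newly crossed level enters with zero ring
# length), hence invertible.
.cone_readout <- function(v, cyt, levels) {
  if (v > cyt) {
    lv <- levels[levels > cyt & levels < v]
    if (length(lv) == 0) return(NA_real_)
    w <- v - lv
  } else if (v < cyt) {
    lv <- levels[levels < cyt & levels > v]
    if (length(lv) == 0) return(NA_real_)
    w <- lv - v
  } else {
    return(NA_real_)
  }
  sum(lv * w) / sum(w)
}

# Invert .cone_readout: peak value whose contour readout equals `target`.
# Returns the clamped achievable peak and the level actually realized.
.invert_readout <- function(target, cyt, levels, max_val = 255) {
  lo_read <- .cone_readout(0, cyt, levels)
  hi_read <- .cone_readout(max_val, cyt, levels)
  if (target <= lo_read) {
    return(list(peak = 0, realized = lo_read, clipped = TRUE))
  }
  if (target >= hi_read) {
    return(list(peak = max_val, realized = hi_read, clipped = TRUE))
  }
  # dead zone between the highest dip readout and the lowest cone readout:
  # pick the closer side
  lv_above <- levels[levels > cyt]
  lv_below <- levels[levels < cyt]
  dip_max <- if (length(lv_below)) max(lv_below) else -Inf    # readout as v -> cyt-
  cone_min <- if (length(lv_above)) min(lv_above) else Inf    # readout as v -> cyt+
  # Quantization dead zone between the highest dip readout and the lowest
  # cone readout: snap to the nearer side, backing the peak off by a full
  # level so the single remaining contour survives 8-bit rounding.
  if (target > dip_max && target < cone_min) {
    step <- if (length(levels) > 1) diff(levels[1:2]) else 1
    if (target - dip_max <= cone_min - target) {
      v <- max(lv_below) - step
    } else {
      v <- min(lv_above) + step
    }
    return(list(peak = v, realized = .cone_readout(v, cyt, levels),
                clipped = TRUE))
  }
  if (target >= cone_min) {
    f <- function(v) .cone_readout(v, cyt, levels) - target
    v <- stats::uniroot(f, c(cone_min + 1e-9, max_val), tol = 1e-8)$root
  } else {
    f <- function(v) .cone_readout(v, cyt, levels) - target
    v <- stats::uniroot(f, c(0, dip_max - 1e-9), tol = 1e-8)$root
  }
  list(peak = v, realized = target, clipped = FALSE)
}

# 3D scaffold of the simulated retina: field size, ommatidium positions and
# axes, per-slice per-cell centers (in pixels).
.retina_geometry <- function(cfg) {
  px <- cfg$voxel_size_um[3]
  vz <- cfg$voxel_size_um[1]
  hex <- .hex_positions(cfg$n_ommatidia) * cfg$lattice_spacing_um
  margin <- cfg$ommatidium_radius_um + cfg$edge_ramp_um + 2
  half <- max(abs(hex)) + margin
  n_px <- 2 * ceiling(half / px) + 1
  center_px <- (n_px + 1) / 2
  z_um <- (seq_len(cfg$n_slices) - 1) * vz        # slice 1 deepest
  z_top <- max(z_um)
  R <- cfg$curvature_radius_um

  rho <- sqrt(rowSums(hex^2))
  # bowl surface height above each ommatidium; apex (center) sits 2 um above
  # the top slice
  sag <- if (is.finite(R)) R - sqrt(pmax(R^2 - rho^2, 0)) else rep(0, length(rho))
  surf_z <- z_top + 2 + sag
  # unit axis pointing from the surface point toward the sphere center
  if (is.finite(R)) {
    apex_center <- c(0, 0, z_top + 2 + R)
    ax <- cbind(-hex[, 1], -hex[, 2], apex_center[3] - surf_z)
    ax <- ax / sqrt(rowSums(ax^2))
  } else {
    ax <- cbind(rep(0, nrow(hex)), 0, 1)
  }

  layout0 <- .pr_layout(cfg$chirality) * (cfg$pr_center_spacing_um / 2)
  n_omm <- cfg$n_ommatidia
  omm_centers <- array(NA_real_, c(n_omm, cfg$n_slices, 2))  # (y, x) px
  cell_centers <- array(NA_real_, c(n_omm, 7, cfg$n_slices, 2))
  angles <- cfg$orientation_deg +
    stats::runif(n_omm, -1, 1) * cfg$orientation_jitter_deg
  for (i in seq_len(n_omm)) {
    th <- angles[i] * pi / 180
    rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    lay <- layout0 %*% t(rot)                     # (x, y) um in local frame
    drift <- ax[i, 1:2] / ax[i, 3]                # lateral um per um of z
    for (s in seq_len(cfg$n_slices)) {
      dz <- z_um[s] - surf_z[i]                   # negative: below surface
      tw <- cfg$helix_deg_per_um * dz * pi / 180
      rot_tw <- matrix(c(cos(tw), sin(tw), -sin(tw), cos(tw)), 2)
      lay_s <- lay %*% t(rot_tw)
      cx <- hex[i, 1] + drift[1] * dz
      cy <- hex[i, 2] + drift[2] * dz
      omm_centers[i, s, ] <- c(cy, cx) / px + center_px
      cell_centers[i, , s, 1] <- (cy + lay_s[, 2]) / px + center_px
      cell_centers[i, , s, 2] <- (cx + lay_s[, 1]) / px + center_px
    }
  }
  list(n_px = n_px, center_px = center_px, z_um = z_um,
       hex_um = hex, rho_um = rho, surf_z_um = surf_z, axes = ax,
       omm_centers_px = omm_centers, cell_centers_px = cell_centers,
       angles_deg = angles)
}

#' Generate a synthetic retina stack with ground truth
#'
#' Renders the structural (phalloidin-like) channel and any number of
#' reporter channels, applies curvature-dependent attenuation, scatter
#' halos, sensor noise, and 8-bit quantization, and returns the stack
#' together with the complete ground truth (ommatidium and cell centers per
#' slice, PR identities, programmed expression levels and on/off states).
#'
#' Reporter levels are programmed in relative-intensity (I_l) units: each
#' rhabdomere is rendered as a linear radial profile whose peak is chosen so
#' that its length-weighted contour readout, normalized by the expected
#' ommatidial background, equals the programmed level.  Levels below the
#' representable floor render as intensity dips (dark rhabdomeres against
#' cytoplasm); levels outside the 8-bit-representable range are clamped and
#' flagged in the ground truth.
#'
#' @param cfg A `retina_sim_config`.
#' @param expression Named list of `two_state_params`, one per reporter
#'   channel (may be empty for a structural-only stack).
#' @return A list with `stack` (a `confocal_stack`) and `truth` (a
#'   `retina_ground_truth`: data frames `ommatidia` and `cells`, per-slice
#'   center arrays, the expected background reference, and the echoed
#'   config).
#' @export
generate_retina_stack <- function(cfg,
                                  expression = list(
                                    Rh6 = reference_two_state_fits("Rh6", "2wk"))) {
  stopifnot(inherits(cfg, "retina_sim_config"))
  if (length(expression) > 0 &&
      (is.null(names(expression)) || any(names(expression) == ""))) {
    stop("expression must be a named list of two_state_params")
  }
  set.seed(cfg$seed)
  geom <- .retina_geometry(cfg)
  px <- cfg$voxel_size_um[3]
  n_px <- geom$n_px
  n_omm <- cfg$n_ommatidia
  cyt <- cfg$cytoplasm_level
  levels_q <- .quant_levels(cfg$n_levels_quant)
  m_hat <- expected_background_level(cfg)
  r_rh <- cfg$rhabdomere_radius_um / px
  r_omm <- cfg$ommatidium_radius_um / px
  w_ramp <- cfg$edge_ramp_um / px
  max_val <- 2^cfg$bit_depth - 1

  # per-cell programmed expression
  chans <- names(expression)
  cells <- data.frame(ommatidium = rep(seq_len(n_omm), each = 7),
                      cell = rep(seq_len(7), n_omm),
                      label = rep(.pr_labels, n_omm))
  peaks <- list()
  for (ch in chans) {
    draw <- sample_two_state_levels(expression[[ch]], n_omm * 7)
    inv <- lapply(draw$levels * m_hat, .invert_readout, cyt = cyt,
                  levels = levels_q, max_val = max_val)
    cells[[paste0("level_", ch)]] <- draw$levels
    cells[[paste0("state_", ch)]] <- as.character(draw$states)
    cells[[paste0("rendered_level_", ch)]] <-
      vapply(inv, `[[`, numeric(1), "realized") / m_hat
    cells[[paste0("clipped_", ch)]] <- vapply(inv, `[[`, logical(1), "clipped")
    peaks[[ch]] <- matrix(vapply(inv, `[[`, numeric(1), "peak"),
                          nrow = n_omm, ncol = 7, byrow = TRUE)
  }

  # render clean channels slice by slice
  render_channel <- function(peak_fun) {
    arr <- array(0, c(n_px, n_px, cfg$n_slices))
    for (s in seq_len(cfg$n_slices)) {
      img <- matrix(0, n_px, n_px)
      for (i in seq_len(n_omm)) {
        oc <- geom$omm_centers_px[i, s, ]
        # ommatidium crop: disc with linear edge ramp, then the 7 cones
        rc <- ceiling(r_omm + w_ramp)
        ys <- max(1, floor(oc[1]) - rc):min(n_px, ceiling(oc[1]) + rc)
        xs <- max(1, floor(oc[2]) - rc):min(n_px, ceiling(oc[2]) + rc)
        r <- sqrt(outer((ys - oc[1])^2, (xs - oc[2])^2, "+"))
        crop <- cyt * pmin(pmax((r_omm + w_ramp - r) / w_ramp, 0), 1)
        crop[r <= r_omm] <- cyt
        for (k in seq_len(7)) {
          cc <- geom$cell_centers_px[i, k, s, ]
          rk <- sqrt(outer((ys - cc[1])^2, (xs - cc[2])^2, "+"))
          inside <- rk <= r_rh
          pk <- peak_fun(i, k)
          crop[inside] <- pk + (cyt - pk) * rk[inside] / r_rh
        }
        img[ys, xs] <- pmax(img[ys, xs], crop)
      }
      arr[, , s] <- img
    }
    arr
  }

  channels <- list(
    phalloidin = render_channel(function(i, k) cfg$structural_peak))
  for (ch in chans) {
    pk <- peaks[[ch]]
    channels[[ch]] <- render_channel(function(i, k) pk[i, k])
  }

  stack <- confocal_stack(channels, cfg$voxel_size_um)
  stack <- apply_depth_attenuation(stack, cfg)

  # scatter: a fixed fraction of bright-cell intensity, blurred into a halo
  if (cfg$scatter_fraction > 0) {
    sigma_px <- cfg$scatter_sigma_um / px
    thr <- 0.4 * max_val
    for (ch in names(stack$channels)) {
      arr <- stack$channels[[ch]]
      for (s in seq_len(cfg$n_slices)) {
        img <- arr[, , s]
        bright <- pmax(img - thr, 0)
        if (any(bright > 0)) {
          halo <- EBImage::gblur(bright, sigma = sigma_px)
          arr[, , s] <- img + cfg$scatter_fraction * halo
        }
      }
      stack$channels[[ch]] <- arr
    }
  }

  # sensor noise and quantization
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    if (cfg$noise_sd > 0) {
      arr <- arr + stats::rnorm(length(arr), 0, cfg$noise_sd)
    }
    arr <- round(pmin(pmax(arr, 0), max_val))
    storage.mode(arr) <- "integer"
    stack$channels[[ch]] <- arr
  }

  omm_df <- data.frame(
    ommatidium = seq_len(n_omm),
    x_um = geom$hex_um[, 1], y_um = geom$hex_um[, 2],
    rho_um = geom$rho_um, surface_z_um = geom$surf_z_um,
    tilt_deg = acos(pmin(geom$axes[, 3], 1)) * 180 / pi,
    orientation_deg = geom$angles_deg)

  truth <- structure(list(
    ommatidia = omm_df,
    cells = cells,
    omm_centers_px = geom$omm_centers_px,
    cell_centers_px = geom$cell_centers_px,
    expected_reference = m_hat,
    config = cfg), class = "retina_ground_truth")
  list(stack = stack, truth = truth)
}

#' Apply depth- and curvature-dependent attenuation
#'
#' Scales every voxel by `exp(-attenuation_coeff * path)` where `path` is
#' the overlying tissue path length under the spherical-cap retina model:
#' the tissue surface is a bowl, so at equal depth light reaching peripheral
#' positions crosses more tissue and arrives dimmer.  With a flat retina
#' (`curvature_radius_um = Inf`) and zero coefficient the stack is
#' unchanged.
#'
#' @param stack A `confocal_stack`.
#' @param cfg A `retina_sim_config` supplying the curvature and coefficient.
#' @return The attenuated `confocal_stack`.
#' @export
apply_depth_attenuation <- function(stack, cfg) {
  stopifnot(inherits(stack, "confocal_stack"),
            inherits(cfg, "retina_sim_config"))
  if (cfg$attenuation_coeff == 0) return(stack)
  d <- dim(stack$channels[[1]])
  px <- stack$voxel_size_um[3]
  vz <- stack$voxel_size_um[1]
  cy <- (d[1] + 1) / 2
  cx <- (d[2] + 1) / 2
  rho2 <- outer(((seq_len(d[1]) - cy) * px)^2, ((seq_len(d[2]) - cx) * px)^2, "+")
  R <- cfg$curvature_radius_um
  sag <- if (is.finite(R)) R - sqrt(pmax(R^2 - rho2, 0)) else 0
  z_top <- (d[3] - 1) * vz
  surf <- z_top + 2 + sag
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    int_in <- is.integer(arr)
    arr <- arr * 1.0
    for (s in seq_len(d[3])) {
      path <- surf - (s - 1) * vz
      arr[, , s] <- arr[, , s] * exp(-cfg$attenuation_coeff * path)
    }
    if (int_in) {
      arr <- round(arr)
      storage.mode(arr) <- "integer"
    }
    stack$channels[[ch]] <- arr
  }
  stack
}

#' Read programmed contrast back from a clean simulated stack
#'
#' For each cell, the mean reporter intensity inside the rhabdomere disc
#' divided by the expected local background reference.  On a noise-free,
#' attenuation-free, scatter-free stack this equals the programmed level (up
#' to quantization), because for a linear radial profile the area-mean and
#' the length-weighted contour mean coincide.
#'
#' @param sim Result of [generate_retina_stack()].
#' @param channel Reporter channel name.
#' @param slice Slice index at which to read (default: middle slice).
#' @return Numeric vector of readback levels, one per cell (row order of
#'   `sim$truth$cells`).
#' @export
gt_readback_contrast <- function(sim, channel, slice = NULL) {
  cfg <- sim$truth$config
  if (is.null(slice)) slice <- ceiling(cfg$n_slices / 2)
  arr <- sim$stack$channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  img <- arr[, , slice]
  r_rh <- cfg$rhabdomere_radius_um / cfg$voxel_size_um[3]
  m_hat <- sim$truth$expected_reference
  out <- numeric(nrow(sim$truth$cells))
  idx <- 1
  for (i in seq_len(cfg$n_ommatidia)) {
    for (k in seq_len(7)) {
      cc <- sim$truth$cell_centers_px[i, k, slice, ]
      ys <- floor(cc[1] - r_rh):ceiling(cc[1] + r_rh)
      xs <- floor(cc[2] - r_rh):ceiling(cc[2] + r_rh)
      r <- sqrt(outer((ys - cc[1])^2, (xs - cc[2])^2, "+"))
      vals <- img[ys, xs][r <= r_rh]
      out[idx] <- mean(vals) / m_hat
      idx <- idx + 1
    }
  }
  out
}

#' Write a simulated retina to disk
#'
#' One multi-page 8-bit TIFF per channel plus a JSON ground-truth sidecar
#' echoing all generator parameters.
#'
#' @param sim Result of [generate_retina_stack()].
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Invisibly, the paths written.
#' @export
write_simulated_retina <- function(sim, dir, name = "retina") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(sim$stack$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", name, ch))
    write_stack_channel(sim$stack, ch, p)
    paths <- c(paths, p)
  }
  truth <- sim$truth
  side <- list(
    config = unclass(truth$config),
    expected_reference = truth$expected_reference,
    ommatidia = truth$ommatidia,
    cells = truth$cells,
    omm_centers_px = truth$omm_centers_px,
    cell_centers_px = truth$cell_centers_px)
  pj <- file.path(dir, sprintf("%s_truth.json", name))
  jsonlite::write_json(side, pj, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, pj))
}
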