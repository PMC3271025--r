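# Shared fixtures, generated once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# small flat noiseless retina: 7 ommatidia, ideal optics
clean_flat_config <- function(...) {
  args <- list(n_ommatidia = 7, n_slices = 20, noise_sd = 0,
               attenuation_coeff = 0, scatter_fraction = 0,
               curvature_radius_um = Inf, seed = 42)
  override <- list(...)
  args[names(override)] <- override
  do.call(retina_sim_config, args)
}

clean_sim <- function() {
  fixture("clean_sim", function() generate_retina_stack(clean_flat_config()))
}

clean_analysis <- function() {
  fixture("clean_analysis", function() {
    suppressWarnings(analyze_stack(clean_sim()$stack,
                                   pipeline_config(reporters = "Rh6",
                                                   seed = 7)))
  })
}

# one full default-conditions stack (curved, attenuated, noisy, scatter)
default_sim <- function() {
  fixture("default_sim", function() {
    generate_retina_stack(retina_sim_config(seed = 101), expression = list())
  })
}

default_analysis <- function() {
  fixture("default_analysis", function() {
    suppressWarnings(analyze_stack(default_sim()$stack,
                                   pipeline_config(seed = 3)))
  })
}

# total probability mass of a two-state density by piecewise quadrature
# (the on component can have an integrable singularity at its shift)
two_state_total_mass <- function(p) {
  f <- function(x) dtwo_state(x, p)
  integrate(f, p$dx, p$shift_on, rel.tol = 1e-9,
            subdivisions = 500L)$value +
    integrate(f, p$shift_on, p$shift_on + 1, rel.tol = 1e-9,
              subdivisions = 500L)$value +
    integrate(f, p$shift_on + 1, Inf, rel.tol = 1e-9,
              subdivisions = 500L)$value
}

# match detected resolved volumes to ground-truth ommatidia; returns rows of
# (volume index, gt ommatidium, distance)
match_volumes_to_truth <- function(analysis, truth) {
  cfg <- truth$config
  zr <- analysis$zrange$z
  out <- NULL
  for (i in which(analysis$resolved)) {
    v <- analysis$volumes[[i]]
    zsel <- max(zr[1], v$z_first):min(zr[2], v$z_last)
    sel <- v$centroids[, "slice"] %in% zsel
    det_c <- colMeans(v$centroids[sel, c("y", "x"), drop = FALSE])
    gt_c <- t(vapply(seq_len(cfg$n_ommatidia), function(g) {
      colMeans(truth$omm_centers_px[g, zsel, , drop = FALSE][1, , ])
    }, numeric(2)))
    d <- sqrt((gt_c[, 1] - det_c[1])^2 + (gt_c[, 2] - det_c[2])^2)
    out <- rbind(out, data.frame(volume = i, gt = which.min(d),
                                 dist = min(d)))
  }
  out
}
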