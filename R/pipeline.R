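# End-to-end orchestration: detect -> trace -> z-range -> label -> quantify,
# plus file I/O, configuration validation, and the identity benchmark
# against synthetic ground truth.

#' Pipeline configuration
#'
#' Validates all stage parameters against the module preconditions at load
#' time.
#'
#' @param input Named character vector of TIFF paths (channel -> path), or
#'   `NULL` when an in-memory stack is supplied to [run_pipeline()].
#' @param structural Name of the structural (phalloidin) channel.
#' @param reporters Character vector of reporter channel names (may be
#'   empty).
#' @param voxel_size_um Voxel size `c(z, y, x)` in microns.
#' @param n_levels_detect Contour levels for Step-1 detection (over 0-255).
#' @param size_range Acceptable ommatidial region size (pixels).
#' @param link_window Linking window (slices).
#' @param filter_type Max-filter semantics (`"tiled"` or `"sliding"`).
#' @param n_points Points per tracing window.
#' @param displacement_cap z-range selection cap (pixels).
#' @param n_levels_quant Contour levels for quantification.
#' @param pad_px Crop padding for quantification (pixels).
#' @param label_tol Relative tie tolerance of the labeling chain.
#' @param seed Integer seed driving all randomness.
#' @param output_dir Output directory for [run_pipeline()] tables.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            structural = "phalloidin",
                            reporters = character(0),
                            voxel_size_um = c(0.25, 0.16, 0.16),
                            n_levels_detect = 20,
                            size_range = c(500, 1000),
                            link_window = 5,
                            filter_type = c("tiled", "sliding"),
                            n_points = 800,
                            displacement_cap = 2,
                            n_levels_quant = 255,
                            pad_px = 18,
                            label_tol = 0.05,
                            seed = 1,
                            output_dir = NULL) {
  filter_type <- match.arg(filter_type)
  if (!is.null(input)) {
    if (is.null(names(input)) || any(names(input) == "")) {
      stop("input paths must be named by channel")
    }
    if (!structural %in% names(input)) {
      stop("missing structural channel role '", structural, "' in input")
    }
    if (!all(reporters %in% names(input))) {
      stop("missing reporter channel role(s): ",
           paste(setdiff(reporters, names(input)), collapse = ", "))
    }
  }
  if (n_levels_detect < 2 || n_levels_quant < 2) stop("need >= 2 levels")
  if (length(size_range) != 2 || size_range[1] >= size_range[2] ||
      size_range[1] <= 0) stop("invalid size_range")
  if (link_window < 2) stop("link_window must be >= 2")
  if (n_points < 7) stop("n_points must be >= 7")
  if (displacement_cap <= 0) stop("displacement_cap must be > 0")
  if (pad_px < 0) stop("pad_px must be >= 0")
  structure(list(input = input, structural = structural,
                 reporters = reporters, voxel_size_um = voxel_size_um,
                 n_levels_detect = n_levels_detect, size_range = size_range,
                 link_window = link_window, filter_type = filter_type,
                 n_points = n_points, displacement_cap = displacement_cap,
                 n_levels_quant = n_levels_quant, pad_px = pad_px,
                 label_tol = label_tol, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Analyze a confocal stack in memory
#'
#' The full chain: ommatidium detection, photoreceptor tracing, z-range
#' selection, geometric labeling, and (for each reporter channel) local
#' relative intensity quantification.
#'
#' @param stack A `confocal_stack`.
#' @param config A `pipeline_config`.
#' @return An object of class `retina_analysis`: `volumes`, `traces`
#'   (aligned with volumes), `zrange`, `labels` (per volume, `pr_label_map`
#'   or NULL), `resolved` (logical per volume), `measurements` (data.frame:
#'   ommatidium, cell, label, channel, I_l, n_slices_used).
#' @export
analyze_stack <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "confocal_stack"))
  if (n_slices(stack) < config$link_window) {
    stop("stack has fewer than ", config$link_window, " slices")
  }
  if (!config$structural %in% names(stack$channels)) {
    stop("stack lacks structural channel '", config$structural, "'")
  }
  volumes <- detect_ommatidia(stack, channel = config$structural,
                              n_levels = config$n_levels_detect,
                              size_range = config$size_range,
                              window = config$link_window,
                              filter_type = config$filter_type)
  if (length(volumes) == 0) stop("no ommatidia detected")

  traceable <- vapply(volumes, function(v) {
    (v$z_last - v$z_first + 1) >= config$link_window
  }, logical(1))
  traces <- vector("list", length(volumes))
  for (i in which(traceable)) {
    traces[[i]] <- trace_photoreceptors(
      volumes[[i]], stack, channel = config$structural,
      n_points = config$n_points, window = config$link_window,
      seed = config$seed + volumes[[i]]$id)
  }
  qualities <- lapply(traces[traceable], clustering_goodness)
  zr <- select_quantification_zrange(qualities,
                                     displacement_cap = config$displacement_cap)
  included <- logical(length(volumes))
  included[which(traceable)] <- zr$included

  labels <- vector("list", length(volumes))
  resolved <- logical(length(volumes))
  for (i in which(included)) {
    zlo <- max(zr$z[1], volumes[[i]]$z_first)
    zhi <- min(zr$z[2], volumes[[i]]$z_last)
    if (zhi < zlo) next
    ctr <- mean_centers(traces[[i]], c(zlo, zhi))
    lm <- label_pr_types(ctr, rel_tol = config$label_tol)
    labels[[i]] <- lm
    resolved[i] <- lm$determined
  }

  measurements <- NULL
  for (ch in config$reporters) {
    for (i in which(resolved)) {
      m <- quantify_ommatidium(stack, ch, volumes[[i]], traces[[i]], zr$z,
                               n_levels = config$n_levels_quant,
                               pad_px = config$pad_px)
      m$label <- labels[[i]]$labels[m$cell]
      measurements <- rbind(measurements, m)
    }
  }
  if (!is.null(measurements)) {
    measurements <- measurements[, c("ommatidium", "cell", "label",
                                     "channel", "I_l", "n_slices_used")]
  }
  structure(list(volumes = volumes, traces = traces, zrange = zr,
                 labels = labels, resolved = resolved,
                 measurements = measurements, config = config),
            class = "retina_analysis")
}

#' @export
print.retina_analysis <- function(x, ...) {
  cat(sprintf(paste0("retina analysis: %d ommatidium volumes, %d resolved; ",
                     "z-range %d-%d\n"),
              length(x$volumes), sum(x$resolved), x$zrange$z[1],
              x$zrange$z[2]))
  if (!is.null(x$measurements)) {
    cat(sprintf("  %d measurements across channels: %s\n",
                nrow(x$measurements),
                paste(unique(x$measurements$channel), collapse = ", ")))
  }
  invisible(x)
}

#' Run the pipeline from files to tables
#'
#' Reads the input TIFFs, runs [analyze_stack()], and writes the region
#' table, trace table, measurement table (TSV) and a JSON manifest
#' (parameters, seed, z-range, per-stage timings) to the output directory.
#'
#' @param config A `pipeline_config` with `input` and `output_dir` set.
#' @param stack Optional in-memory `confocal_stack` (skips reading).
#' @return The `retina_analysis`, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config, stack = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  if (is.null(stack)) {
    if (is.null(config$input)) stop("config has no input paths")
    stack <- read_stack(config$input, config$voxel_size_um)
  }
  timings$read <- proc.time()[["elapsed"]] - t0
  res <- analyze_stack(stack, config)
  timings$analyze <- proc.time()[["elapsed"]] - t0 - timings$read

  dir <- config$output_dir
  if (is.null(dir)) stop("config has no output_dir")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  region_rows <- do.call(rbind, lapply(res$volumes, function(v) {
    data.frame(id = v$id, slice = v$centroids[, "slice"],
               y = v$centroids[, "y"], x = v$centroids[, "x"],
               size = as.numeric(v$sizes))
  }))
  utils::write.table(region_rows, file.path(dir, "regions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  trace_rows <- NULL
  for (i in seq_along(res$traces)) {
    tr <- res$traces[[i]]
    if (is.null(tr)) next
    lm <- res$labels[[i]]
    for (k in seq_len(7)) {
      trace_rows <- rbind(trace_rows, data.frame(
        ommatidium = tr$ommatidium, cell = k,
        label = if (!is.null(lm) && lm$determined) lm$labels[k] else NA,
        slice = tr$z, y = tr$centers[k, , 1], x = tr$centers[k, , 2]))
    }
  }
  utils::write.table(trace_rows, file.path(dir, "traces.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  if (!is.null(res$measurements)) {
    utils::write.table(res$measurements, file.path(dir, "measurements.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("ommaquant")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(unclass(config)),
                                         c("input", "output_dir"))],
    z_range = res$zrange$z,
    n_volumes = length(res$volumes),
    n_resolved = sum(res$resolved),
    timings_s = timings)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Photoreceptor identity error against synthetic ground truth
#'
#' Matches resolved ommatidium volumes to ground-truth ommatidia (centroid
#' within one ommatidium radius) and, within each matched ommatidium,
#' assigns every ground-truth photoreceptor to its nearest traced cell
#' (mean centers over the quantification range).  The error rate is the
#' fraction of ground-truth PRs in resolved ommatidia whose assigned
#' identity (R1-R6, R7/8) is wrong.
#'
#' @param analysis A `retina_analysis`.
#' @param truth A `retina_ground_truth`.
#' @return A list with `n_resolved`, `n_cells`, `n_wrong`, `error_rate`.
#' @export
pr_identity_error <- function(analysis, truth) {
  cfg <- truth$config
  r_px <- cfg$ommatidium_radius_um / cfg$voxel_size_um[3]
  zr <- analysis$zrange$z
  n_wrong <- 0L
  n_cells <- 0L
  n_resolved <- 0L
  for (i in which(analysis$resolved)) {
    v <- analysis$volumes[[i]]
    tr <- analysis$traces[[i]]
    zlo <- max(zr[1], v$z_first); zhi <- min(zr[2], v$z_last)
    if (zhi < zlo) next
    sel <- v$centroids[, "slice"] >= zlo & v$centroids[, "slice"] <= zhi
    det_c <- colMeans(v$centroids[sel, c("y", "x"), drop = FALSE])
    zsel <- zlo:zhi
    gt_c <- t(vapply(seq_len(cfg$n_ommatidia), function(g) {
      colMeans(truth$omm_centers_px[g, zsel, , drop = FALSE][1, , ])
    }, numeric(2)))
    d <- sqrt((gt_c[, 1] - det_c[1])^2 + (gt_c[, 2] - det_c[2])^2)
    g <- which.min(d)
    if (d[g] > r_px) next
    n_resolved <- n_resolved + 1L
    det_centers <- mean_centers(tr, c(zlo, zhi))
    det_labels <- analysis$labels[[i]]$labels
    for (k in seq_len(7)) {
      gt_cc <- colMeans(truth$cell_centers_px[g, k, zsel, , drop = FALSE][1, 1, , ])
      dd <- sqrt(rowSums(sweep(det_centers, 2, gt_cc)^2))
      assigned <- det_labels[which.min(dd)]
      n_cells <- n_cells + 1L
      if (is.na(assigned) || assigned != truth$cells$label[
        truth$cells$ommatidium == g & truth$cells$cell == k]) {
        n_wrong <- n_wrong + 1L
      }
    }
  }
  list(n_resolved = n_resolved, n_cells = n_cells, n_wrong = n_wrong,
       error_rate = if (n_cells > 0) n_wrong / n_cells else NA_real_)
}
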