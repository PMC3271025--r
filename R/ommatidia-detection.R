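# Ommatidium segmentation: per-slice contour-level local thresholding
# (Step 1) and 3D linking into ommatidium volumes with fused-region
# correction (Step 2).

#' Label connected components of a binary image
#'
#' 8-connected labeling, built from 4-connected labeling
#' (`EBImage::bwlabel`) with a vectorized diagonal-adjacency merge.
#'
#' @param binary Logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(binary, connectivity = 8) {
  m <- matrix(as.numeric(binary != 0), nrow(binary), ncol(binary))
  lab <- EBImage::bwlabel(m)
  mx <- max(lab)
  if (connectivity == 4 || mx <= 1) {
    return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  }
  nr <- nrow(lab)
  n_all <- length(lab)
  nz <- which(lab > 0)
  lv <- lab[nz]
  row_i <- ((nz - 1L) %% nr) + 1L
  pairs <- NULL
  for (off in c(nr + 1L, nr - 1L)) {    # down-right / up-right diagonals
    ok <- if (off == nr + 1L) row_i < nr else row_i > 1L
    nb <- nz[ok] + off
    ok2 <- nb >= 1L & nb <= n_all
    nbv <- lab[nb[ok2]]
    a <- lv[ok][ok2]
    sel <- nbv > 0 & nbv != a
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], nbv[sel]))
  }
  if (is.null(pairs)) {
    return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  }
  pairs <- unique(pairs)
  # union-find over the (few) label adjacencies
  parent <- seq_len(mx)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find_root(pairs[r, 1])
    b <- find_root(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(mx), find_root, numeric(1))
  root <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, ncol(lab))
  out[nz] <- as.integer(root[lv])
  out
}

#' Maximum-value filter
#'
#' Replaces intensities by the maximum over a `window` x `window`
#' neighborhood.  `type = "tiled"` computes one maximum per non-overlapping
#' window and assigns it to all pixels of that window; `type = "sliding"`
#' is the conventional moving-window maximum filter.  The filter blurs
#' differences between photoreceptors within an ommatidium while keeping
#' the contrast between ommatidia and background.
#'
#' @param img 2D numeric matrix.
#' @param window Odd window size >= 1 (pixels).
#' @param type `"tiled"` (default) or `"sliding"`.
#' @return Filtered matrix of the same size.
#' @export
max_filter <- function(img, window = 5, type = c("tiled", "sliding")) {
  type <- match.arg(type)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window == 1) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (type == "tiled") {
    nrp <- ceiling(nr / window) * window
    ncp <- ceiling(nc / window) * window
    mp <- matrix(-Inf, nrp, ncp)
    mp[seq_len(nr), seq_len(nc)] <- img
    rmax <- mp[seq(1, nrp, window), , drop = FALSE]
    for (k in seq_len(window - 1)) {
      rmax <- pmax(rmax, mp[seq(1 + k, nrp, window), , drop = FALSE])
    }
    bmax <- rmax[, seq(1, ncp, window), drop = FALSE]
    for (k in seq_len(window - 1)) {
      bmax <- pmax(bmax, rmax[, seq(1 + k, ncp, window), drop = FALSE])
    }
    out <- bmax[rep(seq_len(nrow(bmax)), each = window)[seq_len(nr)],
                rep(seq_len(ncol(bmax)), each = window)[seq_len(nc)],
                drop = FALSE]
    return(out)
  }
  # sliding: running pmax over all shifts within the half-window
  h <- (window - 1) / 2
  out <- img
  for (dy in -h:h) {
    ys_src <- max(1, 1 + dy):min(nr, nr + dy)
    ys_dst <- max(1, 1 - dy):min(nr, nr - dy)
    shifted_rows <- img[ys_src, , drop = FALSE]
    for (dx in -h:h) {
      if (dy == 0 && dx == 0) next
      xs_src <- max(1, 1 + dx):min(nc, nc + dx)
      xs_dst <- max(1, 1 - dx):min(nc, nc - dx)
      out[ys_dst, xs_dst] <- pmax(out[ys_dst, xs_dst],
                                  shifted_rows[, xs_src, drop = FALSE])
    }
  }
  out
}

# region bookkeeping helper
.region_from_pixels <- function(pixels, dims) {
  yx <- arrayInd(pixels, dims)
  list(pixels = pixels, size = length(pixels),
       bbox = c(range(yx[, 1]), range(yx[, 2])),
       centroid = c(mean(yx[, 1]), mean(yx[, 2])))
}

#' Find putative ommatidial regions in one optical slice
#'
#' Iterates intensity contour levels from highest to lowest over the
#' max-filtered structural slice.  At each level the superlevel set is
#' thresholded and its 8-connected components found; a growing region is
#' frozen the first time its pixel count enters `size_range`.  Regions that
#' are never within range at any level are discarded.  The local (per
#' region) stopping rule lets both dim and bright ommatidia be detected
#' despite intensity variation across the retina.
#'
#' @param slice 2D matrix (max-filtered structural channel, 0-255).
#' @param n_levels Number of equally spaced contour levels over 0-255.
#' @param size_range Acceptable region size `c(min, max)` in pixels
#'   (a typical ommatidial cross-section is 500-1000 px at 160 nm pixels).
#' @return An object of class `slice_region_set`: list with `regions`
#'   (each with `pixels`, `size`, `bbox`, `centroid`), `dims`, `n_levels`.
#' @export
find_ommatidia_2d <- function(slice, n_levels = 20, size_range = c(500, 1000)) {
  dims <- dim(slice)
  levels <- seq(0, 255, length.out = n_levels)
  levels <- sort(levels[levels > 0], decreasing = TRUE)
  frozen <- matrix(FALSE, dims[1], dims[2])
  regions <- list()
  for (lv in levels) {
    binary <- slice >= lv
    if (!any(binary)) next
    lab <- label_components(binary, connectivity = 8)
    n_comp <- max(lab)
    if (n_comp == 0) next
    sizes <- tabulate(lab[lab > 0], nbins = n_comp)
    hit <- which(sizes >= size_range[1] & sizes <= size_range[2])
    # a component that contains pixels of a frozen region is that region's
    # continued growth: the region has stopped, so the component is skipped
    stopped <- unique(lab[frozen])
    hit <- setdiff(hit, stopped)
    if (length(hit) == 0) next
    cand <- which(lab %in% hit)
    by_comp <- split(cand, lab[cand])
    for (pix in by_comp) {
      regions[[length(regions) + 1]] <- .region_from_pixels(pix, dims)
      frozen[pix] <- TRUE
    }
  }
  structure(list(regions = regions, dims = dims, n_levels = n_levels,
                 size_range = size_range),
            class = "slice_region_set")
}

#' @export
print.slice_region_set <- function(x, ...) {
  cat(sprintf("slice region set: %d regions (%d x %d px)\n",
              length(x$regions), x$dims[1], x$dims[2]))
  invisible(x)
}

#' Split an oversized (possibly fused) region across volumes
#'
#' Implements the Step-2 correction: if an incoming region exceeds the
#' running mean region size of its ommatidium by more than one SD, only the
#' directly overlapping portion joins that ommatidium; the remainder is
#' tested against adjacent ommatidia and re-assigned where it overlaps,
#' otherwise it seeds a new nascent ommatidium.
#'
#' @param new_pixels Integer pixel indices of the incoming region.
#' @param overlap_map Integer vector over the image (0 = unassigned) giving
#'   the volume id occupying each pixel within the current linking window.
#' @param primary_id Volume id the region directly overlaps (largest
#'   overlap).
#' @param running_mean,running_sd Running size statistics of `primary_id`
#'   over its recent slices.  The effective tolerance is
#'   `max(running_sd, 0.05 * running_mean)` so that ordinary slice-to-slice
#'   size jitter never triggers a split when the running SD happens to be
#'   tiny.
#' @param min_new_size Minimum pixel count for a split remainder to seed a
#'   new nascent ommatidium; smaller remainders are ordinary growth and
#'   stay with the primary volume.
#' @return A list: `assignments` (named list volume id -> pixel indices)
#'   and `new_volume_pixels` (pixels seeding a new volume, possibly empty).
#' @export
split_fused_regions <- function(new_pixels, overlap_map, primary_id,
                                running_mean, running_sd,
                                min_new_size = 200) {
  size <- length(new_pixels)
  if (!is.finite(running_sd)) running_sd <- Inf
  tol <- max(running_sd, 0.05 * running_mean)
  if (size <= running_mean + tol) {
    out <- list(assignments = stats::setNames(list(new_pixels),
                                              as.character(primary_id)),
                new_volume_pixels = integer(0))
    return(out)
  }
  owner <- overlap_map[new_pixels]
  assignments <- list()
  assignments[[as.character(primary_id)]] <- new_pixels[owner == primary_id]
  rest <- new_pixels[owner != primary_id]
  other_ids <- setdiff(unique(owner[owner != primary_id]), 0)
  for (id in other_ids) {
    assignments[[as.character(id)]] <- rest[overlap_map[rest] == id]
  }
  leftover <- rest[overlap_map[rest] == 0]
  if (length(leftover) >= min_new_size) {
    return(list(assignments = assignments, new_volume_pixels = leftover))
  }
  assignments[[as.character(primary_id)]] <-
    c(assignments[[as.character(primary_id)]], leftover)
  list(assignments = assignments, new_volume_pixels = integer(0))
}

#' Link per-slice regions into 3D ommatidium volumes
#'
#' Slides a window of `window` slices from the deepest slice upward.
#' Regions overlapping (sharing at least one (y, x) pixel with) a nascent
#' ommatidium's recent footprint are added to it; in-range regions with no
#' overlap seed new nascent ommatidia.  Every incoming region is screened
#' by the fused-region correction ([split_fused_regions()]) against the
#' running size statistics of its target volume (window of
#' `stats_window` slices).  Volumes are trimmed to their longest contiguous
#' z-run; volumes spanning fewer than `window` slices are dropped (an
#' isolated single-slice region is not an ommatidium).
#'
#' @param per_slice List of `slice_region_set`, index 1 = deepest slice.
#' @param window Linking window in slices.
#' @param stats_window Number of recent slices for the running size
#'   statistics.
#' @return List of `ommatidium_volume` objects: `id`, `slices` (named list
#'   slice -> pixel indices), `z_first`, `z_last`, `centroids` (matrix with
#'   slice, y, x), `sizes`, `dims`, `on_border`.
#' @export
link_ommatidia_3d <- function(per_slice, window = 5, stats_window = 20) {
  n_sl <- length(per_slice)
  if (n_sl < window) stop("need at least ", window, " slices")
  dims <- per_slice[[1]]$dims
  npx <- prod(dims)
  volumes <- list()           # id -> list(slices = list("z" = pixels))
  slice_assign <- vector("list", n_sl)  # per slice: list(pixels, ids)
  next_id <- 1L

  overlap_map_for <- function(s) {
    map <- integer(npx)
    lo <- max(1, s - (window - 1))
    for (z in lo:(s - 1)) {
      sa <- slice_assign[[z]]
      if (!is.null(sa)) map[sa$pixels] <- sa$ids
    }
    map
  }

  assign_region <- function(pix, id, s) {
    zc <- as.character(s)
    volumes[[id]]$slices[[zc]] <<- c(volumes[[id]]$slices[[zc]], pix)
    sa <- slice_assign[[s]]
    slice_assign[[s]] <<- list(pixels = c(sa$pixels, pix),
                               ids = c(sa$ids, rep(as.integer(id), length(pix))))
  }

  new_volume <- function(pix, s) {
    id <- next_id
    next_id <<- next_id + 1L
    volumes[[id]] <<- list(slices = list())
    assign_region(pix, id, s)
    id
  }

  for (s in seq_len(n_sl)) {
    regs <- per_slice[[s]]$regions
    if (length(regs) == 0) next
    map <- if (s == 1) integer(npx) else overlap_map_for(s)
    for (r in regs) {
      owners <- map[r$pixels]
      ids <- unique(owners[owners > 0])
      if (length(ids) == 0) {
        new_volume(r$pixels, s)
        next
      }
      primary <- ids[which.max(vapply(ids, function(i) sum(owners == i),
                                      numeric(1)))]
      # running size statistics of the primary volume's recent slices
      szs <- vapply(volumes[[primary]]$slices, length, numeric(1))
      szs <- utils::tail(szs, stats_window)
      run_mean <- mean(szs)
      run_sd <- if (length(szs) >= 2) stats::sd(szs) else Inf
      sp <- split_fused_regions(r$pixels, map, primary, run_mean, run_sd)
      for (idc in names(sp$assignments)) {
        pix <- sp$assignments[[idc]]
        if (length(pix) > 0) assign_region(pix, as.integer(idc), s)
      }
      if (length(sp$new_volume_pixels) > 0) {
        new_volume(sp$new_volume_pixels, s)
      }
    }
  }

  # assemble: trim to the longest contiguous run, drop short volumes
  out <- list()
  for (id in seq_along(volumes)) {
    v <- volumes[[id]]
    if (length(v$slices) == 0) next
    zs <- sort(as.integer(names(v$slices)))
    runs <- split(zs, cumsum(c(1, diff(zs) != 1)))
    best <- runs[[which.max(vapply(runs, length, numeric(1)))]]
    if (length(best) < window) next
    slices <- v$slices[as.character(best)]
    cents <- t(vapply(slices, function(p) {
      yx <- arrayInd(p, dims)
      c(mean(yx[, 1]), mean(yx[, 2]))
    }, numeric(2)))
    all_yx <- arrayInd(unlist(slices, use.names = FALSE), dims)
    on_border <- min(all_yx) <= 1 || max(all_yx[, 1]) >= dims[1] ||
      max(all_yx[, 2]) >= dims[2]
    out[[length(out) + 1]] <- structure(list(
      id = length(out) + 1L,
      slices = slices,
      z_first = min(best), z_last = max(best),
      centroids = cbind(slice = best, y = cents[, 1], x = cents[, 2]),
      sizes = vapply(slices, length, numeric(1)),
      dims = dims, on_border = on_border),
      class = "ommatidium_volume")
  }
  out
}

#' @export
print.ommatidium_volume <- function(x, ...) {
  cat(sprintf("ommatidium volume %d: slices %d-%d, mean size %.0f px%s\n",
              x$id, x$z_first, x$z_last, mean(x$sizes),
              if (x$on_border) " (touches border)" else ""))
  invisible(x)
}

#' Detect ommatidia in a confocal stack
#'
#' Runs the max filter and per-slice region finding on the structural
#' channel of every optical section, then links regions through z into
#' ommatidium volumes.
#'
#' @param stack A `confocal_stack` (>= 5 slices).
#' @param channel Structural channel name.
#' @param n_levels,size_range Passed to [find_ommatidia_2d()].
#' @param window Linking window in slices.
#' @param filter_type Max-filter semantics, `"tiled"` or `"sliding"`.
#' @return List of `ommatidium_volume`.
#' @export
detect_ommatidia <- function(stack, channel = "phalloidin", n_levels = 20,
                             size_range = c(500, 1000), window = 5,
                             filter_type = "tiled") {
  stopifnot(inherits(stack, "confocal_stack"))
  if (n_slices(stack) < window) {
    stop("stack must have at least ", window, " slices")
  }
  arr <- stack$channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  per_slice <- lapply(seq_len(dim(arr)[3]), function(s) {
    find_ommatidia_2d(max_filter(arr[, , s], 5, filter_type),
                      n_levels = n_levels, size_range = size_range)
  })
  link_ommatidia_3d(per_slice, window = window)
}

#' Render a 16-bit label volume from detected ommatidia
#'
#' @param volumes List of `ommatidium_volume`.
#' @param n_sl Total number of slices.
#' @return Integer 3D array (0 = background, k = ommatidium id).
#' @export
label_volume <- function(volumes, n_sl) {
  if (length(volumes) == 0) stop("no volumes")
  dims <- volumes[[1]]$dims
  arr <- array(0L, c(dims, n_sl))
  for (v in volumes) {
    for (zc in names(v$slices)) {
      z <- as.integer(zc)
      sl <- arr[, , z]
      sl[v$slices[[zc]]] <- v$id
      arr[, , z] <- sl
    }
  }
  arr
}
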