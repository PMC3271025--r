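# Local relative Rhodopsin quantification.
#
# Within each ommatidium and optical section, iso-intensity contours of the
# raw reporter channel are partitioned into mutually exclusive sets: A_x
# (contours exclusively overlapping photoreceptor x), B (contours enclosing
# all 7 PR masks — the ommatidial background), and discards (contours
# touching several cells, the signature of scattering from a bright
# neighbor).  Per-slice levels are length-weighted means of contour levels;
# the local relative intensity I_l = <I_pr / I_omma> over the
# quantification z-range.  Normalizing by the local background cancels the
# depth- and curvature-dependent intensity variation across the retina.

#' Build an iso-intensity contour map for an ommatidium crop
#'
#' Closed iso-intensity polylines of the raw (unfiltered) reporter slice
#' within a bounding box, at quantized intensity levels (by default every
#' integer level of the 8-bit range).  Contours clipped open by the box are
#' closed along the box edge and flagged.
#'
#' @param channel_slice 2D matrix of raw reporter intensities (full slice).
#' @param bbox `c(y_min, y_max, x_min, x_max)` crop in pixels.
#' @param n_levels Number of equally spaced levels over (0, 255].
#' @return List of contours, each a list with `level`, `y`, `x` (closed
#'   polyline in full-slice pixel coordinates), `length` (perimeter, px),
#'   `clipped`.
#' @export
build_contour_map <- function(channel_slice, bbox, n_levels = 255) {
  ys <- max(1, bbox[1]):min(nrow(channel_slice), bbox[2])
  xs <- max(1, bbox[3]):min(ncol(channel_slice), bbox[4])
  crop <- channel_slice[ys, xs, drop = FALSE]
  rng <- range(crop)
  if (diff(rng) == 0) return(list())
  lv <- .quant_levels(n_levels)
  lv <- lv[lv > rng[1] & lv < rng[2]]
  if (length(lv) == 0) return(list())
  cl <- grDevices::contourLines(ys, xs, crop, levels = lv)
  lapply(cl, function(cc) {
    y <- cc$x   # contourLines' first grid axis runs along matrix rows
    x <- cc$y
    clipped <- !(y[1] == y[length(y)] && x[1] == x[length(x)])
    if (clipped) {
      y <- c(y, y[1])
      x <- c(x, x[1])
    }
    per <- sum(sqrt(diff(y)^2 + diff(x)^2))
    list(level = cc$level, y = y, x = x, length = per, clipped = clipped)
  })
}

#' Circular photoreceptor masks from traced centers
#'
#' For each cell, `d` is the minimal distance to the other six centers; the
#' mask is a disc of radius `0.45 d` (plus an optional uniform growth,
#' capped at 3 px) centered on the cell.  Since 0.45 < 0.5, masks from a
#' valid geometry never overlap.
#'
#' @param centers 7 x 2 matrix of (y, x) centers in one slice.
#' @param grow_px Uniform growth applied to the radius, capped at 3 px.
#' @return A data.frame with `cell`, `y`, `x`, `radius`.
#' @export
make_pr_masks <- function(centers, grow_px = 0) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 7, ncol(centers) == 2)
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  d_min <- apply(D, 1, min)
  if (any(d_min == 0)) stop("coincident cell centers")
  grow_px <- min(grow_px, 3)
  data.frame(cell = seq_len(7), y = centers[, 1], x = centers[, 2],
             radius = 0.45 * d_min + grow_px)
}

# does a closed contour overlap a disc mask: any polyline vertex inside the
# disc, or the disc center enclosed by the polygon
.contour_overlaps_mask <- function(contour, my, mx, mr) {
  d2 <- (contour$y - my)^2 + (contour$x - mx)^2
  if (any(d2 <= mr^2)) return(TRUE)
  bnd <- cbind(contour$y, contour$x)
  as.logical(mgcv::in.out(bnd, matrix(c(my, mx), 1)))
}

.contour_encloses_points <- function(contour, pts) {
  bnd <- cbind(contour$y, contour$x)
  all(mgcv::in.out(bnd, as.matrix(pts)))
}

#' Partition contours into PR-exclusive, background, and discarded sets
#'
#' A contour enclosing all 7 masks joins the background set B; a contour
#' overlapping exactly one mask joins that cell's exclusive set A_x; a
#' contour overlapping two or more masks without enclosing all of them is
#' discarded as a scattering artifact; other contours are left unassigned.
#' Any photoreceptor left without contours triggers one retry with its mask
#' grown by up to `grow_retry_px` (<= 3 px), reassigning only unassigned
#' contours that overlap the grown mask exclusively.
#'
#' @param contours List of contours from [build_contour_map()].
#' @param masks Mask table from [make_pr_masks()].
#' @param grow_retry_px Mask growth used in the retry (capped at 3 px).
#' @return An object of class `contour_assignment`: `A` (list of 7 contour
#'   index vectors), `B`, `discarded`, `unassigned` (index vectors), and
#'   `grown` (cells whose mask was grown).
#' @export
assign_contours <- function(contours, masks, grow_retry_px = 3) {
  grow_retry_px <- min(grow_retry_px, 3)
  n <- length(contours)
  A <- rep(list(integer(0)), 7)
  B <- integer(0)
  discarded <- integer(0)
  unassigned <- integer(0)
  centers <- as.matrix(masks[, c("y", "x")])
  for (i in seq_len(n)) {
    cc <- contours[[i]]
    if (.contour_encloses_points(cc, centers)) {
      B <- c(B, i)
      next
    }
    hits <- which(vapply(seq_len(7), function(k) {
      .contour_overlaps_mask(cc, masks$y[k], masks$x[k], masks$radius[k])
    }, logical(1)))
    if (length(hits) == 1) {
      A[[hits]] <- c(A[[hits]], i)
    } else if (length(hits) >= 2) {
      discarded <- c(discarded, i)
    } else {
      unassigned <- c(unassigned, i)
    }
  }
  grown <- integer(0)
  empty <- which(vapply(A, length, integer(1)) == 0)
  if (length(empty) > 0 && grow_retry_px > 0 && length(unassigned) > 0) {
    for (k in empty) {
      rk <- masks$radius[k] + grow_retry_px
      claimed <- integer(0)
      for (i in unassigned) {
        cc <- contours[[i]]
        if (!.contour_overlaps_mask(cc, masks$y[k], masks$x[k], rk)) next
        others <- setdiff(seq_len(7), k)
        other_hit <- any(vapply(others, function(j) {
          .contour_overlaps_mask(cc, masks$y[j], masks$x[j], masks$radius[j])
        }, logical(1)))
        if (!other_hit) claimed <- c(claimed, i)
      }
      if (length(claimed) > 0) {
        A[[k]] <- claimed
        unassigned <- setdiff(unassigned, claimed)
        grown <- c(grown, k)
      }
    }
  }
  structure(list(A = A, B = B, discarded = discarded,
                 unassigned = unassigned, grown = grown),
            class = "contour_assignment")
}

#' @export
print.contour_assignment <- function(x, ...) {
  cat(sprintf(paste0("contour assignment: %d PR-exclusive, %d background, ",
                     "%d discarded, %d unassigned\n"),
              sum(vapply(x$A, length, integer(1))), length(x$B),
              length(x$discarded), length(x$unassigned)))
  invisible(x)
}

# length-weighted mean of contour levels
.length_weighted_level <- function(contours, idx) {
  if (length(idx) == 0) return(NA_real_)
  l <- vapply(contours[idx], `[[`, numeric(1), "length")
  I <- vapply(contours[idx], `[[`, numeric(1), "level")
  sum(l * I) / sum(l)
}

#' Ommatidial background reference level
#'
#' Length-weighted mean of the levels of the background contours:
#' `I_omma = sum(l_j I_j) / sum(l_j)` over the set B.
#'
#' @param contours Contour list.
#' @param assignment A `contour_assignment`.
#' @return `I_omma`, or `NA` when B is empty (the ommatidium-slice is then
#'   excluded from averaging).
#' @export
reference_level <- function(contours, assignment) {
  .length_weighted_level(contours, assignment$B)
}

#' Photoreceptor level in one slice
#'
#' Length-weighted mean of the levels of the cell's exclusive contours
#' (same formula as [reference_level()], over A_x).
#'
#' @param contours Contour list.
#' @param assignment A `contour_assignment`.
#' @param cell Cell index 1-7.
#' @return `I_pr`, or `NA` when A_x is empty after the growth retry.
#' @export
pr_level <- function(contours, assignment, cell) {
  .length_weighted_level(contours, assignment$A[[cell]])
}

#' Average per-slice ratios into the local relative intensity
#'
#' `I_l = < I_pr / I_omma >` over the slices where both are defined and
#' `I_omma > 0`.
#'
#' @param I_pr,I_omma Numeric vectors over the quantification slices.
#' @return A list with `I_l` and `n_slices_used`; `I_l` is `NA` when no
#'   slice qualifies.
#' @export
local_relative_intensity <- function(I_pr, I_omma) {
  ok <- is.finite(I_pr) & is.finite(I_omma) & I_omma > 0
  if (!any(ok)) return(list(I_l = NA_real_, n_slices_used = 0L))
  list(I_l = mean(I_pr[ok] / I_omma[ok]), n_slices_used = sum(ok))
}

#' Quantify Rhodopsin levels for one ommatidium
#'
#' For each slice of the quantification range, builds the contour map of
#' the reporter crop, forms PR masks at the traced centers, assigns
#' contours, and computes the per-slice levels; returns the per-cell I_l.
#'
#' @param stack The `confocal_stack`.
#' @param channel Reporter channel name.
#' @param volume The `ommatidium_volume`.
#' @param traces The matching `pr_traces`.
#' @param z_range `c(first, last)` quantification slice interval.
#' @param n_levels Contour quantization (see [build_contour_map()]).
#' @param pad_px Padding added around the volume bounding box so that the
#'   ommatidium-enclosing background contours fall inside the crop.
#' @return A data.frame with one row per cell: `ommatidium`, `cell`,
#'   `channel`, `I_l`, `n_slices_used`.
#' @export
quantify_ommatidium <- function(stack, channel, volume, traces, z_range,
                                n_levels = 255, pad_px = 18) {
  arr <- stack$channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  zs <- max(z_range[1], volume$z_first):min(z_range[2], volume$z_last)
  if (length(zs) == 0) stop("quantification range misses the volume")
  # bounding box over the range
  bb <- c(Inf, -Inf, Inf, -Inf)
  for (z in zs) {
    pix <- volume$slices[[as.character(z)]]
    yx <- arrayInd(pix, volume$dims)
    bb <- c(min(bb[1], min(yx[, 1])), max(bb[2], max(yx[, 1])),
            min(bb[3], min(yx[, 2])), max(bb[4], max(yx[, 2])))
  }
  bbox <- c(bb[1] - pad_px, bb[2] + pad_px, bb[3] - pad_px, bb[4] + pad_px)
  I_pr <- matrix(NA_real_, 7, length(zs))
  I_om <- rep(NA_real_, length(zs))
  for (i in seq_along(zs)) {
    z <- zs[i]
    contours <- build_contour_map(arr[, , z], bbox, n_levels = n_levels)
    if (length(contours) == 0) next
    ctr <- traces$centers[, match(z, traces$z), ]
    if (any(!is.finite(ctr))) next
    masks <- make_pr_masks(ctr)
    asg <- assign_contours(contours, masks)
    I_om[i] <- reference_level(contours, asg)
    for (k in seq_len(7)) I_pr[k, i] <- pr_level(contours, asg, k)
  }
  rows <- lapply(seq_len(7), function(k) {
    r <- local_relative_intensity(I_pr[k, ], I_om)
    data.frame(ommatidium = volume$id, cell = k, channel = channel,
               I_l = r$I_l, n_slices_used = r$n_slices_used)
  })
  do.call(rbind, rows)
}
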