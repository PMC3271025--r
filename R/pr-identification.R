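# Photoreceptor identification: seeded sliding-window k-means tracing of
# the 7 rhabdomeres (Step 3), a center-displacement measure of clustering
# quality, selection of the quantification z-range, and geometric
# assignment of photoreceptor identities (Step 4).

# Lloyd iterations with the re-seeding rule for empty clusters: an emptied
# cluster is re-seeded at the most intense point not currently serving as a
# center.  Used when stats::kmeans rejects a degenerate seeded start.
.lloyd_with_reseed <- function(pts, centers, intensity, iter_max = 30) {
  k <- nrow(centers)
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(pts^2), rowSums(centers^2), "+") -
      2 * pts %*% t(centers)
    cl <- max.col(-d2, ties.method = "first")
    new_centers <- centers
    for (j in seq_len(k)) {
      sel <- cl == j
      if (!any(sel)) {
        cand <- order(intensity, decreasing = TRUE)
        taken <- vapply(seq_len(k), function(jj) {
          which.min(rowSums(sweep(pts, 2, centers[jj, ])^2))
        }, integer(1))
        pick <- setdiff(cand, taken)[1]
        new_centers[j, ] <- pts[pick, ]
      } else {
        new_centers[j, ] <- colMeans(pts[sel, , drop = FALSE])
      }
    }
    if (max(abs(new_centers - centers)) < 1e-8) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  d2 <- outer(rowSums(pts^2), rowSums(centers^2), "+") - 2 * pts %*% t(centers)
  list(centers = centers, cluster = max.col(-d2, ties.method = "first"))
}

.seeded_kmeans <- function(pts, centers, intensity) {
  fit <- tryCatch(
    stats::kmeans(pts, centers = centers, iter.max = 50,
                  algorithm = "Lloyd"),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit) && nrow(fit$centers) == nrow(centers)) {
    return(list(centers = fit$centers, cluster = fit$cluster))
  }
  .lloyd_with_reseed(pts, centers, intensity)
}

#' Trace the seven photoreceptors through an ommatidium
#'
#' k-means with k = 7 on the (y, x) positions of the `n_points` most
#' intense structural-channel pixels within the deepest `window` slices of
#' the ommatidium volume (random seeding, best of `n_restarts` by inertia).
#' The window is then shifted up one slice at a time, each clustering
#' seeded with the previous centers, so the seven center lineages trace the
#' rhabdomeres through z.  Cluster identity follows the seed lineage.
#'
#' @param volume An `ommatidium_volume`.
#' @param stack The `confocal_stack`.
#' @param channel Structural channel name.
#' @param n_points Number of most intense points per window (all available
#'   points are used, with a warning, if fewer).
#' @param window Window size in slices.
#' @param n_restarts Random restarts for the first window.
#' @param seed Integer seed for the random first-window seeding.
#' @return An object of class `pr_traces`: `ommatidium` (id), `z` (slices),
#'   `centers` (array `[7, n_z, 2]`, (y, x) per slice).
#' @export
trace_photoreceptors <- function(volume, stack, channel = "phalloidin",
                                 n_points = 800, window = 5,
                                 n_restarts = 10, seed = 1) {
  stopifnot(inherits(volume, "ommatidium_volume"))
  zs <- volume$z_first:volume$z_last
  if (length(zs) < window) stop("volume spans fewer than ", window, " slices")
  arr <- stack$channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  dims <- volume$dims

  # candidate points come from the padded bounding box of the volume's
  # regions in the window, so a rhabdomere partially clipped by the Step-1
  # region mask still contributes its bright pixels
  window_points <- function(z0, pad = 8) {
    sl <- z0:(z0 + window - 1)
    bb <- c(Inf, -Inf, Inf, -Inf)
    for (z in sl) {
      pix <- volume$slices[[as.character(z)]]
      if (is.null(pix)) next
      yx <- arrayInd(pix, dims)
      bb <- c(min(bb[1], min(yx[, 1])), max(bb[2], max(yx[, 1])),
              min(bb[3], min(yx[, 2])), max(bb[4], max(yx[, 2])))
    }
    ys <- max(1, bb[1] - pad):min(dims[1], bb[2] + pad)
    xs <- max(1, bb[3] - pad):min(dims[2], bb[4] + pad)
    yx <- as.matrix(expand.grid(y = ys, x = xs))
    yx <- yx[rep(seq_len(nrow(yx)), length(sl)), ]
    ints <- as.vector(arr[ys, xs, sl])
    if (nrow(yx) > n_points) {
      keep <- order(ints, decreasing = TRUE)[seq_len(n_points)]
      yx <- yx[keep, , drop = FALSE]
      ints <- ints[keep]
    } else if (nrow(yx) < n_points) {
      warning("fewer than ", n_points, " candidate pixels in window at slice ",
              z0, "; using all ", nrow(yx))
    }
    list(yx = yx, intensity = ints)
  }

  starts <- zs[seq_len(length(zs) - window + 1)]
  centers <- array(NA_real_, c(7, length(zs), 2))

  set.seed(seed)
  wp <- window_points(starts[1])
  wss <- function(fit) {
    sum((wp$yx - fit$centers[fit$cluster, , drop = FALSE])^2)
  }
  # random restarts plus a farthest-point start (one seed per well-separated
  # rhabdomere), best within-cluster sum of squares kept
  best <- NULL
  best_wss <- Inf
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(stats::kmeans(wp$yx, centers = 7, iter.max = 50),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) next
    if (fit$tot.withinss < best_wss) {
      best <- list(centers = fit$centers, cluster = fit$cluster)
      best_wss <- fit$tot.withinss
    }
  }
  fp <- matrix(NA_real_, 7, 2)
  fp[1, ] <- wp$yx[which.max(wp$intensity), ]
  d_min <- rowSums(sweep(wp$yx, 2, fp[1, ])^2)
  for (k in 2:7) {
    fp[k, ] <- wp$yx[which.max(d_min), ]
    d_min <- pmin(d_min, rowSums(sweep(wp$yx, 2, fp[k, ])^2))
  }
  fit <- .seeded_kmeans(wp$yx, fp, wp$intensity)
  if (wss(fit) < best_wss) best <- fit
  prev <- as.matrix(best$centers)
  centers[, 1, ] <- prev

  for (i in seq_along(starts)[-1]) {
    wp <- window_points(starts[i])
    fit <- .seeded_kmeans(wp$yx, prev, wp$intensity)
    prev <- as.matrix(fit$centers)
    centers[, i, ] <- prev
  }
  # trailing slices (no full window starts there) carry the last centers
  n_st <- length(starts)
  if (length(zs) > n_st) {
    for (i in (n_st + 1):length(zs)) centers[, i, ] <- centers[, n_st, ]
  }
  structure(list(ommatidium = volume$id, z = zs, centers = centers),
            class = "pr_traces")
}

#' @export
print.pr_traces <- function(x, ...) {
  cat(sprintf("PR traces for ommatidium %d over slices %d-%d\n",
              x$ommatidium, min(x$z), max(x$z)))
  invisible(x)
}

#' Goodness of clustering from center displacements
#'
#' For every transition between consecutive slices, the maximum over the
#' seven cells of the center displacement (pixels).  Small displacements
#' mean the cluster centers are stationary and the rhabdomeres well
#' resolved; the deep, twisted part of the ommatidium shows large
#' displacements and is excluded from quantification.
#'
#' @param traces A `pr_traces` object.
#' @return An object of class `cluster_quality`: `ommatidium`,
#'   `transition_z` (starting slice of each transition), `max_disp`,
#'   `mean_disp`, and the overall summary `max` and `mean`.
#' @export
clustering_goodness <- function(traces) {
  stopifnot(inherits(traces, "pr_traces"))
  nz <- length(traces$z)
  if (nz < 2) stop("need at least 2 slices")
  disp <- matrix(NA_real_, 7, nz - 1)
  for (i in seq_len(nz - 1)) {
    d <- traces$centers[, i + 1, ] - traces$centers[, i, ]
    disp[, i] <- sqrt(rowSums(d^2))
  }
  structure(list(ommatidium = traces$ommatidium,
                 transition_z = traces$z[-nz],
                 max_disp = apply(disp, 2, max),
                 mean_disp = apply(disp, 2, mean),
                 max = max(disp), mean = mean(disp)),
            class = "cluster_quality")
}

#' Select the quantification z-range
#'
#' Enumerates contiguous slice intervals and counts, for each, the
#' ommatidia whose maximal center displacement within the interval stays at
#' or below `displacement_cap`.  Returns the interval maximizing
#' (number of qualifying ommatidia) x (interval length), ties broken toward
#' longer intervals — the optimum of the interval-length versus
#' ommatidia-count landscape.
#'
#' @param qualities List of `cluster_quality`, one per traced ommatidium.
#' @param displacement_cap Maximum tolerated center displacement (pixels).
#' @return An object of class `quantification_range`: `z` (c(first, last)),
#'   `included` (logical per ommatidium), `objective`, and the landscape
#'   data.frame (`z_first`, `z_last`, `length`, `n_ommatidia`).
#' @export
select_quantification_zrange <- function(qualities, displacement_cap = 2) {
  if (length(qualities) < 1) stop("need at least one traced ommatidium")
  z_min <- min(vapply(qualities, function(q) min(q$transition_z), numeric(1)))
  z_max <- max(vapply(qualities, function(q) max(q$transition_z), numeric(1))) + 1
  zs <- z_min:z_max
  n_z <- length(zs)
  n_o <- length(qualities)
  # disp[o, t]: displacement of transition starting at slice zs[t]; Inf where
  # the ommatidium is not traced
  disp <- matrix(Inf, n_o, n_z - 1)
  for (o in seq_len(n_o)) {
    q <- qualities[[o]]
    disp[o, match(q$transition_z, zs[-n_z])] <- q$max_disp
  }
  traced <- matrix(FALSE, n_o, n_z)
  for (o in seq_len(n_o)) {
    q <- qualities[[o]]
    traced[o, zs %in% c(q$transition_z, max(q$transition_z) + 1)] <- TRUE
  }

  best <- NULL
  landscape <- list()
  for (a in seq_len(n_z)) {
    ok <- traced[, a]
    for (b in a:n_z) {
      if (b > a) {
        ok <- ok & traced[, b] & (disp[, b - 1] <= displacement_cap)
      }
      n_omm <- sum(ok)
      len <- b - a + 1
      landscape[[length(landscape) + 1]] <-
        c(zs[a], zs[b], len, n_omm)
      if (n_omm == 0) next
      obj <- n_omm * len
      if (is.null(best) || obj > best$objective ||
          (obj == best$objective && len > best$len)) {
        best <- list(a = zs[a], b = zs[b], objective = obj, len = len,
                     included = ok)
      }
    }
  }
  if (is.null(best)) stop("no interval with a qualifying ommatidium")
  land <- as.data.frame(do.call(rbind, landscape))
  names(land) <- c("z_first", "z_last", "length", "n_ommatidia")
  structure(list(z = c(best$a, best$b), included = best$included,
                 objective = best$objective, landscape = land),
            class = "quantification_range")
}

#' @export
print.quantification_range <- function(x, ...) {
  cat(sprintf("quantification z-range: slices %d-%d, %d ommatidia included\n",
              x$z[1], x$z[2], sum(x$included)))
  invisible(x)
}

# guarded argmax: index of the largest value, NA when the runner-up is
# within rel_tol of the winner (ambiguous geometry)
.argmax_with_margin <- function(vals, rel_tol) {
  ord <- order(vals, decreasing = TRUE)
  if (length(vals) > 1 &&
      (vals[ord[1]] - vals[ord[2]]) <= rel_tol * vals[ord[1]]) {
    return(NA_integer_)
  }
  ord[1]
}

#' Assign photoreceptor identities from cell-center geometry
#'
#' Implements the geometric labeling chain on the mean cell centers: the
#' cluster nearest the centroid of all seven is the central R7/8; the cell
#' furthest from it is R3; R3's two nearest neighbors are R2/R4; the
#' remaining neighbors of those are R1/R5, distinguished because R5 has a
#' neighbor (R6) among the unlabeled cells while R1 does not; R5's
#' neighbor closest to R3 is R4, the other is R6; the cell between R1 and
#' R3 is R2.  The chain uses pairwise distances only, so the labels are
#' invariant under rigid motions and uniform scaling.  Geometry whose
#' decisive comparisons are closer than `rel_tol` (relative) is declared
#' undetermined and the ommatidium excluded.
#'
#' @param centers 7 x 2 matrix of (y, x) cell centers (mean over the
#'   quantification z-range).
#' @param central_index Optional index of the central (R7/8) cell; default
#'   is the cell nearest the centroid.
#' @param rel_tol Relative margin below which a decisive comparison is a
#'   tie.
#' @return An object of class `pr_label_map`: `labels` (character, per cell
#'   index), `determined` (logical), `reason` (when undetermined).
#' @export
label_pr_types <- function(centers, central_index = NULL, rel_tol = 0.05) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 7, ncol(centers) == 2)
  D <- as.matrix(stats::dist(centers))
  undet <- function(reason) {
    structure(list(labels = rep(NA_character_, 7), determined = FALSE,
                   reason = reason), class = "pr_label_map")
  }
  if (is.null(central_index)) {
    ctr <- colMeans(centers)
    d_ctr <- sqrt(colSums((t(centers) - ctr)^2))
    ord <- order(d_ctr)
    if ((d_ctr[ord[2]] - d_ctr[ord[1]]) <= rel_tol * d_ctr[ord[2]]) {
      return(undet("ambiguous central cell"))
    }
    central_index <- ord[1]
  }
  outer_idx <- setdiff(seq_len(7), central_index)
  # R3: furthest outer cell from the central cell
  d_c <- D[central_index, outer_idx]
  i3 <- .argmax_with_margin(d_c, rel_tol)
  if (is.na(i3)) return(undet("ambiguous furthest cell (R3)"))
  r3 <- outer_idx[i3]
  rest <- setdiff(outer_idx, r3)
  # R3's two nearest neighbors -> candidates for R2/R4
  ord <- rest[order(D[r3, rest])]
  if ((D[r3, ord[3]] - D[r3, ord[2]]) <= rel_tol * D[r3, ord[3]]) {
    return(undet("ambiguous R2/R4 neighbors of R3"))
  }
  cand <- ord[1:2]
  rem <- setdiff(rest, cand)
  # each candidate's nearest remaining cell -> R1/R5 partners
  partners <- vapply(cand, function(cc) rem[which.min(D[cc, rem])], integer(1))
  if (partners[1] == partners[2]) return(undet("R1/R5 partners coincide"))
  r6 <- setdiff(rem, partners)
  if (length(r6) != 1) return(undet("no unique remaining cell for R6"))
  # of the partners, the one with a neighbor among the unlabeled (R6) is R5
  d6 <- D[partners, r6]
  if (abs(d6[1] - d6[2]) <= rel_tol * max(d6)) {
    return(undet("ambiguous R1/R5 assignment"))
  }
  i5 <- which.min(d6)
  r5 <- partners[i5]; r1 <- partners[-i5]
  r4 <- cand[i5]; r2 <- cand[-i5]
  labels <- rep(NA_character_, 7)
  labels[c(r1, r2, r3, r4, r5, r6, central_index)] <-
    c("R1", "R2", "R3", "R4", "R5", "R6", "R7/8")
  structure(list(labels = labels, determined = TRUE, reason = NULL),
            class = "pr_label_map")
}

#' @export
print.pr_label_map <- function(x, ...) {
  if (x$determined) {
    cat("PR labels:", paste(x$labels, collapse = " "), "\n")
  } else {
    cat("PR labels undetermined:", x$reason, "\n")
  }
  invisible(x)
}

#' Mean cell centers over a slice interval
#'
#' @param traces A `pr_traces` object.
#' @param z_range `c(first, last)` slice interval.
#' @return 7 x 2 matrix of mean (y, x) centers.
#' @export
mean_centers <- function(traces, z_range = range(traces$z)) {
  sel <- traces$z >= z_range[1] & traces$z <= z_range[2]
  if (!any(sel)) stop("z_range does not intersect the trace")
  t(apply(traces$centers[, sel, , drop = FALSE], 1, colMeans))
}
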