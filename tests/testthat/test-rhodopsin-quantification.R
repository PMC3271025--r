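# Contour-based quantification: contour maps, masks, assignment, length-
# weighted levels, I_l.

make_contour <- function(level, len) list(level = level, y = 0, x = 0,
                                          length = len, clipped = FALSE)

circle_contour <- function(level, yc, xc, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  y <- yc + r * sin(th); x <- xc + r * cos(th)
  list(level = level, y = y, x = x,
       length = sum(sqrt(diff(y)^2 + diff(x)^2)), clipped = FALSE)
}

test_that("contour maps of simple fields match analytic geometry", {
  expect_length(build_contour_map(matrix(50, 40, 40), c(1, 40, 1, 40)), 0)

  # radial cone peaking at 3.7 over 0: integer-level contours at 1, 2, 3
  n <- 41; ctr <- 21
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  R <- 15
  img <- pmax(3.7 * (1 - r / R), 0)
  cm <- build_contour_map(img, c(1, n, 1, n))
  lv <- vapply(cm, `[[`, numeric(1), "level")
  expect_setequal(lv, c(1, 2, 3))
  lens <- vapply(cm, `[[`, numeric(1), "length")
  # nested rings: perimeter decreases with level and tracks 2*pi*r(level)
  expect_true(all(diff(lens[order(lv)]) < 0))
  for (i in seq_along(cm)) {
    r_exp <- R * (1 - lv[i] / 3.7)
    expect_equal(lens[i], 2 * pi * r_exp, tolerance = 0.05)
  }

  # two disjoint bumps: contours split into two nests
  img2 <- matrix(0, 40, 80)
  r1 <- sqrt(outer((1:40 - 20)^2, (1:80 - 20)^2, "+"))
  r2 <- sqrt(outer((1:40 - 20)^2, (1:80 - 60)^2, "+"))
  img2 <- pmax(2.5 * (1 - r1 / 10), 0) + pmax(2.5 * (1 - r2 / 10), 0)
  cm2 <- build_contour_map(img2, c(1, 40, 1, 80))
  xs <- vapply(cm2, function(cc) mean(cc$x), numeric(1))
  expect_equal(sum(xs < 40), sum(xs > 40))
  expect_length(cm2, 4)  # levels 1, 2 around each bump
})

test_that("PR masks are 0.45 of the nearest-neighbor distance", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  centers <- rbind(cbind(12 * sin(th), 12 * cos(th)), c(0, 0))
  m <- make_pr_masks(centers)
  # outer cells: nearest neighbor is the adjacent ring cell at 12 px
  expect_equal(m$radius[1:6], rep(0.45 * 12, 6))
  # growth capped at 3 px
  m2 <- make_pr_masks(centers, grow_px = 4)
  expect_equal(m2$radius - m$radius, rep(3, 7))
  expect_error(make_pr_masks(centers[c(1, 1:6), ]), "coincident")

  # masks from trapezoid-like geometries never overlap (0.45 < 0.5)
  set.seed(30)
  for (rep in 1:20) {
    ctr <- matrix(rnorm(14, sd = 5), 7, 2)
    if (min(dist(ctr)) < 1e-3) next
    mm <- make_pr_masks(ctr)
    D <- as.matrix(dist(ctr))
    for (i in 1:6) for (j in (i + 1):7) {
      expect_gt(D[i, j], mm$radius[i] + mm$radius[j] - 1e-9)
    }
  }
})

test_that("contours partition into exclusive, background, discarded sets", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  centers <- rbind(cbind(30 + 12 * sin(th), 30 + 12 * cos(th)), c(30, 30))
  masks <- make_pr_masks(centers)
  contours <- list(
    circle_contour(40, centers[3, 1], centers[3, 2], 2),    # inside mask 3
    circle_contour(5, (centers[2, 1] + centers[3, 1]) / 2,  # spans masks 2+3
                   (centers[2, 2] + centers[3, 2]) / 2,
                   0.6 * dist(centers[2:3, ])),
    circle_contour(2, 30, 30, 25))                          # encloses all
  asg <- assign_contours(contours, masks)
  expect_identical(asg$A[[3]], 1L)
  expect_identical(asg$discarded, 2L)
  expect_identical(asg$B, 3L)

  # mutual exclusivity over a synthetic crop
  all_idx <- c(unlist(asg$A), asg$B, asg$discarded, asg$unassigned)
  expect_equal(anyDuplicated(all_idx), 0)
})

test_that("a contour-less PR claims an unassigned contour after mask growth", {
  centers <- rbind(c(10, 10), c(10, 40), c(40, 10), c(40, 40),
                   c(10, 70), c(40, 70), c(25, 25))
  masks <- make_pr_masks(centers)
  # a small contour just beyond mask 1 (radius 0.45*21.2 = 9.55), neither
  # touching the disc nor enclosing its center
  contours <- list(circle_contour(30, 10, 23, 1.5))
  asg0 <- assign_contours(contours, masks, grow_retry_px = 0)
  expect_length(asg0$A[[1]], 0)
  asg <- assign_contours(contours, masks, grow_retry_px = 3)
  expect_identical(asg$A[[1]], 1L)
  expect_identical(asg$grown, 1L)
})

test_that("length-weighted levels follow the printed arithmetic", {
  contours <- list(make_contour(50, 10))
  asg <- list(A = c(list(1L), rep(list(integer(0)), 6)), B = 1L)
  expect_equal(reference_level(contours, asg), 50)

  contours2 <- list(make_contour(100, 10), make_contour(60, 30))
  asg2 <- list(A = c(list(1:2), rep(list(integer(0)), 6)), B = 1:2)
  expect_equal(reference_level(contours2, asg2), 70)
  expect_equal(pr_level(contours2, asg2, 1), 70)

  contours3 <- list(make_contour(120, 20), make_contour(180, 10))
  asg3 <- list(A = c(list(1:2), rep(list(integer(0)), 6)), B = integer(0))
  expect_equal(pr_level(contours3, asg3, 1), 140)
  expect_true(is.na(reference_level(contours3, asg3)))  # B empty -> excluded

  # constant levels are invariant to the length weights
  contours4 <- list(make_contour(42, 3), make_contour(42, 97))
  asg4 <- list(A = c(list(1:2), rep(list(integer(0)), 6)), B = 1:2)
  expect_equal(reference_level(contours4, asg4), 42)

  # weighted means stay within [min level, max level]
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(2:6, 1)
    cs <- lapply(seq_len(k), function(i) {
      make_contour(runif(1, 1, 255), runif(1, 1, 100))
    })
    a <- list(A = c(list(seq_len(k)), rep(list(integer(0)), 6)),
              B = seq_len(k))
    m <- reference_level(cs, a)
    lv <- vapply(cs, `[[`, numeric(1), "level")
    expect_gte(m, min(lv)); expect_lte(m, max(lv))
  }
})

test_that("I_l averages ratios over qualifying slices only", {
  expect_equal(local_relative_intensity(c(5, 5, 5), c(5, 5, 5))$I_l, 1)
  r <- local_relative_intensity(c(10, 15, 20), c(5, 5, 5))
  expect_equal(r$I_l, 3)
  expect_equal(r$n_slices_used, 3L)
  r2 <- local_relative_intensity(c(10, NA, 20), c(5, 5, 0))
  expect_equal(r2$I_l, 2)
  expect_equal(r2$n_slices_used, 1L)
  r3 <- local_relative_intensity(c(NA, NA), c(1, 1))
  expect_true(is.na(r3$I_l))
})

test_that("I_l is invariant under per-ommatidium intensity scaling", {
  # the curvature-correction property: doubling a whole crop's intensities
  # (exact under 8-bit: values stay on the integer grid) leaves I_l fixed
  n <- 61; ctr <- 31
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  img <- matrix(0, n, n)
  img[r <= 25] <- 12
  ramp <- r > 25 & r <= 30
  img[ramp] <- 12 * (30 - r[ramp]) / 5
  cone <- r <= 5
  img[cone] <- 60 - (60 - 12) * r[cone] / 5
  img <- round(img)
  centers <- rbind(ctr + cbind(c(0, 8, 8, 0, -8, -8, 0),
                               c(-9, -5, 5, 9, 5, -5, 0)))
  measure <- function(im) {
    cm <- build_contour_map(im, c(1, n, 1, n))
    masks <- make_pr_masks(centers)
    asg <- assign_contours(cm, masks)
    pr_level(cm, asg, 7) / reference_level(cm, asg)
  }
  i1 <- measure(img)
  i2 <- measure(img * 2)
  expect_equal(i2, i1, tolerance = 0.05)
  i3 <- measure(round(img * 1.5))
  expect_equal(i3, i1, tolerance = 0.05)
})

test_that("normalization cancels curvature attenuation across the retina", {
  cfg <- retina_sim_config(n_ommatidia = 19, n_slices = 14, noise_sd = 0,
                           scatter_fraction = 0, attenuation_coeff = 0.02,
                           curvature_radius_um = 100, seed = 13)
  sim <- generate_retina_stack(cfg)
  res <- suppressWarnings(
    analyze_stack(sim$stack, pipeline_config(reporters = "Rh6", seed = 9)))
  matches <- match_volumes_to_truth(res, sim$truth)
  zr <- res$zrange$z
  rel_err <- c(); rho <- c()
  for (rr in seq_len(nrow(matches))) {
    i <- matches$volume[rr]; g <- matches$gt[rr]
    v <- res$volumes[[i]]
    zsel <- max(zr[1], v$z_first):min(zr[2], v$z_last)
    det_centers <- mean_centers(res$traces[[i]], range(zsel))
    m <- res$measurements[res$measurements$ommatidium == v$id, ]
    for (k in 1:7) {
      gt_cc <- colMeans(sim$truth$cell_centers_px[g, k, zsel, , drop = FALSE][1, 1, , ])
      kk <- which.min(rowSums(sweep(det_centers, 2, gt_cc)^2))
      prog <- sim$truth$cells$rendered_level_Rh6[
        sim$truth$cells$ommatidium == g & sim$truth$cells$cell == k]
      rel_err <- c(rel_err, abs(m$I_l[m$cell == kk] - prog) / prog)
      rho <- c(rho, sim$truth$ommatidia$rho_um[g])
    }
  }
  # both central and peripheral ommatidia recover programmed contrast
  central <- rho <= median(rho)
  expect_lt(median(rel_err[central], na.rm = TRUE), 0.1)
  expect_lt(median(rel_err[!central], na.rm = TRUE), 0.1)
})

test_that("discarding multi-mask contours rejects scatter bleed", {
  # bright cell at left, dim neighbor at right; a low-intensity halo lobe
  # spans both masks
  centers <- rbind(c(30, 20), c(30, 44), c(6, 6), c(6, 56),
                   c(56, 6), c(56, 56), c(30, 32))
  masks <- make_pr_masks(centers)
  contours <- c(
    lapply(c(40, 80, 120), function(l) circle_contour(l, 30, 20, 4)),
    lapply(c(10, 14), function(l) circle_contour(l, 30, 44, 3)),
    list(circle_contour(4, 30, 31, 14)))  # halo spanning cells 1, 2 and 7
  asg <- assign_contours(contours, masks)
  expect_identical(asg$discarded, 6L)
  clean <- pr_level(contours, asg, 2)   # equal-perimeter rings at 10 and 14
  expect_equal(clean, 12, tolerance = 0.01)
  # including the halo contour would drag the dim cell's level down
  asg_bad <- asg
  asg_bad$A[[2]] <- c(asg_bad$A[[2]], 6L)
  polluted <- pr_level(contours, asg_bad, 2)
  expect_lt(polluted, clean)
})
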