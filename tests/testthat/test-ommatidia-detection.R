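# Step 1-2: max filter, contour-level region finding, 3D linking, fused
# region correction.

disc_pixels <- function(dims, yc, xc, r) {
  yx <- arrayInd(seq_len(prod(dims)), dims)
  which((yx[, 1] - yc)^2 + (yx[, 2] - xc)^2 <= r^2)
}

test_that("max filter matches brute-force oracles in both semantics", {
  const <- matrix(7, 11, 13)
  expect_equal(max_filter(const, 5, "tiled"), const)
  expect_equal(max_filter(const, 5, "sliding"), const)

  # single bright pixel: a tiled window block / a sliding plateau
  img <- matrix(0, 10, 10); img[7, 7] <- 9
  tiled <- max_filter(img, 5, "tiled")
  expect_true(all(tiled[6:10, 6:10] == 9))
  expect_true(all(tiled[1:5, ] == 0))
  slid <- max_filter(img, 5, "sliding")
  expect_true(all(slid[5:9, 5:9] == 9))
  expect_equal(sum(slid == 9), 25)

  # random image vs naive double-loop oracles
  set.seed(8)
  r <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  oracle_slide <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    oracle_slide[i, j] <- max(r[max(1, i - 2):min(20, i + 2),
                                max(1, j - 2):min(20, j + 2)])
  }
  expect_equal(max_filter(r, 5, "sliding"), oracle_slide)
  oracle_tiled <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    bi <- floor((i - 1) / 5) * 5 + 1
    bj <- floor((j - 1) / 5) * 5 + 1
    oracle_tiled[i, j] <- max(r[bi:min(20, bi + 4), bj:min(20, bj + 4)])
  }
  expect_equal(max_filter(r, 5, "tiled"), oracle_tiled)
  expect_error(max_filter(r, 4), "odd")
})

test_that("local thresholding finds dim and bright discs alike", {
  expect_length(find_ommatidia_2d(matrix(0, 60, 60))$regions, 0)

  dims <- c(80, 240)
  img <- matrix(0, dims[1], dims[2])
  truth <- list()
  for (k in 1:3) {
    pix <- disc_pixels(dims, 40, 40 + (k - 1) * 80, 15)  # ~709 px each
    img[pix] <- c(200, 100, 50)[k]                       # 2:1 ratios
    truth[[k]] <- pix
  }
  rs <- find_ommatidia_2d(img)
  expect_length(rs$regions, 3)
  expect_true(all(vapply(rs$regions, `[[`, numeric(1), "size") >= 500))
  expect_true(all(vapply(rs$regions, `[[`, numeric(1), "size") <= 1000))
  # each found region overlaps >= 90% of its true disc
  for (k in 1:3) {
    best <- max(vapply(rs$regions, function(r) {
      length(intersect(r$pixels, truth[[k]])) / length(truth[[k]])
    }, numeric(1)))
    expect_gte(best, 0.9)
  }
})

test_that("within a slice no pixel belongs to two regions", {
  sim <- default_sim()
  arr <- sim$stack$channels$phalloidin
  for (s in c(1, 25)) {
    rs <- find_ommatidia_2d(max_filter(arr[, , s]))
    pix <- unlist(lapply(rs$regions, `[[`, "pixels"))
    expect_equal(anyDuplicated(pix), 0)
  }
})

test_that("detection is invariant to rescaling within quantization bins", {
  sim <- clean_sim()
  arr <- sim$stack$channels$phalloidin
  img <- max_filter(arr[, , 3])
  # monotone remap that keeps every value inside its 20-level bin
  lv <- seq(0, 255, length.out = 20)
  bin <- findInterval(img, lv, rightmost.closed = TRUE)
  jit <- pmin(img + 3, lv[pmin(bin + 1, 20)] - 1e-9)
  jit[img == 0] <- 0
  a <- find_ommatidia_2d(img)
  b <- find_ommatidia_2d(jit)
  expect_equal(length(a$regions), length(b$regions))
  expect_identical(lapply(a$regions, `[[`, "pixels"),
                   lapply(b$regions, `[[`, "pixels"))
})

test_that("3D linking joins cylinders and drops isolated regions", {
  dims <- c(60, 200)
  centers <- cbind(30, seq(20, 180, length.out = 7))
  make_slice <- function(drift = 0, s = 1) {
    regions <- lapply(seq_len(7), function(k) {
      pix <- disc_pixels(dims, centers[k, 1] + drift * (s - 1),
                         centers[k, 2], 13.5)
      list(pixels = pix, size = length(pix),
           bbox = NULL, centroid = c(centers[k, 1], centers[k, 2]))
    })
    structure(list(regions = regions, dims = dims), class = "slice_region_set")
  }
  per_slice <- lapply(1:60, function(s) make_slice(0, s))
  vols <- link_ommatidia_3d(per_slice)
  expect_length(vols, 7)
  expect_true(all(vapply(vols, function(v) v$z_last - v$z_first + 1,
                         numeric(1)) >= 55))

  # tilted cylinders (1 px/slice drift) still link into single volumes
  per_tilt <- lapply(1:30, function(s) make_slice(1, s))
  vols_t <- link_ommatidia_3d(per_tilt)
  expect_length(vols_t, 7)
  expect_true(all(vapply(vols_t, function(v) v$z_last, numeric(1)) == 30))

  # a region present in exactly one slice is not an ommatidium
  lone <- structure(list(regions = list(list(
    pixels = disc_pixels(dims, 30, 100, 13.5), size = 573,
    bbox = NULL, centroid = c(30, 100))), dims = dims),
    class = "slice_region_set")
  empty <- structure(list(regions = list(), dims = dims),
                     class = "slice_region_set")
  vols_l <- link_ommatidia_3d(c(list(lone), rep(list(empty), 5)))
  expect_length(vols_l, 0)
})

test_that("fused-region correction splits along existing volumes", {
  dims <- c(40, 80)
  map <- integer(prod(dims))
  volA <- disc_pixels(dims, 20, 20, 10)
  volB <- disc_pixels(dims, 20, 60, 10)
  map[volA] <- 1L
  map[volB] <- 2L

  # in-tolerance region: assigned whole, no split
  r_small <- disc_pixels(dims, 20, 20, 10)
  sp <- split_fused_regions(r_small, map, 1L, running_mean = 314,
                            running_sd = 20)
  expect_identical(sp$assignments[["1"]], r_small)
  expect_length(sp$new_volume_pixels, 0)

  # dumbbell across A and B: each half returns to its volume
  dumbbell <- union(volA, volB)
  sp2 <- split_fused_regions(dumbbell, map, 1L, running_mean = 314,
                             running_sd = 10)
  expect_setequal(sp2$assignments[["1"]], volA)
  expect_setequal(sp2$assignments[["2"]], volB)
  expect_length(sp2$new_volume_pixels, 0)

  # oversized region overlapping only A: the remainder seeds a new volume
  blob <- union(volA, disc_pixels(dims, 20, 45, 10))
  map3 <- integer(prod(dims)); map3[volA] <- 1L
  sp3 <- split_fused_regions(blob, map3, 1L, running_mean = 314,
                             running_sd = 10)
  expect_setequal(sp3$assignments[["1"]], volA)
  expect_gt(length(sp3$new_volume_pixels), 200)
  expect_true(all(map3[sp3$new_volume_pixels] == 0))
})

test_that("detection on default synthetic stacks has >= 90% recall/precision", {
  sim <- default_sim()
  res <- default_analysis()
  truth <- sim$truth
  cfg <- truth$config
  r_px <- cfg$ommatidium_radius_um / cfg$voxel_size_um[3]
  # match every volume (not only resolved) at its own mid slice
  hits <- logical(cfg$n_ommatidia)
  n_match <- 0
  for (v in res$volumes) {
    zmid <- round((v$z_first + v$z_last) / 2)
    det_c <- v$centroids[v$centroids[, "slice"] == zmid, c("y", "x")]
    gt_c <- t(vapply(seq_len(cfg$n_ommatidia), function(g) {
      truth$omm_centers_px[g, zmid, ]
    }, numeric(2)))
    d <- sqrt((gt_c[, 1] - det_c[1])^2 + (gt_c[, 2] - det_c[2])^2)
    if (min(d) <= r_px) {
      n_match <- n_match + 1
      hits[which.min(d)] <- TRUE
    }
  }
  recall <- mean(hits)
  precision <- n_match / length(res$volumes)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})
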