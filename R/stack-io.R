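# Multi-channel 3D confocal stack container and TIFF I/O.

#' Multi-channel confocal stack
#'
#' A named list of 3D intensity arrays indexed `[y, x, z]` with z = 1 the
#' deepest optical section, plus physical voxel sizes.  Intensities are
#' 8-bit (0-255).
#'
#' @param channels Named list of 3D arrays with identical dimensions.
#' @param voxel_size_um Voxel size as `c(z, y, x)` in microns.
#' @return An object of class `confocal_stack`.
#' @export
confocal_stack <- function(channels, voxel_size_um = c(0.25, 0.16, 0.16)) {
  if (!is.list(channels) || length(channels) == 0 ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop("channels must be a non-empty named list of 3D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, integer(1)) != 3)) {
    stop("each channel must be a 3D array [y, x, z]")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop("all channels must share dimensions")
  }
  rng <- range(channels[[1]], na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 255) stop("intensities must lie in [0, 255]")
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0)) {
    stop("voxel_size_um must be positive c(z, y, x)")
  }
  structure(list(channels = channels, voxel_size_um = voxel_size_um),
            class = "confocal_stack")
}

#' @export
print.confocal_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("confocal stack: %d x %d px, %d slices, channels: %s\n",
              d[1], d[2], d[3], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Number of optical sections in a stack
#' @param stack A `confocal_stack`.
#' @return Integer slice count.
#' @export
n_slices <- function(stack) dim(stack$channels[[1]])[3]

#' Read a multi-page TIFF into a stack channel
#'
#' @param paths Named character vector: channel name -> TIFF path.  Each
#'   file is a multi-page 8-bit TIFF with one page per optical section,
#'   page 1 the deepest.
#' @param voxel_size_um Voxel size as `c(z, y, x)` in microns.
#' @return A `confocal_stack`.
#' @export
read_stack <- function(paths, voxel_size_um = c(0.25, 0.16, 0.16)) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    stop("paths must be named by channel role")
  }
  channels <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("TIFF not found: ", p)
    pages <- tryCatch(tiff::readTIFF(p, all = TRUE),
                      error = function(e) stop("malformed TIFF '", p, "': ",
                                               conditionMessage(e)))
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0L, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
    for (s in seq_along(pages)) {
      pg <- pages[[s]]
      if (length(dim(pg)) == 3) pg <- pg[, , 1]   # grayscale stored with extra plane
      arr[, , s] <- as.integer(round(pg * 255))
    }
    arr
  })
  confocal_stack(channels, voxel_size_um)
}

#' Write one stack channel as a multi-page 8-bit TIFF
#'
#' @param stack A `confocal_stack`.
#' @param channel Channel name.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_stack_channel <- function(stack, channel, path) {
  arr <- stack$channels[[channel]]
  if (is.null(arr)) stop("unknown channel: ", channel)
  pages <- lapply(seq_len(dim(arr)[3]), function(s) {
    m <- arr[, , s] / 255
    storage.mode(m) <- "double"
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}
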