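#' Confocal image stack container
#'
#' A minimal container for 2-D images or 3-D stacks of one or more
#' fluorescence channels (`actinin` for the sarcomeric z-disc signal,
#' `membrane` for the WGA membrane/ECM signal) with a calibrated voxel
#' size. The default voxel size 0.1 x 0.1 x 0.2 um matches high-resolution
#' confocal acquisition of myocyte structure.
#'
#' @param channels Named list of numeric arrays (all of identical
#'   dimension).
#' @param voxel_size Voxel edge lengths, um per axis.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, voxel_size = c(0.1, 0.1, 0.2)) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  dims <- lapply(channels, function(ch) dim(ch) %||% length(ch))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort_domain("all channels must have identical dimensions")
  }
  nd <- length(dims[[1]])
  if (any(voxel_size <= 0)) abort_domain("voxel sizes must be positive")
  structure(list(channels = channels, voxel_size = voxel_size[seq_len(nd)]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]]) %||% length(x$channels[[1]])
  cat(sprintf("<image_stack> %s voxels (%s um), channels: %s\n",
              paste(d, collapse = " x "),
              paste(signif(x$voxel_size, 3), collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(x, channel) {
  if (inherits(x, "image_stack")) {
    if (!channel %in% names(x$channels)) {
      abort_domain(sprintf("stack has no '%s' channel", channel))
    }
    list(img = x$channels[[channel]], voxel = x$voxel_size)
  } else {
    list(img = x, voxel = NULL)
  }
}

#' Synthetic striation phantom
#'
#' Generates an alpha-actinin-like striation pattern: a sinusoidal
#' intensity grating of the given spatial period along the fibre axis,
#' multiplied by a slow band envelope across the fibre (myofibril bundles),
#' with optional Gaussian intensity noise and phase disorder (a smooth
#' random phase field that locally stretches/compresses the striation).
#'
#' @param period Striation period (sarcomere length), um.
#' @param orientation Fibre-axis angle in the image plane, degrees.
#' @param noise_sd Gaussian intensity noise SD, as a fraction of the
#'   grating amplitude.
#' @param disorder Phase-disorder amplitude (fraction of a period).
#' @param dim Image dimension in pixels, length 2 (or 3 for a z-stack of
#'   identical planes plus noise).
#' @param voxel_size Voxel size, um.
#' @param seed RNG seed for noise and disorder.
#' @return An [image_stack()] with an `actinin` channel.
#' @export
#' @examples
#' st <- gen_striated_stack(1.8, seed = 1)
gen_striated_stack <- function(period, orientation = 0, noise_sd = 0,
                               disorder = 0, dim = c(256, 256),
                               voxel_size = c(0.1, 0.1, 0.2), seed = NULL) {
  check_positive(period, "period")
  nx <- dim[1]; ny <- dim[2]
  nz <- if (length(dim) >= 3) dim[3] else 1
  hx <- voxel_size[1]; hy <- voxel_size[2]
  th <- orientation * pi / 180
  x <- (seq_len(nx) - 1) * hx
  y <- (seq_len(ny) - 1) * hy
  u <- outer(x, y, function(xx, yy) xx * cos(th) + yy * sin(th))
  v <- outer(x, y, function(xx, yy) -xx * sin(th) + yy * cos(th))
  with_seed(seed, {
    phase <- 0
    if (disorder > 0) {
      # smooth random phase field: low-order cosine mixture
      k <- 3
      a <- rnorm(k, 0, disorder * 2 * pi / sqrt(k))
      fr <- runif(k, 0.02, 0.08) # cycles per um, well below the band
      ph <- runif(k, 0, 2 * pi)
      phase <- Reduce(`+`, lapply(seq_len(k), function(i) {
        a[i] * cos(2 * pi * fr[i] * u + ph[i])
      }))
    }
    grating <- 0.5 + 0.35 * sin(2 * pi * u / period + phase)
    envelope <- 0.75 + 0.25 * sin(2 * pi * v / 8) # 8 um myofibril banding
    plane <- grating * envelope
    stack <- array(rep(plane, nz), c(nx, ny, nz))
    if (noise_sd > 0) {
      stack <- stack + rnorm(length(stack), 0, noise_sd * 0.35)
    }
    if (nz == 1) stack <- stack[, , 1]
    image_stack(list(actinin = stack), voxel_size)
  })
}

#' Synthetic membrane phantoms
#'
#' `gen_slab_stack()` builds parallel membrane planes (one voxel thick)
#' with a clear gap of `spacing` um between membrane surfaces - the
#' analytic test object for the membrane-distance estimator, whose mean
#' intracellular distance is `spacing / 4`. `gen_cell_grid_stack()` builds
#' a 2-D grid of square cells of the given pitch with one-voxel membrane
#' walls, the test object for cross-section areas. `gen_labelled_stack()`
#' builds an intensity image in which a given volume fraction carries
#' bright (membrane/ECM-like) signal.
#'
#' @param spacing Gap between membrane surfaces, um.
#' @param n_gaps Number of complete membrane-to-membrane gaps along `axis`
#'   (the extent along `axis` is derived so that no partial gap remains).
#' @param cross_dim Extent of the remaining axes, voxels.
#' @param voxel_size Voxel size, um.
#' @param axis Axis perpendicular to the membrane planes (1, 2 or 3).
#' @return A logical mask array (`TRUE` = membrane voxel) for the mask
#'   generators; an [image_stack()] for `gen_labelled_stack()`.
#' @export
gen_slab_stack <- function(spacing, n_gaps = 4, cross_dim = c(40, 20),
                           voxel_size = c(0.1, 0.1, 0.2), axis = 1) {
  h <- voxel_size[axis]
  m <- round(spacing / h)
  if (abs(m * h - spacing) > 1e-9) {
    abort_domain("`spacing` must be an integer multiple of the voxel size along `axis`")
  }
  n_axis <- n_gaps * (m + 1) + 1 # membranes bound every gap on both sides
  dims <- append(cross_dim, n_axis, after = axis - 1)
  idx <- slice.index(array(0, dims), axis)
  mask <- (idx - 1) %% (m + 1) == 0
  array(mask, dims)
}

#' @rdname gen_slab_stack
#' @param pitch Cell pitch (wall centre to wall centre), um.
#' @export
gen_cell_grid_stack <- function(pitch = 20, dim = c(601, 601),
                                voxel_size = c(0.1, 0.1)) {
  mx <- round(pitch / voxel_size[1])
  my <- round(pitch / voxel_size[2])
  ix <- (seq_len(dim[1]) - 1) %% mx == 0
  iy <- (seq_len(dim[2]) - 1) %% my == 0
  outer(ix, iy, `|`)
}

#' @rdname gen_slab_stack
#' @param fraction Labelled volume fraction.
#' @param seed RNG seed.
#' @export
gen_labelled_stack <- function(fraction = 0.2, dim = c(128, 128, 8),
                               voxel_size = c(0.1, 0.1, 0.2), seed = NULL) {
  if (fraction < 0 || fraction > 1) abort_domain("`fraction` must be in [0, 1]")
  with_seed(seed, {
    n <- prod(dim)
    lab <- array(FALSE, dim)
    lab[sample.int(n, round(fraction * n))] <- TRUE
    img <- array(0.1, dim)
    img[lab] <- 0.9
    img <- img + rnorm(n, 0, 0.03)
    image_stack(list(membrane = img), voxel_size)
  })
}

# fibre-axis estimate from the structure tensor: intensity varies fastest
# along the striation periodicity, so the dominant gradient direction is
# the fibre axis
estimate_fibre_axis <- function(img, voxel) {
  gx <- (img[c(2:nrow(img), nrow(img)), ] -
           img[c(1, 1:(nrow(img) - 1)), ]) / (2 * voxel[1])
  gy <- (img[, c(2:ncol(img), ncol(img))] -
           img[, c(1, 1:(ncol(img) - 1))]) / (2 * voxel[2])
  st <- matrix(c(sum(gx * gx), sum(gx * gy), sum(gx * gy), sum(gy * gy)), 2)
  e <- eigen(st, symmetric = TRUE)
  v <- e$vectors[, 1]
  atan2(v[2], v[1]) * 180 / pi
}

#' Sarcomere length from the striation power spectrum
#'
#' Estimates the sarcomere length as the inverse of the dominant spatial
#' frequency of the alpha-actinin signal within the physiological band of
#' 1/3 to 1 per um (sarcomeres of 1-3 um). The image is projected onto the
#' fibre axis (estimated from the image structure tensor unless given), the
#' axial profile is Hann-windowed and zero-padded, and the power-spectrum
#' peak is refined by local quadratic interpolation of log power. Periods
#' outside the band (or a band without a peak clearly above the noise
#' floor) raise a no-structure error.
#'
#' @param x An [image_stack()] with an `actinin` channel, or a numeric
#'   matrix/array.
#' @param voxel_size Voxel size, um (taken from the stack if omitted).
#' @param band Frequency band searched, 1/um.
#' @param fibre_axis Fibre-axis angle in degrees, or `NULL` to estimate it.
#' @param pad Zero-padding factor for spectral interpolation.
#' @param min_peak_ratio Minimum ratio of peak power to the median in-band
#'   power for the peak to count as structure.
#' @return Sarcomere length, um.
#' @export
#' @examples
#' st <- gen_striated_stack(1.8, noise_sd = 0.1, seed = 1)
#' sarcomere_length(st)
sarcomere_length <- function(x, voxel_size = NULL, band = c(1 / 3, 1),
                             fibre_axis = NULL, pad = 4,
                             min_peak_ratio = 10) {
  ch <- get_channel(x, "actinin")
  img <- ch$img
  voxel <- voxel_size %||% ch$voxel
  if (is.null(voxel)) abort_format("voxel size calibration is required")
  if (length(dim(img)) == 3) {
    img <- apply(img, c(1, 2), mean) # z-projection
  }
  if (is.null(fibre_axis)) fibre_axis <- estimate_fibre_axis(img, voxel)
  th <- fibre_axis * pi / 180

  # project pixel positions onto the fibre axis and bin the profile
  hx <- voxel[1]; hy <- voxel[2]
  h <- min(hx, hy)
  xs <- (seq_len(nrow(img)) - 1) * hx
  ys <- (seq_len(ncol(img)) - 1) * hy
  u <- outer(xs, ys, function(xx, yy) xx * cos(th) + yy * sin(th))
  bin <- round((u - min(u)) / h)
  profile <- tapply(as.numeric(img), as.numeric(bin), mean)
  prof <- as.numeric(profile)
  n <- length(prof)
  prof <- prof - mean(prof)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1)) # Hann
  prof <- prof * w

  nfft <- nextn(n * pad, 2)
  p <- Mod(fft(c(prof, numeric(nfft - n))))^2
  freq <- (seq_len(nfft) - 1) / (nfft * h)
  in_band <- which(freq >= band[1] & freq <= band[2])
  if (length(in_band) < 3) abort_domain("frequency band too narrow for this image")
  # the dominant structural frequency (ignoring residual low-frequency
  # envelope content) must itself lie in the band: a strong out-of-band
  # periodicity would otherwise leak a spurious shoulder across the band
  # edge
  searchable <- which(freq >= 0.15 & freq <= 1 / (2 * h))
  dom <- searchable[which.max(p[searchable])]
  if (freq[dom] < band[1] * 0.98 || freq[dom] > band[2] * 1.02) {
    abort_convergence("dominant spatial frequency lies outside the sarcomere band")
  }
  pk <- in_band[which.max(p[in_band])]
  if (p[pk] < min_peak_ratio * median(p[in_band])) {
    abort_convergence("no striation peak above the noise floor within the frequency band")
  }
  # quadratic refinement of the peak position on log power
  if (pk > 1 && pk < nfft) {
    lp <- log(p[(pk - 1):(pk + 1)] + 1e-300)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    delta <- if (abs(denom) > 1e-12) 0.5 * (lp[1] - lp[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
  } else {
    delta <- 0
  }
  f0 <- (pk - 1 + delta) / (nfft * h)
  len <- 1 / f0
  # the refined peak may land marginally outside the band for a period at
  # its very edge; reject only estimates clearly beyond it
  if (len < 0.98 / band[2] || len > 1.02 / band[1]) {
    abort_convergence("estimated period outside the sarcomere band")
  }
  len
}

#' Extracellular-matrix volume fraction
#'
#' Fraction of voxels carrying segmented membrane/ECM (WGA-like) signal,
#' used as a fibrosis indicator. Intensity images are segmented with Otsu's
#' threshold; logical masks are used as given.
#'
#' @param x An [image_stack()] with a `membrane` channel, a numeric array,
#'   or a logical mask.
#' @param threshold `"otsu"` or a numeric cut-off.
#' @return Volume fraction in `[0, 1]`.
#' @export
ecm_fraction <- function(x, threshold = "otsu") {
  ch <- get_channel(x, "membrane")
  img <- ch$img
  if (is.logical(img)) return(mean(img))
  v <- as.numeric(img)
  if (diff(range(v)) < 1e-12) {
    return(as.numeric(v[1] > 0))
  }
  th <- if (identical(threshold, "otsu")) {
    v01 <- (v - min(v)) / diff(range(v))
    otsu01 <- EBImage::otsu(EBImage::Image(matrix(v01, nrow = 1)))
    min(v) + otsu01 * diff(range(v))
  } else {
    threshold
  }
  mean(v > th)
}

#' Mean intracellular distance to the nearest membrane
#'
#' Density proxy for the transverse tubular system: the Euclidean distance
#' transform (exact, honouring anisotropic voxel sizes) of the
#' non-membrane space with respect to the segmented membrane, averaged over
#' all intracellular voxels. Distances are measured to the membrane-voxel
#' surface (half-voxel correction per axis), so a slab phantom with plane
#' gap `d` reproduces the analytic mean of `d / 4`.
#'
#' @param mask Logical membrane mask (2-D or 3-D array), or an
#'   [image_stack()] whose `membrane` channel is logical.
#' @param voxel_size Voxel size, um.
#' @return Mean distance, um (0 for an all-membrane mask).
#' @export
#' @examples
#' m <- gen_slab_stack(2, n_gaps = 3, cross_dim = c(20, 10))
#' mean_membrane_distance(m) # ~0.5
mean_membrane_distance <- function(mask, voxel_size = c(0.1, 0.1, 0.2)) {
  if (inherits(mask, "image_stack")) {
    voxel_size <- mask$voxel_size
    mask <- mask$channels$membrane
  }
  if (!is.logical(mask)) abort_domain("`mask` must be a logical membrane mask")
  if (!any(mask)) abort_domain("mask contains no membrane voxels")
  if (all(mask)) return(0)
  d <- dim(mask) %||% length(mask)
  nd <- length(d)
  voxel <- voxel_size[seq_len(nd)]
  res <- .edt_anisotropic(as.logical(mask), as.integer(d), as.numeric(voxel))
  # surface correction: distance from voxel centre to the face of the
  # nearest membrane voxel along each axis
  idx <- seq_along(res$distance) - 1L
  px <- idx %% d[1]
  py <- if (nd >= 2) (idx %/% d[1]) %% d[2] else 0L
  pz <- if (nd >= 3) idx %/% (d[1] * d[2]) else 0L
  dx <- pmax(0, abs(px - res$fx) * voxel[1] - voxel[1] / 2)
  dy <- if (nd >= 2) pmax(0, abs(py - res$fy) * voxel[2] - voxel[2] / 2) else 0
  dz <- if (nd >= 3) pmax(0, abs(pz - res$fz) * voxel[3] - voxel[3] / 2) else 0
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  mean(dist[!as.logical(mask)])
}

#' Myocyte cross-section areas
#'
#' Labels the enclosed intracellular regions of a transverse membrane mask
#' (connected components of the non-membrane space), converts voxel counts
#' to um^2, discards components touching the image border (cells cut by the
#' field of view) and components below the minimum-size filter (capillary
#' lumina and segmentation debris), and flags implausibly large components
#' that indicate broken membranes merging neighbouring cells.
#'
#' @param mask Logical 2-D membrane mask (or 3-D array with `z` selecting
#'   the analysed plane).
#' @param voxel_size Pixel size, um.
#' @param z Plane index for 3-D input (default: middle plane).
#' @param min_area Minimum component area, um^2.
#' @param oversize_area Area above which a component is flagged as merged,
#'   um^2.
#' @return A list with `mean_area` (um^2, `NA` if no component passes the
#'   filter) and `components`, a tibble (`component`, `area_um2`,
#'   `oversized`).
#' @export
#' @examples
#' m <- gen_cell_grid_stack(20)
#' cross_section_area(m)$mean_area # ~400
cross_section_area <- function(mask, voxel_size = c(0.1, 0.1), z = NULL,
                               min_area = 50, oversize_area = 1000) {
  if (inherits(mask, "image_stack")) {
    voxel_size <- mask$voxel_size
    mask <- mask$channels$membrane
  }
  if (!is.logical(mask)) abort_domain("`mask` must be a logical membrane mask")
  if (length(dim(mask)) == 3) {
    if (is.null(z)) z <- ceiling(dim(mask)[3] / 2)
    mask <- mask[, , z]
  }
  interior <- !mask
  lab <- EBImage::bwlabel(EBImage::Image(interior * 1))
  lab <- EBImage::imageData(lab)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  counts <- table(lab[lab > 0 & !(lab %in% border_labels)])
  px_area <- voxel_size[1] * voxel_size[2]
  areas <- as.numeric(counts) * px_area
  keep <- areas >= min_area
  components <- tibble(component = as.integer(names(counts))[keep],
                       area_um2 = areas[keep],
                       oversized = areas[keep] > oversize_area)
  list(mean_area = if (nrow(components)) mean(components$area_um2) else NA_real_,
       components = components)
}

#' Read and write image stacks as TIFF
#'
#' One multi-page TIFF per channel; intensities are clipped to `[0, 1]` on
#' write (32-bit float samples, lossless for the phantom generators).
#'
#' @param stack An [image_stack()].
#' @param path Output path; for multi-channel stacks the channel name is
#'   inserted before the extension.
#' @return `write_stack()`: the written path(s), invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  paths <- character()
  multi <- length(stack$channels) > 1
  for (nm in names(stack$channels)) {
    p <- if (multi) sub("(\\.[^.]+)$", sprintf("_%s\\1", nm), path) else path
    arr <- stack$channels[[nm]]
    arr <- pmin(pmax(arr, 0), 1)
    pages <- if (length(dim(arr)) == 3) {
      lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
    } else {
      list(arr)
    }
    tiff::writeTIFF(pages, p, bits.per.sample = 32L, reduce = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_stack
#' @param channel Channel name to assign on read.
#' @param voxel_size Voxel size, um.
#' @export
read_stack <- function(path, channel = "actinin",
                       voxel_size = c(0.1, 0.1, 0.2)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- if (length(pages) == 1) {
    pages[[1]]
  } else {
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  ch <- list(arr)
  names(ch) <- channel
  image_stack(ch, voxel_size)
}
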