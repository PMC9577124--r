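#' Optical-density transform
#'
#' Maps transmitted-light fractions to optical density, `-log(max(v, 1e-3))`
#' with the natural log, so pixel values become proportional to the amount
#' of light-absorbing stain. White background (1.0) maps to 0; the 1e-3
#' floor caps the output at `-log(1e-3) ~ 6.9078`.
#'
#' @param image Numeric array (any shape) of linear-light values in \[0, 1\].
#' @param floor Lower clamp applied before the log (default `1e-3`).
#' @return Array of the same shape, values in `[0, -log(floor)]`.
#' @export
od_transform <- function(image, floor = 1e-3) {
  if (any(image < 0 | image > 1, na.rm = TRUE)) {
    stop("linear image values must lie in [0, 1]; normalize before the OD transform")
  }
  -log(pmax(image, floor))
}

#' Normalize an optical-density image to zero mean and unit SD
#'
#' Per-channel standardisation over tissue pixels so that downstream models
#' see pigment content rather than scanner-specific light transmission.
#' A channel with zero variance is returned as all zeros with a warning.
#'
#' @param od HxWx3 optical-density array.
#' @param tissue_mask Optional HxW logical mask restricting the statistics
#'   (and the pixels considered "tissue"); default uses every pixel.
#' @return Array of the same shape; over masked pixels each channel has
#'   mean 0 and SD 1.
#' @export
normalize_od <- function(od, tissue_mask = NULL) {
  d <- dim(od)
  if (length(d) != 3) stop("expected an HxWx3 array")
  if (is.null(tissue_mask)) tissue_mask <- matrix(TRUE, d[1], d[2])
  if (!any(tissue_mask)) stop("empty tissue mask: nothing to normalize over")
  out <- od
  for (ch in seq_len(d[3])) {
    v <- od[, , ch][tissue_mask]
    m <- mean(v)
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      warning("channel ", ch, " is constant over the mask; returning zeros")
      out[, , ch] <- 0
    } else {
      out[, , ch] <- (od[, , ch] - m) / s
    }
  }
  out
}

#' Random color augmentation of a spot image
#'
#' Perturbs brightness, contrast, saturation and hue with factors drawn
#' uniformly from symmetric ranges (defaults: brightness 2%, contrast 5%,
#' saturation 20%, hue 5%), applied once per spot in that order, before
#' any preprocessing. Output is clipped to \[0, 1\]. Uses R's global RNG.
#'
#' @param image HxWx3 linear RGB array in \[0, 1\].
#' @param brightness,contrast,saturation,hue Half-widths of the uniform
#'   perturbation ranges (fractions; hue as a fraction of a full hue turn).
#' @return Augmented HxWx3 array in \[0, 1\], with the drawn factors in
#'   `attr(, "factors")`.
#' @export
augment_color <- function(image, brightness = 0.02, contrast = 0.05,
                          saturation = 0.20, hue = 0.05) {
  f <- c(
    brightness = stats::runif(1, -brightness, brightness),
    contrast = stats::runif(1, -contrast, contrast),
    saturation = stats::runif(1, -saturation, saturation),
    hue = stats::runif(1, -hue, hue)
  )
  out <- image * (1 + f["brightness"])
  m <- mean(out)
  out <- m + (out - m) * (1 + f["contrast"])
  # saturation: interpolate between per-pixel luma and the image
  d <- dim(out)
  luma <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
  for (ch in 1:3) out[, , ch] <- luma + (out[, , ch] - luma) * (1 + f["saturation"])
  if (f["hue"] != 0) out <- rotate_hue(out, f["hue"])
  out <- pmin(pmax(out, 0), 1)
  attr(out, "factors") <- f
  out
}

# Rotate hue by `frac` of a full turn using the RGB-space rotation about the
# grey axis (YIQ approximation); cheap and invertible, adequate for small angles.
rotate_hue <- function(image, frac) {
  theta <- 2 * pi * frac
  u <- cos(theta); w <- sin(theta)
  m <- matrix(c(
    0.299 + 0.701 * u + 0.168 * w, 0.587 - 0.587 * u + 0.330 * w, 0.114 - 0.114 * u - 0.497 * w,
    0.299 - 0.299 * u - 0.328 * w, 0.587 + 0.413 * u + 0.035 * w, 0.114 - 0.114 * u + 0.292 * w,
    0.299 - 0.300 * u + 1.250 * w, 0.587 - 0.588 * u - 1.050 * w, 0.114 + 0.886 * u - 0.203 * w
  ), nrow = 3, byrow = TRUE)
  d <- dim(image)
  flat <- matrix(image, ncol = 3)
  array(flat %*% t(m), dim = d)
}

#' Dihedral variant of a square patch
#'
#' Indexes the 8 elements of the dihedral group of the square: `k` in 0-3
#' rotates by `k * 90` degrees counter-clockwise; `k` in 4-7 mirrors
#' horizontally first, then rotates by `(k - 4) * 90` degrees. `k = 0` is
#' the identity.
#'
#' @param patch A square PxP or PxPxC array.
#' @param k Integer 0-7.
#' @return The transformed patch, same shape.
#' @export
dihedral_variant <- function(patch, k) {
  if (length(k) != 1 || is.na(k) || k %% 1 != 0 || k < 0 || k > 7) {
    stop("k must be an integer in 0..7")
  }
  d <- dim(patch)
  if (d[1] != d[2]) stop("patch must be square")
  apply_plane <- function(m) {
    if (k >= 4) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]  # horizontal mirror
    r <- k %% 4
    for (i in seq_len(r)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]  # rot90 CCW
    m
  }
  if (length(d) == 2) return(apply_plane(patch))
  out <- array(0, dim = d)
  for (ch in seq_len(d[3])) out[, , ch] <- apply_plane(patch[, , ch])
  out
}

#' Fraction of tissue pixels in a spot image
#'
#' A pixel counts as tissue when its mean optical density across channels
#' exceeds a threshold; white background has OD ~ 0.
#'
#' @param image HxWx3 linear RGB array in \[0, 1\].
#' @param threshold Mean-OD threshold (default 0.15).
#' @return Fraction in \[0, 1\].
#' @export
tissue_fraction <- function(image, threshold = 0.15) {
  mean(tissue_mask_of(image, threshold))
}

tissue_mask_of <- function(image, threshold = 0.15) {
  od <- od_transform(image)
  (od[, , 1] + od[, , 2] + od[, , 3]) / 3 > threshold
}

#' Scale specification for instance creation
#'
#' The defaults mirror the three magnification contexts used by the
#' ensemble: full scale for nuclear texture, quarter scale for glandular
#' architecture, half scale with a larger patch for a mix of both.
#'
#' @param scale_factor Resampling factor applied to the spot (1 = native).
#' @param patch_px Patch side length in (resampled) pixels.
#' @return A `scale_spec` list.
#' @export
scale_spec <- function(scale_factor, patch_px) {
  if (scale_factor <= 0 || scale_factor > 1) stop("scale_factor must be in (0, 1]")
  if (patch_px < 4) stop("patch_px too small")
  structure(list(scale_factor = scale_factor, patch_px = as.integer(patch_px)),
            class = "scale_spec")
}

#' Default three-scale configuration
#'
#' @param patch_px Patch sizes for scales 1.0, 0.25 and 0.5 respectively.
#'   The full-resolution defaults are `c(224, 224, 352)`; pass smaller
#'   values (e.g. `c(32, 32, 48)`) for small synthetic spots.
#' @return A named list of three `scale_spec`s: `s1`, `s025`, `s05`.
#' @export
default_scales <- function(patch_px = c(224, 224, 352)) {
  list(
    s1 = scale_spec(1.0, patch_px[1]),
    s025 = scale_spec(0.25, patch_px[2]),
    s05 = scale_spec(0.5, patch_px[3])
  )
}

# Area-average downscale of one channel by integer-ish factor via bilinear
# block averaging. `scale` in (0,1]; output dims floor(dim * scale).
resample_area <- function(mat, scale) {
  if (scale == 1) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  nh <- max(1L, floor(h * scale)); nw <- max(1L, floor(w * scale))
  # map each output pixel to a block of input pixels (area averaging)
  ri <- findInterval(seq_len(h) - 1e-9, seq(0, h, length.out = nh + 1), all.inside = TRUE)
  ci <- findInterval(seq_len(w) - 1e-9, seq(0, w, length.out = nw + 1), all.inside = TRUE)
  rs <- rowsum(mat, ri)
  rs <- t(rowsum(t(rs), ci))
  counts <- outer(tabulate(ri, nh), tabulate(ci, nw))
  rs / counts
}

resample_image <- function(image, scale) {
  if (scale == 1) return(image)
  ch <- lapply(seq_len(dim(image)[3]), function(c) resample_area(image[, , c], scale))
  array(unlist(ch), dim = c(dim(ch[[1]]), length(ch)))
}

#' Lay out the non-overlapping patch grid for a spot
#'
#' Pure geometry: number of tiles and 0-based top-left origins (in the
#' resampled pixel space) for a spot of the given size. The random spatial
#' shift draws an offset uniformly per axis, truncated so that at least one
#' tile always fits when the resampled spot can hold a patch.
#'
#' @param h,w Spot height and width in native pixels.
#' @param spec A [scale_spec()].
#' @param offset Integer length-2 offset (row, col) in resampled pixels, or
#'   `NULL` to draw it from the global RNG.
#' @return A tibble of tile origins `row0`, `col0` (0-based, half-open
#'   tiles) with the drawn offset in `attr(, "offset")`.
#' @export
grid_origins <- function(h, w, spec, offset = NULL) {
  p <- spec$patch_px
  hs <- max(1L, floor(h * spec$scale_factor))
  ws <- max(1L, floor(w * spec$scale_factor))
  if (hs < p || ws < p) {
    stop(sprintf("spot too small: %dx%d at scale %g cannot hold a %d px patch",
                 h, w, spec$scale_factor, p))
  }
  if (is.null(offset)) {
    offset <- c(
      sample.int(min(p, hs - p + 1L), 1) - 1L,
      sample.int(min(p, ws - p + 1L), 1) - 1L
    )
  }
  rows <- seq(offset[1], hs - p, by = p)
  cols <- seq(offset[2], ws - p, by = p)
  out <- tidyr::expand_grid(row0 = rows, col0 = cols)
  attr(out, "offset") <- offset
  out
}

#' Create the instance bag for one spot at one scale
#'
#' Resamples the spot by the scale factor (area averaging), lays a
#' non-overlapping grid of `patch_px` tiles with a random spatial shift,
#' drops tiles with too little tissue, and returns the surviving patches.
#' Patches are cut from the OD-normalized image (normalisation statistics
#' computed per spot over tissue pixels); the tissue filter is evaluated
#' on the raw optical density.
#'
#' @param image HxWx3 linear RGB array in \[0, 1\] (a rendered or loaded
#'   spot).
#' @param spec A [scale_spec()].
#' @param min_tissue Minimum per-patch tissue fraction (default 0.25).
#' @param offset Optional fixed grid offset, see [grid_origins()].
#' @param normalize If `TRUE` (default) patches come from the per-spot
#'   OD-normalized image; otherwise from raw OD.
#' @return An `instance_bag`: list with `patches` (list of PxPx3 arrays),
#'   `origins` (tibble of 0-based top-left coordinates in resampled pixel
#'   space), and `scale`.
#' @export
make_instances <- function(image, spec, min_tissue = 0.25, offset = NULL,
                           normalize = TRUE) {
  small <- resample_image(image, spec$scale_factor)
  small <- pmin(pmax(small, 0), 1)
  od <- od_transform(small)
  mask <- (od[, , 1] + od[, , 2] + od[, , 3]) / 3 > 0.15
  if (!any(mask)) {
    stop("no instances: the spot holds no tissue above the threshold")
  }
  source_img <- if (normalize) normalize_od(od, mask) else od

  origins <- grid_origins(nrow(image), ncol(image), spec, offset = offset)
  p <- spec$patch_px
  keep <- logical(nrow(origins))
  patches <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    r <- origins$row0[i]; cc <- origins$col0[i]
    tile_mask <- mask[(r + 1):(r + p), (cc + 1):(cc + p)]
    if (mean(tile_mask) >= min_tissue) {
      keep[i] <- TRUE
      patches[[i]] <- source_img[(r + 1):(r + p), (cc + 1):(cc + p), , drop = FALSE]
    }
  }
  if (!any(keep)) {
    stop("no instances: every tile fell below the tissue threshold")
  }
  structure(
    list(patches = patches[keep], origins = origins[keep, ], scale = spec),
    class = "instance_bag"
  )
}

#' @export
print.instance_bag <- function(x, ...) {
  cat(sprintf("<instance_bag> %d patches of %d px at scale %g\n",
              length(x$patches), x$scale$patch_px, x$scale$scale_factor))
  invisible(x)
}
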