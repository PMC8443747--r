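## Per-channel smoothing and binarization.
##
## All operations are deterministic and, for 3D stacks, act slice-wise in
## the xy plane: at the 1 um z-interval typical of the targeted confocal
## acquisitions the axial sampling is far coarser than the lateral one, and
## in-plane filtering avoids anisotropy artifacts.

.as_zyx <- function(a) if (is.matrix(a)) array(a, dim = c(1, dim(a))) else a

.slicewise <- function(arr, f) {
  was_matrix <- is.matrix(arr)
  arr <- .as_zyx(arr)
  out <- arr
  for (z in seq_len(dim(arr)[1])) out[z, , ] <- f(arr[z, , ])
  if (was_matrix) out[1, , ] else out
}

#' Edge-preserving bilateral smoothing
#'
#' Smooths each xy slice with a bilateral filter: every pixel is replaced by
#' a weighted mean of its neighbours, where the weight is the product of a
#' spatial Gaussian (sigma \code{spatial_sigma} voxels) and an intensity
#' Gaussian (variance \code{degree_of_smoothing}, intensity-squared units).
#' Neighbours of similar intensity dominate, so uniform regions are smoothed
#' while edges are preserved.  Setting either parameter to 0 disables the
#' filter and returns the input unchanged.
#'
#' @param grid numeric intensity array, (z, y, x) or (y, x).
#' @param degree_of_smoothing intensity-variance scale; 0 disables.
#' @param spatial_sigma spatial Gaussian sigma in voxels; 0 disables.
#' @return smoothed array of the same shape.
#' @export
bilateral_smooth <- function(grid, degree_of_smoothing, spatial_sigma) {
  stopifnot(degree_of_smoothing >= 0, spatial_sigma >= 0)
  if (degree_of_smoothing == 0 || spatial_sigma == 0) return(grid)
  w <- max(1L, as.integer(ceiling(2 * spatial_sigma)))
  .slicewise(grid, function(m) {
    ny <- nrow(m); nx <- ncol(m)
    # replicate-pad so border pixels see a full window
    pad <- m[pmin(pmax(seq_len(ny + 2 * w) - w, 1), ny),
             pmin(pmax(seq_len(nx + 2 * w) - w, 1), nx)]
    acc <- matrix(0, ny, nx); wacc <- matrix(0, ny, nx)
    for (dy in -w:w) for (dx in -w:w) {
      sw <- exp(-(dy^2 + dx^2) / (2 * spatial_sigma^2))
      sh <- pad[(1 + w + dy):(ny + w + dy), (1 + w + dx):(nx + w + dx)]
      iw <- sw * exp(-(sh - m)^2 / (2 * degree_of_smoothing))
      acc <- acc + iw * sh
      wacc <- wacc + iw
    }
    acc / wacc
  })
}

# Discriminant-analysis (Otsu) threshold on a numeric vector.
# Returns c(threshold, sep): foreground rule is x >= threshold; sep is the
# class-mean separation in units of the within-class standard deviation at
# the optimum (Inf for perfectly separated classes).  NA threshold for
# degenerate (constant) input.
.otsu <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(c(threshold = NA_real_, sep = 0))
  integerish <- all(x == round(x)) && (rng[2] - rng[1]) <= 65535
  if (integerish) {
    edges <- seq(rng[1], rng[2] + 1)            # bin per integer value
    counts <- tabulate(x - rng[1] + 1, nbins = rng[2] - rng[1] + 1)
    mids <- seq(rng[1], rng[2])
  } else {
    nb <- 256L
    edges <- seq(rng[1], rng[2], length.out = nb + 1)
    counts <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE),
                            nb), nbins = nb)
    mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  }
  n <- sum(counts)
  w0 <- cumsum(counts) / n                       # background weight up to bin
  mu0 <- cumsum(counts * mids) / n
  mu_t <- mu0[length(mu0)]
  k <- seq_len(length(counts) - 1)               # cut after bin k
  sigma_b <- (mu_t * w0[k] - mu0[k])^2 / (w0[k] * (1 - w0[k]))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  best <- which.max(sigma_b)                     # ties -> lowest cut
  sigma_t <- sum(counts * (mids - mu_t)^2) / n
  mu_bg <- mu0[best] / w0[best]
  mu_fg <- (mu_t - mu0[best]) / (1 - w0[best])
  sigma_w2 <- max(sigma_t - sigma_b[best], 0)
  sep <- if (sigma_w2 == 0) Inf else (mu_fg - mu_bg) / sqrt(sigma_w2)
  c(threshold = edges[best + 1], sep = sep)
}

# Minimum class-mean separation (in within-class standard deviations) for a
# discriminant threshold to be trusted.  Otsu always returns a cut, even on
# pure noise, where the two "classes" are the halves of one Gaussian: their
# means then sit ~1.6 sigma apart against a within-class spread of ~0.6
# sigma (ratio ~2.7).  Genuine stain/background mixtures separate far more
# strongly; 4 cleanly rejects unimodal windows without losing sparse signal.
.sep_min <- 4

.otsu_valid <- function(o) !is.na(o["threshold"]) && o[["sep"]] >= .sep_min

# bilinear interpolation of tile-centre thresholds to every pixel
.interp_grid <- function(gy, gx, Tm, ny, nx) {
  ry <- if (length(gy) == 1) matrix(Tm, ny, length(gx), byrow = TRUE)
        else apply(Tm, 2, function(col)
          stats::approx(gy, col, xout = seq_len(ny), rule = 2)$y)
  if (length(gx) == 1) matrix(ry, ny, nx)
  else t(apply(ry, 1, function(row)
    stats::approx(gx, row, xout = seq_len(nx), rule = 2)$y))
}

#' Locally adaptive discriminant-analysis thresholding
#'
#' Computes an Otsu (between-class-variance maximising) threshold in
#' overlapping square windows tiled across each slice, interpolates the
#' window thresholds bilinearly to every voxel, scales them by
#' \code{sensitivity}, and marks a voxel foreground iff its intensity is
#' greater than or equal to its local effective threshold.
#'
#' Windows whose intensity distribution is degenerate (constant) or lacks a
#' genuine two-class structure (class-mean separation under 4 within-class
#' standard deviations) fall back to the slice-global threshold, then to
#' the stack-global one; if no level of the image shows two-class structure
#' the result is all background, so pure-noise or constant images never
#' produce spurious foreground.
#'
#' @param grid numeric intensity array, (z, y, x) or (y, x).
#' @param sensitivity multiplier in (0, 1] on the local thresholds; lower
#'   values admit dimmer voxels into the foreground.
#' @param window side length of the local window in voxels (>= 3).
#' @return logical mask of the same shape.
#' @export
threshold_adaptive <- function(grid, sensitivity = 1.0, window = 65) {
  stopifnot(sensitivity > 0, sensitivity <= 1, window >= 3)
  arr <- .as_zyx(grid)
  glob <- .otsu(as.numeric(arr))
  t_stack <- if (.otsu_valid(glob)) glob[["threshold"]] else Inf
  out <- .slicewise(grid, function(m) {
    sl <- .otsu(as.numeric(m))
    t_slice <- if (.otsu_valid(sl)) sl[["threshold"]] else t_stack
    # finite stand-in for "no foreground here": still above every intensity
    # after the sensitivity scaling, but safe to interpolate
    sentinel <- (max(m) + 1) / sensitivity
    if (!is.finite(t_slice)) t_slice <- sentinel
    ny <- nrow(m); nx <- ncol(m)
    if (window >= ny && window >= nx)
      return((m >= sensitivity * t_slice) * 1)
    step <- max(1L, as.integer(ceiling(window / 2)))  # 50% window overlap
    gy <- unique(pmin(seq(1L, ny, by = step), ny))
    gx <- unique(pmin(seq(1L, nx, by = step), nx))
    h <- window %/% 2
    Tm <- matrix(NA_real_, length(gy), length(gx))
    for (i in seq_along(gy)) for (j in seq_along(gx)) {
      ys <- max(1, gy[i] - h):min(ny, gy[i] + h)
      xs <- max(1, gx[j] - h):min(nx, gx[j] + h)
      loc <- .otsu(as.numeric(m[ys, xs]))
      Tm[i, j] <- if (.otsu_valid(loc)) loc[["threshold"]] else t_slice
    }
    thr <- .interp_grid(gy, gx, Tm, ny, nx)
    (m >= sensitivity * thr) * 1
  })
  if (is.matrix(out)) out >= 0.5 else out >= 0.5
}

#' Manual (global) thresholding
#'
#' Marks a voxel foreground iff its intensity is greater than or equal to
#' the fixed threshold.
#'
#' @param grid numeric intensity array.
#' @param threshold intensity cut-off.
#' @return logical mask of the same shape.
#' @export
threshold_manual <- function(grid, threshold) {
  grid >= threshold
}

.disc_brush <- function(w) {
  r <- as.integer(round(w))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

.morph_slicewise <- function(mask, w, op) {
  if (w == 0) return(mask)
  if (round(w) < 1) return(mask)
  br <- .disc_brush(w)
  res <- .slicewise(mask * 1, function(m) op(m, br))
  res >= 0.5
}

#' Reconnect fragmented signal by morphological closing
#'
#' Applies a slice-wise morphological closing with a disk of radius
#' \code{w1} voxels, bridging gaps narrower than about \code{2 * w1} voxels
#' between fragments of the same object.  \code{w1 = 0} disables the step.
#' Closing never removes foreground voxels.
#'
#' @param mask logical mask, (z, y, x) or (y, x).
#' @param w1 disk radius in voxels (>= 0).
#' @return logical mask of the same shape.
#' @export
morph_reconnect <- function(mask, w1) {
  stopifnot(w1 >= 0)
  .morph_slicewise(mask, w1, EBImage::closing)
}

#' Remove specks by morphological opening
#'
#' Applies a slice-wise morphological opening with a disk of radius
#' \code{w2} voxels, deleting foreground specks of radius below \code{w2}.
#' \code{w2 = 0} disables the step.  Opening never adds foreground voxels.
#'
#' @param mask logical mask, (z, y, x) or (y, x).
#' @param w2 disk radius in voxels (>= 0).
#' @return logical mask of the same shape.
#' @export
morph_denoise <- function(mask, w2) {
  stopifnot(w2 >= 0)
  .morph_slicewise(mask, w2, EBImage::opening)
}

# full preparation of one channel: smooth -> threshold -> close -> open
.prepare_channel <- function(grid, channel, params) {
  prep <- params$per_channel[[channel]]
  g <- bilateral_smooth(grid, prep$degree_of_smoothing, prep$spatial_sigma)
  mask <- if (params$threshold_mode == "adaptive") {
    threshold_adaptive(g, params$adaptive_sensitivity, params$adaptive_window)
  } else {
    threshold_manual(g, params$manual_threshold[[channel]])
  }
  mask <- morph_reconnect(mask, prep$morph_reconnect_w1)
  morph_denoise(mask, prep$morph_denoise_w2)
}
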