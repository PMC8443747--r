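## Seedable synthetic Z-stacks with ground truth.
##
## The generator emulates the imaging regime the pipeline targets: confocal
## Z-stacks at a 1 um axial interval, 10-15 optical sections, ellipsoidal
## nuclei with semi-axes around 6-7.5 um, micronuclei with equivalent radii
## of 0.5-1.9 um, an optional 1-voxel nuclear-envelope shell in the green
## channel and a cell-marker coat in the red channel, plus additive
## Gaussian noise clipped to the 8-bit range.

#' Specify a synthetic phantom
#'
#' @param shape stack dimensions \code{c(nz, ny, nx)} in voxels.
#' @param spacing voxel spacing \code{c(dx, dy, dz)} in um.
#' @param objects list of objects, each a list with \code{center_um}
#'   (\code{c(z, y, x)} physical coordinates), \code{semi_axes_um}
#'   (\code{c(az, ay, ax)}), \code{pattern} (\code{"chromatin"},
#'   \code{"chromatin+envelope"} or \code{"cell_marker_coat"} -- the coat
#'   also renders the chromatin core) and optional \code{border = TRUE}
#'   allowing the object to protrude from the volume.
#' @param intensity named foreground intensities per channel.
#' @param background_level background intensity.
#' @param noise_sigma additive Gaussian noise sd (0 = noise-free).
#' @param coat_margin_um thickness of the red cell-marker coat beyond the
#'   object surface.
#' @param seed integer seed; fully determines the rendered stack.
#' @return list of class \code{"mn_phantom_spec"}.
#' @export
phantom_spec <- function(shape, spacing, objects,
                         intensity = c(red = 180, green = 200, blue = 220),
                         background_level = 10, noise_sigma = 0,
                         coat_margin_um = 1.0, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  spacing <- stats::setNames(as.numeric(spacing), c("dx", "dy", "dz"))
  stopifnot(all(spacing > 0), noise_sigma >= 0, background_level >= 0)
  extent <- (rev(shape) - 1) * spacing  # physical extent per x, y, z
  for (ob in objects) {
    stopifnot(length(ob$center_um) == 3, length(ob$semi_axes_um) == 3,
              all(ob$semi_axes_um > 0))
    if (!isTRUE(ob$border)) {
      lo <- ob$center_um - ob$semi_axes_um
      hi <- ob$center_um + ob$semi_axes_um
      if (any(lo < 0) || any(hi > c(extent["dz"], extent["dy"], extent["dx"])))
        stop("object extends outside the volume; set border = TRUE if intended")
    }
    if (!ob$pattern %in% c("chromatin", "chromatin+envelope",
                           "cell_marker_coat"))
      stop("unknown channel pattern: ", ob$pattern)
  }
  structure(list(shape = shape, spacing = spacing, objects = objects,
                 intensity = intensity, background_level = background_level,
                 noise_sigma = noise_sigma, coat_margin_um = coat_margin_um,
                 seed = as.integer(seed)),
            class = "mn_phantom_spec")
}

# logical ellipsoid mask on the (z, y, x) voxel grid; centre/axes in um
.rasterize_ellipsoid <- function(shape, spacing, center_um, semi_axes_um) {
  zc <- (seq_len(shape[1]) - 1) * spacing["dz"]
  yc <- (seq_len(shape[2]) - 1) * spacing["dy"]
  xc <- (seq_len(shape[3]) - 1) * spacing["dx"]
  tz <- ((zc - center_um[1]) / semi_axes_um[1])^2
  ty <- ((yc - center_um[2]) / semi_axes_um[2])^2
  tx <- ((xc - center_um[3]) / semi_axes_um[3])^2
  outer(outer(tz, ty, "+"), tx, "+") <= 1
}

#' Render a phantom stack with ground truth
#'
#' Rasterises each object (a voxel belongs to an ellipsoid iff its centre
#' lies inside it), renders the chromatin signal in blue, a 1-voxel-thick
#' envelope shell in green for \code{"chromatin+envelope"} objects, and a
#' dilated cell-marker coat in red for \code{"cell_marker_coat"} objects,
#' then adds seeded Gaussian noise clipped to [0, 255].
#'
#' @param spec an \code{\link{phantom_spec}}.
#' @return list with \code{stack} (an \code{\link{mn_stack}}) and
#'   \code{truth} (per-object data frame plus expected per-image counts).
#' @export
make_phantom <- function(spec) {
  sh <- spec$shape; sp <- spec$spacing
  bg <- spec$background_level
  ch <- list(red = array(bg, dim = sh), green = array(bg, dim = sh),
             blue = array(bg, dim = sh))
  used <- c(red = FALSE, green = FALSE, blue = TRUE)
  rows <- list()
  for (i in seq_along(spec$objects)) {
    ob <- spec$objects[[i]]
    core <- .rasterize_ellipsoid(sh, sp, ob$center_um, ob$semi_axes_um)
    ch$blue[core] <- spec$intensity["blue"]
    has_env <- ob$pattern == "chromatin+envelope"
    if (has_env) {
      shell_outer <- .rasterize_ellipsoid(sh, sp, ob$center_um,
                                          ob$semi_axes_um +
                                            c(sp["dz"], sp["dy"], sp["dx"]))
      ch$green[shell_outer & !core] <- spec$intensity["green"]
      used["green"] <- TRUE
    }
    if (ob$pattern == "cell_marker_coat") {
      coat <- .rasterize_ellipsoid(sh, sp, ob$center_um,
                                   ob$semi_axes_um + spec$coat_margin_um)
      ch$red[coat] <- spec$intensity["red"]
      used["red"] <- TRUE
    }
    r_true <- prod(ob$semi_axes_um)^(1 / 3)  # sphere-equivalent radius
    rows[[i]] <- data.frame(
      object = i, r_true_um = r_true,
      class = if (r_true <= 2.0) "micronucleus"
              else if (r_true >= 4.0) "nucleus" else "unclassified",
      envelope = has_env, border = isTRUE(ob$border))
  }
  set.seed(spec$seed)
  for (nm in c("red", "green", "blue")) {  # fixed draw order: reproducible
    if (spec$noise_sigma > 0)
      ch[[nm]] <- ch[[nm]] + stats::rnorm(length(ch[[nm]]),
                                          sd = spec$noise_sigma)
    ch[[nm]] <- round(pmin(pmax(ch[[nm]], 0), 255))
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(object = integer(0), r_true_um = numeric(0),
               class = character(0), envelope = logical(0),
               border = logical(0))
  counts <- list(
    n_nuclei = sum(truth$class == "nucleus"),
    n_micronuclei = sum(truth$class == "micronucleus"),
    n_micronuclei_envelope_positive =
      sum(truth$class == "micronucleus" & truth$envelope),
    n_micronuclei_envelope_negative =
      sum(truth$class == "micronucleus" & !truth$envelope))
  stack <- mn_stack(ch[used], sp, source = sprintf("phantom(seed=%d)",
                                                   spec$seed))
  list(stack = stack, truth = truth, counts = counts, spec = spec)
}

#' Grazing-section confound scenario
#'
#' One 6 um-radius spherical nucleus positioned so that the top optical
#' section grazes it: that slice shows a small cross-section (radius about
#' 1.7 um) that a slice-by-slice 2D analysis classifies into the
#' micronucleus band, while full 3D reconstruction correctly yields one
#' nucleus and zero micronuclei.  Ground truth: 1 nucleus, 0 micronuclei.
#'
#' @param spacing voxel spacing in um (default 0.25 x 0.25 x 1, i.e. a 1 um
#'   confocal z-interval).
#' @return as \code{\link{make_phantom}}, with \code{truth$grazing_slice}
#'   and \code{truth$equator_slice} (1-based z indices) attached to the
#'   counts element.
#' @export
edge_slice_scenario <- function(spacing = c(0.25, 0.25, 1)) {
  sh <- c(12L, 96L, 96L)
  cy <- (sh[2] - 1) / 2 * spacing[2]
  cx <- (sh[3] - 1) / 2 * spacing[1]
  # centre 5.25 um up the 0..11 um z range: the top slice (z = 11 um) cuts
  # the sphere 5.75 um from centre, a sqrt(36 - 33.06) ~ 1.71 um section
  sp <- phantom_spec(
    shape = sh, spacing = spacing,
    objects = list(list(center_um = c(5.25, cy, cx),
                        semi_axes_um = c(6, 6, 6),
                        pattern = "chromatin", border = TRUE)),
    noise_sigma = 0, seed = 1L)
  ph <- make_phantom(sp)
  ph$grazing_slice <- 12L
  ph$equator_slice <- 6L
  ph
}

#' Dense fused-nuclei scenario
#'
#' Places \code{n_nuclei} spherical nuclei (radius about 5 um) in a row
#' with controlled pairwise overlap: consecutive centres sit
#' \code{2 R (1 - overlap_fraction)} apart, so any positive overlap fuses
#' the binarized nuclei into fewer connected components and ellipse fitting
#' is required to recover the true count.  With \code{overlap_fraction = 0}
#' the nuclei are placed fully disjoint.  Seeded jitter perturbs the radii
#' (+/- 5 percent) and the lateral positions (+/- 0.5 um).
#'
#' @param n_nuclei number of nuclei (>= 2).
#' @param overlap_fraction pairwise overlap in [0, 0.5).
#' @param seed integer seed.
#' @param spacing voxel spacing in um.
#' @return as \code{\link{make_phantom}}.
#' @export
dense_scenario <- function(n_nuclei = 5, overlap_fraction = 0.2, seed = 1L,
                           spacing = c(0.5, 0.5, 1)) {
  stopifnot(n_nuclei >= 2, overlap_fraction >= 0, overlap_fraction < 0.5)
  R <- 5.0
  set.seed(seed)
  radii <- R * stats::runif(n_nuclei, 0.95, 1.05)
  jitter_y <- stats::runif(n_nuclei, -0.5, 0.5)
  step <- if (overlap_fraction > 0) 2 * R * (1 - overlap_fraction)
          else 2 * R + 3 * spacing[1]
  x0 <- R + 2.5
  xs <- x0 + (seq_len(n_nuclei) - 1) * step
  extent_x <- xs[n_nuclei] + R + 2.5
  nx <- as.integer(ceiling(extent_x / spacing[1])) + 1L
  ny <- as.integer(ceiling((2 * R + 6) / spacing[2])) + 1L
  nz <- 13L
  cy <- (ny - 1) / 2 * spacing[2]
  objects <- lapply(seq_len(n_nuclei), function(i)
    list(center_um = c(6, cy + jitter_y[i], xs[i]),
         semi_axes_um = rep(radii[i], 3),
         pattern = "chromatin", border = TRUE))  # poles graze the z faces
  sp <- phantom_spec(shape = c(nz, ny, nx), spacing = spacing,
                     objects = objects, noise_sigma = 0, seed = seed)
  make_phantom(sp)
}
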