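#' Analysis parameters
#'
#' Constructs the full parameter set controlling the micronucleus
#' quantification pipeline: voxel spacing, size bands, overlap rate,
#' per-channel smoothing/morphology/ellipse-fitting settings, thresholding
#' mode and border handling.  Every argument has a documented default; the
#' returned object is a validated list of class \code{"mn_params"}.
#'
#' Size classes are defined on the equivalent radius \eqn{R_{cal}} in
#' micrometres.  A region is a micronucleus when \eqn{R_{cal}} falls inside
#' \code{micronucleus_band} (inclusive at both ends), a nucleus inside
#' \code{nucleus_band}, otherwise unclassified.  The default micronucleus
#' ceiling of 2.0 um reflects the convention that micronuclei are bounded by
#' a 2.0 um semi-major axis, while regular nuclei of neurons and astrocytes
#' have major axes of roughly 12--15 um (equivalent radius 6--7.5 um).
#'
#' @param dim_cell_analyze 2 or 3; whether connected components are formed
#'   per slice (2) or across the full stack (3).
#' @param dim_cell_radius 2 or 3; whether the equivalent radius is computed
#'   from the maximum cross-sectional area (2) or from the volume (3).
#' @param voxel_spacing numeric length-3 \code{c(dx, dy, dz)} in um/voxel.
#' @param micronucleus_band,nucleus_band numeric length-2 inclusive
#'   \code{c(r_min, r_max)} equivalent-radius bands in um; must be disjoint.
#' @param rate_cover_r_min overlap-rate threshold in [0, 1] used for
#'   objective-nucleus and envelope classification (default 0.5).
#' @param overlap_mode \code{"overlapped"} (objective iff overlap rate >=
#'   \code{rate_cover_r_min}) or \code{"non_overlapped"} (the complement).
#' @param per_channel named list (\code{red}, \code{green}, \code{blue}) of
#'   per-channel preparation settings; see \code{\link{channel_prep_params}}.
#' @param fitting_ellipse_n_div_ang number of discrete ellipse orientations;
#'   the angular step is 180 / n degrees (default 30, i.e. 6 degree steps).
#' @param fitting_link_radius um; maximum centroid displacement between
#'   consecutive slices for linking fitted ellipses into one 3D nucleus.
#' @param clear_border drop components touching the lateral (x/y) image
#'   borders; components cut only by the top/bottom z faces are kept.
#' @param insert_numbers rasterize label ids into exported label images.
#' @param threshold_mode \code{"adaptive"} (local discriminant analysis) or
#'   \code{"manual"}.
#' @param adaptive_sensitivity multiplier in (0, 1] applied to each local
#'   discriminant threshold (default 1).
#' @param adaptive_window side length in voxels of the local thresholding
#'   window (default 65).
#' @param manual_threshold named numeric per-channel intensity used when
#'   \code{threshold_mode = "manual"}.
#' @param channel_roles named character remapping of channel roles; defaults
#'   to red = cell-type marker, green = nuclear envelope, blue = chromatin.
#' @param connectivity_3d,connectivity_2d voxel connectivity used for
#'   component labelling (26 in 3D, 8 in 2D).
#' @return object of class \code{"mn_params"}.
#' @seealso \code{\link{validate_params}}, \code{\link{load_params}}
#' @export
mn_params <- function(dim_cell_analyze = 3,
                      dim_cell_radius = 3,
                      voxel_spacing = c(1, 1, 1),
                      micronucleus_band = c(0.2, 2.0),
                      nucleus_band = c(4.0, 10.0),
                      rate_cover_r_min = 0.5,
                      overlap_mode = "overlapped",
                      per_channel = list(),
                      fitting_ellipse_n_div_ang = 30,
                      fitting_link_radius = 4.0,
                      clear_border = TRUE,
                      insert_numbers = FALSE,
                      threshold_mode = "adaptive",
                      adaptive_sensitivity = 1.0,
                      adaptive_window = 65,
                      manual_threshold = c(red = 128, green = 128, blue = 128),
                      channel_roles = c(cell_marker = "red",
                                        envelope = "green",
                                        chromatin = "blue"),
                      connectivity_3d = 26,
                      connectivity_2d = 8) {
  pc <- list(red = channel_prep_params(), green = channel_prep_params(),
             blue = channel_prep_params())
  for (ch in names(per_channel)) {
    if (!ch %in% names(pc))
      stop("unknown channel in per_channel: ", ch)
    pc[[ch]] <- do.call(channel_prep_params, as.list(per_channel[[ch]]))
  }
  p <- list(
    dim_cell_analyze = as.integer(dim_cell_analyze),
    dim_cell_radius = as.integer(dim_cell_radius),
    voxel_spacing = stats::setNames(as.numeric(voxel_spacing),
                                    c("dx", "dy", "dz")),
    micronucleus_band = as.numeric(micronucleus_band),
    nucleus_band = as.numeric(nucleus_band),
    rate_cover_r_min = as.numeric(rate_cover_r_min),
    overlap_mode = as.character(overlap_mode),
    per_channel = pc,
    fitting_ellipse_n_div_ang = as.integer(fitting_ellipse_n_div_ang),
    fitting_link_radius = as.numeric(fitting_link_radius),
    clear_border = isTRUE(as.logical(clear_border)),
    insert_numbers = isTRUE(as.logical(insert_numbers)),
    threshold_mode = as.character(threshold_mode),
    adaptive_sensitivity = as.numeric(adaptive_sensitivity),
    adaptive_window = as.integer(adaptive_window),
    manual_threshold = unlist(manual_threshold),
    channel_roles = unlist(channel_roles),
    connectivity_3d = as.integer(connectivity_3d),
    connectivity_2d = as.integer(connectivity_2d)
  )
  class(p) <- "mn_params"
  v <- validate_params(p)
  if (length(v)) stop("invalid parameters:\n  ", paste(v, collapse = "\n  "))
  p
}

#' Per-channel preparation parameters
#'
#' Smoothing, morphology and ellipse-fitting knobs applied to one channel.
#' A value of 0 disables the corresponding step.
#'
#' @param degree_of_smoothing bilateral-filter intensity variance
#'   (intensity-squared units); 0 disables smoothing.
#' @param spatial_sigma bilateral-filter spatial Gaussian sigma in voxels;
#'   0 disables smoothing.
#' @param morph_reconnect_w1 disk radius (voxels) of the morphological
#'   closing that reconnects fragmented signal; 0 disables.
#' @param morph_denoise_w2 disk radius (voxels) of the morphological opening
#'   that removes specks; 0 disables.
#' @param fitting_ellipse_max_ratio maximum major/minor axis ratio for
#'   ellipse-fitting separation; 0 disables fitting, 1 restricts to circles,
#'   values > 1 allow ellipses.
#' @return named list of class \code{"mn_channel_prep"}.
#' @export
channel_prep_params <- function(degree_of_smoothing = 0,
                                spatial_sigma = 0,
                                morph_reconnect_w1 = 0,
                                morph_denoise_w2 = 0,
                                fitting_ellipse_max_ratio = 0) {
  structure(list(
    degree_of_smoothing = as.numeric(degree_of_smoothing),
    spatial_sigma = as.numeric(spatial_sigma),
    morph_reconnect_w1 = as.numeric(morph_reconnect_w1),
    morph_denoise_w2 = as.numeric(morph_denoise_w2),
    fitting_ellipse_max_ratio = as.numeric(fitting_ellipse_max_ratio)
  ), class = "mn_channel_prep")
}

band_ok <- function(b) length(b) == 2 && all(is.finite(b)) && b[1] < b[2]

bands_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

#' Validate an analysis parameter set
#'
#' Checks every invariant of the parameter set and returns a character
#' vector of violation messages (empty when all hold).  Each message names
#' the offending key.  Unlike the constructor this never raises, so it can
#' be used to vet user-edited configurations.
#'
#' @param p an \code{"mn_params"} object (or a compatible list).
#' @return character vector of violations; \code{character(0)} if valid.
#' @export
validate_params <- function(p) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  if (!p$dim_cell_analyze %in% c(2L, 3L))
    add("dim_cell_analyze: must be 2 or 3")
  if (!p$dim_cell_radius %in% c(2L, 3L))
    add("dim_cell_radius: must be 2 or 3")
  sp <- p$voxel_spacing
  if (length(sp) != 3 || !all(is.finite(sp)) || any(sp <= 0))
    add("voxel_spacing: dx, dy, dz must all be finite and strictly positive")
  if (!band_ok(p$micronucleus_band))
    add("micronucleus_band: requires finite r_min < r_max")
  if (!band_ok(p$nucleus_band))
    add("nucleus_band: requires finite r_min < r_max")
  if (band_ok(p$micronucleus_band) && band_ok(p$nucleus_band) &&
      bands_overlap(p$micronucleus_band, p$nucleus_band))
    add("micronucleus_band/nucleus_band: size bands must not overlap")
  if (!is.finite(p$rate_cover_r_min) ||
      p$rate_cover_r_min < 0 || p$rate_cover_r_min > 1)
    add("rate_cover_r_min: must lie in [0, 1]")
  if (!p$overlap_mode %in% c("overlapped", "non_overlapped"))
    add("overlap_mode: must be 'overlapped' or 'non_overlapped'")
  for (ch in names(p$per_channel)) {
    cp <- p$per_channel[[ch]]
    for (k in c("degree_of_smoothing", "spatial_sigma",
                "morph_reconnect_w1", "morph_denoise_w2")) {
      if (!is.finite(cp[[k]]) || cp[[k]] < 0)
        add(sprintf("per_channel.%s.%s: must be non-negative", ch, k))
    }
    fr <- cp$fitting_ellipse_max_ratio
    if (!is.finite(fr) || fr < 0 || (fr > 0 && fr < 1))
      add(sprintf(
        "per_channel.%s.fitting_ellipse_max_ratio: must be 0 (off) or >= 1",
        ch))
  }
  if (is.na(p$fitting_ellipse_n_div_ang) || p$fitting_ellipse_n_div_ang < 1)
    add("fitting_ellipse_n_div_ang: must be a positive integer")
  if (!is.finite(p$fitting_link_radius) || p$fitting_link_radius <= 0)
    add("fitting_link_radius: must be strictly positive")
  if (!p$threshold_mode %in% c("adaptive", "manual"))
    add("threshold_mode: must be 'adaptive' or 'manual'")
  if (!is.finite(p$adaptive_sensitivity) ||
      p$adaptive_sensitivity <= 0 || p$adaptive_sensitivity > 1)
    add("adaptive_sensitivity: must lie in (0, 1]")
  if (is.na(p$adaptive_window) || p$adaptive_window < 3)
    add("adaptive_window: must be >= 3 voxels")
  if (any(!is.finite(p$manual_threshold)) || any(p$manual_threshold < 0))
    add("manual_threshold: per-channel thresholds must be non-negative")
  if (!all(c("cell_marker", "envelope", "chromatin") %in%
           names(p$channel_roles)) ||
      !all(p$channel_roles %in% c("red", "green", "blue")))
    add("channel_roles: must map cell_marker/envelope/chromatin to red/green/blue")
  if (!p$connectivity_3d %in% c(6L, 18L, 26L))
    add("connectivity_3d: must be 6, 18 or 26")
  if (!p$connectivity_2d %in% c(4L, 8L))
    add("connectivity_2d: must be 4 or 8")
  v
}

# keys accepted at the top level of a config file
.scalar_keys <- c("dim_cell_analyze", "dim_cell_radius", "voxel_spacing",
                  "micronucleus_band", "nucleus_band", "rate_cover_r_min",
                  "overlap_mode", "fitting_ellipse_n_div_ang",
                  "fitting_link_radius", "clear_border", "insert_numbers",
                  "threshold_mode", "adaptive_sensitivity", "adaptive_window",
                  "manual_threshold", "channel_roles",
                  "connectivity_3d", "connectivity_2d")

#' Load analysis parameters from a YAML configuration file
#'
#' Reads a flat YAML key/value file (per-channel settings live under a
#' \code{per_channel:} map with \code{red}/\code{green}/\code{blue}
#' sub-maps).  Keys omitted from the file take their documented defaults;
#' unknown keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param path path to a YAML configuration file.
#' @param overrides optional named list applied on top of the file contents
#'   (used by the command-line driver for \code{--key value} flags).
#' @return validated \code{"mn_params"} object.
#' @export
load_params <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("malformed config file: ", path)
  cfg <- utils::modifyList(cfg, overrides)
  unknown <- setdiff(names(cfg), c(.scalar_keys, "per_channel"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$per_channel)) {
    for (ch in names(cfg$per_channel)) {
      bad <- setdiff(names(cfg$per_channel[[ch]]),
                     names(channel_prep_params()))
      if (length(bad))
        stop("unknown per_channel key(s) for ", ch, ": ",
             paste(bad, collapse = ", "))
    }
  }
  do.call(mn_params, cfg)
}

#' Write analysis parameters to a YAML configuration file
#'
#' Serialises a parameter set so that \code{load_params} restores an
#' identical object (round-trip property).
#'
#' @param p an \code{"mn_params"} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(p, path) {
  out <- unclass(p)
  out$per_channel <- lapply(out$per_channel, unclass)
  out$voxel_spacing <- as.list(out$voxel_spacing)
  out$manual_threshold <- as.list(out$manual_threshold)
  out$channel_roles <- as.list(out$channel_roles)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.mn_params <- function(x, ...) {
  cat("mn3d analysis parameters\n")
  cat(sprintf("  analysis: %dD components, R_cal from %s\n",
              x$dim_cell_analyze,
              if (x$dim_cell_radius == 3) "volume" else "max slice area"))
  cat(sprintf("  voxel spacing (um): dx=%g dy=%g dz=%g\n",
              x$voxel_spacing[1], x$voxel_spacing[2], x$voxel_spacing[3]))
  cat(sprintf("  micronucleus band: [%g, %g] um; nucleus band: [%g, %g] um\n",
              x$micronucleus_band[1], x$micronucleus_band[2],
              x$nucleus_band[1], x$nucleus_band[2]))
  cat(sprintf("  overlap: %s, rate threshold %g\n",
              x$overlap_mode, x$rate_cover_r_min))
  cat(sprintf("  threshold: %s (sensitivity %g, window %d)\n",
              x$threshold_mode, x$adaptive_sensitivity, x$adaptive_window))
  fit <- vapply(x$per_channel, function(cp) cp$fitting_ellipse_max_ratio,
                numeric(1))
  cat(sprintf("  ellipse fitting (max ratio): red=%g green=%g blue=%g; N_ang=%d\n",
              fit["red"], fit["green"], fit["blue"],
              x$fitting_ellipse_n_div_ang))
  invisible(x)
}
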