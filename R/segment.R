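## Connected-component labelling, morphometry and label editing.

# half-space neighbour offsets (dz, dy, dx) for a given connectivity; only
# "forward" offsets are needed to enumerate every adjacency once
.neighbour_offsets <- function(connectivity) {
  full <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  full <- full[!(full$dz == 0 & full$dy == 0 & full$dx == 0), ]
  keep <- switch(as.character(connectivity),
    "6" = rowSums(abs(full)) == 1,
    "18" = rowSums(abs(full)) <= 2,
    "26" = rep(TRUE, nrow(full)),
    "4" = full$dz == 0 & rowSums(abs(full)) == 1,
    "8" = full$dz == 0,
    stop("unsupported connectivity: ", connectivity))
  full <- full[keep, ]
  # forward half: first non-zero coordinate positive
  fwd <- (full$dz > 0) | (full$dz == 0 & full$dy > 0) |
    (full$dz == 0 & full$dy == 0 & full$dx > 0)
  as.matrix(full[fwd, , drop = FALSE])
}

#' Label connected components of a binary mask
#'
#' In 3D mode (\code{dim_cell_analyze = 3}) foreground voxels are linked
#' across slices with 26-connectivity, so the optical sections of one
#' nucleus form a single component -- the property that lets the method
#' distinguish a genuine micronucleus from the grazing section of a regular
#' nucleus.  In 2D mode each slice is labelled independently with
#' 8-connectivity, so the same physical nucleus yields one label per slice.
#' Labels are consecutive positive integers, ordered deterministically by
#' each component's first voxel in array order.
#'
#' @param mask logical array, (z, y, x) or (y, x).
#' @param dim_cell_analyze 2 or 3.
#' @param connectivity voxel connectivity; defaults to 26 (3D) / 8 (2D).
#' @return integer label array of the same (z, y, x) shape.
#' @export
label_components <- function(mask, dim_cell_analyze = 3,
                             connectivity = NULL) {
  arr <- .as_zyx(mask)
  d <- dim(arr)
  if (any(d == 0)) stop("mask has a degenerate shape")
  if (is.null(connectivity))
    connectivity <- if (dim_cell_analyze == 3) 26 else 8
  if (dim_cell_analyze == 2 && !connectivity %in% c(4, 8))
    stop("2D analysis requires in-plane (4 or 8) connectivity")
  fg <- which(arr)
  labels <- array(0L, dim = d)
  if (!length(fg)) return(labels)
  nid <- array(0L, dim = d)
  nid[fg] <- seq_along(fg)

  offs <- .neighbour_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  for (i in seq_len(nrow(offs))) {
    dz <- offs[i, 1]; dy <- offs[i, 2]; dx <- offs[i, 3]
    if (max(1, 1 - dz) > min(nz, nz - dz) ||
        max(1, 1 - dy) > min(ny, ny - dy) ||
        max(1, 1 - dx) > min(nx, nx - dx)) next  # offset exceeds the extent
    zr <- max(1, 1 - dz):min(nz, nz - dz)
    yr <- max(1, 1 - dy):min(ny, ny - dy)
    xr <- max(1, 1 - dx):min(nx, nx - dx)
    a <- nid[zr, yr, xr, drop = FALSE]
    b <- nid[zr + dz, yr + dy, xr + dx, drop = FALSE]
    sel <- a > 0L & b > 0L
    if (any(sel)) edges[[i]] <- rbind(a[sel], b[sel])
  }
  edges <- do.call(cbind, edges)
  memb <- if (is.null(edges)) {
    seq_along(fg)
  } else {
    g <- igraph::make_graph(as.vector(edges), n = length(fg),
                            directed = FALSE)
    igraph::components(g)$membership
  }
  labels[fg] <- match(memb, unique(memb))  # relabel in first-voxel order
  labels
}

#' Remove components touching the lateral image borders
#'
#' Deletes every label having at least one voxel on the x or y faces of the
#' volume; labels touching only the top or bottom z face are retained, since
#' a nucleus cut by the first or last optical section is still a valid 3D
#' object whereas one clipped laterally has an unknown extent.  Remaining
#' labels are renumbered consecutively.
#'
#' @param labels integer label array, (z, y, x) or (y, x).
#' @return relabelled array of the same shape.
#' @export
clear_lateral_border <- function(labels) {
  arr <- .as_zyx(labels)
  d <- dim(arr)
  border <- unique(c(arr[, c(1, d[2]), ], arr[, , c(1, d[3])]))
  border <- border[border > 0]
  if (length(border)) {
    arr[arr %in% border] <- 0L
    keep <- sort(unique(arr[arr > 0]))
    arr[arr > 0] <- match(arr[arr > 0], keep)
  }
  if (is.matrix(labels)) arr[1, , ] else arr
}

#' Measure per-region morphometry
#'
#' Computes, for each label, the voxel count, physical volume and areas,
#' the equivalent radius \eqn{R_{cal}}, the centroid in micrometres and the
#' border-contact flags.  With \code{dim_cell_radius = 3} the equivalent
#' radius comes from the volume assuming a sphere,
#' \eqn{R_{cal} = (3V / 4\pi)^{1/3}}; with \code{dim_cell_radius = 2} it
#' comes from the maximum cross-sectional slice area assuming a circle,
#' \eqn{R_{cal} = \sqrt{A_{max} / \pi}}.  Volumes use dx dy dz, slice areas
#' dx dy, so anisotropic voxels are handled exactly.
#'
#' @param labels integer label array, (z, y, x) or (y, x).
#' @param spacing voxel spacing \code{c(dx, dy, dz)} in um.
#' @param dim_cell_radius 2 or 3 (see above).
#' @param dim_cell_analyze 2 or 3; with 2 the per-region area equals its
#'   (single-slice) footprint area.
#' @return data frame with one row per label.
#' @export
measure_regions <- function(labels, spacing, dim_cell_radius = 3,
                            dim_cell_analyze = 3) {
  arr <- .as_zyx(labels)
  d <- dim(arr)
  dx <- spacing[[1]]; dy <- spacing[[2]]; dz <- spacing[[3]]
  idx <- which(arr > 0L)
  empty <- data.frame(label = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), area_um2 = numeric(0),
                      max_slice_area_um2 = numeric(0), r_cal_um = numeric(0),
                      centroid_z_um = numeric(0), centroid_y_um = numeric(0),
                      centroid_x_um = numeric(0),
                      touches_lateral_border = logical(0),
                      touches_z_face = logical(0))
  if (!length(idx)) return(empty)
  lab <- arr[idx]
  co <- arrayInd(idx, d)  # columns z, y, x (1-based)
  nlab <- max(lab)
  count <- tabulate(lab, nbins = nlab)

  # per-(label, slice) voxel counts -> maximum cross-sectional area
  kz <- (lab - 1L) * d[1] + co[, 1]
  cz <- tabulate(kz, nbins = nlab * d[1])
  max_slice <- apply(matrix(cz, nrow = d[1]), 2, max)

  volume <- count * dx * dy * dz
  max_slice_area <- max_slice * dx * dy
  area <- if (dim_cell_analyze == 2) count * dx * dy else rep(NA_real_, nlab)
  r_cal <- if (dim_cell_radius == 3) (3 * volume / (4 * pi))^(1 / 3)
           else sqrt(max_slice_area / pi)

  centroid <- function(axis, step)
    (rowsum(co[, axis] - 1, lab)[, 1] / count) * step
  lat <- co[, 2] == 1L | co[, 2] == d[2] | co[, 3] == 1L | co[, 3] == d[3]
  zf <- co[, 1] == 1L | co[, 1] == d[1]
  touches_lat <- tabulate(lab[lat], nbins = nlab) > 0
  touches_z <- tabulate(lab[zf], nbins = nlab) > 0

  data.frame(label = seq_len(nlab), voxel_count = count,
             volume_um3 = volume, area_um2 = area,
             max_slice_area_um2 = max_slice_area, r_cal_um = r_cal,
             centroid_z_um = centroid(1, dz), centroid_y_um = centroid(2, dy),
             centroid_x_um = centroid(3, dx),
             touches_lateral_border = touches_lat, touches_z_face = touches_z)
}

#' Classify regions into size bands
#'
#' Assigns \code{"micronucleus"} when the equivalent radius falls inside the
#' micronucleus band (inclusive at both ends), \code{"nucleus"} inside the
#' nucleus band, and \code{"unclassified"} otherwise.  With the default
#' bands a region is a micronucleus up to exactly 2.0 um equivalent radius.
#'
#' @param records data frame from \code{\link{measure_regions}}.
#' @param micronucleus_band,nucleus_band inclusive \code{c(r_min, r_max)}
#'   bands in um; must be disjoint.
#' @return \code{records} with an added \code{class} column.
#' @export
classify_size <- function(records, micronucleus_band = c(0.2, 2.0),
                          nucleus_band = c(4.0, 10.0)) {
  if (bands_overlap(micronucleus_band, nucleus_band))
    stop("size bands must be disjoint")
  r <- records$r_cal_um
  cls <- rep("unclassified", length(r))
  cls[r >= micronucleus_band[1] & r <= micronucleus_band[2]] <- "micronucleus"
  cls[r >= nucleus_band[1] & r <= nucleus_band[2]] <- "nucleus"
  records$class <- cls
  records
}

# geodesic nearest-seed partition of one label's voxel set; seeds is an
# n x 3 matrix of (z, y, x) voxel coordinates inside the label
.split_label <- function(arr, label, seeds) {
  idx <- which(arr == label)
  if (!length(idx)) stop("unknown label: ", label)
  d <- dim(arr)
  sid <- array(0L, dim = d)
  seed_idx <- (seeds[, 3] - 1L) * d[1] * d[2] + (seeds[, 2] - 1L) * d[1] +
    seeds[, 1]
  if (any(arr[seed_idx] != label))
    stop("split seed(s) fall outside label ", label)
  sid[seed_idx] <- seq_len(nrow(seeds))
  inside <- array(FALSE, dim = d)
  inside[idx] <- TRUE
  offs <- .neighbour_offsets(26)
  offs <- rbind(offs, -offs)  # both directions for frontier propagation
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  repeat {
    changed <- FALSE
    prop <- array(0L, dim = d)
    for (i in seq_len(nrow(offs))) {
      dzo <- offs[i, 1]; dyo <- offs[i, 2]; dxo <- offs[i, 3]
      if (max(1, 1 - dzo) > min(nz, nz - dzo) ||
          max(1, 1 - dyo) > min(ny, ny - dyo) ||
          max(1, 1 - dxo) > min(nx, nx - dxo)) next
      zr <- max(1, 1 - dzo):min(nz, nz - dzo)
      yr <- max(1, 1 - dyo):min(ny, ny - dyo)
      xr <- max(1, 1 - dxo):min(nx, nx - dxo)
      src <- sid[zr + dzo, yr + dyo, xr + dxo, drop = FALSE]
      dst <- prop[zr, yr, xr, drop = FALSE]
      # keep the lowest seed id reaching a voxel this wave (deterministic)
      take <- src > 0L & (dst == 0L | src < dst)
      dst[take] <- src[take]
      prop[zr, yr, xr] <- dst
    }
    new <- inside & sid == 0L & prop > 0L
    if (!any(new)) break
    sid[new] <- prop[new]
    changed <- TRUE
  }
  if (any(inside & sid == 0L))
    # disconnected remnants unreachable from any seed join the nearest seed
    # by euclidean distance
    for (j in which(inside & sid == 0L)) {
      co <- arrayInd(j, d)
      dists <- (seeds[, 1] - co[1])^2 + (seeds[, 2] - co[2])^2 +
        (seeds[, 3] - co[3])^2
      sid[j] <- which.min(dists)
    }
  sid
}

#' Apply a reproducible label-edit script
#'
#' Replaces interactive correction of the binarized result with an explicit,
#' replayable list of commands.  Supported operations: \code{delete}
#' removes a label; \code{merge} unions a second label into the first;
#' \code{split} partitions a label among two or more seed points by
#' geodesic nearest-seed assignment within the label.  Commands are applied
#' in order against the current state; the result is renumbered
#' consecutively.
#'
#' @param labels integer label array.
#' @param edits list of commands, each a list with \code{op}
#'   (\code{"delete"}, \code{"merge"}, \code{"split"}), \code{label},
#'   optional \code{with} (merge source), optional \code{seeds}
#'   (n x 3 matrix of 1-based (z, y, x) voxel coordinates).
#' @return relabelled array of the same shape.
#' @seealso \code{\link{read_edit_script}}
#' @export
edit_labels <- function(labels, edits) {
  arr <- .as_zyx(labels)
  next_id <- max(arr) + 1L
  for (e in edits) {
    if (!e$label %in% arr) stop("unknown label: ", e$label)
    switch(e$op,
      delete = { arr[arr == e$label] <- 0L },
      merge = {
        if (!e$with %in% arr) stop("unknown label: ", e$with)
        arr[arr == e$with] <- as.integer(e$label)
      },
      split = {
        seeds <- e$seeds
        if (is.null(dim(seeds))) seeds <- matrix(seeds, ncol = 3, byrow = TRUE)
        if (nrow(seeds) < 2) stop("split requires at least 2 seeds")
        sid <- .split_label(arr, e$label, seeds)
        part <- sid > 0L
        arr[part] <- next_id + sid[part] - 1L
        next_id <- next_id + max(sid)
      },
      stop("unknown edit op: ", e$op))
  }
  keep <- sort(unique(arr[arr > 0L]))
  if (length(keep)) arr[arr > 0L] <- match(arr[arr > 0L], keep)
  if (is.matrix(labels)) arr[1, , ] else arr
}

#' Read a label-edit script from CSV
#'
#' Columns: \code{channel} (optional, default \code{"blue"}), \code{op},
#' \code{label}, \code{with} (merge source label), \code{seeds} (split seed
#' points as \code{"z y x; z y x; ..."} in 1-based voxel coordinates).
#'
#' @param path CSV path.
#' @return named list (by channel) of command lists for
#'   \code{\link{edit_labels}}.
#' @export
read_edit_script <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$channel)) df$channel <- "blue"
  out <- list()
  for (i in seq_len(nrow(df))) {
    cmd <- list(op = df$op[i], label = as.integer(df$label[i]))
    if (!is.null(df$with) && !is.na(df$with[i]) && nzchar(df$with[i]))
      cmd$with <- as.integer(df$with[i])
    if (!is.null(df$seeds) && !is.na(df$seeds[i]) && nzchar(df$seeds[i])) {
      pts <- strsplit(trimws(strsplit(df$seeds[i], ";")[[1]]), "\\s+")
      cmd$seeds <- do.call(rbind, lapply(pts, as.integer))
    }
    out[[df$channel[i]]] <- c(out[[df$channel[i]]], list(cmd))
  }
  out
}
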