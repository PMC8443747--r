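## Separation of fused nuclei by greedy ellipse covering.
##
## Only two knobs of the original procedure are documented anywhere: the
## maximum major/minor axis ratio and the discrete rotation grid (angular
## step 180 / n_div_ang degrees).  The covering algorithm here is our own
## deterministic interpretation honouring both: repeatedly seed the largest
## inscribed ellipse at the distance-transform maximum of the uncovered
## region, search its orientation over the discrete angle grid, grow the
## semi-major axis until boundary contact or the ratio limit, subtract, and
## recurse on the remaining fragments.

# voxel footprint of an ellipse inside a (ny, nx) slice; 1-based centre
.ellipse_footprint <- function(cy, cx, a, b, theta_deg, ny, nx) {
  th <- theta_deg * pi / 180
  y0 <- max(1L, floor(cy - a)); y1 <- min(ny, ceiling(cy + a))
  x0 <- max(1L, floor(cx - a)); x1 <- min(nx, ceiling(cx + a))
  if (y0 > y1 || x0 > x1) return(integer(0))
  ys <- y0:y1; xs <- x0:x1
  yy <- matrix(ys - cy, length(ys), length(xs))
  xx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  u <- xx * cos(th) + yy * sin(th)
  v <- -xx * sin(th) + yy * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  w <- which(inside, arr.ind = TRUE)
  (xs[w[, 2]] - 1L) * ny + ys[w[, 1]]  # linear indices into the slice
}

#' Cover a fused 2D region with ratio-constrained ellipses
#'
#' Greedy covering of one binary region: the largest ellipse is placed with
#' its centre at the maximum of the region's Euclidean distance transform,
#' its semi-minor axis set by the inscribed-circle radius there, and its
#' orientation chosen among the \code{n_div_ang} discrete angles
#' (step 180 / n) as the one admitting the longest semi-major axis that
#' keeps the ellipse inside the uncovered region without exceeding
#' \code{max_ratio}.  The footprint is subtracted and the procedure recurses
#' on the remaining fragments until a fragment is smaller than
#' \code{min_fragment_area} voxels or too thin to seat an ellipse
#' (inscribed radius below \code{min_inscribed_radius} voxels).
#'
#' @param region_mask logical (y, x) matrix of one region's slice footprint.
#' @param max_ratio maximum semi-major/semi-minor ratio (>= 1; 1 = circles).
#' @param n_div_ang number of discrete orientations searched (>= 1).
#' @param min_fragment_area voxels; fragments below it are left uncovered
#'   (returned to background by the relabelling step).
#' @param min_inscribed_radius voxels; minimum inscribed-circle radius for
#'   seating a further ellipse.
#' @param min_inscribed_frac fraction of the first (largest) placement's
#'   semi-minor axis below which no further ellipse is seated; keeps thin
#'   residual slivers between adjacent nuclei from receiving ellipses of
#'   their own (their voxels are later assigned to the nearest real
#'   ellipse).
#' @return data frame of ellipses (1-based voxel coordinates
#'   \code{center_y}, \code{center_x}; \code{semi_major}, \code{semi_minor}
#'   in voxels; \code{orientation_deg}), with attributes
#'   \code{orientations_evaluated} (total orientation evaluations) and
#'   \code{placements}.
#' @export
fit_region_ellipses <- function(region_mask, max_ratio, n_div_ang,
                                min_fragment_area = 1,
                                min_inscribed_radius = 1.5,
                                min_inscribed_frac = 0.35) {
  stopifnot(max_ratio >= 1, n_div_ang >= 1)
  if (!any(region_mask)) stop("empty region")
  ny <- nrow(region_mask); nx <- ncol(region_mask)
  angles <- (seq_len(n_div_ang) - 1L) * 180 / n_div_ang
  remaining <- region_mask
  out <- list()
  n_orient <- 0L
  r_floor <- min_inscribed_radius
  repeat {
    if (sum(remaining) < max(1, min_fragment_area)) break
    dt <- EBImage::distmap(matrix(as.numeric(remaining), ny, nx))
    dmax <- max(dt)
    if (dmax < r_floor) break
    ctr <- which.max(dt)  # first maximum in column-major order: deterministic
    cy <- (ctr - 1L) %% ny + 1L
    cx <- (ctr - 1L) %/% ny + 1L
    b <- max(dmax - 0.5, 0.5)  # half-voxel margin keeps the disc inside
    best_a <- b; best_theta <- angles[1]
    for (th in angles) {
      n_orient <- n_orient + 1L
      a <- b
      repeat {
        a_try <- a + 0.25
        if (a_try > b * max_ratio) break
        fp <- .ellipse_footprint(cy, cx, a_try, b, th, ny, nx)
        if (!length(fp) || !all(remaining[fp])) break
        a <- a_try
      }
      if (a > best_a) { best_a <- a; best_theta <- th }
    }
    fp <- .ellipse_footprint(cy, cx, best_a, b, best_theta, ny, nx)
    fp <- fp[remaining[fp]]
    out[[length(out) + 1L]] <- data.frame(
      center_y = cy, center_x = cx, semi_major = best_a, semi_minor = b,
      orientation_deg = best_theta)
    if (length(out) == 1L)
      r_floor <- max(r_floor, min_inscribed_frac * b)
    remaining[fp] <- FALSE
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(center_y = numeric(0), center_x = numeric(0),
               semi_major = numeric(0), semi_minor = numeric(0),
               orientation_deg = numeric(0))
  attr(res, "orientations_evaluated") <- n_orient
  attr(res, "placements") <- nrow(res)
  res
}

# normalised ellipse-frame distance of points (y, x) to one ellipse
.ellipse_distance <- function(e, y, x) {
  th <- e$orientation_deg * pi / 180
  u <- (x - e$center_x) * cos(th) + (y - e$center_y) * sin(th)
  v <- -(x - e$center_x) * sin(th) + (y - e$center_y) * cos(th)
  (u / e$semi_major)^2 + (v / e$semi_minor)^2
}

#' Split fused labels by per-slice ellipse fitting
#'
#' For each label, fits ellipses to its footprint on every slice, links the
#' per-slice ellipses across z into nucleus chains by centroid proximity
#' (consecutive-slice centroid displacement below \code{link_radius_um}),
#' and, when a label yields two or more chains, partitions its voxels by
#' nearest-ellipse (normalised ellipse-frame distance) assignment.  Labels
#' yielding at most one chain are unchanged.  Every foreground voxel of the
#' input keeps exactly one label, so the output partitions the input
#' foreground; the final map is renumbered consecutively.
#'
#' With \code{max_ratio = 0} fitting is disabled and the input is returned
#' unchanged.
#'
#' @param labels integer label array, (z, y, x) or (y, x).
#' @param max_ratio per-channel maximum axis ratio (0 disables; 1 circles).
#' @param n_div_ang number of discrete orientations.
#' @param spacing voxel spacing \code{c(dx, dy, dz)} in um (xy must be
#'   square pixels).
#' @param link_radius_um maximum xy centroid displacement between
#'   consecutive slices for chain linking.
#' @param min_fragment_area_um2 um^2; slice fragments below it are not
#'   given ellipses of their own.
#' @param qc_prefix optional path prefix; writes the before/after label
#'   maps as a QC TIFF pair.
#' @return relabelled array of the same shape.
#' @export
relabel_with_ellipses <- function(labels, max_ratio, n_div_ang = 30,
                                  spacing = c(1, 1, 1),
                                  link_radius_um = 4.0,
                                  min_fragment_area_um2 = 0,
                                  qc_prefix = NULL) {
  if (max_ratio == 0) return(labels)
  stopifnot(max_ratio >= 1)
  dx <- spacing[[1]]; dy <- spacing[[2]]; dz <- spacing[[3]]
  if (abs(dx - dy) > 1e-9)
    stop("ellipse fitting requires square xy pixels (dx == dy)")
  arr <- .as_zyx(labels)
  d <- dim(arr)
  min_area_vox <- max(1, min_fragment_area_um2 / (dx * dy))
  out <- array(0L, dim = d)
  next_label <- 0L
  for (id in seq_len(max(arr))) {
    idx <- which(arr == id)
    if (!length(idx)) next
    co <- arrayInd(idx, d)
    zs <- sort(unique(co[, 1]))
    ellipses <- list()
    for (z in zs) {
      sel <- co[, 1] == z
      m <- matrix(FALSE, d[2], d[3])
      m[cbind(co[sel, 2], co[sel, 3])] <- TRUE
      if (sum(m) < min_area_vox) next
      ef <- fit_region_ellipses(m, max_ratio, n_div_ang,
                                min_fragment_area = min_area_vox)
      if (nrow(ef)) { ef$slice <- z; ellipses[[length(ellipses) + 1L]] <- ef }
    }
    ellipses <- if (length(ellipses)) do.call(rbind, ellipses) else NULL
    chains <- .link_chains(ellipses, dx, link_radius_um)
    n_chains <- if (is.null(chains)) 0L else max(chains)
    if (n_chains <= 1L) {
      next_label <- next_label + 1L
      out[idx] <- next_label
      next
    }
    ellipses$chain <- chains
    assign_chain <- .assign_voxels(co, ellipses, c(dx, dy, dz))
    out[idx] <- next_label + assign_chain
    next_label <- next_label + n_chains
  }
  res <- if (is.matrix(labels)) out[1, , ] else out
  if (!is.null(qc_prefix)) {
    write_annotated_labels(.as_zyx(labels), paste0(qc_prefix, "_before.tif"))
    write_annotated_labels(out, paste0(qc_prefix, "_after.tif"))
  }
  res
}

# link per-slice ellipses into chains across z; returns chain id per row
.link_chains <- function(ellipses, dx, link_radius_um) {
  if (is.null(ellipses) || !nrow(ellipses)) return(NULL)
  link_vox <- link_radius_um / dx
  chain <- integer(nrow(ellipses))
  n_chain <- 0L
  zs <- sort(unique(ellipses$slice))
  prev_rows <- integer(0)
  for (z in zs) {
    rows <- which(ellipses$slice == z)
    if (!length(prev_rows)) {
      for (r in rows) { n_chain <- n_chain + 1L; chain[r] <- n_chain }
    } else {
      # greedy nearest matching, closest pairs first, one ellipse per chain
      pairs <- expand.grid(cur = rows, prev = prev_rows)
      pairs$dist <- sqrt(
        (ellipses$center_y[pairs$cur] - ellipses$center_y[pairs$prev])^2 +
        (ellipses$center_x[pairs$cur] - ellipses$center_x[pairs$prev])^2)
      pairs <- pairs[pairs$dist < link_vox, , drop = FALSE]
      pairs <- pairs[order(pairs$dist, pairs$cur), , drop = FALSE]
      used_cur <- integer(0); used_chain <- integer(0)
      for (k in seq_len(nrow(pairs))) {
        cu <- pairs$cur[k]; pc <- chain[pairs$prev[k]]
        if (cu %in% used_cur || pc %in% used_chain) next
        chain[cu] <- pc
        used_cur <- c(used_cur, cu); used_chain <- c(used_chain, pc)
      }
      for (r in setdiff(rows, used_cur)) {
        n_chain <- n_chain + 1L; chain[r] <- n_chain
      }
    }
    prev_rows <- rows
  }
  chain
}

# assign each voxel (co = z,y,x rows) of a label to the chain of its
# nearest ellipse; slices without ellipses fall back to 3D distance
.assign_voxels <- function(co, ellipses, spacing) {
  n <- nrow(co)
  res <- integer(n)
  for (z in sort(unique(co[, 1]))) {
    vsel <- which(co[, 1] == z)
    es <- which(ellipses$slice == z)
    if (length(es)) {
      dmat <- vapply(es, function(e)
        .ellipse_distance(ellipses[e, ], co[vsel, 2], co[vsel, 3]),
        numeric(length(vsel)))
      dmat <- matrix(dmat, nrow = length(vsel))
      res[vsel] <- ellipses$chain[es[max.col(-dmat, ties.method = "first")]]
    } else {
      # 3D fallback in physical units
      dmat <- vapply(seq_len(nrow(ellipses)), function(e)
        ((co[vsel, 2] - ellipses$center_y[e]) * spacing[2])^2 +
        ((co[vsel, 3] - ellipses$center_x[e]) * spacing[1])^2 +
        ((z - ellipses$slice[e]) * spacing[3])^2,
        numeric(length(vsel)))
      dmat <- matrix(dmat, nrow = length(vsel))
      res[vsel] <- ellipses$chain[max.col(-dmat, ties.method = "first")]
    }
  }
  res
}
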