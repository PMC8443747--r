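## Multi-channel overlap-rate computation and final classification.

#' Overlap rate of a region with another channel's mask
#'
#' Fraction of the region's voxels covered by the other mask,
#' \eqn{|region \cap other| / |region|}, counted volumetrically in the
#' analysis dimensionality.
#'
#' @param region logical mask or integer vector of voxel indices.
#' @param other logical mask of the same geometry.
#' @return fraction in [0, 1].
#' @export
overlap_rate <- function(region, other) {
  idx <- if (is.logical(region)) which(region) else region
  if (!length(idx)) stop("empty region")
  sum(other[idx]) / length(idx)
}

# per-label overlap rates against a mask, vectorised over all labels
.label_overlap <- function(arr, nlab, mask) {
  idx <- which(arr > 0L)
  lab <- arr[idx]
  count <- tabulate(lab, nbins = nlab)
  hit <- tabulate(lab[mask[idx]], nbins = nlab)
  ifelse(count > 0, hit / count, NA_real_)
}

#' Classify objective nuclei by overlap rate
#'
#' Computes each region's volumetric overlap rate with the union of the
#' green and blue masks and with each mask individually, then flags the
#' region objective.  In \code{"overlapped"} mode a region is objective iff
#' its union overlap rate is at least \code{rate_min} (the attainment
#' reading of the default 0.5: half the region covered counts); in
#' \code{"non_overlapped"} mode objectivity is the exact complement, so the
#' two modes partition the regions.
#'
#' @param regions data frame of measured regions (one row per label).
#' @param labels integer label array the regions were measured from.
#' @param green_mask,blue_mask logical masks (either may be \code{NULL},
#'   but not both).
#' @param rate_min overlap-rate threshold in [0, 1].
#' @param mode \code{"overlapped"} or \code{"non_overlapped"}.
#' @return \code{regions} with \code{overlap_rate_green},
#'   \code{overlap_rate_blue} and \code{is_objective} columns.
#' @export
classify_objective <- function(regions, labels, green_mask = NULL,
                               blue_mask = NULL, rate_min = 0.5,
                               mode = c("overlapped", "non_overlapped")) {
  mode <- match.arg(mode)
  stopifnot(rate_min >= 0, rate_min <= 1)
  if (is.null(green_mask) && is.null(blue_mask))
    stop("at least one of green_mask or blue_mask is required")
  arr <- .as_zyx(labels)
  nlab <- if (nrow(regions)) max(regions$label) else 0L
  if (!nlab) {
    regions$overlap_rate_green <- numeric(0)
    regions$overlap_rate_blue <- numeric(0)
    regions$is_objective <- logical(0)
    return(regions)
  }
  g <- if (is.null(green_mask)) NULL else .as_zyx(green_mask)
  b <- if (is.null(blue_mask)) NULL else .as_zyx(blue_mask)
  union_mask <- if (is.null(g)) b else if (is.null(b)) g else (g | b)
  rate_union <- .label_overlap(arr, nlab, union_mask)
  regions$overlap_rate_green <-
    if (is.null(g)) NA_real_ else .label_overlap(arr, nlab, g)[regions$label]
  regions$overlap_rate_blue <-
    if (is.null(b)) NA_real_ else .label_overlap(arr, nlab, b)[regions$label]
  hit <- rate_union[regions$label] >= rate_min
  regions$is_objective <- if (mode == "overlapped") hit else !hit
  regions
}

#' Nuclear-envelope status of micronuclei
#'
#' A micronucleus is envelope-positive (e.g. Lamin B1 positive) when its
#' overlap rate with the envelope-marker (green) mask reaches
#' \code{rate_min}, envelope-negative otherwise.  Regions that are not
#' micronuclei, and all regions when no green channel exists, are marked
#' \code{"not_applicable"}.
#'
#' @param regions data frame with a \code{class} column.
#' @param labels integer label array the regions were measured from.
#' @param green_mask logical envelope mask or \code{NULL}.
#' @param rate_min overlap-rate threshold in [0, 1].
#' @return \code{regions} with an \code{envelope_status} column.
#' @export
envelope_status <- function(regions, labels, green_mask, rate_min = 0.5) {
  st <- rep("not_applicable", nrow(regions))
  if (!is.null(green_mask) && nrow(regions)) {
    arr <- .as_zyx(labels)
    rate <- .label_overlap(arr, max(regions$label), .as_zyx(green_mask))
    mn <- regions$class == "micronucleus"
    st[mn] <- ifelse(rate[regions$label[mn]] >= rate_min,
                     "positive", "negative")
  }
  regions$envelope_status <- st
  regions
}

#' Summarize classified regions into per-image counts
#'
#' Counts nuclei and micronuclei (on the chromatin channel when a
#' \code{channel} column is present), envelope-positive/negative
#' micronuclei, objective regions (on the cell-marker channel), and the
#' micronuclei-per-nucleus ratio.
#'
#' @param regions data frame of classified regions.
#' @param chromatin_channel,marker_channel channel names used to scope the
#'   size and objective counts when a \code{channel} column is present.
#' @return named list of counts.
#' @export
summarize_counts <- function(regions, chromatin_channel = "blue",
                             marker_channel = "red") {
  size_rows <- regions
  obj_rows <- regions
  if (!is.null(regions$channel)) {
    size_rows <- regions[regions$channel == chromatin_channel, , drop = FALSE]
    obj_rows <- regions[regions$channel == marker_channel, , drop = FALSE]
  }
  n_nuc <- sum(size_rows$class == "nucleus", na.rm = TRUE)
  n_mn <- sum(size_rows$class == "micronucleus", na.rm = TRUE)
  env <- size_rows$envelope_status[size_rows$class == "micronucleus"]
  n_obj <- if (is.null(obj_rows$is_objective)) 0L
           else sum(obj_rows$is_objective, na.rm = TRUE)
  list(
    n_nuclei = n_nuc,
    n_micronuclei = n_mn,
    n_micronuclei_envelope_positive = sum(env == "positive", na.rm = TRUE),
    n_micronuclei_envelope_negative = sum(env == "negative", na.rm = TRUE),
    n_objective = n_obj,
    micronuclei_per_nucleus = if (n_nuc > 0) n_mn / n_nuc else NA_real_
  )
}
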