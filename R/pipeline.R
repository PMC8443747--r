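## End-to-end orchestration: import -> smooth -> threshold -> binarize ->
## label -> [edit] -> [clear border] -> [ellipse fit] -> measure ->
## size-classify -> overlap-classify -> export.

#' Run the full micronucleus quantification pipeline
#'
#' Executes the fixed stage order on every channel present in the stack:
#' per-channel bilateral smoothing and binarization, connected-component
#' labelling (2D or 3D), optional label edits from a reproducible edit
#' script, optional lateral-border clearing, optional ellipse-fitting
#' separation (channels with a non-zero axis-ratio limit), morphometry,
#' size-band classification, and multi-channel overlap classification:
#' regions of the cell-marker (red) channel are flagged objective by their
#' overlap rate with the green-or-blue union, and micronuclei of the
#' chromatin (blue) channel receive an envelope status from the green mask.
#' Disabling every optional stage reduces the pipeline to
#' threshold -> label -> measure -> classify.
#'
#' The run is fully deterministic: identical input and parameters give
#' byte-identical exported tables.
#'
#' @param stack an \code{\link{mn_stack}}, or a path (or path vector)
#'   passed to \code{\link{read_stack}}.
#' @param params an \code{\link{mn_params}} object; its
#'   \code{voxel_spacing} is used when \code{stack} is a path.
#' @param edits optional label-edit commands: a path to an edit-script CSV
#'   (see \code{\link{read_edit_script}}) or a named-by-channel list of
#'   command lists.
#' @param outdir optional output directory; when given, writes
#'   \code{regions.csv} (+ \code{.txt} mirror with the summary block),
#'   \code{labels_<channel>.tif} and \code{run_log.yaml}.
#' @return object of class \code{"mn_result"}: \code{regions} (classified
#'   region table), \code{summary} (counts), \code{labels} and \code{masks}
#'   per channel, \code{params}, \code{artifacts} (paths), \code{log}.
#' @export
run_pipeline <- function(stack, params = mn_params(), edits = NULL,
                         outdir = NULL) {
  viol <- validate_params(params)
  if (length(viol))
    stop("invalid parameters:\n  ", paste(viol, collapse = "\n  "))
  if (is.character(stack)) stack <- read_stack(stack, params$voxel_spacing)
  if (!inherits(stack, "mn_stack")) stop("stack must be an mn_stack or path")
  if (is.character(edits)) edits <- read_edit_script(edits)

  spacing <- stack$spacing
  roles <- params$channel_roles
  chans <- names(stack$channels)

  masks <- list(); labels <- list(); tables <- list()
  for (ch in chans) {
    mask <- .prepare_channel(stack$channels[[ch]], ch, params)
    masks[[ch]] <- mask
    lab <- label_components(mask, params$dim_cell_analyze,
                            if (params$dim_cell_analyze == 3)
                              params$connectivity_3d else
                              params$connectivity_2d)
    if (!is.null(edits[[ch]])) lab <- edit_labels(lab, edits[[ch]])
    if (params$clear_border) lab <- clear_lateral_border(lab)
    fit_ratio <- params$per_channel[[ch]]$fitting_ellipse_max_ratio
    if (fit_ratio >= 1)
      lab <- relabel_with_ellipses(
        lab, fit_ratio, params$fitting_ellipse_n_div_ang, spacing,
        link_radius_um = params$fitting_link_radius,
        min_fragment_area_um2 = pi * params$micronucleus_band[1]^2)
    labels[[ch]] <- lab

    reg <- measure_regions(lab, spacing, params$dim_cell_radius,
                           params$dim_cell_analyze)
    reg <- classify_size(reg, params$micronucleus_band, params$nucleus_band)
    reg$channel <- if (nrow(reg)) ch else character(0)
    tables[[ch]] <- reg
  }

  # A nuclear-envelope stain labels a shell around the enclosed body, so a
  # micronucleus core never overlaps the raw ring mask.  Fill the ring
  # slice-wise before any overlap computation: "inside the envelope" is the
  # biologically meaningful condition.
  green <- masks[[roles[["envelope"]]]]
  if (!is.null(green)) green <- .fill_holes(green)
  blue <- masks[[roles[["chromatin"]]]]
  red_ch <- roles[["cell_marker"]]
  for (ch in chans) {
    reg <- tables[[ch]]
    others <- list(
      green = if (!is.null(green) && ch != roles[["envelope"]]) green,
      blue = if (!is.null(blue) && ch != roles[["chromatin"]]) blue)
    if (ch == red_ch && (!is.null(others$green) || !is.null(others$blue))) {
      reg <- classify_objective(reg, labels[[ch]], others$green, others$blue,
                                params$rate_cover_r_min, params$overlap_mode)
    } else {
      reg$overlap_rate_green <- if (nrow(reg) && !is.null(others$green))
        .label_overlap(.as_zyx(labels[[ch]]), max(reg$label),
                       .as_zyx(others$green))[reg$label] else
        rep(NA_real_, nrow(reg))
      reg$overlap_rate_blue <- if (nrow(reg) && !is.null(others$blue))
        .label_overlap(.as_zyx(labels[[ch]]), max(reg$label),
                       .as_zyx(others$blue))[reg$label] else
        rep(NA_real_, nrow(reg))
      reg$is_objective <- rep(NA, nrow(reg))
    }
    if (ch == roles[["chromatin"]]) {
      reg <- envelope_status(reg, labels[[ch]], green,
                             params$rate_cover_r_min)
    } else {
      reg$envelope_status <- rep("not_applicable", nrow(reg))
    }
    tables[[ch]] <- reg
  }

  regions <- do.call(rbind, tables)
  rownames(regions) <- NULL
  summary <- summarize_counts(regions, roles[["chromatin"]], red_ch)

  log <- list(package = "mn3d",
              version = as.character(utils::packageVersion("mn3d")),
              source = stack$source,
              channels = chans,
              params = unclass(write_params_list(params)))
  artifacts <- character(0)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(outdir, "regions.csv")
    export_region_table(regions, csv, summary = summary)
    artifacts <- c(regions = csv, table_txt = sub("\\.csv$", ".txt", csv))
    for (ch in chans) {
      if (max(labels[[ch]]) > 0) {
        p <- file.path(outdir, sprintf("labels_%s.tif", ch))
        write_annotated_labels(labels[[ch]], p, params$insert_numbers)
        artifacts[paste0("labels_", ch)] <- p
      }
    }
    logp <- file.path(outdir, "run_log.yaml")
    yaml::write_yaml(log, logp)
    artifacts["run_log"] <- logp
  }
  structure(list(regions = regions, summary = summary, labels = labels,
                 masks = masks, params = params, artifacts = artifacts,
                 log = log),
            class = "mn_result")
}

# slice-wise hole filling of a binary mask (envelope rings -> solid bodies)
.fill_holes <- function(mask) {
  .slicewise(mask * 1, function(m) EBImage::fillHull(m)) >= 0.5
}

# parameter list in plain-serialisable form (shared by run log and config)
write_params_list <- function(p) {
  out <- unclass(p)
  out$per_channel <- lapply(out$per_channel, unclass)
  out$voxel_spacing <- as.list(out$voxel_spacing)
  out$manual_threshold <- as.list(out$manual_threshold)
  out$channel_roles <- as.list(out$channel_roles)
  out
}

#' @export
print.mn_result <- function(x, ...) {
  cat("mn3d pipeline result\n")
  cat(sprintf("  regions: %d (channels: %s)\n", nrow(x$regions),
              paste(names(x$labels), collapse = ", ")))
  s <- x$summary
  cat(sprintf("  nuclei: %d   micronuclei: %d (envelope+ %d / envelope- %d)\n",
              s$n_nuclei, s$n_micronuclei,
              s$n_micronuclei_envelope_positive,
              s$n_micronuclei_envelope_negative))
  cat(sprintf("  objective regions: %d   micronuclei per nucleus: %s\n",
              s$n_objective,
              if (is.na(s$micronuclei_per_nucleus)) "NA"
              else sprintf("%.3f", s$micronuclei_per_nucleus)))
  invisible(x)
}

#' @export
summary.mn_result <- function(object, ...) {
  cat("Per-image counts:\n")
  for (k in names(object$summary))
    cat(sprintf("  %s: %s\n", k, format(object$summary[[k]])))
  cls <- table(object$regions$channel, object$regions$class)
  if (length(cls)) { cat("Regions by channel and class:\n"); print(cls) }
  invisible(object$summary)
}
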