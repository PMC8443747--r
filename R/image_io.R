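#' Multi-channel image stack
#'
#' Container pairing up to three named intensity channels with their voxel
#' spacing.  Channels are stored as arrays with axis order (z, y, x); a
#' single optical section is stored with one z-slice.  Physical coordinates
#' are zero-based: the centre of voxel (i, j, k) sits at
#' ((i-1) dz, (j-1) dy, (k-1) dx) micrometres.
#'
#' @param channels named list of numeric arrays, all of identical (z, y, x)
#'   dimension; names drawn from \code{"red"}, \code{"green"}, \code{"blue"}.
#' @param spacing numeric \code{c(dx, dy, dz)} in um/voxel.
#' @param source provenance string recorded in run logs.
#' @return object of class \code{"mn_stack"}.
#' @export
mn_stack <- function(channels, spacing, source = "in-memory") {
  if (!length(channels) || is.null(names(channels)))
    stop("channels must be a non-empty named list")
  if (!all(names(channels) %in% c("red", "green", "blue")))
    stop("channel names must be among red, green, blue")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(1, dim(ch)))
    if (length(dim(ch)) != 3) stop("channels must be (z, y, x) arrays")
    if (any(ch < 0)) stop("intensities must be non-negative")
    ch
  })
  d <- dim(channels[[1]])
  if (!all(vapply(channels, function(ch) identical(dim(ch), d), logical(1))))
    stop("all channels must share an identical shape")
  spacing <- stats::setNames(as.numeric(spacing), c("dx", "dy", "dz"))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be finite and strictly positive")
  structure(list(channels = channels, spacing = spacing, source = source),
            class = "mn_stack")
}

#' @export
print.mn_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("mn3d stack: %d slice(s) of %d x %d (y x x)\n", d[1], d[2], d[3]))
  cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  spacing (um): dx=%g dy=%g dz=%g\n",
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  source: %s\n", x$source))
  invisible(x)
}

# read all pages, returning raw integer sample values (0..2^bits - 1)
.read_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages)) stop("TIFF has zero pages: ", path)
  lapply(pages, function(pg) {
    bits <- attr(pg, "bits.per.sample")
    if (is.null(bits) || !bits %in% c(8L, 16L))
      stop("unsupported sample format in ", path,
           "; 8- or 16-bit integer TIFF expected")
    round(pg * (2^bits - 1))
  })
}

#' Read single or sequential TIFF stacks
#'
#' Accepts the three layouts produced by common confocal export workflows:
#' a single multi-page TIFF (RGB pages are split into red/green/blue;
#' grayscale pages become the \code{"blue"} chromatin channel), one
#' multi-page grayscale TIFF per channel (named via \code{names(path)} or,
#' unnamed, taken in red, green, blue order), or an ordered list of
#' single-page grayscale files forming the z-slices of one channel.
#' Pages are stacked in ascending z order.  Only 8/16-bit integer samples
#' are accepted.
#'
#' @param path one path or a character vector of paths (optionally named by
#'   channel).
#' @param spacing voxel spacing \code{c(dx, dy, dz)} in um.
#' @return an \code{\link{mn_stack}}.
#' @export
read_stack <- function(path, spacing) {
  stopifnot(is.character(path), length(path) >= 1)
  missing <- path[!file.exists(path)]
  if (length(missing)) stop("file(s) not found: ", paste(missing, collapse = ", "))

  assemble <- function(mats) {
    d <- dim(mats[[1]])
    if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
      stop("pages have differing sizes")
    arr <- array(0, dim = c(length(mats), d[1], d[2]))
    for (z in seq_along(mats)) arr[z, , ] <- mats[[z]]
    arr
  }

  if (length(path) == 1) {
    pages <- .read_pages(path)
    nd <- length(dim(pages[[1]]))
    if (nd == 2) {
      channels <- list(blue = assemble(pages))
    } else {
      ns <- dim(pages[[1]])[3]
      if (ns < 3) stop("unsupported sample layout: ", ns, " samples/pixel")
      channels <- list(
        red = assemble(lapply(pages, function(p) p[, , 1])),
        green = assemble(lapply(pages, function(p) p[, , 2])),
        blue = assemble(lapply(pages, function(p) p[, , 3]))
      )
    }
    return(mn_stack(channels, spacing, source = path))
  }

  per_file <- lapply(path, .read_pages)
  multi_page <- any(vapply(per_file, length, integer(1)) > 1)
  if (any(vapply(per_file, function(p) length(dim(p[[1]])) != 2, logical(1))))
    stop("multi-file input must contain grayscale pages")
  if (multi_page || !is.null(names(path))) {
    ch_names <- names(path)
    if (is.null(ch_names) || any(!nzchar(ch_names))) {
      if (length(path) > 3) stop("at most three channel files supported")
      ch_names <- c("red", "green", "blue")[seq_along(path)]
    }
    channels <- stats::setNames(lapply(per_file, assemble), ch_names)
  } else {
    channels <- list(blue = assemble(lapply(per_file, `[[`, 1)))
  }
  mn_stack(channels, spacing, source = paste(path, collapse = ";"))
}

# write a (z,y,x) integer array as a 16-bit multi-page grayscale TIFF
.write_gray16 <- function(arr, path) {
  if (max(arr) > 65535) stop("values exceed 16-bit range")
  pages <- lapply(seq_len(dim(arr)[1]), function(z) arr[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

# read it back as the integer array (bit-exact round trip)
.read_gray16 <- function(path) {
  pages <- .read_pages(path)
  d <- dim(pages[[1]])
  arr <- array(0L, dim = c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) arr[z, , ] <- as.integer(round(pages[[z]]))
  arr
}

# 3x5 bitmaps for digits 0-9, row-major from the top
.digit_font <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(r)
    matrix(as.integer(unlist(strsplit(r, ""))) == 1L, nrow = 5, byrow = TRUE))
})

# stamp the decimal digits of `value` into matrix m at (y0, x0): the digit
# box is cleared to 0 so the number stays legible inside a filled region,
# then glyph pixels are set to v
.stamp_number <- function(m, value, y0, x0, v) {
  digits <- strsplit(as.character(value), "")[[1]]
  x <- x0
  for (d in digits) {
    glyph <- .digit_font[[d]]
    ys <- y0:(y0 + 4); xs <- x:(x + 2)
    if (all(ys >= 1 & ys <= nrow(m)) && all(xs >= 1 & xs <= ncol(m))) {
      m[ys, xs] <- 0
      m[ys, xs][glyph] <- v
    }
    x <- x + 4
  }
  m
}

#' Write an annotated label image
#'
#' Exports a label map as a 16-bit multi-page grayscale TIFF whose pixel
#' values are the integer label ids.  With \code{insert_numbers} each
#' region's id is additionally rasterised (tiny 3x5 digit font) next to the
#' region centroid on the centroid slice, using the region's own label id as
#' pixel value so relabelling information is never corrupted.
#'
#' @param labels integer (z, y, x) label array (0 = background).
#' @param path output TIFF path.
#' @param insert_numbers logical; rasterise label ids at centroids.
#' @return \code{path}, invisibly.
#' @export
write_annotated_labels <- function(labels, path, insert_numbers = FALSE) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(1, dim(labels)))
  if (length(labels) == 0 || max(labels) == 0)
    stop("label map is empty")
  out <- labels
  if (insert_numbers) {
    ids <- sort(unique(labels[labels > 0]))
    for (id in ids) {
      w <- which(labels == id, arr.ind = TRUE)
      cz <- round(mean(w[, 1])); cy <- round(mean(w[, 2]))
      cx <- round(mean(w[, 3]))
      m <- out[cz, , ]
      m <- .stamp_number(m, id, max(1, cy - 2), max(1, cx - 1), id)
      out[cz, , ] <- m
    }
  }
  .write_gray16(out, path)
}

#' Read a label image written by \code{write_annotated_labels}
#'
#' @param path TIFF path.
#' @return integer (z, y, x) label array.
#' @export
read_labels <- function(path) .read_gray16(path)

.region_table_columns <- c(
  "label", "channel", "class", "voxel_count", "volume_um3", "area_um2",
  "max_slice_area_um2", "r_cal_um", "centroid_z_um", "centroid_y_um",
  "centroid_x_um", "touches_lateral_border", "touches_z_face",
  "overlap_rate_green", "overlap_rate_blue", "is_objective",
  "envelope_status")

#' Export a classified region table
#'
#' Writes one row per region with a stable column order to CSV, plus a
#' tab-separated plain-text mirror alongside (same basename, \code{.txt}).
#' An optional summary-count record is appended as \code{#}-prefixed comment
#' lines so that \code{read.csv(..., comment.char = "#")} round-trips the
#' table exactly.
#'
#' @param regions data frame of classified regions (possibly empty).
#' @param path output CSV path.
#' @param summary optional named list/vector of summary counts.
#' @return \code{path}, invisibly.
#' @export
export_region_table <- function(regions, path, summary = NULL) {
  cols <- .region_table_columns
  if (is.null(regions) || !nrow(regions)) {
    regions <- as.data.frame(stats::setNames(
      replicate(length(cols), logical(0), simplify = FALSE), cols))
  } else {
    for (cn in setdiff(cols, names(regions))) regions[[cn]] <- NA
    regions <- regions[, cols]
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.csv(regions, con, row.names = FALSE)
  if (!is.null(summary)) {
    writeLines("# summary", con)
    for (k in names(summary))
      writeLines(sprintf("# %s,%s", k, format(summary[[k]], digits = 15)), con)
  }
  txt <- sub("\\.csv$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  utils::write.table(regions, txt, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read back a region table written by \code{export_region_table}
#'
#' @param path CSV path.
#' @return data frame of regions (summary comment lines are skipped).
#' @export
read_region_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a stack as multi-page TIFF file(s)
#'
#' Writes each channel as a separate 16-bit multi-page grayscale TIFF
#' (\code{<prefix>_<channel>.tif}), the layout \code{read_stack} accepts as
#' one-file-per-channel input.
#'
#' @param stack an \code{\link{mn_stack}}.
#' @param prefix output path prefix.
#' @return named character vector of written paths, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  paths <- character(0)
  for (ch in names(stack$channels)) {
    p <- sprintf("%s_%s.tif", prefix, ch)
    .write_gray16(round(stack$channels[[ch]]), p)
    paths[ch] <- p
  }
  invisible(paths)
}
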