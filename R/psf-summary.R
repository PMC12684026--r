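# Spatial binning and summary statistics of bead measurements.

.accepted <- function(measurements) {
  measurements[measurements$flag == "accepted", , drop = FALSE]
}

.metric_cols <- c("fwhm_x_um", "fwhm_y_um", "fwhm_z_um", "fwhm_zstar_um")

# Quartiles by linear interpolation of order statistics (type 7).
.iqr7 <- function(x) {
  q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Summarise accepted bead measurements
#'
#' Median and interquartile range (Q3 - Q1, quartiles by linear
#' interpolation of order statistics) of each FWHM metric over accepted
#' measurements, reported as the field's "median +/- IQR (n)".
#'
#' @param measurements data.frame from [measureBeads()].
#' @return data.frame with columns `metric`, `median`, `iqr`, `n`.
#' @export
summarizeBeads <- function(measurements) {
  acc <- .accepted(measurements)
  if (!nrow(acc))
    stop("no accepted measurements to summarise", call. = FALSE)
  data.frame(
    metric = .metric_cols,
    median = vapply(.metric_cols, function(cn) median(acc[[cn]]), numeric(1)),
    iqr = vapply(.metric_cols, function(cn) .iqr7(acc[[cn]]), numeric(1)),
    n = nrow(acc), row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin bead measurements into a spatial resolution map
#'
#' Buckets accepted measurements into a 3D grid of world-space bins and
#' records the per-bin median, IQR and count of one metric. Empty bins are
#' `NA`. Flagged measurements are excluded before binning.
#'
#' @param measurements data.frame from [measureBeads()].
#' @param bin_edges list of three increasing numeric vectors: bin edges for
#'   x, y and z in um. See [resolutionBinEdges()] for the standard grids.
#' @param metric which column to map (default `"fwhm_z_um"`).
#' @return A [ResolutionMap-class].
#' @export
binMeasurements <- function(measurements, bin_edges,
                            metric = "fwhm_z_um") {
  stopifnot(metric %in% .metric_cols, length(bin_edges) == 3L)
  acc <- .accepted(measurements)
  nb <- vapply(bin_edges, function(e) length(e) - 1L, integer(1))
  med <- array(NA_real_, dim = nb)
  iqr <- array(NA_real_, dim = nb)
  cnt <- array(0L, dim = nb)
  if (nrow(acc)) {
    ix <- findInterval(acc$x_um, bin_edges[[1]], rightmost.closed = TRUE)
    iy <- findInterval(acc$y_um, bin_edges[[2]], rightmost.closed = TRUE)
    iz <- findInterval(acc$z_um, bin_edges[[3]], rightmost.closed = TRUE)
    inb <- ix >= 1 & ix <= nb[1] & iy >= 1 & iy <= nb[2] &
           iz >= 1 & iz <= nb[3]
    acc <- acc[inb, , drop = FALSE]
    key <- interaction(ix[inb], iy[inb], iz[inb], drop = TRUE)
    for (k in levels(key)) {
      rows <- acc[key == k, , drop = FALSE]
      i <- c(ix[inb][key == k][1], iy[inb][key == k][1], iz[inb][key == k][1])
      med[i[1], i[2], i[3]] <- median(rows[[metric]])
      iqr[i[1], i[2], i[3]] <- .iqr7(rows[[metric]])
      cnt[i[1], i[2], i[3]] <- nrow(rows)
    }
  }
  new("ResolutionMap", metric = metric, bin_edges = bin_edges,
      median = med, iqr = iqr, count = cnt)
}

#' Standard resolution-map bin edges
#'
#' The standard 3D grid divides the analysis region into bins of
#' `bin_um` (default 32 x 32 x 60 um, i.e. 15 x 10 x 5 bins over a
#' 480 x 320 x 300 um region). With `collapse_depth = TRUE` the grid is the
#' depth-collapsed 2D variant (default 16 x 16 um lateral bins and one bin
#' spanning the full depth).
#'
#' @param extent_um region size (x, y, z) in um.
#' @param origin_um world position of the region's minimum corner.
#' @param bin_um bin size (x, y, z) in um.
#' @param collapse_depth logical; lateral 2D binning over the whole depth.
#' @return List of three edge vectors suitable for [binMeasurements()].
#' @export
resolutionBinEdges <- function(extent_um = c(480, 320, 300),
                               origin_um = c(0, 0, 0),
                               bin_um = c(32, 32, 60),
                               collapse_depth = FALSE) {
  if (collapse_depth)
    bin_um <- c(bin_um[1] / 2, bin_um[2] / 2, extent_um[3])
  lapply(1:3, function(i)
    origin_um[i] + seq(0, extent_um[i], by = bin_um[i]))
}

#' Depth profile of a bead metric
#'
#' Median of one metric in depth slabs, the 1D view used to examine
#' resolution change with remote-refocus distance.
#'
#' @param measurements data.frame from [measureBeads()].
#' @param metric metric column name.
#' @param slab_um depth slab thickness in um.
#' @return data.frame with `depth_um` (slab centre), `median`, `iqr`, `n`.
#' @export
depthProfile <- function(measurements, metric = "fwhm_z_um", slab_um = 20) {
  acc <- .accepted(measurements)
  if (!nrow(acc)) stop("no accepted measurements", call. = FALSE)
  slab <- floor(acc$z_um / slab_um)
  out <- do.call(rbind, lapply(split(acc, slab), function(rows)
    data.frame(depth_um = (floor(rows$z_um[1] / slab_um) + 0.5) * slab_um,
               median = median(rows[[metric]]),
               iqr = .iqr7(rows[[metric]]), n = nrow(rows))))
  rownames(out) <- NULL
  out[order(out$depth_um), ]
}

#' Write a resolution map as a multi-frame TIFF
#'
#' One frame per depth bin of the per-bin median array, scaled by the
#' global maximum; empty bins are written as 0.
#'
#' @param map a [ResolutionMap-class].
#' @param path TIFF file path.
#' @return `path`, invisibly.
#' @export
writeResolutionMap <- function(map, path) {
  stopifnot(is(map, "ResolutionMap"))
  med <- map@median
  med[is.na(med)] <- 0
  mx <- max(med, 1e-12)
  frames <- lapply(seq_len(dim(med)[3]), function(k) t(med[, , k]) / mx)
  suppressWarnings(tiff::writeTIFF(frames, path, bits.per.sample = 32L,
                                   compression = "none"))
  invisible(path)
}

#' Plot one depth layer of a resolution map
#'
#' Heat-map panel of the per-bin median of a metric over the lateral grid,
#' the per-layer view used to inspect resolution variation across the
#' field.
#'
#' @param map a [ResolutionMap-class].
#' @param z_bin depth-bin index (default 1).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, the plotted matrix.
#' @export
plotResolutionMap <- function(map, z_bin = 1L, ...) {
  stopifnot(is(map, "ResolutionMap"))
  m <- map@median[, , z_bin]
  xe <- map@bin_edges[[1]]; ye <- map@bin_edges[[2]]
  graphics::image(x = xe, y = ye, z = m,
                  xlab = "x (um)", ylab = "y (um)",
                  main = sprintf("%s, depth bin %d", map@metric, z_bin),
                  useRaster = TRUE, ...)
  invisible(m)
}
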