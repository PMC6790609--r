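# File formats: labeled grids and gray volumes travel as multi-page
# TIFF stacks with a JSON sidecar (spacing, origin, codes, z-bands);
# fields additionally export to legacy ASCII VTK structured points for
# rendering. All text formats, no compiled dependencies.

#' Write / read a labeled grid as TIFF + JSON sidecar
#'
#' The label array is stored as an 8-bit multi-page TIFF (one z-slice
#' per page, codes as in [gridLabels()]), the layer array alongside it
#' as `<prefix>_layers.tif`, and spacing/origin/z-bands/ports in
#' `<prefix>.json`.
#'
#' @param grid a [LabeledGrid-class].
#' @param prefix output path prefix (no extension).
#' @return `writeLabeledGrid`: invisibly, the files written;
#'   `readLabeledGrid`: the reconstructed [LabeledGrid-class]
#'   (specs in `meta` are not round-tripped).
#' @export
writeLabeledGrid <- function(grid, prefix) {
  d <- dim(grid@label)
  toPages <- function(a) {
    lapply(seq_len(d[3]), function(k) a[, , k] / 255)
  }
  f1 <- paste0(prefix, "_labels.tif")
  f2 <- paste0(prefix, "_layers.tif")
  f3 <- paste0(prefix, ".json")
  tiff::writeTIFF(toPages(grid@label), f1, bits.per.sample = 8L)
  tiff::writeTIFF(toPages(grid@layer), f2, bits.per.sample = 8L)
  meta <- list(
    spacing = grid@spacing, origin = grid@origin, dim = d,
    label_codes = as.list(gridLabels()), layer_codes = as.list(gridLayers()),
    zbands = as.list(grid@meta$zbands %||% list()),
    ports = grid@ports
  )
  jsonlite::write_json(meta, f3, auto_unbox = TRUE, digits = NA)
  invisible(c(f1, f2, f3))
}

#' @rdname writeLabeledGrid
#' @export
readLabeledGrid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  fromPages <- function(file, d) {
    pages <- tiff::readTIFF(file, all = TRUE)
    a <- array(0L, d)
    for (k in seq_len(d[3])) {
      a[, , k] <- as.integer(round(pages[[k]] * 255))
    }
    a
  }
  d <- as.integer(meta$dim)
  ports <- if (length(meta$ports)) as.data.frame(meta$ports) else
    data.frame()
  new("LabeledGrid",
    spacing = meta$spacing, origin = as.numeric(meta$origin),
    label = fromPages(paste0(prefix, "_labels.tif"), d),
    layer = fromPages(paste0(prefix, "_layers.tif"), d),
    ports = ports,
    meta = list(zbands = unlist(meta$zbands))
  )
}

#' Write / read a grayscale volume as 32-bit float TIFF + JSON
#'
#' @param vol a [GrayVolume-class].
#' @param prefix path prefix.
#' @return `writeGrayVolume`: invisibly, the files written;
#'   `readGrayVolume`: the [GrayVolume-class].
#' @export
writeGrayVolume <- function(vol, prefix) {
  d <- dim(vol@intensity)
  # TIFF storage is defined on [0, 1]; keep the affine map in the
  # sidecar so intensities round-trip exactly
  lo <- min(vol@intensity)
  hi <- max(vol@intensity)
  span <- if (hi > lo) hi - lo else 1
  scaled <- (vol@intensity - lo) / span
  pages <- lapply(seq_len(d[3]), function(k) scaled[, , k])
  f1 <- paste0(prefix, ".tif")
  f2 <- paste0(prefix, ".json")
  tiff::writeTIFF(pages, f1, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(spacing = vol@spacing, origin = vol@origin, dim = d,
         intensity_offset = lo, intensity_span = span),
    f2, auto_unbox = TRUE, digits = NA
  )
  invisible(c(f1, f2))
}

#' @rdname writeGrayVolume
#' @export
readGrayVolume <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  a <- array(0, d)
  for (k in seq_len(d[3])) a[, , k] <- pages[[k]]
  a <- a * (meta$intensity_span %||% 1) + (meta$intensity_offset %||% 0)
  new("GrayVolume", intensity = a, spacing = meta$spacing,
      origin = as.numeric(meta$origin))
}

#' Export scalar/vector fields as legacy ASCII VTK structured points
#'
#' Writes cell data on the uniform voxel grid for rendering in ParaView
#' or similar. Scalars are written per named array; a velocity triple
#' (`ux`, `uy`, `uz`) is written as a VECTORS record.
#'
#' @param file output `.vtk` path.
#' @param arrays named list of 3-D arrays (identical dims); an element
#'   named `velocity` may be a list of three arrays.
#' @param spacing voxel size (m).
#' @param origin grid corner (m).
#' @return Invisibly, `file`.
#' @export
writeVTK <- function(file, arrays, spacing, origin = c(0, 0, 0)) {
  stopifnot(length(arrays) >= 1)
  d <- dim(if (is.list(arrays[[1]])) arrays[[1]][[1]] else arrays[[1]])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "ocperfusion field export", "ASCII", "DATASET STRUCTURED_POINTS",
    sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
    sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
    sprintf("SPACING %g %g %g", spacing, spacing, spacing),
    sprintf("POINT_DATA %d", prod(d))
  ), con)
  fmt <- function(x) formatC(x, format = "g", digits = 7)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    if (is.list(a)) {
      writeLines(sprintf("VECTORS %s float", nm), con)
      m <- cbind(as.vector(a[[1]]), as.vector(a[[2]]), as.vector(a[[3]]))
      m[is.na(m)] <- 0
      writeLines(paste(fmt(m[, 1]), fmt(m[, 2]), fmt(m[, 3])), con)
    } else {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      v <- as.vector(a)
      v[is.na(v)] <- 0
      writeLines(fmt(v), con)
    }
  }
  invisible(file)
}

#' Write a microenvironment report to CSV and JSON
#'
#' @param report a [MicroenvReport-class].
#' @param prefix path prefix.
#' @param comparison optional output of [compareReports()] written as
#'   `<prefix>_comparison.csv`.
#' @return Invisibly, the files written.
#' @export
writeReport <- function(report, prefix, comparison = NULL) {
  f1 <- paste0(prefix, ".csv")
  f2 <- paste0(prefix, ".json")
  write.csv(report@table, f1, row.names = FALSE)
  jsonlite::write_json(
    list(table = report@table, mixing = as.list(report@mixing),
         extras = report@extras),
    f2, auto_unbox = TRUE, digits = NA, na = "null"
  )
  out <- c(f1, f2)
  if (!is.null(comparison)) {
    f3 <- paste0(prefix, "_comparison.csv")
    write.csv(comparison, f3, row.names = FALSE)
    out <- c(out, f3)
  }
  invisible(out)
}
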