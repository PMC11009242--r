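# Minimal single-band float64 GeoTIFF writer/reader.
# Little-endian, uncompressed, one strip, north-up (row 1 = max y), with
# ModelPixelScale/ModelTiepoint/GeoKeyDirectory georeferencing and a
# GDAL-style ASCII nodata tag. Covers exactly the rasters this package
# produces; it is not a general TIFF library.

.tif <- list(SHORT = 3L, LONG = 4L, ASCII = 2L, DOUBLE = 12L)

.u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
.f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

.ifd_entry <- function(tag, type, count, value_raw) {
  stopifnot(length(value_raw) <= 4)
  c(.u16(tag), .u16(type), .u32(count),
    value_raw, raw(4 - length(value_raw)))
}

#' Write an interpolation field to GeoTIFF
#'
#' Writes a single-band 64-bit float GeoTIFF (uncompressed, little-endian,
#' north-up) with the grid's affine georeferencing and CRS citation in
#' GeoTIFF tags, and `NaN` as the declared nodata value. Masked and
#' unmasked fields are written identically; masking state only affects
#' which cells hold nodata.
#'
#' @param field An `interp_field` (see [interpolate_grid()]).
#' @param path Output path.
#' @param layer `"prediction"` or `"variance"` (kriging only).
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(field, path, layer = c("prediction", "variance")) {
  stopifnot(inherits(field, "interp_field"))
  layer <- match.arg(layer)
  m <- if (layer == "prediction") field$values else field$variance
  if (is.null(m)) stop("field has no ", layer, " layer", call. = FALSE)
  g <- field$grid
  h <- nrow(m); w <- ncol(m)
  cs <- g$cell_size
  y_top <- g$origin_y + g$n_rows * cs

  data_off <- 8L
  data_len <- w * h * 8L
  pixel_scale <- .f64(c(cs, cs, 0))
  tiepoint <- .f64(c(0, 0, 0, g$origin_x, y_top, 0))
  citation <- paste0(g$crs, " north-up equal-area grid|")
  geo_ascii <- c(charToRaw(citation), as.raw(0))
  if (length(geo_ascii) %% 2) geo_ascii <- c(geo_ascii, as.raw(0))
  # padded beyond 4 bytes so the tag value is always stored by offset
  nodata <- c(charToRaw("nan"), raw(3))
  geokeys <- .u16(c(1, 1, 0, 4,
                    1024, 0, 1, 1,      # projected model
                    1025, 0, 1, 1,      # pixel-is-area
                    3072, 0, 1, 32767,  # user-defined projected CRS
                    3073, 34737, nchar(citation) + 1, 0))  # citation in ascii params

  off_scale <- data_off + data_len
  off_tie <- off_scale + length(pixel_scale)
  off_keys <- off_tie + length(tiepoint)
  off_ascii <- off_keys + length(geokeys)
  off_nodata <- off_ascii + length(geo_ascii)
  off_ifd <- off_nodata + length(nodata)

  entries <- list(
    .ifd_entry(256, .tif$LONG, 1, .u32(w)),
    .ifd_entry(257, .tif$LONG, 1, .u32(h)),
    .ifd_entry(258, .tif$SHORT, 1, .u16(64)),
    .ifd_entry(259, .tif$SHORT, 1, .u16(1)),
    .ifd_entry(262, .tif$SHORT, 1, .u16(1)),
    .ifd_entry(273, .tif$LONG, 1, .u32(data_off)),
    .ifd_entry(277, .tif$SHORT, 1, .u16(1)),
    .ifd_entry(278, .tif$LONG, 1, .u32(h)),
    .ifd_entry(279, .tif$LONG, 1, .u32(data_len)),
    .ifd_entry(284, .tif$SHORT, 1, .u16(1)),
    .ifd_entry(339, .tif$SHORT, 1, .u16(3)),
    .ifd_entry(33550, .tif$DOUBLE, 3, .u32(off_scale)),
    .ifd_entry(33922, .tif$DOUBLE, 6, .u32(off_tie)),
    .ifd_entry(34735, .tif$SHORT, length(geokeys) / 2, .u32(off_keys)),
    .ifd_entry(34737, .tif$ASCII, length(geo_ascii), .u32(off_ascii)),
    .ifd_entry(42113, .tif$ASCII, length(nodata), .u32(off_nodata))
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16(42), .u32(off_ifd)), con)
  writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
  writeBin(c(pixel_scale, tiepoint, geokeys, geo_ascii, nodata), con)
  writeBin(.u16(length(entries)), con)
  for (e in entries) writeBin(e, con)
  writeBin(.u32(0), con)
  invisible(path)
}

#' Read a GeoTIFF written by [write_geotiff()]
#'
#' Parses the subset of TIFF this package writes: single band, 64-bit IEEE
#' float, uncompressed, single strip, little-endian.
#'
#' @param path Path to the file.
#' @return List with `values` (matrix, row 1 = north), `grid` (a
#'   reconstructed [grid_spec()]), and `nodata` (the declared nodata
#'   string).
#' @export
read_geotiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(raw[(off + 1):length(raw)], what, n = n, size = size,
            endian = "little", signed = signed)
  }
  if (rawToChar(raw[1:2]) != "II" || rd(2, "integer", 1, 2) != 42) {
    stop("not a little-endian TIFF", call. = FALSE)
  }
  ifd_off <- rd(4, "integer", 1, 4)
  n_entries <- rd(ifd_off, "integer", 1, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    eo <- ifd_off + 2 + (i - 1) * 12
    tag <- rd(eo, "integer", 1, 2, signed = FALSE)
    type <- rd(eo + 2, "integer", 1, 2)
    count <- rd(eo + 4, "integer", 1, 4)
    type_size <- c(`3` = 2L, `4` = 4L, `2` = 1L, `12` = 8L)[as.character(type)]
    total <- type_size * count
    voff <- if (total <= 4) eo + 8 else rd(eo + 8, "integer", 1, 4)
    val <- switch(as.character(type),
      `3` = rd(voff, "integer", count, 2, signed = FALSE),
      `4` = rd(voff, "integer", count, 4),
      `2` = {
        bytes <- raw[(voff + 1):(voff + count)]
        nul <- which(bytes == as.raw(0))
        rawToChar(bytes[seq_len(if (length(nul)) nul[1] - 1 else count)])
      },
      `12` = rd(voff, "numeric", count, 8)
    )
    tags[[as.character(tag)]] <- val
  }
  w <- tags[["256"]]; h <- tags[["257"]]
  if (tags[["258"]] != 64 || (tags[["339"]] %||% 3) != 3) {
    stop("only 64-bit float samples are supported", call. = FALSE)
  }
  if ((tags[["259"]] %||% 1) != 1) stop("compressed TIFF not supported",
                                        call. = FALSE)
  vals <- rd(tags[["273"]][1], "numeric", w * h, 8)
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  scale <- tags[["33550"]]
  tie <- tags[["33922"]]
  crs <- sub("[| ].*$", "", tags[["34737"]] %||% "unknown")
  grid <- structure(list(crs = crs, cell_size = scale[1],
                         origin_x = tie[4], origin_y = tie[5] - h * scale[2],
                         n_cols = as.integer(w), n_rows = as.integer(h)),
                    class = "grid_spec")
  list(values = m, grid = grid, nodata = tags[["42113"]] %||% NA_character_)
}
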