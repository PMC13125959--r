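# Minimal single-band float32 GeoTIFF I/O.
#
# Scope is deliberately narrow: uncompressed, strip-organised, one
# 32-bit IEEE float sample per pixel, geographic (lon/lat) CRS recorded via
# the GeoTIFF key directory, nodata stored as NaN plus the GDAL_NODATA tag.
# That is exactly the interchange format the pipeline needs for suitability
# and predictor layers; anything else is rejected loudly rather than guessed.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L,
               pixel_scale = 33550L, tiepoint = 33922L, geo_keys = 34735L,
               gdal_nodata = 42113L)

#' Write a raster as a single-band float32 GeoTIFF
#'
#' Nodata cells are stored as NaN and flagged in the GDAL nodata tag; the
#' grid is georeferenced by a pixel-scale and a (0,0) tie point, with a
#' geographic (EPSG:4326) CRS key. Round-tripping through
#' [read_geotiff()] preserves values to float32 precision, the nodata mask
#' and the grid.
#'
#' @param raster An `sdm_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(raster, path) {
  g <- raster$grid
  vals <- as.vector(t(raster$values))     # row-major, row 1 = north
  vals[is.na(vals)] <- NaN
  n_bytes <- 4L * length(vals)

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  data_off <- 8L
  scale_off <- data_off + n_bytes
  tie_off <- scale_off + 24L
  keys_off <- tie_off + 48L
  ifd_off <- keys_off + 32L

  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_off)
  writeBin(vals, con, size = 4, endian = "little")
  writeBin(as.double(c(g$resolution, g$resolution, 0)), con,
           size = 8, endian = "little")
  writeBin(as.double(c(0, 0, 0, g$lon_min, g$lat_max, 0)), con,
           size = 8, endian = "little")
  # GeoKey directory: version 1.1.0, 3 keys:
  #   model type = 2 (geographic), raster type = 1 (pixel-is-area), GCS = 4326
  w2(c(1L, 1L, 0L, 3L,
       1024L, 0L, 1L, 2L,
       1025L, 0L, 1L, 1L,
       2048L, 0L, 1L, 4326L))

  entry <- function(tag, type, count, value, inline_short = FALSE) {
    w2(tag); w2(type); w4(count)
    if (inline_short) { w2(value); w2(0L) } else w4(value)
  }
  w2(14L)  # entry count
  entry(TIFF_TAGS["width"], 4L, 1L, g$n_cols)
  entry(TIFF_TAGS["length"], 4L, 1L, g$n_rows)
  entry(TIFF_TAGS["bits"], 3L, 1L, 32L, inline_short = TRUE)
  entry(TIFF_TAGS["compression"], 3L, 1L, 1L, inline_short = TRUE)
  entry(TIFF_TAGS["photometric"], 3L, 1L, 1L, inline_short = TRUE)
  entry(TIFF_TAGS["strip_offsets"], 4L, 1L, data_off)
  entry(TIFF_TAGS["spp"], 3L, 1L, 1L, inline_short = TRUE)
  entry(TIFF_TAGS["rows_per_strip"], 4L, 1L, g$n_rows)
  entry(TIFF_TAGS["strip_bytes"], 4L, 1L, n_bytes)
  entry(TIFF_TAGS["sample_format"], 3L, 1L, 3L, inline_short = TRUE)
  entry(TIFF_TAGS["pixel_scale"], 12L, 3L, scale_off)
  entry(TIFF_TAGS["tiepoint"], 12L, 6L, tie_off)
  entry(TIFF_TAGS["geo_keys"], 3L, 16L, keys_off)
  # "nan" + NUL fits in the 4-byte inline value field
  w2(TIFF_TAGS["gdal_nodata"]); w2(2L); w4(4L)
  writeBin(c(charToRaw("nan"), as.raw(0)), con)
  w4(0L)  # next IFD
  invisible(path)
}

#' Read a single-band float32 GeoTIFF
#'
#' Accepts the files written by [write_geotiff()] and equivalent
#' single-band, uncompressed float32 GeoTIFFs from other tools (either byte
#' order). Multi-band files, compressed files, and files lacking
#' georeferencing or a geographic CRS are errors, never silently defaulted.
#'
#' @param path File path.
#' @return An `sdm_raster` (NaN and tagged-nodata pixels become `NA`).
#' @export
read_geotiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_mark <- rawToChar(raw[1:2])
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  rd_u2 <- function(off, n = 1) rd(off, "integer", n, 2, signed = FALSE)
  if (rd(2, "integer", 1, 2) != 42L) stop("not a TIFF file: ", path)
  ifd_off <- rd(4, "integer", 1, 4)
  n_entries <- rd_u2(ifd_off)

  type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)
  entries <- list()
  for (k in seq_len(n_entries)) {
    e_off <- ifd_off + 2 + (k - 1) * 12
    tag <- rd_u2(e_off)
    type <- rd_u2(e_off + 2)
    count <- rd(e_off + 4, "integer", 1, 4)
    sz <- type_size[as.character(type)]
    if (is.na(sz)) next
    val_off <- if (count * sz <= 4) e_off + 8 else rd(e_off + 8, "integer", 1, 4)
    value <- switch(as.character(type),
      `1` = as.integer(raw[(val_off + 1):(val_off + count)]),
      `2` = rawToChar(raw[(val_off + 1):(val_off + count)][
              raw[(val_off + 1):(val_off + count)] != as.raw(0)]),
      `3` = rd_u2(val_off, count),
      `4` = rd(val_off, "integer", count, 4),
      `11` = rd(val_off, "double", count, 4),
      `12` = rd(val_off, "double", count, 8))
    entries[[as.character(tag)]] <- value
  }
  tagval <- function(name, default = NULL) {
    v <- entries[[as.character(TIFF_TAGS[[name]])]]
    if (is.null(v)) default else v
  }

  # band count first, then georeferencing/CRS (the defining GeoTIFF
  # properties), then the sample layout this reader supports
  spp <- tagval("spp", 1L)
  if (spp != 1L) stop("multi-band TIFF not supported (", spp, " samples/pixel)")
  scale <- tagval("pixel_scale"); tie <- tagval("tiepoint")
  if (is.null(scale) || is.null(tie))
    stop("TIFF lacks georeferencing (pixel scale / tie point): ", path)
  keys <- tagval("geo_keys")
  if (is.null(keys)) stop("TIFF lacks a CRS (no GeoKey directory): ", path)
  if (tagval("compression", 1L) != 1L) stop("compressed TIFF not supported")
  if (!identical(tagval("bits"), 32L) || !identical(tagval("sample_format"), 3L))
    stop("only 32-bit IEEE float samples are supported")
  km <- matrix(keys[-(1:4)], ncol = 4, byrow = TRUE)
  model <- km[km[, 1] == 1024, 4]
  if (length(model) != 1 || model != 2)
    stop("TIFF CRS is not geographic lon/lat; refusing to guess")
  if (abs(scale[1] - scale[2]) > 1e-9) stop("non-square pixels not supported")
  if (any(tie[1:2] != 0)) stop("tie point must anchor pixel (0,0)")

  n_cols <- tagval("width"); n_rows <- tagval("length")
  res <- scale[1]
  grid <- make_grid(tie[4], tie[4] + n_cols * res,
                    tie[5] - n_rows * res, tie[5], res)

  offs <- tagval("strip_offsets"); lens <- tagval("strip_bytes")
  vals <- unlist(lapply(seq_along(offs), function(i)
    rd(offs[i], "double", lens[i] / 4, 4)))
  vals[is.nan(vals)] <- NA_real_
  nod <- suppressWarnings(as.numeric(tagval("gdal_nodata", "nan")))
  if (!is.na(nod)) vals[!is.na(vals) & vals == nod] <- NA_real_
  sdm_raster(grid, matrix(vals, n_rows, n_cols, byrow = TRUE))
}
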