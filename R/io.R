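#' @include grid-core.R
NULL

.readAsciiHeader <- function(lines, path) {
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) != 2L || is.na(suppressWarnings(as.numeric(parts[2L]))))
      break
    key <- tolower(parts[1L])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value"))
      break
    hdr[[key]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("cannot parse ESRI ASCII grid '", path, "': missing header field ",
         missing[1L], call. = FALSE)
  if (is.null(hdr$xllcorner)) {
    if (is.null(hdr$xllcenter))
      stop("cannot parse ESRI ASCII grid '", path,
           "': missing xllcorner/xllcenter", call. = FALSE)
    hdr$xllcorner <- hdr$xllcenter - hdr$cellsize / 2
    hdr$yllcorner <- hdr$yllcenter - hdr$cellsize / 2
  }
  list(hdr = hdr, skip = i)
}

.readAsciiGrid <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 7L, warn = FALSE)
  h <- .readAsciiHeader(lines, path)
  hdr <- h$hdr
  vals <- scan(path, what = double(), skip = h$skip, quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop("cannot parse ESRI ASCII grid '", path, "': expected ", nc * nr,
         " cell values after the header, found ", length(vals),
         call. = FALSE)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  # file rows run north to south; storage is south-up
  m <- matrix(vals, nr, nc, byrow = TRUE)[nr:1, , drop = FALSE]
  mask <- m == nodata
  list(spec = GridSpec(nc, nr, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                       nodata),
       values = m, mask = mask)
}

#' Read a suitability or elevation raster from an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII grid dialect (`ncols`/`nrows`/
#' `xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header followed by
#' north-to-south rows of cell values). Cells equal to the NoData sentinel
#' are masked. `readSuitabilityRaster()` additionally validates every
#' unmasked value into `[0, 1]` and reports the first offending cell.
#' Coordinates are assumed to be geographic decimal degrees (the format
#' carries no CRS metadata); a message notes this assumption.
#'
#' @param path path to an `.asc` file.
#' @param quiet suppress the CRS-assumption message.
#' @return `readSuitabilityRaster()` a [SuitabilityGrid-class];
#'   `readElevationRaster()` an [ElevationGrid-class].
#' @seealso [writeSuitabilityRaster()]
#' @export
readSuitabilityRaster <- function(path, quiet = FALSE) {
  g <- .readAsciiGrid(path)
  bad <- which(!g$mask & (g$values < 0 | g$values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    j <- bad[1L, 1L]; i <- bad[1L, 2L]
    stop("suitability out of range in '", path, "': value ",
         g$values[j, i], " at column ", i, ", row ", j,
         " (rows counted from the south)", call. = FALSE)
  }
  if (!quiet)
    message("no CRS metadata in ESRI ASCII grid; assuming geographic ",
            "decimal degrees: ", path)
  v <- g$values
  v[g$mask] <- 0
  new("SuitabilityGrid", spec = g$spec, values = v, mask = g$mask)
}

#' @rdname readSuitabilityRaster
#' @export
readElevationRaster <- function(path, quiet = FALSE) {
  g <- .readAsciiGrid(path)
  if (!quiet)
    message("no CRS metadata in ESRI ASCII grid; assuming geographic ",
            "decimal degrees: ", path)
  v <- g$values
  v[g$mask] <- 0
  new("ElevationGrid", spec = g$spec, values = v, mask = g$mask)
}

#' Write a grid as an ESRI ASCII raster
#'
#' Writes the grid in the ESRI ASCII dialect with rows ordered north to
#' south and masked cells as the spec's NoData sentinel. Values are printed
#' with 7 significant digits, so a write/read round trip preserves
#' memberships to well under 1e-7.
#'
#' @param g a [SuitabilityGrid-class] or [ElevationGrid-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeSuitabilityRaster <- function(g, path) {
  s <- g@spec
  v <- g@values
  v[g@mask] <- s@nodata
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", s@nCols),
    paste("nrows", s@nRows),
    paste("xllcorner", format(s@xOrigin, digits = 12)),
    paste("yllcorner", format(s@yOrigin, digits = 12)),
    paste("cellsize", format(s@cellSize, digits = 12)),
    paste("NODATA_value", format(s@nodata, digits = 12))
  ), con)
  for (j in s@nRows:1)
    writeLines(paste(formatC(v[j, ], digits = 7, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' Assemble one indices-table row
#'
#' Flattens a [PRSIndices-class] plus species metadata into the standard
#' one-row data.frame used by [writeIndicesTable()].
#'
#' @param idx a [PRSIndices-class].
#' @param speciesId,genus,scenario metadata strings.
#' @return A one-row data.frame in the indices-table column order.
#' @export
indicesRecord <- function(idx, speciesId, genus = NA_character_,
                          scenario = NA_character_) {
  data.frame(
    species_id = speciesId, genus = genus, scenario = scenario,
    i_index = idx@iIndex, o_index = idx@oIndex,
    dx = idx@dx, dy = idx@dy, dz = idx@dz,
    card_current = idx@cardCurrent, card_future = idx@cardFuture,
    overlap_convention = idx@overlapConvention,
    stringsAsFactors = FALSE
  )
}

.indicesColumns <- c("species_id", "genus", "scenario", "i_index", "o_index",
                     "dx", "dy", "dz", "card_current", "card_future",
                     "overlap_convention")

#' Write and read the per-species indices table
#'
#' CSV serialization of F-PRS index records with a fixed header order,
#' UTF-8 encoding, '.' decimal separator and deterministic row order
#' (species, then scenario). Every row records the overlap convention that
#' produced its O value.
#'
#' @param records data.frame of rows built by [indicesRecord()] (possibly
#'   `rbind`-ed).
#' @param path CSV path.
#' @return `writeIndicesTable()` invisibly returns `path`;
#'   `readIndicesTable()` returns the data.frame.
#' @export
writeIndicesTable <- function(records, path) {
  if (nrow(records) == 0L) stop("no records to write", call. = FALSE)
  if (!all(.indicesColumns %in% names(records)))
    stop("records are missing columns: ",
         paste(setdiff(.indicesColumns, names(records)), collapse = ", "),
         call. = FALSE)
  records <- records[order(records$species_id, records$scenario),
                     .indicesColumns]
  utf8 <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(records, utf8, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIndicesTable
#' @export
readIndicesTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
}
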