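#' Categorical class rasters
#'
#' The atomic data unit of the package: a rectangular 2-D grid of integer
#' class codes with a declared nodata code and minimal grid metadata
#' (lower-left corner, square cell size, free-text CRS tag, optional year).
#' Indexing is row-major with a top-left origin, matching the on-disk row
#' order of common raster formats.
#'
#' @param data integer matrix of class codes; `NA` cells are stored as the
#'   nodata code.
#' @param nodata integer code marking cells with no valid classification.
#' @param xll,yll map coordinates of the lower-left grid corner.
#' @param cellsize square cell edge length in map units (default 30, a
#'   Landsat-class grid).
#' @param crs free-text coordinate reference tag; compared as a string,
#'   never reprojected.
#' @param year optional integer year label.
#' @return An object of class `class_raster`.
#' @export
class_raster <- function(data, nodata = 0L, xll = 0, yll = 0, cellsize = 30,
                         crs = NA_character_, year = NA_integer_) {
  if (!is.matrix(data)) stop("raster data must be a matrix")
  if (is.double(data)) {
    if (any(data != round(data), na.rm = TRUE)) {
      stop("raster data must hold integer class codes")
    }
    storage.mode(data) <- "integer"
  }
  if (!is.integer(data)) stop("raster data must hold integer class codes")
  nodata <- as.integer(nodata)
  data[is.na(data)] <- nodata
  structure(
    list(data = data, nodata = nodata,
         xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize),
         crs = as.character(crs), year = as.integer(year)),
    class = "class_raster"
  )
}

#' @export
dim.class_raster <- function(x) dim(x$data)

#' @export
print.class_raster <- function(x, ...) {
  d <- dim(x$data)
  vals <- setdiff(unique(as.vector(x$data)), x$nodata)
  cat("<class_raster> ", d[1], " x ", d[2], " cells, cellsize ", x$cellsize,
      ", nodata ", x$nodata, if (!is.na(x$year)) paste0(", year ", x$year),
      "\n  codes: ", paste(sort(vals), collapse = " "), "\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize), c(b$xll, b$yll, b$cellsize))) &&
    (is.na(a$crs) && is.na(b$crs) || identical(a$crs, b$crs))
}

#' Read a class raster from an ESRI ASCII grid
#'
#' Rasters are exchanged as ESRI ASCII grids (`.asc`): a six-line text
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of whitespace-separated cell values,
#' top row first. The format is plain text, GDAL-interoperable
#' (`gdal_translate -of AAIGrid` converts losslessly to and from GeoTIFF for
#' integer data), and carries the nodata tag. Cell values must be integers:
#' a grid with fractional values is rejected as a format error, since class
#' codes are categorical.
#'
#' @param path path to an `.asc` file.
#' @param crs,year optional metadata not carried by the format.
#' @return A `class_raster`.
#' @seealso [write_class_raster()]
#' @export
read_class_raster <- function(path, crs = NA_character_, year = NA_integer_) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L) stop("not an ESRI ASCII grid (truncated header): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2L) stop("malformed header line ", i, " in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("ESRI ASCII grid header incomplete in ", path, " (need ",
         paste(need, collapse = ", "), ")")
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("cell count mismatch in ", path, ": header says ", nr * nc,
         ", file holds ", length(vals))
  }
  if (any(vals != round(vals))) {
    stop("non-integer cell values in ", path,
         ": class rasters must hold integer codes")
  }
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  class_raster(m, nodata = as.integer(hdr$nodata_value),
               xll = hdr$xllcorner, yll = hdr$yllcorner,
               cellsize = hdr$cellsize, crs = crs, year = year)
}

#' Write a class raster as an ESRI ASCII grid
#'
#' @param raster a `class_raster`.
#' @param path output path (conventionally `.asc`).
#' @return The path, invisibly. The write/read round trip is bit-exact for
#'   integer grids.
#' @export
write_class_raster <- function(raster, path) {
  stopifnot(inherits(raster, "class_raster"))
  d <- dim(raster$data)
  hdr <- c(
    paste("ncols", d[2]),
    paste("nrows", d[1]),
    paste("xllcorner", format(raster$xll, scientific = FALSE)),
    paste("yllcorner", format(raster$yll, scientific = FALSE)),
    paste("cellsize", format(raster$cellsize, scientific = FALSE)),
    paste("NODATA_value", raster$nodata)
  )
  body <- apply(raster$data, 1L, paste, collapse = " ")
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write raster to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Multi-year raster stacks
#'
#' A `history_stack` is an ordered sequence of co-registered class rasters,
#' oldest first, supplying the temporal evidence for dominance analysis.
#' The reference configuration uses nine annual layers preceding the year
#' under refinement; other lengths are allowed, but dominance thresholds are
#' absolute year counts, so callers using a different depth must set
#' thresholds to match (see [dominance_thresholds()]).
#'
#' @param layers list of `class_raster` objects, oldest to newest.
#' @return An object of class `history_stack` with fields `layers` and
#'   `n_years`.
#' @export
history_stack <- function(layers) {
  if (length(layers) < 1L) stop("a history stack needs at least one layer")
  if (!all(vapply(layers, inherits, logical(1), "class_raster"))) {
    stop("all stack layers must be class_raster objects")
  }
  ref <- layers[[1L]]
  for (i in seq_along(layers)) {
    li <- layers[[i]]
    if (!identical(dim(li$data), dim(ref$data))) {
      stop("alignment error: layer ", i, " has shape ",
           paste(dim(li$data), collapse = "x"), ", expected ",
           paste(dim(ref$data), collapse = "x"))
    }
    if (!same_grid(li, ref)) {
      stop("alignment error: layer ", i, " grid metadata differs from layer 1")
    }
    if (li$nodata != ref$nodata) {
      stop("alignment error: layer ", i, " nodata code ", li$nodata,
           " differs from layer 1 (", ref$nodata, ")")
    }
  }
  structure(list(layers = layers, n_years = length(layers)),
            class = "history_stack")
}

#' Assemble a history stack from raster files
#'
#' Reads an ordered set of ESRI ASCII grids (oldest first) and verifies
#' co-registration: identical shape, grid metadata and nodata code. A
#' mismatch raises an alignment error naming the offending layer.
#'
#' @param paths character vector of file paths, oldest first.
#' @param crs optional CRS tag applied to every layer.
#' @return A `history_stack`.
#' @export
assemble_stack <- function(paths, crs = NA_character_) {
  if (length(paths) < 1L) stop("assemble_stack needs at least one path")
  history_stack(lapply(paths, read_class_raster, crs = crs))
}

#' @export
print.history_stack <- function(x, ...) {
  d <- dim(x$layers[[1L]]$data)
  cat("<history_stack> ", x$n_years, " layers of ", d[1], " x ", d[2],
      " cells\n", sep = "")
  invisible(x)
}

#' Nearest-neighbor resampling
#'
#' Resamples a categorical raster to a new shape by nearest cell-center
#' assignment, the standard method for discrete data: every output cell
#' copies the value of the input cell whose center is nearest, so no new
#' code is ever created. Cell size is rescaled so the raster keeps its
#' spatial extent.
#'
#' @param raster a `class_raster`.
#' @param target_shape integer `(rows, cols)`, both positive.
#' @return A `class_raster` of the target shape.
#' @export
resample_nearest <- function(raster, target_shape) {
  stopifnot(inherits(raster, "class_raster"))
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 2L || any(is.na(target_shape)) ||
      any(target_shape < 1L)) {
    stop("target_shape must be two positive integers (rows, cols)")
  }
  d <- dim(raster$data)
  # nearest input center to output center (i - 0.5)/t, in exact integer
  # arithmetic: ceiling((2i-1) d / 2t), ties resolved to the lower index
  nn_index <- function(t, n) {
    idx <- ((2L * seq_len(t) - 1L) * n + 2L * t - 1L) %/% (2L * t)
    pmin(pmax(idx, 1L), n)
  }
  ri <- nn_index(target_shape[1], d[1])
  ci <- nn_index(target_shape[2], d[2])
  out <- raster$data[ri, ci, drop = FALSE]
  class_raster(out, nodata = raster$nodata, xll = raster$xll, yll = raster$yll,
               cellsize = raster$cellsize * d[1] / target_shape[1],
               crs = raster$crs, year = raster$year)
}

#' Binary reference masks
#'
#' A 0/1 mask co-registered with a class raster, typically a rasterized
#' road network used by the road post-processing step. Rasterization itself
#' is outside this package; masks arrive pre-rasterized and are resampled by
#' nearest neighbor if their shape differs from the target raster.
#'
#' @param data matrix of 0/1 (logical accepted).
#' @param xll,yll,cellsize grid metadata, as for [class_raster()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, xll = 0, yll = 0, cellsize = 30) {
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  }
  if (!is.matrix(data) || !all(data %in% c(0L, 1L))) {
    stop("a binary mask must be a matrix of 0/1")
  }
  storage.mode(data) <- "integer"
  structure(list(data = data, xll = as.numeric(xll), yll = as.numeric(yll),
                 cellsize = as.numeric(cellsize)),
            class = "binary_mask")
}

#' @export
dim.binary_mask <- function(x) dim(x$data)
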