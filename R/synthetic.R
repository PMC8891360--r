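#' Synthetic landscape specification
#'
#' Describes a rectangular landscape of rotating crop fields with embedded
#' constant features (water, forest), road lines, and county-style zones,
#' simulated over several years so refinement accuracy can be measured
#' against a known truth. Crop fields are square blocks on a checkerboard
#' of rotation phases: a field's class cycles annually through
#' `crop_codes`, adjacent fields one step out of phase. Constant patches
#' and roads are identical in every year. The last simulated year is the
#' "current" raster; the preceding years form the history stack.
#'
#' The default scene is a 120x120 grid of 12-pixel corn/soybean fields with
#' two water ponds, one forest patch, one horizontal and one vertical road
#' line, and a 3x3 grid of zones — small enough for seconds-scale runs, rich
#' enough to exercise every branch of the decision tree.
#'
#' @param shape `(rows, cols)` of the grid.
#' @param field_size field block edge in cells (>= 3, so field interiors
#'   contain uniform pixels).
#' @param crop_codes ordered rotation cycle (default corn 1, soybeans 5).
#' @param constant_patches list of `list(code =, rows = c(r1, r2),
#'   cols = c(c1, c2))` rectangles; they must fit the grid and must not
#'   overlap one another.
#' @param road_rows,road_cols grid lines (row / column indices) drawn as
#'   `road_code` in every year, on top of fields and patches.
#' @param road_code class code of road lines (default 121,
#'   Developed/Open Space).
#' @param n_years total simulated years (default 10 = 9 history + current).
#' @param zone_grid `(rows, cols)` of the rectangular zone ("county")
#'   partition.
#' @param nodata nodata code of all generated rasters.
#' @param cellsize cell edge in map units (default 30).
#' @param seed integer seed recorded in the spec (scene construction is
#'   deterministic; the seed feeds noise injection).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape = c(120L, 120L),
                       field_size = 12L,
                       crop_codes = c(1L, 5L),
                       constant_patches = list(
                         list(code = 111L, rows = c(16L, 27L), cols = c(16L, 27L)),
                         list(code = 111L, rows = c(76L, 95L), cols = c(36L, 51L)),
                         list(code = 141L, rows = c(56L, 75L), cols = c(86L, 109L))
                       ),
                       road_rows = 45L,
                       road_cols = 66L,
                       road_code = 121L,
                       n_years = 10L,
                       zone_grid = c(3L, 3L),
                       nodata = 0L,
                       cellsize = 30,
                       seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 3L)) {
    stop("shape must be two integers, each at least 3")
  }
  field_size <- as.integer(field_size)
  if (field_size < 3L) stop("field_size must be at least 3")
  crop_codes <- as.integer(crop_codes)
  if (length(crop_codes) < 1L) stop("need at least one crop code")
  n_years <- as.integer(n_years)
  if (n_years < 2L) stop("n_years must be at least 2 (history + current)")

  occupied <- matrix(FALSE, shape[1], shape[2])
  for (p in constant_patches) {
    p$rows <- as.integer(p$rows); p$cols <- as.integer(p$cols)
    if (p$rows[1] < 1L || p$rows[2] > shape[1] || p$rows[1] > p$rows[2] ||
        p$cols[1] < 1L || p$cols[2] > shape[2] || p$cols[1] > p$cols[2]) {
      stop("constant patch (code ", p$code, ") does not fit the ",
           shape[1], "x", shape[2], " grid")
    }
    cells <- occupied[p$rows[1]:p$rows[2], p$cols[1]:p$cols[2]]
    if (any(cells)) stop("constant patches overlap")
    occupied[p$rows[1]:p$rows[2], p$cols[1]:p$cols[2]] <- TRUE
  }
  structure(list(shape = shape, field_size = field_size,
                 crop_codes = crop_codes,
                 constant_patches = constant_patches,
                 road_rows = as.integer(road_rows),
                 road_cols = as.integer(road_cols),
                 road_code = as.integer(road_code),
                 n_years = n_years, zone_grid = as.integer(zone_grid),
                 nodata = as.integer(nodata), cellsize = cellsize,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

scene_truth_year <- function(spec, t) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  k <- length(spec$crop_codes)
  fi <- ceiling(seq_len(nr) / spec$field_size)
  fj <- ceiling(seq_len(nc) / spec$field_size)
  phase <- outer(fi, fj, "+") %% k
  m <- matrix(spec$crop_codes[((phase + t) %% k) + 1L], nr, nc)
  for (p in spec$constant_patches) {
    m[p$rows[1]:p$rows[2], p$cols[1]:p$cols[2]] <- p$code
  }
  m[spec$road_rows, ] <- spec$road_code
  m[, spec$road_cols] <- spec$road_code
  m
}

#' Generate a synthetic multi-year landscape
#'
#' Builds the truth rasters for every year of a [scene_spec()]: a history
#' stack of `n_years - 1` layers (oldest first), the current-year truth
#' raster, the binary road mask matching the scene's road lines, and a zone
#' raster partitioning the grid into rectangular counties (ids numbered
#' row-major from 1). Scene construction is fully deterministic: the same
#' spec always yields identical output.
#'
#' @param spec a `scene_spec`.
#' @return A list with elements `history` (`history_stack`), `current`
#'   (`class_raster`), `road_mask` (`binary_mask`), `zones`
#'   (`class_raster` of zone ids), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  mk <- function(t) {
    class_raster(scene_truth_year(spec, t), nodata = spec$nodata,
                 cellsize = spec$cellsize, year = t)
  }
  layers <- lapply(seq_len(spec$n_years - 1L), mk)
  current <- mk(spec$n_years)

  mask <- matrix(0L, spec$shape[1], spec$shape[2])
  mask[spec$road_rows, ] <- 1L
  mask[, spec$road_cols] <- 1L

  zr <- ceiling(seq_len(spec$shape[1]) / (spec$shape[1] / spec$zone_grid[1]))
  zc <- ceiling(seq_len(spec$shape[2]) / (spec$shape[2] / spec$zone_grid[2]))
  zones <- outer(pmin(zr, spec$zone_grid[1]) - 1L,
                 pmin(zc, spec$zone_grid[2]), function(a, b) {
                   as.integer(a * spec$zone_grid[2] + b)
                 })

  list(history = history_stack(layers),
       current = current,
       road_mask = binary_mask(mask, cellsize = spec$cellsize),
       zones = class_raster(zones, nodata = -1L, cellsize = spec$cellsize),
       spec = spec)
}

#' Noise specification
#'
#' Controls the misclassification noise injected into synthetic scenes,
#' emulating the error types seen in operational land-cover products:
#' isolated salt-and-pepper flips, field-edge jitter, and independent
#' per-year history errors.
#'
#' @param isolate_rate fraction of valid interior pixels flipped to a
#'   random wrong class (current-year raster).
#' @param boundary_jitter_rate fraction of field-edge pixels (pixels with a
#'   4-neighbor of a different class) set to a random adjacent class.
#' @param history_noise_rate per-year flip rate applied independently to
#'   each history layer.
#' @param seed RNG seed making injection reproducible.
#' @return An object of class `noise_spec`. All rates must lie in
#'   `[0, 0.5)`.
#' @export
noise_spec <- function(isolate_rate = 0.01, boundary_jitter_rate = 0,
                       history_noise_rate = 0.05, seed = 1L) {
  rates <- c(isolate_rate, boundary_jitter_rate, history_noise_rate)
  if (any(rates < 0) || any(rates >= 0.5)) {
    stop("noise rates must lie in [0, 0.5)")
  }
  structure(list(isolate_rate = isolate_rate,
                 boundary_jitter_rate = boundary_jitter_rate,
                 history_noise_rate = history_noise_rate,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# Flip each selected cell to a uniform draw from `codes` minus its own value.
flip_cells <- function(data, idx, codes) {
  if (length(idx) == 0L) return(data)
  for (i in idx) {
    pool <- codes[codes != data[i]]
    data[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
  }
  data
}

#' Inject misclassification noise
#'
#' Adds reproducible noise to a truth raster or a whole history stack.
#' Wrong codes are drawn uniformly from the raster's own code set excluding
#' the true code, so every injected cell differs from truth. For a
#' `class_raster`, `isolate_rate` flips are applied to valid interior
#' pixels and `boundary_jitter_rate` flips to field-edge pixels (the latter
#' take the class of a random differing 4-neighbor). For a
#' `history_stack`, `history_noise_rate` flips are applied to each layer
#' independently.
#'
#' @param x a `class_raster` or `history_stack` of truth values.
#' @param noise a [noise_spec()].
#' @param codes optional code pool to draw wrong classes from; defaults to
#'   the distinct non-nodata codes present in `x`.
#' @return For a raster: list(`raster`, `injected` logical matrix). For a
#'   stack: list(`stack`, `injected` list of logical matrices, one per
#'   layer).
#' @export
inject_noise <- function(x, noise, codes = NULL) UseMethod("inject_noise")

#' @export
inject_noise.class_raster <- function(x, noise, codes = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  set.seed(noise$seed)
  data <- x$data
  nr <- nrow(data); nc <- ncol(data)
  if (is.null(codes)) codes <- setdiff(sort(unique(as.vector(data))), x$nodata)

  interior <- matrix(FALSE, nr, nc)
  if (nr > 2L && nc > 2L) interior[2:(nr - 1L), 2:(nc - 1L)] <- TRUE
  interior <- interior & data != x$nodata

  pick <- which(interior & matrix(stats::runif(nr * nc) < noise$isolate_rate,
                                  nr, nc))
  data <- flip_cells(data, pick, codes)

  if (noise$boundary_jitter_rate > 0) {
    truth <- x$data
    differs <- matrix(FALSE, nr, nc)
    nb <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    shifted <- lapply(nb, function(d) shift_matrix(truth, d[1], d[2]))
    for (s in shifted) differs <- differs | (!is.na(s) & s != truth)
    edge_pick <- which(interior & differs &
                         matrix(stats::runif(nr * nc) < noise$boundary_jitter_rate,
                                nr, nc))
    for (i in edge_pick) {
      rc <- arrayInd(i, dim(truth))
      vals <- vapply(nb, function(d) truth[rc[1] + d[1], rc[2] + d[2]],
                     integer(1))
      vals <- vals[vals != truth[i] & vals != x$nodata]
      if (length(vals) > 0L) {
        data[i] <- if (length(vals) == 1L) vals else sample(vals, 1L)
      }
    }
  }

  noisy <- class_raster(data, nodata = x$nodata, xll = x$xll, yll = x$yll,
                        cellsize = x$cellsize, crs = x$crs, year = x$year)
  list(raster = noisy, injected = data != x$data)
}

#' @export
inject_noise.history_stack <- function(x, noise, codes = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  set.seed(noise$seed)
  if (is.null(codes)) {
    codes <- setdiff(sort(unique(unlist(lapply(x$layers, function(l)
      unique(as.vector(l$data)))))), x$layers[[1L]]$nodata)
  }
  injected <- vector("list", x$n_years)
  layers <- x$layers
  for (i in seq_len(x$n_years)) {
    l <- layers[[i]]
    data <- l$data
    valid <- data != l$nodata
    pick <- which(valid & matrix(stats::runif(length(data)) <
                                   noise$history_noise_rate,
                                 nrow(data), ncol(data)))
    data <- flip_cells(data, pick, codes)
    injected[[i]] <- data != l$data
    layers[[i]] <- class_raster(data, nodata = l$nodata, xll = l$xll,
                                yll = l$yll, cellsize = l$cellsize,
                                crs = l$crs, year = l$year)
  }
  list(stack = history_stack(layers), injected = injected)
}

#' Which injected pixels the filter can correct in principle
#'
#' An injected pixel is recoverable by the spatial-temporal branch when, in
#' the noisy raster, it is an isolate or boundary pixel whose neighbor
#' majority equals its true class, and that true class is also its
#' historical dominant. These are exactly the pixels the decision tree
#' promises to restore.
#'
#' @param truth truth `class_raster`.
#' @param noisy noisy `class_raster`.
#' @param injected logical matrix of injected cells.
#' @param stack `history_stack` used for refinement.
#' @param registry a `class_registry`.
#' @param thresholds a `dominance_thresholds`.
#' @return Logical matrix marking recoverable injected pixels.
#' @export
recoverable_mask <- function(truth, noisy, injected, stack,
                             registry = default_registry(),
                             thresholds = dominance_thresholds()) {
  prof <- classify_neighborhood(noisy)
  dom <- dominance_raster(stack, registry, thresholds)
  cand <- prof$majority_class
  ok <- injected &
    matrix(prof$category %in% c("isolate", "boundary"), nrow(injected)) &
    !is.na(cand) & cand == truth$data &
    !is.na(dom$dominant) & dom$dominant == truth$data
  ok
}

#' Score refinement against known truth
#'
#' Compares a refined raster with the truth it should recover: how many
#' injected errors were corrected, how many remain, and how many clean
#' pixels were damaged. A per-category breakdown (taxonomy of the noisy
#' raster) shows where corrections and failures concentrate.
#'
#' @param truth,noisy,refined co-registered `class_raster` objects.
#' @param injected logical matrix of injected cells (from
#'   [inject_noise()]).
#' @return An object of class `recovery_report`: counts `injected`,
#'   `corrected`, `uncorrected`, `damaged`, the `recovery_rate`
#'   (corrected / injected), and `by_category` (data.frame of injected /
#'   corrected counts per neighborhood category).
#' @export
score_recovery <- function(truth, noisy, refined, injected) {
  for (r in list(truth, noisy, refined)) stopifnot(inherits(r, "class_raster"))
  if (!identical(dim(truth$data), dim(noisy$data)) ||
      !identical(dim(truth$data), dim(refined$data)) ||
      !identical(dim(truth$data), dim(injected))) {
    stop("alignment error: inputs must share one shape")
  }
  corrected <- injected & refined$data == truth$data
  uncorrected <- injected & refined$data != truth$data
  damaged <- !injected & noisy$data == truth$data & refined$data != truth$data

  prof <- classify_neighborhood(noisy)
  cats <- c("uniform", "isolate", "boundary", "mix", "edge", "nodata")
  by_cat <- data.frame(
    category = cats,
    injected = vapply(cats, function(ct) sum(injected[prof$category == ct]),
                      integer(1)),
    corrected = vapply(cats, function(ct) sum(corrected[prof$category == ct]),
                       integer(1)),
    row.names = NULL
  )
  n_inj <- sum(injected)
  structure(list(
    injected = n_inj,
    corrected = sum(corrected),
    uncorrected = sum(uncorrected),
    damaged = sum(damaged),
    recovery_rate = if (n_inj > 0L) sum(corrected) / n_inj else NA_real_,
    by_category = by_cat
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> injected ", x$injected, ": corrected ",
      x$corrected, ", uncorrected ", x$uncorrected, ", clean damaged ",
      x$damaged, "\n", sep = "")
  if (!is.na(x$recovery_rate)) {
    cat(sprintf("  recovery rate %.1f%%\n", 100 * x$recovery_rate))
  }
  print(x$by_category)
  invisible(x)
}
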