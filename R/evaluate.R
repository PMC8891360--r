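#' Refinement confusion statistics from counts
#'
#' Builds the three-cell confusion summary used to validate
#' post-classification refinement. The evaluated pixels are those touched
#' by or relevant to refinement; they split into: originally correct pixels
#' that refinement broke (`cdl_correct_rcdl_incorrect`), originally wrong
#' pixels that refinement fixed (`cdl_incorrect_rcdl_correct`), and
#' originally wrong pixels still wrong afterwards
#' (`cdl_incorrect_rcdl_incorrect` — the "true negatives" of this design,
#' typically mix pixels the filter cannot resolve). Correct pixels left
#' unchanged are excluded by design: the goal is the accuracy of the
#' refined pixels, not of the whole map.
#'
#' Two ratios summarize the table: `overall_accuracy` = fixed / all three
#' cells, and `accuracy_excluding_true_negatives` = fixed / (fixed +
#' broken), which ignores pixels that were wrong both before and after.
#'
#' @param cdl_correct_rcdl_incorrect,cdl_incorrect_rcdl_correct,cdl_incorrect_rcdl_incorrect
#'   non-negative integer counts.
#' @return An object of class `refinement_confusion` with the three counts,
#'   `n_evaluated`, and both accuracy fractions.
#' @examples
#' # the published validation counts of the reference implementation
#' rc <- refinement_confusion_counts(35, 394, 71)
#' rc$overall_accuracy                     # 0.788
#' rc$accuracy_excluding_true_negatives    # 0.918...
#' @export
refinement_confusion_counts <- function(cdl_correct_rcdl_incorrect,
                                        cdl_incorrect_rcdl_correct,
                                        cdl_incorrect_rcdl_incorrect) {
  cnts <- c(cdl_correct_rcdl_incorrect, cdl_incorrect_rcdl_correct,
            cdl_incorrect_rcdl_incorrect)
  if (any(is.na(cnts)) || any(cnts < 0)) {
    stop("confusion counts must be non-negative")
  }
  broken <- as.integer(cdl_correct_rcdl_incorrect)
  fixed <- as.integer(cdl_incorrect_rcdl_correct)
  still_wrong <- as.integer(cdl_incorrect_rcdl_incorrect)
  total <- broken + fixed + still_wrong
  structure(list(
    cdl_correct_rcdl_incorrect = broken,
    cdl_incorrect_rcdl_correct = fixed,
    cdl_incorrect_rcdl_incorrect = still_wrong,
    n_evaluated = total,
    overall_accuracy = if (total > 0L) fixed / total else NA_real_,
    accuracy_excluding_true_negatives =
      if (fixed + broken > 0L) fixed / (fixed + broken) else NA_real_
  ), class = "refinement_confusion")
}

#' Refinement confusion matrix from rasters
#'
#' Computes [refinement_confusion_counts()] from the original map, the
#' refined map and a truth raster. The evaluated set is every pixel the
#' refinement changed plus every pixel the original map got wrong; nodata
#' pixels (in any input) are excluded.
#'
#' @param cdl original `class_raster`.
#' @param rcdl refined `class_raster`.
#' @param truth reference `class_raster`.
#' @return A `refinement_confusion`.
#' @export
refinement_confusion <- function(cdl, rcdl, truth) {
  for (r in list(cdl, rcdl, truth)) stopifnot(inherits(r, "class_raster"))
  if (!identical(dim(cdl$data), dim(rcdl$data)) ||
      !identical(dim(cdl$data), dim(truth$data))) {
    stop("alignment error: rasters must share one shape")
  }
  valid <- cdl$data != cdl$nodata & rcdl$data != rcdl$nodata &
    truth$data != truth$nodata
  evaluated <- valid & (cdl$data != rcdl$data | cdl$data != truth$data)
  cdl_ok <- cdl$data == truth$data
  rcdl_ok <- rcdl$data == truth$data
  refinement_confusion_counts(
    sum(evaluated & cdl_ok & !rcdl_ok),
    sum(evaluated & !cdl_ok & rcdl_ok),
    sum(evaluated & !cdl_ok & !rcdl_ok)
  )
}

#' @export
print.refinement_confusion <- function(x, ...) {
  cat("<refinement_confusion> ", x$n_evaluated, " evaluated pixels\n",
      "  originally wrong, fixed:      ", x$cdl_incorrect_rcdl_correct, "\n",
      "  originally wrong, still wrong:", x$cdl_incorrect_rcdl_incorrect, "\n",
      "  originally right, broken:     ", x$cdl_correct_rcdl_incorrect, "\n",
      sprintf("  overall accuracy %.1f%%; excluding true negatives %.1f%%\n",
              100 * x$overall_accuracy,
              100 * x$accuracy_excluding_true_negatives), sep = "")
  invisible(x)
}

#' County-level acreage table
#'
#' Tabulates per-zone, per-class pixel counts and converts them to acres
#' (1 acre = 4046.8564224 square meters). The default cell area of 900 m2
#' encodes a 30 m grid. The table is sparse: zone/class combinations with
#' no pixels are absent.
#'
#' @param raster `class_raster` of class codes.
#' @param zones co-registered `class_raster` of zone (county) ids.
#' @param cell_area_m2 area of one cell in square meters (default 900).
#' @param classes optional integer codes to restrict the table to.
#' @return A data.frame with columns `zone`, `code`, `pixels`, `acres`.
#' @export
county_acreage <- function(raster, zones, cell_area_m2 = 900,
                           classes = NULL) {
  stopifnot(inherits(raster, "class_raster"), inherits(zones, "class_raster"))
  if (!identical(dim(raster$data), dim(zones$data))) {
    stop("alignment error: zone raster shape differs from class raster")
  }
  if (!is.numeric(cell_area_m2) || cell_area_m2 <= 0) {
    stop("cell_area_m2 must be positive")
  }
  keep <- raster$data != raster$nodata & zones$data != zones$nodata
  if (!is.null(classes)) keep <- keep & raster$data %in% as.integer(classes)
  if (!any(keep)) {
    return(data.frame(zone = integer(0), code = integer(0),
                      pixels = integer(0), acres = numeric(0)))
  }
  tab <- as.data.frame(table(zone = zones$data[keep], code = raster$data[keep]),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  out <- data.frame(zone = as.integer(tab$zone), code = as.integer(tab$code),
                    pixels = as.integer(tab$Freq))
  out <- out[order(out$zone, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out$acres <- out$pixels * cell_area_m2 / 4046.8564224
  out
}

#' Coefficient of determination between acreage vectors
#'
#' The squared Pearson correlation between two paired acreage series, the
#' scatter-agreement statistic used for county-level comparison. Setting
#' `about_identity = TRUE` instead measures agreement about the 1:1 line
#' (`1 - SS_res/SS_tot` with predictions `y = x`), which penalizes bias.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param about_identity use the 1:1-line variant.
#' @return A fraction; in `[0, 1]` for the Pearson form.
#' @export
r_squared <- function(x, y, about_identity = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least two paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined statistic: constant input vector")
  }
  if (about_identity) {
    1 - sum((y - x)^2) / sum((y - mean(y))^2)
  } else {
    stats::cor(x, y)^2
  }
}

#' Mean percentage difference between acreage estimates
#'
#' The signed mean over zones of `100 * (est - ref) / ref`: positive when
#' the estimate runs higher than the reference, negative when lower.
#' Signed differences can cancel across zones; set `absolute = TRUE` for
#' the mean absolute percentage difference.
#'
#' @param est,ref numeric vectors of equal length; `ref` entries must be
#'   strictly positive.
#' @param absolute average `|diff|` instead of signed diff.
#' @return A percentage (scalar).
#' @export
mean_pct_diff <- function(est, ref, absolute = FALSE) {
  if (length(est) != length(ref)) stop("est and ref must have equal length")
  if (any(ref <= 0)) stop("reference entries must be strictly positive")
  d <- 100 * (est - ref) / ref
  if (absolute) d <- abs(d)
  mean(d)
}

#' Published pixel-level validation counts
#'
#' Loads the shipped copy of the published 500-sample validation confusion
#' matrix of the reference refinement of the 2019 Cropland Data Layer
#' (visual validation against high-resolution imagery): 394 originally
#' wrong pixels fixed, 71 wrong before and after, 35 correct pixels broken.
#'
#' @return A `refinement_confusion` built from the published counts.
#' @export
cdl_validation_counts <- function() {
  path <- system.file("extdata", "validation_confusion.csv",
                      package = "cdlrefine", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  get <- function(key) {
    v <- tab$count[tab$cell == key]
    if (length(v) != 1L) stop("validation table lacks cell '", key, "'")
    v
  }
  refinement_confusion_counts(
    cdl_correct_rcdl_incorrect = get("cdl_correct_rcdl_incorrect"),
    cdl_incorrect_rcdl_correct = get("cdl_incorrect_rcdl_correct"),
    cdl_incorrect_rcdl_incorrect = get("cdl_incorrect_rcdl_incorrect")
  )
}
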