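# Offsets of the 8-connected ring, row/col deltas.
RING8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Shift a matrix by (dr, dc), filling vacated cells with NA.
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_integer_, nr, nc)
  sr <- max(1L, 1L + dr):min(nr, nr + dr)
  sc <- max(1L, 1L + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

#' Pixel taxonomy of the 8-connected neighborhood
#'
#' Categorizes every pixel of a class raster against its eight connected
#' neighbors. Interior pixels whose full 3x3 window is valid fall into
#' exactly one of four categories:
#'
#' * `"uniform"` — the pixel and all eight neighbors share one class; such
#'   pixels need no further investigation and are never refined.
#' * `"isolate"` — all eight neighbors share one class different from the
#'   pixel (the classic salt-and-pepper error candidate).
#' * `"boundary"` — the most frequent neighbor class occupies five to seven
#'   of the eight ring positions.
#' * `"mix"` — no neighbor class reaches five (typical field-edge mixtures,
#'   left untouched by the refinement filter).
#'
#' Pixels on the raster border (incomplete ring) are tagged `"edge"`, and
#' pixels whose 3x3 window contains any nodata cell are tagged `"nodata"`;
#' both are excluded from refinement. The "five to seven same neighbors"
#' rule is applied as a plain count over the ring, not as ring-contiguity
#' of those neighbors (see the methods vignette for the rationale).
#'
#' The neighbor majority is computed over the eight ring cells only — the
#' center never votes. On a tie for most frequent, the majority class is
#' `NA` while the count still reports the tied maximum; a tie can never
#' reach count 5, so refinement is unaffected.
#'
#' @param raster a `class_raster`, at least 3x3.
#' @return An object of class `neighborhood_profile`: a list of three
#'   matrices shaped like the raster — `category` (character, one of
#'   uniform/isolate/boundary/mix/edge/nodata), `majority_class` (integer,
#'   `NA` when tied or undefined), `majority_count` (integer 0-8, `NA` for
#'   edge/nodata pixels).
#' @examples
#' m <- matrix(1L, 5, 5); m[3, 3] <- 7L
#' p <- classify_neighborhood(class_raster(m, nodata = -1))
#' p$category[3, 3]        # "isolate"
#' p$majority_class[3, 3]  # 1
#' @export
classify_neighborhood <- function(raster) {
  stopifnot(inherits(raster, "class_raster"))
  data <- raster$data
  nr <- nrow(data); nc <- ncol(data)
  if (nr < 3L || nc < 3L) {
    stop("neighborhood analysis needs a raster of at least 3x3 cells")
  }
  nodata <- raster$nodata

  nbrs <- lapply(seq_len(8L), function(k) {
    shift_matrix(data, RING8[k, "dr"], RING8[k, "dc"])
  })

  edge <- matrix(FALSE, nr, nc)
  edge[c(1L, nr), ] <- TRUE
  edge[, c(1L, nc)] <- TRUE

  has_nodata <- data == nodata
  for (n in nbrs) has_nodata <- has_nodata | (!is.na(n) & n == nodata)
  has_nodata <- !edge & has_nodata

  interior <- !edge & !has_nodata

  best_count <- matrix(0L, nr, nc)
  best_class <- matrix(NA_integer_, nr, nc)
  tied <- matrix(FALSE, nr, nc)
  for (cl in setdiff(sort(unique(as.vector(data))), nodata)) {
    cnt <- matrix(0L, nr, nc)
    for (n in nbrs) cnt <- cnt + (!is.na(n) & n == cl)
    tied <- ifelse(cnt == best_count & cnt > 0L, TRUE, tied)
    better <- cnt > best_count
    tied[better] <- FALSE
    best_class[better] <- cl
    best_count[better] <- cnt[better]
  }
  best_class[tied] <- NA_integer_

  category <- matrix("mix", nr, nc)
  category[best_count >= 5L & best_count <= 7L] <- "boundary"
  full <- best_count == 8L
  category[full & data == best_class] <- "uniform"
  category[full & data != best_class] <- "isolate"
  category[has_nodata] <- "nodata"
  category[edge] <- "edge"

  best_class[!interior] <- NA_integer_
  best_count[!interior] <- NA_integer_

  structure(list(category = category, majority_class = best_class,
                 majority_count = best_count),
            class = "neighborhood_profile")
}

#' @export
print.neighborhood_profile <- function(x, ...) {
  tab <- table(factor(x$category, levels = c("uniform", "isolate", "boundary",
                                             "mix", "edge", "nodata")))
  cat("<neighborhood_profile> ", nrow(x$category), " x ", ncol(x$category),
      " pixels\n", sep = "")
  print(tab)
  invisible(x)
}

#' Majority class of a single 3x3 window
#'
#' Scalar counterpart of [classify_neighborhood()] for one window: returns
#' the most frequent class among the eight ring cells and its count. The
#' center cell (position [2,2]) is ignored. A tie for most frequent yields
#' `NA` for the class with the tied maximum as count. If any ring cell
#' carries the nodata code the result is flagged so the caller can exclude
#' the pixel.
#'
#' @param window a 3x3 integer matrix.
#' @param nodata nodata code (default `NA`, meaning only `NA` cells are
#'   treated as missing).
#' @return A list with `class` (integer or `NA`), `count` (integer), and
#'   `nodata` (TRUE if the ring contained a missing cell, in which case
#'   class and count are `NA`).
#' @export
majority_neighbor <- function(window, nodata = NA_integer_) {
  if (!is.matrix(window) || !identical(dim(window), c(3L, 3L))) {
    stop("window must be a 3x3 matrix")
  }
  ring <- as.vector(window)[-5L]
  bad <- is.na(ring)
  if (!is.na(nodata)) bad <- bad | ring == nodata
  if (any(bad)) {
    return(list(class = NA_integer_, count = NA_integer_, nodata = TRUE))
  }
  tab <- table(ring)
  top <- max(tab)
  winners <- as.integer(names(tab)[tab == top])
  list(class = if (length(winners) == 1L) winners else NA_integer_,
       count = as.integer(top), nodata = FALSE)
}

#' Export a neighborhood profile as a diagnostic raster
#'
#' Encodes the category matrix as integer codes for writing with
#' [write_class_raster()]: uniform 1, isolate 2, boundary 3, mix 4, edge 5,
#' nodata 6.
#'
#' @param profile a `neighborhood_profile`.
#' @param template `class_raster` supplying grid metadata.
#' @return A `class_raster` of category codes (nodata 0).
#' @export
category_raster <- function(profile, template) {
  stopifnot(inherits(profile, "neighborhood_profile"),
            inherits(template, "class_raster"))
  codes <- c(uniform = 1L, isolate = 2L, boundary = 3L, mix = 4L,
             edge = 5L, nodata = 6L)
  m <- matrix(codes[profile$category], nrow(profile$category),
              ncol(profile$category))
  class_raster(m, nodata = 0L, xll = template$xll, yll = template$yll,
               cellsize = template$cellsize, crs = template$crs)
}
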