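`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force references. These deliberately use naive per-pixel
# double loops and table() counting, sharing no code path with the package's
# vectorized implementations.

oracle_window_majority <- function(window, center_excluded = TRUE) {
  ring <- as.vector(window)[-5L]
  tab <- table(ring)
  top <- max(tab)
  winners <- as.integer(names(tab)[tab == top])
  list(class = if (length(winners) == 1L) winners else NA_integer_,
       count = as.integer(top))
}

oracle_classify <- function(raster) {
  data <- raster$data
  nodata <- raster$nodata
  nr <- nrow(data); nc <- ncol(data)
  category <- matrix(NA_character_, nr, nc)
  mclass <- matrix(NA_integer_, nr, nc)
  mcount <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (r == 1L || r == nr || c == 1L || c == nc) {
        category[r, c] <- "edge"
        next
      }
      w <- data[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
      if (any(w == nodata)) {
        category[r, c] <- "nodata"
        next
      }
      maj <- oracle_window_majority(w)
      mclass[r, c] <- maj$class
      mcount[r, c] <- maj$count
      center <- data[r, c]
      category[r, c] <-
        if (maj$count == 8L && !is.na(maj$class) && maj$class == center) {
          "uniform"
        } else if (maj$count == 8L) {
          "isolate"
        } else if (maj$count >= 5L) {
          "boundary"
        } else {
          "mix"
        }
    }
  }
  list(category = category, majority_class = mclass, majority_count = mcount)
}

oracle_dominant <- function(history, registry, thresholds) {
  history <- history[history != registry$nodata_code]
  if (length(history) == 0L) return(list(class = NA_integer_, count = NA_integer_))
  tab <- table(history)
  for (i in seq_along(tab)) {
    code <- as.integer(names(tab)[i])
    need <- if (is_constant_code(registry, code)) thresholds$constant_min
            else thresholds$regular_min
    if (tab[i] >= need) return(list(class = code, count = as.integer(tab[i])))
  }
  list(class = NA_integer_, count = NA_integer_)
}

# Naive single refinement pass, working pixel by pixel directly from the
# history stack (dominance recomputed per pixel with oracle_dominant).
oracle_refine_once <- function(raster, stack, registry, config,
                               road_mask = NULL) {
  data <- raster$data
  nr <- nrow(data); nc <- ncol(data)
  prof <- oracle_classify(raster)
  road_codes <- config$road_codes
  if (is.null(road_codes)) road_codes <- developed_codes(registry)
  new <- data
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!(prof$category[r, c] %in% c("isolate", "boundary", "mix"))) next
      hist <- vapply(stack$layers, function(l) l$data[r, c], integer(1))
      dom <- oracle_dominant(hist, registry, config$thresholds)
      cur <- data[r, c]
      is_cand <- prof$category[r, c] %in% c("isolate", "boundary")
      refined <- FALSE
      if (is_cand && !is.na(dom$class) && cur != dom$class &&
          !is.na(prof$majority_class[r, c]) &&
          prof$majority_class[r, c] == dom$class) {
        new[r, c] <- dom$class
        refined <- TRUE
      }
      kept <- is_cand && !is.na(dom$class) && cur == dom$class
      if (!refined && !kept && is_cand && !is.null(road_mask) &&
          road_mask$data[r, c] == 1L) {
        road_hist <- hist[hist %in% road_codes]
        if (length(road_hist) >= config$road_history_min) {
          tab <- table(road_hist)
          top <- as.integer(names(tab)[tab == max(tab)])
          new[r, c] <- min(top)
        }
      }
    }
  }
  class_raster(new, nodata = raster$nodata, xll = raster$xll, yll = raster$yll,
               cellsize = raster$cellsize)
}

# Nearest-center resampling by explicit per-cell distance search. Distances
# are compared in exact integer arithmetic (scaled by 2 * n * t) so that
# exact ties resolve to the lower index, with no float noise.
oracle_resample <- function(raster, target_shape) {
  d <- dim(raster$data)
  out <- matrix(NA_integer_, target_shape[1], target_shape[2])
  nearest <- function(i, t, n) {
    which.min(abs((2L * seq_len(n) - 1L) * t - (2L * i - 1L) * n))
  }
  for (i in seq_len(target_shape[1])) {
    for (j in seq_len(target_shape[2])) {
      out[i, j] <- raster$data[nearest(i, target_shape[1], d[1]),
                               nearest(j, target_shape[2], d[2])]
    }
  }
  out
}

rand_raster <- function(nr = 12L, nc = 12L, codes = 1:4, nodata = 0L,
                        nodata_frac = 0) {
  m <- matrix(sample(codes, nr * nc, replace = TRUE), nr, nc)
  if (nodata_frac > 0) {
    m[stats::runif(nr * nc) < nodata_frac] <- nodata
  }
  class_raster(m, nodata = nodata)
}

rand_stack <- function(n_years = 9L, nr = 12L, nc = 12L, codes = 1:4,
                       nodata = 0L) {
  history_stack(lapply(seq_len(n_years), function(i) {
    rand_raster(nr, nc, codes, nodata)
  }))
}

# Small uniform landscape with an all-same history, the base fixture for
# hand-traced refinement cases.
uniform_fixture <- function(code = 1L, n = 7L, n_years = 9L) {
  ras <- class_raster(matrix(code, n, n), nodata = 0L)
  stack <- history_stack(replicate(n_years, ras, simplify = FALSE))
  list(raster = ras, stack = stack)
}
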