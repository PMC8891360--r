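#' Historical dominance thresholds
#'
#' A class dominates a pixel's history when it appears in at least a
#' threshold number of the historical years. Constant features (water,
#' forest, developed land) are held to a strict threshold — their
#' classification is not expected to change, so misclassification is
#' tolerable only for a few years — while regular features such as rotating
#' crops use a looser one. The defaults are 7 of 9 for constant classes and
#' 5 of 9 for regular classes. Thresholds are absolute year counts, not
#' fractions: a nodata year counts toward no class and does not shrink the
#' denominator.
#'
#' `regular_min` must exceed `n_years / 2`; this guarantees at most one
#' dominant class per pixel (two classes with count 5 cannot fit in 9
#' years, whereas a threshold of 4 would admit ties).
#'
#' @param constant_min minimum historical count for constant classes
#'   (default 7).
#' @param regular_min minimum historical count for regular classes
#'   (default 5).
#' @param n_years history depth the thresholds refer to (default 9).
#' @return An object of class `dominance_thresholds`.
#' @export
dominance_thresholds <- function(constant_min = 7L, regular_min = 5L,
                                 n_years = 9L) {
  constant_min <- as.integer(constant_min)
  regular_min <- as.integer(regular_min)
  n_years <- as.integer(n_years)
  if (n_years < 1L) stop("n_years must be positive")
  if (!(regular_min > 0L && regular_min <= constant_min &&
        constant_min <= n_years)) {
    stop("need 0 < regular_min <= constant_min <= n_years")
  }
  if (regular_min * 2L <= n_years) {
    stop("regular_min must exceed n_years/2 to keep the dominant class unique")
  }
  structure(list(constant_min = constant_min, regular_min = regular_min,
                 n_years = n_years),
            class = "dominance_thresholds")
}

#' Dominating historical classification of one pixel
#'
#' Scans a pixel's historical class sequence and returns the unique class
#' meeting its type-specific threshold: `constant_min` appearances if the
#' class is a constant feature in the registry, `regular_min` otherwise.
#' Nodata entries never dominate and never shrink the thresholds.
#'
#' @param history integer vector of length `thresholds$n_years`, oldest
#'   first (order is irrelevant — only counts matter).
#' @param registry a `class_registry` deciding which classes are constant.
#' @param thresholds a `dominance_thresholds`.
#' @return A list with `class` (integer, `NA` if no class dominates) and
#'   `count` (its number of appearances; `NA` when no dominant).
#' @examples
#' reg <- default_registry()
#' th <- dominance_thresholds()
#' temporal_dominant(c(rep(1L, 5), rep(5L, 4)), reg, th)    # corn, 5
#' temporal_dominant(c(rep(111L, 6), rep(1L, 3)), reg, th)  # none: 6 < 7
#' @export
temporal_dominant <- function(history, registry, thresholds) {
  stopifnot(inherits(registry, "class_registry"),
            inherits(thresholds, "dominance_thresholds"))
  history <- as.integer(history)
  if (length(history) != thresholds$n_years) {
    stop("history length ", length(history), " does not match n_years ",
         thresholds$n_years)
  }
  history <- history[!is.na(history) & history != registry$nodata_code]
  if (length(history) == 0L) return(list(class = NA_integer_, count = NA_integer_))
  tab <- table(history)
  codes <- as.integer(names(tab))
  need <- ifelse(is_constant_code(registry, codes),
                 thresholds$constant_min, thresholds$regular_min)
  hit <- which(as.integer(tab) >= need)
  if (length(hit) == 0L) return(list(class = NA_integer_, count = NA_integer_))
  # regular_min > n_years/2 makes two hits impossible
  list(class = codes[hit[1L]], count = as.integer(tab)[hit[1L]])
}

#' Group a pixel by agreement between current class and historical dominant
#'
#' Candidate pixels split by temporal evidence: `"I_a"` — a dominant exists
#' and matches the current-year class (the pixel is corroborated and kept);
#' `"I_b"` — a dominant exists but differs (a refinement candidate);
#' `"II"` — no historical dominant (the pixel is discarded from
#' refinement).
#'
#' @param current_class integer current-year class code.
#' @param dominant_class integer dominant code, or `NA` for none.
#' @return One of `"I_a"`, `"I_b"`, `"II"`.
#' @export
temporal_group <- function(current_class, dominant_class) {
  if (is.na(dominant_class)) return("II")
  if (current_class == dominant_class) "I_a" else "I_b"
}

#' Per-pixel dominance over a history stack
#'
#' Applies the dominance rule of [temporal_dominant()] to every pixel of a
#' co-registered multi-year stack. Pixels with no class meeting its
#' threshold (including pixels that are nodata in every layer) report `NA`.
#'
#' @param stack a `history_stack`; its depth must equal
#'   `thresholds$n_years`.
#' @param registry a `class_registry`.
#' @param thresholds a `dominance_thresholds` (default the 7/9, 5/9 rule).
#' @return An object of class `dominance_raster`: matrices `dominant`
#'   (integer, `NA` where no dominant) and `count` (appearance count of the
#'   dominant, `NA` where none).
#' @export
dominance_raster <- function(stack, registry,
                             thresholds = dominance_thresholds()) {
  stopifnot(inherits(stack, "history_stack"),
            inherits(registry, "class_registry"),
            inherits(thresholds, "dominance_thresholds"))
  if (stack$n_years != thresholds$n_years) {
    stop("stack depth ", stack$n_years, " does not match thresholds n_years ",
         thresholds$n_years)
  }
  layers <- lapply(stack$layers, function(l) l$data)
  nodata <- stack$layers[[1L]]$nodata
  d <- dim(layers[[1L]])
  dominant <- matrix(NA_integer_, d[1], d[2])
  dcount <- matrix(NA_integer_, d[1], d[2])
  codes <- setdiff(sort(unique(unlist(lapply(layers, unique)))), nodata)
  for (cl in codes) {
    cnt <- matrix(0L, d[1], d[2])
    for (l in layers) cnt <- cnt + (l == cl)
    need <- if (is_constant_code(registry, cl)) thresholds$constant_min
            else thresholds$regular_min
    hit <- cnt >= need
    dominant[hit] <- cl
    dcount[hit] <- cnt[hit]
  }
  structure(list(dominant = dominant, count = dcount,
                 thresholds = thresholds),
            class = "dominance_raster")
}

#' @export
print.dominance_raster <- function(x, ...) {
  n <- length(x$dominant)
  cat("<dominance_raster> ", nrow(x$dominant), " x ", ncol(x$dominant),
      " pixels; ", sum(!is.na(x$dominant)), " of ", n,
      " have a dominant class\n", sep = "")
  invisible(x)
}
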