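#' Refinement configuration
#'
#' Bundles the tunable parameters of the decision-tree refinement filter.
#'
#' @param thresholds a [dominance_thresholds()] object (default 7/9
#'   constant, 5/9 regular).
#' @param max_iterations hard cap on refinement passes; convergence is
#'   normally reached within four, the cap guards against pathological
#'   oscillation.
#' @param road_history_min minimum number of historical years classified as
#'   a road/developed code for the road post-processing step to fire
#'   (default 3 of 9 — roads that fail the strict 7/9 constant dominance
#'   still deserve correction when corroborated by the reference mask).
#' @param road_codes integer codes eligible as road/developed targets;
#'   `NULL` means the registry's developed set.
#' @param include_mix_in_road if `TRUE`, mix pixels are also road-step
#'   candidates; by default only discarded isolate/boundary candidates are.
#' @return An object of class `refine_config`.
#' @export
refine_config <- function(thresholds = dominance_thresholds(),
                          max_iterations = 10L,
                          road_history_min = 3L,
                          road_codes = NULL,
                          include_mix_in_road = FALSE) {
  stopifnot(inherits(thresholds, "dominance_thresholds"))
  max_iterations <- as.integer(max_iterations)
  road_history_min <- as.integer(road_history_min)
  if (max_iterations < 1L) stop("max_iterations must be at least 1")
  if (road_history_min < 1L || road_history_min > thresholds$n_years) {
    stop("road_history_min must lie in [1, n_years]")
  }
  structure(list(thresholds = thresholds, max_iterations = max_iterations,
                 road_history_min = road_history_min,
                 road_codes = if (is.null(road_codes)) NULL
                              else as.integer(road_codes),
                 include_mix_in_road = isTRUE(include_mix_in_road)),
            class = "refine_config")
}

#' Per-pixel road history from a stack
#'
#' For each pixel, counts the historical years classified as any of the
#' road/developed codes and records the most frequent such code (ties broken
#' toward the lowest code, deterministically).
#'
#' @param stack a `history_stack`.
#' @param road_codes integer vector of road/developed class codes.
#' @return A list of matrices `count` (years with a road code) and
#'   `top_code` (most frequent road code, `NA` where count is 0).
#' @export
road_class_history <- function(stack, road_codes) {
  stopifnot(inherits(stack, "history_stack"))
  road_codes <- sort(as.integer(road_codes))
  d <- dim(stack$layers[[1L]]$data)
  total <- matrix(0L, d[1], d[2])
  best <- matrix(0L, d[1], d[2])
  top <- matrix(NA_integer_, d[1], d[2])
  for (cl in road_codes) {
    cnt <- matrix(0L, d[1], d[2])
    for (l in stack$layers) cnt <- cnt + (l$data == cl)
    total <- total + cnt
    better <- cnt > best  # ascending scan + strict ">" keeps the lowest code on ties
    top[better] <- cl
    best[better] <- cnt[better]
  }
  list(count = total, top_code = top)
}

#' One synchronous refinement pass
#'
#' Applies the decision tree once over the whole raster. All decisions read
#' the input raster (synchronous update), so the result is independent of
#' scan order. Per interior pixel with majority neighbor class M, dominant
#' historical class D and current class C:
#'
#' * uniform window — kept (`kept-uniform`);
#' * isolate/boundary, C = D — corroborated, kept (`kept-I_a`);
#' * isolate/boundary, M = D and C != D — refined to D
#'   (`refined-spatial-temporal`);
#' * isolate/boundary, D exists but M != D — conflict, discarded
#'   (`discarded-conflict`);
#' * isolate/boundary, no D — discarded (`discarded-no-dominant`);
#' * mix — skipped (`mix-skipped`); border / nodata windows — skipped.
#'
#' Discarded candidates then pass through the road step: a pixel under the
#' road mask whose history shows at least `road_history_min` road years is
#' set to its most frequent historical road code.
#'
#' @param raster current `class_raster`.
#' @param dominance a `dominance_raster` computed from the original
#'   (unmodified) history stack.
#' @param registry a `class_registry`.
#' @param config a `refine_config`.
#' @param road_mask optional `binary_mask` co-registered with `raster`.
#' @param road_stats optional result of [road_class_history()]; required
#'   when `road_mask` is given.
#' @return A list: `raster` (refined `class_raster`), `n_changed`,
#'   `changed` (logical matrix), `trace` (character matrix of the decision
#'   codes above).
#' @export
refine_once <- function(raster, dominance, registry, config,
                        road_mask = NULL, road_stats = NULL) {
  stopifnot(inherits(raster, "class_raster"),
            inherits(dominance, "dominance_raster"),
            inherits(registry, "class_registry"),
            inherits(config, "refine_config"))
  data <- raster$data
  if (!identical(dim(data), dim(dominance$dominant))) {
    stop("alignment error: dominance grid shape differs from raster")
  }
  if (!is.null(road_mask)) {
    if (!identical(dim(road_mask$data), dim(data))) {
      stop("alignment error: road mask shape differs from raster")
    }
    if (is.null(road_stats)) {
      stop("road_stats (see road_class_history) are required with a road mask")
    }
  }

  prof <- classify_neighborhood(raster)
  M <- prof$majority_class
  D <- dominance$dominant
  new <- data

  trace <- matrix("mix-skipped", nrow(data), ncol(data))
  trace[prof$category == "uniform"] <- "kept-uniform"
  trace[prof$category == "edge"] <- "edge-skipped"
  trace[prof$category == "nodata"] <- "nodata-skipped"

  cand <- prof$category %in% c("isolate", "boundary")
  dim(cand) <- dim(data)
  has_d <- !is.na(D)

  kept <- cand & has_d & data == D
  trace[kept] <- "kept-I_a"

  refined <- cand & has_d & !is.na(M) & M == D & data != D
  new[refined] <- D[refined]
  trace[refined] <- "refined-spatial-temporal"

  no_dom <- cand & !has_d
  trace[no_dom] <- "discarded-no-dominant"

  conflict <- cand & has_d & data != D & (is.na(M) | M != D)
  trace[conflict] <- "discarded-conflict"

  if (!is.null(road_mask)) {
    eligible <- trace == "discarded-conflict" | trace == "discarded-no-dominant"
    if (config$include_mix_in_road) {
      eligible <- eligible | trace == "mix-skipped"
    }
    road_fix <- eligible & road_mask$data == 1L &
      road_stats$count >= config$road_history_min &
      !is.na(road_stats$top_code) & new != road_stats$top_code
    new[road_fix] <- road_stats$top_code[road_fix]
    trace[road_fix] <- "refined-road"
  }

  changed <- new != data
  out <- class_raster(new, nodata = raster$nodata, xll = raster$xll,
                      yll = raster$yll, cellsize = raster$cellsize,
                      crs = raster$crs, year = raster$year)
  list(raster = out, n_changed = sum(changed), changed = changed,
       trace = trace)
}

#' Iterative spatial-temporal refinement
#'
#' The full refinement workflow: historical dominance is computed once from
#' the original stack, then [refine_once()] is applied repeatedly —
#' neighborhood profiles are re-derived from each pass's output, so a
#' corrected pixel can enable its neighbor's correction in the next pass —
#' until a pass changes no pixel or `max_iterations` is reached. The
#' history is never recomputed from refined output: the current year must
#' not contaminate its own historical evidence.
#'
#' @param raster the current-year `class_raster` to refine (at least 3x3).
#' @param stack a `history_stack` co-registered with `raster`, oldest
#'   first, of depth `config$thresholds$n_years`.
#' @param registry a `class_registry` (default [default_registry()]).
#' @param config a `refine_config`.
#' @param road_mask optional `binary_mask` of reference road locations; it
#'   is resampled to the raster shape by nearest neighbor if needed, and
#'   enables the road post-processing step.
#' @return An object of class `refinement_result`: `refined`
#'   (`class_raster`), `changed` (logical matrix, differs-from-input),
#'   `trace` (character matrix; pixels altered at any pass keep their
#'   refinement code), `iterations_run`, `changes_per_iteration` (integer
#'   vector), `converged` (TRUE when the last pass changed nothing).
#' @examples
#' sc <- generate_scene(scene_spec(
#'   shape = c(40, 40), field_size = 8,
#'   constant_patches = list(list(code = 111L, rows = c(5L, 12L),
#'                                cols = c(5L, 12L))),
#'   road_rows = 20L, road_cols = 30L))
#' noisy <- inject_noise(sc$current, noise_spec(isolate_rate = 0.01, seed = 2))
#' res <- refine(noisy$raster, sc$history, road_mask = sc$road_mask)
#' res$iterations_run
#' @export
refine <- function(raster, stack, registry = default_registry(),
                   config = refine_config(), road_mask = NULL) {
  stopifnot(inherits(raster, "class_raster"), inherits(stack, "history_stack"))
  if (!identical(dim(raster$data), dim(stack$layers[[1L]]$data))) {
    stop("alignment error: history stack shape differs from input raster")
  }
  dom <- dominance_raster(stack, registry, config$thresholds)

  road_stats <- NULL
  if (!is.null(road_mask)) {
    stopifnot(inherits(road_mask, "binary_mask"))
    if (!identical(dim(road_mask$data), dim(raster$data))) {
      rm_r <- resample_nearest(
        class_raster(road_mask$data, nodata = -1L, xll = road_mask$xll,
                     yll = road_mask$yll, cellsize = road_mask$cellsize),
        dim(raster$data))
      road_mask <- binary_mask(rm_r$data, xll = rm_r$xll, yll = rm_r$yll,
                               cellsize = rm_r$cellsize)
    }
    codes <- config$road_codes
    if (is.null(codes)) codes <- developed_codes(registry)
    road_stats <- road_class_history(stack, codes)
  }

  cur <- raster
  changes <- integer(0)
  branch <- matrix(NA_character_, nrow(raster$data), ncol(raster$data))
  last_trace <- NULL
  for (it in seq_len(config$max_iterations)) {
    pass <- refine_once(cur, dom, registry, config, road_mask, road_stats)
    changes <- c(changes, pass$n_changed)
    branch[pass$changed] <- pass$trace[pass$changed]
    last_trace <- pass$trace
    cur <- pass$raster
    if (pass$n_changed == 0L) break
  }

  trace <- last_trace
  keep_branch <- !is.na(branch) &
    !(trace %in% c("refined-spatial-temporal", "refined-road"))
  trace[keep_branch] <- branch[keep_branch]

  structure(list(
    refined = cur,
    changed = cur$data != raster$data,
    trace = trace,
    iterations_run = length(changes),
    changes_per_iteration = changes,
    converged = changes[length(changes)] == 0L
  ), class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("<refinement_result> ", sum(x$changed), " pixels changed in ",
      x$iterations_run, " iteration(s) [",
      paste(x$changes_per_iteration, collapse = ", "), "]",
      if (!x$converged) " (max_iterations hit before convergence)",
      "\n", sep = "")
  tab <- sort(table(x$trace), decreasing = TRUE)
  print(tab)
  invisible(x)
}

#' Export a decision trace as a diagnostic raster
#'
#' Encodes the per-pixel decision codes as integers for writing with
#' [write_class_raster()]: kept-uniform 1, kept-I_a 2,
#' refined-spatial-temporal 3, refined-road 4, discarded-conflict 5,
#' discarded-no-dominant 6, mix-skipped 7, edge-skipped 8, nodata-skipped 9.
#'
#' @param result a `refinement_result`.
#' @param template `class_raster` supplying grid metadata.
#' @return A `class_raster` of trace codes (nodata 0).
#' @export
trace_raster <- function(result, template) {
  stopifnot(inherits(result, "refinement_result"),
            inherits(template, "class_raster"))
  codes <- c("kept-uniform" = 1L, "kept-I_a" = 2L,
             "refined-spatial-temporal" = 3L, "refined-road" = 4L,
             "discarded-conflict" = 5L, "discarded-no-dominant" = 6L,
             "mix-skipped" = 7L, "edge-skipped" = 8L, "nodata-skipped" = 9L)
  m <- matrix(codes[result$trace], nrow(result$trace), ncol(result$trace))
  class_raster(m, nodata = 0L, xll = template$xll, yll = template$yll,
               cellsize = template$cellsize, crs = template$crs)
}
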