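reg <- default_registry()
cfg <- refine_config()

test_that("the decision tree refines, keeps and discards as hand-traced", {
  fx <- uniform_fixture(code = 1L, n = 7L)

  # isolate pixel whose neighbor majority equals its historical dominant
  ras <- fx$raster
  ras$data[4, 4] <- 5L
  dom <- dominance_raster(fx$stack, reg, cfg$thresholds)
  pass <- refine_once(ras, dom, reg, cfg)
  expect_identical(pass$raster$data[4, 4], 1L)
  expect_identical(pass$trace[4, 4], "refined-spatial-temporal")
  expect_identical(pass$n_changed, 1L)

  # same pixel, but its history gives no dominant: discarded
  mixed <- history_stack(lapply(c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L, 2L),
                                function(k) {
                                  r <- fx$raster
                                  r$data[4, 4] <- k
                                  r
                                }))
  dom2 <- dominance_raster(mixed, reg, cfg$thresholds)
  pass2 <- refine_once(ras, dom2, reg, cfg)
  expect_identical(pass2$raster$data[4, 4], 5L)
  expect_identical(pass2$trace[4, 4], "discarded-no-dominant")

  # boundary pixel whose majority conflicts with its dominant: discarded
  ras3 <- fx$raster
  ras3$data[4, 4] <- 5L
  ras3$data[3, 3:5] <- 2L   # neighbors now 1x5, 2x3 -> majority 1, count 5
  hist3 <- history_stack(lapply(1:9, function(i) {
    r <- fx$raster
    r$data[4, 4] <- 2L
    r
  }))
  dom3 <- dominance_raster(hist3, reg, cfg$thresholds)
  pass3 <- refine_once(ras3, dom3, reg, cfg)
  expect_identical(pass3$raster$data[4, 4], 5L)
  expect_identical(pass3$trace[4, 4], "discarded-conflict")

  # corroborated pixel (current equals dominant) is kept even when isolated
  ras4 <- fx$raster
  ras4$data[4, 4] <- 2L
  dom4 <- dominance_raster(hist3, reg, cfg$thresholds)
  pass4 <- refine_once(ras4, dom4, reg, cfg)
  expect_identical(pass4$raster$data[4, 4], 2L)
  expect_identical(pass4$trace[4, 4], "kept-I_a")

  # untouched uniform landscape
  pass5 <- refine_once(fx$raster, dom, reg, cfg)
  expect_identical(pass5$n_changed, 0L)
  expect_identical(pass5$trace[4, 4], "kept-uniform")
})

test_that("road post-processing recovers discarded candidates on the mask", {
  fx <- uniform_fixture(code = 1L, n = 7L)
  # history at (4,4): road (121) x4 + corn x5 -> corn dominates (regular, 5),
  # but the current class conflicts with the neighbor majority, so the
  # spatial-temporal branch discards it and the road step picks it up.
  layers <- lapply(1:9, function(i) {
    r <- fx$raster
    r$data[4, 4] <- if (i <= 4) 121L else 1L
    r
  })
  stack <- history_stack(layers)
  ras <- fx$raster
  ras$data[4, 4] <- 5L
  # five neighbors of class 2: majority 2 conflicts with the corn dominant
  ras$data[cbind(c(3, 3, 3, 4, 4), c(3, 4, 5, 3, 5))] <- 2L

  dom <- dominance_raster(stack, reg, cfg$thresholds)
  rs <- road_class_history(stack, developed_codes(reg))
  mask_on <- binary_mask(matrix(0L, 7, 7), cellsize = 30)
  mask_on$data[4, 4] <- 1L
  pass <- refine_once(ras, dom, reg, cfg, mask_on, rs)
  expect_identical(pass$raster$data[4, 4], 121L)
  expect_identical(pass$trace[4, 4], "refined-road")

  # off the mask: unchanged, still the discarded conflict
  mask_off <- binary_mask(matrix(0L, 7, 7), cellsize = 30)
  pass2 <- refine_once(ras, dom, reg, cfg, mask_off, rs)
  expect_identical(pass2$raster$data[4, 4], 5L)
  expect_identical(pass2$trace[4, 4], "discarded-conflict")

  # on the mask but with no historical road years: unchanged
  dom0 <- dominance_raster(fx$stack, reg, cfg$thresholds)
  rs0 <- road_class_history(fx$stack, developed_codes(reg))
  pass3 <- refine_once(ras, dom0, reg, cfg, mask_on, rs0)
  expect_identical(pass3$raster$data[4, 4], 5L)
})

test_that("a flipped road pixel is restored by the road step and stays", {
  sc <- generate_scene(scene_spec(shape = c(48L, 48L), field_size = 12L,
                                  constant_patches = list(),
                                  road_rows = 20L, road_cols = 30L))
  noisy <- sc$current
  noisy$data[20, 8] <- 1L   # mid-field road pixel misclassified as corn
  res <- refine(noisy, sc$history, reg, cfg, road_mask = sc$road_mask)
  expect_identical(res$refined$data[20, 8], sc$spec$road_code)
  expect_identical(res$trace[20, 8], "refined-road")
  expect_true(res$converged)
})

test_that("historical road code ties break toward the lowest code", {
  mk <- function(code) class_raster(matrix(code, 5, 5), nodata = 0L)
  layers <- lapply(c(124L, 124L, 121L, 121L, 1L, 1L, 1L, 1L, 1L), mk)
  rs <- road_class_history(history_stack(layers), c(82L, 121L, 122L, 123L, 124L))
  expect_true(all(rs$count == 4L))
  expect_true(all(rs$top_code == 121L))
})

test_that("a corrected outer pixel enables its neighbor on the next pass", {
  fx <- uniform_fixture(code = 1L, n = 9L)
  ras <- fx$raster
  # plus-shaped cluster of wrong pixels: arms are boundary pixels (fixed in
  # pass 1), the center is a 4-4 mix until the arms are corrected
  ras$data[cbind(c(5, 4, 6, 5, 5), c(5, 5, 5, 4, 6))] <- 2L
  res <- refine(ras, fx$stack, reg, cfg)
  expect_true(res$iterations_run >= 2L)
  expect_identical(res$refined$data, fx$raster$data)
  expect_true(res$converged)
})

test_that("refinement is conservative, idempotent at fixpoint and deterministic", {
  set.seed(404)
  for (i in 1:6) {
    ras <- rand_raster(14, 14, codes = c(1L, 5L, 111L, 121L))
    st <- rand_stack(9L, 14L, 14L, codes = c(1L, 5L, 111L, 121L))
    mask <- binary_mask(matrix(rbinom(196, 1, 0.2), 14, 14), cellsize = 30)
    res <- refine(ras, st, reg, cfg, road_mask = mask)

    # changed mask is exactly the cell-wise difference
    expect_identical(res$changed, res$refined$data != ras$data)

    # every written value is the pixel's dominant or a historical road code
    dom <- dominance_raster(st, reg, cfg$thresholds)
    rs <- road_class_history(st, developed_codes(reg))
    idx <- which(res$changed)
    ok <- (!is.na(dom$dominant[idx]) &
             res$refined$data[idx] == dom$dominant[idx]) |
      (!is.na(rs$top_code[idx]) & res$refined$data[idx] == rs$top_code[idx])
    expect_true(all(ok))

    if (res$converged) {
      again <- refine(res$refined, st, reg, cfg, road_mask = mask)
      expect_identical(again$refined$data, res$refined$data)
      expect_identical(sum(again$changed), 0L)
    }

    res2 <- refine(ras, st, reg, cfg, road_mask = mask)
    expect_identical(res2$refined$data, res$refined$data)
    expect_identical(res2$changes_per_iteration, res$changes_per_iteration)
  }
})

test_that("a single pass agrees with the naive double-loop reference", {
  set.seed(7001)
  for (i in 1:20) {
    ras <- rand_raster(12, 12, codes = c(1L, 5L, 111L, 121L))
    st <- rand_stack(9L, 12L, 12L, codes = c(1L, 5L, 111L, 121L))
    mask <- if (i %% 2 == 0) {
      binary_mask(matrix(rbinom(144, 1, 0.3), 12, 12), cellsize = 30)
    } else NULL
    dom <- dominance_raster(st, reg, cfg$thresholds)
    rs <- if (!is.null(mask)) road_class_history(st, developed_codes(reg))
          else NULL
    got <- refine_once(ras, dom, reg, cfg, mask, rs)
    want <- oracle_refine_once(ras, st, reg, cfg, mask)
    expect_identical(got$raster$data, want$data)
  }
})

test_that("misaligned inputs raise alignment errors", {
  fx <- uniform_fixture(n = 7L)
  small <- class_raster(matrix(1L, 5, 5), nodata = 0L)
  expect_error(refine(small, fx$stack), "alignment")
  dom <- dominance_raster(fx$stack, reg, cfg$thresholds)
  expect_error(refine_once(small, dom, reg, cfg), "alignment")
})

test_that("stable input is a fixpoint after one iteration", {
  fx <- uniform_fixture(n = 7L)
  res <- refine(fx$raster, fx$stack, reg, cfg)
  expect_identical(res$iterations_run, 1L)
  expect_identical(sum(res$changed), 0L)
  expect_true(res$converged)
})
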