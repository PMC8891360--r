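test_that("rotation arithmetic gives 5/4 history counts and constant patches 9/9", {
  sc <- generate_scene(scene_spec())
  spec <- sc$spec
  hist_at <- function(r, c) {
    vapply(sc$history$layers, function(l) l$data[r, c], integer(1))
  }

  # a crop-field pixel far from patches and roads
  h <- hist_at(3, 3)
  counts <- sort(as.integer(table(h)), decreasing = TRUE)
  expect_identical(counts, c(5L, 4L))
  expect_setequal(unique(h), spec$crop_codes)
  # strict alternation: the current-year class is the 4-count one, the
  # other crop holds the 5-count majority
  cur <- sc$current$data[3, 3]
  expect_identical(sum(h == cur), 4L)
  other <- setdiff(spec$crop_codes, cur)
  expect_identical(sum(h == other), 5L)

  # inside a water pond the constant code appears in all nine years
  expect_identical(sum(hist_at(20, 20) == 111L), 9L)
  expect_identical(sc$current$data[20, 20], 111L)
  # roads identical across all years
  expect_identical(sum(hist_at(45, 3) == spec$road_code), 9L)
  expect_identical(sum(sc$road_mask$data[45, ] == 1L), ncol(sc$road_mask$data))

  # adjacent fields are out of phase
  expect_false(sc$current$data[3, 3] == sc$current$data[3, 15])

  # zones partition the grid into 3x3 rectangular counties
  expect_setequal(unique(as.vector(sc$zones$data)), 1:9)
  expect_identical(sc$zones$data[1, 1], 1L)
  expect_identical(sc$zones$data[120, 120], 9L)
})

test_that("scene generation is deterministic and validates patches", {
  a <- generate_scene(scene_spec())
  b <- generate_scene(scene_spec())
  expect_identical(a$current$data, b$current$data)
  expect_identical(lapply(a$history$layers, `[[`, "data"),
                   lapply(b$history$layers, `[[`, "data"))
  expect_error(scene_spec(constant_patches = list(
    list(code = 111L, rows = c(10L, 20L), cols = c(10L, 20L)),
    list(code = 141L, rows = c(15L, 25L), cols = c(15L, 25L))
  )), "overlap")
  expect_error(scene_spec(field_size = 2L), "field_size")
})

test_that("noise injection flips only what it records, reproducibly", {
  sc <- generate_scene(scene_spec())

  # zero rate is the identity
  nz0 <- inject_noise(sc$current, noise_spec(isolate_rate = 0, seed = 3))
  expect_identical(nz0$raster$data, sc$current$data)
  expect_identical(sum(nz0$injected), 0L)

  nz <- inject_noise(sc$current, noise_spec(isolate_rate = 0.01, seed = 3))
  expect_identical(nz$injected, nz$raster$data != sc$current$data)
  # every injected cell differs from truth and stays inside the code set
  idx <- which(nz$injected)
  expect_true(all(nz$raster$data[idx] != sc$current$data[idx]))
  codes <- setdiff(unique(as.vector(sc$current$data)), sc$current$nodata)
  expect_true(all(nz$raster$data[idx] %in% codes))
  # rate 1% of ~13.9k interior pixels: a loose binomial band
  expect_gt(sum(nz$injected), 70L)
  expect_lt(sum(nz$injected), 220L)
  # no injection on the border ring
  expect_true(all(!nz$injected[c(1, 120), ]) && all(!nz$injected[, c(1, 120)]))

  # same seed, same draw; different seed, different draw
  nz_b <- inject_noise(sc$current, noise_spec(isolate_rate = 0.01, seed = 3))
  expect_identical(nz_b$raster$data, nz$raster$data)
  nz_c <- inject_noise(sc$current, noise_spec(isolate_rate = 0.01, seed = 4))
  expect_false(identical(nz_c$raster$data, nz$raster$data))

  # history noise is independent per layer
  nh <- inject_noise(sc$history, noise_spec(history_noise_rate = 0.05, seed = 5))
  per_layer <- vapply(nh$injected, sum, integer(1))
  expect_true(all(per_layer > 0L))
  expect_identical(length(unique(lapply(nh$stack$layers, `[[`, "data"))), 9L)

  expect_error(noise_spec(isolate_rate = 0.6), "rates")
})

test_that("boundary jitter moves field-edge pixels to an adjacent class", {
  sc <- generate_scene(scene_spec(shape = c(48L, 48L), field_size = 12L,
                                  constant_patches = list(),
                                  road_rows = integer(0),
                                  road_cols = integer(0)))
  nz <- inject_noise(sc$current,
                     noise_spec(isolate_rate = 0, boundary_jitter_rate = 0.3,
                                seed = 9))
  idx <- which(nz$injected)
  expect_gt(length(idx), 0L)
  d <- dim(sc$current$data)
  for (i in idx) {
    rc <- arrayInd(i, d)
    ring4 <- c(sc$current$data[rc[1] - 1, rc[2]],
               sc$current$data[rc[1] + 1, rc[2]],
               sc$current$data[rc[1], rc[2] - 1],
               sc$current$data[rc[1], rc[2] + 1])
    expect_true(nz$raster$data[i] %in% ring4)
    expect_false(nz$raster$data[i] == sc$current$data[i])
  }
})

test_that("recovery scoring conserves counts", {
  sc <- generate_scene(scene_spec())
  nz <- inject_noise(sc$current, noise_spec(isolate_rate = 0.02, seed = 21))

  perfect <- score_recovery(sc$current, nz$raster, sc$current, nz$injected)
  expect_identical(perfect$corrected, perfect$injected)
  expect_identical(perfect$damaged, 0L)
  expect_equal(perfect$recovery_rate, 1)

  none <- score_recovery(sc$current, nz$raster, nz$raster, nz$injected)
  expect_identical(none$corrected, 0L)
  expect_identical(none$uncorrected, none$injected)

  # partial correction still partitions the injected set
  half <- nz$raster
  idx <- which(nz$injected)
  fixed <- idx[seq_len(length(idx) %/% 2)]
  half$data[fixed] <- sc$current$data[fixed]
  part <- score_recovery(sc$current, nz$raster, half, nz$injected)
  expect_identical(part$corrected + part$uncorrected, part$injected)
  expect_identical(part$corrected, length(fixed))
})

test_that("every crop pixel's two-crop history has a class at count >= 5", {
  sc <- generate_scene(scene_spec())
  reg <- default_registry()
  crop <- matrix(is_crop_code(reg, sc$current$data), 120, 120)
  counts <- Reduce(`+`, lapply(sc$history$layers, function(l) {
    l$data == sc$spec$crop_codes[1]
  }))
  top <- pmax(counts, 9L - counts)
  expect_true(all(top[crop] >= 5L))
})
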