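mask_of <- function(occ, spacing = c(1, 1, 1))
  structure(list(occupied = occ, level = 1L, spacing = spacing),
            class = "level_mask")

test_that("superlevel masks nest and respect bounds", {
  set.seed(51)
  g <- random_grid(c(6, 6, 6))
  d <- discretize_es(g, 8)
  expect_true(all(level_mask(d, 1)$occupied))
  for (lvl in 1:7) {
    hi <- level_mask(d, lvl + 1)$occupied
    lo <- level_mask(d, lvl)$occupied
    expect_true(all(lo[hi]))              # mask(g+1) subset of mask(g)
  }
  expect_error(level_mask(d, 0), "outside")
  expect_error(level_mask(d, 9), "outside")
  # a level above the occupied maximum gives an empty mask -> missing fits
  dsm <- discretize_es(make_grid(c(rep(0, 7), 1), c(2, 2, 2)), 4)
  expect_true(is.na(box_counting_dimension(
    mask_of(dsm$levels >= 5))$dimension))
})

test_that("box counts are monotone and anchored correctly", {
  set.seed(52)
  occ <- array(runif(16^3) < 0.2, c(16, 16, 16))
  bc <- box_counting_dimension(mask_of(occ))
  expect_equal(bc$counts[1], sum(occ))    # N(1) = occupied voxels
  expect_true(all(diff(bc$counts) <= 0))  # non-increasing in box size
  expect_equal(bc$box_sizes, c(1, 2, 4, 8))
})

test_that("dimension estimates on analytic sets", {
  solid <- mask_of(array(TRUE, c(32, 32, 32)))
  expect_equal(box_counting_dimension(solid)$dimension, 3, tolerance = 0.05)
  plane <- array(FALSE, c(32, 32, 32)); plane[, , 16] <- TRUE
  expect_equal(box_counting_dimension(mask_of(plane))$dimension, 2, tolerance = 0.075)
  single <- array(FALSE, c(16, 16, 16)); single[3, 3, 3] <- TRUE
  expect_equal(box_counting_dimension(mask_of(single))$dimension, 0)
  line <- array(FALSE, c(32, 4, 4)); line[, 2, 2] <- TRUE
  expect_equal(correlation_dimension(mask_of(line))$dimension, 1, tolerance = 0.2)
  cube16 <- mask_of(array(TRUE, c(16, 16, 16)))
  expect_equal(correlation_dimension(cube16)$dimension, 3, tolerance = 0.3)
  pl <- array(FALSE, c(32, 32, 2)); pl[, , 1] <- TRUE
  expect_equal(correlation_dimension(mask_of(pl))$dimension, 2, tolerance = 0.25)
  # degenerate inputs give missing, not errors
  expect_true(is.na(correlation_dimension(mask_of(single))$dimension))
  expect_true(is.na(box_counting_dimension(mask_of(array(FALSE, c(8, 8, 8))))$dimension))
})

test_that("correlation dimension is deterministic under subsampling", {
  set.seed(53)
  occ <- array(runif(24^3) < 0.5, c(24, 24, 24))   # ~6900 occupied
  a <- correlation_dimension(mask_of(occ), max_points = 500)
  b <- correlation_dimension(mask_of(occ), max_points = 500)
  expect_identical(a$dimension, b$dimension)
  # and does not disturb the caller's RNG stream
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(correlation_dimension(mask_of(occ), max_points = 500))
  expect_identical(runif(1), x1)
})

test_that("volume and surface follow the face-counting oracle", {
  block <- array(FALSE, c(12, 12, 12)); block[2:11, 2:11, 2:11] <- TRUE
  vs <- volume_surface_features(mask_of(block))
  expect_equal(unname(vs["Volume"]), 1000)
  expect_equal(unname(vs["Surface"]), 600)
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  vs1 <- volume_surface_features(mask_of(one))
  expect_equal(unname(vs1), c(1, 6, 6))
  vs2 <- volume_surface_features(mask_of(one, spacing = c(2, 2, 2)))
  expect_equal(unname(vs2["Volume"]), 8)
  expect_equal(unname(vs2["Surface"]), 24)
  # voxels touching the grid boundary contribute boundary faces
  full <- mask_of(array(TRUE, c(2, 2, 2)))
  expect_equal(unname(volume_surface_features(full)["Surface"]), 24)
  expect_true(all(is.na(volume_surface_features(mask_of(array(FALSE, c(2, 2, 2)))))))
  # volume is additive over disjoint masks
  a <- array(FALSE, c(6, 6, 6)); a[1:2, , ] <- TRUE
  b <- array(FALSE, c(6, 6, 6)); b[5:6, , ] <- TRUE
  expect_equal(
    volume_surface_features(mask_of(a))["Volume"] +
      volume_surface_features(mask_of(b))["Volume"],
    volume_surface_features(mask_of(a | b))["Volume"])
})

test_that("geometric block follows the naming grammar and nesting", {
  set.seed(54)
  g <- random_grid(c(10, 10, 10))
  d <- discretize_es(g, 8)
  blk <- geometric_feature_block(d)
  expect_true(all(sprintf("fractal_bc_d_%d__es_8", 1:8) %in% names(blk)))
  expect_true(all(sprintf("fractal_c_d_%d__es_8", 1:8) %in% names(blk)))
  expect_true("Volume_4__es_8" %in% names(blk))
  # nesting: bc dimension non-increasing in g up to fit noise
  bc <- blk[sprintf("fractal_bc_d_%d__es_8", 1:8)]
  bc <- bc[!is.na(bc)]
  expect_true(all(diff(bc) <= 0.2))
  # constant image: level-1 mask is the full volume, higher levels missing
  dc <- discretize_es(make_grid(rep(2, 16^3), c(16, 16, 16)), 8)
  blc <- geometric_feature_block(dc)
  expect_equal(unname(blc["fractal_bc_d_1__es_8"]), 3, tolerance = 0.15)
  expect_true(all(is.na(blc[sprintf("fractal_bc_d_%d__es_8", 2:8)])))
})
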