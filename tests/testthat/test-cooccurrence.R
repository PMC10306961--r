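disc_from_levels <- function(lev, L, scheme = "es") {
  g <- make_grid(as.numeric(lev), dim(lev))
  structure(list(levels = lev, L = as.integer(L), scheme = scheme,
                 bin_edges = seq(0, L, length.out = L + 1),
                 spacing = c(1, 1, 1), source_id = "fix"),
            class = "discretized_image")
}

test_that("GLCM hand examples", {
  # 2x1x1 image [1,2]: only direction (1,0,0) pairs; symmetric halves
  d <- disc_from_levels(array(c(1L, 2L), c(2, 1, 1)), 2)
  gl <- build_glcms(d, 1)
  expect_length(gl, 1L)
  expect_equal(gl[[1]]$matrix, matrix(c(0, .5, .5, 0), 2))
  # constant image: all mass at (1,1) in every direction
  dc <- disc_from_levels(array(1L, c(3, 3, 3)), 2)
  for (g in build_glcms(dc, 1)) expect_equal(g$matrix[1, 1], 1)
  # single voxel: no pairs anywhere
  expect_error(build_glcms(disc_from_levels(array(1L, c(1, 1, 1)), 2)), "no voxel pair")
})

test_that("aggregate_mean conserves mass, symmetry and idempotence", {
  set.seed(41)
  d <- disc_from_levels(array(sample(1:4, 60, TRUE), c(5, 4, 3)), 4)
  gl <- build_glcms(d, 1)
  agg <- aggregate_mean(gl)
  expect_equal(sum(agg$matrix), 1, tolerance = 1e-12)
  expect_equal(agg$matrix, t(agg$matrix))
  same <- aggregate_mean(list(gl[[1]], gl[[1]]))
  expect_equal(same$matrix, gl[[1]]$matrix)
  expect_error(aggregate_mean(list()), "empty")
})

test_that("GLCM statistics match hand substitution", {
  # all mass at (1,1)
  g0 <- structure(list(matrix = matrix(c(1, 0, 0, 0), 2), L = 2L,
                       symmetric = TRUE), class = "glcm")
  s0 <- glcm_statistics(g0)
  expect_equal(unname(s0["Contrast_s"]), 0)
  expect_equal(unname(s0["Homogeneity_s"]), 1)
  expect_equal(unname(s0["Cluster_p_s"]), 0)
  expect_true(is.na(s0["Contrast_s_nd"]))     # no off-diagonal mass
  # p(1,2) = p(2,1) = 1/2
  g1 <- structure(list(matrix = matrix(c(0, .5, .5, 0), 2), L = 2L,
                       symmetric = TRUE), class = "glcm")
  s1 <- glcm_statistics(g1)
  expect_equal(unname(s1["Contrast_s"]), 1)
  expect_equal(unname(s1["Homogeneity_s"]), 0.5)
  expect_equal(unname(s1["Cluster_d_s"]), 1)
  expect_equal(unname(s1["Homogeneity2_e"]), 0.5)
  # mu_i = mu_j = 1.5; (i+j-3) = 0 on the off-diagonal
  expect_equal(unname(s1["Cluster_p_s"]), 0)
  # inverse Gaussian polar: exp(-(1/2)^2) off the diagonal
  expect_equal(unname(s1["Inv_Gauss_2p_s"]), exp(-0.25))
  # cluster shade vanishes when the (i+j) distribution is symmetric about
  # its mean: p(1,1) = p(2,2), p(1,2) = p(2,1)
  m <- matrix(c(0.3, 0.2, 0.2, 0.3), 2)
  gs <- structure(list(matrix = m, L = 2L, symmetric = TRUE), class = "glcm")
  expect_equal(unname(glcm_statistics(gs)["Cluster_sh_s"]), 0, tolerance = 1e-12)
  expect_error(glcm_statistics(structure(list(matrix = m * 2, L = 4L),
                                         class = "glcm")), "not normalized")
})

test_that("GLRLM hand examples and statistics", {
  d <- disc_from_levels(array(c(1L, 1L, 2L, 2L), c(4, 1, 1)), 2)
  rl <- build_glrlm(d, c(1, 0, 0))
  expect_equal(rl$matrix[1, 2], 1)
  expect_equal(rl$matrix[2, 2], 1)
  expect_equal(sum(rl$matrix), 2)
  st <- glrlm_statistics(rl)
  expect_equal(unname(st["GLN"]), 1)
  expect_equal(unname(st["RLN"]), 2)
  # constant line: one run of length n
  dcon <- disc_from_levels(array(1L, c(6, 1, 1)), 2)
  rlc <- build_glrlm(dcon, c(1, 0, 0))
  expect_equal(rlc$matrix[1, 6], 1)
  stc <- glrlm_statistics(rlc)
  expect_equal(unname(stc["GLN"]), 1)
  expect_equal(unname(stc["RLN"]), 1)
  # alternating line: four runs of length 1
  dal <- disc_from_levels(array(c(1L, 2L, 1L, 2L), c(4, 1, 1)), 2)
  sta <- glrlm_statistics(build_glrlm(dal, c(1, 0, 0)))
  expect_equal(unname(sta["GLN"]), 2)
  expect_equal(unname(sta["RLN"]), 4)
  expect_error(build_glrlm(d, c(0, 0, 0)), "nonzero")
})

test_that("GLCM/GLRLM match exhaustive enumeration on random volumes", {
  set.seed(43)
  dirs <- petrad:::unique_directions()
  for (i in 1:20) {
    L <- sample(2:8, 1)
    shp <- sample(2:5, 3, TRUE)
    lev <- array(sample.int(L, prod(shp), TRUE), shp)
    d <- disc_from_levels(lev, L)
    gl <- build_glcms(d, 1)
    for (g in gl) {
      expect_equal(g$matrix, oracle_glcm(lev, g$direction, L), tolerance = 1e-10)
      expect_equal(sum(g$matrix), 1, tolerance = 1e-12)
    }
    dir <- dirs[[sample.int(13, 1)]]
    rl <- build_glrlm(d, dir)
    expect_equal(rl$matrix, oracle_glrlm(lev, dir, L), tolerance = 1e-10)
    # voxel conservation: sum over runs of level x length = voxel count
    expect_equal(sum(rl$matrix %*% seq_len(ncol(rl$matrix))), prod(shp))
  }
})

test_that("direction-averaged block is invariant to identity relabeling", {
  set.seed(44)
  lev <- array(sample.int(4, 64, TRUE), c(4, 4, 4))
  b1 <- petrad:::cooccurrence_feature_block(disc_from_levels(lev, 4))
  b2 <- petrad:::cooccurrence_feature_block(disc_from_levels(lev + 0L, 4))
  expect_identical(b1, b2)
  expect_match(names(b1), "__es_b4_d1_mean$")
})
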