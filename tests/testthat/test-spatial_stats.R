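test_that("radial profile localizes point sources and shells", {
  vox <- c(40, 40, 125)
  st <- array(0, c(40, 40, 10))
  ctr <- c(780, 780, 562.5)  # a voxel centre
  st <- synbracelet:::add_blob(st, ctr, rep(30, 3), 1e4, vox)
  prof <- radial_profile_3d(st, ctr, vox,
                            radial_profile_params(50, 700))
  expect_equal(prof$profile[1], 1)
  expect_lt(max(prof$profile[10:14], na.rm = TRUE), 0.05)

  # spherical shell of intensity at 250 nm radius
  sh <- array(0, c(40, 40, 10))
  n_dir <- 500
  set.seed(1)
  dirs <- matrix(rnorm(3 * n_dir), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (i in seq_len(n_dir)) {
    sh <- synbracelet:::add_blob(sh, ctr + 250 * dirs[i, ],
                                 rep(20, 3), 100, vox)
  }
  profs <- radial_profile_3d(sh, ctr, vox, radial_profile_params(50, 700))
  expect_equal(profs$bin_mid[which.max(profs$profile)], 275,
               tolerance = 55)
})

test_that("constant stacks give a degenerate all-zero profile with warning", {
  st <- array(5, c(20, 20, 5))
  expect_warning(
    prof <- radial_profile_3d(st, c(400, 400, 300), c(40, 40, 125),
                              radial_profile_params(50, 300)),
    "degenerate")
  expect_true(all(prof$profile == 0))
})

test_that("NN distances follow the sphere model and the exhaustive oracle", {
  A <- data.frame(cx = 0, cy = 0, cz = 0, radius = 0)
  B <- data.frame(cx = c(300, 500), cy = 0, cz = 0, radius = 0)
  expect_equal(as.numeric(nn_distances(A, B, "centre")), 300)
  # tangent spheres: surface distance 0
  At <- data.frame(cx = 0, cy = 0, cz = 0, radius = 100)
  Bt <- data.frame(cx = 250, cy = 0, cz = 0, radius = 150)
  expect_equal(as.numeric(nn_distances(At, Bt, "surface")), 0)
  set.seed(8)
  Ar <- data.frame(cx = runif(15, 0, 1000), cy = runif(15, 0, 1000),
                   cz = runif(15, 0, 1000), radius = runif(15, 10, 120))
  Br <- data.frame(cx = runif(9, 0, 1000), cy = runif(9, 0, 1000),
                   cz = runif(9, 0, 1000), radius = runif(9, 10, 120))
  expect_equal(as.numeric(nn_distances(Ar, Br, "surface")),
               brute_surface_nn(Ar, Br))
  # surface NN never exceeds centre NN; directionality differs
  expect_true(all(nn_distances(Ar, Br, "surface") <=
                    nn_distances(Ar, Br, "centre")))
  expect_error(nn_distances(Ar, Br[0, ], "centre"), "empty")
})

test_that("CSR realisations respect the sphere geometry", {
  set.seed(2)
  re <- csr_realisation(20, 20, sphere_diameter = 800)
  rA <- sqrt(re$A$cx^2 + re$A$cy^2 + re$A$cz^2)
  rB <- sqrt(re$B$cx^2 + re$B$cy^2 + re$B$cz^2)
  expect_true(all(rA <= 400))
  expect_equal(rB, rep(400, 20), tolerance = 1e-9)
  # any A-B centre distance bounded by the diameter
  d <- nn_distances(re$A, re$B, "centre")
  expect_true(all(d <= 800))
  expect_warning(csr_realisation(1, 1, radii_a = 500), "exceeds")
})

test_that("toroidal shift wraps at the field bounds and shifts by the set magnitude", {
  b <- c(0, 1000, 0, 1000)
  p <- toroidal_wrap(cbind(990, 0), c(20, 0), b)
  expect_equal(as.numeric(p), c(10, 0))
  expect_equal(toroidal_wrap(cbind(500, 500), c(0, 0), b),
               cbind(500, 500))
  A <- cbind(runif(10, 100, 900), runif(10, 100, 900))
  B <- A + 10
  res <- toroidal_shift_null(A, B, b, shift = 20, seed = 4)
  expect_equal(sqrt(sum(res$shift_vector^2)), 20)
  expect_error(toroidal_shift_null(A, B, b, shift = 0), "shift")
  expect_error(toroidal_shift_null(cbind(2000, 0), B, b), "bounds")
})

test_that("histogram aggregation equals the nested two-level oracle", {
  mk_hist <- function(counts) {
    data.frame(bin_lo = seq(0, by = 50, length.out = length(counts)),
               bin_hi = seq(50, by = 50, length.out = length(counts)),
               count = counts)
  }
  same <- mk_hist(c(3, 2, 1))
  agg <- aggregate_histograms(list(same, same, same, same),
                              experiment = c("e1", "e1", "e2", "e2"))
  expect_equal(agg$mean, c(3, 2, 1))
  expect_equal(agg$sem, c(0, 0, 0))
  expect_warning(
    one <- aggregate_histograms(list(same, same), c("e1", "e1")),
    "single experiment")
  expect_true(all(is.na(one$sem)))
  set.seed(6)
  counts <- matrix(rpois(8 * 5, 10), nrow = 8)
  exps <- rep(c("a", "b", "c", "d"), each = 2)
  hl <- lapply(seq_len(8), function(i) mk_hist(counts[i, ]))
  agg2 <- aggregate_histograms(hl, exps)
  oracle <- nested_mean_oracle(counts, exps)
  expect_equal(agg2$mean, unname(oracle$mean))
  expect_equal(agg2$sem, unname(oracle$sem))
  bad <- mk_hist(c(1, 2, 3)); bad$bin_lo <- bad$bin_lo + 1
  expect_error(aggregate_histograms(list(same, bad), c("a", "b")),
               "mismatched")
})

test_that("envelope orderings hold and observed-from-null data are covered", {
  set.seed(31)
  counts <- data.frame(n_a = pmax(1, rpois(30, 5)),
                       n_b = pmax(1, rpois(30, 5)))
  env <- csr_null(counts, csr_params(), mode = "centre", seed = 17)
  expect_true(all(env$lower <= env$null_mean + 1e-12))
  expect_true(all(env$null_mean <= env$upper + 1e-12))
  obs <- lapply(seq_len(nrow(counts)), function(s) {
    withr::with_seed(900 + s, {
      re <- csr_realisation(counts$n_a[s], counts$n_b[s],
                            sphere_diameter = 800)
      as.numeric(nn_distances(re$A, re$B, "centre"))
    })
  })
  oh <- observed_nn_histogram(obs)
  expect_gte(envelope_coverage(oh, env), 0.9)
})
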