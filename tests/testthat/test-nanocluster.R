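test_that("DBSCAN follows the min-points convention counting the point itself", {
  five <- matrix(0, 5, 2)
  cs <- detect_clusters_dbscan(five, cluster_params(20, 5))
  expect_equal(cs$labels, rep(1L, 5))
  four <- matrix(0, 4, 2)
  cs4 <- detect_clusters_dbscan(four, cluster_params(20, 5))
  expect_equal(cs4$labels, rep(0L, 4))
  empty <- detect_clusters_dbscan(matrix(numeric(0), 0, 2))
  expect_equal(length(empty$labels), 0L)
  expect_equal(nrow(empty$clusters), 0L)
})

test_that("DBSCAN partition equals the density-reachability oracle", {
  for (i in 1:25) {
    set.seed(i)
    n <- sample(20:120, 1)
    pts <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
    # add a few planted tight clusters so non-trivial structure exists
    for (k in 1:3) {
      c0 <- runif(2, 100, 900)
      pts <- rbind(pts, cbind(rnorm(8, c0[1], 8), rnorm(8, c0[2], 8)))
    }
    cs <- detect_clusters_dbscan(pts, cluster_params(20, 5))
    expect_equal(canonical_labels(cs$labels),
                 oracle_dbscan(pts, 20, 5))
  }
})

test_that("longest axis matches the exhaustive oracle and is rigid-motion invariant", {
  expect_equal(cluster_longest_axis(matrix(c(0, 0), 1, 2)), 0)
  expect_equal(cluster_longest_axis(rbind(c(0, 0), c(37, 0))), 37)
  set.seed(11)
  m <- cbind(rnorm(50), rnorm(50)) * 30
  expect_equal(cluster_longest_axis(m), brute_longest_axis(m))
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  m2 <- sweep(m %*% rot, 2, c(123, -456), "+")
  expect_equal(cluster_longest_axis(m2), cluster_longest_axis(m),
               tolerance = 1e-10)
})

test_that("size histogram uses half-open 15-nm bins with an overflow bin", {
  h <- size_histogram(c(10, 20, 431), bin_width = 15, overflow_cap = 400)
  expect_equal(h$count[1], 1L)  # [0,15)
  expect_equal(h$count[2], 1L)  # [15,30)
  expect_equal(h$count[h$overflow], 1L)
  expect_equal(sum(h$count), 3L)
  # bin boundary goes to the upper bin (half-open [lo, hi))
  hb <- size_histogram(15, bin_width = 15, overflow_cap = 400)
  expect_equal(hb$count[2], 1L)
  expect_equal(sum(size_histogram(numeric(0))$count), 0L)
  set.seed(5)
  v <- runif(500, 0, 600)
  expect_equal(sum(size_histogram(v)$count), 500L)
  expect_error(size_histogram(c(-1, 5)), "negative")
})

test_that("ring fit is exact on noiseless circles and flags degenerate input", {
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  circ <- cbind(400 * cos(th) + 50, 400 * sin(th) - 20)
  est <- estimate_ring_diameter(circ)
  expect_true(est$defined)
  expect_equal(est$diameter, 800, tolerance = 1e-9)
  expect_equal(est$residual, 0, tolerance = 1e-9)
  expect_equal(unname(est$centre), c(50, -20), tolerance = 1e-9)
  expect_false(estimate_ring_diameter(circ[1:2, ])$defined)
  line <- cbind(1:5 * 10, 1:5 * 10)
  expect_false(estimate_ring_diameter(line)$defined)
})

test_that("ring fit is unbiased on arbitrary non-collinear support", {
  set.seed(3)
  for (k in 1:10) {
    n <- sample(3:12, 1)
    th <- runif(n, 0, 2 * pi)
    r <- runif(1, 100, 600)
    c0 <- runif(2, -200, 200)
    est <- estimate_ring_diameter(cbind(c0[1] + r * cos(th),
                                        c0[2] + r * sin(th)))
    expect_equal(est$diameter, 2 * r, tolerance = 1e-6)
  }
})

test_that("bracelet score separates rings from collapsed or empty arrangements", {
  th <- (0:7) * pi / 4 + pi / 8
  ring <- cbind(400 * cos(th), 400 * sin(th))
  cs_ring <- build_fake_cluster_set(ring)
  res <- classify_bracelet(cs_ring, centre = c(0, 0))
  expect_true(res$bracelet)
  expect_equal(res$score, 1)
  coincident <- build_fake_cluster_set(matrix(0, 6, 2))
  res0 <- classify_bracelet(coincident, centre = c(0, 0))
  expect_false(res0$bracelet)
  none <- detect_clusters_dbscan(matrix(numeric(0), 0, 2))
  resn <- classify_bracelet(none, centre = c(0, 0))
  expect_false(resn$bracelet)
  expect_equal(resn$score, 0)
})
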