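vox_iso <- c(40, 40, 40)
vox_aniso <- c(40, 40, 125)

make_sphere_stack <- function(dim3, centre, radius, voxel, value = 100) {
  st <- array(0, dim3)
  synbracelet:::add_ball(st, centre, radius, value, voxel)
}

test_that("threshold segmentation finds spheres with analytic volumes", {
  st <- make_sphere_stack(c(40, 40, 40), c(800, 800, 800), 300, vox_iso)
  objs <- segment_by_threshold(st, vox_iso,
                               segmentation_params(gaussian_sigma = 20))
  expect_length(objs, 1L)
  expect_true(all(abs(objs[[1]]$centroid - 800) <= 40))
  v_true <- 4 / 3 * pi * 300^3 / 1e9
  expect_equal(objs[[1]]$volume, v_true, tolerance = 0.15)

  two <- make_sphere_stack(c(60, 60, 20), c(600, 600, 400), 250, vox_aniso)
  two <- synbracelet:::add_ball(two, c(1800, 1800, 2000), 250, 100,
                                vox_aniso)
  objs2 <- segment_by_threshold(two, vox_aniso,
                                segmentation_params(gaussian_sigma = 20))
  expect_length(objs2, 2L)
  v2 <- vapply(objs2, `[[`, numeric(1), "volume")
  expect_equal(v2, rep(4 / 3 * pi * 250^3 / 1e9, 2), tolerance = 0.15)
})

test_that("blank stacks yield no objects with a warning", {
  blank <- array(0, c(10, 10, 5))
  expect_warning(objs <- segment_by_threshold(blank, vox_iso),
                 "constant")
  expect_length(objs, 0L)
})

test_that("segmentation is intensity-scale invariant", {
  st <- make_sphere_stack(c(30, 30, 12), c(600, 600, 600), 250,
                          vox_aniso)
  set.seed(4)
  st <- st + array(abs(rnorm(length(st), 0, 0.5)), dim(st))
  o1 <- segment_by_threshold(st, vox_aniso,
                             segmentation_params(gaussian_sigma = 20))
  o2 <- segment_by_threshold(st * 37.5, vox_aniso,
                             segmentation_params(gaussian_sigma = 20))
  expect_equal(lapply(o1, `[[`, "voxels"), lapply(o2, `[[`, "voxels"))
})

test_that("sphericity formula matches closed forms on digitized solids", {
  # digitized cube: psi = (pi/6)^(1/3) ~ 0.806, retained by the filter
  cube <- array(0, c(20, 20, 20))
  cube[5:14, 5:14, 5:14] <- 1
  objs <- synbracelet:::objects_from_labels(
    synbracelet:::label_components(cube > 0), vox_iso)
  expect_length(objs, 1L)
  expect_equal(objs[[1]]$sphericity, (pi / 6)^(1 / 3), tolerance = 1e-6)
  expect_length(filter_objects(objs, 0.4, 1e-6), 1L)

  # 1-voxel-thick sheet: far below the sphericity floor, removed
  sheet <- array(0, c(30, 30, 6))
  sheet[3:28, 3:28, 3] <- 1
  sobjs <- synbracelet:::objects_from_labels(
    synbracelet:::label_components(sheet > 0), vox_iso)
  expect_lt(sobjs[[1]]$sphericity, 0.4)
  expect_length(suppressMessages(filter_objects(sobjs, 0.4, 1e-9)), 0L)
})

test_that("digitized-sphere sphericity approaches the face-count limit", {
  # face-count (Manhattan) surface area of a digitized sphere converges
  # to 1.5x the true area, so sphericity of a fine sphere approaches
  # 2/3 -- comfortably above the 0.4 filter floor at every resolution
  psi <- vapply(c(80, 40, 20), function(h) {
    vox <- rep(h, 3)
    st <- make_sphere_stack(rep(ceiling(1600 / h), 3),
                            rep(800, 3), 500, vox)
    objs <- synbracelet:::objects_from_labels(
      synbracelet:::label_components(st > 0), vox)
    objs[[1]]$sphericity
  }, numeric(1))
  expect_true(all(psi > 0.4))
  expect_equal(psi[3], 2 / 3, tolerance = 0.08)
})

test_that("equivalent-sphere radius inverts the sphere volume", {
  expect_equal(equivalent_sphere_radius(4.18879e-3), 100,
               tolerance = 1e-4)
  expect_equal(equivalent_sphere_radius(0), 0)
  expect_error(equivalent_sphere_radius(-1), "negative")
  set.seed(2)
  v <- runif(20, 1e-4, 1)
  r <- equivalent_sphere_radius(v)
  expect_equal(4 / 3 * pi * r^3 / 1e9, v, tolerance = 1e-12)
})

test_that("blob finder splits fused blobs when h lies below the saddle", {
  vox <- c(40, 40, 125)
  st <- array(0, c(60, 60, 10))
  st <- synbracelet:::add_blob(st, c(1200, 900, 625), rep(100, 3), 1e5,
                               vox)
  st <- synbracelet:::add_blob(st, c(1200, 1400, 625), rep(100, 3), 1e5,
                               vox)
  # constructed saddle-height oracle in the robust z-units the watershed
  # uses: peak and saddle of the smoothed z-scored stack
  z0 <- array(synbracelet:::robust_z(st), dim(st))
  zs <- synbracelet:::gaussian_filter(z0, (500 / 4) / vox)
  peak <- max(zs)
  saddle <- max(zs[, 29, ])  # column between the two blob centres
  depth <- peak - saddle
  split <- suppressMessages(blob_find_anchors(
    st, vox, segmentation_params(blob_watershed_level = depth / 2,
                                 min_volume = 1e-4)))
  merged <- suppressMessages(blob_find_anchors(
    st, vox, segmentation_params(blob_watershed_level = 2 * depth,
                                 min_volume = 1e-4)))
  expect_length(split, 2L)
  expect_length(merged, 1L)
})

test_that("blob finder locates isolated anchors", {
  vox <- c(40, 40, 125)
  set.seed(9)
  st <- array(rnorm(60 * 60 * 10, 0, 1), c(60, 60, 10))
  st <- synbracelet:::add_ball(st, c(1000, 1000, 625), 224, 100, vox)
  a <- suppressMessages(blob_find_anchors(st, vox))
  expect_length(a, 1L)
  expect_true(all(abs(a[[1]]$centroid - c(1000, 1000, 625)) <=
                    c(60, 60, 150)))
  blank <- array(rnorm(60 * 60 * 10, 0, 1), c(60, 60, 10))
  expect_length(suppressMessages(blob_find_anchors(blank, vox)), 0L)
})

test_that("synapse assembly respects the distance cutoff", {
  mk <- function(centre) {
    structure(list(centroid = centre, volume = 0.01,
                   equivalent_radius = 100, sphericity = 0.9,
                   n_voxels = 10, voxels = NULL, voxel_size = vox_iso),
              class = "segmented_object")
  }
  anchor <- mk(c(0, 0, 0))
  near <- mk(c(1000, 0, 0))
  far <- mk(c(3000, 0, 0))
  res <- assemble_synapses(list(anchor),
                           list(MPP2 = list(near),
                                SynCAM1 = list(near)),
                           cutoff = 2500)
  expect_true(res$synapses[[1]]$complete)
  expect_equal(res$completeness_fraction, 1)
  res2 <- assemble_synapses(list(anchor),
                            list(MPP2 = list(near),
                                 SynCAM1 = list(far)),
                            cutoff = 2500)
  expect_false(res2$synapses[[1]]$complete)
  expect_equal(assemble_synapses(list(), list())$completeness_fraction,
               NA_real_)
})

test_that("TIFF stack round-trip preserves relative intensities", {
  st <- list(ch = array(runif(20 * 20 * 4), c(20, 20, 4)))
  d <- withr::local_tempdir()
  write_stack_tiff(st, d)
  back <- read_stack_tiff(file.path(d, "ch.tif"))
  expect_equal(dim(back), c(20, 20, 4))
  rng <- range(st$ch)
  expect_equal(back, (st$ch - rng[1]) / diff(rng), tolerance = 1e-6)
})
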