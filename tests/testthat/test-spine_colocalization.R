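test_that("dendrite skeletonization thins a bar to its midline", {
  img <- matrix(0, 120, 450)
  img[50:69, 25:424] <- 100  # 20 px wide, 400 px long bar
  img <- img + matrix(abs(rnorm(length(img), 0, 0.5)), nrow(img))
  sk <- skeletonize_dendrite(img)
  expect_true(sum(sk) > 0)
  # thinning erodes each end by about half the bar width; the skeleton
  # length stays within that bound of the bar length
  expect_gte(sum(sk), 400 - 20 - 5)
  expect_lte(sum(sk), 405)
  expect_true(all(which(sk) %in% which(img > 50)))
  # skeleton rows near the bar midline
  rows <- arrayInd(which(sk), dim(sk))[, 1]
  expect_true(all(abs(rows - 59.5) <= 2))
})

test_that("blank images yield an empty skeleton with a warning", {
  expect_warning(sk <- skeletonize_dendrite(matrix(0, 30, 30)), "empty")
  expect_false(any(sk))
})

test_that("puncta detection finds isolated and nearby spots", {
  px <- 70
  img <- matrix(0, 128, 128)
  img <- synbracelet:::add_spot_2d(img, c(50.5, 70.5) * px, 150, 100, px)
  img <- img + matrix(rnorm(length(img), 0, 2), nrow(img))
  p <- detect_puncta(img, spine_params(pixel_size = px))
  expect_equal(nrow(p), 1L)
  expect_true(abs(p[1, "x"] - 50.5 * px) <= px &&
                abs(p[1, "y"] - 70.5 * px) <= px)

  two <- matrix(0, 128, 128)
  two <- synbracelet:::add_spot_2d(two, c(40, 60) * px, 2 * px, 100, px)
  two <- synbracelet:::add_spot_2d(two, c(50, 60) * px, 2 * px, 100, px)
  two <- two + matrix(rnorm(length(two), 0, 2), nrow(two))
  p2 <- detect_puncta(two, spine_params(pixel_size = px))
  expect_equal(nrow(p2), 2L)

  # pure-noise channel: no punctate structure reported
  noise <- matrix(rnorm(128 * 128, 0, 2), 128, 128)
  expect_equal(nrow(detect_puncta(noise,
                                  spine_params(pixel_size = px))), 0L)
})

test_that("detected counts track planted counts on synthetic scenes", {
  scn <- simulate_confocal_scene(
    confocal_scene_config(n_homer_spines = 30L), seed = 5)
  p <- detect_puncta(scn$images$Homer1,
                     spine_params(pixel_size = scn$pixel_size),
                     "Homer1")
  expect_equal(nrow(p), 30L, tolerance = 0.04)
})

test_that("skeleton proximity filter applies the 2-um periphery", {
  sk <- matrix(FALSE, 100, 100)
  sk[50, 10:90] <- TRUE  # horizontal skeleton at y = 49.5 px
  px <- 70
  puncta <- rbind(c(x = 50 * px, y = 49.5 * px + 1000),   # 1 um away
                  c(x = 50 * px, y = 49.5 * px + 3000))   # 3 um away
  colnames(puncta) <- c("x", "y")
  kept <- filter_near_skeleton(puncta, sk, 2000, px)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept[1, "y"], 49.5 * px + 1000, ignore_attr = TRUE)
  all_kept <- filter_near_skeleton(puncta, sk, Inf, px)
  expect_equal(nrow(all_kept), 2L)
  expect_warning(
    none <- filter_near_skeleton(puncta, matrix(FALSE, 5, 5), 2000, px),
    "empty skeleton")
  expect_equal(nrow(none), 0L)
})

test_that("co-occurrence scoring uses the 0.5-um spine radius", {
  homer <- cbind(x = 0, y = 0)
  mpp2 <- cbind(x = 300, y = 0)
  near_gaba <- cbind(x = 0, y = 400)
  far_gaba <- cbind(x = 0, y = 600)
  pos <- score_cooccurrence(homer, mpp2, near_gaba, radius = 500)
  expect_true(pos$records$positive[1])
  expect_equal(pos$fraction, 1)
  neg <- score_cooccurrence(homer, mpp2, far_gaba, radius = 500)
  expect_false(neg$records$positive[1])
  none <- score_cooccurrence(homer[0, , drop = FALSE], mpp2, near_gaba)
  expect_false(none$defined)
  expect_true(is.na(none$fraction))
})

test_that("fraction is monotone in the co-occurrence radius", {
  set.seed(12)
  homer <- cbind(x = runif(30, 0, 5000), y = runif(30, 0, 5000))
  mpp2 <- cbind(x = runif(30, 0, 5000), y = runif(30, 0, 5000))
  gaba <- cbind(x = runif(30, 0, 5000), y = runif(30, 0, 5000))
  fr <- vapply(c(200, 500, 1000, 2500),
               function(r) score_cooccurrence(homer, mpp2, gaba,
                                              r)$fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("end-to-end spine pipeline recovers the planted fraction", {
  scn <- simulate_confocal_scene(
    confocal_scene_config(cooccurrence_fraction = 0.2), seed = 21)
  res <- analyze_spine_scene(scn$images)
  expect_equal(res$fraction, mean(scn$truth$positive), tolerance = 0.06)
})
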