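#' Synthetic data generators with ground truth
#'
#' Every input the analysis pipeline consumes can be generated
#' synthetically with a known ground-truth record: bracelet-arranged
#' localization tables (dSTORM-like), multi-channel 3D voxel scenes
#' (SIM-like), confocal spine scenes, and two-replicate inverted-label
#' peptide ratio tables. Generator defaults encode the study conditions:
#' a central PSD disc of 448 nm diameter surrounded by peripheral
#' nanocluster rings of 894 nm (SynCAM1-like species) and 791 nm
#' (MPP2-like species) diameter, a 65% prevalence of the bracelet
#' morphology, and a pulled-down proteome of 188 stably quantified
#' proteins of which 7 GABA-A receptor subunits are enriched more than
#' 7-fold on the MPP2 side.
#'
#' @name synthetic_data
NULL

#' Bracelet synapse geometry
#'
#' @param psd_disc_diameter central disc diameter, nm.
#' @param ring_diameter_species_A,ring_diameter_species_B diameters of
#'   the two peripheral nanocluster rings, nm.
#' @param n_satellites_per_species number of satellite clusters per ring.
#' @param satellite_radius Gaussian sigma of one satellite cluster, nm.
#' @param locs_per_satellite localizations per satellite cluster.
#' @param locs_in_disc localizations in the central disc.
#' @param precision_mean,precision_sd per-localization precision draw
#'   (normal, truncated at > 0), nm.
#' @param background_density background localizations per um^2.
#' @param bracelet_probability probability that a synapse carries the
#'   bracelet morphology (otherwise peripheral species are uniform in a
#'   disc of their ring diameter).
#' @param angular_jitter_sd SD of angular jitter of satellite positions,
#'   radians.
#' @param field_half_width half-width of the simulated field around the
#'   synapse centre, nm.
#' @export
bracelet_geometry <- function(psd_disc_diameter = 448,
                              ring_diameter_species_A = 894,
                              ring_diameter_species_B = 791,
                              n_satellites_per_species = 6,
                              satellite_radius = 40,
                              locs_per_satellite = 50,
                              locs_in_disc = 200,
                              precision_mean = 10, precision_sd = 4,
                              background_density = 5,
                              bracelet_probability = 0.65,
                              angular_jitter_sd = 0.15,
                              field_half_width = 800) {
  g <- list(psd_disc_diameter = psd_disc_diameter,
            ring_diameter_species_A = ring_diameter_species_A,
            ring_diameter_species_B = ring_diameter_species_B,
            n_satellites_per_species = n_satellites_per_species,
            satellite_radius = satellite_radius,
            locs_per_satellite = locs_per_satellite,
            locs_in_disc = locs_in_disc,
            precision_mean = precision_mean, precision_sd = precision_sd,
            background_density = background_density,
            bracelet_probability = bracelet_probability,
            angular_jitter_sd = angular_jitter_sd,
            field_half_width = field_half_width)
  num <- unlist(g)
  if (!all(is.finite(num))) stop("non-finite geometry value")
  lens <- c(psd_disc_diameter, ring_diameter_species_A,
            ring_diameter_species_B, satellite_radius, field_half_width)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (ring_diameter_species_A <= psd_disc_diameter ||
      ring_diameter_species_B <= psd_disc_diameter) {
    stop("ring diameters must exceed psd_disc_diameter")
  }
  if (bracelet_probability < 0 || bracelet_probability > 1) {
    stop("bracelet_probability must be in [0, 1]")
  }
  structure(g, class = "bracelet_geometry")
}

# uniform points in a disc of given radius centred at origin
runif_disc <- function(n, radius) {
  r <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

rprecision <- function(n, mean, sd) {
  p <- stats::rnorm(n, mean, sd)
  while (any(p <= 0)) p[p <= 0] <- stats::rnorm(sum(p <= 0), mean, sd)
  p
}

# one peripheral species: satellites on a ring, or uniform when
# the synapse is not bracelet-like
sim_peripheral_species <- function(geometry, ring_diameter, bracelet,
                                   channel) {
  g <- geometry
  n_sat <- g$n_satellites_per_species
  if (bracelet) {
    phase <- stats::runif(1, 0, 2 * pi)
    angles <- phase + 2 * pi * (seq_len(n_sat) - 1) / n_sat +
      stats::rnorm(n_sat, 0, g$angular_jitter_sd)
    centres <- cbind(x = ring_diameter / 2 * cos(angles),
                     y = ring_diameter / 2 * sin(angles))
    pts <- do.call(rbind, lapply(seq_len(n_sat), function(i) {
      cbind(x = stats::rnorm(g$locs_per_satellite, centres[i, 1],
                             g$satellite_radius),
            y = stats::rnorm(g$locs_per_satellite, centres[i, 2],
                             g$satellite_radius))
    }))
  } else {
    centres <- NULL
    pts <- runif_disc(n_sat * g$locs_per_satellite, ring_diameter / 2)
  }
  list(points = pts, satellite_centres = centres)
}

add_background <- function(pts, geometry) {
  g <- geometry
  area_um2 <- (2 * g$field_half_width / 1000)^2
  n_bg <- stats::rpois(1, g$background_density * area_um2)
  if (n_bg > 0) {
    bg <- cbind(x = stats::runif(n_bg, -g$field_half_width,
                                 g$field_half_width),
                y = stats::runif(n_bg, -g$field_half_width,
                                 g$field_half_width))
    pts <- rbind(pts, bg)
  }
  pts
}

finish_species_table <- function(pts, geometry, channel) {
  n <- nrow(pts)
  prec <- rprecision(n, geometry$precision_mean, geometry$precision_sd)
  localization_table(
    x = pts[, 1] + stats::rnorm(n, 0, prec),
    y = pts[, 2] + stats::rnorm(n, 0, prec),
    frame = seq_len(n), uncertainty = prec, channel = channel)
}

#' Simulate one bracelet-like synapse as localization tables
#'
#' Central-species localizations are uniform in a disc; the two
#' peripheral species form rings of satellite Gaussian clusters (or are
#' placed uniformly when the synapse is drawn as non-bracelet).
#' Per-localization precision is drawn, added as positional jitter, and
#' recorded in the uncertainty column. The true synapse centre is at
#' (0, 0).
#'
#' @param geometry a [bracelet_geometry()].
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `localizations` (named list of
#'   [localization_table()]s for channels `PSD95`, `SynCAM1`, `MPP2`)
#'   and `truth` (centre, ring diameters, bracelet flag, satellite
#'   centres).
#' @export
simulate_bracelet_synapse <- function(geometry = bracelet_geometry(),
                                      seed = 1L) {
  stopifnot(inherits(geometry, "bracelet_geometry"))
  withr::with_seed(seed, {
    g <- geometry
    bracelet <- stats::runif(1) < g$bracelet_probability
    central_pts <- runif_disc(g$locs_in_disc, g$psd_disc_diameter / 2)
    spA <- sim_peripheral_species(g, g$ring_diameter_species_A, bracelet,
                                  "SynCAM1")
    spB <- sim_peripheral_species(g, g$ring_diameter_species_B, bracelet,
                                  "MPP2")
    tabs <- list(
      PSD95 = finish_species_table(add_background(central_pts, g), g,
                                   "PSD95"),
      SynCAM1 = finish_species_table(add_background(spA$points, g), g,
                                     "SynCAM1"),
      MPP2 = finish_species_table(add_background(spB$points, g), g,
                                  "MPP2"))
    truth <- list(
      centre = c(x = 0, y = 0),
      psd_disc_diameter = g$psd_disc_diameter,
      ring_diameters = c(SynCAM1 = g$ring_diameter_species_A,
                         MPP2 = g$ring_diameter_species_B),
      bracelet = bracelet,
      satellite_centres = list(SynCAM1 = spA$satellite_centres,
                               MPP2 = spB$satellite_centres))
    list(localizations = tabs, truth = truth)
  })
}

#' Voxel scene configuration (SIM-like 3D stacks)
#'
#' @param voxel_size_xy,voxel_size_z voxel edge lengths, nm (axial
#'   anisotropy allowed; `voxel_size_z >= voxel_size_xy`).
#' @param field_size integer vector `c(ny, nx, nz)` of stack dimensions.
#' @param psf_sigma Gaussian blur sigma applied to each channel, nm.
#' @param channel_names ordered channel labels.
#' @param photon_scale intensity scale of rendered structures.
#' @param noise_sd additive Gaussian noise SD, intensity units.
#' @export
voxel_scene_config <- function(voxel_size_xy = 40, voxel_size_z = 125,
                               field_size = c(96L, 96L, 20L),
                               psf_sigma = 60,
                               channel_names = c("PSD95", "MPP2",
                                                 "SynCAM1", "vGlut1"),
                               photon_scale = 100, noise_sd = 1) {
  stopifnot(voxel_size_xy > 0, voxel_size_z >= voxel_size_xy,
            length(field_size) == 3L)
  structure(list(voxel_size_xy = voxel_size_xy,
                 voxel_size_z = voxel_size_z,
                 field_size = as.integer(field_size),
                 psf_sigma = psf_sigma, channel_names = channel_names,
                 photon_scale = photon_scale, noise_sd = noise_sd),
            class = "voxel_scene_config")
}

# add a Gaussian blob of total mass `amp` at world position `centre` (nm)
add_blob <- function(stack, centre, sigma, amp, voxel) {
  d <- dim(stack)
  ctr_vox <- centre / voxel + 0.5  # world -> (fractional) voxel index
  half <- ceiling(3 * sigma / voxel) + 1L
  rng <- lapply(1:3, function(j) {
    max(1L, floor(ctr_vox[j] - half[j])):min(d[j], ceiling(ctr_vox[j] + half[j]))
  })
  if (any(lengths(rng) == 0)) return(stack)
  g <- lapply(1:3, function(j) {
    u <- (rng[[j]] - 0.5) * voxel[j]
    stats::pnorm(u + voxel[j] / 2, centre[j], sigma[j]) -
      stats::pnorm(u - voxel[j] / 2, centre[j], sigma[j])
  })
  blob <- amp * outer(outer(g[[1]], g[[2]]), g[[3]])
  stack[rng[[1]], rng[[2]], rng[[3]]] <-
    stack[rng[[1]], rng[[2]], rng[[3]]] + blob
  stack
}

# add a uniform ball of intensity `value` (per voxel) at `centre`
add_ball <- function(stack, centre, radius, value, voxel) {
  d <- dim(stack)
  rng <- lapply(1:3, function(j) {
    lo <- max(1L, floor((centre[j] - radius) / voxel[j]))
    hi <- min(d[j], ceiling((centre[j] + radius) / voxel[j]) + 1L)
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(rng) == 0)) return(stack)
  w <- lapply(1:3, function(j) (rng[[j]] - 0.5) * voxel[j] - centre[j])
  d2 <- outer(outer(w[[1]]^2, w[[2]]^2, "+"), w[[3]]^2, "+")
  inside <- d2 <= radius^2
  sub <- stack[rng[[1]], rng[[2]], rng[[3]]]
  sub[inside] <- sub[inside] + value
  stack[rng[[1]], rng[[2]], rng[[3]]] <- sub
  stack
}

# random rotation of ring plane: returns two orthonormal in-plane axes
random_ring_plane <- function() {
  v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))  # normal
  a <- c(1, 0, 0)
  if (abs(sum(a * v)) > 0.9) a <- c(0, 1, 0)
  e1 <- a - sum(a * v) * v; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2, normal = v)
}

#' Simulate a multi-channel 3D voxel scene of bracelet synapses
#'
#' Each synapse consists of a central uniform PSD-95 ball (diameter =
#' `geometry$psd_disc_diameter`), peripheral MPP2 / SynCAM1 satellite
#' blobs on rings of the configured diameters lying in a randomly
#' oriented plane, and one vGlut1 blob adjacent to the centre. Channels
#' are blurred with the configured PSF sigma and additive Gaussian noise
#' is applied. Synapse centres are placed on a jittered grid so that
#' synapses never overlap at the bracelet scale.
#'
#' @param config a [voxel_scene_config()].
#' @param geometry a [bracelet_geometry()].
#' @param n_synapses number of synapses to place.
#' @param seed integer seed.
#' @return list with `stack` (named list of 3D arrays, dims
#'   `c(ny, nx, nz)`), `voxel_size` (nm per axis, y/x/z), and `truth`
#'   (per-synapse centres in nm, ring diameters, satellite centres).
#' @export
simulate_voxel_scene <- function(config = voxel_scene_config(),
                                 geometry = bracelet_geometry(),
                                 n_synapses = 4L, seed = 1L) {
  stopifnot(inherits(config, "voxel_scene_config"))
  withr::with_seed(seed, {
    d <- config$field_size
    voxel <- c(config$voxel_size_xy, config$voxel_size_xy,
               config$voxel_size_z)
    extent <- d * voxel
    margin <- geometry$ring_diameter_species_A / 2 + 3 * config$psf_sigma
    spacing <- 2 * margin
    nx_slots <- floor((extent[2] - 2 * margin) / spacing) + 1
    ny_slots <- floor((extent[1] - 2 * margin) / spacing) + 1
    capacity <- max(0, nx_slots) * max(0, ny_slots)
    if (n_synapses > capacity) {
      stop(sprintf(
        "cannot place %d synapses without overlap; at most %d fit",
        n_synapses, capacity))
    }
    stacks <- stats::setNames(
      lapply(config$channel_names, function(ch) array(0, d)),
      config$channel_names)
    truth <- list()
    zc <- extent[3] / 2
    slot <- 0L
    for (s in seq_len(n_synapses)) {
      ix <- slot %% nx_slots; iy <- slot %/% nx_slots; slot <- slot + 1L
      centre <- c(margin + iy * spacing +
                    stats::runif(1, -0.1, 0.1) * margin,   # y (rows)
                  margin + ix * spacing +
                    stats::runif(1, -0.1, 0.1) * margin,   # x (cols)
                  zc + stats::runif(1, -0.5, 0.5) * voxel[3])
      plane <- random_ring_plane()
      amp <- config$photon_scale
      stacks$PSD95 <- add_ball(stacks$PSD95, centre,
                               geometry$psd_disc_diameter / 2, amp, voxel)
      sat_truth <- list()
      for (sp in c("MPP2", "SynCAM1")) {
        ring_d <- if (sp == "SynCAM1") geometry$ring_diameter_species_A
                  else geometry$ring_diameter_species_B
        n_sat <- geometry$n_satellites_per_species
        phase <- stats::runif(1, 0, 2 * pi)
        angles <- phase + 2 * pi * (seq_len(n_sat) - 1) / n_sat
        cents <- t(vapply(angles, function(a) {
          centre + ring_d / 2 * (cos(a) * plane$e1 + sin(a) * plane$e2)
        }, numeric(3)))
        for (i in seq_len(n_sat)) {
          stacks[[sp]] <- add_blob(
            stacks[[sp]], cents[i, ],
            rep(geometry$satellite_radius, 3),
            amp * geometry$locs_per_satellite, voxel)
        }
        sat_truth[[sp]] <- cents
      }
      vg_centre <- centre + (geometry$psd_disc_diameter / 2 + 100) *
        plane$normal
      stacks$vGlut1 <- add_blob(stacks$vGlut1, vg_centre, rep(80, 3),
                                amp * 50, voxel)
      truth[[s]] <- list(centre = centre,
                         ring_diameters = c(
                           SynCAM1 = geometry$ring_diameter_species_A,
                           MPP2 = geometry$ring_diameter_species_B),
                         psd_radius = geometry$psd_disc_diameter / 2,
                         satellite_centres = sat_truth,
                         vglut1_centre = vg_centre)
    }
    sig_vox <- config$psf_sigma / voxel
    for (ch in names(stacks)) {
      if (config$psf_sigma > 0 && ch != "PSD95") {
        # satellite blobs already carry their own width; apply PSF to the
        # structured channels uniformly for realism
        stacks[[ch]] <- gaussian_filter(stacks[[ch]], sig_vox)
      } else if (config$psf_sigma > 0 && ch == "PSD95") {
        stacks[[ch]] <- gaussian_filter(stacks[[ch]], sig_vox)
      }
      if (config$noise_sd > 0) {
        stacks[[ch]] <- stacks[[ch]] +
          array(stats::rnorm(prod(d), 0, config$noise_sd), d)
      }
    }
    list(stack = stacks, voxel_size = voxel, truth = truth)
  })
}

#' Confocal scene configuration
#'
#' @param pixel_size nm per pixel.
#' @param image_size `c(ny, nx)` pixels.
#' @param dendrite_path polyline matrix (columns x, y, in nm); default a
#'   gentle diagonal across the field.
#' @param n_homer_spines number of Homer1-positive spines.
#' @param cooccurrence_fraction fraction of Homer spines that also carry
#'   MPP2 and GABA-A receptor puncta.
#' @param off_dendrite_puncta_density GABA-A-only shaft puncta per um^2.
#' @param spot_sigma punctum Gaussian sigma, nm.
#' @param spine_spacing minimum spacing of Homer spines along the
#'   dendrite, nm.
#' @param amplitude,noise_sd punctum intensity and background noise SD.
#' @export
confocal_scene_config <- function(pixel_size = 70,
                                  image_size = c(256L, 256L),
                                  dendrite_path = NULL,
                                  n_homer_spines = 20L,
                                  cooccurrence_fraction = 0.2,
                                  off_dendrite_puncta_density = 0.05,
                                  spot_sigma = 150,
                                  spine_spacing = 1500,
                                  amplitude = 100, noise_sd = 2) {
  stopifnot(pixel_size > 0,
            cooccurrence_fraction >= 0, cooccurrence_fraction <= 1)
  extent <- rev(image_size) * pixel_size  # c(x, y)
  if (is.null(dendrite_path)) {
    dendrite_path <- cbind(
      x = c(0.1, 0.9) * extent[1],
      y = c(0.2, 0.8) * extent[2])
  }
  if (any(dendrite_path[, 1] < 0 | dendrite_path[, 1] > extent[1] |
          dendrite_path[, 2] < 0 | dendrite_path[, 2] > extent[2])) {
    stop("dendrite polyline outside image bounds")
  }
  structure(list(pixel_size = pixel_size,
                 image_size = as.integer(image_size),
                 dendrite_path = dendrite_path,
                 n_homer_spines = as.integer(n_homer_spines),
                 cooccurrence_fraction = cooccurrence_fraction,
                 off_dendrite_puncta_density = off_dendrite_puncta_density,
                 spot_sigma = spot_sigma, spine_spacing = spine_spacing,
                 amplitude = amplitude, noise_sd = noise_sd),
            class = "confocal_scene_config")
}

# sample points along a polyline at arclength positions
polyline_point <- function(path, t) {
  seg <- sqrt(diff(path[, 1])^2 + diff(path[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  s <- t * total
  i <- pmin(findInterval(s, cum, all.inside = TRUE), length(seg))
  f <- (s - cum[i]) / seg[i]
  cbind(x = path[i, 1] + f * (path[i + 1, 1] - path[i, 1]),
        y = path[i, 2] + f * (path[i + 1, 2] - path[i, 2]))
}

add_spot_2d <- function(img, centre, sigma, amp, px) {
  ny <- nrow(img); nx <- ncol(img)
  half <- ceiling(3 * sigma / px) + 1L
  jc <- floor(centre[1] / px) + 1L
  ic <- floor(centre[2] / px) + 1L
  js <- max(1L, jc - half):min(nx, jc + half)
  is <- max(1L, ic - half):min(ny, ic + half)
  if (!length(js) || !length(is)) return(img)
  gx <- stats::pnorm(js * px, centre[1], sigma) -
    stats::pnorm((js - 1) * px, centre[1], sigma)
  gy <- stats::pnorm(is * px, centre[2], sigma) -
    stats::pnorm((is - 1) * px, centre[2], sigma)
  # scale so `amp` is the peak pixel value, not the integrated mass
  peak_scale <- 2 * pi * sigma^2 / px^2
  img[is, js] <- img[is, js] + amp * peak_scale * outer(gy, gx)
  img
}

#' Simulate a confocal spine scene
#'
#' The MAP2 channel renders the dendrite polyline as a thick filament;
#' Homer1 puncta are placed near the dendrite; a configured fraction of
#' them receives MPP2 and GABA-A receptor puncta within 250 nm
#' (triple-positive spines), the rest receive MPP2 only; additional
#' GABA-A-only puncta sit on the dendrite shaft. Truth records each
#' spine's class.
#'
#' @param config a [confocal_scene_config()].
#' @param seed integer seed.
#' @return list with `images` (named list of matrices: MAP2, Homer1,
#'   MPP2, GABAAR), `pixel_size`, and `truth` (data.frame of spine
#'   positions and co-occurrence flags).
#' @export
simulate_confocal_scene <- function(config = confocal_scene_config(),
                                    seed = 1L) {
  stopifnot(inherits(config, "confocal_scene_config"))
  withr::with_seed(seed, {
    cfg <- config
    px <- cfg$pixel_size
    ny <- cfg$image_size[1]; nx <- cfg$image_size[2]
    blank <- matrix(0, ny, nx)
    images <- list(MAP2 = blank, Homer1 = blank, MPP2 = blank,
                   GABAAR = blank)
    # MAP2 filament: dense spots along the polyline, width ~ 2 px
    tt <- seq(0, 1, length.out = 400)
    pp <- polyline_point(cfg$dendrite_path, tt)
    for (i in seq_len(nrow(pp))) {
      images$MAP2 <- add_spot_2d(images$MAP2, pp[i, ], 1.5 * px,
                                 cfg$amplitude / 4, px)
    }
    n <- cfg$n_homer_spines
    truth <- NULL
    if (n > 0) {
      # spines spread along the dendrite with jitter perpendicular to it
      t_pos <- (seq_len(n) - 0.5) / n
      base <- polyline_point(cfg$dendrite_path, t_pos)
      offs <- stats::runif(n, 400, 1200)       # spine neck length, nm
      # alternate sides so consecutive spines stay well separated and a
      # neighbouring spine's partner puncta cannot fall into this
      # spine's co-occurrence radius
      side <- rep_len(c(-1, 1), n)
      dir <- polyline_point(cfg$dendrite_path, pmin(t_pos + 0.01, 1)) -
        polyline_point(cfg$dendrite_path, pmax(t_pos - 0.01, 0))
      nrm <- cbind(-dir[, 2], dir[, 1]) /
        sqrt(rowSums(dir^2))
      homer <- base + nrm * (side * offs)
      homer[, 1] <- pmin(pmax(homer[, 1], 2 * px), (nx - 2) * px)
      homer[, 2] <- pmin(pmax(homer[, 2], 2 * px), (ny - 2) * px)
      n_pos <- round(cfg$cooccurrence_fraction * n)
      positive <- rep(FALSE, n)
      if (n_pos > 0) positive[sample.int(n, n_pos)] <- TRUE
      place_near <- function(p) {
        ang <- stats::runif(1, 0, 2 * pi)
        r <- stats::runif(1, 0, 250)
        p + r * c(cos(ang), sin(ang))
      }
      mpp2 <- t(apply(homer, 1, place_near))
      gaba <- t(apply(homer, 1, place_near))
      for (i in seq_len(n)) {
        images$Homer1 <- add_spot_2d(images$Homer1, homer[i, ],
                                     cfg$spot_sigma, cfg$amplitude, px)
        images$MPP2 <- add_spot_2d(images$MPP2, mpp2[i, ],
                                   cfg$spot_sigma, cfg$amplitude, px)
        if (positive[i]) {
          images$GABAAR <- add_spot_2d(images$GABAAR, gaba[i, ],
                                       cfg$spot_sigma, cfg$amplitude, px)
        }
      }
      truth <- data.frame(x = homer[, 1], y = homer[, 2],
                          positive = positive)
    } else {
      truth <- data.frame(x = numeric(0), y = numeric(0),
                          positive = logical(0))
    }
    # GABA-A-only puncta on the shaft, kept away from Homer spines so a
    # shaft punctum does not fall into a spine's co-occurrence radius
    area_um2 <- (nx * px / 1000) * (ny * px / 1000)
    n_shaft <- stats::rpois(1, cfg$off_dendrite_puncta_density * area_um2)
    placed <- 0L; tries <- 0L
    while (placed < n_shaft && tries < 50 * n_shaft) {
      tries <- tries + 1L
      p <- polyline_point(cfg$dendrite_path, stats::runif(1))[1, ]
      if (nrow(truth) == 0 ||
          min(sqrt((truth$x - p[1])^2 + (truth$y - p[2])^2)) > 800) {
        images$GABAAR <- add_spot_2d(images$GABAAR, p, cfg$spot_sigma,
                                     cfg$amplitude, px)
        placed <- placed + 1L
      }
    }
    if (cfg$noise_sd > 0) {
      for (ch in names(images)) {
        images[[ch]] <- images[[ch]] +
          matrix(stats::rnorm(ny * nx, 0, cfg$noise_sd), ny, nx)
      }
    }
    list(images = images, pixel_size = px, truth = truth)
  })
}

#' Peptide table configuration (two-replicate inverted-label design)
#'
#' Defaults emulate the comparative SH3GK pull-down dataset: 188 stably
#' quantified proteins including GST (for normalization), 7 GABA-A
#' receptor subunits planted above 7-fold enrichment on the MPP2 side,
#' a handful of strong PSD-95-side interactors, a majority of background
#' proteins with ratios near 1, plus unstable proteins that the
#' quantification filters are expected to remove.
#'
#' @param n_proteins number of stable (filter-passing) interacting
#'   proteins; GST is generated in addition and not counted.
#' @param mpp2_enriched named numeric vector of planted MPP2-side fold
#'   enrichments (> 1 means enriched towards MPP2).
#' @param psd95_enriched named numeric vector of planted PSD-95-side
#'   fold enrichments.
#' @param background_log2_sd SD of background true log2 ratios
#'   (truncated to less than 5-fold).
#' @param peptides_per_protein_range inclusive range of quantified
#'   peptides per protein and replicate.
#' @param peptide_log_ratio_noise_sd SD of multiplicative log-normal
#'   peptide ratio noise (natural log scale).
#' @param intensity_meanlog,intensity_sdlog log-normal peptide intensity
#'   parameters.
#' @param gst_true_ratio true (pre-normalization) GST ratio.
#' @param n_single_replicate,n_high_dispersion numbers of planted
#'   filter-failing proteins.
#' @export
peptide_table_config <- function(
    n_proteins = 188L,
    mpp2_enriched = c(Gabra1 = 14, Gabra2 = 12, Gabra4 = 11, Gabrb1 = 13,
                      Gabrb2 = 12, Gabrb3 = 16, Gabrd = 10),
    psd95_enriched = c(Map1a = 12, Mecp2 = 10, Camk2a = 11, Fxr1 = 10),
    background_log2_sd = 0.6,
    peptides_per_protein_range = c(2L, 8L),
    peptide_log_ratio_noise_sd = 0.12,
    intensity_meanlog = 14, intensity_sdlog = 1,
    gst_true_ratio = 1.0,
    n_single_replicate = 15L, n_high_dispersion = 15L) {
  stopifnot(n_proteins >= length(mpp2_enriched) + length(psd95_enriched),
            peptides_per_protein_range[1] >= 1,
            gst_true_ratio > 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 mpp2_enriched = mpp2_enriched,
                 psd95_enriched = psd95_enriched,
                 background_log2_sd = background_log2_sd,
                 peptides_per_protein_range = peptides_per_protein_range,
                 peptide_log_ratio_noise_sd = peptide_log_ratio_noise_sd,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 gst_true_ratio = gst_true_ratio,
                 n_single_replicate = as.integer(n_single_replicate),
                 n_high_dispersion = as.integer(n_high_dispersion)),
            class = "peptide_table_config")
}

#' Simulate a two-replicate peptide quantification table
#'
#' True protein ratios are expressed in the PSD-95-enrichment-positive
#' orientation (ratio > 1 means enriched towards PSD-95). Replicate A
#' stores raw heavy/light ratios in that orientation; replicate B is
#' label-switched, so its raw ratios are stored inverted. Peptide ratios
#' are the true protein ratio times multiplicative log-normal noise.
#'
#' @param config a [peptide_table_config()].
#' @param seed integer seed.
#' @return list with `peptides` (data.frame: protein, peptide, replicate,
#'   ratio, intensity) and `truth` (data.frame: protein, true_ratio in
#'   the PSD-95-positive orientation, enriched flag for
#'   `abs(log2(true_ratio)) > log2(7)`, side, stable flag).
#' @export
simulate_peptide_table <- function(config = peptide_table_config(),
                                   seed = 1L) {
  stopifnot(inherits(config, "peptide_table_config"))
  withr::with_seed(seed, {
    cfg <- config
    n_special <- length(cfg$mpp2_enriched) + length(cfg$psd95_enriched)
    n_background <- cfg$n_proteins - n_special  # GST generated extra
    # PSD-95-positive orientation: MPP2-side enrichment => ratio < 1
    true_ratio <- c(
      GST = cfg$gst_true_ratio,
      1 / cfg$mpp2_enriched,
      cfg$psd95_enriched,
      stats::setNames(
        2^pmin(pmax(stats::rnorm(n_background, 0,
                                 cfg$background_log2_sd),
                    -log2(5)), log2(5)),
        sprintf("Prot%03d", seq_len(n_background))))
    stable <- rep(TRUE, length(true_ratio))
    # filter-failing proteins
    extra_single <- stats::setNames(
      2^stats::rnorm(cfg$n_single_replicate, 0, cfg$background_log2_sd),
      sprintf("Single%02d", seq_len(cfg$n_single_replicate)))
    extra_disp <- stats::setNames(
      2^stats::rnorm(cfg$n_high_dispersion, 0, cfg$background_log2_sd),
      sprintf("Noisy%02d", seq_len(cfg$n_high_dispersion)))
    all_ratio <- c(true_ratio, extra_single, extra_disp)
    stable <- c(stable, rep(FALSE, length(extra_single) +
                              length(extra_disp)))
    rows <- list()
    rng_pep <- cfg$peptides_per_protein_range
    for (i in seq_along(all_ratio)) {
      prot <- names(all_ratio)[i]
      r_true <- all_ratio[[i]]
      reps <- c("A", "B")
      if (prot %in% names(extra_single)) reps <- "A"
      high_disp <- prot %in% names(extra_disp)
      for (rep_id in reps) {
        n_pep <- sample(seq(rng_pep[1], rng_pep[2]), 1L)
        # high-dispersion proteins get a large replicate-specific bias so
        # their geometric SD across replicates exceeds the filter
        bias <- if (high_disp) {
          exp(ifelse(rep_id == "A", 1, -1) * 1.2)
        } else 1
        oriented <- r_true * bias *
          exp(stats::rnorm(n_pep, 0, cfg$peptide_log_ratio_noise_sd))
        raw <- if (rep_id == "B") 1 / oriented else oriented
        rows[[length(rows) + 1L]] <- data.frame(
          protein = prot,
          peptide = sprintf("%s_pep%02d_%s", prot, seq_len(n_pep), rep_id),
          replicate = rep_id,
          ratio = raw,
          intensity = stats::rlnorm(n_pep, cfg$intensity_meanlog,
                                    cfg$intensity_sdlog))
      }
    }
    peptides <- do.call(rbind, rows)
    rownames(peptides) <- NULL
    truth <- data.frame(
      protein = names(all_ratio),
      true_ratio = unname(all_ratio),
      stable = stable)
    truth$enriched <- abs(log2(truth$true_ratio)) > log2(7) & truth$stable
    truth$side <- ifelse(truth$true_ratio > 1, "PSD95",
                         ifelse(truth$true_ratio < 1, "MPP2", "none"))
    list(peptides = peptides, truth = truth)
  })
}
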