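#' 3D multi-channel stack segmentation
#'
#' Segments anisotropic 3D stacks into objects: histogram-threshold
#' segmentation (Gaussian filtering, background subtraction, the larger
#' of Otsu's and Yen's threshold, 26-connected labelling) for the
#' peripheral channels, and a seeded-watershed "blob finder" for the
#' central PSD anchor channel. Objects carry volume, centroid, surface
#' area, sphericity and equivalent-sphere radius; anchors and partner
#' objects are assembled into synapses by a distance cutoff.
#'
#' Conventions: stacks are arrays with dims `c(ny, nx, nz)`; world
#' coordinates are nm with `world = (index - 0.5) * voxel_size` per
#' axis, in (y, x, z) order matching the array dims.
#'
#' @name volumetric_segmentation
NULL

#' Segmentation parameters
#'
#' @param gaussian_sigma smoothing sigma in nm (isotropic in physical
#'   units; anisotropy-corrected per axis).
#' @param threshold_method threshold combination; default the larger of
#'   Otsu's and Yen's thresholds (conservative foreground).
#' @param blob_watershed_level h-depth (in robust z-score units) below
#'   which touching watershed basins are merged.
#' @param blob_threshold seed threshold in robust z-score units.
#' @param expected_blob_diameter expected anchor diameter, nm.
#' @param min_sphericity,min_volume object filters (strict >); volume in
#'   um^3.
#' @param partner_distance_cutoff `c(low, high)` nm; partner objects are
#'   attached to an anchor when within the high cutoff.
#' @param background_percentile percentile subtracted as background.
#' @param z_window optional `c(zmin, zmax)` plane window (1-based,
#'   inclusive) restricting segmentation to a range of planes.
#' @export
segmentation_params <- function(gaussian_sigma = 80,
                                threshold_method = c("max_otsu_yen",
                                                     "otsu", "yen"),
                                blob_watershed_level = 6.7,
                                blob_threshold = 4.5,
                                expected_blob_diameter = 500,
                                min_sphericity = 0.4,
                                min_volume = 0.005,
                                partner_distance_cutoff = c(2000, 2500),
                                background_percentile = 0.2,
                                z_window = NULL) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(partner_distance_cutoff[1] <= partner_distance_cutoff[2],
            min_sphericity > 0, min_sphericity <= 1, min_volume > 0)
  structure(list(gaussian_sigma = gaussian_sigma,
                 threshold_method = threshold_method,
                 blob_watershed_level = blob_watershed_level,
                 blob_threshold = blob_threshold,
                 expected_blob_diameter = expected_blob_diameter,
                 min_sphericity = min_sphericity,
                 min_volume = min_volume,
                 partner_distance_cutoff = partner_distance_cutoff,
                 background_percentile = background_percentile,
                 z_window = z_window),
            class = "segmentation_params")
}

# geometry of one labelled voxel region
object_geometry <- function(coords, voxel_size) {
  n <- nrow(coords)
  vox_vol_nm3 <- prod(voxel_size)
  volume_um3 <- n * vox_vol_nm3 / 1e9
  world <- voxel_world(coords, voxel_size)
  centroid <- colMeans(world)
  # surface area from exposed voxel faces (anisotropy-aware)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  kset <- key(coords)
  area <- 0
  face_area <- c(voxel_size[2] * voxel_size[3],  # faces normal to y
                 voxel_size[1] * voxel_size[3],  # normal to x
                 voxel_size[1] * voxel_size[2])  # normal to z
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- coords
      nb[, ax] <- nb[, ax] + dir
      exposed <- !(key(nb) %in% kset)
      area <- area + sum(exposed) * face_area[ax]
    }
  }
  vol_nm3 <- n * vox_vol_nm3
  sphericity <- (pi^(1 / 3) * (6 * vol_nm3)^(2 / 3)) / area
  list(n_voxels = n, volume = volume_um3, centroid = centroid,
       surface_area = area, sphericity = sphericity,
       equivalent_radius = equivalent_sphere_radius(volume_um3),
       voxels = coords, voxel_size = voxel_size)
}

objects_from_labels <- function(labels, voxel_size) {
  ids <- sort(unique(labels[labels > 0]))
  lapply(ids, function(id) {
    coords <- arrayInd(which(labels == id), dim(labels))
    obj <- object_geometry(coords, voxel_size)
    obj$label <- id
    structure(obj, class = "segmented_object")
  })
}

#' @export
print.segmented_object <- function(x, ...) {
  cat(sprintf(
    "segmented_object: %d voxel(s), %.4g um^3, sphericity %.2f, r_eq %.0f nm\n",
    x$n_voxels, x$volume, x$sphericity, x$equivalent_radius))
  invisible(x)
}

apply_z_window <- function(stack, z_window) {
  if (is.null(z_window)) return(stack)
  keep <- seq(z_window[1], z_window[2])
  out <- array(0, dim(stack))
  out[, , keep] <- stack[, , keep]
  out
}

#' Threshold-based segmentation of one channel stack
#'
#' Gaussian smoothing (physical-unit sigma, anisotropy-corrected),
#' percentile background subtraction, binarization at the configured
#' histogram threshold (default the larger of Otsu's and Yen's), and
#' 26-connected component labelling.
#'
#' @param stack 3D array `c(ny, nx, nz)`.
#' @param voxel_size nm per axis `(y, x, z)`.
#' @param params a [segmentation_params()].
#' @return list of `segmented_object`s.
#' @export
segment_by_threshold <- function(stack, voxel_size,
                                 params = segmentation_params()) {
  stopifnot(length(dim(stack)) == 3L, length(voxel_size) == 3L)
  stack <- apply_z_window(stack, params$z_window)
  sm <- gaussian_filter(stack, params$gaussian_sigma / voxel_size)
  bg <- stats::quantile(sm, params$background_percentile, names = FALSE)
  sm <- pmax(sm - bg, 0)
  thr <- auto_threshold(sm, params$threshold_method)
  if (is.na(thr)) {
    warning("constant-intensity stack: no objects")
    return(list())
  }
  mask <- sm > thr
  labels <- label_components(mask)
  objects_from_labels(labels, voxel_size)
}

# seeded watershed with h-level merging on mask voxels, flooding in
# decreasing intensity order from the given seed voxels
seeded_watershed <- function(intensity, seeds, mask, h) {
  d <- dim(intensity)
  lab <- array(0L, d)
  lab[seeds] <- seq_along(seeds)
  peak <- intensity[seeds]
  parent <- seq_along(seeds)
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ord <- which(mask)
  ord <- ord[order(intensity[ord], decreasing = TRUE)]
  coords <- arrayInd(ord, d)
  # neighbour linear offsets for 26-connectivity (guarded by coords)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), 3)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  pending <- integer(0)
  process <- function(lin, crd) {
    val <- intensity[lin]
    found <- 0L
    for (r in seq_len(nrow(offs))) {
      nc <- crd + offs[r, ]
      if (any(nc < 1L) || any(nc > d)) next
      nlin <- nc[1] + (nc[2] - 1L) * d[1] + (nc[3] - 1L) * d[1] * d[2]
      nl <- lab[nlin]
      if (nl > 0L) {
        root <- find_root(nl)
        if (found == 0L) {
          found <- root
        } else if (root != found) {
          # saddle between two basins at this intensity
          if (min(peak[root], peak[found]) - val < h) {
            hi <- if (peak[root] >= peak[found]) root else found
            lo <- if (hi == root) found else root
            parent[lo] <<- hi
            found <- hi
          }
        }
      }
    }
    if (found > 0L && lab[lin] == 0L) lab[lin] <<- found
    found > 0L || lab[lin] > 0L
  }
  repeat {
    progressed <- FALSE
    deferred <- logical(length(ord))
    for (q in seq_along(ord)) {
      lin <- ord[q]
      if (lab[lin] > 0L) {
        # still visit for merging checks at already-labelled voxels
        process(lin, coords[q, ])
        next
      }
      ok <- process(lin, coords[q, ])
      if (ok) progressed <- TRUE else deferred[q] <- TRUE
    }
    if (!any(deferred) || !progressed) break
    keep <- deferred
    ord <- ord[keep]
    coords <- coords[keep, , drop = FALSE]
  }
  roots <- vapply(seq_along(seeds), find_root, integer(1))
  lab_arr <- lab
  pos <- which(lab_arr > 0L)
  lab_arr[pos] <- roots[lab_arr[pos]]
  # renumber consecutively
  ids <- sort(unique(lab_arr[lab_arr > 0L]))
  re <- integer(max(ids)); re[ids] <- seq_along(ids)
  lab_arr[pos] <- re[lab_arr[pos]]
  lab_arr
}

#' Blob-finder segmentation for anchor (PSD) channels
#'
#' Seeds are smoothed local maxima (smoothing scale set by the expected
#' blob diameter) whose robust z-score exceeds `blob_threshold`;
#' marker-controlled watershed grows basins over foreground voxels with
#' basin merging controlled by the h-depth `blob_watershed_level`.
#' Objects are then filtered by [filter_objects()].
#'
#' @inheritParams segment_by_threshold
#' @return list of `segmented_object`s passing the sphericity/volume
#'   filters.
#' @export
blob_find_anchors <- function(stack, voxel_size,
                              params = segmentation_params()) {
  stopifnot(length(dim(stack)) == 3L)
  if (params$expected_blob_diameter <= 2 * voxel_size[2]) {
    stop("expected_blob_diameter must exceed 2 lateral voxels")
  }
  stack <- apply_z_window(stack, params$z_window)
  sigma_nm <- params$expected_blob_diameter / 4
  # robust z-units are defined on the raw stack (noise MAD = 1), then
  # smoothed at the blob scale; smoothing suppresses noise but preserves
  # blob-scale structure, so seeds sit far above the threshold while
  # smoothed noise stays near zero
  z0 <- array(robust_z(stack), dim(stack))
  z <- gaussian_filter(z0, sigma_nm / voxel_size)
  mask <- z > params$blob_threshold / 2
  seeds <- local_maxima(z, mask = z > params$blob_threshold)
  if (length(seeds) == 0) return(list())
  # suppress maxima closer than half the expected diameter (keep higher)
  if (length(seeds) > 1) {
    sc <- voxel_world(arrayInd(seeds, dim(z)), voxel_size)
    o <- order(z[seeds], decreasing = TRUE)
    keep <- logical(length(seeds))
    for (i in o) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      dmin <- min(sqrt(rowSums(
        sweep(sc[keep, , drop = FALSE], 2, sc[i, ], "-")^2)))
      if (dmin > params$expected_blob_diameter / 2) keep[i] <- TRUE
    }
    seeds <- seeds[keep]
  }
  labels <- seeded_watershed(z, seeds, mask, params$blob_watershed_level)
  objects <- objects_from_labels(labels, voxel_size)
  filter_objects(objects, params$min_sphericity, params$min_volume)
}

#' Filter segmented objects by sphericity and volume
#'
#' Strict `>` comparisons on both criteria; the number removed per
#' criterion is reported via `message()`.
#'
#' @param objects list of `segmented_object`s.
#' @param min_sphericity,min_volume filter floors (volume in um^3).
#' @export
filter_objects <- function(objects, min_sphericity = 0.4,
                           min_volume = 0.005) {
  if (!length(objects)) return(objects)
  sph <- vapply(objects, `[[`, numeric(1), "sphericity")
  vol <- vapply(objects, `[[`, numeric(1), "volume")
  keep <- sph > min_sphericity & vol > min_volume
  n_sph <- sum(sph <= min_sphericity)
  n_vol <- sum(vol <= min_volume)
  if (any(!keep)) {
    message(sprintf(
      "filter_objects: removed %d (sphericity <= %.2f: %d, volume <= %.4g: %d)",
      sum(!keep), min_sphericity, n_sph, min_volume, n_vol))
  }
  objects[keep]
}

#' Equivalent-sphere radius from a volume
#'
#' `r = (3V / 4 pi)^(1/3)`, volume in um^3, radius returned in nm.
#'
#' @param volume volume(s) in um^3.
#' @export
equivalent_sphere_radius <- function(volume) {
  if (any(volume < 0)) stop("negative volume")
  (3 * volume * 1e9 / (4 * pi))^(1 / 3)
}

#' Assemble synapses from anchors and partner channels
#'
#' For each anchor, the nearest object of every partner channel within
#' the cutoff is attached; a synapse is complete when all required
#' channels are attached.
#'
#' @param anchors list of `segmented_object`s (e.g. PSD-95 anchors).
#' @param partners named list of `segmented_object` lists per channel.
#' @param cutoff maximum centre distance, nm (the high end of the
#'   configured cutoff range by default).
#' @param required_channels channels required for completeness.
#' @return list with `synapses` (one record per anchor: anchor, partner
#'   map, complete flag) and `completeness_fraction`.
#' @export
assemble_synapses <- function(anchors, partners, cutoff = 2500,
                              required_channels = names(partners)) {
  if (!length(anchors)) {
    return(list(synapses = list(), completeness_fraction = NA_real_))
  }
  partner_centroids <- lapply(partners, function(objs) {
    if (!length(objs)) return(NULL)
    do.call(rbind, lapply(objs, `[[`, "centroid"))
  })
  synapses <- lapply(anchors, function(a) {
    att <- list()
    for (ch in names(partners)) {
      pc <- partner_centroids[[ch]]
      if (is.null(pc)) next
      dists <- sqrt(rowSums(sweep(pc, 2, a$centroid, "-")^2))
      j <- which.min(dists)
      if (dists[j] <= cutoff) {
        att[[ch]] <- list(object = partners[[ch]][[j]],
                          distance = dists[j])
      }
    }
    list(anchor = a, partners = att,
         complete = all(required_channels %in% names(att)))
  })
  frac <- mean(vapply(synapses, `[[`, logical(1), "complete"))
  list(synapses = synapses, completeness_fraction = frac)
}

#' Write a multi-channel stack as multi-page TIFF files
#'
#' One float TIFF per channel, pages = z planes. Each channel is min-max
#' scaled to `[0, 1]` on write (TIFF float convention); downstream
#' segmentation is intensity-scale invariant, so this is lossless for
#' the pipeline.
#' @param stacks named list of 3D arrays.
#' @param dir output directory.
#' @export
write_stack_tiff <- function(stacks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(stacks)) {
    s <- stacks[[ch]]
    rng <- range(s)
    if (diff(rng) > 0) s <- (s - rng[1]) / diff(rng)
    pages <- lapply(seq_len(dim(s)[3]), function(k) s[, , k])
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(dir)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#'
#' @param path TIFF file path.
#' @return 3D array `c(ny, nx, nz)`.
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}
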