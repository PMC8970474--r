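#' Radial profiles and nearest-neighbour statistics with null models
#'
#' 3D radial intensity profiles around anchor centres, directional
#' nearest-neighbour (NN) distances between object sets (centre-to-centre
#' or surface-to-surface), and two null models: complete spatial
#' randomness (CSR) within/on a 0.8-um sphere representing a simplified
#' postsynapse, and a toroidal shift of one channel. Null histograms
#' carry per-bin simulation envelopes.
#'
#' @name spatial_stats
NULL

#' Radial profile parameters
#'
#' @param bin_width shell width, nm.
#' @param max_radius largest shell radius, nm.
#' @export
radial_profile_params <- function(bin_width = 50, max_radius = 1000) {
  stopifnot(bin_width > 0, max_radius >= bin_width)
  structure(list(bin_width = bin_width, max_radius = max_radius),
            class = "radial_profile_params")
}

#' 3D radial intensity profile around anchor centres
#'
#' Voxels are binned by (anisotropy-corrected) Euclidean distance from
#' each anchor centre into shells `[k*w, (k+1)*w)`; the shell value is
#' the mean voxel intensity. Shells that extend past the stack border
#' for a given anchor are excluded for that anchor (truncation guard).
#' The per-image profile is the mean over anchors, then min-max
#' normalized to `[0, 1]`.
#'
#' @param stack 3D array `c(ny, nx, nz)`.
#' @param centres matrix of anchor centres in nm, columns in (y, x, z)
#'   order matching the array dims.
#' @param voxel_size nm per axis `(y, x, z)`.
#' @param params a [radial_profile_params()].
#' @param normalize min-max normalize the aggregated profile.
#' @return data.frame with bin_mid, bin_lo, bin_hi, profile (normalized
#'   mean intensity), n_anchors contributing per bin.
#' @export
radial_profile_3d <- function(stack, centres, voxel_size,
                              params = radial_profile_params(),
                              normalize = TRUE) {
  stopifnot(length(dim(stack)) == 3L)
  centres <- matrix(centres, ncol = 3)
  d <- dim(stack)
  w <- params$bin_width
  n_bins <- ceiling(params$max_radius / w)
  extent <- d * voxel_size
  acc <- matrix(NA_real_, nrow(centres), n_bins)
  coords <- arrayInd(seq_len(prod(d)), d)
  world <- voxel_world(coords, voxel_size)
  for (a in seq_len(nrow(centres))) {
    ctr <- centres[a, ]
    border_dist <- min(c(ctr, extent - ctr))
    dist_vox <- sqrt((world[, 1] - ctr[1])^2 + (world[, 2] - ctr[2])^2 +
                       (world[, 3] - ctr[3])^2)
    bin <- floor(dist_vox / w) + 1L
    ok <- bin <= n_bins
    sums <- tapply(stack[ok], bin[ok], mean)
    prof <- rep(NA_real_, n_bins)
    prof[as.integer(names(sums))] <- sums
    # truncated shells: any shell whose outer edge passes the border
    trunc_from <- floor(border_dist / w) + 1L
    if (trunc_from <= n_bins) prof[trunc_from:n_bins] <- NA_real_
    acc[a, ] <- prof
  }
  prof <- colMeans(acc, na.rm = TRUE)
  n_anchors <- colSums(!is.na(acc))
  prof[n_anchors == 0] <- NA_real_
  if (normalize) {
    rng <- range(prof, na.rm = TRUE)
    if (diff(rng) == 0 || !all(is.finite(rng))) {
      warning("degenerate intensity range; profile set to zero")
      prof <- rep(0, n_bins)
    } else {
      prof <- (prof - rng[1]) / diff(rng)
    }
  }
  data.frame(bin_lo = (seq_len(n_bins) - 1) * w,
             bin_hi = seq_len(n_bins) * w,
             bin_mid = (seq_len(n_bins) - 0.5) * w,
             profile = prof, n_anchors = n_anchors)
}

#' Radius at which a normalized radial profile crosses half maximum
#'
#' Linear interpolation between the bin centres bracketing the first
#' downward crossing of 0.5.
#' @param profile data.frame from [radial_profile_3d()].
#' @export
profile_half_max_radius <- function(profile) {
  p <- profile$profile
  m <- profile$bin_mid
  ok <- which(!is.na(p))
  p <- p[ok]; m <- m[ok]
  below <- which(p < 0.5)
  above <- which(p >= 0.5)
  if (!length(below) || !length(above)) return(NA_real_)
  i <- below[below > above[1]][1]
  if (is.na(i) || i == 1) return(NA_real_)
  j <- i - 1
  m[j] + (0.5 - p[j]) / (p[i] - p[j]) * (m[i] - m[j])
}

# object sets for NN analysis: data.frame with centroid columns and a
# radius column (sphere model), or lists of segmented_objects
as_sphere_set <- function(objects) {
  if (is.data.frame(objects)) {
    cols <- intersect(c("cx", "cy", "cz"), names(objects))
    if (!length(cols)) cols <- intersect(c("x", "y", "z"), names(objects))
    m <- as.matrix(objects[, cols, drop = FALSE])
    r <- if ("radius" %in% names(objects)) objects$radius else
      rep(0, nrow(objects))
    return(list(centres = m, radii = r, surfaces = NULL))
  }
  if (is.matrix(objects)) {
    return(list(centres = objects, radii = rep(0, nrow(objects)),
                surfaces = NULL))
  }
  # list of segmented_objects
  centres <- do.call(rbind, lapply(objects, `[[`, "centroid"))
  radii <- vapply(objects, `[[`, numeric(1), "equivalent_radius")
  surfaces <- lapply(objects, function(o) {
    coords <- o$voxels
    voxel_world(coords, o$voxel_size)
  })
  list(centres = centres, radii = radii, surfaces = surfaces)
}

#' Directional nearest-neighbour distances between two object sets
#'
#' For every object in `from`, the minimum distance to any object in
#' `to`. Centre mode uses Euclidean centroid distances. Surface mode
#' uses the sphere model `max(0, centre_distance - r1 - r2)` when radii
#' are available (or voxel-surface minimum distances for voxel objects
#' with `use_voxels = TRUE`).
#'
#' @param from,to object sets: data.frames with centroid (cx/cy[/cz])
#'   and radius columns, coordinate matrices, or lists of
#'   `segmented_object`s.
#' @param mode "centre" or "surface".
#' @param use_voxels use voxel surfaces instead of the sphere model.
#' @return numeric vector of distances (nm), one per `from` object, with
#'   attributes `from_n`, `to_n`, `mode`.
#' @export
nn_distances <- function(from, to, mode = c("centre", "surface"),
                         use_voxels = FALSE) {
  mode <- match.arg(mode)
  A <- as_sphere_set(from)
  B <- as_sphere_set(to)
  if (!nrow(A$centres)) stop("empty 'from' set")
  if (!nrow(B$centres)) stop("empty 'to' set")
  if (mode == "surface" && use_voxels &&
      (is.null(A$surfaces) || is.null(B$surfaces))) {
    stop("voxel surfaces not available for these object sets")
  }
  nA <- nrow(A$centres); nB <- nrow(B$centres)
  cd <- matrix(0, nA, nB)
  for (j in seq_len(ncol(A$centres))) {
    cd <- cd + outer(A$centres[, j], B$centres[, j], "-")^2
  }
  cd <- sqrt(cd)
  if (mode == "centre") {
    out <- apply(cd, 1, min)
  } else if (!use_voxels) {
    sd_ <- pmax(cd - outer(A$radii, B$radii, "+"), 0)
    out <- apply(sd_, 1, min)
  } else {
    out <- vapply(seq_len(nA), function(i) {
      min(vapply(seq_len(nB), function(j) {
        sa <- A$surfaces[[i]]; sb <- B$surfaces[[j]]
        d2 <- outer(sa[, 1], sb[, 1], "-")^2 +
          outer(sa[, 2], sb[, 2], "-")^2 +
          outer(sa[, 3], sb[, 3], "-")^2
        sqrt(min(d2))
      }, numeric(1)))
    }, numeric(1))
  }
  attr(out, "from_n") <- nA
  attr(out, "to_n") <- nB
  attr(out, "mode") <- mode
  out
}

#' CSR null parameters
#'
#' @param sphere_diameter diameter of the simplified postsynapse sphere,
#'   nm.
#' @param n_simulations_per_synapse simulation rounds.
#' @param envelope_level nominal envelope level.
#' @param envelope "sd" (a t-based prediction band across rounds,
#'   `mean +/- t * sd * sqrt(1 + 1/n)`: the band a single new
#'   realisation falls inside with the nominal probability), "sem"
#'   (mean +/- z * SEM, a confidence band on the null mean), or
#'   "minmax".
#' @export
csr_params <- function(sphere_diameter = 800,
                       n_simulations_per_synapse = 10,
                       envelope_level = 0.95,
                       envelope = c("sd", "sem", "minmax")) {
  envelope <- match.arg(envelope)
  stopifnot(sphere_diameter > 0, n_simulations_per_synapse >= 2)
  structure(list(sphere_diameter = sphere_diameter,
                 n_simulations_per_synapse = n_simulations_per_synapse,
                 envelope_level = envelope_level, envelope = envelope),
            class = "csr_params")
}

# uniform points within a ball of radius R (inverse-CDF radius)
runif_ball <- function(n, R) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  v * (R * stats::runif(n)^(1 / 3))
}

# uniform points on the sphere surface of radius R
runif_sphere_surface <- function(n, R) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  R * v / sqrt(rowSums(v^2))
}

#' Draw one CSR realisation for a synapse
#'
#' Species A centres uniform within the sphere volume, species B centres
#' uniform on its surface; object radii are preserved from the
#' segmentation.
#'
#' @param n_a,n_b object counts.
#' @param radii_a,radii_b object radii, nm.
#' @param sphere_diameter nm.
#' @return list of two sphere sets (data.frames with cx, cy, cz,
#'   radius).
#' @export
csr_realisation <- function(n_a, n_b, radii_a = rep(0, n_a),
                            radii_b = rep(0, n_b),
                            sphere_diameter = 800) {
  R <- sphere_diameter / 2
  if (any(c(radii_a, radii_b) > R)) {
    warning("object radius exceeds sphere radius; centre placed per rule")
  }
  A <- runif_ball(n_a, R)
  B <- runif_sphere_surface(n_b, R)
  list(A = data.frame(cx = A[, 1], cy = A[, 2], cz = A[, 3],
                      radius = radii_a),
       B = data.frame(cx = B[, 1], cy = B[, 2], cz = B[, 3],
                      radius = radii_b))
}

hist_counts <- function(d, edges) {
  # half-open bins [e_k, e_{k+1}); values beyond the last edge dropped
  tabulate(findInterval(d, edges, left.open = FALSE), nbins =
             length(edges) - 1L)[seq_len(length(edges) - 1L)]
}

#' CSR null model with simulation envelope
#'
#' For each synapse and each simulation round, species-A objects are
#' placed uniformly within and species-B objects uniformly on the
#' surface of a sphere of `sphere_diameter`, radii preserved; NN
#' distances are computed and histogrammed (averaged over synapses
#' within each round). The envelope is computed per bin across rounds.
#'
#' @param synapse_counts data.frame with one row per synapse: columns
#'   `n_a`, `n_b` and optionally list-columns `radii_a`, `radii_b`.
#' @param params a [csr_params()].
#' @param mode NN mode ("centre" or "surface").
#' @param bin_width,max_distance histogram geometry, nm.
#' @param seed integer seed.
#' @return object of class `nn_envelope`: data.frame with bin edges,
#'   null_mean, lower, upper, plus attributes (per-round matrix, mode).
#' @export
csr_null <- function(synapse_counts, params = csr_params(),
                     mode = "centre", bin_width = 50,
                     max_distance = 1000, seed = 1L) {
  stopifnot(nrow(synapse_counts) >= 1)
  edges <- seq(0, max_distance, by = bin_width)
  n_bins <- length(edges) - 1L
  n_rounds <- params$n_simulations_per_synapse
  rounds <- matrix(0, n_rounds, n_bins)
  withr::with_seed(seed, {
    for (r in seq_len(n_rounds)) {
      per_syn <- matrix(0, nrow(synapse_counts), n_bins)
      for (s in seq_len(nrow(synapse_counts))) {
        n_a <- synapse_counts$n_a[s]
        n_b <- synapse_counts$n_b[s]
        ra <- if (!is.null(synapse_counts$radii_a))
          synapse_counts$radii_a[[s]] else rep(0, n_a)
        rb <- if (!is.null(synapse_counts$radii_b))
          synapse_counts$radii_b[[s]] else rep(0, n_b)
        re <- csr_realisation(n_a, n_b, ra, rb, params$sphere_diameter)
        d <- nn_distances(re$A, re$B, mode = mode)
        per_syn[s, ] <- hist_counts(d, edges)
      }
      rounds[r, ] <- colMeans(per_syn)
    }
  })
  null_mean <- colMeans(rounds)
  if (params$envelope == "minmax") {
    lower <- apply(rounds, 2, min)
    upper <- apply(rounds, 2, max)
  } else if (params$envelope == "sem") {
    spread <- apply(rounds, 2, stats::sd) / sqrt(n_rounds)
    zq <- stats::qnorm(1 - (1 - params$envelope_level) / 2)
    lower <- null_mean - zq * spread
    upper <- null_mean + zq * spread
  } else {
    # prediction band for one new realisation given n_rounds draws
    spread <- apply(rounds, 2, stats::sd) * sqrt(1 + 1 / n_rounds)
    tq <- stats::qt(1 - (1 - params$envelope_level) / 2, n_rounds - 1)
    lower <- null_mean - tq * spread
    upper <- null_mean + tq * spread
  }
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    null_mean = null_mean,
                    lower = pmax(lower, 0), upper = upper)
  attr(out, "rounds") <- rounds
  attr(out, "mode") <- mode
  class(out) <- c("nn_envelope", "data.frame")
  out
}

#' Observed per-synapse NN histogram (averaged over synapses)
#'
#' Companion to [csr_null()]: histograms each synapse's NN distances and
#' averages across synapses, yielding a profile on the same scale as the
#' null rounds.
#'
#' @param distances_per_synapse list of numeric distance vectors.
#' @param bin_width,max_distance histogram geometry, nm.
#' @export
observed_nn_histogram <- function(distances_per_synapse, bin_width = 50,
                                  max_distance = 1000) {
  edges <- seq(0, max_distance, by = bin_width)
  per <- t(vapply(distances_per_synapse, hist_counts,
                  numeric(length(edges) - 1L), edges = edges))
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             count = colMeans(per))
}

#' Fraction of histogram bins inside a null envelope
#'
#' @param observed data.frame from [observed_nn_histogram()].
#' @param envelope an `nn_envelope`.
#' @export
envelope_coverage <- function(observed, envelope) {
  stopifnot(nrow(observed) == nrow(envelope))
  inside <- observed$count >= envelope$lower &
    observed$count <= envelope$upper
  mean(inside)
}

#' Toroidal-shift null for cluster centre pairs
#'
#' Translates species-A centres by a vector of magnitude `shift` in one
#' random direction per image, wrapping at the field bounds (torus
#' topology), then recomputes centre-mode NN distances to species B.
#'
#' @param centres_a,centres_b matrices of cluster centres (nm), 2
#'   columns.
#' @param bounds field bounds `c(xmin, xmax, ymin, ymax)` nm.
#' @param shift shift magnitude, nm (must be > 0).
#' @param seed integer seed.
#' @return list with `null_distances`, `observed_distances`, and
#'   `shift_vector`.
#' @export
toroidal_shift_null <- function(centres_a, centres_b, bounds,
                                shift = 20, seed = 1L) {
  if (shift <= 0) stop("shift must be > 0")
  centres_a <- matrix(centres_a, ncol = 2)
  centres_b <- matrix(centres_b, ncol = 2)
  if (any(centres_a[, 1] < bounds[1] | centres_a[, 1] > bounds[2] |
          centres_a[, 2] < bounds[3] | centres_a[, 2] > bounds[4])) {
    stop("field bounds must enclose all points")
  }
  withr::with_seed(seed, {
    theta <- stats::runif(1, 0, 2 * pi)
    v <- shift * c(cos(theta), sin(theta))
    shifted <- toroidal_wrap(centres_a, v, bounds)
    obs <- nn_distances(centres_a, centres_b, mode = "centre")
    nul <- nn_distances(shifted, centres_b, mode = "centre")
    list(null_distances = as.numeric(nul),
         observed_distances = as.numeric(obs),
         shift_vector = v)
  })
}

#' Translate points with wrap-around at field bounds
#'
#' @param points 2-column matrix (nm).
#' @param v translation vector (nm).
#' @param bounds `c(xmin, xmax, ymin, ymax)`.
#' @export
toroidal_wrap <- function(points, v, bounds) {
  w <- c(bounds[2] - bounds[1], bounds[4] - bounds[3])
  out <- points
  out[, 1] <- bounds[1] + (points[, 1] - bounds[1] + v[1]) %% w[1]
  out[, 2] <- bounds[3] + (points[, 2] - bounds[3] + v[2]) %% w[2]
  out
}

#' Two-level aggregation of per-image histograms
#'
#' Histograms are first averaged within each experiment, then the
#' experiment means are averaged with SEM across experiments (the
#' "n images from N independent experiments" convention).
#'
#' @param histograms list of data.frames with identical `bin_lo`,
#'   `bin_hi` and a `count` column.
#' @param experiment factor/character vector assigning each histogram to
#'   an experiment.
#' @return data.frame with bin edges, mean, sem (NA with a warning when
#'   only one experiment is present).
#' @export
aggregate_histograms <- function(histograms, experiment) {
  stopifnot(length(histograms) == length(experiment))
  ref <- histograms[[1]][, c("bin_lo", "bin_hi")]
  for (h in histograms) {
    if (!isTRUE(all.equal(h$bin_lo, ref$bin_lo)) ||
        !isTRUE(all.equal(h$bin_hi, ref$bin_hi))) {
      stop("mismatched bin edges")
    }
  }
  counts <- t(vapply(histograms, function(h) h$count,
                     numeric(nrow(ref))))
  exp_means <- rowsum(counts, group = experiment) /
    as.vector(table(experiment)[sort(unique(as.character(experiment)))])
  n_exp <- nrow(exp_means)
  mean_ <- colMeans(exp_means)
  if (n_exp < 2) {
    warning("single experiment: SEM undefined")
    sem <- rep(NA_real_, ncol(exp_means))
  } else {
    sem <- apply(exp_means, 2, stats::sd) / sqrt(n_exp)
  }
  data.frame(bin_lo = ref$bin_lo, bin_hi = ref$bin_hi,
             mean = mean_, sem = sem, n_experiments = n_exp)
}
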