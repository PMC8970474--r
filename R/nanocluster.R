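#' Nanocluster detection and bracelet geometry
#'
#' Density-based detection of protein nanoclusters in localization point
#' clouds (DBSCAN, default eps = 20 nm and a minimum of 5 points,
#' counting the point itself), cluster sizing by longest axis, size
#' histograms with an overflow bin, algebraic ring (circle) fitting to
#' cluster centroids, and a ring-score heuristic that classifies whether
#' peripheral clusters form a bracelet around a central reference point.
#'
#' @name nanocluster
NULL

#' DBSCAN parameters
#'
#' @param epsilon neighbourhood radius, nm.
#' @param min_points minimum number of points in an eps-neighbourhood
#'   (including the point itself) for a core point.
#' @export
cluster_params <- function(epsilon = 20, min_points = 5) {
  stopifnot(epsilon > 0, min_points >= 1)
  structure(list(epsilon = epsilon, min_points = min_points),
            class = "cluster_params")
}

loc_coords <- function(table) {
  cols <- c("x", "y", if (!is.null(table$z)) "z")
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}

#' Detect nanoclusters with DBSCAN
#'
#' Density-based clustering with Euclidean eps-neighbourhoods in nm; the
#' point itself counts towards `min_points` (original-algorithm
#' convention). Noise is labelled 0. Border points reachable from more
#' than one cluster are assigned to the cluster of the earliest core
#' point (by input order) among their neighbours, so the labelling is
#' deterministic given input order. Cluster ids are numbered by first
#' occurrence in input order.
#'
#' @param table a [localization_table()] or a matrix of coordinates (nm).
#' @param params a [cluster_params()].
#' @return an object of class `cluster_set`: list with `labels`
#'   (integer per localization; 0 = noise) and `clusters` (data.frame:
#'   cluster, n, centroid columns, longest_axis).
#' @export
detect_clusters_dbscan <- function(table, params = cluster_params()) {
  pts <- if (is.matrix(table)) table else loc_coords(table)
  n <- nrow(pts)
  if (n == 0) {
    return(structure(list(labels = integer(0),
                          clusters = empty_cluster_df(ncol(pts))),
                     class = "cluster_set"))
  }
  stopifnot_finite(pts, "coordinates")
  eps <- params$epsilon
  dmat <- as.matrix(stats::dist(pts))
  nb <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  core <- lengths(nb) >= params$min_points
  labels <- integer(n)  # 0 = unassigned/noise
  cluster_id <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cluster_id <- cluster_id + 1L
    labels[i] <- cluster_id
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (k in nb[[j]]) {
        if (core[k] && labels[k] == 0L) {
          labels[k] <- cluster_id
          queue <- c(queue, k)
        }
      }
    }
  }
  # border points: earliest core neighbour in input order
  for (i in which(!core)) {
    cores_near <- nb[[i]][core[nb[[i]]]]
    if (length(cores_near)) labels[i] <- labels[min(cores_near)]
  }
  build_cluster_set(pts, labels)
}

empty_cluster_df <- function(nd) {
  df <- data.frame(cluster = integer(0), n = integer(0),
                   cx = numeric(0), cy = numeric(0))
  if (nd >= 3) df$cz <- numeric(0)
  df$longest_axis <- numeric(0)
  df
}

build_cluster_set <- function(pts, labels) {
  ids <- unique(labels[labels > 0])
  nd <- ncol(pts)
  if (length(ids) == 0) {
    clusters <- empty_cluster_df(nd)
  } else {
    clusters <- do.call(rbind, lapply(ids, function(id) {
      m <- pts[labels == id, , drop = FALSE]
      row <- data.frame(cluster = id, n = nrow(m),
                        cx = mean(m[, 1]), cy = mean(m[, 2]))
      if (nd >= 3) row$cz <- mean(m[, 3])
      row$longest_axis <- cluster_longest_axis(m)
      row
    }))
  }
  structure(list(labels = labels, clusters = clusters,
                 points = pts), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d localization(s), %d cluster(s), %d noise\n",
              length(x$labels), nrow(x$clusters), sum(x$labels == 0)))
  invisible(x)
}

#' Longest axis of a cluster
#'
#' Maximum pairwise Euclidean distance among member points; 0 for a
#' single point.
#'
#' @param members matrix of member coordinates (nm).
#' @export
cluster_longest_axis <- function(members) {
  members <- as.matrix(members)
  if (nrow(members) < 2) return(0)
  max(stats::dist(members))
}

#' Histogram of cluster sizes with overflow bin
#'
#' Half-open bins `[k*w, (k+1)*w)`; values at or above `overflow_cap`
#' are pooled into a terminal overflow bin. Total counts are conserved.
#'
#' @param values non-negative lengths, nm.
#' @param bin_width bin width, nm (default 15, the cluster-size
#'   histogram convention).
#' @param overflow_cap pooling threshold, nm, or `NULL` for no overflow
#'   bin (default 400 nm).
#' @return data.frame with columns lower, upper, count, overflow.
#' @export
size_histogram <- function(values, bin_width = 15, overflow_cap = 400) {
  stopifnot(bin_width > 0)
  if (any(values < 0)) stop("negative values not allowed")
  if (!is.null(overflow_cap)) {
    over <- sum(values >= overflow_cap)
    vals <- values[values < overflow_cap]
    n_bins <- ceiling(overflow_cap / bin_width)
  } else {
    over <- NULL
    vals <- values
    n_bins <- if (length(values)) max(1L, floor(max(values) / bin_width) + 1L)
              else 1L
  }
  counts <- tabulate(floor(vals / bin_width) + 1L, nbins = n_bins)
  df <- data.frame(lower = (seq_len(n_bins) - 1L) * bin_width,
                   upper = seq_len(n_bins) * bin_width,
                   count = counts, overflow = FALSE)
  if (!is.null(over)) {
    df <- rbind(df, data.frame(lower = overflow_cap, upper = Inf,
                               count = over, overflow = TRUE))
  }
  df
}

#' Algebraic circle fit to cluster centroids (ring diameter)
#'
#' Least-squares (Kasa) fit of a circle to centroids projected into the
#' synapse plane: solves the linear system in (x, y, x^2 + y^2). Returns
#' the fitted centre, diameter and RMS radial residual. Degenerate input
#' (fewer than `min_support` points or collinear centroids) yields an
#' estimate flagged as undefined.
#'
#' @param centroids matrix or data.frame with columns x and y (or
#'   cx/cy), nm.
#' @param min_support minimum number of supporting centroids.
#' @return object of class `ring_estimate`: list(centre, diameter,
#'   residual, n_support, defined).
#' @export
estimate_ring_diameter <- function(centroids, min_support = 3) {
  m <- as.matrix(as.data.frame(centroids))
  if (!is.null(colnames(m)) && all(c("cx", "cy") %in% colnames(m))) {
    m <- m[, c("cx", "cy"), drop = FALSE]
  } else {
    m <- m[, 1:2, drop = FALSE]
  }
  undefined <- structure(list(centre = c(NA_real_, NA_real_),
                              diameter = NA_real_, residual = NA_real_,
                              n_support = nrow(m), defined = FALSE),
                         class = "ring_estimate")
  if (nrow(m) < min_support) return(undefined)
  x <- m[, 1]; y <- m[, 2]
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol) || qr(A)$rank < 3) return(undefined)
  cx <- sol[1] / 2; cy <- sol[2] / 2
  r2 <- sol[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(undefined)
  r <- sqrt(r2)
  radial <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(centre = c(x = unname(cx), y = unname(cy)),
                 diameter = unname(2 * r),
                 residual = unname(sqrt(mean((radial - r)^2))),
                 n_support = nrow(m), defined = TRUE),
            class = "ring_estimate")
}

#' @export
print.ring_estimate <- function(x, ...) {
  if (x$defined) {
    cat(sprintf(
      "ring_estimate: diameter %.1f nm (residual %.1f nm, n = %d)\n",
      x$diameter, x$residual, x$n_support))
  } else {
    cat("ring_estimate: undefined (insufficient or degenerate support)\n")
  }
  invisible(x)
}

#' Quantile-based diameter of a filled disc of localizations
#'
#' For points uniform in a disc of radius R, the median radial distance
#' from the centre is R/sqrt(2); the diameter estimate is therefore
#' `2 * sqrt(2) * median(radial distance)` about the centroid. The
#' median makes the estimate robust to the sparse background
#' localizations that surround a synapse. Used for the central (filled)
#' PSD species, where a ring fit does not apply.
#'
#' @param points matrix/data.frame with x and y in nm.
#' @export
estimate_disc_diameter <- function(points) {
  m <- as.matrix(as.data.frame(points))[, 1:2, drop = FALSE]
  if (nrow(m) < 2) return(NA_real_)
  ctr <- colMeans(m)
  r <- sqrt((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2)
  2 * sqrt(2) * stats::median(r)
}

#' Classify a bracelet-like arrangement of peripheral clusters
#'
#' Ring score = (fraction of 8 angular sectors around the centre that
#' contain at least one peripheral cluster centroid) x (1 - central-void
#' violation ratio). The violation ratio is the fraction of centroids
#' falling inside half the 90th-percentile radial distance, scaled by
#' the 25% expected for a uniform filled disc and capped at 1; a clean
#' ring has no inner centroids and scores near 1, a filled or collapsed
#' arrangement scores near 0. A synapse with no peripheral clusters
#' scores 0.
#'
#' @param cluster_sets one `cluster_set` or a list of them (the two
#'   peripheral species).
#' @param centre central reference point `c(x, y)` nm.
#' @param threshold classification threshold on the score.
#' @return list(bracelet = logical, score, n_sectors_occupied,
#'   void_violation).
#' @export
classify_bracelet <- function(cluster_sets, centre = c(0, 0),
                              threshold = 0.5) {
  if (inherits(cluster_sets, "cluster_set")) {
    cluster_sets <- list(cluster_sets)
  }
  cents <- do.call(rbind, lapply(cluster_sets, function(cs) {
    as.matrix(cs$clusters[, c("cx", "cy"), drop = FALSE])
  }))
  if (is.null(cents) || nrow(cents) == 0) {
    return(list(bracelet = FALSE, score = 0,
                n_sectors_occupied = 0L, void_violation = NA_real_))
  }
  dx <- cents[, 1] - centre[1]
  dy <- cents[, 2] - centre[2]
  r <- sqrt(dx^2 + dy^2)
  r_ref <- stats::quantile(r, 0.9, names = FALSE)
  if (r_ref <= 0) {
    return(list(bracelet = FALSE, score = 0,
                n_sectors_occupied = 1L, void_violation = 1))
  }
  sector <- floor(((atan2(dy, dx) + 2 * pi) %% (2 * pi)) / (pi / 4)) + 1L
  n_occ <- length(unique(sector))
  inner_frac <- mean(r < 0.5 * r_ref)
  violation <- min(1, inner_frac / 0.25)
  score <- (n_occ / 8) * (1 - violation)
  list(bracelet = score >= threshold, score = score,
       n_sectors_occupied = n_occ, void_violation = violation)
}

#' Export a cluster table as TSV
#'
#' @param cluster_set a `cluster_set`.
#' @param path output path.
#' @export
write_cluster_table <- function(cluster_set, path) {
  utils::write.table(cluster_set$clusters, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
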