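# Internal numerical helpers shared across modules: separable Gaussian
# filtering for 2D/3D arrays with anisotropic (physical-unit) sigmas,
# histogram-based auto-thresholds, connected-component labelling and
# local-maximum detection. Kept in-package so 2D and 3D branches share one
# implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in '%s'", name), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# convolve along one dimension of a 2D/3D array with replicate padding
convolve_along <- function(a, k, dim_idx) {
  if (length(k) == 1L) return(a)
  d <- dim(a)
  half <- (length(k) - 1L) / 2L
  n <- d[dim_idx]
  # index with clamping (replicate edges)
  out <- array(0, d)
  for (off in seq_along(k)) {
    shift <- off - half - 1L
    idx <- pmin(pmax(seq_len(n) + shift, 1L), n)
    if (length(d) == 2L) {
      slice <- if (dim_idx == 1L) a[idx, , drop = FALSE] else a[, idx, drop = FALSE]
    } else {
      slice <- switch(dim_idx,
        a[idx, , , drop = FALSE],
        a[, idx, , drop = FALSE],
        a[, , idx, drop = FALSE])
    }
    out <- out + k[off] * slice
  }
  out
}

#' Separable Gaussian filter for 2D or 3D arrays
#'
#' `sigma` is given per dimension (in voxel units); pass physical sigmas
#' divided by the voxel size to get anisotropy-corrected smoothing.
#' @keywords internal
gaussian_filter <- function(a, sigma) {
  d <- dim(a)
  if (length(sigma) == 1L) sigma <- rep(sigma, length(d))
  stopifnot(length(sigma) == length(d))
  for (i in seq_along(d)) {
    a <- convolve_along(a, gaussian_kernel_1d(sigma[i]), i)
  }
  a
}

# --- histogram auto-thresholds ------------------------------------------

# All three operate on a 256-bin histogram of the data range and return a
# threshold on the original intensity scale. Values > threshold are
# foreground.

intensity_histogram <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(NULL)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = levels)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(counts = counts, mids = mids)
}

threshold_otsu <- function(x, levels = 256L) {
  h <- intensity_histogram(x, levels)
  if (is.null(h)) return(NA_real_)
  p <- h$counts / sum(h$counts)
  omega <- cumsum(p)
  mu <- cumsum(p * h$mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  h$mids[which.max(sigma_b)]
}

threshold_yen <- function(x, levels = 256L) {
  h <- intensity_histogram(x, levels)
  if (is.null(h)) return(NA_real_)
  p <- h$counts / sum(h$counts)
  p1 <- cumsum(p)
  p1_sq <- cumsum(p^2)
  p2_sq <- sum(p^2) - p1_sq
  crit <- -log(pmax(p1_sq * p2_sq, .Machine$double.xmin)) +
    2 * log(pmax(p1 * (1 - p1), .Machine$double.xmin))
  h$mids[which.max(crit)]
}

# Tsai's moment-preserving threshold
threshold_moments <- function(x, levels = 256L) {
  h <- intensity_histogram(x, levels)
  if (is.null(h)) return(NA_real_)
  p <- h$counts / sum(h$counts)
  m1 <- sum(p * h$mids)
  m2 <- sum(p * h$mids^2)
  m3 <- sum(p * h$mids^3)
  cd <- m2 - m1^2
  if (cd <= 0) return(stats::median(x))
  c0 <- (-m2^2 + m1 * m3) / cd
  c1 <- (m1 * m2 - m3) / cd
  z0 <- 0.5 * (-c1 - sqrt(pmax(c1^2 - 4 * c0, 0)))
  z1 <- 0.5 * (-c1 + sqrt(pmax(c1^2 - 4 * c0, 0)))
  if (z1 == z0) return(stats::median(x))
  pd <- (z1 - m1) / (z1 - z0)  # fraction of pixels below threshold
  cum <- cumsum(p)
  h$mids[which.min(abs(cum - pd))]
}

#' Histogram-based automatic threshold
#'
#' @param x numeric vector or array of intensities.
#' @param method one of "otsu", "yen", "moments", or "max_otsu_yen" (the
#'   larger of Otsu's and Yen's threshold; conservative foreground).
#' @return threshold value; voxels with intensity strictly above it are
#'   considered foreground. `NA` for constant input.
#' @export
auto_threshold <- function(x, method = c("otsu", "yen", "moments",
                                         "max_otsu_yen")) {
  method <- match.arg(method)
  switch(method,
    otsu = threshold_otsu(x),
    yen = threshold_yen(x),
    moments = threshold_moments(x),
    max_otsu_yen = {
      t1 <- threshold_otsu(x)
      t2 <- threshold_yen(x)
      if (is.na(t1) || is.na(t2)) NA_real_ else max(t1, t2)
    })
}

# --- connected components ------------------------------------------------

# 26-connected (3D) / 8-connected (2D) labelling of a logical array via
# graph components on the foreground voxels.
label_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  labels <- array(0L, d)
  if (length(idx) == 0L) return(labels)
  nd <- length(d)
  coords <- arrayInd(idx, d)
  pos <- integer(prod(d))
  pos[idx] <- seq_along(idx)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # keep only half the offsets (undirected edges counted once)
  keep <- apply(offsets, 1, function(o) {
    nz <- which(o != 0)[1]
    o[nz] > 0
  })
  offsets <- offsets[keep, , drop = FALSE]
  edges_from <- integer(0); edges_to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[r, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (j in seq_len(nd)) ok <- ok & nb[, j] >= 1L & nb[, j] <= d[j]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1]
    if (nd >= 2) nb_lin <- nb_lin + (nb[ok, 2] - 1L) * d[1]
    if (nd >= 3) nb_lin <- nb_lin + (nb[ok, 3] - 1L) * d[1] * d[2]
    nb_pos <- pos[nb_lin]
    hit <- nb_pos > 0L
    edges_from <- c(edges_from, which(ok)[hit])
    edges_to <- c(edges_to, nb_pos[hit])
  }
  g <- igraph::make_graph(edges = as.vector(rbind(edges_from, edges_to)),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # canonical labels by first occurrence in linear order
  first <- match(unique(comp), comp)
  relabel <- integer(max(comp))
  relabel[comp[sort(first)]] <- seq_along(first)
  labels[idx] <- relabel[comp]
  labels
}

# local maxima of a 2D/3D array over the full (8/26) neighbourhood;
# strict greater-than against all neighbours, with >= against later ties
# broken by linear index so coincident plateaus yield one maximum.
local_maxima <- function(a, mask = NULL) {
  d <- dim(a)
  nd <- length(d)
  offsets <- as.matrix(do.call(expand.grid, rep(list(-1:1), nd)))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  is_max <- array(TRUE, d)
  lin <- array(seq_len(prod(d)), d)
  for (r in seq_len(nrow(offsets))) {
    shifted <- a
    shifted_lin <- lin
    for (j in seq_len(nd)) {
      o <- offsets[r, j]
      if (o == 0) next
      n <- d[j]
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      if (nd == 2L) {
        shifted <- if (j == 1L) shifted[idx, , drop = FALSE] else shifted[, idx, drop = FALSE]
        shifted_lin <- if (j == 1L) shifted_lin[idx, , drop = FALSE] else shifted_lin[, idx, drop = FALSE]
      } else {
        shifted <- switch(j, shifted[idx, , , drop = FALSE],
                          shifted[, idx, , drop = FALSE],
                          shifted[, , idx, drop = FALSE])
        shifted_lin <- switch(j, shifted_lin[idx, , , drop = FALSE],
                              shifted_lin[, idx, , drop = FALSE],
                              shifted_lin[, , idx, drop = FALSE])
      }
    }
    same <- shifted_lin == lin  # clamped at border: not a real neighbour
    is_max <- is_max & (same | (a > shifted) |
                          (a == shifted & lin < shifted_lin))
  }
  if (!is.null(mask)) is_max <- is_max & mask
  which(is_max)
}

# robust z-score: (x - median) / (1.4826 * MAD)
robust_z <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x, center = med)
  if (s == 0) s <- stats::sd(x)
  if (is.na(s) || s == 0) return(x * 0)
  (x - med) / s
}

# voxel-centre world coordinates (nm): world = (index - 0.5) * voxel_size
voxel_world <- function(coords, voxel_size) {
  sweep(coords - 0.5, 2, voxel_size, "*")
}
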