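#' Confocal spine co-occurrence pipeline
#'
#' Reproduces the confocal branch: the MAP2 channel is thresholded,
#' blurred, re-binarized and thinned to a dendrite skeleton; puncta are
#' detected per channel (mean filter, histogram threshold, Gaussian
#' blur, local maxima); Homer1 puncta farther than 2 um from the
#' skeleton are discarded; each remaining Homer1 punctum is scored for
#' co-occurrence of MPP2 and GABA-A receptor puncta within a 0.5-um
#' radius (an average spine head), and the per-image triple-positive
#' fraction is reported.
#'
#' @name spine_colocalization
NULL

#' Spine pipeline parameters
#'
#' @param mean_filter_radius mean (box) filter radius, pixels.
#' @param gaussian_sigma blur sigma, pixels.
#' @param threshold_method named character: threshold method per channel
#'   ("otsu", "yen", or "moments"); unnamed single value applies to all.
#' @param maxima_prominence minimum height of a maximum above the robust
#'   background (`NULL` = 3 x MAD of the blurred image).
#' @param dendrite_proximity maximum punctum-to-skeleton distance, nm.
#' @param cooccurrence_radius spine co-occurrence radius, nm.
#' @param pixel_size nm per pixel.
#' @export
spine_params <- function(mean_filter_radius = 1.5, gaussian_sigma = 1.5,
                         threshold_method = "otsu",
                         maxima_prominence = NULL,
                         dendrite_proximity = 2000,
                         cooccurrence_radius = 500,
                         pixel_size = 70) {
  stopifnot(mean_filter_radius > 0, gaussian_sigma > 0, pixel_size > 0)
  structure(list(mean_filter_radius = mean_filter_radius,
                 gaussian_sigma = gaussian_sigma,
                 threshold_method = threshold_method,
                 maxima_prominence = maxima_prominence,
                 dendrite_proximity = dendrite_proximity,
                 cooccurrence_radius = cooccurrence_radius,
                 pixel_size = pixel_size),
            class = "spine_params")
}

mean_filter_2d <- function(img, radius) {
  r <- floor(radius)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  ny <- nrow(img); nx <- ncol(img)
  acc <- matrix(0, ny, nx)
  for (k in seq_len(nrow(offs))) {
    iy <- pmin(pmax(seq_len(ny) + offs$dy[k], 1L), ny)
    ix <- pmin(pmax(seq_len(nx) + offs$dx[k], 1L), nx)
    acc <- acc + img[iy, ix]
  }
  acc / nrow(offs)
}

# Zhang-Suen thinning of a logical matrix to a 1-pixel skeleton
thin_mask <- function(mask) {
  m <- mask
  pad <- function(x) {
    out <- matrix(FALSE, nrow(x) + 2, ncol(x) + 2)
    out[2:(nrow(x) + 1), 2:(ncol(x) + 1)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      ny <- nrow(m); nx <- ncol(m)
      ci <- 2:(ny + 1); cj <- 2:(nx + 1)
      p2 <- p[ci - 1, cj]; p3 <- p[ci - 1, cj + 1]; p4 <- p[ci, cj + 1]
      p5 <- p[ci + 1, cj + 1]; p6 <- p[ci + 1, cj]
      p7 <- p[ci + 1, cj - 1]; p8 <- p[ci, cj - 1]; p9 <- p[ci - 1, cj - 1]
      bp <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      ap <- matrix(0L, ny, nx)
      for (k in 1:8) {
        ap <- ap + (!seqs[[k]] & seqs[[k + 1]])
      }
      if (step == 1) {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & bp >= 2 & bp <= 6 & ap == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Skeletonize the MAP2 dendrite channel
#'
#' Otsu threshold, Gaussian blur of the binary mask, re-binarization at
#' half maximum, then morphological thinning to a 1-pixel skeleton.
#'
#' @param map2 2D matrix (maximum projection).
#' @param params a [spine_params()].
#' @return logical matrix skeleton mask.
#' @export
skeletonize_dendrite <- function(map2, params = spine_params()) {
  thr <- auto_threshold(map2, "otsu")
  if (is.na(thr)) {
    warning("empty foreground: empty skeleton")
    return(matrix(FALSE, nrow(map2), ncol(map2)))
  }
  binary <- (map2 > thr) * 1
  if (!any(binary > 0)) {
    warning("empty foreground: empty skeleton")
    return(matrix(FALSE, nrow(map2), ncol(map2)))
  }
  blurred <- gaussian_filter(binary, params$gaussian_sigma)
  rebin <- blurred >= max(blurred) / 2
  thin_mask(rebin)
}

#' Detect puncta in one channel
#'
#' Mean filter, histogram threshold, Gaussian blur, local maxima above
#' the threshold and above a prominence floor; positions refined by the
#' intensity centroid of the 3x3 neighbourhood (sub-pixel) and returned
#' in nm.
#'
#' @param img 2D matrix.
#' @param params a [spine_params()].
#' @param channel optional channel name to select the per-channel
#'   threshold method.
#' @return matrix with columns x, y (nm).
#' @export
detect_puncta <- function(img, params = spine_params(), channel = NULL) {
  method <- params$threshold_method
  if (!is.null(names(method)) && !is.null(channel) &&
      channel %in% names(method)) {
    method <- method[[channel]]
  } else {
    method <- method[[1]]
  }
  filtered <- mean_filter_2d(img, params$mean_filter_radius)
  # clip at a fixed robust z before thresholding: saturated or
  # overlapping puncta otherwise stretch the histogram and pull the
  # threshold above ordinary spot peaks, while clipping far above the
  # noise floor never touches the background mode
  s_mad <- stats::mad(filtered)
  capped <- if (s_mad > 0) {
    pmin(filtered, stats::median(filtered) + 30 * s_mad)
  } else {
    filtered
  }
  thr <- auto_threshold(capped, method)
  if (is.na(thr)) return(cbind(x = numeric(0), y = numeric(0)))
  # a threshold that keeps a large area has split the background mode,
  # i.e. the channel carries no punctate signal
  if (mean(filtered > thr) > 0.25) {
    return(cbind(x = numeric(0), y = numeric(0)))
  }
  blurred <- gaussian_filter(filtered, params$gaussian_sigma)
  prom <- params$maxima_prominence %||%
    (3 * stats::mad(blurred))
  floor_val <- max(thr, stats::median(blurred) + prom)
  idx <- local_maxima(blurred, mask = blurred > floor_val)
  if (!length(idx)) return(cbind(x = numeric(0), y = numeric(0)))
  d <- dim(img)
  coords <- arrayInd(idx, d)
  px <- params$pixel_size
  pos <- t(apply(coords, 1, function(rc) {
    iy <- pmin(pmax((rc[1] - 1):(rc[1] + 1), 1L), d[1])
    ix <- pmin(pmax((rc[2] - 1):(rc[2] + 1), 1L), d[2])
    w <- blurred[iy, ix]
    w <- pmax(w, 0)
    if (sum(w) == 0) w <- w + 1
    cy <- sum(outer(iy, rep(1, length(ix))) * w) / sum(w)
    cx <- sum(outer(rep(1, length(iy)), ix) * w) / sum(w)
    c((cx - 0.5) * px, (cy - 0.5) * px)
  }))
  cbind(x = pos[, 1], y = pos[, 2])
}

#' Keep puncta within a distance of the dendrite skeleton
#'
#' @param puncta matrix with x, y columns (nm).
#' @param skeleton logical skeleton mask.
#' @param max_distance nm (default 2000: the 2-um dendrite periphery).
#' @param pixel_size nm per pixel.
#' @export
filter_near_skeleton <- function(puncta, skeleton, max_distance = 2000,
                                 pixel_size = 70) {
  if (!any(skeleton)) {
    warning("empty skeleton: all puncta removed")
    return(puncta[integer(0), , drop = FALSE])
  }
  if (!nrow(puncta)) return(puncta)
  sk <- arrayInd(which(skeleton), dim(skeleton))
  skx <- (sk[, 2] - 0.5) * pixel_size
  sky <- (sk[, 1] - 0.5) * pixel_size
  keep <- vapply(seq_len(nrow(puncta)), function(i) {
    min(sqrt((skx - puncta[i, "x"])^2 + (sky - puncta[i, "y"])^2)) <=
      max_distance
  }, logical(1))
  puncta[keep, , drop = FALSE]
}

#' Score per-spine co-occurrence of MPP2 and GABA-A puncta
#'
#' For each Homer1 punctum, `has_mpp2` / `has_gabaar` are true iff at
#' least one punctum of that channel lies within `radius`; the reported
#' fraction is (# spines with both) / (# Homer1 puncta).
#'
#' @param homer,mpp2,gabaar puncta matrices with x, y columns (nm).
#' @param radius co-occurrence radius, nm.
#' @return list with `records` (data.frame: x, y, has_mpp2, has_gabaar,
#'   positive) and `fraction` (NA with a flag when there are no Homer
#'   puncta).
#' @export
score_cooccurrence <- function(homer, mpp2, gabaar, radius = 500) {
  if (!nrow(homer)) {
    return(list(records = data.frame(), fraction = NA_real_,
                defined = FALSE))
  }
  near_any <- function(p, set) {
    if (!nrow(set)) return(rep(FALSE, nrow(p)))
    vapply(seq_len(nrow(p)), function(i) {
      any(sqrt((set[, "x"] - p[i, "x"])^2 +
                 (set[, "y"] - p[i, "y"])^2) <= radius)
    }, logical(1))
  }
  has_mpp2 <- near_any(homer, mpp2)
  has_gabaar <- near_any(homer, gabaar)
  records <- data.frame(x = homer[, "x"], y = homer[, "y"],
                        has_mpp2 = has_mpp2, has_gabaar = has_gabaar,
                        positive = has_mpp2 & has_gabaar)
  list(records = records, fraction = mean(records$positive),
       defined = TRUE)
}

#' Run the full spine pipeline on one scene
#'
#' @param images named list of matrices (MAP2, Homer1, MPP2, GABAAR).
#' @param params a [spine_params()].
#' @return list with `fraction`, `records`, `n_homer`, `skeleton`.
#' @export
analyze_spine_scene <- function(images, params = spine_params()) {
  skeleton <- skeletonize_dendrite(images$MAP2, params)
  homer <- detect_puncta(images$Homer1, params, "Homer1")
  mpp2 <- detect_puncta(images$MPP2, params, "MPP2")
  gabaar <- detect_puncta(images$GABAAR, params, "GABAAR")
  homer <- filter_near_skeleton(homer, skeleton,
                                params$dendrite_proximity,
                                params$pixel_size)
  res <- score_cooccurrence(homer, mpp2, gabaar,
                            params$cooccurrence_radius)
  list(fraction = res$fraction, records = res$records,
       n_homer = nrow(homer), skeleton = skeleton)
}
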