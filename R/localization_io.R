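#' Localization tables: I/O, precision filtering and Gaussian rendering
#'
#' Single-molecule localization microscopy produces tables of detections
#' (x/y and optionally z in nm) with a per-detection localization
#' precision (Thompson estimate, nm). These functions read and write the
#' CSV dialect used throughout the package, apply the precision quality
#' filter, and render filtered localizations as a super-resolved image in
#' which every localization contributes a unit-mass Gaussian.
#'
#' @name localization_io
NULL

# canonical column order and CSV header aliases
.loc_columns <- c("x", "y", "z", "frame", "intensity", "uncertainty",
                  "channel")

.loc_aliases <- list(
  x = c("x", "x [nm]", "x_nm", "xnm", "x(nm)"),
  y = c("y", "y [nm]", "y_nm", "ynm", "y(nm)"),
  z = c("z", "z [nm]", "z_nm", "znm", "z(nm)"),
  frame = c("frame", "frame id", "t"),
  intensity = c("intensity", "intensity [photon]", "photons",
                "intensity [photons]"),
  uncertainty = c("uncertainty", "uncertainty [nm]", "uncertainty_xy [nm]",
                  "precision", "precision [nm]", "loc_precision"),
  channel = c("channel", "channel id", "color", "species")
)

#' Construct a localization table
#'
#' @param x,y,z coordinates in nm (`z` optional).
#' @param frame acquisition frame index.
#' @param intensity photon count (optional).
#' @param uncertainty localization precision in nm.
#' @param channel channel/species label.
#' @return a `data.frame` of class `localization_table`; all lengths in nm.
#' @export
localization_table <- function(x, y, z = NULL, frame = 1L,
                               intensity = NA_real_,
                               uncertainty, channel = "ch1") {
  stopifnot_finite(x, "x"); stopifnot_finite(y, "y")
  stopifnot_finite(uncertainty, "uncertainty")
  if (any(uncertainty < 0)) stop("uncertainty must be >= 0")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (!is.null(z)) df$z <- as.numeric(z)
  n <- nrow(df)
  df$frame <- rep_len(as.integer(frame), n)
  df$intensity <- rep_len(as.numeric(intensity), n)
  df$uncertainty <- rep_len(as.numeric(uncertainty), n)
  df$channel <- rep_len(as.character(channel), n)
  class(df) <- c("localization_table", "data.frame")
  df
}

#' Read a localization CSV file
#'
#' Columns are mapped by header-name aliases (e.g. `"x [nm]"`,
#' `"uncertainty [nm]"`). Rows with non-numeric coordinates are dropped
#' with a message reporting the count. x, y and uncertainty are mandatory.
#'
#' @param path path to a comma-separated file with a header row.
#' @param aliases optional list extending the built-in header alias map.
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, aliases = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  amap <- .loc_aliases
  for (nm in names(aliases)) {
    amap[[nm]] <- unique(c(amap[[nm]], aliases[[nm]]))
  }
  lowered <- tolower(trimws(names(raw)))
  cols <- list()
  for (canon in names(amap)) {
    hit <- which(lowered %in% tolower(amap[[canon]]))
    if (length(hit)) cols[[canon]] <- raw[[hit[1]]]
  }
  for (req in c("x", "y", "uncertainty")) {
    if (is.null(cols[[req]])) {
      stop(sprintf("mandatory column '%s' not found in %s", req, path))
    }
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  xs <- num(cols$x); ys <- num(cols$y); us <- num(cols$uncertainty)
  zs <- if (!is.null(cols$z)) num(cols$z) else NULL
  bad <- !is.finite(xs) | !is.finite(ys) | !is.finite(us)
  if (!is.null(zs)) bad <- bad | !is.finite(zs)
  if (any(bad)) {
    message(sum(bad), " row(s) with non-numeric coordinates dropped")
  }
  keep <- !bad
  localization_table(
    x = xs[keep], y = ys[keep],
    z = if (!is.null(zs)) zs[keep] else NULL,
    frame = if (!is.null(cols$frame)) num(cols$frame)[keep] else 1L,
    intensity = if (!is.null(cols$intensity)) num(cols$intensity)[keep]
                else NA_real_,
    uncertainty = us[keep],
    channel = if (!is.null(cols$channel)) as.character(cols$channel)[keep]
              else "ch1")
}

#' Write a localization table in the package CSV dialect
#'
#' @param table a [localization_table()].
#' @param path output path.
#' @export
write_localizations <- function(table, path) {
  out <- data.frame(check.names = FALSE,
                    `x [nm]` = table$x, `y [nm]` = table$y)
  if (!is.null(table$z)) out[["z [nm]"]] <- table$z
  out[["frame"]] <- table$frame
  out[["intensity [photon]"]] <- table$intensity
  out[["uncertainty [nm]"]] <- table$uncertainty
  out[["channel"]] <- table$channel
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter localizations by precision
#'
#' Keeps rows whose localization precision is at least as good as
#' `max_uncertainty`: localizations with precision *worse than* the
#' threshold are excluded, so the boundary value is retained
#' (`uncertainty <= max_uncertainty`). Row order is preserved.
#'
#' @param table a [localization_table()].
#' @param max_uncertainty threshold in nm (default 20).
#' @return the filtered table; the number of removed rows is reported via
#'   `message()` and attached as attribute `"n_removed"`.
#' @export
filter_by_precision <- function(table, max_uncertainty = 20) {
  if (is.null(table$uncertainty)) stop("uncertainty column required")
  keep <- table$uncertainty <= max_uncertainty
  removed <- sum(!keep)
  if (removed > 0) {
    message(removed, " localization(s) removed by precision filter")
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- removed
  out
}

#' Rendering parameters
#'
#' @param render_width Gaussian kernel width in nm; interpreted as FWHM
#'   by default (`width_is` = "fwhm"), optionally as sigma.
#' @param pixel_size rendered pixel size in nm.
#' @param width_is how to interpret `render_width`.
#' @export
render_params <- function(render_width = 20, pixel_size = 10,
                          width_is = c("fwhm", "sigma")) {
  width_is <- match.arg(width_is)
  stopifnot(render_width > 0, pixel_size > 0)
  structure(list(render_width = render_width, pixel_size = pixel_size,
                 width_is = width_is), class = "render_params")
}

#' Convert a Gaussian FWHM to sigma
#'
#' sigma = FWHM / (2 * sqrt(2 * log(2))).
#' @param fwhm full width at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Render localizations as a Gaussian-blurred 2D image
#'
#' Every localization contributes a unit-mass isotropic Gaussian of
#' constant width, so the image integral equals the number of rendered
#' localizations. Image convention: y increases downward (rows), pixels
#' are half-open bins `[lo, hi)`.
#'
#' @param table a [localization_table()].
#' @param params a [render_params()].
#' @param bounds numeric `c(xmin, xmax, ymin, ymax)` in nm; inferred from
#'   the data (plus a 3-sigma margin) when `NULL`.
#' @return numeric matrix (rows = y, columns = x) with attributes
#'   `bounds` and `pixel_size`.
#' @export
render_gaussian <- function(table, params = render_params(),
                            bounds = NULL) {
  sigma <- if (params$width_is == "fwhm") {
    fwhm_to_sigma(params$render_width)
  } else {
    params$render_width
  }
  px <- params$pixel_size
  if (px > params$render_width) {
    warning("pixel_size exceeds render_width: kernel is undersampled")
  }
  if (is.null(bounds)) {
    m <- 3 * sigma + px
    if (nrow(table) == 0) {
      bounds <- c(0, px, 0, px)
    } else {
      bounds <- c(min(table$x) - m, max(table$x) + m,
                  min(table$y) - m, max(table$y) + m)
    }
  }
  nx <- max(1L, ceiling((bounds[2] - bounds[1]) / px))
  ny <- max(1L, ceiling((bounds[4] - bounds[3]) / px))
  img <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(table) > 0) {
    half <- ceiling(4 * sigma / px)
    for (i in seq_len(nrow(table))) {
      cx <- (table$x[i] - bounds[1]) / px
      cy <- (table$y[i] - bounds[3]) / px
      jc <- floor(cx) + 1L
      ic <- floor(cy) + 1L
      js <- max(1L, jc - half):min(nx, jc + half)
      is <- max(1L, ic - half):min(ny, ic + half)
      # integrate the Gaussian over each pixel via the error function
      # difference, preserving unit mass under discretization
      gx <- stats::pnorm((js * px), cx * px, sigma) -
        stats::pnorm(((js - 1) * px), cx * px, sigma)
      gy <- stats::pnorm((is * px), cy * px, sigma) -
        stats::pnorm(((is - 1) * px), cy * px, sigma)
      img[is, js] <- img[is, js] + outer(gy, gx)
    }
  }
  attr(img, "bounds") <- bounds
  attr(img, "pixel_size") <- px
  img
}
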