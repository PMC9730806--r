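#' Piecewise-linear histogram-matching intensity standardizer
#'
#' Implements Nyul-style intensity standardization: a standard intensity
#' scale is learned from a training set as the per-landmark mean of each
#' volume's foreground percentile intensities, after each volume's landmarks
#' are affinely mapped to a fixed range (0 to 100).  New volumes are
#' normalized by the piecewise-linear map sending their landmark intensities
#' to the standard ones, with linear extrapolation beyond the outermost
#' landmarks.
#'
#' Landmarks default to the 1st and 99th percentiles plus the deciles.
#' Percentiles are computed within the brain mask when one is provided and
#' over strictly positive voxels otherwise, so that background zeros do not
#' dominate the histogram.
#'
#' @param volumes list of `volume3d` (the training set; both timepoints of
#'   all training cases are pooled into one scale).
#' @param masks optional list of `lesion_mask` brain masks, parallel to
#'   `volumes`.
#' @param landmark_percentiles strictly increasing percentiles in (0, 100).
#' @return An object of class `intensity_standardizer`.
#' @export
fit_standardizer <- function(volumes, masks = NULL,
                             landmark_percentiles = c(1, seq(10, 90, by = 10), 99)) {
  if (inherits(volumes, "volume3d")) volumes <- list(volumes)
  if (length(volumes) < 1L) stop("fit_standardizer: at least one volume required")
  lp <- as.numeric(landmark_percentiles)
  if (any(diff(lp) <= 0) || any(lp <= 0) || any(lp >= 100))
    stop("fit_standardizer: landmark percentiles must be strictly increasing in (0, 100)")
  mapped <- vapply(seq_along(volumes), function(i) {
    fg <- foreground_values(volumes[[i]], if (!is.null(masks)) masks[[i]])
    q <- stats::quantile(fg, lp / 100, names = FALSE, type = 7)
    if (q[length(q)] - q[1] <= 0)
      stop("degenerate intensity distribution: landmark range collapses")
    (q - q[1]) / (q[length(q)] - q[1]) * 100
  }, numeric(length(lp)))
  std <- rowMeans(matrix(mapped, nrow = length(lp)))
  if (any(diff(std) <= 0))
    stop("degenerate intensity distribution: standard scale not strictly increasing")
  structure(list(landmark_percentiles = lp, standard_scale_landmarks = std,
                 trained = TRUE),
            class = "intensity_standardizer")
}

foreground_values <- function(vol, mask = NULL) {
  fg <- if (!is.null(mask)) vol$data[mask$data > 0] else vol$data[vol$data > 0]
  if (length(fg) < 2L || length(unique(fg)) < 2L)
    stop("degenerate intensity distribution: volume is (near-)constant")
  fg
}

#' @export
print.intensity_standardizer <- function(x, ...) {
  cat("<intensity_standardizer> landmarks at percentiles",
      paste(x$landmark_percentiles, collapse = ", "), "\n")
  cat("  standard scale:", paste(signif(x$standard_scale_landmarks, 4),
                                 collapse = ", "), "\n")
  invisible(x)
}

# Monotone piecewise-linear map through (nodes, values) with linear
# extrapolation using the slopes of the outermost segments.
piecewise_linear_map <- function(x, nodes, values) {
  y <- stats::approx(nodes, values, xout = pmin(pmax(x, nodes[1]),
                                                nodes[length(nodes)]),
                     ties = "ordered")$y
  lo <- x < nodes[1]
  if (any(lo)) {
    s <- (values[2] - values[1]) / (nodes[2] - nodes[1])
    y[lo] <- values[1] + s * (x[lo] - nodes[1])
  }
  n <- length(nodes)
  hi <- x > nodes[n]
  if (any(hi)) {
    s <- (values[n] - values[n - 1]) / (nodes[n] - nodes[n - 1])
    y[hi] <- values[n] + s * (x[hi] - nodes[n])
  }
  y
}

#' Normalize a volume onto the standard intensity scale
#'
#' @param vol a `volume3d`.
#' @param std a trained [fit_standardizer()] object.
#' @param mask optional brain `lesion_mask`; when given, the volume's
#'   landmark intensities are estimated within it (the same foreground rule
#'   used during fitting).
#' @return A `volume3d` on the same grid with standardized intensities.
#' @export
normalize_volume <- function(vol, std, mask = NULL) {
  if (!inherits(std, "intensity_standardizer") || !isTRUE(std$trained))
    stop("normalize_volume: standardizer is not trained")
  fg <- foreground_values(vol, mask)
  nodes <- stats::quantile(fg, std$landmark_percentiles / 100,
                           names = FALSE, type = 7)
  if (any(diff(nodes) <= 0))
    stop("degenerate intensity distribution: landmark intensities not strictly increasing")
  out <- piecewise_linear_map(as.numeric(vol$data), nodes,
                              std$standard_scale_landmarks)
  volume3d(array(out, dim(vol$data)), vol$spacing, vol$affine)
}

#' Save / load an intensity standardizer as JSON
#'
#' @param std an `intensity_standardizer`.
#' @param path JSON file path.
#' @export
save_standardizer <- function(std, path) {
  jsonlite::write_json(list(landmark_percentiles = std$landmark_percentiles,
                            standard_scale_landmarks = std$standard_scale_landmarks),
                       path, digits = NA)
  invisible(path)
}

#' @rdname save_standardizer
#' @export
load_standardizer <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(landmark_percentiles = as.numeric(x$landmark_percentiles),
                 standard_scale_landmarks = as.numeric(x$standard_scale_landmarks),
                 trained = TRUE),
            class = "intensity_standardizer")
}

#' Trivial intensity-threshold brain mask
#'
#' A deliberately simple stand-in for full skull stripping, intended for
#' phantoms and for already skull-stripped inputs: voxels above
#' `threshold_fraction` times the 99th-percentile intensity, keeping only the
#' largest 26-connected component, with interior holes filled.
#'
#' @param vol a `volume3d` (must not be constant).
#' @param threshold_fraction fraction in (0, 1) of the 99th-percentile
#'   intensity used as the threshold.
#' @return A `lesion_mask` marking brain voxels.
#' @export
trivial_brain_mask <- function(vol, threshold_fraction = 0.5) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1)
  x <- vol$data
  if (max(x) - min(x) <= 0)
    stop("degenerate intensity distribution: volume is constant")
  thr <- threshold_fraction * stats::quantile(x, 0.99, names = FALSE)
  m <- array(as.integer(x > thr), dim(x))
  lab <- .label_components3d(m, dim(m), 26L)
  if (max(lab) == 0L)
    stop("degenerate intensity distribution: no voxels above threshold")
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  m <- array(as.integer(lab == keep), dim(x))
  m <- fill_holes(m)
  lesion_mask(m, vol$spacing, affine = vol$affine)
}

# Fill interior cavities: 6-connected background components that do not
# touch the array border are inside the object.
fill_holes <- function(m) {
  inv <- array(as.integer(m == 0L), dim(m))
  lab <- .label_components3d(inv, dim(inv), 6L)
  d <- dim(m)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  hole <- lab > 0L & !(lab %in% border)
  m[hole] <- 1L
  m
}
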