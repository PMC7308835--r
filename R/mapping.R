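#' @include AllClasses.R
NULL

#' Pixel-wise FP prediction over a leaf
#'
#' Applies a fitted calibration model to the spectrum of every in-mask
#' pixel, using exactly the band subset the model was trained on (bands
#' are matched by wavelength against the cube grid). Out-of-mask pixels
#' are no-data (NA). Negative predictions are preserved in the stored
#' map (the display range clips them at rendering time), so diagnostics
#' do not hide model behaviour.
#'
#' @param cube Reflectance [SpectralCube-class], trimmed to the analysis
#'   window.
#' @param mask Logical rows x cols leaf mask (e.g. from [segmentLeaf()]).
#' @param model A fitted PLS, LS-SVM or ELM model.
#' @param range Optional display range, mg/g; defaults to the in-mask
#'   prediction range (widened minimally if degenerate).
#' @return A [PredictionMap-class].
#' @export
predictMap <- function(cube, mask, model, range = NULL) {
  stopifnot(is(cube, "SpectralCube"))
  d <- dim(cube@values)
  if (!identical(dim(mask), d[2:3])) stop("mask dims must match the cube")
  if (!any(mask)) stop("empty mask")
  mwl <- wavelengths(model)
  bidx <- vapply(mwl, function(w) {
    j <- which.min(abs(cube@wavelength - w))
    if (abs(cube@wavelength[j] - w) > 1e-6)
      stop(sprintf("band mismatch: model band %.2f nm not in cube", w))
    j
  }, 0L)
  flat <- matrix(cube@values, nrow = d[1])
  idx <- which(mask)
  spectra <- t(flat[bidx, idx, drop = FALSE])
  pred <- predict(model, spectra)
  vals <- matrix(NA_real_, d[2], d[3])
  vals[idx] <- pred
  if (is.null(range)) {
    range <- range(pred)
    if (diff(range) <= 0) range <- range + c(-1e-6, 1e-6)
  }
  new("PredictionMap", values = vals, mask = mask, range = as.numeric(range))
}

#' Mean predicted FP of a map
#' @param map A [PredictionMap-class].
#' @return Mean of the in-mask predictions, mg/g.
#' @export
mapMean <- function(map) mean(map@values[map@mask])

#' Shared display range for a panel of maps
#'
#' The 1st-99th percentile of the pooled in-mask predictions of all
#' maps, so one colour scale serves a whole treatment panel.
#'
#' @param maps List of [PredictionMap-class] objects.
#' @param probs Length-2 probability vector.
#' @return Length-2 numeric range, mg/g.
#' @export
panelRange <- function(maps, probs = c(0.01, 0.99)) {
  v <- unlist(lapply(maps, function(m) m@values[m@mask]))
  r <- as.numeric(stats::quantile(v, probs))
  if (diff(r) <= 0) r <- r + c(-1e-6, 1e-6)
  r
}

#' Render a prediction map as a pseudo-colour PNG
#'
#' Maps each in-mask FP estimate linearly onto a fixed colour palette
#' over the display range (values outside the range are clipped to its
#' ends); background pixels are light grey. A vertical colour bar strip
#' spanning the display range is appended on the right, and the range in
#' mg/g is written to a `.range.txt` sidecar so rendered panels remain
#' quantitatively interpretable.
#'
#' @param map A [PredictionMap-class].
#' @param path Output PNG path.
#' @param range Display range, mg/g; defaults to the map's own.
#' @param palette Character vector of colours (low to high).
#' @param colorbar Append the colour bar strip.
#' @return Invisibly, `path`.
#' @export
renderPseudocolor <- function(map, path, range = map@range,
                              palette = grDevices::hcl.colors(256, "viridis"),
                              colorbar = TRUE) {
  stopifnot(is(map, "PredictionMap"))
  if (length(range) != 2 || range[1] >= range[2])
    stop("display range must satisfy lo < hi")
  ncol_ <- length(palette)
  rgbPal <- t(grDevices::col2rgb(palette)) / 255
  lookup <- function(v) {
    u <- pmin(pmax((v - range[1]) / diff(range), 0), 1)
    pmin(ncol_, 1L + as.integer(floor(u * (ncol_ - 1) + 0.5)))
  }
  nr <- nrow(map@values); nc <- ncol(map@values)
  img <- array(0.85, dim = c(nr, nc, 3))  # light grey background
  idx <- which(map@mask)
  ci <- lookup(map@values[idx])
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[idx] <- rgbPal[ci, ch]
    img[, , ch] <- plane
  }
  if (colorbar) {
    barw <- max(4L, nc %/% 16)
    bar <- array(1, dim = c(nr, barw + 2L, 3))
    # top row = high end of the range
    bi <- lookup(seq(range[2], range[1], length.out = nr))
    for (ch in 1:3) bar[, 1:barw, ch] <- matrix(rgbPal[bi, ch], nr, barw)
    img2 <- array(0.85, dim = c(nr, nc + barw + 2L, 3))
    img2[, 1:nc, ] <- img
    img2[, (nc + 1):(nc + barw + 2L), ] <- bar
    img <- img2
  }
  png::writePNG(img, path)
  writeLines(sprintf("display range (mg/g): %.6f %.6f", range[1], range[2]),
             paste0(path, ".range.txt"))
  invisible(path)
}

#' Write a prediction map as a single-band ENVI file
#'
#' No-data pixels are stored as the configured marker value.
#'
#' @param map A [PredictionMap-class].
#' @param path Output path without extension.
#' @param noData No-data marker value.
#' @return Invisibly, the header path.
#' @export
writeMap <- function(map, path, noData = -9999) {
  v <- map@values
  v[!map@mask] <- noData
  cube <- SpectralCube(array(v, dim = c(1, nrow(v), ncol(v))),
                       wavelength = 700,
                       metadata = list(kind = "fp-map", no_data = noData))
  writeCube(cube, path)
}
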