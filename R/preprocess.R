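#' @include AllClasses.R
NULL

#' Segment the leaf from the background
#'
#' Thresholds the reflectance of the band nearest `nirWavelength`
#' (leaves are bright in the NIR, backgrounds dark) and keeps the
#' largest connected component of the thresholded pixels.
#'
#' @param cube Corrected reflectance [SpectralCube-class].
#' @param nirWavelength Segmentation band, nm (nearest band centre used).
#' @param threshold Reflectance threshold.
#' @param minPixels Minimum pixel count of a usable leaf.
#' @return Logical rows x cols mask.
#' @export
segmentLeaf <- function(cube, nirWavelength = 800, threshold = 0.25,
                        minPixels = 50L) {
  stopifnot(is(cube, "SpectralCube"))
  b <- which.min(abs(cube@wavelength - nirWavelength))
  plane <- cube@values[b, , ]
  hit <- plane > threshold
  if (!any(hit)) stop("no leaf found: no pixel exceeds the NIR threshold")
  lab <- EBImage::bwlabel(hit * 1)
  tab <- tabulate(lab[lab > 0])
  mask <- lab == which.max(tab)
  if (sum(mask) < minPixels)
    stop("no usable leaf: largest component below ", minPixels, " pixels")
  mask
}

#' Mean spectrum over a mask
#'
#' Per-band arithmetic mean of the reflectance of all in-mask pixels.
#'
#' @param cube A [SpectralCube-class].
#' @param mask Logical rows x cols mask.
#' @return Numeric vector of length nbands.
#' @export
meanSpectrum <- function(cube, mask) {
  stopifnot(is(cube, "SpectralCube"))
  d <- dim(cube@values)
  if (!identical(dim(mask), d[2:3])) stop("mask dims must match the cube")
  if (!any(mask)) stop("empty mask")
  m <- matrix(cube@values, nrow = d[1])
  rowMeans(m[, as.vector(mask), drop = FALSE])
}

.trimIdx <- function(wavelength, window) {
  if (length(window) != 2 || window[1] > window[2])
    stop("window must be c(lo, hi) with lo <= hi")
  keep <- which(wavelength >= window[1] & wavelength <= window[2])
  if (length(keep) == 0) stop("empty window: no band centre inside it")
  keep
}

#' @rdname trimBands
setMethod("trimBands", "SpectralCube", function(x, window) {
  keep <- .trimIdx(x@wavelength, window)
  SpectralCube(x@values[keep, , , drop = FALSE], x@wavelength[keep],
               x@metadata)
})

#' @rdname trimBands
setMethod("trimBands", "SpectraTable", function(x, window) {
  keep <- .trimIdx(wavelengths(x), window)
  x[keep, ]
})

#' Assemble leaf spectra into the sample-level modeling table
#'
#' Averages the spectra of each sample's leaves (per band) and joins the
#' result with the sample's FP reference value and group labels. Every
#' sample must contribute exactly `leavesPerSample` spectra; the row is
#' invariant to the order of the leaves.
#'
#' @param leafSpectra Numeric leaves x bands matrix.
#' @param sampleIds Character, sample id of each leaf spectrum row.
#' @param reference data.frame with sample_id, day, cd_um, fp_mg_g.
#' @param wavelength Band centres in nm.
#' @param leavesPerSample Required leaves per sample.
#' @return A [SpectraTable-class], one row per sample.
#' @export
assembleSamples <- function(leafSpectra, sampleIds, reference, wavelength,
                            leavesPerSample = 4L) {
  leafSpectra <- as.matrix(leafSpectra)
  if (nrow(leafSpectra) != length(sampleIds))
    stop("one sample id per leaf spectrum required")
  counts <- table(sampleIds)
  if (any(counts != leavesPerSample))
    stop("every sample needs exactly ", leavesPerSample, " leaf spectra; ",
         "offending: ", paste(names(counts)[counts != leavesPerSample],
                              collapse = ", "))
  ids <- unique(reference$sample_id)
  if (!all(names(counts) %in% ids))
    stop("missing FP reference for: ",
         paste(setdiff(names(counts), ids), collapse = ", "))
  ids <- ids[ids %in% names(counts)]
  X <- t(vapply(ids, function(id)
    colMeans(leafSpectra[sampleIds == id, , drop = FALSE]),
    numeric(ncol(leafSpectra))))
  ref <- reference[match(ids, reference$sample_id), ]
  SpectraTable(X, wavelength, fp = ref$fp_mg_g, day = ref$day,
               cd_um = ref$cd_um, sample_id = ids)
}

#' Extract the modeling table from a directory of leaf cubes
#'
#' Convenience wrapper over the full image-processing path: reads each
#' raw leaf cube, applies white/dark reflectance correction with its
#' session's frames, segments the leaf, extracts the mean spectrum,
#' trims to the analysis window and assembles the per-sample table.
#'
#' @param dataset The manifest returned by [makeDataset()], or a list
#'   with `cubes`, `frames` and `reference` of the same shape.
#' @param window Analysis window in nm.
#' @param ... Passed to [segmentLeaf()].
#' @return A [SpectraTable-class].
#' @export
extractStudyTable <- function(dataset, window = c(500, 950), ...) {
  ref <- dataset$reference
  spectra <- NULL
  ids <- character(0)
  for (pth in dataset$cubes) {
    raw <- readCube(pth)
    base <- basename(pth)  # sample/leaf ids are encoded in the filename
    sid <- sub("_leaf[0-9]+$", "", base)
    day <- ref$day[match(sid, ref$sample_id)]
    fr <- dataset$frames[[as.character(day)]]
    cube <- reflectanceCorrect(raw, readCube(fr["white"]), readCube(fr["dark"]))
    cube <- trimBands(cube, window)
    mask <- segmentLeaf(cube, ...)
    spectra <- rbind(spectra, meanSpectrum(cube, mask))
    ids <- c(ids, sid)
  }
  wl <- .trimIdx(readCube(dataset$cubes[1])@wavelength, window)
  assembleSamples(spectra, ids, ref,
                  readCube(dataset$cubes[1])@wavelength[wl],
                  leavesPerSample = as.integer(table(ids)[1]))
}

#' Write a SpectraTable as CSV
#'
#' Columns: sample_id, day, cd_um, fp_mg_g, then one reflectance column
#' per band named by its centre to two decimals.
#'
#' @param st A [SpectraTable-class].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
writeSpectraTable <- function(st, path) {
  df <- cbind(groupLabels(st)[, c("sample_id", "day", "cd_um")],
              fp_mg_g = fpValues(st),
              as.data.frame(spectraMatrix(st)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a SpectraTable written by [writeSpectraTable()]
#'
#' @param path CSV path.
#' @return A [SpectraTable-class].
#' @export
readSpectraTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- c("sample_id", "day", "cd_um", "fp_mg_g")
  bands <- setdiff(colnames(df), meta)
  SpectraTable(as.matrix(df[, bands]), as.numeric(bands),
               fp = df$fp_mg_g, day = df$day, cd_um = df$cd_um,
               sample_id = df$sample_id)
}
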