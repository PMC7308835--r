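#' @include AllClasses.R
NULL

# Minimal ENVI-style I/O: text header (.hdr) plus raw band-sequential
# binary (.raw). Supported data types are 4 (float32) and 5 (float64);
# writing uses 5 so that round trips are exact.

.enviDataBytes <- c("4" = 4L, "5" = 8L)

#' Write a cube as ENVI header + raw binary
#'
#' Writes `<path>.hdr` (text header with dimensions, BSQ interleave, byte
#' order and the wavelength list in nm) and `<path>.raw` (band-sequential
#' little-endian binary). Doubles are written (ENVI data type 5), so a
#' write/read round trip reproduces values and grid exactly.
#'
#' @param cube A [SpectralCube-class].
#' @param path Output path without extension.
#' @return Invisibly, the header path.
#' @export
writeCube <- function(cube, path) {
  stopifnot(is(cube, "SpectralCube"))
  d <- dim(cube@values)
  hdr <- c(
    "ENVI",
    "description = {hyperFP spectral cube}",
    sprintf("samples = %d", d[3]),
    sprintf("lines = %d", d[2]),
    sprintf("bands = %d", d[1]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("wavelength = {%s}",
            paste(format(cube@wavelength, digits = 17, trim = TRUE,
                         scientific = FALSE), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  # BSQ: full image of band 1, then band 2, ... row-major within a band
  con <- file(paste0(path, ".raw"), "wb")
  on.exit(close(con))
  v <- aperm(cube@values, c(3, 2, 1))  # cols vary fastest, then rows, bands
  writeBin(as.vector(v), con, size = 8, endian = "little")
  invisible(paste0(path, ".hdr"))
}

.parseEnviHeader <- function(hdrPath) {
  txt <- paste(readLines(hdrPath, warn = FALSE), collapse = "\n")
  getNum <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*([0-9]+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_integer_ else as.integer(m[2])
  }
  getStr <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key, "\\s*=\\s*([^\\{\\n]+)"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) NA_character_ else trimws(m[2])
  }
  wlm <- regmatches(txt, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", txt))[[1]]
  wl <- if (length(wlm) < 2) numeric(0) else
    as.numeric(strsplit(wlm[2], ",")[[1]])
  list(samples = getNum("samples"), lines = getNum("lines"),
       bands = getNum("bands"), dataType = getNum("data type"),
       byteOrder = getNum("byte order"),
       interleave = tolower(getStr("interleave")), wavelength = wl)
}

#' Read an ENVI cube
#'
#' @param path Path without extension, or the `.hdr` path.
#' @return A [SpectralCube-class].
#' @export
readCube <- function(path) {
  path <- sub("\\.(hdr|raw)$", "", path)
  hdrPath <- paste0(path, ".hdr")
  rawPath <- paste0(path, ".raw")
  if (!file.exists(hdrPath)) stop("header not found: ", hdrPath)
  h <- .parseEnviHeader(hdrPath)
  if (anyNA(c(h$samples, h$lines, h$bands)))
    stop("malformed header: missing dimensions")
  if (length(h$wavelength) == 0)
    stop("malformed header: missing wavelength list")
  if (length(h$wavelength) != h$bands)
    stop("wavelength list length disagrees with band count")
  if (!identical(h$interleave, "bsq"))
    stop("unsupported interleave: ", h$interleave)
  if (!as.character(h$dataType) %in% names(.enviDataBytes))
    stop("unsupported data type: ", h$dataType)
  bytes <- .enviDataBytes[[as.character(h$dataType)]]
  nvals <- h$samples * h$lines * h$bands
  expected <- as.numeric(nvals) * bytes
  if (file.info(rawPath)$size != expected)
    stop(sprintf("dim mismatch: header implies %.0f bytes, file has %.0f",
                 expected, file.info(rawPath)$size))
  con <- file(rawPath, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = nvals, size = bytes,
               endian = if (isTRUE(h$byteOrder == 1)) "big" else "little")
  arr <- aperm(array(v, dim = c(h$samples, h$lines, h$bands)), c(3, 2, 1))
  SpectralCube(arr, h$wavelength, metadata = list(path = path))
}

#' Convert raw intensity to reflectance with white/dark references
#'
#' Two-point radiometric calibration: `(raw - dark) / (white - dark)`
#' elementwise, the dark frame giving the 0% and the whiteboard the
#' ~100% reflectance level. Reference frames may have any number of
#' image rows; by default they are averaged over rows (per band and
#' column) before use, suppressing reference noise. The result is
#' clipped to [0, 1.5]; the ceiling guards specular pixels.
#'
#' @param raw Raw intensity [SpectralCube-class].
#' @param white,dark Calibration frames ([SpectralCube-class]) with the
#'   same band count and column count as `raw`.
#' @param averageRows Average reference frames over rows before use.
#' @param clip Length-2 clipping range for the corrected reflectance.
#' @return Reflectance [SpectralCube-class].
#' @examples
#' wl <- makeWavelengthGrid(4, c(500, 950))
#' w <- SpectralCube(array(100, c(4, 3, 3)), wl)
#' d <- SpectralCube(array(10, c(4, 3, 3)), wl)
#' r <- reflectanceCorrect(w, w, d)   # whiteboard maps to 1.0
#' @export
reflectanceCorrect <- function(raw, white, dark, averageRows = TRUE,
                               clip = c(0, 1.5)) {
  stopifnot(is(raw, "SpectralCube"), is(white, "SpectralCube"),
            is(dark, "SpectralCube"))
  d <- dim(raw@values)
  dw <- dim(white@values); dd <- dim(dark@values)
  if (dw[1] != d[1] || dd[1] != d[1] || dw[3] != d[3] || dd[3] != d[3])
    stop("dim mismatch between raw cube and calibration frames")
  if (!averageRows && (dw[2] != d[2] || dd[2] != d[2]))
    stop("dim mismatch: per-pixel correction needs equal row counts")
  if (averageRows) {
    w <- apply(white@values, c(1, 3), mean)  # bands x cols
    k <- apply(dark@values, c(1, 3), mean)
    denom <- w - k
    if (any(denom <= 0)) stop("white - dark must be positive everywhere")
    w3 <- array(rep(w, times = d[2]), dim = c(d[1], d[3], d[2]))
    k3 <- array(rep(k, times = d[2]), dim = c(d[1], d[3], d[2]))
    wArr <- aperm(w3, c(1, 3, 2)); kArr <- aperm(k3, c(1, 3, 2))
  } else {
    wArr <- white@values; kArr <- dark@values
    if (any(wArr - kArr <= 0)) stop("white - dark must be positive everywhere")
  }
  refl <- (raw@values - kArr) / (wArr - kArr)
  refl <- pmin(pmax(refl, clip[1]), clip[2])
  SpectralCube(refl, raw@wavelength,
               metadata = c(raw@metadata, list(corrected = TRUE)))
}
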