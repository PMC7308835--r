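#' @include AllClasses.R
NULL

# Calibrated wavelength-grid constants: first band centre (nm), initial
# spacing (nm) and per-band spacing increment (nm). With 350 bands these
# place every consensus characteristic wavelength (CARS and Bw lists)
# within 0.006 nm of a band centre.
.GRID_FIRST <- 500.979
.GRID_D0 <- 1.22866
.GRID_STEP <- 2.6975e-4

# Consensus FP-related wavelengths (nm) used as centres of the planted
# FP-linked absorber in the synthetic forward model.
.FP_WAVELENGTHS <- c(601.37, 625.18, 626.44, 650.34, 689.56, 943.52)

# Forward-model mixing constants (reflectance units).
.PIG_DEPTH <- 0.04   # chlorophyll-like absorption depth at unit abundance
.WAT_DEPTH <- 0.06   # water-band absorption depth
.K_FP <- 0.25        # reflectance decrease per (mg/g FP) at the planted bands
.ABUND_CV <- 0.05    # leaf-to-leaf coefficient of variation of abundances
.DRY_SD <- 0.01      # SD of the dry-matter slope coefficient
.STRESS_PIG_LOSS <- 0.15  # max fractional chlorophyll loss at full severity

.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Build the spectrometer wavelength grid
#'
#' Band centres with affinely increasing spacing (about 1.229 nm at the
#' blue end growing to 1.323 nm at the NIR end), the spacing pattern of a
#' V10E-class imaging spectrograph over 500-950 nm. The default 350-band
#' grid spans 500.98-946.16 nm and places every consensus characteristic
#' wavelength within 0.01 nm of a band centre. For non-default sizes or
#' windows an affine-spacing grid with the same spacing-growth ratio is
#' laid edge-to-edge across the window.
#'
#' @param n_bands Number of band centres (>= 2).
#' @param window Length-2 numeric, nm; must lie within [400, 1000].
#' @return Strictly increasing numeric vector of band centres in nm.
#' @examples
#' wl <- makeWavelengthGrid()
#' length(wl)          # 350
#' range(wl)           # within [500, 950]
#' @export
makeWavelengthGrid <- function(n_bands = 350L, window = c(500, 950)) {
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 2)
    stop("n_bands must be an integer >= 2")
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be c(lo, hi) with lo < hi")
  if (window[1] < 400 || window[2] > 1000)
    stop("window must lie within [400, 1000] nm")
  k <- seq_len(n_bands) - 1
  if (n_bands == 350L && isTRUE(all.equal(as.numeric(window), c(500, 950)))) {
    wl <- .GRID_FIRST + .GRID_D0 * k + .GRID_STEP * k * (k - 1) / 2
  } else {
    ratio <- (.GRID_D0 + .GRID_STEP * 348) / .GRID_D0
    span <- diff(window)
    if (n_bands == 2L) {
      wl <- window
    } else {
      d0 <- span / ((n_bands - 1) * (1 + (ratio - 1) / 2))
      s <- d0 * (ratio - 1) / (n_bands - 2)
      wl <- window[1] + d0 * k + s * k * (k - 1) / 2
    }
  }
  as.numeric(wl)
}

#' Day-level FP reference statistics of the stress study
#'
#' Per-day summary statistics (n, min, max, mean, SD; mg/g fresh weight)
#' of the FP wet-chemistry reference values that the synthetic study is
#' calibrated to reproduce at the pooled-day level.
#'
#' @return data.frame with columns day, n, min, max, mean, sd.
#' @export
referenceDayStats <- function() {
  data.frame(
    day = c(5, 10, 15, 20),
    n = c(25L, 25L, 25L, 25L),
    min = c(0.0740, 0.1170, 0.1304, 0.1401),
    max = c(0.1359, 0.1479, 0.1795, 0.2186),
    mean = c(0.1027, 0.1335, 0.1622, 0.1880),
    sd = c(0.0172, 0.0096, 0.0138, 0.0192))
}

#' Default FP trend table of the synthetic study
#'
#' Group-level FP means and within-group SDs for each (Cd concentration,
#' day) cell. The cell means are interpolated so that (i) pooling the
#' five groups of a day reproduces the day-level mean exactly and the
#' day-level SD approximately (between-group plus within-group variance),
#' and (ii) the ordinal narrative of the stress response holds: at day 5
#' the 5 uM group is highest while higher concentrations fall below the
#' control; at days 15 and 20 group means increase monotonically with
#' concentration and the control is lowest at day 20.
#'
#' @return data.frame with columns day, cd_um, mean, sd (mg/g).
#' @export
defaultTrendTable <- function() {
  cd <- c(0, 5, 25, 50, 100)
  data.frame(
    day = rep(c(5, 10, 15, 20), each = 5),
    cd_um = rep(cd, times = 4),
    mean = c(0.1030, 0.1260, 0.0980, 0.0940, 0.0925,
             0.1300, 0.1450, 0.1315, 0.1310, 0.1300,
             0.1430, 0.1540, 0.1625, 0.1700, 0.1815,
             0.1630, 0.1760, 0.1880, 0.1990, 0.2140),
    sd = rep(c(0.0121, 0.0077, 0.0041, 0.0074), each = 5))
}

#' FP ground truth of a synthetic study
#'
#' @slot samples data.frame: sample_id, day, cd_um, fp_mg_g (one row per
#'   biological sample; the wet-chemistry reference value).
#' @slot leaves data.frame: sample_id, leaf, fp_mg_g (one row per leaf;
#'   each sample's value is exactly the mean of its leaves).
#' @export
setClass("FPTruth", representation(samples = "data.frame",
                                   leaves = "data.frame"))

setValidity("FPTruth", function(object) {
  msg <- NULL
  if (any(object@samples$fp_mg_g <= 0) || any(object@leaves$fp_mg_g <= 0))
    msg <- c(msg, "all FP values must be > 0")
  m <- tapply(object@leaves$fp_mg_g, object@leaves$sample_id, mean)
  if (max(abs(m[object@samples$sample_id] - object@samples$fp_mg_g)) > 1e-10)
    msg <- c(msg, "per-sample FP must equal the mean of its leaves")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "FPTruth", function(object) {
  cat(sprintf("FPTruth: %d samples, %d leaves, FP %.4f-%.4f mg/g\n",
              nrow(object@samples), nrow(object@leaves),
              min(object@samples$fp_mg_g), max(object@samples$fp_mg_g)))
})

#' Simulate FP ground truth for a study design
#'
#' Draws one FP reference value per biological sample around its group
#' mean (Gaussian, truncated at zero by redraw) and then per-leaf values
#' around the sample value with mean-centred deviations, so that every
#' sample's FP equals the mean of its leaves exactly.
#'
#' @param design A [StudyDesign-class].
#' @param trend Trend table as from [defaultTrendTable()]; must cover
#'   every (concentration, day) cell of the design with sd >= 0.
#' @param leafSd SD (mg/g) of leaf-to-leaf FP variation within a sample.
#' @param seed Seed; defaults to the design's seed.
#' @return An [FPTruth-class] object.
#' @export
simulateFPTruth <- function(design, trend = defaultTrendTable(),
                            leafSd = 0.006, seed = design@seed) {
  stopifnot(is(design, "StudyDesign"))
  if (any(trend$sd < 0)) stop("trend SDs must be >= 0")
  key <- paste(trend$day, trend$cd_um)
  .withSeed(seed, {
    samples <- leaves <- list()
    for (d in design@days) for (cc in design@concentrations) {
      row <- match(paste(d, cc), key)
      if (is.na(row)) stop(sprintf("trend table missing cell day=%g cd=%g", d, cc))
      mu <- trend$mean[row]; sdev <- trend$sd[row]
      for (i in seq_len(design@samplesPerGroup)) {
        fp <- mu + if (sdev > 0) stats::rnorm(1, 0, sdev) else 0
        while (fp <= 0) fp <- mu + stats::rnorm(1, 0, sdev)
        id <- sprintf("d%02d_c%03d_s%02d", d, cc, i)
        L <- design@leavesPerSample
        dev <- if (leafSd > 0 && L > 1) stats::rnorm(L, 0, leafSd) else rep(0, L)
        dev <- dev - mean(dev)
        lf <- fp + dev
        if (any(lf <= 0)) lf <- pmax(lf, 1e-4) + (fp - mean(pmax(lf, 1e-4)))
        samples[[id]] <- data.frame(sample_id = id, day = d, cd_um = cc,
                                    fp_mg_g = fp)
        leaves[[id]] <- data.frame(sample_id = id, leaf = seq_len(L),
                                   fp_mg_g = lf)
      }
    }
    new("FPTruth",
        samples = do.call(rbind, c(samples, make.row.names = FALSE)),
        leaves = do.call(rbind, c(leaves, make.row.names = FALSE)))
  })
}

#' Endmember spectra of the synthetic leaf forward model
#'
#' The synthetic reflectance of a leaf pixel is
#' `base - aPig * pigment - aWat * water + aDry * dry - kFp * FP * fp`,
#' where `base` is a smooth green-leaf reflectance curve (green peak,
#' chlorophyll well, red-edge rise to a NIR plateau), `pigment` and
#' `water` are absorption shapes, `dry` a broad slope, and `fp` the
#' FP-linked absorber: unit weight at the six planted informative bands
#' (nearest grid bands to 601.37, 625.18, 626.44, 650.34, 689.56 and
#' 943.52 nm) and zero elsewhere. The band-localised absorber is a
#' deliberate design device: it makes wavelength-selection recovery a
#' well-posed assertion.
#'
#' @param wavelength Band centres in nm.
#' @return List with components `base`, `pigment`, `water`, `dry`, `fp`
#'   (numeric vectors over the grid) and `informative` (integer indices
#'   of the planted bands present in the grid).
#' @export
endmemberSet <- function(wavelength) {
  wl <- as.numeric(wavelength)
  base <- 0.10 + 0.38 * stats::plogis((wl - 712) / 16) +
    0.08 * exp(-0.5 * ((wl - 553) / 35)^2)
  pig <- exp(-0.5 * ((wl - 675) / 28)^2) +
    0.5 * exp(-0.5 * ((wl - 605) / 45)^2)
  pig <- pig / max(pig)
  wat <- exp(-0.5 * ((wl - 960) / 45)^2)
  dry <- (wl - 720) / 450
  fp <- numeric(length(wl))
  idx <- integer(0)
  for (w in .FP_WAVELENGTHS) {
    j <- which.min(abs(wl - w))
    if (abs(wl[j] - w) <= 2) idx <- c(idx, j)
  }
  idx <- sort(unique(idx))
  fp[idx] <- 1
  list(base = base, pigment = pig, water = wat, dry = dry, fp = fp,
       informative = idx)
}

# Stress severity in [0, 1] from the ordinal position of (cd, day) in the
# design; drives the gradual chlorophyll loss that broadens spectral group
# differences as stress time accumulates.
.severity <- function(cd, day, design) {
  ks <- sort(design@concentrations); ds <- sort(design@days)
  sc <- if (length(ks) > 1) (match(cd, ks) - 1) / (length(ks) - 1) else 0
  sd_ <- if (length(ds) > 1) (match(day, ds) - 1) / (length(ds) - 1) else 0
  sc * sd_
}

# Draw per-leaf abundance coefficients. Order of RNG draws is fixed.
.drawAbundances <- function(cd, day, design) {
  sev <- .severity(cd, day, design)
  list(pig = .PIG_DEPTH * (1 - .STRESS_PIG_LOSS * sev) *
         (1 + stats::rnorm(1, 0, .ABUND_CV)),
       wat = .WAT_DEPTH * (1 + stats::rnorm(1, 0, .ABUND_CV)),
       dry = stats::rnorm(1, 0, .DRY_SD))
}

# Leaf-level mean reflectance spectrum given abundances and FP (mg/g).
.forwardSpectrum <- function(em, ab, fp) {
  em$base - ab$pig * em$pigment - ab$wat * em$water + ab$dry * em$dry -
    .K_FP * fp * em$fp
}

#' Render a synthetic leaf hypercube with known per-pixel FP
#'
#' Builds a lanceolate leaf mask, assigns each pixel an FP value
#' `leaf_fp` times a tip-to-petiole gradient factor (linear along the
#' main axis, normalised to mean 1 over the mask so the leaf mean FP is
#' preserved; tip >= petiole), and renders mixture spectra with additive
#' per-band Gaussian noise. Background pixels carry a flat background
#' spectrum.
#'
#' @param leaf_fp Leaf-mean FP, mg/g (> 0).
#' @param wavelength Band centres in nm.
#' @param rows,cols Image dimensions (>= 32 each).
#' @param gradient Length-2 raw gradient factor range petiole..tip.
#' @param noiseSd Per-pixel per-band additive noise SD (reflectance).
#' @param background Background reflectance level.
#' @param abundances Optional list(pig, wat, dry); drawn if NULL.
#' @param cd_um,day Group labels used when drawing abundances.
#' @param design Design supplying the severity scale for abundances.
#' @param specNoiseSd SD of the per-leaf band-wise spectral residual
#'   (shared by all pixels of the leaf).
#' @param seed Seed controlling all randomness.
#' @return List with `cube` ([SpectralCube-class] of reflectance),
#'   `mask` (logical rows x cols), `fpMap` (numeric rows x cols, NA off
#'   the leaf) and `abundances`.
#' @export
renderLeafCube <- function(leaf_fp, wavelength, rows = 64L, cols = 64L,
                           gradient = c(0.9, 1.15), noiseSd = 0.01,
                           background = 0.04, abundances = NULL,
                           cd_um = 0, day = 5, design = studyDesign(),
                           specNoiseSd = 0.0025, seed = 1L) {
  if (leaf_fp <= 0) stop("leaf_fp must be > 0")
  if (rows < 32 || cols < 32) stop("image dims must be >= 32 x 32")
  wl <- as.numeric(wavelength)
  p <- length(wl)
  em <- endmemberSet(wl)
  .withSeed(seed, {
    # lanceolate mask: pointed petiole (left) and tip (right), broadest
    # about a third of the way up from the petiole
    jj <- seq_len(cols)
    t <- (jj - 2) / (cols - 4)
    hw <- ifelse(t <= 0 | t >= 1, -1,
                 0.30 * rows * (t^0.18 * (1 - t)^0.45) /
                   (0.286^0.18 * 0.714^0.45))
    mid <- (rows + 1) / 2
    mask <- outer(seq_len(rows), jj, function(r, j) abs(r - mid) <= hw[j])
    if (!any(mask)) stop("degenerate leaf shape: empty mask")
    if (sum(mask) < 50) stop("degenerate leaf shape: fewer than 50 pixels")
    # tip-to-petiole gradient, normalised to mean 1 over the mask
    g <- outer(rep(1, rows), gradient[1] + diff(gradient) * pmin(pmax(t, 0), 1))
    g <- g / mean(g[mask])
    fpMap <- matrix(NA_real_, rows, cols)
    fpMap[mask] <- leaf_fp * g[mask]
    if (is.null(abundances)) abundances <- .drawAbundances(cd_um, day, design)
    leafResid <- if (specNoiseSd > 0) stats::rnorm(p, 0, specNoiseSd) else numeric(p)
    base_noFp <- .forwardSpectrum(em, abundances, 0) + leafResid
    idx <- which(mask)
    # in-mask spectra are linear in pixel FP: base_noFp - kFp * fp_px * em$fp
    m <- matrix(base_noFp, nrow = p, ncol = length(idx)) -
      outer(.K_FP * em$fp, fpMap[idx])
    if (noiseSd > 0)
      m <- m + matrix(stats::rnorm(p * length(idx), 0, noiseSd), nrow = p)
    flat <- matrix(background, nrow = p, ncol = rows * cols)
    flat[, idx] <- m
    vals <- array(pmax(flat, 0), dim = c(p, rows, cols))
    list(cube = SpectralCube(vals, wl,
                             metadata = list(kind = "synthetic-leaf",
                                             leaf_fp = leaf_fp)),
         mask = mask, fpMap = fpMap, abundances = abundances)
  })
}

#' Simulate the sample-level modeling table of a study
#'
#' Generates the [SpectraTable-class] of the synthetic study directly at
#' the sample level: per-leaf mean spectra are computed in closed form
#' (the forward model is linear in pixel FP, so the pixel average equals
#' the model at the leaf-mean FP, with pixel noise attenuated by the
#' in-mask pixel count) and the configured number of leaves is averaged
#' into each sample row. Statistically equivalent to rendering every
#' leaf cube and extracting mean spectra, at a small fraction of the cost.
#'
#' @param design A [StudyDesign-class].
#' @param trend Trend table, see [defaultTrendTable()].
#' @param wavelength Band centres; default the 350-band grid.
#' @param noiseSd Per-pixel per-band noise SD (attenuated by `npixEff`).
#' @param specNoiseSd Per-leaf band-wise spectral residual SD.
#' @param npixEff Effective in-mask pixel count per leaf.
#' @param seed Seed; defaults to the design's seed.
#' @return A [SpectraTable-class]; `S4Vectors::metadata()` carries
#'   `informative` (planted band indices), `truth` (the [FPTruth-class])
#'   and the design.
#' @export
simulateSpectraTable <- function(design = studyDesign(),
                                 trend = defaultTrendTable(),
                                 wavelength = makeWavelengthGrid(),
                                 noiseSd = 0.01, specNoiseSd = 0.0025,
                                 npixEff = 900, seed = design@seed) {
  wl <- as.numeric(wavelength)
  p <- length(wl)
  em <- endmemberSet(wl)
  truth <- simulateFPTruth(design, trend, seed = seed)
  effSd <- noiseSd / sqrt(npixEff)
  .withSeed(seed + 1000L, {
    n <- nrow(truth@samples)
    X <- matrix(0, n, p)
    for (i in seq_len(n)) {
      s <- truth@samples[i, ]
      lf <- truth@leaves$fp_mg_g[truth@leaves$sample_id == s$sample_id]
      acc <- numeric(p)
      for (l in seq_along(lf)) {
        ab <- .drawAbundances(s$cd_um, s$day, design)
        spec <- .forwardSpectrum(em, ab, lf[l])
        if (specNoiseSd > 0) spec <- spec + stats::rnorm(p, 0, specNoiseSd)
        if (effSd > 0) spec <- spec + stats::rnorm(p, 0, effSd)
        acc <- acc + spec
      }
      X[i, ] <- acc / length(lf)
    }
    st <- SpectraTable(X, wl, fp = truth@samples$fp_mg_g,
                       day = truth@samples$day, cd_um = truth@samples$cd_um,
                       sample_id = truth@samples$sample_id)
    S4Vectors::metadata(st) <- list(informative = em$informative,
                                    truth = truth, design = design)
    st
  })
}

#' Write a full synthetic study to disk
#'
#' Writes one ENVI raw-intensity cube per leaf, one white and one dark
#' calibration frame per imaging session (one session per stress day),
#' and a CSV of FP reference values with one row per sample.
#'
#' @param design A [StudyDesign-class].
#' @param dir Output directory (created if needed).
#' @param trend Trend table, see [defaultTrendTable()].
#' @param rows,cols Per-leaf image dimensions.
#' @param noiseSd,specNoiseSd Noise settings, see [renderLeafCube()].
#' @param seed Seed; defaults to the design's seed.
#' @return Invisibly, a list with `reference` (the sample table),
#'   `cubes` (paths of the leaf cubes), `frames` (paths of white/dark
#'   frames per session) and `truth`.
#' @export
makeDataset <- function(design, dir, trend = defaultTrendTable(),
                        rows = 64L, cols = 64L, noiseSd = 0.01,
                        specNoiseSd = 0.0025, seed = design@seed) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  wl <- makeWavelengthGrid()
  truth <- simulateFPTruth(design, trend, seed = seed)
  # smooth instrument response: white counts per band, flat dark level
  white_counts <- 3500 * (0.6 + 0.4 * exp(-0.5 * ((wl - 720) / 180)^2))
  dark_counts <- 120
  frames <- list()
  for (d in design@days) {
    wcube <- SpectralCube(array(rep(white_counts, 8L * cols),
                                dim = c(length(wl), 8L, cols)), wl,
                          metadata = list(kind = "white", day = d))
    dcube <- SpectralCube(array(dark_counts, dim = c(length(wl), 8L, cols)),
                          wl, metadata = list(kind = "dark", day = d))
    wp <- file.path(dir, sprintf("white_d%02d", d))
    dp <- file.path(dir, sprintf("dark_d%02d", d))
    writeCube(wcube, wp); writeCube(dcube, dp)
    frames[[as.character(d)]] <- c(white = wp, dark = dp)
  }
  cubes <- character(0)
  for (i in seq_len(nrow(truth@samples))) {
    s <- truth@samples[i, ]
    lf <- truth@leaves$fp_mg_g[truth@leaves$sample_id == s$sample_id]
    for (l in seq_along(lf)) {
      leafSeed <- (seed + 7L * i + l) %% .Machine$integer.max
      r <- renderLeafCube(lf[l], wl, rows = rows, cols = cols,
                          noiseSd = noiseSd, specNoiseSd = specNoiseSd,
                          cd_um = s$cd_um, day = s$day, design = design,
                          seed = leafSeed)
      raw <- r$cube@values * rep(white_counts - dark_counts,
                                 times = rows * cols) + dark_counts
      rawCube <- SpectralCube(raw, wl,
                              metadata = list(kind = "raw-leaf",
                                              sample_id = s$sample_id,
                                              leaf = l))
      pth <- file.path(dir, sprintf("%s_leaf%d", s$sample_id, l))
      writeCube(rawCube, pth)
      cubes <- c(cubes, pth)
    }
  }
  ref <- truth@samples
  utils::write.csv(ref, file.path(dir, "fp_reference.csv"), row.names = FALSE)
  invisible(list(reference = ref, cubes = cubes, frames = frames,
                 truth = truth))
}
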