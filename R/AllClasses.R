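#' @include AllGenerics.R
NULL

# ---- StudyDesign ------------------------------------------------------------

#' Cadmium-stress study design
#'
#' Describes the factorial layout of the stress experiment: Cd
#' concentrations (uM), stress durations (days), number of biological
#' samples per (concentration, day) group and number of leaves averaged
#' into each sample.
#'
#' @slot concentrations Numeric, Cd levels in uM.
#' @slot days Numeric, stress durations in days.
#' @slot samplesPerGroup Integer, samples per group.
#' @slot leavesPerSample Integer, leaves averaged into a sample.
#' @slot seed Integer, master seed for all generator randomness.
#' @export
setClass("StudyDesign", representation(
  concentrations = "numeric",
  days = "numeric",
  samplesPerGroup = "integer",
  leavesPerSample = "integer",
  seed = "integer"
))

setValidity("StudyDesign", function(object) {
  msg <- NULL
  if (length(object@concentrations) < 1 || anyDuplicated(object@concentrations))
    msg <- c(msg, "concentrations must be non-empty and unique")
  if (any(object@concentrations < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (length(object@days) < 1 || any(object@days <= 0))
    msg <- c(msg, "days must be positive")
  if (object@samplesPerGroup < 1) msg <- c(msg, "samplesPerGroup must be >= 1")
  if (object@leavesPerSample < 1) msg <- c(msg, "leavesPerSample must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn StudyDesign constructor; defaults reproduce the full study
#'   layout (5 Cd levels x 4 time points x 5 samples, 4 leaves each).
#' @param concentrations,days,samplesPerGroup,leavesPerSample,seed see slots.
#' @export
studyDesign <- function(concentrations = c(0, 5, 25, 50, 100),
                        days = c(5, 10, 15, 20),
                        samplesPerGroup = 5L,
                        leavesPerSample = 4L,
                        seed = 1L) {
  new("StudyDesign",
      concentrations = as.numeric(concentrations),
      days = as.numeric(days),
      samplesPerGroup = as.integer(samplesPerGroup),
      leavesPerSample = as.integer(leavesPerSample),
      seed = as.integer(seed))
}

#' Total number of samples in a design
#' @param design A [StudyDesign-class].
#' @return Integer sample count.
#' @export
nSamples <- function(design) {
  stopifnot(is(design, "StudyDesign"))
  length(design@concentrations) * length(design@days) * design@samplesPerGroup
}

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", length(object@concentrations), "Cd levels x",
      length(object@days), "days x", object@samplesPerGroup, "samples (",
      nSamples(object), "samples,", object@leavesPerSample, "leaves each )\n")
  cat("  Cd (uM):", paste(object@concentrations, collapse = ", "), "\n")
  cat("  days:   ", paste(object@days, collapse = ", "), "\n")
})

# ---- SpectralCube -----------------------------------------------------------

#' Hyperspectral data cube
#'
#' A bands x rows x cols array of reflectance (or raw intensity before
#' calibration) together with its wavelength grid and free-form metadata.
#'
#' @slot values Numeric array, bands x rows x cols.
#' @slot wavelength Numeric band centres in nm, strictly increasing.
#' @slot metadata List of identifiers (sample, leaf, kind, ...).
#' @export
setClass("SpectralCube", representation(
  values = "array",
  wavelength = "numeric",
  metadata = "list"
))

setValidity("SpectralCube", function(object) {
  d <- dim(object@values)
  msg <- NULL
  if (length(d) != 3) msg <- c(msg, "values must be a 3-d array (bands x rows x cols)")
  else if (d[1] != length(object@wavelength))
    msg <- c(msg, "first dimension must equal the number of wavelengths")
  if (length(object@wavelength) &&
      (any(diff(object@wavelength) <= 0) ||
       min(object@wavelength) < 400 || max(object@wavelength) > 1000))
    msg <- c(msg, "wavelengths must be strictly increasing within [400, 1000] nm")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SpectralCube constructor.
#' @param values,wavelength,metadata see slots.
#' @export
SpectralCube <- function(values, wavelength, metadata = list()) {
  new("SpectralCube", values = values, wavelength = as.numeric(wavelength),
      metadata = metadata)
}

#' @rdname wavelengths
setMethod("wavelengths", "SpectralCube", function(x) x@wavelength)

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("SpectralCube: %d bands x %d rows x %d cols, %.2f-%.2f nm\n",
              d[1], d[2], d[3], min(object@wavelength), max(object@wavelength)))
})

#' Dimensions of a cube
#' @param x A [SpectralCube-class].
#' @export
setMethod("dim", "SpectralCube", function(x) dim(x@values))

# ---- SpectraTable -----------------------------------------------------------

#' Sample-by-band modeling table
#'
#' The modeling substrate: mean reflectance spectra of the leaf samples
#' stored as a [SummarizedExperiment::SummarizedExperiment-class] with
#' bands as rows (rowData column `wavelength_nm`) and samples as columns
#' (colData columns `sample_id`, `day`, `cd_um`, `fp_mg_g`).
#'
#' @export
setClass("SpectraTable", contains = "SummarizedExperiment")

setValidity("SpectraTable", function(object) {
  msg <- NULL
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!"wavelength_nm" %in% colnames(rd))
    msg <- c(msg, "rowData must contain wavelength_nm")
  else if (any(diff(rd$wavelength_nm) <= 0))
    msg <- c(msg, "wavelength_nm must be strictly increasing")
  need <- c("sample_id", "day", "cd_um", "fp_mg_g")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  else if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if (!"reflectance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'reflectance' missing")
  else if (anyNA(SummarizedExperiment::assay(object, "reflectance")))
    msg <- c(msg, "reflectance must have no missing values")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SpectraTable constructor from a samples x bands matrix.
#' @param X Numeric samples x bands reflectance matrix.
#' @param wavelength Band centres in nm (length = ncol(X)).
#' @param fp FP reference values, mg/g fresh weight.
#' @param day,cd_um Group labels per sample.
#' @param sample_id Unique sample identifiers.
#' @export
SpectraTable <- function(X, wavelength, fp, day, cd_um,
                         sample_id = paste0("S", seq_len(nrow(X)))) {
  X <- as.matrix(X)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = t(X)),
    rowData = S4Vectors::DataFrame(wavelength_nm = as.numeric(wavelength)),
    colData = S4Vectors::DataFrame(
      sample_id = as.character(sample_id),
      day = as.numeric(day), cd_um = as.numeric(cd_um),
      fp_mg_g = as.numeric(fp)))
  colnames(se) <- as.character(sample_id)
  new("SpectraTable", se)
}

#' @rdname wavelengths
setMethod("wavelengths", "SpectraTable", function(x)
  SummarizedExperiment::rowData(x)$wavelength_nm)

#' @rdname fpValues
setMethod("fpValues", "SpectraTable", function(x)
  SummarizedExperiment::colData(x)$fp_mg_g)

#' @rdname groupLabels
setMethod("groupLabels", "SpectraTable", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = cd$sample_id, day = cd$day, cd_um = cd$cd_um,
             stringsAsFactors = FALSE)
})

#' @rdname spectraMatrix
setMethod("spectraMatrix", "SpectraTable", function(x) {
  m <- t(SummarizedExperiment::assay(x, "reflectance"))
  colnames(m) <- sprintf("%.2f", wavelengths(x))
  rownames(m) <- SummarizedExperiment::colData(x)$sample_id
  m
})

setMethod("show", "SpectraTable", function(object) {
  cat(sprintf("SpectraTable: %d samples x %d bands (%.2f-%.2f nm)\n",
              ncol(object), nrow(object),
              min(wavelengths(object)), max(wavelengths(object))))
  fp <- fpValues(object)
  cat(sprintf("  FP (mg/g): %.4f-%.4f, mean %.4f\n",
              min(fp), max(fp), mean(fp)))
})

# ---- CVResult ---------------------------------------------------------------

#' Cross-validation search result
#'
#' Records the candidate hyperparameter grid, the leave-one-out RMSECV
#' (mg/g) attained by each candidate and the index of the chosen one.
#' Ties in RMSECV are broken toward the simpler candidate, so the chosen
#' index is the first minimiser in grid order (candidates are ordered
#' simple to complex).
#'
#' @slot candidates data.frame of candidate hyperparameters, one row each.
#' @slot rmsecv Numeric RMSECV per candidate, mg/g.
#' @slot chosen Integer row index of the selected candidate.
#' @export
setClass("CVResult", representation(
  candidates = "data.frame", rmsecv = "numeric", chosen = "integer"))

setValidity("CVResult", function(object) {
  msg <- NULL
  if (nrow(object@candidates) != length(object@rmsecv))
    msg <- c(msg, "one RMSECV per candidate required")
  if (length(object@chosen) != 1 || object@chosen < 1 ||
      object@chosen > length(object@rmsecv))
    msg <- c(msg, "chosen out of range")
  else if (is.finite(object@rmsecv[object@chosen]) &&
           object@rmsecv[object@chosen] > min(object@rmsecv) + 1e-12)
    msg <- c(msg, "chosen candidate must attain the minimum RMSECV")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d candidates, best RMSECV %.5g mg/g at\n",
              nrow(object@candidates), object@rmsecv[object@chosen]))
  print(object@candidates[object@chosen, , drop = FALSE])
})

# ---- Calibration models -----------------------------------------------------

#' NIPALS PLS1 calibration model
#'
#' Partial least squares regression of FP on mean-centred spectra; the
#' latent-variable count is selected at the minimum leave-one-out RMSECV.
#' Prediction is the affine map `(x - xMean) %*% coef + yMean`; `coef`
#' is the regression-coefficient vector over bands (the Bw profile used
#' for wavelength selection).
#'
#' @slot nLV Integer, latent variables used.
#' @slot xMean,yMean Centering vectors.
#' @slot weights,loadings p x A weight and loading matrices.
#' @slot yLoadings Length-A response loadings.
#' @slot coef Regression coefficients over bands.
#' @slot wavelength Band centres the model was trained on.
#' @slot cv [CVResult-class] of the latent-variable search.
#' @export
setClass("PLSModel", representation(
  nLV = "integer", xMean = "numeric", yMean = "numeric",
  weights = "matrix", loadings = "matrix", yLoadings = "numeric",
  coef = "numeric", wavelength = "numeric", cv = "CVResult"))

setValidity("PLSModel", function(object) {
  p <- length(object@xMean)
  if (object@nLV < 1) return("nLV must be >= 1")
  if (length(object@coef) != p) return("coef length must match bands")
  if (length(object@wavelength) != p) return("wavelength length must match bands")
  TRUE
})

#' LS-SVM calibration model (RBF kernel)
#'
#' Least-squares support vector regression: the dual problem reduces to a
#' single linear (KKT) system in the support values `alpha` and bias.
#' `gam` is the regularisation constant and `sig2` the squared RBF
#' bandwidth, both selected at minimum leave-one-out RMSECV.
#'
#' @slot alpha Support values, one per training sample.
#' @slot bias Scalar bias term.
#' @slot gam,sig2 Positive hyperparameters.
#' @slot Xtrain Stored training spectra.
#' @slot kktResidual Max-norm residual of the solved KKT system.
#' @slot wavelength Band centres the model was trained on.
#' @slot cv [CVResult-class] of the (gam, sig2) search.
#' @export
setClass("LSSVMModel", representation(
  alpha = "numeric", bias = "numeric", gam = "numeric", sig2 = "numeric",
  Xtrain = "matrix", kktResidual = "numeric", wavelength = "numeric",
  cv = "CVResult"))

setValidity("LSSVMModel", function(object) {
  if (object@gam <= 0 || object@sig2 <= 0) return("gam and sig2 must be > 0")
  if (length(object@alpha) != nrow(object@Xtrain))
    return("one alpha per training sample required")
  if (object@kktResidual > 1e-8)
    return("KKT residual of the dual system exceeds 1e-8")
  TRUE
})

#' Extreme learning machine calibration model
#'
#' Single-hidden-layer network with sigmoid activation: input weights and
#' biases are drawn uniform(-1, 1) from a recorded seed and never trained;
#' output weights are the least-squares solution. The hidden-node count is
#' selected by leave-one-out RMSECV by default (see [elmFit()]).
#'
#' @slot nNodes Integer, hidden nodes used.
#' @slot inputWeights nNodes x p random input weights.
#' @slot inputBias Length-nNodes random biases.
#' @slot outputWeights Least-squares output weights.
#' @slot seed Integer seed that generated the random layer.
#' @slot wavelength Band centres the model was trained on.
#' @slot cv [CVResult-class] of the node-count search.
#' @export
setClass("ELMModel", representation(
  nNodes = "integer", inputWeights = "matrix", inputBias = "numeric",
  outputWeights = "numeric", seed = "integer", wavelength = "numeric",
  cv = "CVResult"))

setValidity("ELMModel", function(object) {
  if (object@nNodes < 1) return("nNodes must be >= 1")
  if (nrow(object@inputWeights) < object@nNodes)
    return("inputWeights must have at least nNodes rows")
  TRUE
})

#' @rdname wavelengths
setMethod("wavelengths", "PLSModel", function(x) x@wavelength)
#' @rdname wavelengths
setMethod("wavelengths", "LSSVMModel", function(x) x@wavelength)
#' @rdname wavelengths
setMethod("wavelengths", "ELMModel", function(x) x@wavelength)

#' @rdname cvResult
setMethod("cvResult", "PLSModel", function(x) x@cv)
#' @rdname cvResult
setMethod("cvResult", "LSSVMModel", function(x) x@cv)
#' @rdname cvResult
setMethod("cvResult", "ELMModel", function(x) x@cv)

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variables, %d bands, RMSECV %.5g mg/g\n",
              object@nLV, length(object@coef),
              object@cv@rmsecv[object@cv@chosen]))
})
setMethod("show", "LSSVMModel", function(object) {
  cat(sprintf("LSSVMModel: gam %.6g, sig2 %.6g, %d support values\n",
              object@gam, object@sig2, length(object@alpha)))
})
setMethod("show", "ELMModel", function(object) {
  cat(sprintf("ELMModel: %d hidden nodes (seed %d), %d bands\n",
              object@nNodes, object@seed, ncol(object@inputWeights)))
})

# ---- SelectionResult --------------------------------------------------------

#' Wavelength-selection result
#'
#' @slot method One of "CARS", "GA", "Bw".
#' @slot indices Sorted unique 1-based band indices.
#' @slot wavelength Selected band centres in nm.
#' @slot trace data.frame diagnostic trace (per-iteration retained count
#'   and RMSECV for CARS, per-generation best fitness for GA, the signed
#'   coefficient profile for Bw).
#' @slot seed Integer seed (NA for deterministic Bw).
#' @export
setClass("SelectionResult", representation(
  method = "character", indices = "integer", wavelength = "numeric",
  trace = "data.frame", seed = "integer"))

setValidity("SelectionResult", function(object) {
  msg <- NULL
  if (!object@method %in% c("CARS", "GA", "Bw"))
    msg <- c(msg, "method must be CARS, GA or Bw")
  i <- object@indices
  if (length(i) < 1 || anyDuplicated(i) || is.unsorted(i) || any(i < 1))
    msg <- c(msg, "indices must be sorted, unique, >= 1 and non-empty")
  if (length(object@wavelength) != length(i))
    msg <- c(msg, "one wavelength per index required")
  if (is.null(msg)) TRUE else msg
})

#' @rdname selectedIndices
setMethod("selectedIndices", "SelectionResult", function(x) x@indices)
#' @rdname selectedWavelengths
setMethod("selectedWavelengths", "SelectionResult", function(x) x@wavelength)
#' @rdname wavelengths
setMethod("wavelengths", "SelectionResult", function(x) x@wavelength)

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult (%s): %d bands\n", object@method,
              length(object@indices)))
  cat(" ", paste(sprintf("%.2f", object@wavelength), collapse = ", "), "\n")
})

# ---- EvaluationReport -------------------------------------------------------

#' Calibration/prediction performance report
#'
#' @slot Rc Correlation between leave-one-out predictions and reference
#'   values over the calibration set.
#' @slot RMSECV Leave-one-out root mean square error, mg/g.
#' @slot Rp Correlation on the independent prediction set.
#' @slot RMSEP Prediction-set root mean square error, mg/g.
#' @slot nCal,nPred Set sizes.
#' @export
setClass("EvaluationReport", representation(
  Rc = "numeric", RMSECV = "numeric", Rp = "numeric", RMSEP = "numeric",
  nCal = "integer", nPred = "integer"))

setValidity("EvaluationReport", function(object) {
  if (object@RMSECV < 0 || object@RMSEP < 0) return("RMSEs must be >= 0")
  if (abs(object@Rc) > 1 + 1e-12 || abs(object@Rp) > 1 + 1e-12)
    return("|R| must be <= 1")
  TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("Rc %.4f  RMSECV %.4f  Rp %.4f  RMSEP %.4f  (n = %d/%d)\n",
              object@Rc, object@RMSECV, object@Rp, object@RMSEP,
              object@nCal, object@nPred))
})

# ---- PredictionMap ----------------------------------------------------------

#' Pixel-wise FP prediction map
#'
#' Per-pixel FP estimates (mg/g) over a leaf mask; pixels outside the
#' mask are NA. `range` is the display range used for pseudo-colour
#' rendering.
#'
#' @slot values rows x cols numeric matrix, NA outside the mask.
#' @slot mask rows x cols logical leaf mask.
#' @slot range Length-2 display range in mg/g, lo < hi.
#' @export
setClass("PredictionMap", representation(
  values = "matrix", mask = "matrix", range = "numeric"))

setValidity("PredictionMap", function(object) {
  msg <- NULL
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask dims must agree")
  if (any(!is.na(object@values[!object@mask])))
    msg <- c(msg, "estimates must be present only inside the mask")
  if (any(!is.finite(object@values[object@mask])))
    msg <- c(msg, "in-mask estimates must be finite")
  if (length(object@range) != 2 || object@range[1] >= object@range[2])
    msg <- c(msg, "display range must satisfy lo < hi")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "PredictionMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("PredictionMap: %d x %d, %d leaf pixels, FP %.4f-%.4f mg/g\n",
              nrow(object@values), ncol(object@values), sum(object@mask),
              min(v), max(v)))
})
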