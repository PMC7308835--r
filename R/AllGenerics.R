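#' @import methods
NULL

#' Band centres of an object
#'
#' Accessor for the wavelength grid (band centres in nm) carried by cubes,
#' spectra tables, fitted models and selection results.
#'
#' @param x An object with a wavelength grid.
#' @return Numeric vector of band centres in nm, strictly increasing.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Free proline reference values
#'
#' @param x A [SpectraTable-class].
#' @return Numeric vector of FP reference values (mg/g fresh weight),
#'   one per sample.
#' @export
setGeneric("fpValues", function(x) standardGeneric("fpValues"))

#' Treatment group labels
#'
#' @param x A [SpectraTable-class].
#' @return A data.frame with columns `sample_id`, `day` and `cd_um`.
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Sample-by-band reflectance matrix
#'
#' @param x A [SpectraTable-class].
#' @return Numeric matrix, samples in rows, bands in columns, column
#'   names the band centres in nm.
#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' Restrict an object to a wavelength window
#'
#' Keeps the bands whose centre lies inside `window` (both endpoints
#' inclusive) and drops the rest, keeping values and grid aligned.
#'
#' @param x A [SpectralCube-class] or [SpectraTable-class].
#' @param window Numeric length-2, `c(lo, hi)` in nm.
#' @return Object of the same class restricted to the window.
#' @examples
#' st <- toySpectraTable()
#' trimBands(st, c(600, 700))
#' @export
setGeneric("trimBands", function(x, window) standardGeneric("trimBands"))

#' Selected band indices
#'
#' @param x A [SelectionResult-class].
#' @return Sorted integer vector of selected band indices (1-based).
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' Selected band centres
#'
#' @param x A [SelectionResult-class].
#' @return Numeric vector of selected band centres in nm.
#' @export
setGeneric("selectedWavelengths", function(x) standardGeneric("selectedWavelengths"))

#' Cross-validation summary of a fitted model
#'
#' @param x A fitted calibration model.
#' @return The [CVResult-class] recorded during hyperparameter search.
#' @export
setGeneric("cvResult", function(x) standardGeneric("cvResult"))

#' Refit a calibration model on new data with fixed hyperparameters
#'
#' Used internally by cross-validated evaluation: the hyperparameters
#' (latent variables, kernel parameters, node count and seed) are taken
#' from `object` and only the data-dependent parameters are re-estimated.
#'
#' @param object A fitted model.
#' @param X Training spectra, samples x bands.
#' @param y Training FP values.
#' @return A fitted model of the same class.
#' @export
setGeneric("refit", function(object, X, y) standardGeneric("refit"))

#' Evaluate a calibration model on a calibration/prediction split
#'
#' Computes the four headline figures of merit of a calibration:
#' Rc and RMSECV from leave-one-out cross-validation over the calibration
#' set (refitting with the model's fixed hyperparameters), and Rp and
#' RMSEP on the untouched prediction set.
#'
#' @param object A fitted model.
#' @param Xc,yc Calibration spectra and FP values.
#' @param Xp,yp Prediction-set spectra and FP values.
#' @return An [EvaluationReport-class].
#' @export
setGeneric("evaluateModel", function(object, Xc, yc, Xp, yp)
  standardGeneric("evaluateModel"))
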