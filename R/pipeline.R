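#' @include AllClasses.R
NULL

#' Configuration of an end-to-end pipeline run
#'
#' Collects every knob of the reproduction pipeline in one serialisable
#' list: the study design, analysis window, engine and selector settings
#' and all seeds (each stage derives its own sub-seed from `seed` by a
#' fixed offset).
#'
#' @param design A [StudyDesign-class].
#' @param window Analysis window, nm.
#' @param seed Master seed.
#' @param selectors Wavelength-selection methods to run.
#' @param engines Calibration engines to run.
#' @param maxLV PLS latent-variable budget.
#' @param carsIterations CARS iteration count.
#' @param gaPopSize,gaGenerations GA population and generations.
#' @param mapsPerGroup Leaves rendered into FP maps per treatment group.
#' @param mapDims rows, cols of rendered map leaves.
#' @return A named list with class "fpPipelineConfig".
#' @export
pipelineConfig <- function(design = studyDesign(), window = c(500, 950),
                           seed = design@seed,
                           selectors = c("full", "GA", "CARS", "Bw"),
                           engines = c("PLS", "LSSVM", "ELM"),
                           maxLV = 15L, carsIterations = 50L,
                           gaPopSize = 30L, gaGenerations = 100L,
                           mapsPerGroup = 1L, mapDims = c(64L, 64L)) {
  cfg <- list(design = design, window = window, seed = as.integer(seed),
              selectors = selectors, engines = engines,
              maxLV = as.integer(maxLV),
              carsIterations = as.integer(carsIterations),
              gaPopSize = as.integer(gaPopSize),
              gaGenerations = as.integer(gaGenerations),
              mapsPerGroup = as.integer(mapsPerGroup),
              mapDims = as.integer(mapDims))
  class(cfg) <- "fpPipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.serializeModel <- function(model, path) {
  info <- switch(class(model),
    PLSModel = list(type = "PLS", n_lv = model@nLV,
                    wavelength = model@wavelength, coef = model@coef,
                    x_mean = model@xMean, y_mean = model@yMean),
    LSSVMModel = list(type = "LS-SVM", gam = model@gam, sig2 = model@sig2,
                      wavelength = model@wavelength, alpha = model@alpha,
                      bias = model@bias),
    ELMModel = list(type = "ELM", n_nodes = model@nNodes, seed = model@seed,
                    wavelength = model@wavelength,
                    output_weights = model@outputWeights))
  jsonlite::write_json(info, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Run the full synthetic-study reproduction pipeline
#'
#' simulate -> preprocess -> split -> select -> fit -> evaluate -> map:
#' generates the synthetic study table, trims to the analysis window,
#' performs the rank-based 3:1 split, runs the configured wavelength
#' selectors, fits every configured engine on the full spectrum and on
#' each selected subset, evaluates all of them (Rc/RMSECV by
#' leave-one-out over calibration, Rp/RMSEP on the held-out set) and
#' renders pixel-wise FP maps for a panel of freshly rendered leaves
#' using the best model. Any stage failure aborts with the stage name;
#' outputs of completed stages persist in `outdir`.
#'
#' @param config A [pipelineConfig()] list.
#' @param outdir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the report data.frame, selections,
#'   models, evaluation reports, map paths and the run-log path.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir = tempfile("fprun"),
                        verbose = TRUE) {
  stopifnot(inherits(config, "fpPipelineConfig"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  say <- function(...) if (verbose) message(...)
  seed <- config$seed

  say("stage: simulate")
  st <- .stage("simulate", {
    st <- simulateSpectraTable(config$design, seed = seed)
    writeSpectraTable(st, file.path(outdir, "spectra_table.csv"))
    st
  })

  say("stage: preprocess")
  st <- .stage("preprocess", trimBands(st, config$window))
  X <- spectraMatrix(st)
  y <- fpValues(st)
  wl <- wavelengths(st)

  say("stage: split")
  split <- .stage("split", rankSplit(y))
  Xc <- X[split$calibration, , drop = FALSE]; yc <- y[split$calibration]
  Xp <- X[split$prediction, , drop = FALSE]; yp <- y[split$prediction]

  say("stage: select")
  selections <- .stage("select", {
    out <- list(full = NULL)
    if ("Bw" %in% config$selectors || "GA" %in% config$selectors ||
        "CARS" %in% config$selectors) {
      if ("CARS" %in% config$selectors)
        out$CARS <- carsSelect(Xc, yc, nIterations = config$carsIterations,
                               seed = seed + 11L, wavelength = wl)
      if ("GA" %in% config$selectors)
        out$GA <- gaSelect(Xc, yc, popSize = config$gaPopSize,
                           nGenerations = config$gaGenerations,
                           seed = seed + 12L, wavelength = wl)
      if ("Bw" %in% config$selectors) {
        pls0 <- plsFit(Xc, yc, maxLV = config$maxLV, wavelength = wl)
        out$Bw <- bwSelect(pls0, quantile = 0.5)
      }
    }
    for (nm in setdiff(names(out), "full"))
      utils::write.csv(
        data.frame(index = selectedIndices(out[[nm]]),
                   wavelength_nm = selectedWavelengths(out[[nm]])),
        file.path(outdir, sprintf("selection_%s.csv", nm)),
        row.names = FALSE)
    out[c("full", intersect(c("GA", "CARS", "Bw"), names(out)))]
  })

  say("stage: fit+evaluate")
  cells <- .stage("fit", {
    cells <- list()
    for (selName in intersect(config$selectors,
                              c("full", names(selections)))) {
      sel <- selections[[selName]]
      idx <- if (is.null(sel)) seq_len(ncol(Xc)) else selectedIndices(sel)
      for (eng in config$engines) {
        model <- switch(eng,
          PLS = plsFit(Xc[, idx, drop = FALSE], yc, maxLV = config$maxLV,
                       wavelength = wl[idx]),
          LSSVM = lssvmFit(Xc[, idx, drop = FALSE], yc,
                           wavelength = wl[idx]),
          ELM = elmFit(Xc[, idx, drop = FALSE], yc, seed = seed + 21L,
                       wavelength = wl[idx]))
        param <- switch(eng,
          PLS = as.character(model@nLV),
          LSSVM = sprintf("%.2f; %.2f", model@gam, model@sig2),
          ELM = as.character(model@nNodes))
        rep_ <- evaluateModel(model, Xc[, idx, drop = FALSE], yc,
                              Xp[, idx, drop = FALSE], yp)
        key <- paste(selName, eng, sep = "-")
        .serializeModel(model, file.path(outdir,
                                         sprintf("model_%s.json", key)))
        cells[[key]] <- list(selection = selName, engine = eng,
                             n_bands = length(idx), parameter = param,
                             model = model, report = rep_)
      }
    }
    cells
  })

  report <- data.frame(
    Selection = vapply(cells, `[[`, "", "selection"),
    Model = vapply(cells, `[[`, "", "engine"),
    Bands = vapply(cells, function(c) as.integer(c$n_bands), 0L),
    Parameter = vapply(cells, `[[`, "", "parameter"),
    Rc = vapply(cells, function(c) c$report@Rc, 0),
    RMSECV = vapply(cells, function(c) c$report@RMSECV, 0),
    Rp = vapply(cells, function(c) c$report@Rp, 0),
    RMSEP = vapply(cells, function(c) c$report@RMSEP, 0),
    row.names = NULL)
  utils::write.csv(report, file.path(outdir, "report.csv"),
                   row.names = FALSE)

  say("stage: map")
  best <- cells[[which.max(vapply(cells, function(c) c$report@Rp, 0))]]
  maps <- .stage("map", {
    truth <- S4Vectors::metadata(st)$truth
    paths <- character(0)
    mapList <- list()
    groups <- unique(truth@samples[, c("day", "cd_um")])
    for (gi in seq_len(nrow(groups))) {
      gRows <- truth@samples$day == groups$day[gi] &
        truth@samples$cd_um == groups$cd_um[gi]
      s <- truth@samples[which(gRows)[1], ]
      for (l in seq_len(config$mapsPerGroup)) {
        r <- renderLeafCube(s$fp_mg_g, wavelengths(st),
                            rows = config$mapDims[1],
                            cols = config$mapDims[2],
                            cd_um = s$cd_um, day = s$day,
                            design = config$design,
                            seed = seed + 100L + 10L * gi + l)
        m <- predictMap(trimBands(r$cube, config$window), r$mask,
                        best$model)
        mapList[[sprintf("d%02d_c%03d_%d", s$day, s$cd_um, l)]] <- m
      }
    }
    rng <- panelRange(mapList)
    for (nm in names(mapList)) {
      pth <- file.path(outdir, sprintf("map_%s.png", nm))
      renderPseudocolor(mapList[[nm]], pth, range = rng)
      paths <- c(paths, pth)
    }
    list(maps = mapList, paths = paths, range = rng)
  })

  log <- c(sprintf("hyperFP %s", as.character(utils::packageVersion("hyperFP"))),
           sprintf("R %s", getRversion()),
           sprintf("seed %d", seed),
           sprintf("design: %d samples", nSamples(config$design)),
           sprintf("window: %g-%g nm", config$window[1], config$window[2]),
           sprintf("best cell: %s-%s (Rp %.4f)", best$selection,
                   best$engine, best$report@Rp))
  writeLines(log, file.path(outdir, "run_log.txt"))

  invisible(list(report = report, selections = selections, cells = cells,
                 maps = maps, table = st, split = split, outdir = outdir))
}
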