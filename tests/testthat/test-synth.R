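test_that("default wavelength grid matches the instrument layout", {
  wl <- makeWavelengthGrid()
  expect_length(wl, 350)
  expect_gte(min(wl), 500)
  expect_lte(max(wl), 950)
  expect_true(all(diff(wl) > 0))
  # affinely increasing spacing
  expect_true(all(diff(diff(wl)) > 0))
  expect_equal(max(abs(diff(diff(wl)) - diff(diff(wl))[1])), 0,
               tolerance = 1e-9)
  # the printed characteristic wavelengths sit on band centres
  for (w in c(650.34, 662.97, 665.5, 601.37, 943.52))
    expect_lt(min(abs(wl - w)), 0.15)
  expect_equal((max(wl) - min(wl)) / 349, mean(diff(wl)), tolerance = 1e-12)
})

test_that("wavelength grid rejects degenerate arguments", {
  expect_error(makeWavelengthGrid(0), "n_bands")
  expect_error(makeWavelengthGrid(10, c(900, 500)), "lo < hi")
  expect_error(makeWavelengthGrid(10, c(300, 900)), "400")
  wl <- makeWavelengthGrid(25, c(520, 800))
  expect_length(wl, 25)
  expect_equal(range(wl), c(520, 800))
})

test_that("FP truth reproduces the configured day-level means", {
  truth <- simulateFPTruth(studyDesign(seed = 1L))
  ref <- referenceDayStats()
  pooled <- aggregate(fp_mg_g ~ day, truth@samples, mean)
  for (i in seq_len(nrow(ref))) {
    se <- ref$sd[i] / sqrt(ref$n[i])
    expect_lt(abs(pooled$fp_mg_g[pooled$day == ref$day[i]] - ref$mean[i]),
              2 * se)
  }
  # stress response accumulates over time
  expect_gt(pooled$fp_mg_g[pooled$day == 20], pooled$fp_mg_g[pooled$day == 5])
  # mild stress peaks early: day-5 5 uM above day-5 control
  g5 <- aggregate(fp_mg_g ~ cd_um, truth@samples[truth@samples$day == 5, ],
                  mean)
  expect_gt(g5$fp_mg_g[g5$cd_um == 5], g5$fp_mg_g[g5$cd_um == 0])
  # late stress monotone in concentration
  for (d in c(15, 20)) {
    g <- aggregate(fp_mg_g ~ cd_um, truth@samples[truth@samples$day == d, ],
                   mean)
    expect_true(all(diff(g$fp_mg_g[order(g$cd_um)]) > 0))
  }
})

test_that("noise-free truth equals the trend table exactly", {
  tr <- defaultTrendTable()
  tr$sd <- 0
  truth <- simulateFPTruth(studyDesign(seed = 3L), trend = tr, leafSd = 0)
  key <- paste(truth@samples$day, truth@samples$cd_um)
  expect_equal(truth@samples$fp_mg_g,
               tr$mean[match(key, paste(tr$day, tr$cd_um))])
  expect_equal(truth@leaves$fp_mg_g,
               truth@samples$fp_mg_g[match(truth@leaves$sample_id,
                                           truth@samples$sample_id)])
})

test_that("per-sample FP equals the mean of its leaves", {
  truth <- simulateFPTruth(studyDesign(seed = 2L))
  m <- tapply(truth@leaves$fp_mg_g, truth@leaves$sample_id, mean)
  expect_equal(as.numeric(m[truth@samples$sample_id]),
               truth@samples$fp_mg_g, tolerance = 1e-12)
  expect_true(all(truth@samples$fp_mg_g > 0))
})

test_that("truth generation rejects malformed trend tables", {
  tr <- defaultTrendTable()
  expect_error(simulateFPTruth(studyDesign(concentrations = c(0, 7)),
                               trend = tr), "missing cell")
  tr$sd[1] <- -1
  expect_error(simulateFPTruth(studyDesign(), trend = tr), ">= 0")
})

test_that("generator is deterministic under a fixed seed", {
  t1 <- simulateFPTruth(studyDesign(seed = 5L))
  t2 <- simulateFPTruth(studyDesign(seed = 5L))
  expect_identical(t1@samples, t2@samples)
  expect_identical(t1@leaves, t2@leaves)
  wl <- makeWavelengthGrid(40, c(500, 950))
  r1 <- renderLeafCube(0.15, wl, rows = 32, cols = 32, seed = 9)
  r2 <- renderLeafCube(0.15, wl, rows = 32, cols = 32, seed = 9)
  expect_identical(r1$cube@values, r2$cube@values)
  d <- studyDesign(samplesPerGroup = 1L, seed = 4L)
  s1 <- simulateSpectraTable(d)
  s2 <- simulateSpectraTable(d)
  expect_identical(spectraMatrix(s1), spectraMatrix(s2))
})

test_that("rendered leaves carry the configured spatial FP pattern", {
  wl <- makeWavelengthGrid(30, c(500, 950))
  # degenerate homogeneous leaf: no noise, flat gradient
  r0 <- renderLeafCube(0.15, wl, rows = 32, cols = 32,
                       gradient = c(1, 1), noiseSd = 0, specNoiseSd = 0,
                       seed = 1)
  px <- matrix(r0$cube@values, nrow = 30)[, which(r0$mask)]
  expect_equal(max(apply(px, 1, function(v) diff(range(v)))), 0)
  expect_equal(r0$fpMap[r0$mask], rep(0.15, sum(r0$mask)))
  # gradient leaf: leaf mean preserved, tip above petiole
  r <- renderLeafCube(0.15, wl, rows = 40, cols = 40, seed = 2)
  expect_equal(mean(r$fpMap[r$mask]), 0.15, tolerance = 1e-12)
  cols <- ncol(r$fpMap)
  tip <- r$fpMap[, (2 * cols %/% 3):cols]
  pet <- r$fpMap[, 1:(cols %/% 3)]
  expect_gte(mean(tip, na.rm = TRUE), mean(pet, na.rm = TRUE))
  expect_error(renderLeafCube(-0.1, wl), "> 0")
  expect_error(renderLeafCube(0.15, wl, rows = 8, cols = 8), "32")
})

test_that("planted informative bands out-correlate the noise bands", {
  st <- defaultStudyTable()
  info <- S4Vectors::metadata(st)$informative
  expect_length(info, 6)
  cors <- abs(cor(spectraMatrix(st), fpValues(st)))
  expect_gte(mean(cors[-info] < min(cors[info])), 0.90)
})

test_that("a written dataset round-trips through the imaging pipeline", {
  d <- studyDesign(concentrations = 0, days = 5, samplesPerGroup = 1L,
                   seed = 6L)
  dir <- withr::local_tempdir()
  man <- makeDataset(d, dir, rows = 40L, cols = 40L)
  expect_equal(nrow(man$reference), 1L)
  expect_equal(length(man$cubes), 4L)          # samples x leaves
  expect_true(all(file.exists(paste0(man$cubes, ".hdr"))))
  expect_true(file.exists(file.path(dir, "fp_reference.csv")))
  st <- extractStudyTable(man)
  expect_s4_class(st, "SpectraTable")
  expect_equal(dim(spectraMatrix(st)), c(1L, 350L))
  expect_equal(fpValues(st), man$reference$fp_mg_g)
  # extracted mean spectrum close to the closed-form sample-level model
  expect_true(all(spectraMatrix(st) > 0 & spectraMatrix(st) < 1))
})
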