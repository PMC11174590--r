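test_that("design enumeration yields the expected plot-season counts", {
  expect_equal(nrow(generateDesign(treatmentDesign())), 54)
  one <- generateDesign(treatmentDesign("A", "B", 1, 1))
  expect_equal(nrow(one), 1)
  tw <- generateDesign(treatmentDesign(c("A", "B"), c("x", "y", "z"),
                                       2, 1))
  expect_equal(nrow(tw), 12)
  expect_error(treatmentDesign(character(0)), "level")
  expect_error(treatmentDesign(replicates = 0), "positive")
  d <- generateDesign(treatmentDesign())
  expect_false(anyDuplicated(paste(d$plot_id, d$season)) > 0)
  # the same 27 plots recur each season
  expect_equal(sort(unique(d$plot_id[d$season == 1])),
               sort(unique(d$plot_id[d$season == 2])))
})

test_that("moisture draw is the additive treatment model", {
  rows <- generateDesign(treatmentDesign(seasons = 1))
  cfg0 <- sceneConfig(moistureSd = 0, moistureBaseline = 70,
                      mulchEffect = c(SM = 0, FM = 0, NM = 0),
                      irrigationEffect = c(W1 = 0, W2 = 0, W3 = 0))
  expect_true(all(drawMoisture(rows, cfg0) == 70))
  cfg4 <- sceneConfig(moistureSd = 0, moistureBaseline = 70,
                      mulchEffect = c(SM = 0, FM = 0, NM = 0),
                      irrigationEffect = c(W1 = 0, W2 = 0, W3 = 4))
  m <- drawMoisture(rows, cfg4)
  expect_true(all(m[rows$irrigation == "W3"] == 74))
  expect_true(all(m[rows$irrigation != "W3"] == 70))
  expect_error(drawMoisture(data.frame(mulch = "??", irrigation = "W1"),
                            cfg0), "effect")
})

test_that("moisture sample mean concentrates at the baseline (CLT bound)", {
  n <- 1e4
  rows <- data.frame(plot_id = sprintf("P%05d", 1:n), season = 1,
                     mulch = "NM", irrigation = "W1",
                     stringsAsFactors = FALSE)
  cfg <- sceneConfig(moistureSd = 2, moistureBaseline = 70,
                     mulchEffect = c(NM = 0),
                     irrigationEffect = c(W1 = 0), seed = 99L)
  m <- drawMoisture(rows, cfg)
  expect_lt(abs(mean(m) - 70), 3 * 2 / sqrt(n))
  expect_true(all(m > 0 & m < 100))
})

test_that("scene generation is deterministic per seed", {
  cfg <- sceneConfig(seed = 31L)
  s1 <- simulateScene(treatmentDesign(seasons = 1), cfg)
  s2 <- simulateScene(treatmentDesign(seasons = 1), cfg)
  expect_identical(s1$samples$moisture_pct, s2$samples$moisture_pct)
  expect_identical(bandArray(s1$scene), bandArray(s2$scene))
  s3 <- simulateScene(treatmentDesign(seasons = 1),
                      sceneConfig(seed = 32L))
  expect_false(identical(bandArray(s1$scene), bandArray(s3$scene)))
})

test_that("noise-free plots are constant and track the linear band response", {
  rows <- data.frame(plot_id = c("A", "B"), season = 1,
                     stringsAsFactors = FALSE)
  cfg <- sceneConfig(noiseSd = 0, plotNoiseSd = 0, textureLink = 0)
  scene <- renderScene(rows, c(60, 80), cfg)
  mA <- vapply(1:6, function(b) meanReflectance(scene, "A", b), 0)
  mB <- vapply(1:6, function(b) meanReflectance(scene, "B", b), 0)
  expect_equal(mA, cfg$bandIntercept + cfg$bandSlope * 60,
               tolerance = 1e-12)
  # wetter plot is brighter in NIR (positive slope), darker in red
  expect_gt(mB[6], mA[6])
  expect_lt(mB[3], mA[3])
  # constant within plot
  px <- bandArray(scene)[5:10, 5:10, 6]
  expect_equal(max(px) - min(px), 0)
})

test_that("with a planted link and vanishing noise NIR means recover moisture", {
  rows <- data.frame(plot_id = sprintf("P%02d", 1:20), season = 1,
                     stringsAsFactors = FALSE)
  moist <- seq(55, 85, length.out = 20)
  cfg <- sceneConfig(noiseSd = 1e-6, plotNoiseSd = 0, textureLink = 0)
  scene <- renderScene(rows, moist, cfg)
  nir <- vapply(rows$plot_id, function(p)
    meanReflectance(scene, p, 6), 0)
  expect_gt(cor(nir, moist), 0.999)
})

test_that("plot raster variance rises with moisture when texture is linked", {
  rows <- data.frame(plot_id = sprintf("P%02d", 1:20), season = 1,
                     stringsAsFactors = FALSE)
  moist <- seq(55, 85, length.out = 20)
  cfg <- sceneConfig(noiseSd = 0, plotNoiseSd = 0, textureLink = 0.06,
                     seed = 8L)
  scene <- renderScene(rows, moist, cfg)
  v <- vapply(seq_len(20), function(i) {
    poly <- plotRegions(scene)$polygon[[i]]
    px <- bandArray(scene)[(poly[1, 2] + 1):poly[3, 2],
                           (poly[1, 1] + 1):poly[2, 1], 6]
    var(as.numeric(px))
  }, 0)
  expect_gt(cor(v, moist, method = "spearman"), 0)
})

test_that("a band response outside [0,1] is a configuration error", {
  rows <- data.frame(plot_id = "A", season = 1, stringsAsFactors = FALSE)
  cfg <- sceneConfig(bandIntercept = c(2, rep(0.1, 5)))
  expect_error(renderScene(rows, 70, cfg), "outside \\[0,1\\]")
})

test_that("scene files round-trip through TIFF/GeoJSON/CSV", {
  sim <- simulateScene(treatmentDesign(replicates = 1, seasons = 1),
                       sceneConfig(seed = 3L, plotSizePx = c(11L, 11L)))
  dir <- withr::local_tempdir()
  writeScene(sim$scene, dir, sim$samples)
  back <- readScene(dir, expectedBands = 6)
  expect_equal(bandArray(back), bandArray(sim$scene), tolerance = 1e-6)
  expect_equal(wavelengths(back), wavelengths(sim$scene))
  expect_equal(plotRegions(back)$plot_id, plotRegions(sim$scene)$plot_id)
  expect_equal(plotRegions(back)$polygon[[3]],
               unname(plotRegions(sim$scene)$polygon[[3]]))
  tab <- read.csv(file.path(dir, "moisture.csv"))
  expect_equal(tab$moisture_pct, sim$samples$moisture_pct,
               tolerance = 1e-12)
  expect_error(readScene(dir, expectedBands = 4), "band count")
  expect_error(readScene(file.path(dir, "nope")), "not found")
})

test_that("a fully decoupled scene yields near-null downstream screening", {
  cfg <- list(bandSlope = rep(0, 6), textureLink = 0,
              plotSizePx = c(15L, 15L))
  run <- suppressWarnings(
    runPipeline(defaultConfig(seed = 12, scene = cfg,
                              design = list(seasons = 1L))))
  scr <- run$screen
  # no planted link: the significant fraction should look like alpha
  expect_lt(mean(scr$significant, na.rm = TRUE), 0.25)
})
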