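test_that("gray quantization bins linearly with top-edge inclusion", {
  expect_equal(quantizeGray(c(0, 1), 2), c(0L, 1L))
  expect_equal(quantizeGray(c(0, 0.25, 0.5, 1), 4), c(0L, 1L, 2L, 3L))
  expect_true(all(quantizeGray(matrix(0.5, 3, 3), 64) == 0L))
  set.seed(2)
  q <- quantizeGray(runif(1000), 64)
  expect_true(all(q >= 0 & q <= 63))
})

test_that("co-occurrence of the worked 2x2 example matches the brute count", {
  x <- matrix(c(0L, 1L, 0L, 1L), 2, 2)  # rows: 0 0 / 1 1
  P <- cooccurrence(x, c(0, 1), symmetric = TRUE)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2), tolerance = 1e-15)
  f <- textureFeatures(P)
  expect_equal(unname(f["CON"]), 0)
  expect_equal(unname(f["HOM"]), 1)
  expect_equal(unname(f["SEM"]), 0.5)
  expect_equal(unname(f["ENT"]), log(2), tolerance = 1e-12)
  expect_equal(unname(f["MEA"]), 0.5)
  expect_equal(unname(f["VAR"]), 0.25)
})

test_that("constant and checkerboard windows give the textbook extremes", {
  P1 <- cooccurrence(matrix(3L, 4, 4), c(1, 1), levels = 8)
  expect_equal(sum(P1), 1)
  f1 <- textureFeatures(P1)
  expect_equal(unname(f1[c("VAR", "CON", "DIS", "ENT")]), rep(0, 4))
  expect_equal(unname(f1[c("HOM", "SEM")]), c(1, 1))
  expect_true(is.na(f1["COR"]))

  ch <- outer(1:4, 1:4, function(r, c) as.integer((r + c) %% 2))
  fch <- textureFeatures(cooccurrence(ch, c(0, 1)))
  expect_equal(unname(fch["CON"]), 1)
  expect_equal(unname(fch["DIS"]), 1)
  expect_equal(unname(fch["HOM"]), 0.5)
})

test_that("co-occurrence matrices normalize and symmetrize on random windows", {
  set.seed(10)
  for (k in 1:10) {
    x <- matrix(sample(0:5, 49, replace = TRUE), 7, 7)
    Ps <- cooccurrence(x, c(1, 1), symmetric = TRUE, levels = 6)
    expect_equal(sum(Ps), 1, tolerance = 1e-12)
    expect_equal(Ps, t(Ps), tolerance = 1e-15)
    Pa <- cooccurrence(x, c(0, 1), symmetric = FALSE, levels = 6)
    expect_equal(sum(Pa), 1, tolerance = 1e-12)
    expect_equal(Pa, naiveGlcm(x, 0, 1, FALSE, 6), tolerance = 1e-15)
  }
})

test_that("gray-level translation leaves structure features unchanged", {
  set.seed(11)
  x <- matrix(sample(0:20, 64, replace = TRUE), 8, 8)
  f1 <- textureFeatures(cooccurrence(x, c(1, 1), levels = 40))
  f2 <- textureFeatures(cooccurrence(x + 3L, c(1, 1), levels = 40))
  keep <- c("HOM", "CON", "DIS", "ENT", "SEM")
  expect_equal(f1[keep], f2[keep], tolerance = 1e-12)
  expect_equal(unname(f2["MEA"] - f1["MEA"]), 3, tolerance = 1e-12)
})

test_that("the compiled sliding-window map agrees with the windowed R path", {
  set.seed(12)
  vals <- matrix(runif(12 * 10), 12, 10)
  q <- quantizeGray(vals, 8)
  w <- 5L
  map <- canopywater:::glcm_feature_map(q, w, 1L, 1L, 8L, TRUE)
  # every center, via the exported single-window functions
  half <- w %/% 2
  k <- 0
  for (r in (half + 1):(12 - half)) {
    for (cc in (half + 1):(10 - half)) {
      k <- k + 1
      win <- q[(r - half):(r + half), (cc - half):(cc + half)]
      fr <- textureFeatures(cooccurrence(win, c(1, 1), levels = 8))
      expect_equal(unname(map[k, "row"]), r)
      expect_equal(unname(map[k, "col"]), cc)
      expect_equal(unname(map[k, names(fr)]), unname(fr),
                   tolerance = 1e-12)
    }
  }
  expect_equal(k, nrow(map))
})

test_that("region texture averages windows and handles masked polygons", {
  sim <- simulateScene(treatmentDesign(replicates = 1, seasons = 1),
                       sceneConfig(seed = 6L, plotSizePx = c(13L, 13L)))
  cfg <- glcmConfig(window = 7)
  tf <- regionTexture(sim$scene, plotRegions(sim$scene)$polygon[[1]], 6,
                      cfg)
  expect_equal(names(tf), c("MEA", "VAR", "HOM", "CON", "DIS", "ENT",
                            "SEM", "COR"))
  expect_equal(attr(tf, "nWindows"), 49)  # (13 - 7 + 1)^2
  expect_true(tf[["HOM"]] > 0 && tf[["HOM"]] <= 1)
  expect_true(tf[["SEM"]] > 0 && tf[["SEM"]] <= 1)
  expect_true(tf[["ENT"]] >= 0 && tf[["VAR"]] >= 0)
  expect_true(abs(tf[["COR"]]) <= 1)

  # an L-shaped region loses the windows overlapping the notch
  sim2 <- simulateScene(treatmentDesign(replicates = 1, seasons = 1),
                        sceneConfig(seed = 6L, plotSizePx = c(17L, 17L)))
  poly <- plotRegions(sim2$scene)$polygon[[1]]
  x0 <- poly[1, 1]; y0 <- poly[1, 2]
  lshape <- cbind(x = x0 + c(0, 17, 17, 10, 10, 0),
                  y = y0 + c(0, 0, 10, 10, 17, 17))
  tfL <- regionTexture(sim2$scene, lshape, 6, cfg)
  full <- regionTexture(sim2$scene, poly, 6, cfg)
  expect_lt(attr(tfL, "nWindows"), attr(full, "nWindows"))

  expect_error(regionTexture(sim$scene,
                             cbind(x = x0 + c(0, 4, 4, 0),
                                   y = y0 + c(0, 0, 4, 4)), 6, cfg),
               "too small")
})

test_that("constant plots yield the degenerate texture signature", {
  rows <- data.frame(plot_id = "A", season = 1, stringsAsFactors = FALSE)
  scene <- renderScene(rows, 70, sceneConfig(noiseSd = 0, plotNoiseSd = 0,
                                             textureLink = 0))
  tf <- regionTexture(scene, "A", 1)
  expect_equal(unname(tf[c("VAR", "CON", "DIS", "ENT")]), rep(0, 4))
  expect_equal(unname(tf[c("HOM", "SEM")]), c(1, 1))
  expect_equal(unname(tf[["COR"]]), 0)  # undefined everywhere -> sentinel
  expect_equal(attr(tf, "nCorUndefined"), attr(tf, "nWindows"))
})

test_that("texture features attach to the container in band-major order", {
  sim <- simulateScene(treatmentDesign(replicates = 1, seasons = 1),
                       sceneConfig(seed = 6L, plotSizePx = c(11L, 11L)))
  se <- extractSamples(sim$scene, sim$samples)
  se <- addTextureFeatures(se, sim$scene)
  expect_equal(nrow(se), 6 + 48)
  nms <- rownames(se)[featureClasses(se) == "texture"]
  expect_equal(nms, textureFeatureNames())
  expect_equal(nms[1:9], c("Mean1", "Variance1", "Homogeneity1",
                           "Contrast1", "Dissimilarity1", "Entropy1",
                           "Second Moment1", "Correlation1", "Mean2"))
  # spot check one sample/band against regionTexture
  tf <- regionTexture(sim$scene, plotRegions(sim$scene)$polygon[[4]], 2)
  X <- featureMatrix(se)
  expect_equal(unname(X[4, "Variance2"]), unname(tf[["VAR"]]),
               tolerance = 1e-12)
})
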