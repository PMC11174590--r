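#' Treatment design of the emulated field trial
#'
#' A mulch-by-irrigation split-plot trial: three mulching treatments
#' (straw mulch SM, film mulch FM, no mulch NM) crossed with three
#' irrigation levels (W1 < W2 < W3), replicated, over one or more growing
#' seasons. The default 3 x 3 x 3 design over 2 seasons yields the 54
#' plot-season samples the downstream analysis expects.
#'
#' @param mulchLevels,irrigationLevels character vectors of treatment labels.
#' @param replicates plots per treatment cell per season.
#' @param seasons number of growing seasons.
#' @return A list of class `treatmentDesign`.
#' @export
treatmentDesign <- function(mulchLevels = c("SM", "FM", "NM"),
                            irrigationLevels = c("W1", "W2", "W3"),
                            replicates = 3L, seasons = 2L) {
  if (length(mulchLevels) < 1 || length(irrigationLevels) < 1)
    stop("treatment design needs at least one level per factor")
  if (replicates < 1 || seasons < 1)
    stop("replicates and seasons must be positive")
  structure(list(mulchLevels = mulchLevels,
                 irrigationLevels = irrigationLevels,
                 replicates = as.integer(replicates),
                 seasons = as.integer(seasons)),
            class = "treatmentDesign")
}

#' Scene generator configuration
#'
#' Parameters of the synthetic multispectral scene. Per-plot band means
#' follow a linear moisture response
#' `mean_b = bandIntercept[b] + bandSlope[b] * moisture` (clamped to
#' `[0, 1]`), perturbed by per-plot calibration jitter (`plotNoiseSd`,
#' emulating residual illumination/calibration drift between plots).
#' Within-plot texture is a kernel-smoothed Gaussian field, shared across
#' bands, whose standard deviation grows linearly with moisture
#' (`textureLink * (moisture - 50) / 25` relative to the band mean,
#' clamped at zero below 50 %), so GLCM features carry moisture signal.
#' `noiseSd` is additive per-pixel sensor
#' noise. Defaults give canopy-like reflectance (NIR about 0.45 at 70 %
#' moisture, wetter canopies brighter in NIR/red edge and darker in the
#' visible).
#'
#' @param plotSizePx `c(rows, cols)` of each plot region in pixels.
#' @param gapPx gap between plots in the scene mosaic, pixels.
#' @param wavelengths band center wavelengths (nm), band order 1..6.
#' @param bandIntercept,bandSlope linear moisture response per band
#'   (reflectance, and reflectance per percent moisture).
#' @param moistureBaseline baseline leaf moisture (% fresh mass).
#' @param mulchEffect,irrigationEffect named additive treatment effects
#'   (percentage points) keyed by treatment label.
#' @param moistureSd residual plot-to-plot moisture s.d. (percentage points).
#' @param textureLink scalar linking moisture to the relative s.d. of the
#'   within-plot spatial field; 0 disables texture.
#' @param noiseSd per-pixel additive sensor noise s.d. (reflectance).
#' @param plotNoiseSd per-plot, per-band calibration jitter s.d.
#'   (reflectance).
#' @param seed integer master seed; identical config + seed gives
#'   bit-identical scenes.
#' @return A list of class `sceneConfig`.
#' @export
sceneConfig <- function(plotSizePx = c(21L, 21L), gapPx = 4L,
                        wavelengths = c(450, 555, 660, 720, 750, 840),
                        bandIntercept = c(0.068, 0.136, 0.120,
                                          0.145, 0.210, 0.240),
                        bandSlope = c(-0.0004, -0.0008, -0.0010,
                                      0.0015, 0.0020, 0.0030),
                        moistureBaseline = 66,
                        mulchEffect = c(SM = 3, FM = 1.5, NM = 0),
                        irrigationEffect = c(W1 = 0, W2 = 2.5, W3 = 5),
                        moistureSd = 2,
                        textureLink = 0.06,
                        noiseSd = 0.01,
                        plotNoiseSd = 0.002,
                        seed = 1L) {
  stopifnot(length(bandIntercept) == length(wavelengths),
            length(bandSlope) == length(wavelengths),
            moistureSd >= 0, textureLink >= 0, noiseSd >= 0,
            plotNoiseSd >= 0, all(plotSizePx >= 3))
  structure(list(plotSizePx = as.integer(plotSizePx),
                 gapPx = as.integer(gapPx), wavelengths = wavelengths,
                 bandIntercept = bandIntercept, bandSlope = bandSlope,
                 moistureBaseline = moistureBaseline,
                 mulchEffect = mulchEffect,
                 irrigationEffect = irrigationEffect,
                 moistureSd = moistureSd, textureLink = textureLink,
                 noiseSd = noiseSd, plotNoiseSd = plotNoiseSd,
                 seed = as.integer(seed)),
            class = "sceneConfig")
}

#' Enumerate plot-season rows of a treatment design
#'
#' @param design a [treatmentDesign()].
#' @return `data.frame(plot_id, season, mulch, irrigation)`; one row per
#'   plot and season (54 rows at the default design). Plot layout is
#'   deterministic: replicates nested in irrigation nested in mulch.
#' @export
generateDesign <- function(design = treatmentDesign()) {
  stopifnot(inherits(design, "treatmentDesign"))
  cell <- expand.grid(replicate = seq_len(design$replicates),
                      irrigation = design$irrigationLevels,
                      mulch = design$mulchLevels,
                      stringsAsFactors = FALSE)
  cell$plot_id <- sprintf("P%02d", seq_len(nrow(cell)))
  out <- do.call(rbind, lapply(seq_len(design$seasons), function(s) {
    data.frame(plot_id = cell$plot_id, season = s, mulch = cell$mulch,
               irrigation = cell$irrigation, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Draw leaf moisture for each plot-season row
#'
#' Moisture = baseline + mulch effect + irrigation effect + Gaussian
#' noise, clamped to the open interval (0, 100).
#'
#' @param rows output of [generateDesign()].
#' @param config a [sceneConfig()].
#' @return Numeric vector of moisture percentages, one per row.
#' @export
drawMoisture <- function(rows, config = sceneConfig()) {
  stopifnot(nrow(rows) > 0)
  me <- config$mulchEffect[rows$mulch]
  ie <- config$irrigationEffect[rows$irrigation]
  if (anyNA(me) || anyNA(ie))
    stop("treatment label without a configured effect")
  set.seed(config$seed + 1L)
  m <- config$moistureBaseline + as.numeric(me) + as.numeric(ie) +
    rnorm(nrow(rows), 0, config$moistureSd)
  pmin(pmax(m, 1e-6), 100 - 1e-6)
}

# Smoothed (3x3 box kernel) Gaussian field with empirical sd rescaled to
# `sdTarget`; zero field when sdTarget is 0.
smoothNoiseField <- function(rows, cols, sdTarget) {
  if (sdTarget <= 0) return(matrix(0, rows, cols))
  f <- matrix(rnorm(rows * cols), rows, cols)
  k <- matrix(1 / 9, 3, 3)
  f <- EBImage::filter2(f, k, boundary = "circular")
  f / sd(f) * sdTarget
}

#' Render a synthetic multispectral scene
#'
#' Lays the plot-season rows out on a rectangular mosaic and fills each
#' plot with its band means plus the moisture-linked spatial field and
#' sensor noise (see [sceneConfig()]).
#'
#' @param rows output of [generateDesign()].
#' @param moisture moisture percentages, one per row.
#' @param config a [sceneConfig()].
#' @return A [MultispectralScene-class].
#' @export
renderScene <- function(rows, moisture, config = sceneConfig()) {
  stopifnot(nrow(rows) > 0, length(moisture) == nrow(rows))
  nb <- length(config$wavelengths)
  pr <- config$plotSizePx[1]; pc <- config$plotSizePx[2]; g <- config$gapPx
  n <- nrow(rows)
  gridCols <- ceiling(sqrt(n)); gridRows <- ceiling(n / gridCols)
  nr <- gridRows * (pr + g) + g
  nc <- gridCols * (pc + g) + g
  bands <- array(0, dim = c(nr, nc, nb))

  targets <- outer(moisture, config$bandSlope) +
    matrix(config$bandIntercept, n, nb, byrow = TRUE)
  bad <- targets < 0 | targets > 1
  if (any(bad))
    stop("configured band response puts mean reflectance outside [0,1] ",
         "for sample(s) ", paste(head(which(rowSums(bad) > 0), 5),
                                 collapse = ", "))

  set.seed(config$seed + 2L)
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    gr <- (i - 1) %/% gridCols; gc <- (i - 1) %% gridCols
    r0 <- g + gr * (pr + g); c0 <- g + gc * (pc + g)  # 0-based offsets
    field <- smoothNoiseField(pr, pc,
                              config$textureLink *
                                max(moisture[i] - 50, 0) / 25)
    for (b in seq_len(nb)) {
      mu <- targets[i, b] + rnorm(1, 0, config$plotNoiseSd)
      px <- mu * (1 + field)
      if (config$noiseSd > 0)
        px <- px + matrix(rnorm(pr * pc, 0, config$noiseSd), pr, pc)
      bands[r0 + seq_len(pr), c0 + seq_len(pc), b] <- pmin(pmax(px, 0), 1)
    }
    polys[[i]] <- cbind(x = c(c0, c0 + pc, c0 + pc, c0),
                        y = c(r0, r0, r0 + pr, r0 + pr))
  }
  plots <- data.frame(plot_id = rows$plot_id, season = rows$season,
                      stringsAsFactors = FALSE)
  plots$polygon <- polys
  MultispectralScene(bands, config$wavelengths, plots)
}

#' Simulate a full labelled scene
#'
#' Convenience wrapper: enumerate the design, draw moisture, render the
#' scene.
#'
#' @param design a [treatmentDesign()].
#' @param config a [sceneConfig()].
#' @return `list(scene = MultispectralScene, samples = data.frame)` where
#'   `samples` has columns `plot_id, season, mulch, irrigation,
#'   moisture_pct`.
#' @examples
#' sim <- simulateScene(treatmentDesign(seasons = 1),
#'                      sceneConfig(seed = 7))
#' sim$scene
#' head(sim$samples)
#' @export
simulateScene <- function(design = treatmentDesign(),
                          config = sceneConfig()) {
  rows <- generateDesign(design)
  m <- drawMoisture(rows, config)
  scene <- renderScene(rows, m, config)
  samples <- cbind(rows, moisture_pct = m)
  list(scene = scene, samples = samples)
}

#' Texture table with a planted feature-pair signal
#'
#' Generates a sample-by-feature texture table in which moisture is
#' driven through one designated texture-index pair: all 48 features are
#' i.i.d. Uniform(0.5, 1.5) (positive, so reciprocal indices are
#' well-defined), and moisture is a linear function of the chosen index
#' of the two planted features plus Gaussian noise calibrated so the
#' population correlation between index and moisture is `plantedR`. Used
#' to verify that the exhaustive pair search recovers a known ground
#' truth.
#'
#' @param nSamples number of samples.
#' @param planted `c(feature_i, feature_j)`, names from
#'   [textureFeatureNames()].
#' @param family texture-index family driving moisture (see
#'   [textureIndex()]).
#' @param plantedR target correlation between planted index and moisture.
#' @param moistureMean,moistureSd moisture distribution (% fresh mass).
#' @param seed integer seed.
#' @return `list(textures = matrix, moisture = numeric)`.
#' @export
simulatePlantedTextures <- function(nSamples = 54,
                                    planted = c("Variance1", "Correlation5"),
                                    family = "RDTI", plantedR = 0.9,
                                    moistureMean = 70, moistureSd = 2,
                                    seed = 1L) {
  nms <- textureFeatureNames()
  stopifnot(all(planted %in% nms), length(planted) == 2,
            plantedR > 0, plantedR < 1)
  set.seed(seed)
  X <- matrix(runif(nSamples * length(nms), 0.5, 1.5),
              nrow = nSamples, dimnames = list(NULL, nms))
  z <- textureIndex(family, X[, planted[1]], X[, planted[2]])
  zs <- (z - mean(z)) / sd(z)
  eps <- rnorm(nSamples)
  m <- moistureMean + moistureSd *
    (plantedR * zs + sqrt(1 - plantedR^2) * eps)
  list(textures = X, moisture = pmin(pmax(m, 1e-6), 100 - 1e-6))
}
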