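#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline. All stage seeds derive
#' from the single master `seed`, so a config fully determines the run.
#' Flags: `osaviCanonical` / `msaviAsPrinted` select vegetation-index
#' formula variants ([computeVI()]); `paperFaithful = TRUE` runs the
#' texture-index pair search on all samples instead of the training set
#' only (the default avoids leaking validation moisture into feature
#' construction); `permutations > 0` adds a selection-bias-adjusted
#' permutation p-value to each family's best pair.
#'
#' @param seed master integer seed.
#' @param ... named overrides, merged into the defaults (nested lists
#'   merge recursively), e.g. `scene = list(noiseSd = 0)`.
#' @return A config list of class `pipelineConfig`.
#' @export
defaultConfig <- function(seed = 1L, ...) {
  seed <- as.integer(seed)
  cfg <- list(
    seed = seed,
    design = list(mulchLevels = c("SM", "FM", "NM"),
                  irrigationLevels = c("W1", "W2", "W3"),
                  replicates = 3L, seasons = 2L),
    scene = as.list(sceneConfig(seed = seed))[
      setdiff(names(sceneConfig()), "seed")],
    glcm = list(window = 7L, offset = c(1L, 1L), levels = 64L,
                symmetric = TRUE),
    redEdgeBand = 4L,
    alpha = 0.05,
    trainFraction = 2 / 3,
    flags = list(osaviCanonical = FALSE, msaviAsPrinted = FALSE,
                 paperFaithful = FALSE, permutations = 0L),
    elm = list(hiddenNeurons = 60L, restarts = 50L),
    xgb = list(nrounds = 100L, eta = 0.03, maxDepth = 5L),
    bpnn = list(hiddenNeurons = 15L, maxEpochs = 300L))
  over <- list(...)
  merge2 <- function(a, b) {
    for (nm in names(b))
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge2(a[[nm]], b[[nm]]) else b[[nm]]
    a
  }
  structure(merge2(cfg, over), class = "pipelineConfig")
}

#' Validate a pipeline configuration
#'
#' @param config a config list (e.g. from [defaultConfig()] or parsed
#'   from YAML).
#' @return `TRUE` if valid, otherwise a character vector of problems.
#' @export
validateConfig <- function(config) {
  probs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) probs <<- c(probs, msg)
  chk(is.numeric(config$seed) && length(config$seed) == 1,
      "seed must be a single integer")
  d <- config$design
  chk(length(d$mulchLevels) >= 1 && length(d$irrigationLevels) >= 1,
      "design needs at least one level per factor")
  chk(isTRUE(d$replicates >= 1) && isTRUE(d$seasons >= 1),
      "replicates and seasons must be positive")
  chk(config$alpha > 0 && config$alpha < 1, "alpha must be in (0, 1)")
  chk(config$trainFraction > 0 && config$trainFraction < 1,
      "trainFraction must be in (0, 1)")
  g <- config$glcm
  chk(g$window >= 3 && g$window %% 2 == 1, "glcm window must be odd >= 3")
  chk(g$levels >= 2, "glcm levels must be >= 2")
  chk(any(g$offset != 0), "glcm offset must be nonzero")
  chk(config$redEdgeBand %in% c(4L, 5L), "redEdgeBand must be 4 or 5")
  s <- config$scene
  chk(all(s$plotSizePx >= g$window + max(abs(g$offset))),
      "plot size too small for the texture window")
  if (length(probs)) probs else TRUE
}

#' Run the full estimation pipeline
#'
#' simulate (or load) a scene, extract reflectance, add vegetation
#' indices and GLCM textures, search texture-index pairs, screen at
#' `alpha`, assemble the four combinations, and fit the 3 x 4
#' model-by-combination grid. With `outDir` set, writes the scene
#' files, feature table, screening table, per-family r-matrices,
#' results, predictions and a manifest (config + seeds + package
#' versions) so a rerun from the same manifest reproduces `results.csv`.
#'
#' @param config a [defaultConfig()] list.
#' @param outDir optional output directory.
#' @param scene,samples optional pre-built scene + moisture table; by
#'   default both are simulated from the config.
#' @return A list with elements `se` (feature container), `screen`,
#'   `search` (hits/matrices), `combinations`, `split`, `fit`
#'   (results/predictions/models), `samples`, `scene`, `config`.
#' @export
runPipeline <- function(config = defaultConfig(), outDir = NULL,
                        scene = NULL, samples = NULL) {
  v <- validateConfig(config)
  if (!isTRUE(v)) stop("invalid config: ", paste(v, collapse = "; "))
  seed <- as.integer(config$seed)

  if (is.null(scene)) {
    design <- treatmentDesign(config$design$mulchLevels,
                              config$design$irrigationLevels,
                              config$design$replicates,
                              config$design$seasons)
    scfg <- do.call(sceneConfig, c(config$scene, list(seed = seed)))
    sim <- simulateScene(design, scfg)
    scene <- sim$scene; samples <- sim$samples
  }
  stopifnot(!is.null(samples))

  se <- extractSamples(scene, samples)
  se <- addVegetationIndices(se, redEdgeBand = config$redEdgeBand,
                             osaviCanonical = config$flags$osaviCanonical,
                             msaviAsPrinted = config$flags$msaviAsPrinted)
  gcfg <- do.call(glcmConfig, config$glcm)
  se <- addTextureFeatures(se, scene, gcfg)

  split <- splitSamples(ncol(se), config$trainFraction, seed + 3L)
  searchIdx <- if (isTRUE(config$flags$paperFaithful)) NULL
               else split$train
  search <- tryCatch(
    searchAllFamilies(se, samples = searchIdx,
                      permutations = config$flags$permutations,
                      permSeed = seed + 7L),
    error = function(e) {
      if (!grepl("singular", conditionMessage(e))) stop(e)
      warning("texture-index search degenerate (constant textures); ",
              "skipping texture indices")
      NULL
    })
  if (!is.null(search)) se <- addTextureIndices(se, search$hits)

  screen <- screenFeatures(se, alpha = config$alpha)
  combos <- buildCombinations(screen)

  fit <- runModelMatrix(se, combos, split,
                        elm = do.call(elmSpec,
                                      c(config$elm, list(seed = seed + 4L))),
                        xgb = do.call(xgbSpec,
                                      c(config$xgb, list(seed = seed + 5L))),
                        bpnn = do.call(bpnnSpec,
                                       c(config$bpnn, list(seed = seed + 6L))))

  out <- list(se = se, screen = screen, search = search,
              combinations = combos, split = split, fit = fit,
              samples = samples, scene = scene, config = config)
  if (!is.null(outDir)) writePipelineOutputs(out, outDir)
  out
}

# Serialize a pipeline run: scene files, tables, manifest.
writePipelineOutputs <- function(run, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeScene(run$scene, file.path(outDir, "scene"), run$samples)
  feat <- cbind(run$samples[, c("plot_id", "season")],
                as.data.frame(featureMatrix(run$se)))
  write.csv(feat, file.path(outDir, "features.csv"), row.names = FALSE)
  write.csv(run$screen, file.path(outDir, "screening.csv"),
            row.names = FALSE)
  if (!is.null(run$search)) {
    write.csv(run$search$hits,
              file.path(outDir, "texture_index_hits.csv"),
              row.names = FALSE)
    for (fam in names(run$search$matrices))
      write.csv(run$search$matrices[[fam]],
                file.path(outDir, paste0("rmatrix_", fam, ".csv")))
  }
  write.csv(run$fit$results, file.path(outDir, "results.csv"),
            row.names = FALSE)
  write.csv(run$fit$predictions, file.path(outDir, "predictions.csv"),
            row.names = FALSE)
  manifest <- list(config = unclass(run$config),
                   combinations = run$combinations,
                   train = run$split$train,
                   packages = list(
                     canopywater = as.character(
                       utils::packageVersion("canopywater")),
                     xgboost = as.character(utils::packageVersion("xgboost")),
                     R = paste(R.version$major, R.version$minor, sep = ".")))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(outDir)
}

#' Read a pipeline config from YAML
#'
#' Reads a YAML file and merges it over [defaultConfig()]; the file only
#' needs to state overrides. Round-trips with [yaml::write_yaml()].
#'
#' @param path YAML file path.
#' @return A `pipelineConfig` list.
#' @export
readConfig <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) y$seed else 1L
  y$seed <- NULL
  do.call(defaultConfig, c(list(seed = seed), y))
}
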