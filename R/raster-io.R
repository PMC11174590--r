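#' Write a scene to disk
#'
#' Serializes the band stack as a multi-page float32 TIFF, the plot
#' regions as GeoJSON polygons (raster coordinates, properties `plot_id`
#' and `season`), band wavelengths as a JSON sidecar, and, when given,
#' the moisture table as CSV. Reading the directory back with
#' [readScene()] reproduces values to float32 precision.
#'
#' @param scene a [MultispectralScene-class].
#' @param path output directory (created if needed).
#' @param samples optional `data.frame` with `plot_id, season, mulch,
#'   irrigation, moisture_pct`, written as `moisture.csv`.
#' @return `path`, invisibly.
#' @export
writeScene <- function(scene, path, samples = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  b <- scene@bands
  pages <- lapply(seq_len(dim(b)[3]), function(k) b[, , k])
  tiff::writeTIFF(pages, file.path(path, "bands.tif"),
                  bits.per.sample = 32L)
  jsonlite::write_json(list(wavelengths_nm = scene@wavelengths,
                            dims = dim(b)),
                       file.path(path, "scene.json"),
                       auto_unbox = FALSE, digits = NA)
  feats <- lapply(seq_len(nrow(scene@plots)), function(i) {
    poly <- scene@plots$polygon[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(plot_id = scene@plots$plot_id[i],
                           season = scene@plots$season[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(j) as.numeric(ring[j, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       file.path(path, "plots.geojson"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(samples))
    write.csv(samples[, c("plot_id", "season", "mulch", "irrigation",
                          "moisture_pct")],
              file.path(path, "moisture.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a scene from disk
#'
#' Counterpart of [writeScene()]. `rasterPath`/`regionsPath` may also be
#' given explicitly to read foreign TIFF + GeoJSON pairs; in that case
#' `wavelengths` must be supplied unless a `scene.json` sidecar sits next
#' to the raster.
#'
#' @param path directory written by [writeScene()], or `NULL` when the
#'   two file paths are given.
#' @param rasterPath,regionsPath explicit file paths (optional).
#' @param wavelengths band centers (nm); default from the sidecar.
#' @param expectedBands if not `NULL`, error unless the raster has this
#'   many bands.
#' @return A [MultispectralScene-class].
#' @export
readScene <- function(path = NULL, rasterPath = NULL, regionsPath = NULL,
                      wavelengths = NULL, expectedBands = NULL) {
  if (!is.null(path)) {
    rasterPath <- file.path(path, "bands.tif")
    regionsPath <- file.path(path, "plots.geojson")
  }
  if (!file.exists(rasterPath)) stop("raster file not found: ", rasterPath)
  if (!file.exists(regionsPath)) stop("regions file not found: ", regionsPath)
  pages <- tiff::readTIFF(rasterPath, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!is.null(expectedBands) && length(pages) != expectedBands)
    stop("band count mismatch in ", rasterPath, ": found ", length(pages),
         ", expected ", expectedBands)
  bands <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
  if (is.null(wavelengths)) {
    side <- file.path(dirname(rasterPath), "scene.json")
    if (file.exists(side))
      wavelengths <- jsonlite::read_json(side,
                                         simplifyVector = TRUE)$wavelengths_nm
    else wavelengths <- seq_len(length(pages))
  }
  gj <- jsonlite::read_json(regionsPath, simplifyVector = FALSE)
  feats <- gj$features
  if (length(feats) == 0) stop("no plot regions in ", regionsPath)
  plots <- data.frame(
    plot_id = vapply(feats, function(f) as.character(f$properties$plot_id), ""),
    season = vapply(feats, function(f) as.numeric(f$properties$season), 0),
    stringsAsFactors = FALSE)
  plots$polygon <- lapply(feats, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    unname(ring[-nrow(ring), , drop = FALSE])  # drop closing vertex
  })
  scene <- MultispectralScene(bands, wavelengths, plots)
  validObject(scene)
  scene
}

#' Mean reflectance over a plot region
#'
#' Arithmetic mean of one band over the pixels whose centers fall inside
#' the region polygon, optionally after masking. Masking excludes pixels
#' whose NIR (last-band) reflectance falls below `nirFloor` — a simple
#' shadow/soil exclusion — and/or pixels listed in `mask`.
#'
#' @param scene a [MultispectralScene-class].
#' @param region a `plot_id` string, or a two-column `(x, y)` polygon
#'   matrix in raster coordinates.
#' @param band band index.
#' @param season season (needed when a `plot_id` spans several seasons).
#' @param nirFloor optional reflectance floor on the last band; pixels
#'   below it are excluded. Default `NULL` (off).
#' @param mask optional logical vector/matrix, `TRUE` = exclude, aligned
#'   with the region's pixel list (row-major within the bounding box).
#' @return Scalar mean reflectance in `[0, 1]`.
#' @export
meanReflectance <- function(scene, region, band, season = NULL,
                            nirFloor = NULL, mask = NULL) {
  stopifnot(band >= 1, band <= nBands(scene))
  poly <- if (is.character(region))
    regionRow(scene, region, season)$polygon[[1]] else region
  px <- pixelsInPolygon(dim(scene@bands)[1:2], poly)
  if (nrow(px) == 0) stop("region contains no pixels")
  keep <- rep(TRUE, nrow(px))
  if (!is.null(mask)) {
    m <- as.logical(mask)
    if (length(m) != nrow(px))
      stop("mask length ", length(m), " does not match the region's ",
           nrow(px), " pixels")
    keep <- keep & !m
  }
  if (!is.null(nirFloor)) {
    nir <- scene@bands[cbind(px[, 1], px[, 2], nBands(scene))]
    keep <- keep & nir >= nirFloor
  }
  if (!any(keep)) stop("region is empty after masking")
  mean(scene@bands[cbind(px[keep, 1], px[keep, 2], band)])
}

#' Extract per-plot samples into a SummarizedExperiment
#'
#' Joins the moisture table to the scene's plot regions on
#' `plot_id + season` and computes the mean reflectance of every band
#' over each region. The result is the package's central container: a
#' `SummarizedExperiment` with one column per plot-season sample, a
#' `features` assay (rows `b1..b6`, feature class `"reflectance"` in
#' `rowData`), and the treatment labels and measured moisture in
#' `colData`.
#'
#' @param scene a [MultispectralScene-class].
#' @param samples `data.frame(plot_id, season, mulch, irrigation,
#'   moisture_pct)`; row order is preserved in the columns.
#' @param nirFloor optional shadow/soil exclusion floor, see
#'   [meanReflectance()].
#' @return A [SummarizedExperiment::SummarizedExperiment].
#' @export
extractSamples <- function(scene, samples, nirFloor = NULL) {
  key <- paste(samples$plot_id, samples$season)
  skey <- paste(scene@plots$plot_id, scene@plots$season)
  missing <- setdiff(key, skey)
  if (length(missing))
    stop("no scene region for sample(s): ",
         paste(missing, collapse = ", "))
  nb <- nBands(scene)
  refl <- vapply(key, function(k) {
    i <- match(k, skey)
    vapply(seq_len(nb), function(b)
      meanReflectance(scene, scene@plots$polygon[[i]], b,
                      nirFloor = nirFloor), 0)
  }, numeric(nb))
  rownames(refl) <- paste0("b", seq_len(nb))
  colnames(refl) <- paste0(samples$plot_id, "_S", samples$season)
  cd <- S4Vectors::DataFrame(samples, row.names = colnames(refl))
  rd <- S4Vectors::DataFrame(class = rep("reflectance", nb),
                             row.names = rownames(refl))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = refl), rowData = rd, colData = cd)
}

#' Sample-by-feature matrix from the container
#'
#' @param se the `SummarizedExperiment` built by [extractSamples()].
#' @param features feature (row) names to keep; default all.
#' @return Numeric matrix, samples in rows, features in columns.
#' @export
featureMatrix <- function(se, features = NULL) {
  a <- SummarizedExperiment::assay(se, "features")
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(a))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    a <- a[features, , drop = FALSE]
  }
  t(a)
}

#' Measured leaf moisture of the samples
#' @param se the container built by [extractSamples()].
#' @return Numeric vector (% fresh mass), one per sample.
#' @export
moisturePct <- function(se) {
  SummarizedExperiment::colData(se)$moisture_pct
}

#' Feature classes (reflectance / vi / texture / texture_index)
#' @param se the container built by [extractSamples()].
#' @return Character vector aligned with feature rows.
#' @export
featureClasses <- function(se) {
  SummarizedExperiment::rowData(se)$class
}

# rbind a new feature block onto the container, tagging its class.
addFeatureBlock <- function(se, block, class) {
  stopifnot(ncol(block) == ncol(se))
  a <- rbind(SummarizedExperiment::assay(se, "features"), block)
  rd <- S4Vectors::DataFrame(
    class = c(featureClasses(se), rep(class, nrow(block))),
    row.names = rownames(a))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = a), rowData = rd,
    colData = SummarizedExperiment::colData(se))
}
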