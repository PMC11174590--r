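#' MultispectralScene: a multiband canopy raster with plot regions
#'
#' Container for a stack of co-registered reflectance bands plus the
#' plot-region polygons (regions of interest) over which per-plot
#' statistics are computed.
#'
#' Raster coordinates follow the image convention: origin at the top-left
#' corner, `x` along columns, `y` along rows, and the center of pixel
#' `(r, c)` (1-based row/column) at `(c - 0.5, r - 0.5)`. A pixel belongs
#' to a region iff its center lies inside the region polygon; polygon
#' vertices sit on integer coordinates so pixel centers are never on an
#' edge and the rule is unambiguous.
#'
#' @slot bands numeric array `[rows, cols, nband]` of reflectance in `[0, 1]`.
#' @slot wavelengths numeric vector of band center wavelengths (nm), one
#'   per band, in file/band order.
#' @slot plots `data.frame` with columns `plot_id`, `season` and a
#'   list-column `polygon` of two-column `(x, y)` vertex matrices.
#'
#' @seealso [simulateScene()], [readScene()], [meanReflectance()]
#' @export
setClass("MultispectralScene",
  representation(bands = "array", wavelengths = "numeric",
                 plots = "data.frame"))

setValidity("MultispectralScene", function(object) {
  b <- object@bands
  msgs <- character()
  if (length(dim(b)) != 3L)
    return("bands must be a 3-d array [rows, cols, nband]")
  if (length(object@wavelengths) != dim(b)[3L])
    msgs <- c(msgs, "one wavelength per band required")
  p <- object@plots
  need <- c("plot_id", "season", "polygon")
  if (!all(need %in% names(p)))
    return("plots needs columns plot_id, season, polygon")
  if (anyDuplicated(paste(p$plot_id, p$season)))
    msgs <- c(msgs, "plot_id x season must be unique")
  if (nrow(p) > 0) {
    xy <- do.call(rbind, p$polygon)
    if (any(xy[, 1] < 0 | xy[, 1] > dim(b)[2L] |
            xy[, 2] < 0 | xy[, 2] > dim(b)[1L]))
      msgs <- c(msgs, "a plot polygon extends outside the raster")
  }
  rng <- range(b, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    msgs <- c(msgs, "reflectance values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MultispectralScene
#'
#' @param bands numeric array `[rows, cols, nband]`.
#' @param wavelengths band center wavelengths (nm).
#' @param plots `data.frame(plot_id, season, polygon)`; `polygon` is a
#'   list of two-column `(x, y)` vertex matrices in raster coordinates.
#' @return A [MultispectralScene-class] object.
#' @export
MultispectralScene <- function(bands, wavelengths, plots) {
  if (!is.list(plots$polygon)) plots$polygon <- as.list(plots$polygon)
  new("MultispectralScene", bands = bands,
      wavelengths = as.numeric(wavelengths), plots = plots)
}

#' @describeIn MultispectralScene-class number of spectral bands
#' @param scene A `MultispectralScene`.
#' @export
nBands <- function(scene) dim(scene@bands)[3L]

#' @describeIn MultispectralScene-class the `[rows, cols, nband]` array
#' @export
bandArray <- function(scene) scene@bands

#' @describeIn MultispectralScene-class band center wavelengths (nm)
#' @export
wavelengths <- function(scene) scene@wavelengths

#' @describeIn MultispectralScene-class the plot-region table
#' @export
plotRegions <- function(scene) scene@plots

setMethod("show", "MultispectralScene", function(object) {
  d <- dim(object@bands)
  cat("MultispectralScene:", d[1], "x", d[2], "px,", d[3], "bands (",
      paste(object@wavelengths, collapse = "/"), "nm ),",
      nrow(object@plots), "plot regions\n")
})

#' Pixel indices whose centers fall inside a polygon
#'
#' @param dims `c(rows, cols)` of the raster.
#' @param polygon two-column `(x, y)` vertex matrix.
#' @return Integer matrix with columns `row`, `col`.
#' @keywords internal
pixelsInPolygon <- function(dims, polygon) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2, nrow(polygon) >= 3)
  cmin <- max(1L, floor(min(polygon[, 1])) + 1L)
  cmax <- min(dims[2L], ceiling(max(polygon[, 1])))
  rmin <- max(1L, floor(min(polygon[, 2])) + 1L)
  rmax <- min(dims[1L], ceiling(max(polygon[, 2])))
  if (cmax < cmin || rmax < rmin)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  grid <- expand.grid(row = rmin:rmax, col = cmin:cmax)
  centers <- cbind(grid$col - 0.5, grid$row - 0.5)
  keep <- mgcv::in.out(rbind(polygon, polygon[1, , drop = FALSE]), centers)
  as.matrix(grid[keep, , drop = FALSE])
}

# Look up one region row by plot_id (+ season when ambiguous).
regionRow <- function(scene, plotId, season = NULL) {
  p <- scene@plots
  hit <- p$plot_id == plotId
  if (!is.null(season)) hit <- hit & p$season == season
  i <- which(hit)
  if (length(i) == 0) stop("no region for plot_id '", plotId, "'",
                           if (!is.null(season)) paste0(" season ", season))
  if (length(i) > 1) stop("plot_id '", plotId,
                          "' matches several seasons; pass season=")
  p[i, , drop = FALSE]
}
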