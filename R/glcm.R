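#' GLCM configuration
#'
#' Defaults follow the common remote-sensing practice for co-occurrence
#' texture filtering: a 7 x 7 moving window, a one-pixel diagonal shift
#' `(dr, dc) = (1, 1)`, 64 gray levels quantized over the region's own
#' min-max range, and symmetric pair counting. The offset is
#' configurable because feature values differ between the diagonal
#' `(1, 1)` and horizontal `(0, 1)` conventions.
#'
#' @param window odd window side length, >= 3.
#' @param offset integer `c(dr, dc)` displacement; nonzero.
#' @param levels number of gray levels (>= 2).
#' @param symmetric count each pair in both directions.
#' @return A list of class `glcmConfig`.
#' @export
glcmConfig <- function(window = 7L, offset = c(1L, 1L), levels = 64L,
                       symmetric = TRUE) {
  stopifnot(window >= 3, window %% 2 == 1, levels >= 2,
            length(offset) == 2, any(offset != 0))
  structure(list(window = as.integer(window), offset = as.integer(offset),
                 levels = as.integer(levels), symmetric = symmetric),
            class = "glcmConfig")
}

#' The 48 texture feature names, band-major
#'
#' `Mean1, Variance1, ..., Correlation1, Mean2, ..., Correlation6`: the
#' eight co-occurrence measures per band, bands 1 to `nBands`.
#'
#' @param nBands number of bands (default 6).
#' @return Character vector of length `8 * nBands`.
#' @export
textureFeatureNames <- function(nBands = 6L) {
  meas <- c("Mean", "Variance", "Homogeneity", "Contrast",
            "Dissimilarity", "Entropy", "Second Moment", "Correlation")
  paste0(rep(meas, nBands), rep(seq_len(nBands), each = 8))
}

# short codes used internally, same order as textureFeatureNames()
glcmMeasureCodes <- function() {
  c("MEA", "VAR", "HOM", "CON", "DIS", "ENT", "SEM", "COR")
}

#' Quantize gray values to integer levels
#'
#' Linear binning of `range` into `levels` equal bins; values at the top
#' edge fall in the last bin. A constant input (zero range) maps
#' entirely to level 0.
#'
#' @param x numeric vector/matrix.
#' @param levels number of bins.
#' @param range `c(min, max)` to bin over; defaults to `range(x)`.
#' @return Integer levels in `0 .. levels - 1`, same shape as `x`.
#' @examples
#' quantizeGray(c(0, 0.25, 0.5, 1), 4)  # 0 1 2 3
#' @export
quantizeGray <- function(x, levels = 64L, range = NULL) {
  stopifnot(levels >= 2)
  if (is.null(range)) range <- base::range(x, na.rm = TRUE)
  w <- (range[2] - range[1]) / levels
  if (w <= 0) {
    q <- x; q[] <- 0L; storage.mode(q) <- "integer"
    return(q)
  }
  q <- pmin(as.integer(floor((x - range[1]) / w)), levels - 1L)
  q <- pmax(q, 0L)
  if (is.matrix(x)) dim(q) <- dim(x)
  q
}

#' Gray-level co-occurrence matrix of one window
#'
#' Counts co-occurring level pairs `(x[r, c], x[r + dr, c + dc])` over
#' all positions where both pixels lie inside the window, optionally in
#' both directions (`symmetric`), and normalizes to sum 1.
#'
#' @param x integer matrix of quantized levels (0-based).
#' @param offset integer `c(dr, dc)`.
#' @param symmetric count pairs in both directions (the result is then
#'   exactly symmetric).
#' @param levels matrix dimension; defaults to `max(x) + 1`.
#' @return `levels x levels` matrix `P` with `sum(P) == 1`.
#' @examples
#' cooccurrence(matrix(c(0L, 1L, 0L, 1L), 2), c(0, 1))
#' @export
cooccurrence <- function(x, offset = c(1L, 1L), symmetric = TRUE,
                         levels = NULL) {
  stopifnot(is.matrix(x))
  dr <- offset[1]; dc <- offset[2]
  if (dr == 0 && dc == 0) stop("offset must be nonzero")
  if (is.null(levels)) levels <- max(x) + 1L
  nr <- nrow(x); nc <- ncol(x)
  rows <- if (dr >= 0) seq_len(nr - dr) else seq(1 - dr, nr)
  cols <- if (dc >= 0) seq_len(nc - dc) else seq(1 - dc, nc)
  if (length(rows) == 0 || length(cols) == 0)
    stop("offset larger than window: no co-occurring pairs")
  i <- x[rows, cols, drop = FALSE]
  j <- x[rows + dr, cols + dc, drop = FALSE]
  P <- matrix(0, levels, levels)
  for (k in seq_along(i)) {
    P[i[k] + 1L, j[k] + 1L] <- P[i[k] + 1L, j[k] + 1L] + 1
    if (symmetric) P[j[k] + 1L, i[k] + 1L] <- P[j[k] + 1L, i[k] + 1L] + 1
  }
  P / sum(P)
}

#' Eight texture features of a normalized co-occurrence matrix
#'
#' With `P(i, j)` the normalized co-occurrence probabilities over levels
#' `i, j = 0 .. L-1`:
#' mean `MEA = sum_i i P_i.`, variance `VAR = sum_i (i - MEA)^2 P_i.`,
#' homogeneity `HOM = sum P / (1 + (i - j)^2)`, contrast
#' `CON = sum (i - j)^2 P`, dissimilarity `DIS = sum |i - j| P`, entropy
#' `ENT = -sum P log P` (natural log, `0 log 0 = 0`), second moment
#' `SEM = sum P^2`, and correlation
#' `COR = sum (i - mu_i)(j - mu_j) P / (sigma_i sigma_j)`. When either
#' marginal is degenerate (a constant window) COR is undefined and
#' returned as `NA`; regional averaging excludes such windows.
#'
#' @param P normalized co-occurrence matrix (`sum(P) == 1`).
#' @return Named numeric vector `MEA VAR HOM CON DIS ENT SEM COR`.
#' @export
textureFeatures <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (abs(sum(P) - 1) > 1e-8) stop("P must be normalized to sum 1")
  L <- nrow(P)
  lv <- 0:(L - 1)
  pi. <- rowSums(P); p.j <- colSums(P)
  mi <- sum(lv * pi.); mj <- sum(lv * p.j)
  vi <- sum((lv - mi)^2 * pi.); vj <- sum((lv - mj)^2 * p.j)
  D <- outer(lv, lv, "-")
  nz <- P > 0
  cov <- sum(outer(lv - mi, lv - mj) * P)
  c(MEA = mi,
    VAR = vi,
    HOM = sum(P / (1 + D^2)),
    CON = sum(D^2 * P),
    DIS = sum(abs(D) * P),
    ENT = -sum(P[nz] * log(P[nz])),
    SEM = sum(P^2),
    COR = if (vi > 0 && vj > 0) cov / sqrt(vi * vj) else NA_real_)
}

#' Windowed texture features of one plot region and band
#'
#' Quantizes the region's pixels over their own min-max range, slides
#' the GLCM window over every center whose full window lies inside the
#' region (no padding: pixels outside the region polygon are masked and
#' windows touching them are dropped), computes the eight features per
#' window, and averages each feature over the valid window centers.
#' Windows whose COR is undefined (constant windows) are excluded from
#' the COR average; their count is returned in the `"nCorUndefined"`
#' attribute.
#'
#' @param scene a [MultispectralScene-class].
#' @param region `plot_id` string or `(x, y)` polygon matrix.
#' @param band band index.
#' @param config a [glcmConfig()].
#' @param season season, when `plot_id` is ambiguous.
#' @return Named numeric vector of the 8 region-averaged features, with
#'   attributes `nWindows` and `nCorUndefined`.
#' @export
regionTexture <- function(scene, region, band, config = glcmConfig(),
                          season = NULL) {
  if (is.character(region)) {
    rr <- regionRow(scene, region, season)
    poly <- rr$polygon[[1]]
    label <- rr$plot_id
  } else {
    poly <- region
    label <- "polygon region"
  }
  px <- pixelsInPolygon(dim(scene@bands)[1:2], poly)
  if (nrow(px) == 0) stop("region '", label, "' contains no pixels")
  rrng <- range(px[, 1]); crng <- range(px[, 2])
  vals <- matrix(NA_real_, rrng[2] - rrng[1] + 1L, crng[2] - crng[1] + 1L)
  idx <- cbind(px[, 1] - rrng[1] + 1L, px[, 2] - crng[1] + 1L)
  vals[idx] <- scene@bands[cbind(px[, 1], px[, 2], band)]
  q <- quantizeGray(vals, config$levels,
                    range = range(vals, na.rm = TRUE))
  q[is.na(vals)] <- NA_integer_
  map <- glcm_feature_map(q, config$window, config$offset[1],
                          config$offset[2], config$levels,
                          config$symmetric)
  if (nrow(map) == 0)
    stop("region '", label, "' is too small for a ", config$window, "x",
         config$window, " texture window")
  feats <- map[, glcmMeasureCodes(), drop = FALSE]
  out <- colMeans(feats, na.rm = FALSE)
  corv <- feats[, "COR"]
  nUndef <- sum(is.na(corv))
  out["COR"] <- if (nUndef == nrow(feats)) 0 else mean(corv, na.rm = TRUE)
  attr(out, "nWindows") <- nrow(feats)
  attr(out, "nCorUndefined") <- nUndef
  out
}

#' Add GLCM texture features to the sample container
#'
#' Computes the eight co-occurrence features for every band over every
#' sample's plot region, appending 48 feature rows (band-major order,
#' names from [textureFeatureNames()]) of class `"texture"`.
#'
#' @param se container from [extractSamples()].
#' @param scene the [MultispectralScene-class] the samples came from.
#' @param config a [glcmConfig()].
#' @return The augmented container.
#' @export
addTextureFeatures <- function(se, scene, config = glcmConfig()) {
  cd <- SummarizedExperiment::colData(se)
  skey <- paste(scene@plots$plot_id, scene@plots$season)
  nb <- nBands(scene)
  block <- vapply(seq_len(ncol(se)), function(s) {
    i <- match(paste(cd$plot_id[s], cd$season[s]), skey)
    if (is.na(i)) stop("no scene region for sample ", colnames(se)[s])
    unlist(lapply(seq_len(nb), function(b)
      regionTexture(scene, scene@plots$polygon[[i]], b, config)))
  }, numeric(8L * nb))
  rownames(block) <- textureFeatureNames(nb)
  colnames(block) <- colnames(se)
  addFeatureBlock(se, block, "texture")
}
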