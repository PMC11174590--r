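#' Vegetation index names, in canonical table order
#' @return Character vector of the ten supported index abbreviations.
#' @export
vegetationIndexNames <- function() {
  c("SAVI", "EVI", "MSR", "OSAVI", "RDVI", "MSAVI", "ARVI", "GNDVI",
    "MTCI", "CI")
}

#' Compute one vegetation index from a six-band reflectance vector
#'
#' Bands are ordered blue, green, red, red edge 1 (720 nm), red edge 2
#' (750 nm), NIR. Formulas:
#' \describe{
#'   \item{SAVI}{`1.5 (N - R) / (N + R + 0.5)`}
#'   \item{EVI}{`2.5 (N - R) / (N + 6 R - 7.5 B + 1)`}
#'   \item{MSR}{`(N/R - 1) / sqrt(N/R + 1)`}
#'   \item{OSAVI}{`1.16 (N - G) / (N + G + 0.16)` — the green-band form;
#'     `osaviCanonical = TRUE` substitutes the red band as in the index's
#'     original definition.}
#'   \item{RDVI}{`sqrt((N - R) / (N + R))`; negative radicand is an error.}
#'   \item{MSAVI}{`0.5 (2N + 1 - sqrt((2N + 1)^2 - 8 (N - R)))` (standard
#'     sign convention); `msaviAsPrinted = TRUE` gives the variant
#'     `0.5 ((2N - 1) + sqrt((2N + 1)^2 - 8 (N - R)^2))` sometimes seen
#'     in transcriptions.}
#'   \item{ARVI}{`(N - 2R + B) / (N + 2R - B)`}
#'   \item{GNDVI}{`(N - G) / (N + G)`}
#'   \item{MTCI}{`(N - RE) / (RE - R)`}
#'   \item{CI}{`N / RE - 1`}
#' }
#' where `RE` is the red-edge band selected by `redEdgeBand`.
#'
#' @param name index abbreviation, see [vegetationIndexNames()].
#' @param r numeric reflectance vector of length >= 6 (band order 1..6),
#'   values in `[0, 1]`.
#' @param redEdgeBand which band serves as `R_RE` in MTCI/CI (4 or 5).
#' @param osaviCanonical,msaviAsPrinted formula variants, see above.
#' @return Scalar index value; zero denominators raise an error rather
#'   than returning NaN.
#' @examples
#' r <- c(0.05, 0.08, 0.1, 0.25, 0.35, 0.5)
#' computeVI("SAVI", r)   # 1.5 * 0.4 / 1.1
#' computeVI("CI", r)     # 0.5 / 0.25 - 1 = 1
#' @export
computeVI <- function(name, r, redEdgeBand = 4L, osaviCanonical = FALSE,
                      msaviAsPrinted = FALSE) {
  if (length(r) < 6 || anyNA(r) || any(!is.finite(r)))
    stop("need six finite reflectance values")
  if (any(r < 0 | r > 1)) stop("reflectance must lie in [0, 1]")
  B <- r[1]; G <- r[2]; R <- r[3]; N <- r[6]; RE <- r[redEdgeBand]
  div <- function(num, den, what) {
    if (abs(den) < .Machine$double.eps * 4)
      stop("zero denominator in ", what)
    num / den
  }
  switch(match.arg(name, vegetationIndexNames()),
    SAVI = div((1 + 0.5) * (N - R), N + R + 0.5, "SAVI"),
    EVI = div(2.5 * (N - R), N + 6 * R - 7.5 * B + 1, "EVI"),
    MSR = {
      if (R <= 0) stop("zero denominator in MSR")
      (N / R - 1) / sqrt(N / R + 1)
    },
    OSAVI = if (osaviCanonical)
      div((1 + 0.16) * (N - R), N + R + 0.16, "OSAVI")
    else div((1 + 0.16) * (N - G), N + G + 0.16, "OSAVI"),
    RDVI = {
      q <- div(N - R, N + R, "RDVI")
      if (q < 0) stop("RDVI radicand negative (NIR < red)")
      sqrt(q)
    },
    MSAVI = if (msaviAsPrinted)
      0.5 * ((2 * N - 1) + sqrt((2 * N + 1)^2 - 8 * (N - R)^2))
    else 0.5 * (2 * N + 1 - sqrt((2 * N + 1)^2 - 8 * (N - R))),
    ARVI = div(N - 2 * R + B, N + 2 * R - B, "ARVI"),
    GNDVI = div(N - G, N + G, "GNDVI"),
    MTCI = div(N - RE, RE - R, "MTCI"),
    CI = div(N, RE, "CI") - 1)
}

#' Compute all ten vegetation indices for a reflectance table
#'
#' @param refl samples-by-bands matrix (columns `b1..b6`), or the
#'   container from [extractSamples()].
#' @inheritParams computeVI
#' @return Matrix, samples in rows, the ten indices in table order in
#'   columns.
#' @export
computeAllVIs <- function(refl, redEdgeBand = 4L, osaviCanonical = FALSE,
                          msaviAsPrinted = FALSE) {
  if (methods::is(refl, "SummarizedExperiment"))
    refl <- featureMatrix(refl, paste0("b", 1:6))
  stopifnot(ncol(refl) >= 6)
  out <- t(apply(refl, 1, function(rv)
    vapply(vegetationIndexNames(), computeVI, 0, r = as.numeric(rv),
           redEdgeBand = redEdgeBand, osaviCanonical = osaviCanonical,
           msaviAsPrinted = msaviAsPrinted)))
  colnames(out) <- vegetationIndexNames()
  out
}

#' Add vegetation-index features to the sample container
#'
#' @param se container from [extractSamples()].
#' @inheritParams computeVI
#' @return The container with ten new feature rows of class `"vi"`.
#' @export
addVegetationIndices <- function(se, redEdgeBand = 4L,
                                 osaviCanonical = FALSE,
                                 msaviAsPrinted = FALSE) {
  vi <- computeAllVIs(se, redEdgeBand = redEdgeBand,
                      osaviCanonical = osaviCanonical,
                      msaviAsPrinted = msaviAsPrinted)
  addFeatureBlock(se, t(vi), "vi")
}
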