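#' Pearson correlation with a two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()]: the p-value is the two-sided
#' t-test `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`, both with
#'   nonzero variance.
#' @return Named numeric vector `c(r, p)`.
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  c(r = unname(ct$estimate), p = ct$p.value)
}

#' Screen features by correlation with moisture
#'
#' Correlates every feature column with leaf moisture and flags
#' significance at `p < alpha`. Constant (zero-variance) features are
#' recorded with missing correlation and marked non-significant rather than raising
#' an error, so degenerate synthetic scenes screen cleanly. No
#' multiple-testing correction is applied by default, matching common
#' practice in crop-sensing correlation screens; `adjust = "BH"` applies
#' Benjamini-Hochberg to the p-values before thresholding.
#'
#' @param features samples-by-features matrix with column names, or the
#'   container from [extractSamples()] (all rows of class `vi`,
#'   `texture` and `texture_index` are screened).
#' @param moisture per-sample moisture; default `moisturePct(features)`
#'   when a container is given.
#' @param alpha significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return `data.frame(feature, class, r, p, significant)`, one row per
#'   feature, in input order.
#' @export
screenFeatures <- function(features, moisture = NULL, alpha = 0.05,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  cls <- NULL
  if (methods::is(features, "SummarizedExperiment")) {
    se <- features
    keep <- featureClasses(se) %in% c("vi", "texture", "texture_index")
    cls <- featureClasses(se)[keep]
    if (is.null(moisture)) moisture <- moisturePct(se)
    features <- featureMatrix(se)[, keep, drop = FALSE]
  }
  stopifnot(is.matrix(features), !is.null(colnames(features)))
  n <- nrow(features)
  if (length(moisture) != n) stop("moisture length mismatch")
  if (sd(moisture) == 0) stop("moisture has zero variance")
  if (is.null(cls)) cls <- rep(NA_character_, ncol(features))
  r <- rep(NA_real_, ncol(features))
  ok <- apply(features, 2, function(v) sd(v) > 0 && all(is.finite(v)))
  r[ok] <- as.numeric(cor(features[, ok, drop = FALSE], moisture))
  p <- ifelse(is.na(r), NA_real_, pearsonP(r, n))
  padj <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  data.frame(feature = colnames(features), class = cls, r = r, p = p,
             significant = !is.na(padj) & padj < alpha,
             stringsAsFactors = FALSE)
}

#' Assemble the four model-input combinations
#'
#' From the screening table, builds the four standard input sets:
#' `combination1` = significant vegetation indices, `combination2` =
#' significant texture features, `combination3` = significant
#' best-pair texture indices (the six family columns), and
#' `combination4` = their union in that order. Each combination keeps
#' its source family's canonical ordering. An empty combination is kept
#' (with a warning); the model stage refuses to fit it.
#'
#' @param screen the `data.frame` from [screenFeatures()] with a `class`
#'   column.
#' @return Named list of four character vectors of feature names.
#' @export
buildCombinations <- function(screen) {
  stopifnot(all(c("feature", "class", "significant") %in% names(screen)))
  pick <- function(cl) screen$feature[screen$class == cl &
                                      screen$significant]
  combos <- list(combination1 = pick("vi"),
                 combination2 = pick("texture"),
                 combination3 = pick("texture_index"))
  combos$combination4 <- unique(unlist(combos, use.names = FALSE))
  for (nm in names(combos))
    if (length(combos[[nm]]) == 0)
      warning(nm, " has no significant features")
  combos
}
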