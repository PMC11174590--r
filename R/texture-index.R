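#' The six texture-index families
#' @return Character vector `RTI DTI ATI NDTI RDTI RATI`.
#' @export
textureIndexFamilies <- function() {
  c("RTI", "DTI", "ATI", "NDTI", "RDTI", "RATI")
}

#' Pairwise texture index of two feature vectors
#'
#' Elementwise combination of two texture features `Ti`, `Tj`:
#' ratio `RTI = Ti / Tj`, difference `DTI = Ti - Tj`, sum
#' `ATI = Ti + Tj`, normalized difference
#' `NDTI = (Ti - Tj) / (Ti + Tj)`, reciprocal difference
#' `RDTI = 1/Ti - 1/Tj`, reciprocal sum `RATI = 1/Ti + 1/Tj`.
#'
#' @param family one of [textureIndexFamilies()].
#' @param Ti,Tj numeric vectors of equal length.
#' @return Numeric vector of index values.
#' @examples
#' textureIndex("RDTI", 2, 4)  # 0.25
#' @export
textureIndex <- function(family, Ti, Tj) {
  family <- match.arg(family, textureIndexFamilies())
  stopifnot(length(Ti) == length(Tj))
  bad <- function(den, who) {
    z <- which(den == 0)
    if (length(z))
      stop(family, ": zero ", who, " at sample(s) ",
           paste(head(z, 5), collapse = ", "))
  }
  switch(family,
    RTI = { bad(Tj, "denominator Tj"); Ti / Tj },
    DTI = Ti - Tj,
    ATI = Ti + Tj,
    NDTI = { bad(Ti + Tj, "denominator Ti+Tj"); (Ti - Tj) / (Ti + Tj) },
    RDTI = { bad(Ti, "Ti"); bad(Tj, "Tj"); 1 / Ti - 1 / Tj },
    RATI = { bad(Ti, "Ti"); bad(Tj, "Tj"); 1 / Ti + 1 / Tj })
}

# two-sided p-value of a Pearson r at n samples (t on n-2 df)
pearsonP <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(t), n - 2)
}

#' Exhaustive pair search for one texture-index family
#'
#' Computes the family's index for every ordered feature pair
#' `(i, j), i != j`, correlates each index vector with moisture
#' (Pearson), and returns the pair maximizing `|r|` together with the
#' full r-matrix. Pairs with a singular index (zero denominator on any
#' sample) or zero index variance are skipped and counted, not errors;
#' the diagonal is excluded (degenerate: NDTI identically 0, RTI
#' identically 1). Ties on `|r|` break to the first pair in band-major
#' feature order (row-wise `(1,2), (1,3), ...`), so results are
#' deterministic.
#'
#' The optional permutation test guards against selection bias of the
#' max-|r| statistic: moisture is permuted `permutations` times, the
#' family-wise max `|r|` recomputed each time, and
#' `p_perm = (1 + #(max_perm >= max_obs)) / (permutations + 1)`.
#'
#' @param family one of [textureIndexFamilies()].
#' @param textures samples-by-features numeric matrix with column names.
#' @param moisture numeric vector, one value per sample.
#' @param permutations 0 (default, off) or the number of permutations.
#' @param permSeed seed for the permutation draw.
#' @return A list with `best` (one-row `data.frame`: family, feature_i,
#'   feature_j, r, p, n, and p_perm when requested), `matrix` (the
#'   features x features r-matrix, `NA` where skipped), and `nSkipped`.
#' @export
searchFamily <- function(family, textures, moisture, permutations = 0L,
                         permSeed = 1L) {
  family <- match.arg(family, textureIndexFamilies())
  stopifnot(is.matrix(textures), !is.null(colnames(textures)))
  n <- nrow(textures); p <- ncol(textures)
  if (n < 3) stop("need at least 3 samples")
  if (anyNA(textures) || anyNA(moisture)) stop("missing values in input")
  if (length(moisture) != n) stop("moisture length mismatch")

  pairs <- which(matrix(TRUE, p, p) & !diag(p), arr.ind = TRUE)
  # row-wise enumeration: (1,2) (1,3) ... (2,1) ...
  ord <- order(pairs[, 1], pairs[, 2])
  ii <- pairs[ord, 1]; jj <- pairs[ord, 2]

  A <- textures[, ii, drop = FALSE]
  B <- textures[, jj, drop = FALSE]
  M <- switch(family,
    RTI = A / B, DTI = A - B, ATI = A + B,
    NDTI = (A - B) / (A + B),
    RDTI = 1 / A - 1 / B, RATI = 1 / A + 1 / B)
  ok <- apply(is.finite(M), 2, all)
  sds <- rep(0, length(ii)); sds[ok] <- apply(M[, ok, drop = FALSE], 2, sd)
  ok <- ok & sds > 0
  if (!any(ok)) stop(family, ": every feature pair is singular")
  if (sd(moisture) == 0) stop("moisture has zero variance")

  rAll <- rep(NA_real_, length(ii))
  rAll[ok] <- as.numeric(cor(M[, ok, drop = FALSE], moisture))
  best <- which.max(abs(rAll))  # NA-safe; first index wins ties
  rmat <- matrix(NA_real_, p, p,
                 dimnames = list(colnames(textures), colnames(textures)))
  rmat[cbind(ii, jj)] <- rAll

  out <- data.frame(family = family,
                    feature_i = colnames(textures)[ii[best]],
                    feature_j = colnames(textures)[jj[best]],
                    r = rAll[best], p = pearsonP(rAll[best], n), n = n,
                    stringsAsFactors = FALSE)
  if (permutations > 0) {
    Ms <- scale(M[, ok, drop = FALSE])
    set.seed(permSeed)
    maxObs <- abs(rAll[best])
    exceed <- 0L
    for (b in seq_len(permutations)) {
      ys <- as.numeric(scale(moisture[sample.int(n)]))
      rp <- abs(crossprod(Ms, ys) / (n - 1))
      if (max(rp) >= maxObs) exceed <- exceed + 1L
    }
    out$p_perm <- (1 + exceed) / (permutations + 1)
  }
  list(best = out, matrix = rmat, nSkipped = sum(!ok) )
}

#' Search all six texture-index families
#'
#' @inheritParams searchFamily
#' @param se optionally, the sample container from [extractSamples()];
#'   its `"texture"`-class rows and moisture are used when `textures`
#'   / `moisture` are not given.
#' @param textures samples-by-features matrix (default: texture rows of
#'   `se`).
#' @param moisture per-sample moisture (default: `moisturePct(se)`).
#' @param samples optional index vector restricting the search to a
#'   subset of samples (e.g. the training set, to keep validation
#'   moisture out of feature construction).
#' @return `list(hits = data.frame` (one row per family), `matrices =`
#'   named list of r-matrices, `nSkipped =` named counts`)`.
#' @export
searchAllFamilies <- function(se = NULL, textures = NULL, moisture = NULL,
                              samples = NULL, permutations = 0L,
                              permSeed = 1L) {
  if (is.null(textures)) {
    stopifnot(!is.null(se))
    textures <- featureMatrix(se)[, featureClasses(se) == "texture",
                                  drop = FALSE]
  }
  if (is.null(moisture)) moisture <- moisturePct(se)
  if (!is.null(samples)) {
    textures <- textures[samples, , drop = FALSE]
    moisture <- moisture[samples]
  }
  res <- lapply(textureIndexFamilies(), searchFamily, textures = textures,
                moisture = moisture, permutations = permutations,
                permSeed = permSeed)
  hits <- do.call(rbind, lapply(res, `[[`, "best"))
  rownames(hits) <- NULL
  matrices <- lapply(res, `[[`, "matrix")
  names(matrices) <- textureIndexFamilies()
  nSkipped <- vapply(res, `[[`, 0L, "nSkipped")
  names(nSkipped) <- textureIndexFamilies()
  list(hits = hits, matrices = matrices, nSkipped = nSkipped)
}

#' Materialize the best texture-index columns in the container
#'
#' For each family's best feature pair (from [searchAllFamilies()]),
#' computes the index over all samples and appends it as a feature row
#' named after the family, class `"texture_index"`.
#'
#' @param se container with texture rows.
#' @param hits the `hits` data.frame from [searchAllFamilies()].
#' @return The augmented container.
#' @export
addTextureIndices <- function(se, hits) {
  X <- featureMatrix(se)
  block <- t(vapply(seq_len(nrow(hits)), function(k)
    textureIndex(hits$family[k], X[, hits$feature_i[k]],
                 X[, hits$feature_j[k]]),
    numeric(ncol(se))))
  rownames(block) <- hits$family
  colnames(block) <- colnames(se)
  addFeatureBlock(se, block, "texture_index")
}
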