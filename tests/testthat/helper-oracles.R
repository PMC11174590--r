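# Independent reference implementations used to cross-check the package.
# These deliberately share no code with the package: plain double loops.

# Pair-enumeration co-occurrence matrix over a full integer matrix.
naiveGlcm <- function(x, dr, dc, symmetric = TRUE, levels = max(x) + 1L) {
  P <- matrix(0, levels, levels)
  nr <- nrow(x); nc <- ncol(x)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        i <- x[r, c] + 1L; j <- x[r2, c2] + 1L
        P[i, j] <- P[i, j] + 1
        if (symmetric) P[j, i] <- P[j, i] + 1
      }
    }
  }
  P / sum(P)
}

# The eight co-occurrence statistics by explicit double loop over cells.
naiveGlcmFeatures <- function(P) {
  L <- nrow(P)
  mi <- 0; mj <- 0
  for (i in 1:L) for (j in 1:L) {
    mi <- mi + (i - 1) * P[i, j]
    mj <- mj + (j - 1) * P[i, j]
  }
  vi <- 0; vj <- 0; cv <- 0
  hom <- 0; con <- 0; dis <- 0; ent <- 0; sem <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    vi <- vi + (i - 1 - mi)^2 * p
    vj <- vj + (j - 1 - mj)^2 * p
    cv <- cv + (i - 1 - mi) * (j - 1 - mj) * p
    d <- (i - 1) - (j - 1)
    hom <- hom + p / (1 + d^2)
    con <- con + d^2 * p
    dis <- dis + abs(d) * p
    if (p > 0) ent <- ent - p * log(p)
    sem <- sem + p^2
  }
  c(MEA = mi, VAR = vi, HOM = hom, CON = con, DIS = dis, ENT = ent,
    SEM = sem,
    COR = if (vi > 0 && vj > 0) cv / sqrt(vi * vj) else NA_real_)
}

# Texture-index formulas written out independently.
oracleIndexFun <- function(family) {
  switch(family,
    RTI = function(a, b) a / b,
    DTI = function(a, b) a - b,
    ATI = function(a, b) a + b,
    NDTI = function(a, b) (a - b) / (a + b),
    RDTI = function(a, b) 1 / a - 1 / b,
    RATI = function(a, b) 1 / a + 1 / b)
}

# Brute-force exhaustive pair search: ordered pairs, row-wise
# enumeration, strictly-greater |r| replacement (first pair wins ties).
bruteSearch <- function(family, X, y) {
  f <- oracleIndexFun(family)
  p <- ncol(X)
  best <- NULL
  rmat <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      v <- f(X[, i], X[, j])
      if (any(!is.finite(v)) || sd(v) == 0) next
      r <- cor(v, y)
      rmat[i, j] <- r
      if (is.null(best) || abs(r) > abs(best$r))
        best <- list(i = i, j = j, r = r)
    }
  }
  list(best = best, matrix = rmat)
}

# A tiny two-plot scene built by hand for the I/O tests.
tinyScene <- function(values, nband = 1) {
  nr <- nrow(values); nc <- ncol(values)
  bands <- array(rep(values, nband), dim = c(nr, nc, nband))
  plots <- data.frame(plot_id = "P01", season = 1,
                      stringsAsFactors = FALSE)
  plots$polygon <- list(cbind(x = c(0, nc, nc, 0), y = c(0, 0, nr, nr)))
  MultispectralScene(bands, seq_len(nband) * 100, plots)
}
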