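test_that("texture-index formulas match hand arithmetic and identities", {
  expect_equal(textureIndex("RDTI", 2, 4), 0.25)
  expect_equal(textureIndex("RTI", 4, 2), 2)
  expect_equal(textureIndex("RTI", 2, 4) * textureIndex("RTI", 4, 2), 1)
  T <- c(1.5, 2, 0.7)
  expect_equal(textureIndex("NDTI", T, T), rep(0, 3))
  expect_equal(textureIndex("ATI", T, 2 * T), 3 * T)
  expect_equal(textureIndex("DTI", T, 2 * T), -T)

  set.seed(20)
  a <- runif(50, 0.2, 3); b <- runif(50, 0.2, 3)
  # reciprocal difference is the reversed difference over the product
  expect_equal(textureIndex("RDTI", a, b),
               textureIndex("DTI", b, a) / (a * b), tolerance = 1e-12)
  expect_equal(textureIndex("RATI", a, b),
               textureIndex("ATI", b, a) / (a * b), tolerance = 1e-12)
  expect_error(textureIndex("RTI", a, c(b[-50], 0)), "zero.*50")
  expect_error(textureIndex("NDTI", 1, -1), "denominator")
})

test_that("a feature that moisture tracks linearly wins the DTI search", {
  set.seed(21)
  X <- cbind(f1 = runif(30), f2 = runif(30), f3 = runif(30),
             const = rep(0.5, 30))
  y <- 2 * X[, "f2"] + 1
  res <- searchFamily("DTI", X, y)
  expect_setequal(c(res$best$feature_i, res$best$feature_j),
                  c("f2", "const"))
  expect_equal(abs(res$best$r), 1, tolerance = 1e-12)
  expect_lt(res$best$p, 1e-12)
})

test_that("the vectorized search equals the brute-force oracle on a toy table", {
  set.seed(22)
  X <- matrix(runif(20 * 6, 0.3, 2), 20,
              dimnames = list(NULL, paste0("t", 1:6)))
  y <- rnorm(20, 70, 2)
  for (fam in textureIndexFamilies()) {
    got <- searchFamily(fam, X, y)
    want <- bruteSearch(fam, X, y)
    expect_equal(got$matrix, want$matrix, tolerance = 1e-12)
    expect_equal(got$best$feature_i, colnames(X)[want$best$i])
    expect_equal(got$best$feature_j, colnames(X)[want$best$j])
    expect_equal(got$best$r, want$best$r, tolerance = 1e-12)
  }
})

test_that("duplicated features tie and the first band-major pair wins", {
  set.seed(23)
  X <- matrix(runif(25 * 5, 0.5, 2), 25,
              dimnames = list(NULL, paste0("t", 1:5)))
  X[, 5] <- X[, 3]  # exact duplicate: (i,3) and (i,5) tie for every i
  y <- 3 * (X[, 1] - X[, 3]) + rnorm(25, 0, 0.1)
  got <- searchFamily("DTI", X, y)
  want <- bruteSearch("DTI", X, y)
  expect_equal(c(got$best$feature_i, got$best$feature_j),
               colnames(X)[c(want$best$i, want$best$j)])
  expect_equal(got$best$feature_j, "t3")  # not the later duplicate t5
})

test_that("search matrices carry the family's exchange symmetry", {
  set.seed(24)
  X <- matrix(runif(40 * 8, 0.3, 2), 40,
              dimnames = list(NULL, paste0("t", 1:8)))
  y <- rnorm(40, 70, 2)
  r <- lapply(textureIndexFamilies(), function(f)
    searchFamily(f, X, y)$matrix)
  names(r) <- textureIndexFamilies()
  offd <- function(M) M[upper.tri(M) | lower.tri(M)]
  expect_equal(offd(r$NDTI), -offd(t(r$NDTI)), tolerance = 1e-12)
  expect_equal(offd(r$DTI), -offd(t(r$DTI)), tolerance = 1e-12)
  expect_equal(offd(r$RDTI), -offd(t(r$RDTI)), tolerance = 1e-12)
  expect_equal(offd(r$ATI), offd(t(r$ATI)), tolerance = 1e-12)
  expect_equal(offd(r$RATI), offd(t(r$RATI)), tolerance = 1e-12)
  # the reported best dominates its own matrix
  for (f in textureIndexFamilies()) {
    res <- searchFamily(f, X, y)
    expect_gte(abs(res$best$r) + 1e-12, max(abs(res$matrix), na.rm = TRUE))
  }
})

test_that("singular pairs are skipped and counted, not fatal", {
  set.seed(25)
  X <- matrix(runif(20 * 4, 0.5, 2), 20,
              dimnames = list(NULL, paste0("t", 1:4)))
  X[3, 2] <- 0  # RTI/RDTI/RATI with t2 in a denominator are singular
  y <- rnorm(20, 70, 2)
  res <- searchFamily("RTI", X, y)
  expect_gt(res$nSkipped, 0)
  expect_true(all(is.na(res$matrix[, "t2"])))
  expect_false(res$best$feature_j == "t2")
})

test_that("searchAllFamilies returns one ranked hit per family", {
  set.seed(26)
  X <- matrix(runif(30 * 6, 0.5, 2), 30,
              dimnames = list(NULL, paste0("t", 1:6)))
  y <- rnorm(30, 70, 2)
  res <- searchAllFamilies(textures = X, moisture = y)
  expect_equal(res$hits$family, textureIndexFamilies())
  expect_equal(nrow(res$hits), 6)
  expect_true(all(abs(res$hits$r) <= 1))
  expect_true(all(res$hits$p >= 0 & res$hits$p <= 1))
  expect_named(res$matrices, textureIndexFamilies())
  # restricting to a subset reproduces a direct subset search
  sub <- searchAllFamilies(textures = X, moisture = y, samples = 1:20)
  direct <- searchFamily("RTI", X[1:20, ], y[1:20])
  expect_equal(sub$hits$r[1], direct$best$r, tolerance = 1e-12)
})

test_that("the permutation adjustment separates planted from null signal", {
  sim <- simulatePlantedTextures(nSamples = 54, seed = 30)
  planted <- searchFamily("RDTI", sim$textures, sim$moisture,
                          permutations = 199, permSeed = 2)
  expect_lte(planted$best$p_perm, 0.05)
  set.seed(31)
  null <- searchFamily("RDTI", sim$textures, rnorm(54, 70, 2),
                       permutations = 199, permSeed = 2)
  expect_gt(null$best$p_perm, 0.05)
})

test_that("planted-pair tables are recovered by the matching family search", {
  sim <- simulatePlantedTextures(seed = 77)
  res <- searchFamily("RDTI", sim$textures, sim$moisture)
  expect_setequal(c(res$best$feature_i, res$best$feature_j),
                  c("Variance1", "Correlation5"))
  expect_gt(abs(res$best$r), 0.7)
})
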