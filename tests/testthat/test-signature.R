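test_that("the signature size follows the half-training-set rule", {
  set.seed(20)
  for (nTrain in c(6L, 10L, 23L, 36L, 60L)) {
    nPos <- nTrain %/% 2L
    v <- matrix(rnorm(100 * nTrain, 22), 100, nTrain,
                dimnames = list(sprintf("f%03d", 1:100),
                                sprintf("s%02d", seq_len(nTrain))))
    sig <- deriveSignature(OmicsMatrix(v),
                           sprintf("s%02d", seq_len(nPos)),
                           sprintf("s%02d", (nPos + 1):nTrain))
    expect_equal(sig@k, nTrain %/% 2L)
    expect_equal(length(featureIds(sig)), nTrain %/% 2L)
  }
  # explicit k overrides; k beyond the tested features errors
  v <- matrix(rnorm(10 * 8, 22), 10, 8,
              dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:8)))
  expect_equal(deriveSignature(OmicsMatrix(v), sprintf("s%d", 1:4),
                               sprintf("s%d", 5:8), k = 3)@k, 3L)
  expect_error(deriveSignature(OmicsMatrix(v), sprintf("s%d", 1:4),
                               sprintf("s%d", 5:8), k = 11), "exceeds")
})

test_that("feature selection orders by p with |log2fc| and id tie-breaks", {
  # two features with identical p but different fold change magnitude
  a <- c(0, 0, 1, 1); sA <- sprintf("s%d", 1:4)
  v <- rbind(fBig = c(10, 10, 14, 14), fSmall = c(10, 10, 12, 12),
             fNoise = c(10, 10.1, 10, 10.1))
  colnames(v) <- sA
  sig <- deriveSignature(OmicsMatrix(v), sA[3:4], sA[1:2], k = 2, minObs = 2)
  expect_identical(featureIds(sig), c("fBig", "fSmall"))
  # selection recovers planted features in a strong-effect simulation
  hits <- vapply(1:10, function(s) {
    co <- simulateCohort(smallConfig(
      nPerGroup = c(MLLGA = 8L, `No-MLL` = 8L), nSignatureFeatures = 8L,
      effectSize = 2, noiseSd = 0.5, nKinases = 0L,
      plantedKinaseShifts = NULL, seed = 300L + s))
    meta <- co@metadata
    sig <- deriveSignature(co@omics$phospho,
                           meta$sample_id[meta$group == "MLLGA"],
                           meta$sample_id[meta$group != "MLLGA"])
    setequal(featureIds(sig), co@truth$plantedFeatures)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("PCA reproduces analytic eigenstructure and projects consistently", {
  # rank-1 data: one component carries all variance
  base <- rnorm(6)
  v <- outer(c(1, 2, 3), base) + 5
  dimnames(v) <- list(c("f1", "f2", "f3"), sprintf("s%d", 1:6))
  pca <- fitSignaturePca(OmicsMatrix(v), c("f1", "f2", "f3"))
  expect_equal(pca@explainedVariance[1], 1)
  # projecting the training samples returns the stored scores
  proj <- projectSamples(pca, OmicsMatrix(v))
  expect_equal(unname(proj), unname(pca@scores), tolerance = 1e-10)
  # 2-feature toy: loadings match the covariance eigenvectors
  set.seed(21)
  w <- matrix(rnorm(2 * 50), 2, 50,
              dimnames = list(c("f1", "f2"), sprintf("s%02d", 1:50)))
  w[2, ] <- 0.6 * w[1, ] + 0.3 * w[2, ]
  pc2 <- fitSignaturePca(OmicsMatrix(w), c("f1", "f2"))
  ev <- eigen(cov(t(w)))$vectors
  for (j in 1:2) {
    dot <- abs(sum(pc2@loadings[, j] * ev[, j]))
    expect_equal(dot, 1, tolerance = 1e-8)
  }
  # absent features error, unless dropping is requested
  expect_error(projectSamples(pca, OmicsMatrix(v[1:2, , drop = FALSE])), "f3")
  p2 <- projectSamples(pca, OmicsMatrix(v[1:2, , drop = FALSE]),
                       dropMissingFeatures = TRUE)
  expect_equal(dim(p2), dim(pca@scores))
})

test_that("region definition isolates the main cluster and handles degeneracy", {
  set.seed(22)
  near <- matrix(rnorm(16, 0, 0.3), 8, 2)
  far <- matrix(rnorm(4, 10, 0.3), 2, 2)
  pts <- rbind(near, far)
  rownames(pts) <- sprintf("s%02d", 1:10)
  out <- defineRegion(pts)
  expect_identical(unname(out$clusters), c(rep(1L, 8), rep(2L, 2)))
  inside <- pointInPolygon(pts, regionVertices(out$region))
  expect_true(all(inside[1:8]))
  expect_false(any(inside[9:10]))
  # all points identical: a margin square around the point
  same <- matrix(1, 4, 2, dimnames = list(sprintf("s%d", 1:4), NULL))
  reg <- defineRegion(same, margin = 0.5)$region
  expect_equal(nrow(regionVertices(reg)), 4L)
  expect_true(pointInPolygon(matrix(c(1.3, 1.3), 1), regionVertices(reg)))
  expect_false(pointInPolygon(matrix(c(1.6, 1), 1), regionVertices(reg)))
  # collinear points degrade to a thickened segment
  col <- cbind(1:5, 2 * (1:5))
  rownames(col) <- sprintf("s%d", 1:5)
  regc <- defineRegion(col, margin = 0.2)$region
  expect_equal(nrow(regionVertices(regc)), 4L)
  expect_error(defineRegion(pts[1:2, ]), ">= 3")
})

test_that("the two-cluster cut recovers well-separated blobs exactly", {
  set.seed(23)
  for (i in 1:10) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    blob1 <- matrix(rnorm((n1) * 2, 0, 1), ncol = 2)
    blob2 <- matrix(rnorm((n2) * 2, 20, 1), ncol = 2)
    pts <- rbind(blob1, blob2)
    rownames(pts) <- sprintf("s%02d", seq_len(n1 + n2))
    cl <- defineRegion(pts)$clusters
    km <- kmeans(pts, centers = rbind(c(0, 0), c(20, 20)))$cluster
    expect_equal(length(unique(paste(cl, km))), 2L)  # identical partition
  }
})

test_that("point-in-polygon agrees with an independent implementation", {
  skip_if_not_installed("mgcv")
  set.seed(24)
  for (i in 1:10) {
    raw <- matrix(rnorm(20), 10, 2)
    hull <- raw[grDevices::chull(raw), ]
    pts <- matrix(runif(2000, -3, 3), ncol = 2)
    mine <- pointInPolygon(pts, hull)
    oracle <- mgcv::in.out(rbind(hull, hull[1, ]), pts)
    expect_identical(mine, oracle)
  }
  # the boundary itself counts as inside
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_true(all(pointInPolygon(rbind(c(0, 0.5), c(0.5, 0), c(1, 1)), sq)))
})

test_that("the forest classifier is seeded, accurate and self-consistent", {
  co <- simulateCohort(smallConfig(seed = 41L))
  meta <- co@metadata
  ph <- normalizeIntensities(co@omics$phospho)
  pos <- meta$sample_id[meta$group == "MLLGA"]
  neg <- meta$sample_id[!meta$group %in% c("MLLGA", "Normal")]
  sig <- deriveSignature(ph, pos, neg)
  labels <- setNames(ifelse(c(pos, neg) %in% pos, "MLLGA", "No-MLLGA"),
                     c(pos, neg))
  st <- trainClassifier(ph, sig, labels, seed = 9L, nTrees = 300L)
  expect_gte(st$oobAccuracy, 0.9)
  out <- classifySamples(st, ph)
  expect_true(all(out$probability_mllga >= 0 & out$probability_mllga <= 1))
  # label follows the majority probability with ties to MLLGA
  expect_identical(out$label,
                   ifelse(out$probability_mllga >= 0.5, "MLLGA", "No-MLLGA"))
  # a duplicated sample gets the original's label
  v <- intensities(ph)
  dup <- cbind(v, dup1 = v[, pos[1]])
  out2 <- classifySamples(st, dup, samples = c(pos[1], "dup1"))
  expect_identical(out2$label[1], out2$label[2])
  # same seed, same forest predictions
  st2 <- trainClassifier(ph, sig, labels, seed = 9L, nTrees = 300L)
  expect_identical(classifySamples(st2, ph)$probability_mllga,
                   out$probability_mllga)
  expect_error(trainClassifier(ph, sig, setNames(rep("MLLGA", length(labels)),
                                                 names(labels)), seed = 1L),
               "both classes")
})

test_that("feature importances are normalized, ranked, and flag the signal", {
  set.seed(26)
  n <- 40
  v <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:n)))
  labels <- setNames(rep(c("MLLGA", "No-MLLGA"), each = n / 2), colnames(v))
  v["f01", labels == "MLLGA"] <- v["f01", labels == "MLLGA"] + 4
  st <- trainClassifier(OmicsMatrix(v), rownames(v), labels, seed = 2L,
                        nTrees = 300L)
  imp <- featureImportance(st)
  expect_equal(sum(imp$importance), 1)
  expect_identical(imp$feature_id[1], "f01")
  expect_true(all(diff(imp$importance) <= 0))
  expect_error(featureImportance(list()), "untrained")
})

test_that("stratification uses training samples only (no leakage)", {
  co <- simulateCohort(smallConfig(seed = 51L))
  ph <- normalizeIntensities(co@omics$phospho)
  meta <- co@metadata
  m1 <- stratifyCohort(ph, meta, seed = 3L, nTrees = 200L)
  # perturb every non-training sample drastically
  v <- intensities(ph)
  nonTrain <- meta$sample_id[meta$split != "train"]
  v[, nonTrain] <- v[, nonTrain] + matrix(rnorm(length(v[, nonTrain]), 0, 5),
                                          nrow(v))
  ph2 <- OmicsMatrix(v, sampleData = meta)
  m2 <- stratifyCohort(ph2, meta, seed = 3L, nTrees = 200L)
  expect_identical(m1@signature, m2@signature)
  expect_identical(m1@pca, m2@pca)
  expect_identical(m1@region, m2@region)
  expect_identical(m1@importance, m2@importance)
  train <- meta$sample_id[meta$split == "train"]
  a1 <- assignments(m1); a2 <- assignments(m2)
  expect_identical(a1[a1$sample_id %in% train, ], a2[a2$sample_id %in% train, ])
  # removing validation samples does not change training-set assignments
  keep <- meta$split != "validation"
  m3 <- stratifyCohort(ph[, meta$sample_id[keep]], meta[keep, ], seed = 3L,
                       nTrees = 200L)
  a3 <- assignments(m3)
  expect_identical(a1[a1$sample_id %in% train, ], a3[a3$sample_id %in% train, ])
})

test_that("end-to-end stratification recovers the planted subgroup", {
  skip_if_not_installed("mclust")
  co <- simulateCohort(smallConfig(seed = 61L))
  ph <- normalizeIntensities(co@omics$phospho)
  m <- stratifyCohort(ph, co@metadata, seed = 4L, nTrees = 300L)
  a <- assignments(m)
  truth <- ifelse(co@truth$groups[a$sample_id] == "MLLGA", "MLLGA", "No-MLLGA")
  expect_gte(mclust::adjustedRandIndex(a$label, truth), 0.9)
  expect_gte(m@oobAccuracy, 0.9)
})
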