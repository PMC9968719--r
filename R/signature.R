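#' Derive a phosphoproteomics signature by t-test feature selection
#'
#' Compares the two contrast classes over the training samples only with a
#' per-feature Student's t-test (via [ttestTwoGroup()]), sorts tested features
#' by ascending p-value (ties: larger |log2fc|, then lexicographic feature id)
#' and keeps the top `k`. By default `k = floor(n_train / 2)`, the
#' overfitting-avoidance rule of selecting half as many features as training
#' samples.
#'
#' @param x an [OmicsMatrix-class].
#' @param positive,negative sample ids of the two contrast classes; their
#'   union is the training set.
#' @param k number of features to keep; `NULL` (default) applies the
#'   half-the-training-samples rule.
#' @param contrast character(2) naming the positive and negative class (for
#'   bookkeeping; default `c("positive", "negative")`).
#' @param minObs per-group observation floor passed to [ttestTwoGroup()].
#' @return A [Signature-class].
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 10, 20,
#'             dimnames = list(paste0("f", 1:10), paste0("s", 1:20)))
#' sig <- deriveSignature(OmicsMatrix(m), paste0("s", 1:10), paste0("s", 11:20))
#' sig@k  # floor(20 / 2) capped at the 10 available features
#' @export
deriveSignature <- function(x, positive, negative, k = NULL,
                            contrast = c("positive", "negative"),
                            minObs = 3L) {
  res <- ttestTwoGroup(x, positive, negative, minObs = minObs)
  res <- res[res$tested, , drop = FALSE]
  nTrain <- length(positive) + length(negative)
  if (is.null(k)) k <- min(nTrain %/% 2L, nrow(res))
  k <- as.integer(k)
  if (k > nrow(res))
    stop(sprintf("k = %d exceeds the %d tested features", k, nrow(res)))
  if (k < 1L) stop("k must be >= 1")
  ord <- order(res$p, -abs(res$log2fc), res$feature_id)
  sel <- res[ord[seq_len(k)], c("feature_id", "log2fc", "t_stat", "p")]
  rownames(sel) <- NULL
  new("Signature", featureIds = sel$feature_id, selectionStats = sel,
      k = k, trainSampleIds = c(positive, negative),
      contrast = contrast)
}

.imputeByMeans <- function(v, means) {
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- means[idx[, 1L]]
  v
}

#' Fit a PCA model on a signature submatrix
#'
#' Restricts the matrix to the signature features and the given (training)
#' samples, imputes any missing cell with the training-set feature mean,
#' centers by feature and computes principal components of the sample
#' covariance ([stats::prcomp], unscaled). New cohorts are projected with
#' [projectSamples()], which centers and imputes with the stored training
#' constants — no information flows back from projected samples.
#'
#' @param x an [OmicsMatrix-class].
#' @param signature a [Signature-class] (or character vector of feature ids).
#' @param samples sample ids to fit on; default all.
#' @return A [PcaModel-class].
#' @export
fitSignaturePca <- function(x, signature, samples = sampleIds(x)) {
  feats <- if (is(signature, "Signature")) signature@featureIds else signature
  missing <- setdiff(feats, featureIds(x))
  if (length(missing))
    stop("feature(s) absent from matrix: ", paste(missing, collapse = ", "))
  if (length(samples) < 2L) stop("PCA needs at least 2 samples")
  v <- intensities(x)[feats, samples, drop = FALSE]
  means <- rowMeans(v, na.rm = TRUE)
  if (anyNA(means)) stop("feature(s) with no observed training values: ",
                         paste(feats[is.na(means)], collapse = ", "))
  v <- .imputeByMeans(v, means)
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  new("PcaModel",
      loadings = pc$rotation,
      center = stats::setNames(pc$center, feats),
      featureMeans = stats::setNames(means, feats),
      explainedVariance = ev / sum(ev),
      scores = pc$x)
}

#' Project samples onto a fitted PCA model
#'
#' @param model a [PcaModel-class].
#' @param x an [OmicsMatrix-class] containing the model's features, or a
#'   numeric matrix (features x samples).
#' @param samples sample ids to project; default all columns of `x`.
#' @param dropMissingFeatures if `TRUE`, features absent from `x` are dropped
#'   from the model before projection (loadings renormalized per component);
#'   default `FALSE`, which errors listing the absent features.
#' @return numeric matrix of scores (samples x components).
#' @export
projectSamples <- function(model, x, samples = NULL,
                           dropMissingFeatures = FALSE) {
  v <- if (is(x, "OmicsMatrix")) intensities(x) else as.matrix(x)
  if (is.null(samples)) samples <- colnames(v)
  feats <- rownames(model@loadings)
  absent <- setdiff(feats, rownames(v))
  loadings <- model@loadings
  center <- model@center
  means <- model@featureMeans
  if (length(absent)) {
    if (!dropMissingFeatures)
      stop("feature(s) absent from new cohort: ",
           paste(absent, collapse = ", "))
    keep <- setdiff(feats, absent)
    scale <- sqrt(colSums(model@loadings^2) /
                  pmax(colSums(model@loadings[keep, , drop = FALSE]^2), 1e-12))
    loadings <- sweep(model@loadings[keep, , drop = FALSE], 2L, scale, "*")
    center <- center[keep]
    means <- means[keep]
    feats <- keep
  }
  sub <- v[feats, samples, drop = FALSE]
  sub <- .imputeByMeans(sub, means)
  t(sweep(sub, 1L, center, "-")) %*% loadings
}

.expandHull <- function(pts, margin) {
  # pts: k x 2 hull vertices in order; push each vertex away from the centroid
  ctr <- colMeans(pts)
  d <- sweep(pts, 2L, ctr, "-")
  len <- sqrt(rowSums(d^2))
  ok <- len > 1e-12
  d[ok, ] <- d[ok, , drop = FALSE] * (1 + margin / len[ok])
  sweep(d, 2L, ctr, "+")
}

#' Define the MLLGA region from positive-class training scores
#'
#' Hierarchically clusters the positive-class training samples in the
#' (PC1, PC2) plane (Euclidean distance, Ward linkage), cuts the tree into two
#' clusters, and defines the region as the convex hull of the larger cluster,
#' expanded outward from its centroid by `margin` (default 5 percent of the
#' PC1 range of the supplied scores). Collinear or coincident clusters
#' degenerate to a margin-thickened rectangle or square.
#'
#' @param scores numeric matrix with >= 3 rows and columns PC1, PC2 (extra
#'   columns ignored); typically the positive-class rows of
#'   `PcaModel@scores`.
#' @param margin absolute expansion; default `0.05 * diff(range(PC1))`.
#' @return list with `region` (a [Region-class]) and `clusters` (named integer
#'   vector of cluster membership; cluster 1 is the region-defining cluster).
#' @export
defineRegion <- function(scores, margin = NULL) {
  pts <- as.matrix(scores)[, 1:2, drop = FALSE]
  if (nrow(pts) < 3L) stop("region definition needs >= 3 positive-class samples")
  if (is.null(margin)) margin <- 0.05 * diff(range(pts[, 1L]))
  if (margin <= 0) margin <- 1e-6  # degenerate all-identical scores
  hc <- stats::hclust(stats::dist(pts), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2L)
  sizes <- table(cl)
  main <- if (sizes[1L] >= sizes[2L]) 1L else 2L  # ties favour cluster 1
  members <- cl == main
  clusters <- ifelse(members, 1L, 2L)
  names(clusters) <- rownames(pts)
  core <- pts[members, , drop = FALSE]
  vert <- .hullVertices(core, margin)
  list(region = new("Region", vertices = vert, margin = margin),
       clusters = clusters)
}

.hullVertices <- function(core, margin) {
  uniq <- unique(core)
  if (nrow(uniq) == 1L) {
    p <- uniq[1L, ]
    return(rbind(p + c(-margin, -margin), p + c(margin, -margin),
                 p + c(margin, margin), p + c(-margin, margin)))
  }
  h <- grDevices::chull(core)
  if (length(h) >= 3L) return(.expandHull(core[h, , drop = FALSE], margin))
  # collinear: thickened segment
  dirv <- uniq[which.max(rowSums(sweep(uniq, 2, uniq[1L, ])^2)), ] - uniq[1L, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  normal <- c(-dirv[2L], dirv[1L])
  proj <- as.vector(sweep(core, 2L, core[1L, ]) %*% dirv)
  lo <- core[1L, ] + (min(proj) - margin) * dirv
  hi <- core[1L, ] + (max(proj) + margin) * dirv
  rbind(lo + margin * normal, hi + margin * normal,
        hi - margin * normal, lo - margin * normal)
}

#' Point-in-polygon test with boundary counted as inside
#'
#' Crossing-number (even-odd ray casting) test against a simple polygon, with
#' an explicit on-segment check so that boundary points are classified inside.
#'
#' @param points numeric matrix (n x 2).
#' @param vertices polygon vertex matrix (k x 2), in order.
#' @param eps tolerance for the on-boundary check.
#' @return logical vector of length n.
#' @export
pointInPolygon <- function(points, vertices, eps = 1e-9) {
  pts <- matrix(as.numeric(points), ncol = 2L)
  vx <- vertices[, 1L]; vy <- vertices[, 2L]
  k <- length(vx)
  jj <- c(k, seq_len(k - 1L))
  vapply(seq_len(nrow(pts)), function(i) {
    x <- pts[i, 1L]; y <- pts[i, 2L]
    inside <- FALSE
    for (e in seq_len(k)) {
      x1 <- vx[jj[e]]; y1 <- vy[jj[e]]; x2 <- vx[e]; y2 <- vy[e]
      # on-segment check
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) <= eps * max(1, abs(x2 - x1) + abs(y2 - y1)) &&
          x >= min(x1, x2) - eps && x <= max(x1, x2) + eps &&
          y >= min(y1, y2) - eps && y <= max(y1, y2) + eps)
        return(TRUE)
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) inside <- !inside
      }
    }
    inside
  }, logical(1))
}

#' Assign samples to MLLGA / No-MLLGA by PCA region membership
#'
#' @param scores matrix of (PC1, PC2, ...) scores with sample row names.
#' @param region a [Region-class].
#' @return data.frame (`sample_id`, `label`, `probability_mllga`, `source`);
#'   probability is 1/0 and `source` is `"region"`.
#' @export
assignByRegion <- function(scores, region) {
  inside <- pointInPolygon(as.matrix(scores)[, 1:2, drop = FALSE],
                           region@vertices)
  data.frame(sample_id = rownames(scores),
             label = ifelse(inside, "MLLGA", "No-MLLGA"),
             probability_mllga = as.numeric(inside),
             source = "region", stringsAsFactors = FALSE)
}

#' Train the random-forest reclassifier on the signature submatrix
#'
#' Fits a [randomForest::randomForest] on the signature features of the
#' training samples with MLLGA / No-MLLGA labels. Missing values are imputed
#' with training-set feature means (stored for reuse at prediction time).
#'
#' @param x an [OmicsMatrix-class].
#' @param signature a [Signature-class] or character vector of features.
#' @param labels named character vector (sample id -> "MLLGA"/"No-MLLGA") for
#'   the training samples.
#' @param seed integer RNG seed; the forest is deterministic given it.
#' @param nTrees ensemble size (default 1000).
#' @return list with `forest`, `featureMeans`, `features`, `oobAccuracy`,
#'   `seed`.
#' @export
trainClassifier <- function(x, signature, labels, seed, nTrees = 1000L) {
  feats <- if (is(signature, "Signature")) signature@featureIds else signature
  if (length(unique(labels)) < 2L)
    stop("training labels must contain both classes")
  v <- intensities(x)[feats, names(labels), drop = FALSE]
  means <- rowMeans(v, na.rm = TRUE)
  v <- .imputeByMeans(v, means)
  y <- factor(labels, levels = c("MLLGA", "No-MLLGA"))
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(x = t(v), y = y, ntree = as.integer(nTrees))
  oob <- mean(forest$predicted == y)
  list(forest = forest, featureMeans = means, features = feats,
       oobAccuracy = oob, seed = as.integer(seed))
}

#' Classify samples with a trained signature forest
#'
#' Votes of the ensemble give `probability_mllga`; the label is the majority
#' class, with ties (probability exactly 0.5) going to MLLGA.
#'
#' @param state list returned by [trainClassifier()].
#' @param x an [OmicsMatrix-class] (or features x samples matrix) containing
#'   the signature features.
#' @param samples sample ids to classify; default all.
#' @return data.frame (`sample_id`, `label`, `probability_mllga`, `source`).
#' @export
classifySamples <- function(state, x, samples = NULL) {
  v <- if (is(x, "OmicsMatrix")) intensities(x) else as.matrix(x)
  if (is.null(samples)) samples <- colnames(v)
  sub <- v[state$features, samples, drop = FALSE]
  sub <- .imputeByMeans(sub, state$featureMeans)
  prob <- stats::predict(state$forest, newdata = t(sub), type = "prob")
  pm <- prob[, "MLLGA"]
  data.frame(sample_id = samples,
             label = ifelse(pm >= 0.5, "MLLGA", "No-MLLGA"),
             probability_mllga = as.numeric(pm),
             source = "classifier", stringsAsFactors = FALSE)
}

#' Rank signature features by classifier importance
#'
#' Mean decrease in Gini impurity, normalized to sum to 1 and sorted
#' descending (ties broken by feature id).
#'
#' @param state list returned by [trainClassifier()].
#' @return data.frame (`feature_id`, `importance`).
#' @export
featureImportance <- function(state) {
  if (is.null(state$forest)) stop("classifier state is untrained")
  imp <- randomForest::importance(state$forest)[, "MeanDecreaseGini"]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ord <- order(-imp, names(imp))
  data.frame(feature_id = names(imp)[ord], importance = as.numeric(imp[ord]),
             stringsAsFactors = FALSE)
}

#' End-to-end cohort stratification
#'
#' Composes the full procedure: t-test feature selection on the training
#' split, PCA of the signature fitted on training samples, definition of the
#' MLLGA region by Ward clustering of the positive-class training scores,
#' region labelling of the training samples, random-forest training on those
#' labels, and classification of every sample. The classifier output is the
#' authoritative final label. All model state (selection, PCA centering,
#' region, forest) is derived from training samples only.
#'
#' @param x an [OmicsMatrix-class] for the phosphoproteomics layer.
#' @param meta metadata data.frame with `sample_id`, `split`
#'   (train/validation/verification/none) and a logical column named by
#'   `positiveCol` marking the positive selection class (e.g. KMT2A
#'   rearrangement).
#' @param positiveCol metadata column with the selection-contrast class
#'   (default `"kmt2ar"`).
#' @param k signature size override (default: half the training samples).
#' @param margin region expansion override (default 5 percent of PC1 range).
#' @param seed RNG seed for the forest.
#' @param nTrees forest size.
#' @param minObs observation floor for the selection t-tests.
#' @return A [StratificationModel-class]; `assignments(model)` holds the final
#'   per-sample labels with probabilities, region labels and PC scores.
#' @export
stratifyCohort <- function(x, meta, positiveCol = "kmt2ar", k = NULL,
                           margin = NULL, seed = 1L, nTrees = 1000L,
                           minObs = 3L) {
  stopifnot(all(c("sample_id", "split") %in% names(meta)))
  if (!positiveCol %in% names(meta))
    stop("metadata lacks the positive-class column '", positiveCol, "'")
  train <- meta$sample_id[meta$split == "train"]
  if (!length(train)) stop("no training samples in metadata")
  pos <- intersect(train, meta$sample_id[meta[[positiveCol]] %in% TRUE])
  neg <- setdiff(train, pos)
  sig <- deriveSignature(x, pos, neg, k = k,
                         contrast = c(positiveCol, paste0("not_", positiveCol)),
                         minObs = minObs)
  pca <- fitSignaturePca(x, sig, samples = train)
  trainScores <- pca@scores
  reg <- defineRegion(trainScores[pos, , drop = FALSE], margin = margin)
  regionTrain <- assignByRegion(trainScores, reg$region)
  labels <- stats::setNames(regionTrain$label, regionTrain$sample_id)
  state <- trainClassifier(x, sig, labels, seed = seed, nTrees = nTrees)
  allScores <- projectSamples(pca, x, samples = meta$sample_id)
  final <- classifySamples(state, x, samples = meta$sample_id)
  regionAll <- assignByRegion(allScores, reg$region)
  final$region_label <- regionAll$label
  final$pc1 <- allScores[, 1L]
  final$pc2 <- allScores[, 2L]
  new("StratificationModel",
      signature = sig, pca = pca, region = reg$region,
      forest = state$forest, assignments = final,
      importance = featureImportance(state),
      oobAccuracy = state$oobAccuracy, seed = as.integer(seed))
}

#' Serialize a stratification model to plain-text files
#'
#' Writes the signature table (rank, feature, p), the per-sample assignment
#' table, and a JSON container with the PCA loadings/centering, region
#' vertices and forest parameters (seed and tree count; the ensemble itself is
#' reproducible from the training data and seed).
#'
#' @param model a [StratificationModel-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStratification <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- model@signature@selectionStats
  sig <- cbind(rank = seq_len(nrow(sig)), sig)
  utils::write.table(sig, file.path(dir, "signature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(model@assignments, file.path(dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  state <- list(
    features = model@signature@featureIds,
    contrast = model@signature@contrast,
    pca = list(loadings = model@pca@loadings,
               center = model@pca@center,
               feature_means = model@pca@featureMeans,
               explained_variance = model@pca@explainedVariance),
    region = list(vertices = model@region@vertices,
                  margin = model@region@margin),
    forest = list(seed = model@seed, ntree = model@forest$ntree,
                  oob_accuracy = model@oobAccuracy))
  jsonlite::write_json(state, file.path(dir, "model.json"), digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(dir)
}
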