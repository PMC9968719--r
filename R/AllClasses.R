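#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- rowData colData colData<-
NULL

#' OmicsMatrix: a log2 intensity feature-by-sample container
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' `log2intensity` assay. Features are rows (phosphopeptides, proteins, PTM
#' peptides or mRNAs), samples are columns; missing measurements are `NA`.
#' Feature annotations (gene symbol, site string such as `"DOT1L S1001"`,
#' modification type) live in `rowData`, per-sample metadata in `colData`.
#'
#' @slot modification character scalar, one of `"phospho"`, `"acetyl"`,
#'   `"methyl"`, `"protein"`, `"mRNA"`; the layer the matrix quantifies.
#' @export
setClass("OmicsMatrix",
  contains = "SummarizedExperiment",
  slots = c(modification = "character"),
  prototype = prototype(modification = "phospho")
)

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (!"log2intensity" %in% names(assays(object)))
    msg <- c(msg, "assay 'log2intensity' is required")
  fid <- rownames(object)
  sid <- colnames(object)
  if (is.null(fid) || anyDuplicated(fid))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "sample ids must be present and unique")
  if ("log2intensity" %in% names(assays(object))) {
    v <- assay(object, "log2intensity")
    if (any(is.infinite(v) | is.nan(v), na.rm = TRUE))
      msg <- c(msg, "intensities must be finite where present")
  }
  if (length(object@modification) != 1L ||
      !object@modification %in% c("phospho", "acetyl", "methyl", "protein", "mRNA"))
    msg <- c(msg, "modification must be one of phospho/acetyl/methyl/protein/mRNA")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix of log2 intensities (features x samples) with
#'   row and column names; `NA` marks missing measurements.
#' @param featureAnnotations optional `DataFrame`/`data.frame` with one row per
#'   feature (columns such as `gene`, `site`).
#' @param sampleData optional `DataFrame`/`data.frame` with one row per sample.
#' @param modification layer label, see [OmicsMatrix-class].
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6, 22), 3, 2,
#'             dimnames = list(paste0("pep", 1:3), c("S1", "S2")))
#' om <- OmicsMatrix(m)
#' intensities(om)
#' @export
OmicsMatrix <- function(values, featureAnnotations = NULL, sampleData = NULL,
                        modification = "phospho") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rd <- if (is.null(featureAnnotations)) DataFrame(row.names = rownames(values))
        else DataFrame(featureAnnotations, row.names = rownames(values))
  cd <- if (is.null(sampleData)) DataFrame(row.names = colnames(values))
        else DataFrame(sampleData, row.names = colnames(values))
  se <- SummarizedExperiment(assays = list(log2intensity = values),
                             rowData = rd, colData = cd)
  new("OmicsMatrix", se, modification = modification)
}

#' Configuration of a synthetic cohort simulation
#'
#' Holds every knob of the generator: cohort composition, planted
#' signature/kinase/drug effects, noise, missingness and screen geometry.
#' Create with [simulationConfig()], which supplies defaults emulating a
#' poor-risk AML cohort with a planted KMT2A-rearranged subgroup.
#'
#' @slot nPerGroup named integer vector over
#'   \{MLLGA, MLLGB, No-MLL, Normal\}.
#' @slot nFeatures integer, features per omic layer.
#' @slot nSignatureFeatures integer, planted informative phosphopeptides.
#' @slot effectSize log2 shift of planted features in MLLGA vs everyone else.
#' @slot noiseSd residual log2 SD.
#' @slot missingRate fraction of entries missing completely at random.
#' @slot intensityMissing logical; if TRUE low-intensity features are more
#'   likely to be missing (off by default).
#' @slot nKinases,substratesPerKinase kinase-substrate set geometry.
#' @slot plantedKinaseShifts named numeric, log2 shift applied to each named
#'   kinase's substrates in MLLGA samples.
#' @slot nDrugs integer, drugs on the screen.
#' @slot plantedSensitiveDrugs integer, drugs given a potency shift in MLLGA.
#' @slot potencyShift log10-concentration potency gain in MLLGA for planted
#'   drugs.
#' @slot concTop top concentration (molar).
#' @slot nDoses,dilutionFactor dose series geometry (default 5 doses, 10-fold).
#' @slot screenNoiseCv multiplicative CV of well luminescence noise.
#' @slot ic50JitterSd per-sample log10 IC50 jitter.
#' @slot seed integer RNG seed; the whole cohort is a deterministic function
#'   of the config.
#' @export
setClass("SimulationConfig", slots = c(
  nPerGroup = "integer",
  nFeatures = "integer",
  nSignatureFeatures = "integer",
  effectSize = "numeric",
  noiseSd = "numeric",
  missingRate = "numeric",
  intensityMissing = "logical",
  nKinases = "integer",
  substratesPerKinase = "integer",
  plantedKinaseShifts = "numeric",
  nDrugs = "integer",
  plantedSensitiveDrugs = "integer",
  potencyShift = "numeric",
  concTop = "numeric",
  nDoses = "integer",
  dilutionFactor = "numeric",
  screenNoiseCv = "numeric",
  ic50JitterSd = "numeric",
  seed = "integer"
))

.validGroups <- c("MLLGA", "MLLGB", "No-MLL", "Normal")

setValidity("SimulationConfig", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  msg <- character()
  if (length(object@nPerGroup) == 0L ||
      is.null(names(object@nPerGroup)) ||
      !all(names(object@nPerGroup) %in% .validGroups))
    msg <- c(msg, bad("nPerGroup", "group labels must be among MLLGA, MLLGB, No-MLL, Normal"))
  counts <- c(nPerGroup = all(object@nPerGroup >= 0L),
              nFeatures = object@nFeatures >= 0L,
              nSignatureFeatures = object@nSignatureFeatures >= 0L,
              nKinases = object@nKinases >= 0L,
              substratesPerKinase = object@substratesPerKinase >= 0L,
              nDrugs = object@nDrugs >= 0L,
              plantedSensitiveDrugs = object@plantedSensitiveDrugs >= 0L)
  for (f in names(counts)[!counts]) msg <- c(msg, bad(f, "counts must be >= 0"))
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, bad("missingRate", "must lie in [0, 1)"))
  if (object@dilutionFactor <= 1)
    msg <- c(msg, bad("dilutionFactor", "must be > 1"))
  if (object@nDoses < 2L)
    msg <- c(msg, bad("nDoses", "must be >= 2"))
  if (object@noiseSd < 0) msg <- c(msg, bad("noiseSd", "must be >= 0"))
  if (object@concTop <= 0) msg <- c(msg, bad("concTop", "must be > 0"))
  if (object@nSignatureFeatures > object@nFeatures)
    msg <- c(msg, bad("nSignatureFeatures", "cannot exceed nFeatures"))
  if (object@nKinases * object@substratesPerKinase >
      object@nFeatures - object@nSignatureFeatures)
    msg <- c(msg, bad("nKinases", "kinase substrate sets do not fit among non-signature features"))
  if (object@plantedSensitiveDrugs > object@nDrugs)
    msg <- c(msg, bad("plantedSensitiveDrugs", "cannot exceed nDrugs"))
  if (length(msg)) msg else TRUE
})

#' A simulated multi-omic cohort with recorded ground truth
#'
#' @slot omics named list of [OmicsMatrix-class] layers (at least `phospho`).
#' @slot metadata data.frame of per-sample labels (centre, tissue, karyotype,
#'   fusion partner, split, group, qc flags).
#' @slot kinaseSets named list mapping kinase names to substrate feature ids.
#' @slot truth list recording planted feature ids, planted kinase shifts,
#'   planted drug potency shifts and true group labels.
#' @slot config the [SimulationConfig-class] used.
#' @export
setClass("SyntheticCohort", slots = c(
  omics = "list",
  metadata = "data.frame",
  kinaseSets = "list",
  truth = "list",
  config = "SimulationConfig"
))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  if (!length(object@omics) || !all(vapply(object@omics, is, TRUE, "OmicsMatrix")))
    msg <- c(msg, "omics must be a non-empty list of OmicsMatrix")
  sid <- object@metadata$sample_id
  for (nm in names(object@omics)) {
    if (!identical(colnames(object@omics[[nm]]), sid))
      msg <- c(msg, sprintf("sample ids of layer '%s' must match metadata", nm))
  }
  planted <- object@truth$plantedFeatures
  if (length(planted) && "phospho" %in% names(object@omics) &&
      !all(planted %in% rownames(object@omics$phospho)))
    msg <- c(msg, "planted feature ids must be a subset of phospho feature ids")
  if (length(msg)) msg else TRUE
})

#' A phosphoproteomics signature: the selected features and their statistics
#'
#' @slot featureIds selected features, ordered by ascending selection p-value
#'   (ties: larger absolute log2 fold change, then lexicographic id).
#' @slot selectionStats data.frame (feature_id, log2fc, t_stat, p) for the
#'   selected features, same order.
#' @slot k number of features (defaults to floor(n_train / 2)).
#' @slot trainSampleIds samples the selection used.
#' @slot contrast character(2): positive and negative class label.
#' @export
setClass("Signature", slots = c(
  featureIds = "character",
  selectionStats = "data.frame",
  k = "integer",
  trainSampleIds = "character",
  contrast = "character"
))

setValidity("Signature", function(object) {
  msg <- character()
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "signature features must be unique")
  if (length(object@featureIds) != object@k)
    msg <- c(msg, "length(featureIds) must equal k")
  if (length(object@contrast) != 2L)
    msg <- c(msg, "contrast must name a positive and a negative class")
  if (length(msg)) msg else TRUE
})

#' A fitted principal component model over a signature submatrix
#'
#' @slot loadings feature x component rotation matrix.
#' @slot center per-feature centering vector (training mean).
#' @slot featureMeans per-feature training means used to impute missing values.
#' @slot explainedVariance per-component fraction of variance.
#' @slot scores fitted sample scores (samples x components).
#' @export
setClass("PcaModel", slots = c(
  loadings = "matrix",
  center = "numeric",
  featureMeans = "numeric",
  explainedVariance = "numeric",
  scores = "matrix"
))

setValidity("PcaModel", function(object) {
  ev <- object@explainedVariance
  msg <- character()
  if (sum(ev) > 1 + 1e-8) msg <- c(msg, "explained variance fractions must sum to <= 1")
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-8))
    msg <- c(msg, "explained variance fractions must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' A convex region in the (PC1, PC2) plane defining group membership
#'
#' @slot vertices matrix (>= 3 x 2) of polygon vertices in order; degenerate
#'   inputs (collinear or identical points) are thickened into a rectangle or
#'   square of half-width `margin`.
#' @slot margin non-negative expansion applied when the region was built.
#' @export
setClass("Region", slots = c(vertices = "matrix", margin = "numeric"))

setValidity("Region", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 2L || nrow(object@vertices) < 3L)
    msg <- c(msg, "vertices must be an (n >= 3) x 2 matrix")
  if (object@margin < 0) msg <- c(msg, "margin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' End-to-end stratification model and per-sample assignments
#'
#' Returned by [stratifyCohort()]. Bundles the derived [Signature-class], the
#' training-set [PcaModel-class], the MLLGA [Region-class], the fitted random
#' forest and the per-sample assignments.
#'
#' @slot signature the derived signature.
#' @slot pca PCA fitted on training samples only.
#' @slot region MLLGA area in (PC1, PC2).
#' @slot forest fitted `randomForest` object.
#' @slot assignments data.frame (sample_id, label, probability_mllga, source,
#'   region_label, pc1, pc2).
#' @slot importance data.frame (feature_id, importance) sorted descending.
#' @slot oobAccuracy out-of-bag accuracy of the classifier.
#' @slot seed RNG seed used for the forest.
#' @export
setClass("StratificationModel", slots = c(
  signature = "Signature",
  pca = "PcaModel",
  region = "Region",
  forest = "ANY",
  assignments = "data.frame",
  importance = "data.frame",
  oobAccuracy = "numeric",
  seed = "integer"
))
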