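#' Accessors for PhosphoStrat classes
#'
#' `intensities()` returns the log2 intensity assay; `featureIds()` and
#' `sampleIds()` the dimension names; `featureAnnotations()` the rowData;
#' `signatureFeatures()` the ordered selected features of a signature;
#' `regionVertices()` the polygon of an MLLGA region; `assignments()` the
#' per-sample label table of a stratification model.
#'
#' @param x an object of the documented class.
#' @return The corresponding component (matrix, character vector, DataFrame or
#'   data.frame).
#' @name accessors
#' @examples
#' m <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' om <- OmicsMatrix(m)
#' featureIds(om)
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setMethod("intensities", "OmicsMatrix", function(x) assay(x, "log2intensity"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("featureIds", "Signature", function(x) x@featureIds)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("featureAnnotations", function(x) standardGeneric("featureAnnotations"))

#' @rdname accessors
#' @export
setMethod("featureAnnotations", "OmicsMatrix", function(x) rowData(x))

#' @rdname accessors
#' @export
setGeneric("signatureFeatures", function(x) standardGeneric("signatureFeatures"))

#' @rdname accessors
#' @export
setMethod("signatureFeatures", "Signature", function(x) x@featureIds)

#' @rdname accessors
#' @export
setMethod("signatureFeatures", "StratificationModel",
          function(x) x@signature@featureIds)

#' @rdname accessors
#' @export
setGeneric("regionVertices", function(x) standardGeneric("regionVertices"))

#' @rdname accessors
#' @export
setMethod("regionVertices", "Region", function(x) x@vertices)

#' @rdname accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname accessors
#' @export
setMethod("assignments", "StratificationModel", function(x) x@assignments)

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(object@nPerGroup),
                                  object@nPerGroup), collapse = ", "), "\n")
  cat(sprintf("  features: %d (%d planted, effect %.2g log2, noise sd %.2g, missing %.2g)\n",
              object@nFeatures, object@nSignatureFeatures, object@effectSize,
              object@noiseSd, object@missingRate))
  cat(sprintf("  kinases: %d x %d substrates; planted shifts: %s\n",
              object@nKinases, object@substratesPerKinase,
              if (length(object@plantedKinaseShifts))
                paste(sprintf("%s=%+.2g", names(object@plantedKinaseShifts),
                              object@plantedKinaseShifts), collapse = ", ")
              else "none"))
  cat(sprintf("  screen: %d drugs (%d planted, %+.2g log10 shift), %d doses %.3g M top, %g-fold\n",
              object@nDrugs, object@plantedSensitiveDrugs, -object@potencyShift,
              object@nDoses, object@concTop, object@dilutionFactor))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat("SyntheticCohort\n")
  cat(sprintf("  %d samples: %s\n", nrow(object@metadata),
              paste(sprintf("%s=%d", names(table(object@metadata$group)),
                            table(object@metadata$group)), collapse = ", ")))
  for (nm in names(object@omics))
    cat(sprintf("  layer %-8s %d features\n", nm, nrow(object@omics[[nm]])))
  cat(sprintf("  %d kinase sets, %d planted signature features\n",
              length(object@kinaseSets), length(object@truth$plantedFeatures)))
})

setMethod("show", "Signature", function(object) {
  cat(sprintf("Signature: %d features (%s vs %s), trained on %d samples\n",
              object@k, object@contrast[1], object@contrast[2],
              length(object@trainSampleIds)))
  print(utils::head(object@selectionStats, 5))
  if (object@k > 5) cat(sprintf("  ... and %d more\n", object@k - 5L))
})

setMethod("show", "Region", function(object) {
  cat(sprintf("Region: convex polygon with %d vertices, margin %.3g\n",
              nrow(object@vertices), object@margin))
})

setMethod("show", "StratificationModel", function(object) {
  tab <- table(object@assignments$label)
  cat("StratificationModel\n")
  cat(sprintf("  signature: %d features; OOB accuracy %.3f\n",
              object@signature@k, object@oobAccuracy))
  cat("  assignments:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
})
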