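#' Build a synthetic-cohort simulation configuration
#'
#' Defaults emulate a desk-scale poor-risk AML cohort with a planted
#' KMT2A-rearranged subgroup: 8 MLLGA, 4 MLLGB, 20 No-MLL patients and 4
#' healthy donors; 2000 phosphopeptides of which 18 carry a 2 log2-unit MLLGA
#' shift over 0.5 log2 residual noise; 20 kinase-substrate sets of 10
#' substrates with a planted +1 log2 CDK1 activity shift in MLLGA; and a
#' 24-drug screen (5 concentrations, 10-fold dilutions from 10 uM) where 3
#' drugs gain one decade of potency in MLLGA.
#'
#' @param nPerGroup named counts over MLLGA / MLLGB / No-MLL / Normal.
#' @param nFeatures phosphopeptides per layer.
#' @param nSignatureFeatures planted informative features.
#' @param effectSize log2 shift of planted features in MLLGA.
#' @param noiseSd residual log2 SD.
#' @param missingRate fraction missing completely at random.
#' @param intensityMissing make low intensities likelier to be missing.
#' @param nKinases,substratesPerKinase kinase-set geometry.
#' @param plantedKinaseShifts named log2 shifts applied to substrates in
#'   MLLGA.
#' @param nDrugs,plantedSensitiveDrugs,potencyShift screen effects.
#' @param concTop,nDoses,dilutionFactor dose series.
#' @param screenNoiseCv,ic50JitterSd screen noise knobs.
#' @param seed integer RNG seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' simulationConfig(seed = 7)
#' @export
simulationConfig <- function(nPerGroup = c(MLLGA = 8L, MLLGB = 4L,
                                           `No-MLL` = 20L, Normal = 4L),
                             nFeatures = 2000L, nSignatureFeatures = 18L,
                             effectSize = 2, noiseSd = 0.5,
                             missingRate = 0.05, intensityMissing = FALSE,
                             nKinases = 20L, substratesPerKinase = 10L,
                             plantedKinaseShifts = c(CDK1 = 1.0),
                             nDrugs = 24L, plantedSensitiveDrugs = 3L,
                             potencyShift = 1.0, concTop = 1e-5, nDoses = 5L,
                             dilutionFactor = 10, screenNoiseCv = 0.05,
                             ic50JitterSd = 0.15, seed = 1L) {
  if (is.null(plantedKinaseShifts)) plantedKinaseShifts <- numeric()
  plantedKinaseShifts <- unlist(plantedKinaseShifts)  # tolerate YAML maps
  nPerGroup <- unlist(nPerGroup)
  cfg <- new("SimulationConfig",
             nPerGroup = stats::setNames(as.integer(nPerGroup), names(nPerGroup)),
             nFeatures = as.integer(nFeatures),
             nSignatureFeatures = as.integer(nSignatureFeatures),
             effectSize = as.numeric(effectSize),
             noiseSd = as.numeric(noiseSd),
             missingRate = as.numeric(missingRate),
             intensityMissing = isTRUE(intensityMissing),
             nKinases = as.integer(nKinases),
             substratesPerKinase = as.integer(substratesPerKinase),
             plantedKinaseShifts = plantedKinaseShifts,
             nDrugs = as.integer(nDrugs),
             plantedSensitiveDrugs = as.integer(plantedSensitiveDrugs),
             potencyShift = as.numeric(potencyShift),
             concTop = as.numeric(concTop),
             nDoses = as.integer(nDoses),
             dilutionFactor = as.numeric(dilutionFactor),
             screenNoiseCv = as.numeric(screenNoiseCv),
             ic50JitterSd = as.numeric(ic50JitterSd),
             seed = as.integer(seed))
  validObject(cfg)
  cfg
}

.simMetadata <- function(config) {
  groups <- rep(names(config@nPerGroup), config@nPerGroup)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  partners <- rep(NA_character_, n)
  partners[groups == "MLLGA"] <- sample(c("MLLT4", "MLLT10", "MLLT3", "TET1"),
                                        sum(groups == "MLLGA"), replace = TRUE,
                                        prob = c(0.5, 0.25, 0.15, 0.1))
  partners[groups == "MLLGB"] <- sample(c("ELL", "MLLT1"),
                                        sum(groups == "MLLGB"), replace = TRUE)
  karyotype <- ifelse(groups %in% c("MLLGA", "MLLGB"), "KMT2Ar",
                      ifelse(groups == "Normal", "normal",
                             sample(c("complex", "-7/del(7)", "other"), n,
                                    replace = TRUE)))
  centre <- split <- rep(NA_character_, n)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (g == "Normal") {
      centre[idx] <- "BCI"
      split[idx] <- "none"
      next
    }
    nBci <- max(1L, round(0.7 * length(idx)))
    bci <- idx[seq_len(nBci)]
    fimm <- setdiff(idx, bci)
    centre[bci] <- "BCI"; centre[fimm] <- "FIMM"
    nTrain <- ceiling(0.8 * length(bci))
    split[bci[seq_len(nTrain)]] <- "train"
    if (nTrain < length(bci)) split[bci[-seq_len(nTrain)]] <- "validation"
    split[fimm] <- "verification"
  }
  data.frame(sample_id = ids, centre = centre,
             tissue = sample(c("PB", "BM"), n, replace = TRUE),
             karyotype = karyotype, kmt2a_partner = partners,
             kmt2ar = groups %in% c("MLLGA", "MLLGB"),
             viability = round(stats::runif(n, 65, 99), 1),
             qc_flags = "", split = split, group = groups,
             stringsAsFactors = FALSE)
}

.applyMissing <- function(v, config) {
  if (config@missingRate <= 0) return(v)
  if (config@intensityMissing) {
    # low-intensity cells are likelier to drop out; marginal rate preserved
    r <- rank(v) / length(v)
    p <- config@missingRate * 2 * (1 - r)
    v[stats::runif(length(v)) < p] <- NA
  } else {
    v[sample(length(v), round(config@missingRate * length(v)))] <- NA
  }
  v
}

#' Simulate a multi-omic cohort with planted structure
#'
#' Draws log2 intensities as `baseline + group effect + N(0, noiseSd)`:
#' baselines are feature-specific `N(22, 2)` (a typical MS dynamic range);
#' exactly `nSignatureFeatures` randomly placed phosphopeptides gain
#' `effectSize` in MLLGA samples relative to everyone else; every named
#' kinase's substrate set gains its planted shift in MLLGA; all remaining
#' features are null. Entries are then removed completely at random at
#' `missingRate`. A protein layer with the same geometry but no planted
#' effects is generated alongside. The whole cohort is a deterministic
#' function of the config (one seed drives every draw).
#'
#' @param config a [SimulationConfig-class].
#' @return A [SyntheticCohort-class]: omics layers (`phospho`, `protein`),
#'   metadata with centre / karyotype / split labels, kinase substrate sets,
#'   and the ground-truth record of planted features, kinases and drugs.
#' @examples
#' cohort <- simulateCohort(simulationConfig(
#'   nPerGroup = c(MLLGA = 4L, MLLGB = 3L, `No-MLL` = 6L, Normal = 2L),
#'   nFeatures = 100L, nSignatureFeatures = 5L, nKinases = 3L, seed = 1L))
#' cohort
#' @export
simulateCohort <- function(config) {
  validObject(config)
  set.seed(config@seed)
  meta <- .simMetadata(config)
  n <- nrow(meta)
  isA <- meta$group == "MLLGA"

  fid <- sprintf("pp%04d", seq_len(config@nFeatures))
  # disjoint random placement of planted signature features and kinase sets
  shuffled <- sample(fid)
  planted <- sort(shuffled[seq_len(config@nSignatureFeatures)])
  pool <- shuffled[-seq_len(config@nSignatureFeatures)]
  kinNames <- character()
  kinaseSets <- list()
  if (config@nKinases > 0L) {
    plantedKin <- names(config@plantedKinaseShifts)
    kinNames <- c(plantedKin,
                  sprintf("KIN%02d", seq_len(max(0L, config@nKinases -
                                                 length(plantedKin)))))
    kinNames <- kinNames[seq_len(config@nKinases)]
    for (i in seq_along(kinNames)) {
      kinaseSets[[kinNames[i]]] <-
        sort(pool[(i - 1L) * config@substratesPerKinase +
                  seq_len(config@substratesPerKinase)])
    }
  }

  baseline <- stats::rnorm(config@nFeatures, 22, 2)
  v <- baseline + matrix(stats::rnorm(config@nFeatures * n, 0, config@noiseSd),
                         config@nFeatures, n)
  dimnames(v) <- list(fid, meta$sample_id)
  v[planted, isA] <- v[planted, isA] + config@effectSize
  for (kin in names(config@plantedKinaseShifts)) {
    if (!kin %in% names(kinaseSets)) next
    v[kinaseSets[[kin]], isA] <- v[kinaseSets[[kin]], isA] +
      config@plantedKinaseShifts[[kin]]
  }
  v <- .applyMissing(v, config)
  anno <- data.frame(
    gene = sprintf("GENE%04d", seq_len(config@nFeatures)),
    site = sprintf("GENE%04d S%d", seq_len(config@nFeatures),
                   sample(50:1500, config@nFeatures, replace = TRUE)),
    stringsAsFactors = FALSE)
  phospho <- OmicsMatrix(v, featureAnnotations = anno,
                         sampleData = meta, modification = "phospho")

  pid <- sprintf("prot%04d", seq_len(config@nFeatures))
  pv <- stats::rnorm(config@nFeatures, 22, 2) +
    matrix(stats::rnorm(config@nFeatures * n, 0, config@noiseSd),
           config@nFeatures, n)
  dimnames(pv) <- list(pid, meta$sample_id)
  pv <- .applyMissing(pv, config)
  protein <- OmicsMatrix(pv,
                         featureAnnotations = data.frame(
                           gene = sprintf("GENE%04d", seq_len(config@nFeatures)),
                           stringsAsFactors = FALSE),
                         sampleData = meta, modification = "protein")

  drugs <- .drugParams(config)
  cohort <- new("SyntheticCohort",
                omics = list(phospho = phospho, protein = protein),
                metadata = meta, kinaseSets = kinaseSets,
                truth = list(plantedFeatures = planted,
                             plantedKinases = config@plantedKinaseShifts,
                             plantedDrugs = stats::setNames(
                               rep(config@potencyShift,
                                   sum(drugs$planted)),
                               drugs$drug[drugs$planted]),
                             groups = stats::setNames(meta$group,
                                                      meta$sample_id)),
                config = config)
  validObject(cohort)
  cohort
}

# drug identities and curve parameters; seeded independently of the cohort
# stream so cohort and screen can be generated in either order
.drugParams <- function(config) {
  set.seed(config@seed + 1L)
  nd <- config@nDrugs
  x2 <- log10(config@concTop)
  x1 <- x2 - (config@nDoses - 1) * log10(config@dilutionFactor)
  planted <- rep(FALSE, nd)
  if (config@plantedSensitiveDrugs > 0L)
    planted[sample(nd, config@plantedSensitiveDrugs)] <- TRUE
  data.frame(drug = sprintf("DRUG%03d", seq_len(nd)),
             planted = planted,
             log10ic50 = stats::runif(nd, x1 + 0.5, x2 - 0.5),
             slope = stats::runif(nd, 0.8, 1.5),
             top = 100,
             stringsAsFactors = FALSE)
}

#' Simulate a raw ex vivo drug screen for a cohort
#'
#' Per drug and sample, viability at each of `nDoses` concentrations (10-fold
#' dilutions from `concTop` by default) follows a four-parameter log-logistic
#' curve with a drug-specific IC50, jittered per sample and shifted
#' `potencyShift` decades more potent in MLLGA samples for the planted
#' sensitive drugs. Each sample's plate carries vehicle (DMSO) wells defining
#' 100 percent viability, positive-control wells at the kill floor, and
#' untreated day-0 wells so that proliferation can be estimated: MLLGA
#' samples grow fastest (3-fold over 3 days versus 2-fold for other AML and
#' 1.5-fold for healthy donors). All well signals get multiplicative
#' log-normal noise of CV `screenNoiseCv`.
#'
#' @param config a [SimulationConfig-class].
#' @param metadata cohort metadata with `sample_id` and `group` columns.
#' @return long-format data.frame (`drug`, `sample`, `dose_index`,
#'   `concentration`, `signal`, `well_type`, `day`) with the drug truth table
#'   attached as `attr(, "truth")`.
#' @export
simulateScreen <- function(config, metadata) {
  validObject(config)
  if (is.null(metadata$group) || anyNA(metadata$group))
    stop("metadata must carry group labels for every sample")
  drugs <- .drugParams(config)
  # continue from a distinct stream point so adding drugs does not change
  # the cohort matrices
  set.seed(config@seed + 2L)
  doses <- config@concTop / config@dilutionFactor^(seq_len(config@nDoses) - 1)
  doses <- rev(doses)  # ascending
  noise <- function(k) exp(stats::rnorm(k, 0, config@screenNoiseCv))
  growth <- c(MLLGA = 3, MLLGB = 2, `No-MLL` = 2, Normal = 1.5)
  posFloor <- 50
  day0Base <- 5000
  out <- vector("list", nrow(metadata))
  for (si in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[si]
    grp <- metadata$group[si]
    fold <- growth[[grp]] * noise(1)
    L0 <- day0Base * noise(1)
    V <- L0 * fold
    ctrl <- data.frame(
      drug = NA_character_, sample = sid,
      dose_index = NA_integer_, concentration = NA_real_,
      signal = c(V * noise(4), posFloor * noise(4), L0 * noise(4)),
      well_type = rep(c("vehicle", "positive", "untreated"), each = 4),
      day = rep(c(3L, 3L, 0L), each = 4),
      stringsAsFactors = FALSE)
    ic50 <- drugs$log10ic50 +
      stats::rnorm(nrow(drugs), 0, config@ic50JitterSd) -
      ifelse(drugs$planted & grp == "MLLGA", config@potencyShift, 0)
    dw <- do.call(rbind, lapply(seq_len(nrow(drugs)), function(di) {
      inh <- .fourPL(log10(doses), 0, drugs$top[di], ic50[di], drugs$slope[di])
      viability <- pmax(1 - inh / 100, 0)
      data.frame(drug = drugs$drug[di], sample = sid,
                 dose_index = seq_along(doses), concentration = doses,
                 signal = (posFloor + (V - posFloor) * viability) *
                   noise(length(doses)),
                 well_type = "drug", day = 3L, stringsAsFactors = FALSE)
    }))
    out[[si]] <- rbind(ctrl, dw)
  }
  screen <- do.call(rbind, out)
  rownames(screen) <- NULL
  attr(screen, "truth") <- drugs
  screen
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits each omics layer as TSV, the metadata as TSV and the kinase sets as
#' GMT; optionally simulates and writes the drug screen.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory.
#' @param screen logical; also write `screen.tsv` (default TRUE).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, screen = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort@omics))
    writeOmicsMatrix(cohort@omics[[nm]], file.path(dir, paste0(nm, ".tsv")))
  writeSampleMetadata(cohort@metadata, file.path(dir, "metadata.tsv"))
  if (length(cohort@kinaseSets))
    writeGmt(cohort@kinaseSets, file.path(dir, "kinase_sets.gmt"))
  if (screen)
    writeScreen(simulateScreen(cohort@config, cohort@metadata),
                file.path(dir, "screen.tsv"))
  invisible(dir)
}
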