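.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulation = list(),          # overrides for simulationConfig()
    qc = TRUE,
    normalize = "median_center",
    rule = list(p_max = 0.05, lfc_min = 0.8),
    signature = list(k = NULL, margin = NULL, n_trees = 1000L, min_obs = 3L),
    ksea = list(min_substrates = 3L),
    dss = list(t = 10, variant = "DSS2", min_n = 3L),
    association = list(alpha = 0.05, min_pairs = 5L, adjust = "none"),
    out_dir = NULL
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      .mergeConfig(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

# short stable tag of the resolved config, stamped on outputs
.configHash <- function(config) {
  j <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  sprintf("cfg%08x", sum(utf8ToInt(j) * (seq_len(nchar(j)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the end-to-end synthetic-cohort analysis
#'
#' Executes every stage in dependency order on a simulated cohort: generation,
#' QC, median-centering, signature stratification, MLLGA differential tables
#' and counting rules, per-contrast and per-sample KSEA, screen simulation,
#' DSS computation, group-wise drug comparison, proliferation stratification,
#' and DSS-versus-protein Spearman correlation. Reruns with the same config
#' are identical (one seed drives all stochastic stages).
#'
#' @param config a nested list overriding the defaults (see
#'   `PhosphoStrat:::.defaultPipelineConfig()` for the shape), or the path to
#'   a YAML file holding such a list. Notable fields: `seed`, `simulation`
#'   (arguments to [simulationConfig()]), `rule$p_max` / `rule$lfc_min`,
#'   `signature$k` / `signature$margin` / `signature$n_trees`,
#'   `dss$t` / `dss$variant` / `dss$min_n`, `association$alpha`, `out_dir`.
#' @return A list bundle: `config` (resolved, with `hash`), `cohort`,
#'   `qcReport`, `model` ([StratificationModel-class]), `differential`,
#'   `counts`, `kseaContrast`, `kseaPerSample`, `dss`, `drugComparison`,
#'   `proliferation`, `correlation`. When `out_dir` is set, tables and the
#'   resolved config are also written there.
#' @examples
#' \donttest{
#' bundle <- runPipeline(list(seed = 1L,
#'   simulation = list(nFeatures = 300L, nDrugs = 6L)))
#' table(assignments(bundle$model)$label)
#' }
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  cfg$hash <- .configHash(cfg[setdiff(names(cfg), "hash")])

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  simArgs <- cfg$simulation
  simArgs$seed <- cfg$seed
  cohort <- stage("simulate", do.call(simulationConfig, simArgs))
  cohort <- stage("simulate", simulateCohort(cohort))

  meta <- cohort@metadata
  qcReport <- NULL
  if (isTRUE(cfg$qc)) {
    qc <- stage("qc", applyQC(meta))
    meta <- qc$retained
    qcReport <- qc$report
  }
  phospho <- cohort@omics$phospho[, meta$sample_id]
  phospho <- stage("normalize",
                   normalizeIntensities(phospho, method = cfg$normalize))

  model <- stage("signature", stratifyCohort(
    phospho, meta, k = cfg$signature$k, margin = cfg$signature$margin,
    seed = cfg$seed, nTrees = cfg$signature$n_trees,
    minObs = cfg$signature$min_obs))
  assign <- assignments(model)
  mllga <- assign$sample_id[assign$label == "MLLGA"]
  others <- setdiff(meta$sample_id[meta$group != "Normal"], mllga)

  diffRes <- stage("differential", ttestTwoGroup(
    phospho, mllga, others, minObs = cfg$signature$min_obs))
  counts <- stage("differential", countSignificant(
    diffRes, pMax = cfg$rule$p_max, lfcMin = cfg$rule$lfc_min))

  kseaC <- kseaS <- NULL
  if (length(cohort@kinaseSets)) {
    kseaC <- stage("ksea", kseaContrast(diffRes, cohort@kinaseSets,
                                        minSubstrates = cfg$ksea$min_substrates))
    kseaS <- stage("ksea", kseaPerSample(phospho, cohort@kinaseSets,
                                         minSubstrates = cfg$ksea$min_substrates))
  }

  screen <- stage("screen", simulateScreen(cohort@config, meta))
  dssTab <- stage("dss", computeDss(screen, t = cfg$dss$t,
                                    variant = cfg$dss$variant))
  cmp <- stage("dss", compareDrugResponse(dssTab, mllga,
                                          intersect(others, dssTab$sample),
                                          minN = cfg$dss$min_n))
  prolif <- stage("proliferation", proliferationFromScreen(screen))
  kmtIds <- meta$sample_id[meta$kmt2ar]
  prolifStrat <- stage("proliferation", stratifyByProliferation(
    stats::setNames(prolif$ratio, prolif$sample_id), kmtIds))

  corr <- stage("correlate", correlateMatrix(
    dssMatrix(dssTab), cohort@omics$protein[, meta$sample_id],
    alpha = cfg$association$alpha, adjust = cfg$association$adjust,
    minPairs = cfg$association$min_pairs))

  bundle <- list(config = cfg, cohort = cohort, qcReport = qcReport,
                 model = model, differential = diffRes, counts = counts,
                 kseaContrast = kseaC, kseaPerSample = kseaS, dss = dssTab,
                 drugComparison = cmp, proliferation = prolif,
                 proliferationStrata = prolifStrat, correlation = corr)
  if (!is.null(cfg$out_dir)) .writeBundle(bundle, cfg$out_dir)
  bundle
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  writeStratification(bundle$model, file.path(dir, "stratification"))
  utils::write.table(bundle$differential, file.path(dir, "differential.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(bundle$dss, file.path(dir, "dss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(bundle$drugComparison$results))
    utils::write.table(bundle$drugComparison$results,
                       file.path(dir, "drug_comparison.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$proliferation, file.path(dir, "proliferation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$kseaPerSample))
    writeKinaseActivity(bundle$kseaPerSample,
                        file.path(dir, "kinase_activity.tsv"))
  writeCorrelationMatrix(bundle$correlation, file.path(dir, "correlation.tsv"))
  invisible(dir)
}
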