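makeScreenRows <- function(sample, vehicle, positive, drugSignals = NULL,
                           doses = NULL) {
  ctrl <- data.frame(drug = NA_character_, sample = sample,
                     dose_index = NA_integer_, concentration = NA_real_,
                     signal = c(rep(vehicle, 2), rep(positive, 2)),
                     well_type = rep(c("vehicle", "positive"), each = 2),
                     day = 3L, stringsAsFactors = FALSE)
  if (is.null(drugSignals)) return(ctrl)
  rbind(ctrl, data.frame(drug = "D1", sample = sample,
                         dose_index = seq_along(doses), concentration = doses,
                         signal = drugSignals, well_type = "drug", day = 3L,
                         stringsAsFactors = FALSE))
}

test_that("well normalization anchors the controls and interpolates linearly", {
  doses <- 10^seq(-9, -5)
  scr <- makeScreenRows("s1", vehicle = 10000, positive = 100,
                        drugSignals = c(10000, 100, 5050, 10000, 100),
                        doses = doses)
  out <- normalizeWells(scr)
  expect_equal(out$inhibition, c(0, 100, 50, 0, 100))
  # dead plate: vehicle below positive control
  expect_error(normalizeWells(makeScreenRows("s1", 50, 100)), "dead plate")
})

test_that("noiseless 4PL curves are recovered to 1e-3 relative accuracy", {
  set.seed(40)
  x <- seq(-9, -5)
  for (i in 1:20) {
    truth <- list(bottom = runif(1, 0, 10), top = runif(1, 60, 110),
                  log10ic50 = runif(1, -8.5, -5.5), slope = runif(1, 0.5, 3))
    y <- truth$bottom + (truth$top - truth$bottom) /
      (1 + 10^(truth$slope * (truth$log10ic50 - x)))
    fit <- fitDoseResponse(10^x, y)
    expect_true(fit$converged)
    for (p in names(truth))
      expect_equal(fit[[p]], truth[[p]], tolerance = 1e-3 * max(1, abs(truth[[p]])))
  }
  # flat zero inhibition: top pinned near 0, downstream DSS 0
  flat <- fitDoseResponse(10^x, rep(0, 5))
  expect_lt(abs(flat$top), 1e-6)
  expect_equal(drugSensitivityScore(flat, c(-9, -5)), 0)
  # inhibition falling with dose cannot be described by a rising 4PL:
  # the failure is recorded, never silent
  bad <- fitDoseResponse(10^x, c(90, 70, 50, 30, 10))
  expect_true(!bad$converged || bad$atBound)
  expect_error(fitDoseResponse(c(1e-9, NA), c(1, 2)), "non-finite")
  expect_error(fitDoseResponse(c(1e-9, 1e-9), c(1, 2)), "distinct")
})

test_that("DSS hits its analytic boundary values", {
  win <- c(-9, -5)
  zero <- list(bottom = 0, top = 0, log10ic50 = -7, slope = 1)
  expect_equal(drugSensitivityScore(zero, win), 0)
  # saturated inhibition: the area above t=10 fills the whole window
  sat <- list(bottom = 100, top = 100, log10ic50 = -7, slope = 1)
  expect_equal(drugSensitivityScore(sat, win, t = 10, variant = "DSS1"), 100)
  expect_error(drugSensitivityScore(sat, c(-5, -9)), "x1 < x2")
  expect_error(drugSensitivityScore(sat, win, t = 100), "t must lie")
})

test_that("closed-form DSS integration matches a fine trapezoid grid", {
  set.seed(41)
  win <- c(-9, -5)
  for (i in 1:25) {
    fit <- list(bottom = runif(1, -5, 20), top = runif(1, 20, 115),
                log10ic50 = runif(1, -10, -4), slope = runif(1, 0.3, 6))
    for (variant in c("DSS1", "DSS2")) {
      t0 <- sample(c(0, 10, 25), 1)
      expect_equal(drugSensitivityScore(fit, win, t = t0, variant = variant),
                   dssTrapezoidOracle(fit, win, t = t0, variant = variant),
                   tolerance = 1e-4)
    }
  }
  # the worked mid-window case
  fit <- list(bottom = 0, top = 80, log10ic50 = -7, slope = 1)
  expect_equal(drugSensitivityScore(fit, win, t = 10),
               dssTrapezoidOracle(fit, win, t = 10), tolerance = 1e-4)
})

test_that("DSS is monotone in potency and in the activity threshold", {
  win <- c(-9, -5)
  base <- list(bottom = 0, top = 90, slope = 1.2)
  ic50s <- seq(-4.5, -9.5, by = -0.5)
  dss <- vapply(ic50s, function(m)
    drugSensitivityScore(c(base, log10ic50 = m), win), 0)
  expect_true(all(diff(dss) >= 0))
  fit <- c(base, log10ic50 = -7)
  expect_gte(drugSensitivityScore(fit, win, t = 0),
             drugSensitivityScore(fit, win, t = 10))
})

test_that("proliferation follows the printed luminescence-ratio convention", {
  pr <- proliferationRate(100, 200)
  expect_equal(pr$ratio, 50)
  expect_equal(pr$growth_fold, 2)
  expect_equal(proliferationRate(150, 150)$ratio, 100)
  set.seed(42)
  d0 <- runif(20, 100, 1e5); d3 <- runif(20, 100, 1e5)
  pr <- proliferationRate(d0, d3)
  expect_equal(pr$ratio * pr$growth_fold, rep(100, 20))
  expect_error(proliferationRate(-1, 10), "positive")
})

test_that("group comparison flags planted drugs and enforces the n filter", {
  cfg <- smallConfig(screenNoiseCv = 0, ic50JitterSd = 0, seed = 43L)
  co <- simulateCohort(cfg)
  scr <- simulateScreen(cfg, co@metadata)
  dss <- computeDss(scr)
  truth <- attr(scr, "truth")
  mllga <- co@metadata$sample_id[co@metadata$group == "MLLGA"]
  rest <- co@metadata$sample_id[co@metadata$group %in% c("MLLGB", "No-MLL")]
  cmp <- compareDrugResponse(dss, mllga, rest, minN = 3)
  sig <- cmp$results$drug[cmp$results$fdr < 0.05 & cmp$results$mean_diff > 0]
  expect_true(all(truth$drug[truth$planted] %in% sig))
  # a drug observed in too few samples is excluded and listed
  sparse <- dss[!(dss$drug == "DRUG001" & dss$sample != mllga[1]), ]
  cmp2 <- compareDrugResponse(sparse, mllga, rest, minN = 3)
  expect_true("DRUG001" %in% cmp2$excluded)
  # cohort-level pre-filter
  cmp3 <- compareDrugResponse(dss, mllga, rest, minN = 3,
                              cohortMinN = nrow(co@metadata) + 1)
  expect_equal(nrow(cmp3$results), 0L)
  expect_error(compareDrugResponse(dss, mllga, c(rest, mllga[1])), "overlap")
})

test_that("proliferation stratification uses the reference mean with ties high", {
  r <- c(a = 10, b = 20, c = 30)
  out <- stratifyByProliferation(r, names(r))
  expect_equal(out$threshold, 20)
  expect_identical(unname(out$labels), c("Low pro", "High pro", "High pro"))
  allEq <- stratifyByProliferation(c(a = 5, b = 5), c("a", "b"))
  expect_true(all(allEq$labels == "High pro"))
  expect_error(stratifyByProliferation(r, "zz"), "empty reference")
  # signature stratification separates planted drugs more than proliferation
  cfg <- smallConfig(screenNoiseCv = 0, ic50JitterSd = 0, seed = 44L)
  co <- simulateCohort(cfg)
  scr <- simulateScreen(cfg, co@metadata)
  dss <- computeDss(scr)
  truth <- attr(scr, "truth")
  meta <- co@metadata
  kmt <- meta$sample_id[meta$kmt2ar]
  pr <- proliferationFromScreen(scr)
  strat <- stratifyByProliferation(setNames(pr$ratio, pr$sample_id), kmt)
  mllga <- meta$sample_id[meta$group == "MLLGA"]
  mllgb <- meta$sample_id[meta$group == "MLLGB"]
  hi <- intersect(kmt, names(which(strat$labels == "High pro")))
  lo <- intersect(kmt, names(which(strat$labels == "Low pro")))
  for (d in truth$drug[truth$planted]) {
    sub <- dss[dss$drug == d, ]
    dSig <- abs(mean(sub$dss[sub$sample %in% mllga]) -
                mean(sub$dss[sub$sample %in% mllgb]))
    dPro <- abs(mean(sub$dss[sub$sample %in% hi]) -
                mean(sub$dss[sub$sample %in% lo]))
    expect_gte(dSig, dPro)
  }
})
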