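#' Normalize drug-screen wells to percent inhibition
#'
#' Converts raw luminescence to percent inhibition against the per-sample
#' plate controls: `inhibition = 100 * (vehicle - signal) / (vehicle -
#' positive)`, where `vehicle` is the mean negative-control (DMSO) signal and
#' `positive` the mean positive-control (full kill) signal of the sample's
#' plate at day 3. Vehicle-level signals map to 0 and positive-control-level
#' signals to 100; inhibition below 0 (stimulated growth) is kept.
#'
#' @param screen long-format screen data.frame (see [readScreen()]).
#' @return data.frame of drug wells: `drug`, `sample`, `dose_index`,
#'   `concentration`, `inhibition`, plus per-row `vehicle` and `positive`
#'   control means.
#' @export
normalizeWells <- function(screen) {
  d3 <- screen[screen$day == 3, , drop = FALSE]
  ctrl <- do.call(rbind, lapply(split(d3, d3$sample), function(s) {
    v <- mean(s$signal[s$well_type == "vehicle"])
    p <- mean(s$signal[s$well_type == "positive"])
    if (!is.finite(v) || !is.finite(p))
      stop("sample ", s$sample[1], " lacks vehicle or positive control wells")
    if (v <= p)
      stop("dead plate for sample ", s$sample[1],
           ": vehicle signal <= positive control signal")
    data.frame(sample = s$sample[1], vehicle = v, positive = p,
               stringsAsFactors = FALSE)
  }))
  wells <- d3[d3$well_type == "drug", , drop = FALSE]
  wells <- merge(wells, ctrl, by = "sample", sort = FALSE)
  wells$inhibition <- 100 * (wells$vehicle - wells$signal) /
    (wells$vehicle - wells$positive)
  wells[order(wells$drug, wells$sample, wells$dose_index),
        c("drug", "sample", "dose_index", "concentration", "inhibition",
          "vehicle", "positive")]
}

.fourPL <- function(x, bottom, top, log10ic50, slope) {
  bottom + (top - bottom) / (1 + 10^(slope * (log10ic50 - x)))
}

#' Fit a four-parameter log-logistic inhibition curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + 10^(slope *
#' (log10ic50 - x)))` to percent inhibition versus log10 molar concentration,
#' using bounded Levenberg-Marquardt ([minpack.lm::nlsLM]) from a fixed grid
#' of starting points (IC50 at the bottom, middle, top and mid-response point
#' of the dose range, crossed with three slope guesses); the best residual
#' wins. Bounds: bottom in \[-10, 50\], top in \[0, 120\], slope
#' in \[0.2, 10\], log10 IC50 within 3 decades of the dose range. Flat
#' response vectors short-circuit to a constant fit. The `converged` flag is
#' honest: `FALSE` when no start converged (the least-bad parameters are still
#' returned).
#'
#' @param conc dose concentrations (molar) or, if `logConc = TRUE`, log10
#'   concentrations.
#' @param inhibition percent inhibition at each dose.
#' @param logConc whether `conc` is already log10-transformed.
#' @return list with `bottom`, `top`, `log10ic50`, `slope`, `residual` (RSS),
#'   `converged`, and `atBound` (TRUE when a parameter sits on a bound).
#' @examples
#' x <- seq(-9, -5)
#' y <- 80 / (1 + 10^(1.2 * (-7 - x)))
#' fitDoseResponse(10^x, y)[c("top", "log10ic50", "slope")]
#' @export
fitDoseResponse <- function(conc, inhibition, logConc = FALSE) {
  x <- if (logConc) conc else log10(conc)
  y <- inhibition
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite dose or inhibition values")
  if (length(unique(x)) < 2L) stop("need >= 2 distinct doses")
  if (stats::sd(y) < 1e-9) {
    lev <- mean(y)
    return(list(bottom = lev, top = max(lev, 0), log10ic50 = mean(range(x)),
                slope = 1, residual = 0, converged = TRUE, atBound = FALSE))
  }
  lower <- c(bottom = -10, top = 0, log10ic50 = min(x) - 3, slope = 0.2)
  upper <- c(bottom = 50, top = 120, log10ic50 = max(x) + 3, slope = 10)
  # crude mid-response guess for the IC50 plus a fixed grid; local minima at
  # the parameter bounds are common with 5-point curves, so start widely
  midGuess <- x[which.min(abs(y - (min(y) + max(y)) / 2))]
  starts <- expand.grid(m = unique(c(min(x), mean(range(x)), max(x), midGuess)),
                        s = c(0.5, 1, 2.5), KEEP.OUT.ATTRS = FALSE)
  starts <- lapply(seq_len(nrow(starts)), function(i)
    list(bottom = max(min(y), -10), top = min(max(max(y), 1), 120),
         log10ic50 = starts$m[i], slope = starts$s[i]))
  best <- NULL
  anyConverged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ bottom + (top - bottom) /
                          (1 + 10^(slope * (log10ic50 - x))),
                        start = st, lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    conv <- fit$convInfo$isConv
    anyConverged <- anyConverged || isTRUE(conv)
    if (is.null(best) || rss < best$residual) {
      cf <- stats::coef(fit)
      best <- list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                   log10ic50 = unname(cf["log10ic50"]),
                   slope = unname(cf["slope"]), residual = rss,
                   converged = isTRUE(conv))
    }
  }
  if (is.null(best))
    stop("4PL fit failed from all starting points")
  best$converged <- best$converged && anyConverged
  tol <- 1e-6
  best$atBound <- any(abs(unlist(best[c("bottom", "top", "log10ic50", "slope")]) -
                          lower) < tol |
                      abs(unlist(best[c("bottom", "top", "log10ic50", "slope")]) -
                          upper) < tol)
  if (best$bottom > best$top) {  # keep the bottom <= top contract
    mid <- (best$bottom + best$top) / 2
    best$bottom <- best$top <- mid
    best$converged <- FALSE
  }
  best
}

# log(1 + 10^u), overflow-safe
.log1p10 <- function(u) ifelse(u > 30, u * log(10), log1p(10^u))

#' Drug sensitivity score from a fitted dose-response curve
#'
#' Normalized area between the fitted inhibition curve and an activity
#' threshold `t`, over the tested log10 concentration window `[x1, x2]`:
#' `A = integral over {x : y(x) >= t} of (y(x) - t) dx`, evaluated in closed
#' form from the 4PL antiderivative. `DSS1 = 100 * A / ((100 - t) * (x2 -
#' x1))` and `DSS2 = DSS1 * 100 / max(top, 1)`, which discounts curves that
#' never reach full inhibition. Scores are clipped to \[0, 100\]; a flat zero
#' curve scores 0.
#'
#' @param fit list from [fitDoseResponse()].
#' @param window numeric(2), `c(x1, x2)` log10 molar bounds of the tested
#'   doses.
#' @param t activity threshold in percent inhibition (default 10).
#' @param variant `"DSS2"` (default) or `"DSS1"`.
#' @return a single DSS value in \[0, 100\].
#' @examples
#' fit <- list(bottom = 0, top = 100, log10ic50 = -7, slope = 1)
#' drugSensitivityScore(fit, c(-9, -5))
#' @export
drugSensitivityScore <- function(fit, window, t = 10,
                                 variant = c("DSS2", "DSS1")) {
  variant <- match.arg(variant)
  x1 <- window[1]; x2 <- window[2]
  if (x1 >= x2) stop("integration window must have x1 < x2")
  if (t < 0 || t >= 100) stop("activity threshold t must lie in [0, 100)")
  b <- fit$bottom; top <- fit$top; m <- fit$log10ic50; s <- fit$slope
  if (abs(top - b) < 1e-12) {           # flat curve at level b
    A <- max(b - t, 0) * (x2 - x1)
  } else if (top <= t) {
    A <- 0
  } else {
    a <- if (t <= b) x1 else {
      xt <- m - log10((top - b) / (t - b) - 1) / s
      max(x1, xt)
    }
    if (a >= x2) {
      A <- 0
    } else {
      Fab <- function(x) b * x + (top - b) / (s * log(10)) * .log1p10(s * (x - m))
      A <- Fab(x2) - Fab(a) - t * (x2 - a)
      A <- max(A, 0)
    }
  }
  dss <- 100 * A / ((100 - t) * (x2 - x1))
  if (variant == "DSS2") dss <- dss * 100 / max(top, 1)
  min(max(dss, 0), 100)
}

#' Compute DSS for every drug-sample pair of a screen
#'
#' Normalizes wells ([normalizeWells()]), fits a 4PL per drug and sample
#' ([fitDoseResponse()]) and scores it ([drugSensitivityScore()]) over that
#' pair's tested dose window.
#'
#' @param screen long-format screen data.frame.
#' @param t activity threshold.
#' @param variant DSS variant.
#' @return data.frame per drug-sample pair: `drug`, `sample`, `dss`,
#'   `bottom`, `top`, `log10ic50`, `slope`, `converged`, `variant`, `t`.
#' @export
computeDss <- function(screen, t = 10, variant = c("DSS2", "DSS1")) {
  variant <- match.arg(variant)
  wells <- normalizeWells(screen)
  pieces <- split(wells, list(wells$drug, wells$sample), drop = TRUE)
  rows <- lapply(pieces, function(w) {
    fit <- fitDoseResponse(w$concentration, w$inhibition)
    win <- log10(range(w$concentration))
    data.frame(drug = w$drug[1], sample = w$sample[1],
               dss = drugSensitivityScore(fit, win, t = t, variant = variant),
               bottom = fit$bottom, top = fit$top,
               log10ic50 = fit$log10ic50, slope = fit$slope,
               converged = fit$converged, variant = variant, t = t,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$drug, out$sample), ]
}

#' Reshape a DSS table into a drug x sample matrix
#'
#' @param dssTable data.frame from [computeDss()].
#' @return numeric matrix, drugs as rows, samples as columns, `NA` where a
#'   pair was not tested.
#' @export
dssMatrix <- function(dssTable) {
  drugs <- sort(unique(dssTable$drug))
  samples <- sort(unique(dssTable$sample))
  m <- matrix(NA_real_, length(drugs), length(samples),
              dimnames = list(drugs, samples))
  m[cbind(match(dssTable$drug, drugs), match(dssTable$sample, samples))] <-
    dssTable$dss
  m
}

#' Proliferation rate from day-0 and day-3 luminescence
#'
#' The screening convention: `ratio = (day0 / day3) * 100`, so faster-growing
#' samples get *smaller* ratios. The convenience column `growth_fold =
#' day3 / day0` (not the screening statistic) is emitted for interpretation;
#' `ratio * growth_fold = 100` identically.
#'
#' @param day0,day3 positive luminescence readings (vectors of equal length).
#' @param sampleIds optional sample ids.
#' @return data.frame (`sample_id`, `luminescence_day0`, `luminescence_day3`,
#'   `ratio`, `growth_fold`).
#' @examples
#' proliferationRate(100, 200)  # ratio 50, growth_fold 2
#' @export
proliferationRate <- function(day0, day3, sampleIds = NULL) {
  if (any(day0 <= 0) || any(day3 <= 0))
    stop("luminescence values must be positive")
  if (is.null(sampleIds)) sampleIds <- as.character(seq_along(day0))
  data.frame(sample_id = sampleIds, luminescence_day0 = day0,
             luminescence_day3 = day3, ratio = day0 / day3 * 100,
             growth_fold = day3 / day0, stringsAsFactors = FALSE)
}

#' Proliferation rates from a raw screen table
#'
#' Uses the mean untreated luminescence at day 0 and the mean vehicle
#' (untreated, day 3) luminescence per sample.
#'
#' @param screen long-format screen data.frame.
#' @return data.frame as [proliferationRate()].
#' @export
proliferationFromScreen <- function(screen) {
  per <- lapply(split(screen, screen$sample), function(s) {
    d0 <- mean(s$signal[s$well_type == "untreated" & s$day == 0])
    d3 <- mean(s$signal[s$well_type == "vehicle" & s$day == 3])
    if (!is.finite(d0) || !is.finite(d3))
      stop("sample ", s$sample[1], " lacks day-0 untreated or day-3 vehicle wells")
    c(d0 = d0, d3 = d3)
  })
  proliferationRate(vapply(per, `[`, 0, "d0"), vapply(per, `[`, 0, "d3"),
                    sampleIds = names(per))
}

#' Compare drug response between two sample groups
#'
#' Per drug, an unpaired two-sided Student's t-test on DSS values between the
#' groups, with Benjamini-Hochberg adjustment across tested drugs. Drugs
#' observed in fewer than `minN` samples of either group are excluded and
#' listed. An optional cohort-level pre-filter keeps only drugs tested in at
#' least `cohortMinN` samples overall (the "tested in at least 30 patients"
#' style rule).
#'
#' @param dssTable data.frame from [computeDss()].
#' @param groupA,groupB disjoint character vectors of sample ids.
#' @param minN per-group observation floor (default 5).
#' @param cohortMinN optional cohort-wide floor applied before the per-group
#'   filter.
#' @return list with `results` (data.frame `drug`, `mean_a`, `mean_b`,
#'   `mean_diff`, `t_stat`, `p`, `fdr`, `n_a`, `n_b`, sorted by p) and
#'   `excluded` (character vector of drugs dropped by the filters).
#' @export
compareDrugResponse <- function(dssTable, groupA, groupB, minN = 5L,
                                cohortMinN = NULL) {
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  tab <- dssTable[dssTable$sample %in% c(groupA, groupB), , drop = FALSE]
  excluded <- character()
  if (!is.null(cohortMinN)) {
    nAll <- table(dssTable$drug)
    drop <- names(nAll)[nAll < cohortMinN]
    excluded <- c(excluded, drop)
    tab <- tab[!tab$drug %in% drop, , drop = FALSE]
  }
  if (!nrow(tab))
    return(list(results = data.frame(), excluded = unique(excluded)))
  # one row per drug, NA where a pair was not tested; the shared row-wise
  # t-test then applies the per-group observation filter uniformly
  m <- dssMatrix(tab)
  tt <- ttestTwoGroup(m, intersect(groupA, colnames(m)),
                      intersect(groupB, colnames(m)),
                      minObs = max(2L, as.integer(minN)))
  excluded <- c(excluded, tt$feature_id[!tt$tested])
  tt <- tt[tt$tested, , drop = FALSE]
  if (!nrow(tt))
    return(list(results = data.frame(), excluded = unique(excluded)))
  res <- data.frame(drug = tt$feature_id,
                    mean_a = tt$log2fc + 0,  # placeholder, replaced below
                    mean_b = 0, mean_diff = tt$log2fc, t_stat = tt$t_stat,
                    p = tt$p, fdr = bhAdjust(tt$p), n_a = tt$n_a,
                    n_b = tt$n_b, stringsAsFactors = FALSE)
  gm <- function(ids) rowMeans(m[res$drug, intersect(ids, colnames(m)),
                                 drop = FALSE], na.rm = TRUE)
  res$mean_a <- gm(groupA)
  res$mean_b <- gm(groupB)
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  list(results = res, excluded = unique(excluded))
}

#' Stratify samples by proliferation rate relative to a reference group
#'
#' The threshold is the arithmetic mean proliferation rate over the reference
#' set (e.g. the KMT2A-rearranged patients). Samples strictly above it are
#' labelled `High pro`, strictly below `Low pro`; rates exactly equal to the
#' mean go to `High pro` (documented tie rule).
#'
#' @param rates named numeric vector, sample id -> proliferation rate.
#' @param referenceIds sample ids defining the threshold (must be nonempty and
#'   have rates).
#' @return list with `labels` (named character vector over all rated samples)
#'   and `threshold`.
#' @examples
#' r <- c(a = 10, b = 20, c = 30)
#' stratifyByProliferation(r, names(r))
#' @export
stratifyByProliferation <- function(rates, referenceIds) {
  referenceIds <- intersect(referenceIds, names(rates))
  if (!length(referenceIds)) stop("empty reference set")
  thr <- mean(rates[referenceIds])
  list(labels = stats::setNames(
         ifelse(rates >= thr, "High pro", "Low pro"), names(rates)),
       threshold = thr)
}
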