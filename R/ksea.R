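#' Kinase-substrate enrichment z-score over a vector of feature scores
#'
#' For each kinase with substrate set S observed among the scored features
#' (m = |S observed|), the activity z-score is
#' `z = (mean(S) - mean(all)) * sqrt(m) / sd(all)`: the mean substrate change
#' relative to the global score distribution, in standard errors. A two-sided
#' normal p-value is attached and Benjamini-Hochberg adjustment applied across
#' the kinases that pass `minSubstrates`. Kinases with fewer observed
#' substrates are reported with `m` and `NA` statistics.
#'
#' @param values named numeric vector of per-feature scores (e.g. log2 fold
#'   changes or row-centered intensities); `NA` entries are dropped.
#' @param map named list: kinase -> character vector of substrate feature ids.
#' @param minSubstrates minimum observed substrates (default 3).
#' @return data.frame per kinase: `kinase`, `z`, `m`, `p`, `fdr`.
#' @examples
#' vals <- stats::setNames(c(1, 1, 1, 1, rep(0, 96)), paste0("f", 1:100))
#' # 4 substrates at mean 1 against a null background
#' kseaZscore(vals, list(K = paste0("f", 1:4)))
#' @export
kseaZscore <- function(values, map, minSubstrates = 3L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 observed feature scores")
  mu <- mean(values)
  sdev <- stats::sd(values)
  if (sdev == 0) stop("degenerate input: global score sd is 0")
  res <- lapply(names(map), function(kin) {
    s <- values[intersect(map[[kin]], names(values))]
    m <- length(s)
    if (m < minSubstrates)
      return(data.frame(kinase = kin, z = NA_real_, m = m, p = NA_real_,
                        stringsAsFactors = FALSE))
    z <- (mean(s) - mu) * sqrt(m) / sdev
    data.frame(kinase = kin, z = z, m = m, p = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bhAdjust(out$p[ok])
  out
}

#' Per-sample kinase activity matrix
#'
#' Row-centers the intensity matrix (each feature minus its mean across all
#' samples, giving per-sample log2 deviations) and applies [kseaZscore()] to
#' every sample column. Expects a normalized matrix (see
#' [normalizeIntensities()]).
#'
#' @param x an [OmicsMatrix-class].
#' @param map kinase -> substrate feature id list (e.g. from [readGmt()]).
#' @param minSubstrates minimum observed substrates per kinase and sample.
#' @return list of kinase x sample matrices: `z`, `m`, `p`, `fdr` (BH across
#'   kinases within each sample).
#' @export
kseaPerSample <- function(x, map, minSubstrates = 3L) {
  v <- intensities(x)
  centered <- v - rowMeans(v, na.rm = TRUE)
  kin <- names(map)
  mk <- function() matrix(NA_real_, length(kin), ncol(v),
                          dimnames = list(kin, colnames(v)))
  out <- list(z = mk(), m = mk(), p = mk(), fdr = mk())
  for (j in seq_len(ncol(v))) {
    res <- kseaZscore(centered[, j], map, minSubstrates = minSubstrates)
    out$z[, j] <- res$z
    out$m[, j] <- res$m
    out$p[, j] <- res$p
    out$fdr[, j] <- res$fdr
  }
  out
}

#' Kinase activities for a differential contrast
#'
#' Applies [kseaZscore()] to the log2 fold-change vector of a differential
#' result table, giving one activity per kinase for the contrast.
#'
#' @param results data.frame from [ttestTwoGroup()].
#' @param map kinase -> substrate feature id list.
#' @param minSubstrates minimum observed substrates.
#' @return data.frame as [kseaZscore()].
#' @export
kseaContrast <- function(results, map, minSubstrates = 3L) {
  vals <- stats::setNames(results$log2fc, results$feature_id)
  kseaZscore(vals, map, minSubstrates = minSubstrates)
}

#' Write a kinase activity matrix to TSV
#'
#' @param activity list returned by [kseaPerSample()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeKinaseActivity <- function(activity, path) {
  z <- activity$z
  out <- data.frame(kinase = rownames(z), z, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
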