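.permCache <- new.env(parent = emptyenv())

# all permutations of 1:n as an (n! x n) integer matrix, cached
.allPermutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.permCache[[key]])) return(.permCache[[key]])
  perm <- if (n == 1L) matrix(1L) else {
    sub <- .allPermutations(n - 1L)
    p <- nrow(sub)
    out <- matrix(0L, n * p, n)
    rest <- seq_len(n)
    for (i in seq_len(n)) {
      out[(i - 1L) * p + seq_len(p), 1L] <- i
      out[(i - 1L) * p + seq_len(p), -1L] <- matrix(rest[-i][sub], p)
    }
    out
  }
  .permCache[[key]] <- perm
  perm
}

.spearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Spearman rank correlation with small-sample exact p-values
#'
#' Rho is the Pearson correlation of midranks (average ranks on ties). The
#' p-value uses the t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`
#' on `n - 2` degrees of freedom for `n > 9`, and an exact two-sided
#' permutation distribution (all `n!` orderings) for `n <= 9`, where the
#' approximation is poor and enumeration cheap. Pairs with a missing value in
#' either vector are dropped first.
#'
#' @param x,y paired numeric vectors.
#' @param minPairs minimum complete pairs (default 5); fewer is an error.
#' @return list with `rho`, `p`, `n` (complete pairs used) and `method`
#'   (`"exact"` or `"t-approximation"`).
#' @examples
#' spearmanTest(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearmanTest <- function(x, y, minPairs = 5L) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < minPairs)
    stop(sprintf("only %d complete pairs; minPairs = %d", n, minPairs))
  rho <- .spearmanRho(x, y)
  if (is.na(rho))
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "degenerate"))
  if (n <= 9L) {
    rx <- rank(x); ry <- rank(y)
    perms <- .allPermutations(n)
    # rho for every permutation of one margin, vectorized via cross-products
    RX <- matrix(rx[perms], nrow(perms))
    num <- RX %*% ry - n * mean(rx) * mean(ry)
    den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    rhoPerm <- as.vector(num) / den
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    return(list(rho = rho, p = p, n = n, method = "exact"))
  }
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n, method = "t-approximation")
}

#' Correlate drug response with molecular features
#'
#' Pairwise Spearman correlation between every drug row of a DSS matrix and
#' every feature row of an omics matrix, over the samples shared by the two
#' tables (pairwise-complete per cell). Cells with fewer than `minPairs`
#' complete pairs are reported untested (`NA`), not errors. By default no
#' multiple-testing adjustment is applied inside the matrix (per-test
#' significance, as correlation-plot crosses report it); `adjust = "BH"`
#' adjusts within each drug row.
#'
#' @param dss drug x sample numeric matrix (see [dssMatrix()]), or a DSS table
#'   data.frame from [computeDss()].
#' @param x an [OmicsMatrix-class] or feature x sample matrix.
#' @param alpha significance level for the mask (default 0.05).
#' @param adjust `"none"` (default) or `"BH"` (within drug row).
#' @param minPairs minimum complete pairs per cell (default 5).
#' @return list of drug x feature matrices `rho`, `p`, `fdr` (only if
#'   adjusted), `n`, and logical `significant` (p or fdr below `alpha`).
#' @export
correlateMatrix <- function(dss, x, alpha = 0.05, adjust = c("none", "BH"),
                            minPairs = 5L) {
  adjust <- match.arg(adjust)
  if (is.data.frame(dss)) dss <- dssMatrix(dss)
  v <- if (is(x, "OmicsMatrix")) intensities(x) else as.matrix(x)
  shared <- intersect(colnames(dss), colnames(v))
  if (length(shared) < minPairs)
    stop("fewer than minPairs samples shared between DSS and omics tables")
  dss <- dss[, shared, drop = FALSE]
  v <- v[, shared, drop = FALSE]
  drugs <- rownames(dss); feats <- rownames(v)
  mk <- function() matrix(NA_real_, length(drugs), length(feats),
                          dimnames = list(drugs, feats))
  rho <- mk(); p <- mk(); n <- mk()
  for (i in seq_along(drugs)) {
    di <- dss[i, ]
    for (j in seq_along(feats)) {
      ok <- !is.na(di) & !is.na(v[j, ])
      n[i, j] <- sum(ok)
      if (n[i, j] < minPairs) next
      st <- spearmanTest(di[ok], v[j, ok], minPairs = minPairs)
      rho[i, j] <- st$rho
      p[i, j] <- st$p
    }
  }
  out <- list(rho = rho, p = p, n = n, alpha = alpha, adjust = adjust)
  if (adjust == "BH") {
    fdr <- mk()
    for (i in seq_along(drugs)) {
      ok <- !is.na(p[i, ])
      if (any(ok)) fdr[i, ok] <- bhAdjust(p[i, ok])
    }
    out$fdr <- fdr
    out$significant <- !is.na(fdr) & fdr < alpha
  } else {
    out$significant <- !is.na(p) & p < alpha
  }
  out
}

#' Extract positively and negatively correlated feature sets for a drug
#'
#' Splits the significant cells of a drug's correlation row by the sign of
#' rho, yielding the feature sets that feed [enrichSets()].
#'
#' @param cm list from [correlateMatrix()].
#' @param drug drug (row) id.
#' @param alpha significance level; defaults to the matrix's own.
#' @return list with `positive` and `negative` character vectors (disjoint).
#' @export
correlatedSets <- function(cm, drug, alpha = NULL) {
  if (!drug %in% rownames(cm$rho)) stop("unknown drug: ", drug)
  if (is.null(alpha)) alpha <- cm$alpha
  pv <- if (!is.null(cm$fdr)) cm$fdr[drug, ] else cm$p[drug, ]
  rho <- cm$rho[drug, ]
  sig <- !is.na(pv) & pv < alpha
  list(positive = names(which(sig & rho > 0)),
       negative = names(which(sig & rho < 0)))
}

#' Write a correlation matrix in long format
#'
#' @param cm list from [correlateMatrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeCorrelationMatrix <- function(cm, path) {
  long <- expand.grid(row = rownames(cm$rho), col = colnames(cm$rho),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$rho <- as.vector(cm$rho)
  long$p <- as.vector(cm$p)
  long$n <- as.vector(cm$n)
  long$significant <- as.vector(cm$significant)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
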