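#' Per-feature two-group t-test on an intensity matrix
#'
#' Classic unpaired two-sided Student's t-test (pooled variance by default,
#' Welch optional) computed row-wise over observed values only. Features with
#' fewer than `minObs` observed values in either group are reported but marked
#' untested (`NA` statistics). The log2 fold change is the difference of group
#' means of the already-log2 data, `mean(groupA) - mean(groupB)`.
#'
#' Degenerate rows where both groups are constant get `t = 0, p = 1` when the
#' means are equal and `t = +/-Inf, p = 0` otherwise.
#'
#' @param x an [OmicsMatrix-class] or numeric matrix (features x samples).
#' @param groupA,groupB disjoint character vectors of sample ids.
#' @param minObs minimum observed values per group for a feature to be tested
#'   (default 3).
#' @param varEqual pooled-variance Student's test if `TRUE` (default), Welch
#'   otherwise.
#' @return data.frame with one row per feature: `feature_id`, `log2fc`,
#'   `t_stat`, `p`, `fdr` (Benjamini-Hochberg over tested features), `n_a`,
#'   `n_b`, `tested`.
#' @examples
#' m <- matrix(c(4, 5, 6, 1, 2, 3), 1, 6,
#'             dimnames = list("f1", paste0("s", 1:6)))
#' ttestTwoGroup(m, paste0("s", 1:3), paste0("s", 4:6), minObs = 2)
#' @export
ttestTwoGroup <- function(x, groupA, groupB, minObs = 3L, varEqual = TRUE) {
  v <- if (is(x, "OmicsMatrix")) intensities(x) else as.matrix(x)
  if (length(intersect(groupA, groupB)))
    stop("groups overlap: ", paste(intersect(groupA, groupB), collapse = ", "))
  unknown <- setdiff(c(groupA, groupB), colnames(v))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 samples")
  if (minObs < 2L) stop("minObs must be >= 2")

  A <- v[, groupA, drop = FALSE]
  B <- v[, groupB, drop = FALSE]
  nA <- rowSums(!is.na(A))
  nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE)
  mB <- rowMeans(B, na.rm = TRUE)
  ssA <- rowSums((A - mA)^2, na.rm = TRUE)
  ssB <- rowSums((B - mB)^2, na.rm = TRUE)
  tested <- nA >= minObs & nB >= minObs

  lfc <- mA - mB
  tstat <- p <- rep(NA_real_, nrow(v))
  if (any(tested)) {
    na <- nA[tested]; nb <- nB[tested]
    d <- lfc[tested]
    if (varEqual) {
      df <- na + nb - 2
      sp2 <- (ssA[tested] + ssB[tested]) / df
      se <- sqrt(sp2 * (1 / na + 1 / nb))
    } else {
      va <- ssA[tested] / (na - 1)
      vb <- ssB[tested] / (nb - 1)
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
      df[se == 0] <- na[se == 0] + nb[se == 0] - 2  # degenerate: constant rows
    }
    tt <- d / se
    # constant rows: se == 0
    tt[se == 0 & d == 0] <- 0
    tt[se == 0 & d != 0] <- sign(d[se == 0 & d != 0]) * Inf
    pp <- 2 * stats::pt(-abs(tt), df)
    pp[is.infinite(tt)] <- 0
    pp[tt == 0 & se == 0] <- 1
    tstat[tested] <- tt
    p[tested] <- pp
  }
  lfc[!tested] <- ifelse(nA[!tested] >= 1 & nB[!tested] >= 1, lfc[!tested],
                         NA_real_)
  fdr <- rep(NA_real_, nrow(v))
  fdr[tested] <- bhAdjust(p[tested])
  data.frame(feature_id = rownames(v), log2fc = lfc, t_stat = tstat, p = p,
             fdr = fdr, n_a = nA, n_b = nB, tested = tested,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false discovery rate control; a thin wrapper around
#' [stats::p.adjust] that validates its input. Output order matches input
#' order and `fdr >= p` always holds.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted values, same length and order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA")
  stats::p.adjust(p, method = "BH")
}

#' Count significantly changed features under a p-value / fold-change rule
#'
#' Implements the counting rule used for differential phosphopeptide tallies:
#' a feature counts as up when `p < pMax` and `log2fc > lfcMin`, and as down
#' when `p < pMax` and `log2fc < -lfcMin`. Inequalities are strict. Untested
#' features never count.
#'
#' @param results data.frame from [ttestTwoGroup()] (needs `p`, `log2fc`,
#'   and optionally `tested`).
#' @param pMax p-value ceiling (default 0.05).
#' @param lfcMin absolute log2 fold-change floor (default 0.8).
#' @return named integer vector `c(n_up, n_down)`.
#' @examples
#' res <- data.frame(log2fc = c(1, 0.5, -0.9, 0.8),
#'                   p = c(0.01, 0.01, 0.04, 0.06))
#' countSignificant(res, pMax = 0.05, lfcMin = 0.7)
#' @export
countSignificant <- function(results, pMax = 0.05, lfcMin = 0.8) {
  if (pMax <= 0 || pMax > 1) stop("pMax must lie in (0, 1]")
  if (lfcMin < 0) stop("lfcMin must be >= 0")
  ok <- if (is.null(results$tested)) rep(TRUE, nrow(results)) else results$tested
  ok <- ok & !is.na(results$p) & !is.na(results$log2fc)
  sig <- ok & results$p < pMax
  c(n_up = sum(sig & results$log2fc > lfcMin),
    n_down = sum(sig & results$log2fc < -lfcMin))
}

#' Count significant features restricted to an annotation set
#'
#' As [countSignificant()] but only over features whose annotated gene (or the
#' feature id itself, if `results` has no `gene` column) belongs to the named
#' set — e.g. counting drug-responsive phosphopeptides within "nucleolus".
#'
#' @param results data.frame from [ttestTwoGroup()]; a `gene` column is used
#'   for set membership when present, otherwise `feature_id`.
#' @param sets named list of character vectors (e.g. from [readGmt()]).
#' @param setName which set to restrict to.
#' @inheritParams countSignificant
#' @return named integer vector `c(n_up, n_down)`.
#' @export
countInSet <- function(results, sets, setName, pMax = 0.05, lfcMin = 0.8) {
  if (!setName %in% names(sets)) stop("unknown set name: ", setName)
  key <- if (!is.null(results$gene)) results$gene else results$feature_id
  countSignificant(results[key %in% sets[[setName]], , drop = FALSE],
                   pMax = pMax, lfcMin = lfcMin)
}

#' Hypergeometric over-representation of feature sets
#'
#' One-sided (upper tail) hypergeometric test per set: given `length(selected)`
#' draws from a universe, is the overlap with each set larger than chance?
#' P-values are adjusted across sets with Benjamini-Hochberg. This is an exact
#' replacement for web-tool "modified Fisher" enrichment; no EASE-style
#' correction is applied.
#'
#' @param selected character vector of selected feature ids (a subset of
#'   `universe`).
#' @param universe character vector of all tested feature ids.
#' @param sets named list of character vectors; members outside the universe
#'   are ignored.
#' @return data.frame per set: `set`, `overlap`, `set_size` (within universe),
#'   `p`, `fdr`, ordered as `sets`.
#' @examples
#' enrichSets(c("a", "b"), letters[1:10], list(S1 = c("a", "b", "c")))
#' @export
enrichSets <- function(selected, universe, sets) {
  if (!length(sets)) stop("sets must be nonempty")
  if (!all(selected %in% universe))
    stop("selected features must be a subset of the universe")
  universe <- unique(universe)
  selected <- unique(selected)
  N <- length(universe)
  n <- length(selected)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- if (n == 0L || K == 0L) 1
         else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bhAdjust(out$p)
  out
}
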