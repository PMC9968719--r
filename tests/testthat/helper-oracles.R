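# Independent brute-force oracles used to check the package's statistics.
# These deliberately re-derive each quantity by enumeration or fine-grid
# integration, sharing no code with the implementation under test.

# plain recursive permutation enumeration (independent of the package's)
permEnumerate <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permEnumerate(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# exhaustive two-sided permutation p-value for Spearman rho on midranks
spearmanPermOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  perms <- permEnumerate(seq_along(y))
  rhos <- vapply(perms, function(p) cor(rx, ry[p]), 0)
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# exact enrichment p by enumerating every possible selection of size n
hypergeomOracle <- function(k, K, N, n) {
  sets <- utils::combn(N, n)
  inSet <- seq_len(K)  # WLOG the set is the first K elements
  hits <- apply(sets, 2L, function(s) sum(s %in% inSet))
  mean(hits >= k)
}

# fine-grid trapezoid integration of the thresholded 4PL area
dssTrapezoidOracle <- function(fit, window, t = 10, variant = "DSS2",
                               nGrid = 1e5) {
  x <- seq(window[1], window[2], length.out = nGrid)
  y <- fit$bottom + (fit$top - fit$bottom) /
    (1 + 10^(fit$slope * (fit$log10ic50 - x)))
  h <- pmax(y - t, 0)
  A <- sum((h[-1] + h[-nGrid]) / 2) * diff(x)[1]
  dss <- 100 * A / ((100 - t) * diff(window))
  if (variant == "DSS2") dss <- dss * 100 / max(fit$top, 1)
  min(max(dss, 0), 100)
}

# a small cohort configuration for fast tests
smallConfig <- function(...) {
  args <- list(
    nPerGroup = c(MLLGA = 6L, MLLGB = 3L, `No-MLL` = 10L, Normal = 3L),
    nFeatures = 300L, nSignatureFeatures = 8L, nKinases = 5L,
    substratesPerKinase = 10L, nDrugs = 6L, plantedSensitiveDrugs = 2L,
    seed = 11L)
  user <- list(...)
  args[names(user)] <- user
  do.call(simulationConfig, args)
}
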