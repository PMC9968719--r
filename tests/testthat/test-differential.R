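test_that("the pooled t-test matches hand computation and textbook cases", {
  m <- matrix(c(4, 5, 6, 1, 2, 3), 1, 6,
              dimnames = list("f1", sprintf("s%d", 1:6)))
  res <- ttestTwoGroup(m, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  # pooled sd = 1, se = sqrt(2/3), t = 3 / sqrt(2/3)
  expect_equal(res$log2fc, 3)
  expect_equal(res$t_stat, 3 / sqrt(2 / 3))
  expect_equal(res$p, 2 * pt(-3 / sqrt(2 / 3), 4))
  # identical groups
  m2 <- matrix(c(1, 2, 3, 1, 2, 3), 1, 6,
               dimnames = list("f1", sprintf("s%d", 1:6)))
  res2 <- ttestTwoGroup(m2, sprintf("s%d", 1:3), sprintf("s%d", 4:6))
  expect_equal(res2$t_stat, 0)
  expect_equal(res2$p, 1)
  expect_equal(res2$log2fc, 0)
})

test_that("t statistics agree with stats::t.test on random missing-data rows", {
  set.seed(7)
  for (i in 1:100) {
    nA <- sample(3:8, 1); nB <- sample(3:8, 1)
    a <- rnorm(nA); b <- rnorm(nB, sample(c(0, 1), 1))
    v <- matrix(c(a, b), 1, dimnames = list("f",
                c(sprintf("a%d", seq_len(nA)), sprintf("b%d", seq_len(nB)))))
    welch <- i %% 2 == 0
    res <- ttestTwoGroup(v, sprintf("a%d", seq_len(nA)),
                         sprintf("b%d", seq_len(nB)), minObs = 3,
                         varEqual = !welch)
    ref <- t.test(a, b, var.equal = !welch)
    expect_equal(res$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
    expect_equal(res$log2fc, unname(diff(rev(ref$estimate))), tolerance = 1e-10)
  }
})

test_that("group and observation-count preconditions are enforced", {
  m <- matrix(rnorm(12), 2, 6,
              dimnames = list(c("f1", "f2"), sprintf("s%d", 1:6)))
  expect_error(ttestTwoGroup(m, c("s1", "s2"), c("s2", "s3")), "overlap")
  expect_error(ttestTwoGroup(m, c("s1", "sX"), c("s3", "s4")), "sX")
  expect_error(ttestTwoGroup(m, "s1", c("s3", "s4")), "at least 2")
  # a feature observed in one sample of group A is untested
  m[1, 1:2] <- NA
  res <- ttestTwoGroup(m, sprintf("s%d", 1:3), sprintf("s%d", 4:6), minObs = 3)
  expect_false(res$tested[1])
  expect_true(is.na(res$p[1]))
  expect_true(res$tested[2])
})

test_that("BH adjustment reproduces the step-up computation and its invariants", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(8)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    f <- bhAdjust(p)
    expect_true(all(f >= p))
    # monotone non-decreasing in sorted-p order
    expect_true(all(diff(f[order(p)]) >= -1e-15))
    # independent step-up oracle
    n <- length(p); o <- order(p)
    oracle <- rev(cummin(rev(p[o] * n / seq_len(n))))[order(o)]
    expect_equal(f, pmin(oracle, 1))
  }
})

test_that("the counting rule applies strict thresholds and is monotone", {
  res <- data.frame(log2fc = c(1.0, 0.5, -0.9, 0.8),
                    p = c(0.01, 0.01, 0.04, 0.06))
  expect_equal(countSignificant(res, pMax = 0.05, lfcMin = 0.7),
               c(n_up = 1L, n_down = 1L))
  # boundary values do not count (strict inequalities)
  edge <- data.frame(log2fc = c(0.8, 0.81), p = c(0.05, 0.049))
  expect_equal(countSignificant(edge, pMax = 0.05, lfcMin = 0.8),
               c(n_up = 1L, n_down = 0L))
  expect_equal(countSignificant(res[0, ]), c(n_up = 0L, n_down = 0L))
  expect_error(countSignificant(res, pMax = 0), "pMax")
  set.seed(9)
  base <- data.frame(log2fc = rnorm(500), p = runif(500))
  for (i in 1:10) {
    r1 <- c(runif(1, 0.01, 0.1), runif(1, 0, 1.5))
    strict <- countSignificant(base, pMax = r1[1], lfcMin = r1[2])
    relaxed <- countSignificant(base, pMax = min(r1[1] * 2, 1),
                                lfcMin = r1[2] / 2)
    expect_true(all(relaxed >= strict))
  }
})

test_that("set-restricted counts honour annotation membership", {
  res <- data.frame(feature_id = sprintf("f%d", 1:4),
                    gene = c("A", "A", "B", "C"),
                    log2fc = c(1, -1, 1, 1), p = c(0.01, 0.01, 0.01, 0.01))
  sets <- list(SA = c("A"), SD = c("D"), ALL = c("A", "B", "C"))
  expect_equal(countInSet(res, sets, "SA", lfcMin = 0.7),
               c(n_up = 1L, n_down = 1L))
  expect_equal(countInSet(res, sets, "SD", lfcMin = 0.7),
               c(n_up = 0L, n_down = 0L))
  expect_equal(countInSet(res, sets, "ALL", lfcMin = 0.7),
               countSignificant(res, lfcMin = 0.7))
  expect_error(countInSet(res, sets, "nope"), "unknown set")
})

test_that("hypergeometric enrichment equals brute-force enumeration", {
  set.seed(10)
  universe <- sprintf("g%02d", 1:12)
  for (i in 1:30) {
    K <- sample(2:6, 1); n <- sample(2:6, 1)
    set <- universe[seq_len(K)]
    selected <- sample(universe, n)
    res <- enrichSets(selected, universe, list(S = set))
    k <- length(intersect(set, selected))
    expect_equal(res$p, hypergeomOracle(k, K, 12, n), tolerance = 1e-12)
  }
  # a fully selected set is maximally enriched
  res <- enrichSets(universe[1:3], universe, list(S = universe[1:3]))
  expect_equal(res$p, 1 / choose(12, 3), tolerance = 1e-12)
  expect_equal(enrichSets(character(), universe, list(S = universe[1:3]))$p, 1)
  expect_error(enrichSets("zz", universe, list(S = universe[1:3])), "subset")
})
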