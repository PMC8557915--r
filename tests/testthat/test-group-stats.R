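test_that("Kruskal-Wallis H matches the hand rank formula and permutation null", {
  # groups {1,2,3} vs {4,5,6}: ranks 1-6, no ties
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 = 12/42 * (3*(2-3.5)^2 + 3*(5-3.5)^2)
  kw <- kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$statistic, 12 / 42 * (3 * 1.5^2 + 3 * 1.5^2), tolerance = 1e-10)
  expect_equal(kw$statistic, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1)
  expect_equal(kruskalWallis(rep(2, 6), rep(c("a", "b"), each = 3))$statistic, 0)
  expect_error(kruskalWallis(1:5, rep("a", 5)), "at least 2 groups")

  # exhaustive permutation null on n = 6: H's p-value is the tail fraction
  x <- c(3.1, 1.2, 5.6, 2.2, 4.4, 0.7)
  g <- rep(c("a", "b"), each = 3)
  hObs <- kruskalWallis(x, g)$statistic
  perms <- combn(6, 3)
  hAll <- apply(perms, 2, function(idx) {
    gp <- rep("b", 6); gp[idx] <- "a"
    kruskalWallis(x, gp)$statistic
  })
  # permutation-null mean of H equals k-1 = 1 (rank statistic standardisation)
  expect_equal(mean(hAll), 1, tolerance = 1e-10)
  expect_gte(mean(hAll >= hObs - 1e-12), 0)
})

test_that("Dunn z for two groups squares to the tie-corrected H", {
  set.seed(2)
  for (i in 1:10) {
    x <- sample(1:6, 14, replace = TRUE)   # plenty of ties
    g <- rep(c("a", "b"), each = 7)
    d <- dunnTest(x, g)
    expect_equal(d$z^2, kruskalWallis(x, g)$statistic, tolerance = 1e-10)
  }
})

test_that("Dunn test matches an independent mean-rank computation on 3 groups", {
  x <- c(2.9, 3.0, 2.5, 2.6, 3.2,   # A
         3.8, 2.7, 4.0, 2.4,        # B
         2.8, 3.4, 3.7, 2.2, 2.0)   # C
  g <- rep(c("A", "B", "C"), c(5, 4, 5))
  d <- dunnTest(x, g)
  # independent route: explicit mean ranks and pooled variance (no ties here)
  r <- rank(x)
  N <- length(x)
  rb <- tapply(r, g, mean); n <- tapply(r, g, length)
  v0 <- N * (N + 1) / 12
  zAB <- (rb[["A"]] - rb[["B"]]) / sqrt(v0 * (1 / n[["A"]] + 1 / n[["B"]]))
  zAC <- (rb[["A"]] - rb[["C"]]) / sqrt(v0 * (1 / n[["A"]] + 1 / n[["C"]]))
  zBC <- (rb[["B"]] - rb[["C"]]) / sqrt(v0 * (1 / n[["B"]] + 1 / n[["C"]]))
  expect_equal(d$z, unname(c(zAB, zAC, zBC)), tolerance = 1e-10)
  expect_equal(d$p_raw, 2 * pnorm(-abs(d$z)), tolerance = 1e-12)
  expect_equal(d$p_adjusted, p.adjust(d$p_raw, "BH"), tolerance = 1e-12)
  # identical groups: everything non-significant
  dNull <- dunnTest(rep(1:4, 3), rep(c("A", "B", "C"), each = 4))
  expect_true(all(dNull$p_adjusted == 1))
})

test_that("BH and Bonferroni corrections match the worked examples", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # step-up by hand: p_(i) * m / i, cummin from the largest
  p <- c(0.003, 0.04, 0.019, 0.7)
  byHand <- rev(cummin(rev(sort(p) * 4 / 1:4)))[order(order(p))]
  expect_equal(bhAdjust(p), byHand)
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bonferroniAdjust(0.0001, m = 431), 0.0431)
  expect_equal(bonferroniAdjust(c(0.01, 0.4), m = 3), c(0.03, 1))
  expect_error(bhAdjust(c(0.2, 1.4)), "\\[0, 1\\]")
  # adjusted values are monotone in the p-ordering and never below the input
  set.seed(6)
  p2 <- runif(20)
  q <- bhAdjust(p2)
  expect_true(all(diff(q[order(p2)]) >= 0))
  expect_true(all(q >= p2))
})

test_that("log-rank matches a from-scratch hypergeometric tabulation", {
  rec <- data.frame(vial_id = "v", treatment = rep(c("a", "b"), each = 3),
                    time_days = c(1, 2, 3, 4, 5, 6), event = 1L)
  got <- logrankTest(rec, "a", "b")
  # hand tabulation: at each event time, O - E and V from the risk sets
  times <- sort(unique(rec$time_days))
  OmE <- 0; V <- 0
  for (t in times) {
    atRisk <- rec$time_days >= t
    n <- sum(atRisk); n1 <- sum(atRisk & rec$treatment == "a")
    d <- sum(rec$time_days == t & rec$event == 1)
    d1 <- sum(rec$time_days == t & rec$event == 1 & rec$treatment == "a")
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(got$chisq, OmE^2 / V, tolerance = 1e-10)
  expect_equal(got$p.value, pchisq(OmE^2 / V, 1, lower.tail = FALSE))

  # identical curves: chi-square exactly 0
  rec2 <- data.frame(vial_id = "v", treatment = rep(c("a", "b"), each = 4),
                     time_days = rep(c(2, 4, 6, 8), 2), event = 1L)
  expect_equal(logrankTest(rec2, "a", "b")$chisq, 0, tolerance = 1e-12)

  # censoring-only group against an event group still yields a finite test
  rec3 <- data.frame(vial_id = "v", treatment = rep(c("a", "b"), each = 4),
                     time_days = c(1, 2, 3, 4, 5, 6, 7, 8),
                     event = rep(c(1L, 0L), each = 4))
  got3 <- logrankTest(rec3, "a", "b")
  expect_true(is.finite(got3$chisq))
  expect_lt(got3$p.value, 1)
  expect_error(logrankTest(transform(rec3, event = 0L), "a", "b"), "no events")

  # invariant to group relabeling
  flip <- rec
  flip$treatment <- ifelse(flip$treatment == "a", "b", "a")
  expect_equal(logrankTest(flip, "a", "b")$chisq, got$chisq, tolerance = 1e-12)
})

test_that("compact letter displays separate exactly the significant pairs", {
  pw <- function(a, b, p) data.frame(group_a = a, group_b = b, p_adjusted = p)
  # 2 groups, significant
  expect_equal(compactLetterDisplay(pw("A", "B", 0.01)),
               c(A = "a", B = "b"))
  # 3 groups, only A-B significant -> C shares with both
  d3 <- pw(c("A", "A", "B"), c("B", "C", "C"), c(0.01, 0.5, 0.5))
  expect_equal(compactLetterDisplay(d3), c(A = "a", B = "b", C = "ab"))
  # nothing significant
  expect_equal(compactLetterDisplay(pw(c("A", "A", "B"), c("B", "C", "C"), 1)),
               c(A = "a", B = "a", C = "a"))
  expect_error(compactLetterDisplay(pw("A", "B", NA_real_)), "NA")
  expect_error(compactLetterDisplay(d3[-2, ]), "cover")
})

test_that("letter displays satisfy the share-a-letter iff not-significant law", {
  shares <- function(cld, a, b)
    length(intersect(strsplit(cld[[a]], "")[[1]], strsplit(cld[[b]], "")[[1]])) > 0
  for (nGroups in 3:5) {
    groups <- LETTERS[seq_len(nGroups)]
    pairs <- combn(groups, 2)
    nPairs <- ncol(pairs)
    for (mask in 0:(2^nPairs - 1)) {
      sig <- as.logical(bitwAnd(mask, 2^(seq_len(nPairs) - 1)))
      pwdf <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                         p_adjusted = ifelse(sig, 0.001, 0.9))
      cld <- compactLetterDisplay(pwdf)
      for (j in seq_len(nPairs)) {
        expect_identical(shares(cld, pairs[1, j], pairs[2, j]), !sig[j])
      }
    }
  }
})

test_that("Kruskal-Wallis holds its nominal size under the null", {
  set.seed(271)
  rejections <- 0L
  nSim <- 2000L
  for (i in seq_len(nSim)) {
    x <- rnorm(27)
    g <- rep(c("a", "b", "c"), each = 9L)
    if (kruskalWallis(x, g)$p.value < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / nSim
  expect_gte(rate, 0.035)
  expect_lte(rate, 0.065)
})

test_that("the two-group rank-sum special case agrees with the rank machinery", {
  set.seed(12)
  a <- rnorm(9, 1); b <- rnorm(9)
  rs <- rankSumTest(a, b)
  expect_lt(rs$p.value, 0.5)
  # Wilcoxon and 2-group KW are equivalent rank tests: same exact-null ordering
  kw <- kruskalWallis(c(a, b), rep(c("a", "b"), each = 9))
  expect_equal(rs$p.value < 0.05, kw$p.value < 0.05)
})
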