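test_that("summaries report mean, n-1 standard deviation and size", {
  s <- summarizeSample(IndexSample(c(1, 2, 3)))
  expect_equal(s@mean, 2)
  expect_equal(s@sd, 1)
  expect_equal(s@n, 3L)
  single <- summarizeSample(IndexSample(5))
  expect_equal(single@mean, 5)
  expect_true(is.na(single@sd))
  # permutation invariance
  set.seed(71)
  v <- rnorm(10)
  a <- summarizeSample(IndexSample(v))
  b <- summarizeSample(IndexSample(sample(v)))
  expect_equal(a@mean, b@mean)
  expect_equal(a@sd, b@sd)
})

test_that("one-sample t against zero matches an independent oracle", {
  r <- tVsZero(IndexSample(c(-1, 1)))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$sigClass, "ns")

  expect_error(tVsZero(IndexSample(c(1, 1, 1))), "zero variance")

  v <- c(2.1, 1.9, 2.0, 2.2, 1.8)
  r <- tVsZero(IndexSample(v))
  oracle <- t.test(v, mu = 0)
  expect_equal(r$t, unname(oracle$statistic), tolerance = 1e-6)
  expect_equal(r$p, oracle$p.value, tolerance = 1e-6)
  expect_equal(r$sigClass, "**")

  # significance classes at the 0.05 and 0.01 boundaries
  set.seed(72)
  weak <- c(0.8, 1.4, -0.3, 1.1, 0.2, 1.3)
  expect_equal(tVsZero(IndexSample(weak))$sigClass,
               if (t.test(weak)$p.value < 0.01) "**"
               else if (t.test(weak)$p.value < 0.05) "*" else "ns")
})

test_that("one-way ANOVA agrees with the sums-of-squares oracle", {
  set.seed(73)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    sizes <- pmax(2, as.integer(rmultinom(1, sample(k * 2, 1) +
                                            2 * k, rep(1, k))))
    raw <- lapply(sizes, function(n) rnorm(n, sd = runif(1, 0.5, 2)))
    groups <- lapply(seq_along(raw), function(i)
      IndexSample(raw[[i]], scenarioLabel = paste0("s", i)))
    got <- anovaScenarios(groups)
    want <- ssqAnovaF(raw)
    expect_equal(got$F, want$F, tolerance = 1e-9)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})

test_that("ANOVA hits its analytic corner cases", {
  g <- IndexSample(c(1, 2, 3), scenarioLabel = "a")
  identicals <- list(g, IndexSample(c(1, 2, 3), scenarioLabel = "b"),
                     IndexSample(c(1, 2, 3), scenarioLabel = "c"))
  r <- anovaScenarios(identicals)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)

  # two groups: F equals the squared equal-variance two-sample t
  set.seed(74)
  a <- rnorm(6); b <- rnorm(8, mean = 1)
  r2 <- anovaScenarios(list(IndexSample(a, scenarioLabel = "a"),
                            IndexSample(b, scenarioLabel = "b")))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-9)

  # far-separated means with tiny within-group spread
  far <- lapply(c(0, 0, 10), function(m)
    IndexSample(m + rnorm(5, sd = 0.01),
                scenarioLabel = paste0("m", m, sample(1e6, 1))))
  expect_lt(anovaScenarios(far)$p, 1e-6)
})

test_that("LSD-t groups scenarios into letters with the pooled ANOVA error", {
  set.seed(75)
  groups <- list(
    IndexSample(rnorm(8, 0, 0.3), scenarioLabel = "A1B"),
    IndexSample(rnorm(8, 0, 0.3), scenarioLabel = "A2"),
    IndexSample(rnorm(8, 5, 0.3), scenarioLabel = "B1"))
  cmp <- lsdT(groups)
  expect_true(cmp@performed)
  expect_equal(unname(cmp@letters[c("A1B", "A2")]), c("a", "a"))
  expect_equal(unname(cmp@letters[["B1"]]), "b")
  # pairwise t uses pooled MSE and within df
  av <- anovaScenarios(groups)
  m <- vapply(groups, function(g) mean(g@values), numeric(1))
  tManual <- (m[1] - m[3]) / sqrt(av$mse * (1 / 8 + 1 / 8))
  row <- cmp@pairwise[cmp@pairwise$groupA == "A1B" &
                      cmp@pairwise$groupB == "B1", ]
  expect_equal(row$t, tManual, tolerance = 1e-9)
  expect_equal(row$p, 2 * pt(-abs(tManual), av$dfWithin), tolerance = 1e-9)
})

test_that("the ANOVA gate blocks pairwise comparisons for homogeneous groups", {
  g <- lapply(c("a", "b", "c"), function(s)
    IndexSample(c(1, 2, 3), scenarioLabel = s))
  cmp <- lsdT(g)
  expect_false(cmp@performed)
  expect_true(all(is.na(cmp@letters)))
  expect_error(lsdT(g, strict = TRUE), "gate")
})

test_that("letter displays are relabeling-invariant and pairwise-consistent", {
  set.seed(76)
  for (rep in 1:10) {
    k <- sample(3:4, 1)
    means <- sample(c(0, 0, 3, 6), k)
    groups <- lapply(seq_len(k), function(i)
      IndexSample(rnorm(6, means[i], 0.5),
                  scenarioLabel = paste0("s", i)))
    cmp <- lsdT(groups)
    if (!cmp@performed) next
    # letters must agree with every pairwise decision
    for (r in seq_len(nrow(cmp@pairwise))) {
      la <- strsplit(cmp@letters[[cmp@pairwise$groupA[r]]], "")[[1]]
      lb <- strsplit(cmp@letters[[cmp@pairwise$groupB[r]]], "")[[1]]
      shares <- length(intersect(la, lb)) > 0
      expect_equal(shares, cmp@pairwise$p[r] >= 0.10)
    }
    # relabeling the scenarios permutes but does not change the partition
    perm <- sample(k)
    relabeled <- lapply(seq_len(k), function(i) {
      g <- groups[[perm[i]]]
      IndexSample(g@values, scenarioLabel = paste0("z", i))
    })
    cmp2 <- lsdT(relabeled)
    expect_equal(unname(vapply(seq_len(k), function(i)
      nchar(cmp2@letters[[paste0("z", i)]]), integer(1))),
      unname(vapply(perm, function(i)
        nchar(cmp@letters[[i]]), integer(1))))
  }
})

test_that("family pooling concatenates genera with matching labels", {
  genera <- Map(function(g, n) IndexSample(rnorm(n), g, "A1B", "Dy"),
                c("Abies", "Picea", "Larix", "Pinus"), c(12, 12, 6, 16))
  fam <- familyPool(genera)
  expect_equal(length(fam@values), 46)
  expect_equal(fam@groupLabel, "family")
  # pooled mean is the size-weighted mean of genus means
  expect_equal(mean(fam@values),
               weighted.mean(vapply(genera, function(g) mean(g@values),
                                    numeric(1)),
                             vapply(genera, function(g) length(g@values),
                                    numeric(1))))
  solo <- familyPool(genera[1])
  expect_equal(solo@values, genera[[1]]@values)
  mixed <- c(genera[1], list(IndexSample(rnorm(3), "Picea", "A1B", "Dz")))
  expect_error(familyPool(mixed), "different indices")
})
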