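test_that("surrogate tests reject strong coupling and validate inputs", {
  xy <- genCoupledAR(2000, cXY = 0.8, seed = 40)
  spec <- embeddingSpec(d = 1, tau = 1, u = 1, k = 4, theiler = 5)
  st <- surrogateTest(xy[, "x"], xy[, "y"], spec, nSurrogates = 19, seed = 7)
  expect_equal(pValue(st), 1 / 20)             # observed beats all surrogates
  expect_length(surrogates(st), 19)
  expect_true(all(surrogates(st) < couplingValue(st)))
  expect_error(surrogateTest(xy[, "x"], xy[, "y"], spec, nSurrogates = 5),
               ">= 19")
  expect_error(surrogateTest(rnorm(12), rnorm(12), spec), "too short")
})

test_that("surrogate tests are reproducible and method-selectable", {
  xy <- genCoupledAR(1200, cXY = 0.3, seed = 41)
  spec <- embeddingSpec(d = 1, tau = 1, u = 1, k = 4, theiler = 5)
  a <- surrogateTest(xy[, "x"], xy[, "y"], spec, seed = 3)
  b <- surrogateTest(xy[, "x"], xy[, "y"], spec, seed = 3)
  expect_identical(surrogates(a), surrogates(b))
  p <- surrogateTest(xy[, "x"], xy[, "y"], spec, seed = 3, method = "permute")
  expect_s4_class(p, "CouplingEstimate")
  m <- surrogateTest(xy[, "x"], xy[, "y"], spec, seed = 3, statistic = "mi")
  expect_equal(m@estimator, "ksg1")
})

test_that("repeated-measures ANOVA matches the aov oracle on random tables", {
  for (s in 1:20) {
    set.seed(500 + s)
    nS <- sample(3:8, 1); nC <- sample(2:5, 1)
    df <- expand.grid(subject = seq_len(nS), condition = letters[seq_len(nC)])
    df$value <- rnorm(nrow(df)) + rep(rnorm(nS), nC)  # subject offsets
    ours <- rmAnova(df)
    oracle <- aovOracle(df)
    expect_equal(ours$F, oracle$F, tolerance = 1e-10)
    expect_equal(ours$p, oracle$p, tolerance = 1e-10)
    expect_equal(ours$df1, oracle$df1)
    expect_equal(ours$df2, oracle$df2)
  }
})

test_that("repeated-measures ANOVA handles the textbook fixture and edge cases", {
  # 4 subjects x 3 conditions with a real condition effect
  df <- expand.grid(subject = 1:4, condition = c("a", "b", "c"))
  df$value <- c(5, 3, 8, 6,  7, 6, 10, 8,  4, 2, 6, 7)
  ours <- rmAnova(df)
  oracle <- aovOracle(df)
  expect_equal(ours$F, oracle$F, tolerance = 1e-10)
  expect_equal(ours$table$SS[1],
               4 * sum((tapply(df$value, df$condition, mean) - mean(df$value))^2))
  # identical values across conditions
  flat <- expand.grid(subject = 1:4, condition = c("a", "b"))
  flat$value <- rep(c(5, 6, 7, 8), 2)
  res <- rmAnova(flat)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  one <- data.frame(subject = 1, condition = c("a", "b"), value = 1:2)
  expect_error(rmAnova(one), "2 subjects")
  bad <- df[-1, ]
  expect_error(rmAnova(bad), "subject 1 x condition a")
})

test_that("Pearson correlation returns rho, rho-squared and the t-based p", {
  x <- 1:10
  res <- pearsonCorr(x, 2 * x + 1)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 0)
  set.seed(77)
  a <- rnorm(100); b <- rnorm(100)
  res <- pearsonCorr(a, b)
  expect_lt(abs(res$rho), 0.3)
  ct <- cor.test(a, b)
  expect_equal(res$rho, unname(ct$estimate))
  expect_equal(res$p, ct$p.value)
  expect_equal(res$rho2, res$rho^2)
  expect_error(pearsonCorr(1:2, 2:3), "at least 3")
  expect_error(pearsonCorr(rep(1, 10), rnorm(10)), "zero-variance")
})

test_that("condition summaries report mean, sample SD and degeneracy", {
  df <- data.frame(condition = rep("a", 3), value = c(1, 2, 3))
  s <- summarizeConditions(df)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$n, 3L)
  single <- data.frame(condition = c("a", "a", "b"), value = c(1, 3, 5))
  expect_warning(s2 <- summarizeConditions(single), "single value")
  expect_equal(s2$sd[s2$condition == "b"], 0)
  expect_true(s2$degenerate[s2$condition == "b"])
  expect_error(summarizeConditions(data.frame(condition = character(0),
                                              value = numeric(0))), "empty")
  # 9 pseudo-subjects x 5 conditions against a direct tapply computation
  set.seed(9)
  big <- expand.grid(subject = 1:9, condition = 1:5)
  big$value <- rnorm(45)
  s3 <- summarizeConditions(big, by = "condition")
  expect_equal(s3$mean, as.numeric(tapply(big$value, big$condition, mean)))
  expect_equal(s3$sd, as.numeric(tapply(big$value, big$condition, sd)))
})

test_that("surrogate p-values are approximately uniform under the null", {
  # 60 null runs at 19 surrogates: rejection fraction should be near 0.05
  spec <- embeddingSpec(d = 1, tau = 1, u = 1, k = 4, theiler = 3)
  ps <- vapply(1:60, function(s) {
    xy <- genCoupledAR(600, cXY = 0, cYX = 0, seed = 700 + s)
    pValue(surrogateTest(xy[, "x"], xy[, "y"], spec, nSurrogates = 19,
                         seed = s))
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0)
  expect_lte(mean(ps <= 0.05), 0.15)
  expect_gt(mean(ps), 0.3)  # not systematically anticonservative
})
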