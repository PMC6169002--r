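test_that("delay embedding reproduces the reconstruction vectors", {
  m <- delayEmbed(1:6, d = 2, tau = 2)
  expect_equal(m, cbind(c(3, 4, 5, 6), c(1, 2, 3, 4)))
  expect_equal(delayEmbed(1:5, d = 1, tau = 3), cbind(1:5))
  expect_equal(nrow(delayEmbed(rnorm(100), d = 3, tau = 4)), 100 - 8)
  expect_error(delayEmbed(1:10, d = 3, tau = 5), "too short")
})

test_that("the data-driven Theiler window tracks autocorrelation decay", {
  xy <- genCoupledAR(3000, aX = 0.9, aY = 0.1, seed = 4)
  expect_gt(theilerWindow(xy[, "x"]), theilerWindow(xy[, "y"]))
  expect_lte(theilerWindow(xy[, "x"], cap = 10), 10)
})

test_that("Ragwitz selection favors parsimonious embeddings for AR(1) processes", {
  hits <- 0
  for (s in 1:10) {
    x <- genCoupledAR(1500, aX = 0.7, aY = 0.5, seed = 200 + s)[, "x"]
    sel <- ragwitzOptimize(x, dRange = 1:5, tauRange = 1:3, k = 4, theiler = 5)
    hits <- hits + (sel$d <= 2)
  }
  expect_gte(hits, 9)
  expect_error(ragwitzOptimize(rep(1, 100)), "constant")
  expect_error(ragwitzOptimize(rnorm(100), dRange = integer(0)), "empty")
})

test_that("Ragwitz selection needs two lags to resolve a period-4 cycle", {
  s <- rep(c(0, 1, 0, -1), 15)  # s[t+1] ambiguous from s[t] alone
  sel <- ragwitzOptimize(s + seq_along(s) * 1e-9, dRange = 1:3, tauRange = 1,
                         k = 2, theiler = 0)
  expect_equal(sel$d, 2)
  expect_lt(sel$mse["2", "1"], 1e-10)
  expect_gt(sel$mse["1", "1"], 0.1)
})

test_that("transfer entropy vanishes on independent white noise", {
  xy <- genBivariateGaussian(5000, 0, seed = 12)
  spec <- embeddingSpec(d = 1, tau = 1, u = 1, k = 4, theiler = 0)
  expect_lt(abs(couplingValue(teKSG(xy[, 1], xy[, 2], spec))), 0.02)
})

test_that("transfer entropy tracks the Granger oracle on a coupled AR pair", {
  oracle <- analyticLinearTE(aX = 0.5, aY = 0.5, cXY = 0.5)
  spec <- embeddingSpec(d = 1, tau = 1, u = 1, k = 4, theiler = 10)
  est <- vapply(1:5, function(s) {
    xy <- genCoupledAR(8000, cXY = 0.5, seed = 300 + s)
    couplingValue(teKSG(xy[, "x"], xy[, "y"], spec))
  }, numeric(1))
  expect_lt(abs(mean(est) - oracle) / oracle, 0.3)
  xy <- genCoupledAR(8000, cXY = 0.5, seed = 301)
  rev <- couplingValue(teKSG(xy[, "y"], xy[, "x"], spec))
  expect_lt(rev, mean(est))
})

test_that("a pure delay map yields large forward and near-zero reverse TE", {
  x <- genBivariateGaussian(3000, 0, seed = 13)[, 1]
  u <- 5
  y <- c(rep(0, u), x[1:(length(x) - u)])  # y_t = x_{t-u}
  spec <- embeddingSpec(d = 1, tau = 1, u = u, k = 4, theiler = 0)
  fwd <- couplingValue(teKSG(x, y, spec))
  bwd <- couplingValue(teKSG(y, x, spec))
  expect_gt(fwd, 2)
  expect_lt(abs(bwd), 0.05)
})

test_that("TE bias on independent pairs stays inside the expected window", {
  spec <- embeddingSpec(d = 1, tau = 1, u = 1, k = 4, theiler = 0)
  vals <- vapply(1:100, function(s) {
    xy <- genBivariateGaussian(5000, 0, seed = 400 + s)
    couplingValue(teKSG(xy[, 1], xy[, 2], spec))
  }, numeric(1))
  expect_gte(mean(vals), -0.005)
  expect_lte(mean(vals), 0.01)
})

test_that("transfer entropy rejects malformed input", {
  x <- rnorm(200)
  spec <- embeddingSpec(d = 2, tau = 2, u = 2, k = 4, theiler = 0)
  expect_error(teKSG(x, rnorm(199), spec), "equal length")
  expect_error(teKSG(x, replace(rnorm(200), 5, NA), spec), "NaN")
  expect_error(teKSG(numeric(0), numeric(0), spec), "k \\+ 2")
  expect_error(teKSG(rnorm(10), rnorm(10),
                     embeddingSpec(d = 4, tau = 3, u = 5)), "too short")
})

test_that("the prediction-time scan returns the grid maximum with smallest-u ties", {
  xy <- genCoupledAR(3000, cXY = 0.6, lag = 10, seed = 20)
  spec <- embeddingSpec(d = 1, tau = 1, u = 1, k = 4, theiler = 5)
  sc <- scanPredictionTime(xy[, "x"], xy[, "y"], spec, fs = 1000,
                           uGridMs = seq(5, 20, by = 1))
  expect_equal(sc$bestU, 10)  # lag 10 samples = 10 ms at 1 kHz
  expect_equal(nrow(sc$profile), 16)
  sc1 <- scanPredictionTime(xy[, "x"], xy[, "y"], spec, fs = 1000, uGridMs = 7)
  expect_equal(sc1$bestU, 7)
  expect_error(scanPredictionTime(xy[, "x"], xy[, "y"], spec, fs = 1000,
                                  uGridMs = numeric(0)), "empty")
})

test_that("bidirectional TE labels the descending direction correctly", {
  cfg <- synthConfig(nTrials = 3, seed = 31)
  rec <- preprocessRecording(genCMCRecording(stimProtocol(ntb = 250), cfg, "post"))
  seg <- segmentTrials(rec, 1, 1, stimProtocol(ntb = 250))$post
  bi <- teBidirectional(seg@lfp[, 1], seg@emg[, 1], fs = 2000,
                        dRange = 1:3, tauRange = 1:3)
  expect_gt(couplingValue(bi$desc), couplingValue(bi$asc))
  expect_true(all(c("d", "tau", "dSource") %in% names(bi$desc@params)))
  expect_error(teBidirectional(numeric(0), numeric(0), fs = 2000), "zero-length")
})
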