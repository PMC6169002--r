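test_that("bivariate Gaussian generator hits the requested correlation", {
  xy <- genBivariateGaussian(1000, 0, seed = 1)
  expect_lt(abs(cor(xy[, 1], xy[, 2])), 3 / sqrt(1000))
  xy <- genBivariateGaussian(10000, 0.6, seed = 7)
  expect_lt(abs(cor(xy[, 1], xy[, 2]) - 0.6), 0.03)  # ~3 Fisher-z SEs
  expect_identical(genBivariateGaussian(50, 0.3, seed = 4),
                   genBivariateGaussian(50, 0.3, seed = 4))
  expect_error(genBivariateGaussian(1, 0.5), "n")
  expect_error(genBivariateGaussian(100, 1), "rho")
  expect_error(genBivariateGaussian(100, -1.2), "rho")
})

test_that("analytic Gaussian MI matches its closed form", {
  expect_equal(analyticGaussianMI(0), 0)
  expect_equal(analyticGaussianMI(0.9), -0.5 * log(0.19))
  expect_equal(analyticGaussianMI(0.9), 0.83037, tolerance = 1e-5)
  expect_equal(analyticGaussianMI(-0.9), analyticGaussianMI(0.9))
  expect_error(analyticGaussianMI(1), "rho")
})

test_that("coupled AR generator produces independent series at zero coupling", {
  n <- 4000
  xy <- genCoupledAR(n, cXY = 0, cYX = 0, seed = 3)
  cc <- ccf(xy[, 1], xy[, 2], lag.max = 20, plot = FALSE)
  expect_true(all(abs(cc$acf) < 4 / sqrt(n)))
  expect_error(genCoupledAR(1000, aY = 1.2), "stationar")
  expect_error(genCoupledAR(1000, lag = 0), "lag")
  expect_identical(genCoupledAR(500, cXY = 0.4, seed = 9),
                   genCoupledAR(500, cXY = 0.4, seed = 9))
})

test_that("coupled AR cross-correlation peaks at the coupling lag", {
  xy <- genCoupledAR(20000, cXY = 0.5, cYX = 0, lag = 5, seed = 11)
  cc <- ccf(xy[, 1], xy[, 2], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], -5)  # x leads y by 5 samples
})

test_that("exact linear TE agrees with the regression oracle and is nonnegative", {
  expect_equal(analyticLinearTE(cXY = 0), 0)
  expect_equal(analyticLinearTE(cXY = 0.5, direction = "yx"), 0)
  expect_gte(analyticLinearTE(cXY = 0.3, cYX = 0.2), 0)
  # dual route: covariance algebra vs least squares on simulated data
  lyap <- analyticLinearTE(aX = 0.5, aY = 0.5, cXY = 0.5)
  reg <- grangerOracleTE(aX = 0.5, aY = 0.5, cXY = 0.5, n = 2e5)
  expect_lt(abs(lyap - reg) / lyap, 0.02)
  lyap5 <- analyticLinearTE(cXY = 0.5, lag = 5, u = 5)
  reg5 <- grangerOracleTE(cXY = 0.5, lag = 5, u = 5, n = 2e5)
  expect_lt(abs(lyap5 - reg5) / lyap5, 0.02)
  expect_error(analyticLinearTE(aX = 1.1), "nonstationary")
})

test_that("synthetic recordings respect the protocol geometry", {
  p <- stimProtocol(ntb = 200)
  cfg <- synthConfig(nTrials = 4, seed = 2)
  rec <- genCMCRecording(p, cfg, "pre")
  expect_length(triggerTimes(rec), 4)
  expect_equal(diff(triggerTimes(rec)), rep(3.6, 3))
  expect_equal(length(lfp(rec)), length(emg(rec)))
  expect_equal(samplingRate(rec), 2000)
  expect_error(genCMCRecording(p, cfg, "pre", duration = 5), "too short")
})

test_that("generator output is bit-identical under a fixed seed", {
  p <- stimProtocol(ntb = 150)
  cfg <- synthConfig(nTrials = 2, seed = 5)
  r1 <- genCMCRecording(p, cfg, "post")
  r2 <- genCMCRecording(p, cfg, "post")
  expect_identical(lfp(r1), lfp(r2))
  expect_identical(emg(r1), emg(r2))
})

test_that("a zero NTB gain slope makes pre and post phases identical", {
  p <- stimProtocol(ntb = 300)
  cfg <- synthConfig(nTrials = 2, seed = 5, ntbGainSlope = 0)
  pre <- genCMCRecording(p, cfg, "pre")
  post <- genCMCRecording(p, cfg, "post")
  expect_identical(lfp(pre), lfp(post))
  expect_identical(emg(pre), emg(post))
})

test_that("post-stimulation coupling gain is monotone nondecreasing in NTB", {
  cfg <- synthConfig(nTrials = 1, seed = 1)
  gains <- vapply(c(100, 150, 200, 250, 300), function(ntb) {
    rec <- genCMCRecording(stimProtocol(ntb = ntb), cfg, "post")
    rec@metadata$couplingDescEffective
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
  pre <- genCMCRecording(stimProtocol(ntb = 300), cfg, "pre")
  expect_lt(pre@metadata$couplingDescEffective, gains[1])
})

test_that("the descending drive enters the EMG at the conduction delay", {
  # noiseless coupled components: with nuisances off, the rectified EMG
  # envelope tracks the delayed broadband LFP core
  cfg <- synthConfig(nTrials = 3, seed = 8, noiseSd = 0, lineNoiseAmp = 0,
                     driftAmp = 0, couplingAsc = 0)
  rec <- genCMCRecording(stimProtocol(ntb = 200), cfg, "post", oscAmp = 0)
  lagMax <- 80
  cc <- ccf(abs(lfp(rec)), abs(emg(rec)), lag.max = lagMax, plot = FALSE)
  delaySamp <- round(cfg@conductionDelay / 1000 * cfg@fs)
  peak <- cc$lag[which.max(cc$acf)]
  expect_lt(abs(peak - (-delaySamp)), 4)  # LFP leads EMG by ~50 samples
})
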