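fs <- 2000

test_that("the 50 Hz notch removes the line tone and passes the neighborhood", {
  expect_lt(toneAttenuationDb(function(x) notchFilter(x, fs), 50), -40)
  expect_gt(toneAttenuationDb(function(x) notchFilter(x, fs), 10), -0.1)
  expect_gt(toneAttenuationDb(function(x) notchFilter(x, fs), 120), -0.1)
  expect_equal(notchFilter(rep(0, 500), fs), rep(0, 500))
  expect_error(notchFilter(rnorm(100), fs, notchFreq = 1500), "Nyquist")
  expect_error(notchFilter(numeric(0), fs), "empty")
})

test_that("baseline removal subtracts slow drift and preserves fast content", {
  x <- rep(3.7, 2000)
  expect_lt(max(abs(removeBaseline(x, fs))), 1e-9)
  t <- seq(0, 2, by = 1 / fs)
  ramp <- 5 * t
  sine <- sin(2 * pi * 20 * t)
  out <- removeBaseline(ramp + sine, fs, 0.5)
  core <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  expect_lt(max(abs(out[core] - sine[core])), 0.05 * max(ramp))
  expect_error(removeBaseline(numeric(0), fs), "empty")
  expect_error(removeBaseline(rnorm(100), fs, baselineWindow = 1), "longer")
  expect_error(removeBaseline(rnorm(100), fs, baselineWindow = 1e-4), "2/fs")
})

test_that("the band-pass passes in-band tones and rejects out-of-band tones", {
  emgBand <- function(x) bandpassFilter(x, fs, 10, 200)
  expect_gt(toneAttenuationDb(emgBand, 100), -1)
  expect_lt(toneAttenuationDb(emgBand, 1), -20)
  lfpBand <- function(x) bandpassFilter(x, fs, 0.5, 200)
  expect_gt(toneAttenuationDb(lfpBand, 100), -1)
  expect_lt(toneAttenuationDb(lfpBand, 450), -20)
  expect_equal(bandpassFilter(rep(0, 500), fs, 10, 200), rep(0, 500))
  expect_error(bandpassFilter(rnorm(100), fs, 200, 10), "invalid band")
  expect_error(bandpassFilter(rnorm(100), fs, 10, 1200), "invalid band")
})

test_that("rectification is the elementwise absolute value", {
  expect_equal(rectifyEMG(c(-1, 2, -3)), c(1, 2, 3))
  x <- abs(rnorm(100))
  expect_identical(rectifyEMG(x), x)          # idempotent on nonnegative input
  t <- seq(0, 10, by = 1 / fs)
  a <- 2.5
  expect_equal(mean(rectifyEMG(a * sin(2 * pi * 7 * t))), 2 * a / pi,
               tolerance = 0.01)
})

test_that("all filters are zero-phase and preserve sample count", {
  t <- seq(0, 2, by = 1 / fs)
  x <- sin(2 * pi * 40 * t) + 0.2 * sin(2 * pi * 15 * t)
  for (f in list(function(v) notchFilter(v, fs),
                 function(v) removeBaseline(v, fs),
                 function(v) bandpassFilter(v, fs, 10, 200))) {
    y <- f(x)
    expect_length(y, length(x))
    cc <- ccf(x, y, lag.max = 20, plot = FALSE)
    expect_equal(cc$lag[which.max(cc$acf)], 0)
  }
})

test_that("trial segmentation honors windows, sonication offset and bounds", {
  p <- stimProtocol(ntb = 200)  # sonication 0.2 s
  n <- 40 * fs
  rec <- new("TimeSeriesRecording", lfp = rnorm(n), emg = rnorm(n), fs = fs,
             triggerTimes = 1 + (0:9) * 3.6, metadata = list())
  seg <- segmentTrials(rec, 1, 1, p)
  expect_equal(nTrials(seg$pre), 10)
  expect_equal(nTrials(seg$post), 10)
  expect_equal(nrow(seg$pre@lfp), 2000)
  expect_equal(nrow(seg$post@emg), 2000)
  # the post window starts sonicationDuration after the trigger
  i0 <- round((1 + 0.2) * fs) + 1
  expect_equal(seg$post@lfp[, 1], rec@lfp[i0:(i0 + 1999)])
  # a trigger whose pre window would start before the record is dropped
  rec0 <- new("TimeSeriesRecording", lfp = rnorm(n), emg = rnorm(n), fs = fs,
              triggerTimes = c(0, 1 + (0:8) * 3.6), metadata = list())
  expect_message(seg0 <- segmentTrials(rec0, 1, 1, p), "dropped")
  expect_equal(nTrials(seg0$pre), 9)
  expect_equal(seg0$pre@nDropped, 1L)
  expect_error(segmentTrials(rec, 2, 2, p), "overlap")
})

test_that("the preprocessing chain preserves length and rectifies the EMG", {
  cfg <- synthConfig(nTrials = 2, seed = 3)
  rec <- genCMCRecording(stimProtocol(ntb = 100), cfg, "pre")
  prep <- preprocessRecording(rec)
  expect_length(lfp(prep), length(lfp(rec)))
  expect_true(all(emg(prep) >= 0))
  prep2 <- preprocessRecording(rec, rectify = FALSE)
  expect_false(all(emg(prep2) >= 0))
})
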