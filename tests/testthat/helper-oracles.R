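# Independent oracles used across the suite.

# Granger / transfer-entropy oracle for the linear-Gaussian coupled AR
# system: fit the reduced (target past only) and full (plus source past)
# one-lag regressions by least squares on a long simulated realization and
# return 0.5 * log of the residual-variance ratio. Kept independent of
# analyticLinearTE (covariance algebra) and of the kNN estimator.
grangerOracleTE <- function(aX = 0.5, aY = 0.5, cXY = 0.5, cYX = 0,
                            lag = 1, u = 1, n = 2e5, seed = 99L) {
  xy <- genCoupledAR(n, aX = aX, aY = aY, cXY = cXY, cYX = cYX, lag = lag,
                     seed = seed)
  x <- xy[, "x"]; y <- xy[, "y"]
  yf <- y[(1 + u):n]
  yp <- y[1:(n - u)]
  xp <- x[1:(n - u)]
  red <- stats::lm.fit(cbind(1, yp), yf)
  full <- stats::lm.fit(cbind(1, yp, xp), yf)
  0.5 * log(sum(red$residuals^2) / sum(full$residuals^2))
}

# one-way within-subjects ANOVA via stats::aov with an Error(subject) term,
# the independent route against the package's sums-of-squares decomposition
aovOracle <- function(df) {
  df$subject <- factor(df$subject)
  df$condition <- factor(df$condition)
  fit <- stats::aov(value ~ condition + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  list(F = tab["condition", "F value"], p = tab["condition", "Pr(>F)"],
       df1 = tab["condition", "Df"], df2 = tab["Residuals", "Df"])
}

# attenuation of a pure tone by a filter function, in dB, measured on the
# central portion of the record (transients excluded)
toneAttenuationDb <- function(filterFun, freq, fs = 2000, secs = 4) {
  t <- seq(0, secs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  y <- filterFun(x)
  core <- seq(round(length(x) * 0.25), round(length(x) * 0.75))
  20 * log10(sd(y[core]) / sd(x[core]))
}
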