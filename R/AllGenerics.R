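#' Derived sonication duration of a protocol
#'
#' @param object a [StimProtocol-class]
#' @return Sonication duration NTB/PRF in seconds.
#' @export
setGeneric("sonicationDuration", function(object) standardGeneric("sonicationDuration"))

#' @rdname sonicationDuration
#' @export
setMethod("sonicationDuration", "StimProtocol", function(object) {
  object@ntb / object@prf
})

#' Sampling rate accessor
#'
#' @param object an object with a sampling rate
#' @return Sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TimeSeriesRecording", function(object) object@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "TrialSet", function(object) object@fs)

#' Trigger times accessor
#'
#' @param object a [TimeSeriesRecording-class]
#' @return Stimulation onset times in seconds.
#' @export
setGeneric("triggerTimes", function(object) standardGeneric("triggerTimes"))

#' @rdname triggerTimes
#' @export
setMethod("triggerTimes", "TimeSeriesRecording", function(object) object@triggerTimes)

#' Channel accessors
#'
#' @param object a [TimeSeriesRecording-class] or [TrialSet-class]
#' @return The LFP (resp. EMG) samples: a vector for recordings, a
#'   samples-by-trials matrix for trial sets.
#' @export
setGeneric("lfp", function(object) standardGeneric("lfp"))

#' @rdname lfp
#' @export
setGeneric("emg", function(object) standardGeneric("emg"))

#' @rdname lfp
#' @export
setMethod("lfp", "TimeSeriesRecording", function(object) object@lfp)

#' @rdname lfp
#' @export
setMethod("emg", "TimeSeriesRecording", function(object) object@emg)

#' @rdname lfp
#' @export
setMethod("lfp", "TrialSet", function(object) object@lfp)

#' @rdname lfp
#' @export
setMethod("emg", "TrialSet", function(object) object@emg)

#' Number of trials in a trial set
#'
#' @param object a [TrialSet-class]
#' @return Trial count.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' @rdname nTrials
#' @export
setMethod("nTrials", "TrialSet", function(object) ncol(object@lfp))

#' Value of a coupling estimate, in nats or bits
#'
#' @param object a [CouplingEstimate-class]
#' @param units `"nats"` (native) or `"bits"`
#' @return The scalar estimate.
#' @export
setGeneric("couplingValue", function(object, units = "nats") standardGeneric("couplingValue"))

#' @rdname couplingValue
#' @export
setMethod("couplingValue", "CouplingEstimate", function(object, units = "nats") {
  units <- match.arg(units, c("nats", "bits"))
  if (units == "bits") object@value / log(2) else object@value
})

#' Surrogate p-value of a coupling estimate
#'
#' @param object a [CouplingEstimate-class]
#' @return The p-value, or NA when no surrogate test was attached.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "CouplingEstimate", function(object) object@pValue)

#' Surrogate distribution of a coupling estimate
#'
#' @param object a [CouplingEstimate-class]
#' @return Numeric vector of surrogate estimates (possibly empty).
#' @export
setGeneric("surrogates", function(object) standardGeneric("surrogates"))

#' @rdname surrogates
#' @export
setMethod("surrogates", "CouplingEstimate", function(object) object@surrogates)

#' Per-trial estimates table of a report
#'
#' @param object an [AnalysisReport-class]
#' @return The per-trial estimates `data.frame`.
#' @export
setGeneric("estimates", function(object) standardGeneric("estimates"))

#' @rdname estimates
#' @export
setMethod("estimates", "AnalysisReport", function(object) object@estimates)

setMethod("show", "StimProtocol", function(object) {
  cat("StimProtocol: AI =", object@acousticIntensity, "W/cm^2, NC =",
      object@nCyclesPerPulse, ", PRF =", object@prf, "Hz, NTB =", object@ntb,
      ", ITI =", object@iti, "s\n")
  cat("  sonication duration:", sonicationDuration(object), "s\n")
})

setMethod("show", "TimeSeriesRecording", function(object) {
  n <- length(object@lfp)
  cat(sprintf("TimeSeriesRecording: %d samples (%.2f s) at %g Hz, %d triggers\n",
              n, n / object@fs, object@fs, length(object@triggerTimes)))
  if (!is.null(object@metadata$phase))
    cat("  phase:", object@metadata$phase,
        if (!is.null(object@metadata$ntb)) paste0(" NTB: ", object@metadata$ntb),
        "\n")
})

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet (%s, NTB = %g): %d trials x %d samples at %g Hz\n",
              object@phase, object@ntb, ncol(object@lfp), nrow(object@lfp),
              object@fs))
  if (object@nDropped > 0)
    cat("  dropped triggers (window out of bounds):", object@nDropped, "\n")
})

setMethod("show", "EmbeddingSpec", function(object) {
  cat(sprintf("EmbeddingSpec: d = %d, tau = %d, u = %d samples, k = %d, theiler = %d\n",
              object@d, object@tau, object@u, object@k, object@theiler))
})

setMethod("show", "CouplingEstimate", function(object) {
  cat(sprintf("CouplingEstimate [%s]: %.4f nats (n = %d)\n",
              object@estimator, object@value, object@nSamples))
  if (!is.na(object@pValue))
    cat(sprintf("  surrogate p = %.4g (%d surrogates)\n",
                object@pValue, length(object@surrogates)))
})

setMethod("show", "AnalysisReport", function(object) {
  cat("AnalysisReport (seed ", object@seed, ")\n", sep = "")
  cat("\nMutual information (nats, mean +/- SD across subjects):\n")
  s <- object@miSummary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  NTB %3g %-4s: %.4f +/- %.4f (n = %d)\n",
                s$ntb[i], s$phase[i], s$mean[i], s$sd[i], s$n[i]))
  cat("\nTransfer entropy (nats, mean +/- SD across subjects):\n")
  s <- object@teSummary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  NTB %3g %-4s %-4s: %.4f +/- %.4f (n = %d)\n",
                s$ntb[i], s$phase[i], s$direction[i], s$mean[i], s$sd[i], s$n[i]))
  if (length(object@anovaTables)) {
    cat("\nrANOVA tables:", paste(names(object@anovaTables), collapse = ", "), "\n")
  }
  if (nrow(object@correlations)) {
    cat("\nAmplitude-coupling correlations (pooled trials):\n")
    c2 <- object@correlations
    for (i in seq_len(nrow(c2)))
      cat(sprintf("  NTB %3g %-12s: rho^2 = %.3f, p = %.3g\n",
                  c2$ntb[i], c2$pair[i], c2$rho2[i], c2$p[i]))
  }
  invisible(object)
})
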