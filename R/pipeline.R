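#' Build a full-study run configuration
#'
#' Collects everything [runFullStudy()] needs: the NTB conditions, subject
#' and trial counts, the generator template, filter and estimation settings,
#' the prediction-time policy and the master seed. All defaults follow the
#' study design (five NTB levels, nine subjects, k = 4, u in [10, 49] ms);
#' smaller subject/trial counts are the natural choice for quick runs.
#'
#' @param ntbLevels nonempty vector of NTB conditions
#' @param nSubjects number of subjects (paired across all conditions)
#' @param nTrials trials per condition; `NULL` uses the generator default (30)
#' @param windowPre,windowPost trial windows, seconds
#' @param filter a [FilterSpec-class]
#' @param k neighbor count
#' @param dRange,tauRange Ragwitz search grids
#' @param uPolicy `"fixed"` (u = `uMs`) or `"scan"` (maximize over `uGridMs`)
#' @param uMs fixed prediction time, ms
#' @param uGridMs scan grid, ms
#' @param nSurrogates per-trial surrogate count (0 disables surrogate tests)
#' @param synth a [SynthConfig-class] template; its seed is overridden by
#'   derived per-subject seeds
#' @param betweenSubjectSd SD of the log-normal subject-level gain multiplier
#'   (reused across conditions, honoring the repeated-measures design)
#' @param seed master seed
#' @param recordingPaths optional data.frame (subject, ntb, phase, path) of
#'   recordings to load instead of simulating
#' @return A named list (class `"cmcRunConfig"`).
#' @export
runConfig <- function(ntbLevels = c(100, 150, 200, 250, 300), nSubjects = 9,
                      nTrials = NULL, windowPre = 1, windowPost = 1,
                      filter = filterSpec(), k = 4, dRange = 1:4,
                      tauRange = 1:3, uPolicy = c("fixed", "scan"), uMs = 25,
                      uGridMs = seq(10, 49, by = 1), nSurrogates = 0,
                      synth = synthConfig(), betweenSubjectSd = 0.1,
                      seed = 1L, recordingPaths = NULL) {
  if (!length(ntbLevels)) stop("ntbLevels must be nonempty")
  cfg <- list(ntbLevels = ntbLevels, nSubjects = nSubjects, nTrials = nTrials,
              windowPre = windowPre, windowPost = windowPost, filter = filter,
              k = k, dRange = dRange, tauRange = tauRange,
              uPolicy = match.arg(uPolicy), uMs = uMs, uGridMs = uGridMs,
              nSurrogates = nSurrogates, synth = synth,
              betweenSubjectSd = betweenSubjectSd, seed = as.integer(seed),
              recordingPaths = recordingPaths)
  class(cfg) <- "cmcRunConfig"
  cfg
}

# run a pipeline stage, prefixing any failure with the stage name
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

# derive the synthetic configuration of one subject x condition cell
.subjectSynth <- function(config, subjSeed, condIndex, gainMult) {
  tmpl <- config$synth
  nTrials <- if (is.null(config$nTrials)) tmpl@nTrials else config$nTrials
  synthConfig(fs = tmpl@fs, nTrials = nTrials,
              couplingDesc = tmpl@couplingDesc * gainMult,
              couplingAsc = tmpl@couplingAsc * gainMult,
              conductionDelay = tmpl@conductionDelay,
              ntbGainSlope = tmpl@ntbGainSlope,
              lineNoiseAmp = tmpl@lineNoiseAmp, driftAmp = tmpl@driftAmp,
              noiseSd = tmpl@noiseSd, seed = subjSeed + condIndex)
}

#' Run the full simulated study
#'
#' For every subject and NTB condition: obtain pre- and post-stimulation
#' recordings (simulated, or loaded from `recordingPaths`), preprocess,
#' segment into trials, estimate per-trial mutual information and
#' bidirectional transfer entropy (embeddings Ragwitz-optimized once per
#' recording; prediction time fixed or scanned per the config), optionally
#' attach surrogate p-values, then aggregate into the report: per-condition
#' mean +/- SD across subjects, repeated-measures ANOVA tables (pre vs post,
#' across NTB, descending vs ascending) and pooled amplitude-coupling
#' correlations. Fully reproducible from the config and master seed.
#'
#' @param config a configuration from [runConfig()]
#' @return An [AnalysisReport-class].
#' @seealso [buildReport()] to regenerate a report from a stored estimates
#'   table.
#' @export
runFullStudy <- function(config) {
  stopifnot(inherits(config, "cmcRunConfig"))
  paths <- config$recordingPaths
  if (!is.null(paths)) {
    missing <- paths$path[!file.exists(paths$path)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (ss in seq_len(config$nSubjects)) {
    subjSeed <- config$seed + 1009L * ss
    gainMult <- .withSeed(subjSeed, exp(rnorm(1, 0, config$betweenSubjectSd)))
    for (ci in seq_along(config$ntbLevels)) {
      ntb <- config$ntbLevels[ci]
      protocol <- stimProtocol(ntb = ntb)
      cfgS <- .subjectSynth(config, subjSeed, ci, gainMult)
      for (phase in c("pre", "post")) {
        rec <- .stage("acquire", {
          if (!is.null(paths)) {
            sel <- paths[paths$subject == ss & paths$ntb == ntb &
                         paths$phase == phase, , drop = FALSE]
            if (!nrow(sel)) stop("no recording listed for subject ", ss,
                                 ", ntb ", ntb, ", phase ", phase)
            readRecording(sel$path[1])
          } else {
            genCMCRecording(protocol, cfgS, phase)
          }
        })
        prep <- .stage("preprocess", preprocessRecording(rec, config$filter))
        trials <- .stage("segment",
          segmentTrials(prep, config$windowPre, config$windowPost,
                        protocol)[[phase]])
        l1 <- trials@lfp[, 1]; e1 <- trials@emg[, 1]
        thL <- theilerWindow(l1); thE <- theilerWindow(e1)
        embL <- .stage("ragwitz",
          ragwitzOptimize(l1, config$dRange, config$tauRange, k = config$k,
                          theiler = thL, nQueries = 300))
        embE <- .stage("ragwitz",
          ragwitzOptimize(e1, config$dRange, config$tauRange, k = config$k,
                          theiler = thE, nQueries = 300))
        fs <- trials@fs
        uSamp <- msToSamples(config$uMs, fs)
        for (j in seq_len(nTrials(trials))) {
          l <- trials@lfp[, j]; e <- trials@emg[, j]
          lamp <- mean(abs(l)); eamp <- mean(abs(e))
          est <- .stage("estimate", {
            mi <- miKSG(l, e, k = config$k, theiler = max(thL, thE))
            specE <- embeddingSpec(d = embE$d, tau = embE$tau, u = uSamp,
                                   k = config$k, theiler = thE)
            specL <- embeddingSpec(d = embL$d, tau = embL$tau, u = uSamp,
                                   k = config$k, theiler = thL)
            if (config$uPolicy == "scan") {
              scD <- scanPredictionTime(l, e, specE, fs, config$uGridMs,
                                        sourceSpec = specL)
              specE@u <- msToSamples(scD$bestU, fs)
              scA <- scanPredictionTime(e, l, specL, fs, config$uGridMs,
                                        sourceSpec = specE)
              specL@u <- msToSamples(scA$bestU, fs)
            }
            desc <- teKSG(l, e, specE, sourceSpec = specL)
            asc <- teKSG(e, l, specL, sourceSpec = specE)
            list(mi = mi, desc = desc, asc = asc,
                 specE = specE, specL = specL)
          })
          pmi <- pdesc <- pasc <- NA_real_
          if (config$nSurrogates > 0) {
            sseed <- subjSeed + 101L * ci + 7L * j + (phase == "post")
            pdesc <- pValue(.stage("surrogates",
              surrogateTest(l, e, est$specE, config$nSurrogates,
                            seed = sseed, sourceSpec = est$specL)))
            pasc <- pValue(.stage("surrogates",
              surrogateTest(e, l, est$specL, config$nSurrogates,
                            seed = sseed + 1L, sourceSpec = est$specE)))
          }
          add <- function(measure, direction, val, p) {
            data.frame(subject = ss, ntb = ntb, phase = phase,
                       measure = measure, direction = direction, trial = j,
                       value_nats = val, p_surrogate = p,
                       lfp_amp = lamp, emg_amp = eamp)
          }
          rows[[length(rows) + 1]] <- rbind(
            add("mi", "sym", couplingValue(est$mi), pmi),
            add("te", "desc", couplingValue(est$desc), pdesc),
            add("te", "asc", couplingValue(est$asc), pasc))
        }
      }
    }
  }
  estimates <- do.call(rbind, rows)
  buildReport(estimates, config)
}

#' Build the analysis report from a per-trial estimates table
#'
#' Deterministic aggregation layer, separated from estimation so a report can
#' be regenerated bit-identically from a stored estimates table plus config:
#' subject-level means feed the per-condition summaries and the
#' repeated-measures ANOVAs; pooled post-stimulation trials feed the
#' amplitude-coupling correlations.
#'
#' @param estimates per-trial estimates table (see [runFullStudy()])
#' @param config the run configuration
#' @return An [AnalysisReport-class].
#' @export
buildReport <- function(estimates, config) {
  subjMeans <- stats::aggregate(
    value_nats ~ subject + ntb + phase + measure + direction,
    data = estimates, FUN = mean)
  mi <- subjMeans[subjMeans$measure == "mi", ]
  te <- subjMeans[subjMeans$measure == "te", ]
  miSummary <- summarizeConditions(mi, value = "value_nats",
                                   by = c("ntb", "phase"))
  teSummary <- summarizeConditions(te, value = "value_nats",
                                   by = c("ntb", "phase", "direction"))

  nSubj <- length(unique(estimates$subject))
  anovaTables <- list()
  perNtb <- function(dat, condition) {
    out <- lapply(sort(unique(dat$ntb)), function(nn) {
      d <- dat[dat$ntb == nn, ]
      a <- rmAnova(d, value = "value_nats", subject = "subject",
                   condition = condition)
      data.frame(ntb = nn, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p)
    })
    do.call(rbind, out)
  }
  if (nSubj >= 2) {
    anovaTables$miPrePost <- perNtb(mi, "phase")
    anovaTables$teDescPrePost <- perNtb(te[te$direction == "desc", ], "phase")
    anovaTables$teAscPrePost <- perNtb(te[te$direction == "asc", ], "phase")
    if (length(unique(mi$ntb)) >= 2) {
      acrossNtb <- function(dat) {
        a <- rmAnova(dat, value = "value_nats", subject = "subject",
                     condition = "ntb")
        data.frame(F = a$F, df1 = a$df1, df2 = a$df2, p = a$p)
      }
      anovaTables$miAcrossNtbPost <- acrossNtb(mi[mi$phase == "post", ])
      anovaTables$teDescAcrossNtbPost <-
        acrossNtb(te[te$phase == "post" & te$direction == "desc", ])
      anovaTables$teAscAcrossNtbPost <-
        acrossNtb(te[te$phase == "post" & te$direction == "asc", ])
    }
    for (ph in c("pre", "post")) {
      anovaTables[[paste0("descVsAsc", toupper(substr(ph, 1, 1)),
                          substr(ph, 2, 10))]] <-
        perNtb(te[te$phase == ph, ], "direction")
    }
  }

  post <- estimates[estimates$phase == "post", ]
  corRows <- list()
  for (nn in sort(unique(post$ntb))) {
    d <- post[post$ntb == nn, ]
    miD <- d[d$measure == "mi", ]
    deD <- d[d$measure == "te" & d$direction == "desc", ]
    asD <- d[d$measure == "te" & d$direction == "asc", ]
    pairs <- list(
      lfp_vs_mi = list(miD$lfp_amp, miD$value_nats),
      emg_vs_mi = list(miD$emg_amp, miD$value_nats),
      lfp_vs_te_desc = list(deD$lfp_amp, deD$value_nats),
      lfp_vs_te_asc = list(asD$lfp_amp, asD$value_nats))
    for (nm in names(pairs)) {
      pc <- tryCatch(pearsonCorr(pairs[[nm]][[1]], pairs[[nm]][[2]]),
                     error = function(e) NULL)
      if (!is.null(pc))
        corRows[[length(corRows) + 1]] <-
          data.frame(ntb = nn, pair = nm, rho = pc$rho, rho2 = pc$rho2,
                     p = pc$p, n = pc$n)
    }
  }
  correlations <- if (length(corRows)) do.call(rbind, corRows) else
    data.frame(ntb = numeric(0), pair = character(0), rho = numeric(0),
               rho2 = numeric(0), p = numeric(0), n = integer(0))

  new("AnalysisReport", estimates = estimates, miSummary = miSummary,
      teSummary = teSummary, anovaTables = anovaTables,
      correlations = correlations,
      config = unclass(config)[setdiff(names(config), "recordingPaths")],
      seed = as.integer(config$seed))
}
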