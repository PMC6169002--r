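#' Surrogate-data significance test for a coupling estimate
#'
#' Builds a null distribution by breaking the source-target alignment while
#' preserving each signal's autostructure: either circular time shifts of the
#' source (uniform random shift of at least the Theiler window) or a full
#' random permutation of the source samples. The p-value uses the standard
#' rank form `p = (1 + #{surrogate >= observed}) / (1 + nSurrogates)`.
#'
#' @param source,target numeric series of equal length
#' @param spec an [EmbeddingSpec-class] passed to the statistic
#' @param nSurrogates number of surrogates, >= 19 (19 gives p resolution 0.05)
#' @param method `"circular"` (circular time shift, default) or `"permute"`
#'   (random permutation, destroying all temporal structure of the source)
#' @param statistic `"te"` ([teKSG()], default) or `"mi"` ([miKSG()])
#' @param seed integer seed for the surrogate draws
#' @param sourceSpec optional source embedding for TE, as in [teKSG()]
#' @return A [CouplingEstimate-class] carrying the observed value, the
#'   surrogate distribution and the p-value.
#' @export
surrogateTest <- function(source, target, spec, nSurrogates = 19,
                          method = c("circular", "permute"),
                          statistic = c("te", "mi"), seed = 1L,
                          sourceSpec = spec) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  if (nSurrogates < 19) stop("nSurrogates must be >= 19")
  n <- length(source)
  stat <- function(src) {
    if (statistic == "te")
      couplingValue(teKSG(src, target, spec, sourceSpec = sourceSpec))
    else couplingValue(miKSG(src, target, k = spec@k, theiler = spec@theiler))
  }
  minShift <- max(spec@theiler, spec@u, (spec@d - 1L) * spec@tau) + 1L
  if (method == "circular" && n <= 2L * minShift)
    stop("series too short for circular-shift surrogates")
  obs <- stat(source)
  surr <- .withSeed(seed, {
    vapply(seq_len(nSurrogates), function(i) {
      src <- if (method == "circular") {
        s <- sample(minShift:(n - minShift), 1)
        c(source[(s + 1):n], source[1:s])
      } else {
        source[sample.int(n)]
      }
      stat(src)
    }, numeric(1))
  })
  p <- (1 + sum(surr >= obs)) / (1 + nSurrogates)
  new("CouplingEstimate", value = obs,
      estimator = if (statistic == "te") "ksg_cmi" else "ksg1",
      params = list(k = spec@k, theiler = spec@theiler, d = spec@d,
                    tau = spec@tau, u = spec@u, surrogateMethod = method,
                    seed = as.integer(seed)),
      nSamples = n, surrogates = surr, pValue = p)
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject decomposition: with s subjects and c conditions
#' (exactly one value per cell), total variation splits into condition,
#' subject and residual sums of squares; `F = MS_condition / MS_error` on
#' `(c - 1, (c - 1)(s - 1))` degrees of freedom.
#'
#' @param data a data.frame with one row per subject-condition cell
#' @param value,subject,condition column names
#' @return `list(F, df1, df2, p, table)` where `table` is the full ANOVA
#'   decomposition.
#' @examples
#' d <- expand.grid(subject = 1:4, condition = c("a", "b", "c"))
#' d$value <- rnorm(12)
#' rmAnova(d)
#' @export
rmAnova <- function(data, value = "value", subject = "subject",
                    condition = "condition") {
  y <- data[[value]]
  s <- factor(data[[subject]])
  cnd <- factor(data[[condition]])
  if (nlevels(s) < 2) stop("need at least 2 subjects")
  if (nlevels(cnd) < 2) stop("need at least 2 conditions")
  tab <- table(s, cnd)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    cells <- apply(bad, 1, function(i)
      sprintf("subject %s x condition %s (%d values)",
              rownames(tab)[i[1]], colnames(tab)[i[2]], tab[i[1], i[2]]))
    stop("unbalanced design; offending cells: ", paste(cells, collapse = "; "),
         " (aggregate trials to one value per cell first)")
  }
  gm <- mean(y)
  nS <- nlevels(s); nC <- nlevels(cnd)
  condMeans <- tapply(y, cnd, mean)
  subjMeans <- tapply(y, s, mean)
  ssCond <- nS * sum((condMeans - gm)^2)
  ssSubj <- nC * sum((subjMeans - gm)^2)
  ssTot <- sum((y - gm)^2)
  ssErr <- ssTot - ssCond - ssSubj
  df1 <- nC - 1
  df2 <- (nC - 1) * (nS - 1)
  msCond <- ssCond / df1
  msErr <- ssErr / df2
  if (ssCond <= .Machine$double.eps * ssTot) {
    f <- 0; p <- 1
  } else if (msErr <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- msCond / msErr
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  list(F = f, df1 = df1, df2 = df2, p = p,
       table = data.frame(
         source = c("condition", "subject", "error"),
         df = c(df1, nS - 1, df2),
         SS = c(ssCond, ssSubj, ssErr),
         MS = c(msCond, ssSubj / (nS - 1), msErr)))
}

#' Pearson correlation with r-squared and two-sided p
#'
#' Sample Pearson correlation, its square, and the two-sided p-value from
#' `t = r sqrt((n - 2) / (1 - r^2))` (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, >= 3, each with nonzero
#'   variance
#' @return `list(rho, rho2, p, n)`.
#' @export
pearsonCorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  r <- cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    p <- stats::cor.test(x, y, method = "pearson")$p.value
  }
  list(rho = r, rho2 = r^2, p = p, n = length(x))
}

#' Per-condition mean, SD and n
#'
#' Summarizes an estimates table as mean +/- sample SD (denominator n - 1)
#' per condition. Conditions with a single value get SD 0 and a warning flag.
#'
#' @param data a data.frame
#' @param value value column name
#' @param by character vector of grouping column names
#' @return A data.frame with the grouping columns plus `mean`, `sd`, `n` and
#'   `degenerate` (TRUE where n = 1 and the SD is undefined).
#' @export
summarizeConditions <- function(data, value = "value", by = "condition") {
  if (!nrow(data)) stop("empty table")
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  groups <- split(data, key)
  rows <- lapply(groups, function(g) {
    v <- g[[value]]
    deg <- length(v) == 1
    cbind(g[1, by, drop = FALSE],
          data.frame(mean = mean(v), sd = if (deg) 0 else sd(v),
                     n = length(v), degenerate = deg))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$degenerate))
    warning("some conditions have a single value; their SD is reported as 0")
  out
}
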