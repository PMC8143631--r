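#' @title Differential protein abundance between two arms
#' @description Per-protein fold changes and two-tailed unpaired Student's
#'   t-tests on relative abundances, a known-substrate-calibrated fold-change
#'   threshold, the noncentral-t power analysis for the per-group sample
#'   size, the screen nomination filter, and the knockout-intersection rule.
#' @name differential
NULL

#' Two-tailed unpaired Student's t-test
#'
#' Pooled-variance (equal-variance) Student's t with
#' `df = length(x) + length(y) - 2`; the two-tailed p-value comes from the
#' central t distribution.  Zero pooled variance is an error, kept distinct
#' from `p = 0`.
#'
#' @param x,y replicate vectors (each of length >= 2).
#' @return list with `statistic`, `p.value` and `df`.
#' @examples
#' proteinTTest(c(1, 2, 3), c(2, 3, 4))
#' @export
proteinTTest <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two replicates")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("zero pooled variance: t statistic undefined")
  fit <- t.test(x, y, var.equal = TRUE)
  list(statistic = unname(fit$statistic), p.value = fit$p.value,
       df = unname(fit$parameter))
}

#' Fold change between arms
#'
#' Ratio of the treated to the control mean.
#'
#' @param x treated replicate vector.
#' @param y control replicate vector.
#' @return `mean(x) / mean(y)` (positive when both means are positive).
#' @examples
#' foldChange(c(115, 115, 115), c(100, 100, 100))  # 1.15
#' @export
foldChange <- function(x, y) {
  if (mean(y) <= 0) stop("control mean must be positive")
  mean(x) / mean(y)
}

#' Continuous per-group sample size from a power analysis
#'
#' Solves the two-sample, two-sided noncentral-t power equation for the
#' (continuous) number of observations per group needed to detect a
#' `deltaFrac` relative change at the given significance level and power,
#' with effect size `d = (deltaFrac * mean) / sd`.  The result is bounded
#' below by 2 (the smallest group size with a defined variance).
#'
#' @param sd per-protein standard deviation (> 0).
#' @param mean per-protein mean (> 0).
#' @param deltaFrac targeted relative change (default 0.15).
#' @param alpha significance level (default 0.05).
#' @param power target power (default 0.95).
#' @return continuous observations per group, >= 2.
#' @examples
#' requiredN(sd = 5, mean = 100)
#' @export
requiredN <- function(sd, mean, deltaFrac = 0.15, alpha = 0.05,
                      power = 0.95) {
  if (!is.finite(sd) || !is.finite(mean) || sd <= 0 || mean <= 0)
    stop("sd and mean must be positive and finite")
  d <- deltaFrac * mean / sd
  n <- tryCatch(
    power.t.test(delta = d, sd = 1, sig.level = alpha, power = power,
                 type = "two.sample", alternative = "two.sided")$n,
    error = function(e) {
      # effect so large that n = 2 already exceeds the target power
      pw <- tryCatch(
        power.t.test(n = 2, delta = d, sd = 1, sig.level = alpha,
                     type = "two.sample",
                     alternative = "two.sided")$power,
        error = function(e2) NA_real_)
      if (!is.na(pw) && pw >= power) 2 else stop(e)
    })
  max(n, 2)
}

#' Calibrate the fold-change threshold from known substrates
#'
#' Returns the median fold change over the known substrates detected in the
#' results -- the screen's data-driven nomination threshold.
#'
#' @param results differential results (columns `protein`, `fc`).
#' @param knownSubstrates character vector of known-substrate identifiers.
#' @return the median fold change of the detected known substrates.
#' @export
calibrateFcThreshold <- function(results, knownSubstrates) {
  hit <- results$protein %in% knownSubstrates
  if (!any(hit))
    stop("no known substrate detected in the results; ",
         "supply a manual fold-change threshold instead")
  median(results$fc[hit])
}

#' Per-protein differential abundance for a contrast
#'
#' For every protein, computes the fold change (treated mean over control
#' mean), the two-tailed unpaired Student's t-test p-value, a
#' Benjamini-Hochberg q-value (reported for reference; the nomination filter
#' uses raw p-values), and the continuous per-group sample size from the
#' power analysis (pooled within-arm standard deviation, mean over the
#' contrast channels).  Tests run on untransformed relative abundances by
#' default; `logTransform = TRUE` applies log2 before testing (fold changes
#' stay on the linear scale).
#'
#' @param se `SummarizedExperiment` from [quantifyProteins()].
#' @param contrast a [TmtContrast-class].
#' @param deltaFrac,alpha,power power-analysis parameters (see
#'   [requiredN()]).
#' @param logTransform test on log2 abundances.
#' @return data.frame with `protein`, `fc`, `t`, `p`, `q_bh`,
#'   `n_peptides`, `n_required`.
#' @export
runDifferential <- function(se, contrast, deltaFrac = 0.15, alpha = 0.05,
                            power = 0.95, logTransform = FALSE) {
  stopifnot(is(contrast, "TmtContrast"))
  ra <- SummarizedExperiment::assay(se, "ra")
  tIdx <- treatedChannels(contrast)
  cIdx <- controlChannels(contrast)
  if (max(c(tIdx, cIdx)) > ncol(ra))
    stop("contrast channel index outside the RA matrix")
  res <- lapply(seq_len(nrow(ra)), function(i) {
    x <- ra[i, tIdx]
    y <- ra[i, cIdx]
    fc <- foldChange(x, y)
    tt <- if (logTransform) proteinTTest(log2(x), log2(y))
          else proteinTTest(x, y)
    sdPooled <- sqrt(((length(x) - 1) * stats::var(x) +
                      (length(y) - 1) * stats::var(y)) /
                     (length(x) + length(y) - 2))
    nReq <- if (sdPooled > 0)
      requiredN(sdPooled, mean(c(x, y)), deltaFrac, alpha, power) else 2
    c(fc = fc, t = tt$statistic, p = tt$p.value, n_required = nReq)
  })
  res <- do.call(rbind, res)
  nPep <- SummarizedExperiment::rowData(se)$n_peptides
  data.frame(protein = rownames(ra), fc = res[, "fc"], t = res[, "t"],
             p = res[, "p"], q_bh = p.adjust(res[, "p"], "BH"),
             n_peptides = if (is.null(nPep)) NA_integer_ else nPep,
             n_required = res[, "n_required"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen nomination filter
#'
#' Keeps proteins with fold change at or above the (calibrated) threshold,
#' quantified from more than one peptide, and with a raw p-value strictly
#' below `alpha`.
#'
#' @param results differential results (see [runDifferential()]).
#' @param fcThreshold fold-change threshold (inclusive).
#' @param minPeptides minimum peptide count (inclusive; default 2, i.e.
#'   "more than one peptide").
#' @param alpha p-value cutoff (strict).
#' @return the subset of `results` passing all three rules.
#' @export
screenFilter <- function(results, fcThreshold, minPeptides = 2,
                         alpha = 0.05) {
  keep <- results$fc >= fcThreshold &
    results$n_peptides >= minPeptides &
    results$p < alpha
  results[keep & !is.na(keep), , drop = FALSE]
}

#' Intersection rule for two knockout clones
#'
#' A protein is called decreased when it changes significantly (p below
#' `alpha`) in both knockout-vs-wild-type comparisons with a fold change
#' below `1 - changeFrac` in both, and increased when significant in both
#' with a fold change above `1 + changeFrac` in both.  The "more than 20%"
#' rule is symmetric on the linear fold-change scale (below 0.8 or above
#' 1.2), not on the ratio scale.
#'
#' @param res1,res2 differential results for the two clones (shared protein
#'   universe; columns `protein`, `fc`, `p`).
#' @param changeFrac minimal relative change (default 0.20).
#' @param alpha significance cutoff (strict).
#' @return list with character vectors `decreased` and `increased`.
#' @export
koIntersection <- function(res1, res2, changeFrac = 0.20, alpha = 0.05) {
  m <- merge(res1[, c("protein", "fc", "p")],
             res2[, c("protein", "fc", "p")],
             by = "protein", suffixes = c("_1", "_2"))
  sig <- m$p_1 < alpha & m$p_2 < alpha
  dec <- sig & m$fc_1 < 1 - changeFrac & m$fc_2 < 1 - changeFrac
  inc <- sig & m$fc_1 > 1 + changeFrac & m$fc_2 > 1 + changeFrac
  list(decreased = m$protein[dec], increased = m$protein[inc])
}
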