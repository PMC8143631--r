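#' @import methods
#' @importFrom stats rlnorm rpois rbeta runif rnorm median quantile ecdf
#'   p.adjust t.test power.t.test setNames complete.cases
#' @importFrom utils read.delim write.table combn head packageVersion
NULL

#' Configuration for the TMT screen simulator
#'
#' Parameters of the synthetic 10-plex TMT experiment: three biological
#' replicates per arm (control, treated, and optionally a time-zero arm) plus
#' an optional bridge channel.  Reporter noise is multiplicative lognormal
#' with the given coefficient of variation; a configurable minority of
#' proteins carries a treatment-induced fold change.
#'
#' @slot nProteins number of simulated proteins.
#' @slot nReplicatesPerArm biological replicates per arm (>= 2).
#' @slot fracRegulated fraction of proteins with a true fold change != 1.
#' @slot foldChangeRange range (positive) from which true fold changes of
#'   regulated proteins are drawn uniformly.
#' @slot cv coefficient of variation of the multiplicative reporter noise.
#' @slot peptidesPerProteinLambda Poisson rate; peptides per protein are
#'   drawn as 1 + Poisson(lambda).
#' @slot decoyFraction fraction of PSMs that are decoys.
#' @slot posteriorTarget,posteriorDecoy Beta(a, b) parameters for target and
#'   decoy PSM posterior probabilities.
#' @slot baseIntensity signal-to-noise scale of protein abundances.
#' @slot sharedPeptideFraction fraction of peptides shared between two
#'   proteins (exercises parsimony inference).
#' @slot includeT0 simulate a third, time-zero arm (excluded from contrasts).
#' @slot includeBridge add a pooled bridge channel (excluded from contrasts).
#' @slot seed integer seed fixing all randomness.
#'
#' @seealso [tmtSimConfig()], [simulateTmt()]
#' @export
setClass("TmtSimConfig",
  representation(
    nProteins = "integer",
    nReplicatesPerArm = "integer",
    fracRegulated = "numeric",
    foldChangeRange = "numeric",
    cv = "numeric",
    peptidesPerProteinLambda = "numeric",
    decoyFraction = "numeric",
    posteriorTarget = "numeric",
    posteriorDecoy = "numeric",
    baseIntensity = "numeric",
    sharedPeptideFraction = "numeric",
    includeT0 = "logical",
    includeBridge = "logical",
    seed = "integer"
  ),
  prototype(
    nProteins = 1000L,
    nReplicatesPerArm = 3L,
    fracRegulated = 0.05,
    foldChangeRange = c(1.15, 3.6),
    cv = 0.1,
    peptidesPerProteinLambda = 2,
    decoyFraction = 0.05,
    posteriorTarget = c(20, 1),
    posteriorDecoy = c(1, 3),
    baseIntensity = 200,
    sharedPeptideFraction = 0.05,
    includeT0 = TRUE,
    includeBridge = TRUE,
    seed = 1L
  )
)

setValidity("TmtSimConfig", function(object) {
  msg <- character()
  inUnit <- function(x) is.finite(x) && x >= 0 && x <= 1
  if (object@nProteins < 0L) msg <- c(msg, "nProteins must be >= 0")
  if (object@nReplicatesPerArm < 2L)
    msg <- c(msg, "nReplicatesPerArm must be >= 2")
  if (!inUnit(object@fracRegulated))
    msg <- c(msg, "fracRegulated must lie in [0, 1]")
  if (!inUnit(object@decoyFraction) || object@decoyFraction >= 1)
    msg <- c(msg, "decoyFraction must lie in [0, 1)")
  if (!inUnit(object@sharedPeptideFraction))
    msg <- c(msg, "sharedPeptideFraction must lie in [0, 1]")
  if (length(object@foldChangeRange) != 2L ||
      any(!is.finite(object@foldChangeRange)) ||
      any(object@foldChangeRange <= 0) ||
      diff(object@foldChangeRange) < 0)
    msg <- c(msg, "foldChangeRange must be a non-decreasing pair of positive reals")
  if (!is.finite(object@cv) || object@cv < 0)
    msg <- c(msg, "cv must be a non-negative finite number")
  if (!is.finite(object@baseIntensity) || object@baseIntensity <= 0)
    msg <- c(msg, "baseIntensity must be positive and finite")
  if (object@peptidesPerProteinLambda < 0 ||
      !is.finite(object@peptidesPerProteinLambda))
    msg <- c(msg, "peptidesPerProteinLambda must be non-negative and finite")
  for (nm in c("posteriorTarget", "posteriorDecoy")) {
    p <- slot(object, nm)
    if (length(p) != 2L || any(!is.finite(p)) || any(p <= 0))
      msg <- c(msg, paste(nm, "must be two positive Beta parameters"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TMT simulation configuration
#'
#' @param nProteins,nReplicatesPerArm,fracRegulated,foldChangeRange,cv
#'   see [TmtSimConfig-class].
#' @param peptidesPerProteinLambda,decoyFraction,posteriorTarget,posteriorDecoy
#'   see [TmtSimConfig-class].
#' @param baseIntensity,sharedPeptideFraction,includeT0,includeBridge,seed
#'   see [TmtSimConfig-class].
#' @return a validated [TmtSimConfig-class] object.
#' @examples
#' cfg <- tmtSimConfig(nProteins = 50, seed = 7)
#' @export
tmtSimConfig <- function(nProteins = 1000, nReplicatesPerArm = 3,
                         fracRegulated = 0.05,
                         foldChangeRange = c(1.15, 3.6), cv = 0.1,
                         peptidesPerProteinLambda = 2, decoyFraction = 0.05,
                         posteriorTarget = c(20, 1), posteriorDecoy = c(1, 3),
                         baseIntensity = 200, sharedPeptideFraction = 0.05,
                         includeT0 = TRUE, includeBridge = TRUE, seed = 1) {
  new("TmtSimConfig",
    nProteins = as.integer(nProteins),
    nReplicatesPerArm = as.integer(nReplicatesPerArm),
    fracRegulated = as.numeric(fracRegulated),
    foldChangeRange = as.numeric(foldChangeRange),
    cv = as.numeric(cv),
    peptidesPerProteinLambda = as.numeric(peptidesPerProteinLambda),
    decoyFraction = as.numeric(decoyFraction),
    posteriorTarget = as.numeric(posteriorTarget),
    posteriorDecoy = as.numeric(posteriorDecoy),
    baseIntensity = as.numeric(baseIntensity),
    sharedPeptideFraction = as.numeric(sharedPeptideFraction),
    includeT0 = isTRUE(includeT0),
    includeBridge = isTRUE(includeBridge),
    seed = as.integer(seed)
  )
}

setMethod("show", "TmtSimConfig", function(object) {
  cat("TmtSimConfig\n")
  cat("  proteins:", object@nProteins,
      "| replicates/arm:", object@nReplicatesPerArm,
      "| t0 arm:", object@includeT0,
      "| bridge:", object@includeBridge, "\n")
  cat("  regulated fraction:", object@fracRegulated,
      "| fold-change range: [",
      paste(object@foldChangeRange, collapse = ", "), "]\n")
  cat("  reporter CV:", object@cv,
      "| base S/N:", object@baseIntensity,
      "| decoy fraction:", object@decoyFraction, "\n")
  cat("  seed:", object@seed, "\n")
  invisible(object)
})

#' Two-arm contrast over quantification channels
#'
#' Identifies the treated and control channel indices of a relative-abundance
#' matrix.  Bridge and time-zero channels are simply left out of the
#' contrast.
#'
#' @slot treated,control integer channel indices (disjoint, each >= 2).
#' @slot labels character(2): treated and control arm labels.
#' @seealso [tmtContrast()]
#' @export
setClass("TmtContrast",
  representation(treated = "integer", control = "integer",
                 labels = "character"))

setValidity("TmtContrast", function(object) {
  msg <- character()
  if (length(object@treated) < 2L || length(object@control) < 2L)
    msg <- c(msg, "each arm needs at least two channels")
  if (length(intersect(object@treated, object@control)))
    msg <- c(msg, "treated and control channels must be disjoint")
  if (any(object@treated < 1L) || any(object@control < 1L))
    msg <- c(msg, "channel indices must be positive")
  if (length(object@labels) != 2L)
    msg <- c(msg, "labels must be character(2): treated, control")
  if (length(msg)) msg else TRUE
})

#' Construct a contrast between two arms
#'
#' @param treated,control integer channel indices, or -- when `x` is given --
#'   arm labels to look up in `x`.
#' @param x optional `SummarizedExperiment` (or channel `data.frame` with
#'   columns `channel` and `arm`) from which labelled arms are resolved.
#' @param labels arm labels, `c(treated, control)`.
#' @return a [TmtContrast-class] object.
#' @examples
#' tmtContrast(treated = 4:6, control = 1:3)
#' @export
tmtContrast <- function(treated, control, x = NULL,
                        labels = c("treated", "control")) {
  if (!is.null(x)) {
    arms <- if (is(x, "SummarizedExperiment")) {
      as.character(SummarizedExperiment::colData(x)$arm)
    } else as.character(x$arm)
    tIdx <- which(arms == treated)
    cIdx <- which(arms == control)
    labels <- c(as.character(treated), as.character(control))
    treated <- tIdx
    control <- cIdx
  }
  new("TmtContrast", treated = as.integer(treated),
      control = as.integer(control), labels = as.character(labels))
}

setMethod("show", "TmtContrast", function(object) {
  cat("TmtContrast:", object@labels[1], "(channels",
      paste(object@treated, collapse = ","), ") vs",
      object@labels[2], "(channels",
      paste(object@control, collapse = ","), ")\n")
  invisible(object)
})

#' @describeIn TmtContrast-class treated channel indices
#' @param object a `TmtContrast`.
#' @export
treatedChannels <- function(object) object@treated

#' @describeIn TmtContrast-class control channel indices
#' @export
controlChannels <- function(object) object@control
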