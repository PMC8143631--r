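#' Simulate a PSM-level TMT screen with known ground truth
#'
#' Emulates the statistical structure of a G1 APC/C-inhibition screen: a
#' 10-plex design quantifying each protein in biological triplicate per arm,
#' with a minority of proteins stabilised by treatment.  Each PSM carries
#' per-channel reporter signal-to-noise equal to
#' `base intensity x peptide share x arm fold change x lognormal noise`,
#' where the noise is mean-one multiplicative lognormal at the configured
#' coefficient of variation (`cv = 0` gives exactly noiseless channels).
#' Decoy PSMs carry the `"decoy_"` identifier prefix and low posterior
#' probabilities so that picked target-decoy FDR pairing is unambiguous.
#'
#' @param config a [TmtSimConfig-class] object.
#' @return a list with elements
#'   \describe{
#'     \item{psm}{PSM table: `psm_id`, `peptide`, `proteins`
#'       (semicolon-separated candidates), `is_decoy`, `posterior`,
#'       `ch1..chN`.}
#'     \item{channels}{channel design: `channel`, `arm`, `replicate`.}
#'     \item{truth}{ground truth: per-protein true fold change, regulated
#'       flags, and the echoed configuration.}
#'   }
#' @examples
#' sim <- simulateTmt(tmtSimConfig(nProteins = 20, seed = 3))
#' head(sim$psm)
#' @export
simulateTmt <- function(config) {
  stopifnot(is(config, "TmtSimConfig"))
  validObject(config)
  set.seed(config@seed)

  channels <- .tmtChannelDesign(config@nReplicatesPerArm,
                                config@includeT0, config@includeBridge)
  nCh <- nrow(channels)
  chCols <- paste0("ch", seq_len(nCh))

  if (config@nProteins == 0L) {
    psm <- data.frame(psm_id = character(), peptide = character(),
                      proteins = character(), is_decoy = logical(),
                      posterior = numeric(), stringsAsFactors = FALSE)
    for (cc in chCols) psm[[cc]] <- numeric()
    truth <- list(protein = character(), foldChange = numeric(),
                  regulated = logical(), config = config)
    return(list(psm = psm, channels = channels, truth = truth))
  }

  n <- config@nProteins
  proteins <- sprintf("P%05d", seq_len(n))
  nReg <- round(config@fracRegulated * n)
  regulated <- logical(n)
  if (nReg > 0) regulated[sample.int(n, nReg)] <- TRUE
  fc <- rep(1, n)
  if (nReg > 0)
    fc[regulated] <- runif(nReg, config@foldChangeRange[1],
                           config@foldChangeRange[2])
  names(fc) <- names(regulated) <- proteins

  abundance <- rlnorm(n, meanlog = log(config@baseIntensity), sdlog = 1)
  nPep <- 1L + rpois(n, config@peptidesPerProteinLambda)

  pepProtein <- rep(seq_len(n), nPep)
  nPsm <- length(pepProtein)
  peptide <- .randomPeptides(nPsm)
  # flanking ionization efficiency: each peptide sees a share of its protein
  share <- rlnorm(nPsm, meanlog = -0.5, sdlog = 0.7)

  # per-channel arm multiplier per protein
  armMult <- matrix(1, nrow = n, ncol = nCh)
  armMult[, channels$arm == "treated"] <- fc
  if (any(channels$arm == "bridge")) {
    nArms <- if (config@includeT0) 3 else 2
    armMult[, channels$arm == "bridge"] <- (fc + (nArms - 1)) / nArms
  }

  sigma <- sqrt(log(1 + config@cv^2))
  base <- abundance[pepProtein] * share
  sn <- base * armMult[pepProtein, , drop = FALSE]
  if (sigma > 0) {
    noise <- matrix(rlnorm(nPsm * nCh, meanlog = -sigma^2 / 2, sdlog = sigma),
                    nrow = nPsm)
    sn <- sn * noise
  }

  protList <- as.list(proteins[pepProtein])
  nShared <- round(config@sharedPeptideFraction * nPsm)
  if (nShared > 0 && n > 1) {
    sharedIdx <- sample.int(nPsm, nShared)
    for (i in sharedIdx) {
      other <- sample(setdiff(seq_len(n), pepProtein[i]), 1L)
      protList[[i]] <- sort(c(protList[[i]], proteins[other]))
    }
  }

  posterior <- rbeta(nPsm, config@posteriorTarget[1], config@posteriorTarget[2])

  # decoys: decoyFraction of the final PSM table
  nDecoy <- round(config@decoyFraction / (1 - config@decoyFraction) * nPsm)
  if (nDecoy > 0) {
    decoyOf <- sample.int(n, nDecoy, replace = TRUE)
    decoyPep <- .randomPeptides(nDecoy)
    decoyPost <- rbeta(nDecoy, config@posteriorDecoy[1],
                       config@posteriorDecoy[2])
    decoyBase <- rlnorm(nDecoy, meanlog = log(config@baseIntensity) - 0.5,
                        sdlog = 1)
    decoySn <- matrix(decoyBase, nrow = nDecoy, ncol = nCh)
    if (sigma > 0)
      decoySn <- decoySn *
        matrix(rlnorm(nDecoy * nCh, -sigma^2 / 2, sigma), nrow = nDecoy)
    sn <- rbind(sn, decoySn)
    protList <- c(protList, as.list(paste0("decoy_", proteins[decoyOf])))
    peptide <- c(peptide, decoyPep)
    posterior <- c(posterior, decoyPost)
  }
  isDecoy <- c(rep(FALSE, nPsm), rep(TRUE, nDecoy))

  psm <- data.frame(
    psm_id = sprintf("PSM%06d", seq_along(peptide)),
    peptide = peptide,
    proteins = vapply(protList, paste, "", collapse = ";"),
    is_decoy = isDecoy,
    posterior = posterior,
    stringsAsFactors = FALSE
  )
  colnames(sn) <- chCols
  psm <- cbind(psm, as.data.frame(sn))
  rownames(psm) <- NULL

  truth <- list(protein = proteins, foldChange = fc, regulated = regulated,
                config = config)
  list(psm = psm, channels = channels, truth = truth)
}

.tmtChannelDesign <- function(nRep, includeT0, includeBridge) {
  arm <- c(rep("control", nRep), rep("treated", nRep),
           if (includeT0) rep("t0", nRep),
           if (includeBridge) "bridge")
  replicate <- c(seq_len(nRep), seq_len(nRep),
                 if (includeT0) seq_len(nRep),
                 if (includeBridge) 1L)
  data.frame(channel = paste0("ch", seq_along(arm)), arm = arm,
             replicate = replicate, stringsAsFactors = FALSE)
}

.randomPeptides <- function(n, minLen = 8L, maxLen = 18L) {
  if (n == 0L) return(character())
  lens <- sample(minLen:maxLen, n, replace = TRUE)
  aa <- strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]]  # tryptic core, K/R at end
  body <- vapply(lens, function(l)
    paste(sample(aa, l - 1L, replace = TRUE), collapse = ""), "")
  paste0(body, sample(c("K", "R"), n, replace = TRUE))
}
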