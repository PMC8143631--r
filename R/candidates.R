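#' @title Candidate nomination and pipeline orchestration
#' @description Integrates differential results and degron hits into the
#'   candidate table (grouped by D-box / KEN-box / both), and runs the
#'   end-to-end screen: quantification, differential statistics,
#'   known-substrate threshold calibration, degron scanning and filtering,
#'   and nomination, with a machine-readable run manifest.
#' @name candidate-caller
NULL

#' Nominate candidate substrates
#'
#' A protein is nominated when it passed the screen filter and carries at
#' least one passing D-box (minimal or extended; set `dMinEligible = FALSE`
#' to require the extended form) or KEN-box hit.  The degron group is
#' assigned from the classes that passed; within each group, records are
#' sorted by descending fold change with ties broken lexicographically.
#' Per class, the best-scoring passing hit supplies the reported similarity
#' and disorder scores (use `allHits = TRUE` to get all passing scores,
#' slash-separated).
#'
#' @param screenHits screen-passing differential results (see
#'   [screenFilter()]).
#' @param degronHits filtered hit table (see [filterHits()]).
#' @param dMinEligible do minimal D-boxes (without the extended form) make a
#'   protein eligible?
#' @param allHits report all passing hit scores per class, not just the best.
#' @return data.frame of candidates: `protein`, `degron_group` (`D_box`,
#'   `KEN_box`, `D_and_KEN`), `fc`, `p`, `n_peptides`,
#'   `best_d_similarity`, `best_d_disorder`, `best_k_similarity`,
#'   `best_k_disorder`.
#' @export
callCandidates <- function(screenHits, degronHits, dMinEligible = TRUE,
                           allHits = FALSE) {
  emptyOut <- data.frame(protein = character(), degron_group = character(),
                         fc = numeric(), p = numeric(),
                         n_peptides = integer(),
                         best_d_similarity = character(),
                         best_d_disorder = character(),
                         best_k_similarity = character(),
                         best_k_disorder = character(),
                         previously_reported = logical(),
                         stringsAsFactors = FALSE)
  if (!nrow(screenHits) || !nrow(degronHits)) return(emptyOut)
  dClasses <- if (dMinEligible) c("D_min", "D_ext") else "D_ext"
  pass <- degronHits[degronHits$passes, , drop = FALSE]
  pass <- pass[pass$protein %in% screenHits$protein, , drop = FALSE]
  if (!nrow(pass)) return(emptyOut)

  fmt <- function(x) {
    x <- x[order(-x)]
    if (!allHits) x <- x[1L]
    paste(formatC(x, digits = 2, format = "f"), collapse = "/")
  }
  rows <- lapply(split(pass, pass$protein), function(h) {
    d <- h[h$class %in% dClasses, , drop = FALSE]
    k <- h[h$class == "KEN", , drop = FALSE]
    if (!nrow(d) && !nrow(k)) return(NULL)
    group <- if (nrow(d) && nrow(k)) "D_and_KEN"
             else if (nrow(d)) "D_box" else "KEN_box"
    s <- screenHits[screenHits$protein == h$protein[1L], , drop = FALSE]
    data.frame(protein = h$protein[1L], degron_group = group,
               fc = s$fc[1L], p = s$p[1L], n_peptides = s$n_peptides[1L],
               best_d_similarity = if (nrow(d)) fmt(d$similarity) else NA,
               best_d_disorder = if (nrow(d))
                 fmt(d$disorder[order(-d$similarity)]) else NA,
               best_k_similarity = if (nrow(k)) fmt(k$similarity) else NA,
               best_k_disorder = if (nrow(k))
                 fmt(k$disorder[order(-k$similarity)]) else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  grpOrder <- c(D_box = 1L, KEN_box = 2L, D_and_KEN = 3L)
  out <- out[order(grpOrder[out$degron_group], -out$fc, out$protein), ,
             drop = FALSE]
  rownames(out) <- NULL
  out$previously_reported <- FALSE
  out
}

#' Flag previously reported substrates
#'
#' @param candidates candidate table from [callCandidates()].
#' @param knownSubstrates character vector of known-substrate identifiers.
#' @return `candidates` with the `previously_reported` flag set by
#'   membership.
#' @export
annotateKnown <- function(candidates, knownSubstrates) {
  candidates$previously_reported <-
    candidates$protein %in% knownSubstrates
  candidates
}

#' Simulate a coherent end-to-end screen dataset
#'
#' Builds every pipeline input over one protein namespace with a single
#' ground truth: a proteome with degrons planted on the novel substrates
#' (and on a few unregulated proteins, to exercise specificity), a PSM-level
#' TMT table in which novel substrates and a set of "known" substrates are
#' regulated, disorder and localization tables, and the known-substrate
#' list.  Known-substrate fold changes are drawn with true median
#' `knownFcMedian`, so threshold calibration can be exercised; novel
#' substrates carry at least `substrateMinPeptides` distinct peptides
#' because the nomination rule requires multi-peptide quantification.
#'
#' @param nProteins total simulated proteins.
#' @param nSubstrates novel degron-bearing regulated proteins.
#' @param nKnown known (previously reported) regulated substrates.
#' @param nIndirect regulated proteins without degrons (indirect effects).
#' @param nDegronNull unregulated proteins carrying planted degrons.
#' @param substrateFcRange fold-change range of novel substrates.
#' @param knownFcMedian true median fold change of the known substrates.
#' @param cv reporter coefficient of variation.
#' @param substrateMinPeptides minimum distinct peptides for substrates.
#' @param seed integer seed.
#' @return list with `psm`, `channels`, `proteome`, `disorder`,
#'   `localization`, `knownSubstrates` and `truth` (which records
#'   `substrates`, `known`, `indirect`, `degronNull`, per-protein
#'   `foldChange` and planted spans).
#' @export
simulateScreen <- function(nProteins = 1000, nSubstrates = 20, nKnown = 38,
                           nIndirect = 20, nDegronNull = 15,
                           substrateFcRange = c(1.5, 3),
                           knownFcMedian = 1.15, cv = 0.05,
                           substrateMinPeptides = 2, seed = 1) {
  stopifnot(nSubstrates + nKnown + nIndirect + nDegronNull <= nProteins)
  seed <- as.integer(seed)
  proteins <- sprintf("P%05d", seq_len(nProteins))
  set.seed(seed)
  groups <- split(sample(proteins),
                  rep(c("substrate", "known", "indirect", "degronNull",
                        "null"),
                      c(nSubstrates, nKnown, nIndirect, nDegronNull,
                        nProteins - nSubstrates - nKnown - nIndirect -
                          nDegronNull)))

  # proteome: degrons planted on novel substrates and on some null proteins
  degronCarriers <- c(groups$substrate, groups$degronNull)
  prot <- simulateProteome(
    nProteins, lengthRange = c(200L, 500L),
    plantedDegrons = c(D_ext = length(degronCarriers)),
    seed = seed + 1L, plantOn = degronCarriers)
  # also give half of the carriers a KEN box
  kenOn <- degronCarriers[seq_len(ceiling(length(degronCarriers) / 2))]
  protKen <- simulateProteome(
    nProteins, lengthRange = c(200L, 500L),
    plantedDegrons = c(KEN = length(kenOn)),
    seed = seed + 2L, plantOn = kenOn)
  # merge KEN plants into the D_ext proteome (disjoint random positions)
  seqs <- as.character(prot$proteome)
  kenTruth <- protKen$truth
  keep <- logical(nrow(kenTruth))
  for (i in seq_len(nrow(kenTruth))) {
    p <- kenTruth$protein[i]
    span <- kenTruth$start[i]:kenTruth$end[i]
    if (max(span) > nchar(seqs[[p]])) next
    other <- prot$truth[prot$truth$protein == p, , drop = FALSE]
    clash <- any(vapply(seq_len(nrow(other)), function(j)
      any(span %in% (other$start[j]:other$end[j])), TRUE))
    if (clash) next
    substr(seqs[[p]], kenTruth$start[i], kenTruth$end[i]) <- kenTruth$seq[i]
    prot$disorder$score[prot$disorder$protein == p &
                          prot$disorder$position %in% span] <-
      runif(length(span), 0.6, 0.9)
    keep[i] <- TRUE
  }
  planted <- rbind(prot$truth, kenTruth[keep, , drop = FALSE])
  proteome <- Biostrings::AAStringSet(seqs)

  # TMT table with the designated regulation structure
  set.seed(seed + 3L)
  fc <- setNames(rep(1, nProteins), proteins)
  fc[groups$substrate] <- runif(nSubstrates, substrateFcRange[1],
                                substrateFcRange[2])
  fc[groups$known] <- exp(rnorm(nKnown, log(knownFcMedian), 0.25))
  fc[groups$indirect] <- runif(nIndirect, 1.15, 2)
  cfg <- tmtSimConfig(nProteins = nProteins, cv = cv, fracRegulated = 0,
                      seed = seed + 4L)
  sim <- simulateTmt(cfg)
  sim$truth$foldChange <- fc
  sim$truth$regulated <- fc != 1
  # re-scale treated (and bridge) channels to the designated fold changes
  sim$psm <- .applyFoldChanges(sim$psm, sim$channels, fc, cfg)
  # nomination requires >1 peptide: guarantee the floor for novel substrates
  set.seed(seed + 5L)
  sim$psm <- .ensureMinPeptides(sim$psm, groups$substrate,
                                substrateMinPeptides, cfg)

  list(psm = sim$psm, channels = sim$channels, proteome = proteome,
       disorder = prot$disorder, localization = prot$localization,
       knownSubstrates = groups$known,
       truth = list(substrates = groups$substrate, known = groups$known,
                    indirect = groups$indirect,
                    degronNull = groups$degronNull,
                    foldChange = fc, regulated = fc != 1,
                    planted = planted))
}

# add peptides (cloned channel structure, fresh share and noise) until each
# listed protein has at least `minPep` distinct peptides
.ensureMinPeptides <- function(psm, proteins, minPep, cfg) {
  if (minPep <= 1L || !length(proteins)) return(psm)
  chCols <- grep("^ch[0-9]+$", names(psm), value = TRUE)
  sigma <- sqrt(log(1 + cfg@cv^2))
  first <- sub(";.*", "", psm$proteins)
  extra <- list()
  for (p in proteins) {
    idx <- which(first == p & !psm$is_decoy)
    if (!length(idx)) next
    nPep <- length(unique(psm$peptide[idx]))
    while (nPep < minPep) {
      tmpl <- psm[idx[1L], , drop = FALSE]
      tmpl$psm_id <- sprintf("PSM%06d", nrow(psm) + length(extra) + 1L)
      tmpl$peptide <- .randomPeptides(1L)
      tmpl$proteins <- p
      tmpl$posterior <- rbeta(1, cfg@posteriorTarget[1],
                              cfg@posteriorTarget[2])
      share <- rlnorm(1, meanlog = -0.5, sdlog = 0.7)
      noise <- if (sigma > 0)
        rlnorm(length(chCols), -sigma^2 / 2, sigma) else 1
      tmpl[, chCols] <- as.numeric(tmpl[, chCols]) * share * noise
      extra[[length(extra) + 1L]] <- tmpl
      nPep <- nPep + 1L
    }
  }
  if (length(extra)) psm <- rbind(psm, do.call(rbind, extra))
  rownames(psm) <- NULL
  psm
}

# multiply treated/bridge channels of target PSMs by their protein's fc
.applyFoldChanges <- function(psm, channels, fc, cfg) {
  treatedCols <- channels$channel[channels$arm == "treated"]
  bridgeCols <- channels$channel[channels$arm == "bridge"]
  first <- sub(";.*", "", psm$proteins)
  m <- fc[first]
  m[is.na(m) | psm$is_decoy] <- 1
  for (cc in treatedCols) psm[[cc]] <- psm[[cc]] * m
  if (length(bridgeCols)) {
    nArms <- if (cfg@includeT0) 3 else 2
    bm <- (m + (nArms - 1)) / nArms
    for (cc in bridgeCols) psm[[cc]] <- psm[[cc]] * bm
  }
  psm
}

#' Run the end-to-end screen
#'
#' Orchestrates quantification, differential statistics, threshold
#' calibration, degron scanning/filtering and candidate nomination.  Inputs
#' may be in-memory objects (as produced by [simulateScreen()]) or file
#' paths; a YAML config file naming the inputs may be supplied instead.
#' Any stage failure aborts with the stage name and cause; an empty PSM
#' table yields an empty report with a warning, not an error.  The run
#' manifest records parameters, the calibrated fold-change threshold
#' actually used, package version and per-stage row counts.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `psm` (table or TSV path), `channels` (design table; required with
#'   in-memory `psm`), `proteome` (named sequences or FASTA path),
#'   `disorder` (track or TSV path; `NULL` uses the built-in heuristic),
#'   `localization` (table or TSV path), `known_substrates` (vector or text
#'   file), and optional parameters `fdr_target` (0.01), `min_summed_sn`
#'   (100), `fc_threshold` (`"calibrate"` or a number), `min_peptides` (2),
#'   `alpha` (0.05), `classes`, `min_similarity` (0.75), `min_disorder`
#'   (0.4), `d_min_eligible` (TRUE), `contrast` (`c("treated", "control")`
#'   arm labels), `seed`.
#' @param outDir optional output directory for the intermediate tables,
#'   candidate report (TSV + JSON) and manifest.
#' @return list with `quant`, `differential`, `screen`, `degronHits`,
#'   `candidates`, `manifest`.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  getOpt <- function(name, default) {
    if (!is.null(config[[name]])) config[[name]] else default
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  counts <- list()

  psm <- stage("read_psms", {
    if (is.character(config$psm)) readPsmTable(config$psm) else config$psm
  })
  channels <- config$channels
  if (is.character(channels)) channels <- read.delim(channels)
  if (is.null(channels))
    stop("pipeline stage 'read_psms' failed: channel design required")
  counts$psms <- nrow(psm)

  emptyBundle <- function() {
    warning("empty PSM input: returning an empty report")
    list(quant = NULL, differential = data.frame(),
         screen = data.frame(), degronHits = data.frame(),
         candidates = data.frame(),
         manifest = list(counts = counts, empty_input = TRUE))
  }
  if (nrow(psm) == 0L) return(emptyBundle())

  se <- stage("quantify", quantifyProteins(
    psm, channels, fdrTarget = getOpt("fdr_target", 0.01),
    minSummedSN = getOpt("min_summed_sn", 100),
    normalizeFirst = isTRUE(getOpt("normalize_first", FALSE))))
  counts$proteins_quantified <- nrow(se)

  contrastArms <- getOpt("contrast", c("treated", "control"))
  contrast <- stage("contrast",
    tmtContrast(contrastArms[1], contrastArms[2], x = se))
  alpha <- getOpt("alpha", 0.05)
  diffRes <- stage("differential",
    runDifferential(se, contrast, alpha = alpha))

  known <- getOpt("known_substrates", character())
  if (is.character(known) && length(known) == 1L && file.exists(known))
    known <- readKnownSubstrates(known)
  fcOpt <- getOpt("fc_threshold", "calibrate")
  fcThreshold <- stage("fc_threshold", {
    if (identical(fcOpt, "calibrate"))
      calibrateFcThreshold(diffRes, known)
    else as.numeric(fcOpt)
  })

  screen <- stage("screen_filter", screenFilter(
    diffRes, fcThreshold, minPeptides = getOpt("min_peptides", 2),
    alpha = alpha))
  counts$screen_passing <- nrow(screen)

  proteome <- config$proteome
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome)) {
    proteome <- Biostrings::readAAStringSet(proteome)
    names(proteome) <- sub("\\s.*", "", names(proteome))
  }
  disorder <- config$disorder
  if (is.character(disorder)) disorder <- readDisorderTrack(disorder)
  localization <- config$localization
  if (is.character(localization))
    localization <- readLocalization(localization)

  hits <- stage("degron_scan", {
    if (is(proteome, "XStringSet")) proteome <- as.character(proteome)
    sub <- proteome[names(proteome) %in% screen$protein]
    missing <- setdiff(screen$protein, names(proteome))
    if (length(missing))
      warning("screen-passing protein(s) missing from the proteome: ",
              paste(missing, collapse = ", "))
    scanProteome(sub, disorder, localization,
                 classes = getOpt("classes", c("D_min", "D_ext", "KEN")),
                 minSimilarity = getOpt("min_similarity", 0.75),
                 minDisorder = getOpt("min_disorder", 0.4))
  })
  counts$degron_hits <- nrow(hits)
  counts$degron_hits_passing <- sum(hits$passes)

  candidates <- stage("call_candidates", {
    cand <- callCandidates(screen, hits,
                           dMinEligible = isTRUE(getOpt("d_min_eligible",
                                                        TRUE)))
    annotateKnown(cand, known)
  })
  counts$candidates <- nrow(candidates)

  # monotone filtering cascade, asserted on every run
  stopifnot(all(candidates$protein %in% screen$protein),
            all(screen$protein %in% rownames(se)))

  manifest <- list(
    package = "degronScreen",
    version = as.character(packageVersion("degronScreen")),
    parameters = list(
      fdr_target = getOpt("fdr_target", 0.01),
      min_summed_sn = getOpt("min_summed_sn", 100),
      fc_threshold_requested = fcOpt,
      fc_threshold_used = fcThreshold,
      min_peptides = getOpt("min_peptides", 2),
      alpha = alpha,
      min_similarity = getOpt("min_similarity", 0.75),
      min_disorder = getOpt("min_disorder", 0.4),
      contrast = contrastArms,
      seed = getOpt("seed", NA)),
    counts = counts)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeProteinRA(se, file.path(outDir, "protein_ra.tsv"))
    write.table(diffRes, file.path(outDir, "differential.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(hits, file.path(outDir, "degron_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(candidates, file.path(outDir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(candidates,
                         file.path(outDir, "candidates.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(quant = se, differential = diffRes, screen = screen,
       degronHits = hits, candidates = candidates, manifest = manifest)
}
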