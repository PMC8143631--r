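#' @title PSM-to-protein quantification
#' @description Turns a PSM-level reporter table into protein-level relative
#'   abundances: summed-S/N filtering, column normalization, protein
#'   probability from peptide posteriors, picked target-decoy protein FDR,
#'   maximum-parsimony protein inference, and scaling each protein's channel
#'   vector to sum to 100 (the relative-abundance, RA, convention).
#' @name psm-quant
NULL

.snColumns <- function(psm) grep("^ch[0-9]+$", names(psm), value = TRUE)

.snMatrix <- function(psm) {
  cols <- .snColumns(psm)
  if (!length(cols)) stop("no reporter channels (ch1..chN) in PSM table")
  as.matrix(psm[, cols, drop = FALSE])
}

#' Column-normalize reporter channels
#'
#' Corrects for unequal protein loading: every channel is rescaled by
#' `mean(raw channel totals) / (that channel's raw total)`, so that
#' afterwards all channel totals are equal (to the mean of the raw totals,
#' keeping values on the input scale).
#'
#' @param psm PSM table with reporter columns `ch1..chN`.
#' @return the PSM table with rescaled channels.
#' @examples
#' psm <- data.frame(psm_id = "a", peptide = "PEPK", proteins = "P1",
#'                   is_decoy = FALSE, posterior = 0.99, ch1 = 2, ch2 = 4)
#' columnNormalize(psm)[, c("ch1", "ch2")]  # both totals become 3
#' @export
columnNormalize <- function(psm) {
  if (nrow(psm) == 0L) return(psm)
  sn <- .snMatrix(psm)
  totals <- colSums(sn)
  if (any(totals <= 0))
    stop("channel(s) with zero total signal-to-noise: ",
         paste(colnames(sn)[totals <= 0], collapse = ", "))
  factors <- mean(totals) / totals
  psm[, colnames(sn)] <- sweep(sn, 2L, factors, `*`)
  psm
}

#' Drop PSMs with low summed signal-to-noise
#'
#' Retains exactly the PSMs whose channel sum is at least `minTotal`
#' (default 100, the conventional instrument-scale cutoff; the boundary is
#' inclusive -- strictly smaller sums are excluded).
#'
#' @param psm PSM table.
#' @param minTotal minimum summed S/N across channels.
#' @return the filtered PSM table.
#' @export
filterLowSN <- function(psm, minTotal = 100) {
  if (nrow(psm) == 0L) return(psm)
  psm[rowSums(.snMatrix(psm)) >= minTotal, , drop = FALSE]
}

#' Protein-level probability from peptide posteriors
#'
#' The protein probability is the product of per-peptide posterior
#' probabilities (best posterior per distinct peptide sequence), accumulated
#' in log space for numerical stability.
#'
#' @param posteriors numeric posteriors in \[0, 1\].
#' @param peptides optional peptide sequences, one per posterior; when given,
#'   only the best posterior per distinct peptide enters the product.
#' @return a probability in \[0, 1\].
#' @examples
#' proteinProbability(c(0.9, 0.8))  # 0.72
#' @export
proteinProbability <- function(posteriors, peptides = NULL) {
  if (!length(posteriors)) stop("at least one posterior required")
  if (any(posteriors < 0 | posteriors > 1))
    stop("posteriors must lie in [0, 1]")
  if (!is.null(peptides)) {
    stopifnot(length(peptides) == length(posteriors))
    posteriors <- vapply(split(posteriors, peptides), max, 0)
  }
  if (any(posteriors == 0)) {
    warning("posterior of zero encountered; protein probability is 0")
    return(0)
  }
  exp(sum(log(posteriors)))
}

#' Picked target-decoy protein FDR
#'
#' For every target/decoy protein pair (paired via the `"decoy_"` identifier
#' prefix) only the higher-scoring member is kept ("picking"); survivors are
#' ranked by descending score; the FDR at each cutoff is
#' `#decoys at-or-above / #targets at-or-above`; q-values are monotonized
#' from the bottom of the list; targets with `q <= fdrTarget` are accepted.
#' Score ties are broken decoy-first (conservative); a picked pair tie keeps
#' the target.
#'
#' @param proteinScores data.frame with columns `protein` (base identifier,
#'   i.e. without the decoy prefix), `is_decoy`, `score`.
#' @param fdrTarget target FDR in (0, 1\].
#' @return the picked, ranked table with columns `protein`, `is_decoy`,
#'   `score`, `fdr`, `q` and `accepted` (targets only).
#' @examples
#' tab <- data.frame(protein = c("A", "B", "C", "A", "B", "C"),
#'                   is_decoy = rep(c(FALSE, TRUE), each = 3),
#'                   score = c(0.99, 0.95, 0.60, 0.50, 0.97, 0.55))
#' pickedProteinFdr(tab, 0.01)
#' @export
pickedProteinFdr <- function(proteinScores, fdrTarget = 0.01) {
  if (!is.finite(fdrTarget) || fdrTarget <= 0 || fdrTarget > 1)
    stop("fdrTarget must lie in (0, 1]")
  stopifnot(all(c("protein", "is_decoy", "score") %in% names(proteinScores)))
  x <- proteinScores
  if (nrow(x) == 0L)
    return(cbind(x, fdr = numeric(), q = numeric(), accepted = logical()))
  # picking: keep the better-scoring member of each target/decoy pair
  keep <- logical(nrow(x))
  for (idx in split(seq_len(nrow(x)), x$protein)) {
    best <- idx[order(-x$score[idx], x$is_decoy[idx])][1L]
    keep[best] <- TRUE
  }
  x <- x[keep, , drop = FALSE]
  x <- x[order(-x$score, !x$is_decoy), , drop = FALSE]
  nDecoy <- cumsum(x$is_decoy)
  nTarget <- cumsum(!x$is_decoy)
  x$fdr <- ifelse(nTarget == 0, Inf, nDecoy / nTarget)
  x$q <- rev(cummin(rev(x$fdr)))
  x$accepted <- !x$is_decoy & x$q <= fdrTarget
  rownames(x) <- NULL
  x
}

#' Maximum-parsimony protein inference
#'
#' Collapses the candidate proteins of a PSM table to a minimum-cardinality
#' set explaining every peptide.  Ambiguity groups (connected components of
#' the peptide-protein graph) with up to `exactLimit` proteins are solved by
#' exhaustive minimum set cover; larger groups fall back to the standard
#' greedy cover (approximation factor `ln`(#peptides)).  Among minimum
#' covers the lexicographically smallest protein set is chosen; each shared
#' peptide is then assigned to the retained candidate covering the most
#' peptides (ties broken lexicographically).
#'
#' @param psm PSM table (`peptide`, `proteins` semicolon-separated), or a
#'   named list mapping peptide -> candidate protein vector.
#' @param exactLimit largest ambiguity-group size solved exactly.
#' @return list with `proteins` (retained set) and `assignment` (named
#'   character vector, peptide -> protein).
#' @examples
#' psm <- data.frame(peptide = c("p1", "p2", "p3", "p4"),
#'                   proteins = c("X;Y", "X", "Y;Z", "Z"))
#' parsimonyCollapse(psm)$proteins  # "X" "Z"
#' @export
parsimonyCollapse <- function(psm, exactLimit = 12L) {
  pepProts <- if (is.data.frame(psm)) {
    pp <- strsplit(psm$proteins, ";", fixed = TRUE)
    names(pp) <- psm$peptide
    # merge duplicate peptide rows (same sequence may have several PSMs)
    lapply(split(pp, names(pp)), function(l) sort(unique(unlist(l))))
  } else {
    lapply(psm, function(p) sort(unique(p)))
  }
  if (!length(pepProts))
    return(list(proteins = character(), assignment = character()))
  if (any(lengths(pepProts) == 0L))
    stop("every peptide must name at least one candidate protein")

  # connected components over shared proteins (union-find on proteins)
  allProt <- sort(unique(unlist(pepProts)))
  parent <- seq_along(allProt)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (cand in pepProts) {
    ids <- match(cand, allProt)
    r <- find(ids[1L])
    for (j in ids[-1L]) parent[find(j)] <- r
  }
  comp <- vapply(seq_along(allProt), find, 0L)
  compOfPep <- vapply(pepProts, function(p) comp[match(p[1L], allProt)], 0L)

  retained <- character()
  for (cp in unique(comp)) {
    peps <- pepProts[compOfPep == cp]
    prots <- sort(unique(unlist(peps)))
    cover <- if (length(prots) <= exactLimit)
      .exactCover(peps, prots) else .greedyCover(peps, prots)
    retained <- c(retained, cover)
  }
  retained <- sort(retained)

  # razor assignment: retained candidate covering the most peptides
  coverage <- table(unlist(lapply(pepProts, intersect, retained)))
  assignment <- vapply(pepProts, function(cand) {
    opts <- intersect(cand, retained)
    opts[order(-as.numeric(coverage[opts]), opts)][1L]
  }, "")
  list(proteins = retained, assignment = assignment)
}

.exactCover <- function(peps, prots) {
  pepSets <- lapply(peps, function(p) match(p, prots))
  m <- length(prots)
  for (k in seq_len(m)) {
    sets <- combn(m, k, simplify = FALSE)  # lexicographic order
    for (s in sets) {
      if (all(vapply(pepSets, function(ps) any(ps %in% s), TRUE)))
        return(prots[s])
    }
  }
  prots
}

.greedyCover <- function(peps, prots) {
  uncovered <- seq_along(peps)
  chosen <- character()
  while (length(uncovered)) {
    gain <- vapply(prots, function(pr)
      sum(vapply(peps[uncovered], function(p) pr %in% p, TRUE)), 0)
    best <- prots[order(-gain, prots)][1L]
    chosen <- c(chosen, best)
    uncovered <- uncovered[!vapply(peps[uncovered],
                                   function(p) best %in% p, TRUE)]
    prots <- setdiff(prots, best)
  }
  chosen
}

#' Roll PSMs up to protein relative abundances
#'
#' Per protein, channel values are summed over its assigned PSMs and the
#' resulting vector is scaled so that it sums to 100 (the RA convention).
#' Proteins whose channel vector is all zero are dropped with a warning.
#'
#' @param psm PSM table whose `proteins` column holds a single assigned
#'   protein per PSM (see [parsimonyCollapse()]).
#' @param channels optional channel design data.frame (`channel`, `arm`,
#'   `replicate`) stored as `colData`.
#' @return a `SummarizedExperiment` with assay `ra` (proteins x channels)
#'   and `rowData` column `n_peptides` (distinct peptide sequences).
#' @export
rollupToRA <- function(psm, channels = NULL) {
  sn <- .snMatrix(psm)
  if (any(grepl(";", psm$proteins, fixed = TRUE)))
    stop("PSMs must be assigned to a single protein before rollup")
  prot <- psm$proteins
  sums <- rowsum(sn, prot)
  nPep <- vapply(split(psm$peptide, prot), function(p) length(unique(p)), 0L)
  nPep <- nPep[rownames(sums)]
  tot <- rowSums(sums)
  if (any(tot == 0)) {
    warning("dropping protein(s) with all-zero channel vector: ",
            paste(rownames(sums)[tot == 0], collapse = ", "))
    keep <- tot > 0
    sums <- sums[keep, , drop = FALSE]
    nPep <- nPep[keep]
    tot <- tot[keep]
  }
  ra <- 100 * sums / tot
  cd <- if (!is.null(channels)) {
    S4Vectors::DataFrame(channels[match(colnames(ra), channels$channel), ,
                                  drop = FALSE], row.names = colnames(ra))
  } else S4Vectors::DataFrame(row.names = colnames(ra))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(ra = ra),
    rowData = S4Vectors::DataFrame(n_peptides = as.integer(nPep),
                                   row.names = rownames(ra)),
    colData = cd)
}

#' Full PSM-to-protein quantification chain
#'
#' Runs the identification and quantification rules in order: protein
#' probabilities from peptide posteriors; picked protein FDR at
#' `fdrTarget`; removal of decoy PSMs and rejected proteins;
#' maximum-parsimony collapse; summed-S/N filtering (on the raw instrument
#' scale by default) and column normalization; rollup to relative
#' abundances.  Set `normalizeFirst = TRUE` to normalize before the S/N
#' filter instead.
#'
#' Column normalization equalizes channel totals and therefore assumes the
#' regulated protein mass is a negligible share of the total; when treatment
#' shifts a substantial mass, fold changes are compressed toward 1
#' (compositional bias).  `normalize = "none"` skips the loading correction,
#' e.g. for data with loading equalized by construction.
#'
#' @param psm PSM table as written by [simulateTmt()] / [readPsmTable()].
#' @param channels optional channel design data.frame.
#' @param fdrTarget picked protein FDR target (default 0.01).
#' @param minSummedSN summed-S/N exclusion threshold (default 100).
#' @param normalize `"total"` (equalize channel totals) or `"none"`.
#' @param normalizeFirst normalize before the S/N filter.
#' @return a `SummarizedExperiment` (see [rollupToRA()]) with extra
#'   `rowData` columns `protein_probability` and `q_value`.
#' @export
quantifyProteins <- function(psm, channels = NULL, fdrTarget = 0.01,
                             minSummedSN = 100,
                             normalize = c("total", "none"),
                             normalizeFirst = FALSE) {
  normalize <- match.arg(normalize)
  normFun <- if (normalize == "total") columnNormalize else identity
  if (nrow(psm) == 0L) stop("empty PSM table")
  cand <- strsplit(psm$proteins, ";", fixed = TRUE)

  # identification: probability per candidate protein over all its PSMs
  protein <- unlist(cand)
  peptide <- rep(psm$peptide, lengths(cand))
  posterior <- rep(psm$posterior, lengths(cand))
  idx <- split(seq_along(protein), protein)
  scores <- vapply(idx, function(i)
    proteinProbability(posterior[i], peptide[i]), 0)
  base <- sub("^decoy_", "", names(scores))
  fdrTab <- pickedProteinFdr(
    data.frame(protein = base, is_decoy = startsWith(names(scores), "decoy_"),
               score = unname(scores), stringsAsFactors = FALSE),
    fdrTarget)
  accepted <- fdrTab$protein[fdrTab$accepted]

  # quantification-side PSM set: targets whose candidates survived
  cand <- lapply(cand, intersect, accepted)
  keep <- !psm$is_decoy & lengths(cand) > 0L
  psmQ <- psm[keep, , drop = FALSE]
  psmQ$proteins <- vapply(cand[keep], paste, "", collapse = ";")
  if (nrow(psmQ) == 0L)
    stop("no PSMs survive protein FDR filtering")

  if (normalizeFirst) {
    psmQ <- normFun(psmQ)
    psmQ <- filterLowSN(psmQ, minSummedSN)
  } else {
    psmQ <- filterLowSN(psmQ, minSummedSN)
    psmQ <- normFun(psmQ)
  }
  if (nrow(psmQ) == 0L)
    stop("no PSMs survive the summed signal-to-noise filter")

  pars <- parsimonyCollapse(psmQ)
  psmQ$proteins <- unname(pars$assignment[psmQ$peptide])
  se <- rollupToRA(psmQ, channels)

  rd <- SummarizedExperiment::rowData(se)
  rd$protein_probability <- unname(scores[rownames(se)])
  qv <- fdrTab$q[match(rownames(se), fdrTab$protein)]
  rd$q_value <- qv
  SummarizedExperiment::rowData(se) <- rd
  se
}
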