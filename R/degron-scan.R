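#' @title Degron motif scanning and filtering
#' @description Scans protein sequences for APC/C degrons -- minimal D-box
#'   (`RxxL`), extended D-box (`RxxLxxxxN`) and KEN-box (`KEN`) -- scores
#'   hits against a reference alignment with a position-weight matrix,
#'   annotates per-hit disorder and localization, and applies the hit-level
#'   filters (similarity >= 0.75, consensus medium or high, disorder >= 0.4,
#'   intracellular and non-secreted).  Coordinates are 1-based inclusive
#'   throughout.
#' @name degron-scan
NULL

.degronPatterns <- list(
  D_min = list(regex = "R..L",      length = 4L),
  D_ext = list(regex = "R..L....N", length = 9L),
  KEN   = list(regex = "KEN",       length = 3L)
)

#' Packaged reference degron alignment
#'
#' A small synthetic stand-in alignment of D-box / KEN-box sequences with
#' the correct anchor residues, shipped for scoring and for planting motifs
#' in simulations.  It is not the validated-substrate alignment used by
#' dedicated motif servers; substitute your own alignment (a named list of
#' equal-length sequences per class) for production scoring.
#'
#' @param file optional path to a TSV with columns `class`, `sequence`.
#' @return named list of character vectors, one per degron class.
#' @export
referenceDegrons <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "degron_reference_synthetic.tsv",
                        package = "degronScreen", mustWork = TRUE)
  tab <- read.delim(file, stringsAsFactors = FALSE)
  split(tab$sequence, tab$class)
}

#' Scan sequences for degron motifs
#'
#' Reports every occurrence, including overlapping and nested ones: a span
#' matching the extended D-box is reported as `D_ext` and additionally as
#' `D_min` over its first four residues when `D_min` is requested (flagged
#' in `nested_in_ext`).  Anchored positions never match the unknown residue
#' `X`; wildcard positions match any residue.
#'
#' @param sequences named character vector or `AAStringSet`.
#' @param classes degron classes to scan for (subset of `"D_min"`,
#'   `"D_ext"`, `"KEN"`, plus names of `custom` patterns).
#' @param custom optional named list of custom motif classes, each
#'   `list(regex = , length = )` -- e.g. a user-supplied ABBA consensus (no
#'   default is provided).
#' @return data.frame of hits: `protein`, `class`, `start`, `end`,
#'   `matched_seq`, `nested_in_ext`.
#' @examples
#' scanMotifs(c(A = "AAKENAA"), "KEN")
#' @export
scanMotifs <- function(sequences, classes = c("D_min", "D_ext", "KEN"),
                       custom = NULL) {
  if (is(sequences, "XStringSet")) sequences <- as.character(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  patterns <- c(.degronPatterns, custom)
  unknown <- setdiff(classes, names(patterns))
  if (length(unknown))
    stop("unknown degron class(es): ", paste(unknown, collapse = ", "))
  hits <- list()
  for (cls in classes) {
    pat <- patterns[[cls]]
    rx <- paste0("(?=", pat$regex, ")")  # lookahead: overlapping matches
    for (nm in names(sequences)) {
      s <- sequences[[nm]]
      if (!nzchar(s)) next
      m <- gregexpr(rx, s, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      starts <- as.integer(m)
      starts <- starts[starts + pat$length - 1L <= nchar(s)]
      if (!length(starts)) next
      hits[[length(hits) + 1L]] <- data.frame(
        protein = nm, class = cls, start = starts,
        end = starts + pat$length - 1L,
        matched_seq = substring(s, starts, starts + pat$length - 1L),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(protein = character(), class = character(),
               start = integer(), end = integer(),
               matched_seq = character(), stringsAsFactors = FALSE)
  out$nested_in_ext <- logical(nrow(out))
  if (nrow(out)) {
    ext <- out[out$class == "D_ext", c("protein", "start")]
    if (nrow(ext)) {
      key <- paste(out$protein, out$start)
      out$nested_in_ext <- out$class == "D_min" &
        key %in% paste(ext$protein, ext$start)
    }
    out <- out[order(out$protein, out$start, out$class), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# PWM log-odds score of one sequence (pseudocount 1, uniform background)
.pwmLogOdds <- function(refs) {
  L <- nchar(refs[1L])
  if (any(nchar(refs) != L)) stop("reference sequences must be aligned")
  counts <- matrix(0, nrow = length(.AA20), ncol = L,
                   dimnames = list(.AA20, NULL))
  for (r in refs) {
    res <- strsplit(r, "")[[1L]]
    for (j in seq_len(L)) counts[res[j], j] <- counts[res[j], j] + 1
  }
  freq <- (counts + 1) / (length(refs) + 20)
  log(freq / (1 / 20))
}

.pwmScore <- function(seq, lo) {
  res <- strsplit(seq, "")[[1L]]
  sum(vapply(seq_along(res), function(j) {
    v <- lo[res[j], j]
    if (is.na(v)) min(lo[, j]) else v   # unknown residue scores worst
  }, 0))
}

#' Position-weight-matrix similarity score
#'
#' Scores each hit's matched sequence against the reference alignment of its
#' class: a log-odds PWM is built from the references (pseudocount 1,
#' uniform 1/20 background) and the hit's summed log-odds is min-max
#' rescaled so that the best-scoring reference sequence maps to 1 and the
#' worst possible sequence to 0 (values are clamped to \[0, 1\]; a hit can
#' only reach 1 by matching the references at least as well as the best
#' reference itself).
#'
#' @param hits hit table from [scanMotifs()].
#' @param references named list of reference alignments per class (default:
#'   the packaged alignment, [referenceDegrons()]).
#' @return `hits` with a `similarity` column and a `consensus_class` column
#'   (see [assignConsensusClass()]).
#' @export
similarityScore <- function(hits, references = referenceDegrons()) {
  hits$similarity <- NA_real_
  for (cls in unique(hits$class)) {
    refs <- references[[cls]]
    if (is.null(refs))
      stop("no reference alignment for class ", cls)
    sel <- hits$class == cls
    if (any(nchar(hits$matched_seq[sel]) != nchar(refs[1L])))
      stop("hit length differs from the reference alignment length")
    lo <- .pwmLogOdds(refs)
    best <- max(vapply(refs, .pwmScore, 0, lo = lo))
    worst <- sum(apply(lo, 2L, min))
    raw <- vapply(hits$matched_seq[sel], .pwmScore, 0, lo = lo)
    hits$similarity[sel] <- pmin(1, pmax(0, (raw - worst) / (best - worst)))
  }
  hits$consensus_class <- assignConsensusClass(hits$similarity)
  hits
}

#' Consensus-similarity class from the similarity score
#'
#' The categorical consensus-similarity output is derived from the same
#' similarity score: `high` at or above `high`, `medium` at or above
#' `medium`, `low` otherwise.  The boundaries are configurable because no
#' canonical definition of the categories exists.
#'
#' @param similarity numeric scores in \[0, 1\].
#' @param high,medium class boundaries (inclusive).
#' @return character vector of `"low"`, `"medium"`, `"high"`.
#' @export
assignConsensusClass <- function(similarity, high = 0.9, medium = 0.75) {
  ifelse(similarity >= high, "high",
         ifelse(similarity >= medium, "medium", "low"))
}

#' Annotate hits with mean disorder over their span
#'
#' @param hits hit table from [scanMotifs()].
#' @param disorderTrack data.frame `protein`, `position`, `score` covering
#'   every hit span (missing residues are an error).
#' @return `hits` with a `disorder` column.
#' @export
annotateDisorder <- function(hits, disorderTrack) {
  byProt <- split(disorderTrack, disorderTrack$protein)
  hits$disorder <- vapply(seq_len(nrow(hits)), function(i) {
    tr <- byProt[[hits$protein[i]]]
    if (is.null(tr))
      stop("no disorder track for protein ", hits$protein[i])
    pos <- hits$start[i]:hits$end[i]
    sc <- tr$score[match(pos, tr$position)]
    if (anyNA(sc))
      stop("disorder track for ", hits$protein[i],
           " does not cover positions ", hits$start[i], "-", hits$end[i])
    mean(sc)
  }, 0)
  hits
}

#' Apply the hit-level degron filters
#'
#' A hit passes when similarity >= `minSimilarity`, the consensus class is
#' allowed, mean disorder >= `minDisorder` (all boundaries inclusive), and
#' the protein is intracellular and non-secreted.  Proteins absent from the
#' localization table are treated as intracellular and non-secreted, with a
#' warning.
#'
#' @param hits scored, disorder-annotated hit table.
#' @param localization data.frame `protein`, `intracellular`, `secreted`
#'   (or `NULL` to treat everything as intracellular).
#' @param minSimilarity,minDisorder,allowedConsensus filter parameters.
#' @return `hits` with `intracellular`, `secreted` and `passes` columns.
#' @export
filterHits <- function(hits, localization = NULL, minSimilarity = 0.75,
                       minDisorder = 0.4,
                       allowedConsensus = c("medium", "high")) {
  if (is.null(localization)) {
    hits$intracellular <- TRUE
    hits$secreted <- FALSE
  } else {
    idx <- match(hits$protein, localization$protein)
    if (anyNA(idx))
      warning("protein(s) absent from the localization table treated as ",
              "intracellular, non-secreted: ",
              paste(unique(hits$protein[is.na(idx)]), collapse = ", "))
    hits$intracellular <- ifelse(is.na(idx), TRUE,
                                 localization$intracellular[idx])
    hits$secreted <- ifelse(is.na(idx), FALSE, localization$secreted[idx])
  }
  hits$passes <- hits$similarity >= minSimilarity &
    hits$consensus_class %in% allowedConsensus &
    hits$disorder >= minDisorder &
    hits$intracellular & !hits$secreted
  hits
}

#' Scan, score and filter a proteome in one call
#'
#' @param proteome named character vector or `AAStringSet`.
#' @param disorder per-residue disorder track (data.frame), or `NULL` to
#'   fall back on the built-in heuristic ([predictDisorder()]; clearly not
#'   equivalent to curated disorder predictions).
#' @param localization localization table or `NULL`.
#' @param classes degron classes to scan.
#' @param references reference alignments (see [similarityScore()]).
#' @param ... further arguments to [filterHits()].
#' @return annotated hit table with a `passes` column.
#' @export
scanProteome <- function(proteome, disorder = NULL, localization = NULL,
                         classes = c("D_min", "D_ext", "KEN"),
                         references = referenceDegrons(), ...) {
  hits <- scanMotifs(proteome, classes)
  if (!nrow(hits)) {
    for (col in c("similarity", "consensus_class", "disorder",
                  "intracellular", "secreted", "passes"))
      hits[[col]] <- logical(0)
    return(hits)
  }
  hits <- similarityScore(hits, references)
  if (is.null(disorder)) {
    if (is(proteome, "XStringSet")) proteome <- as.character(proteome)
    disorder <- do.call(rbind, lapply(names(proteome), function(nm)
      data.frame(protein = nm,
                 position = seq_len(nchar(proteome[[nm]])),
                 score = predictDisorder(proteome[[nm]]),
                 stringsAsFactors = FALSE)))
  }
  hits <- annotateDisorder(hits, disorder)
  filterHits(hits, localization, ...)
}

# Kyte-Doolittle hydropathy
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

#' Heuristic per-residue disorder fallback
#'
#' A window-averaged charge/hydropathy heuristic: residues in windows of low
#' mean hydropathy and high charged-residue fraction score as disordered.
#' This is a coarse stand-in, not equivalent to curated disorder
#' predictors; supply a real disorder track whenever one is available.
#'
#' @param sequence a protein sequence.
#' @param window smoothing window (odd, default 21).
#' @return numeric vector of per-residue scores in \[0, 1\].
#' @export
predictDisorder <- function(sequence, window = 21L) {
  res <- strsplit(sequence, "")[[1L]]
  h <- .KD[res]
  h[is.na(h)] <- 0
  charged <- as.numeric(res %in% c("D", "E", "K", "R"))
  half <- window %/% 2L
  n <- length(res)
  smooth <- function(v) vapply(seq_len(n), function(i)
    mean(v[max(1L, i - half):min(n, i + half)]), 0)
  hN <- (smooth(h) + 4.5) / 9      # hydropathy mapped to [0, 1]
  pmin(1, pmax(0, 0.6 * (1 - hN) + 0.4 * smooth(charged)))
}

#' Packaged synthetic surrogate of the IRS2 sequence
#'
#' A 1338-residue synthetic sequence carrying a single extended D-box
#' (`RxxLxxxxN`) spanning residues 972-980, mirroring the documented
#' position of the degron in human IRS2.  The rest of the sequence is a
#' scrubbed random background (no other extended D-box), so it is a
#' surrogate for worked examples -- not the real IRS2 sequence.
#'
#' @return a named character vector of length 1.
#' @examples
#' seqs <- irs2SyntheticSequence()
#' scanMotifs(seqs, "D_ext")
#' @export
irs2SyntheticSequence <- function() {
  f <- system.file("extdata", "irs2_synthetic.fasta",
                   package = "degronScreen", mustWork = TRUE)
  s <- Biostrings::readAAStringSet(f)
  stats::setNames(as.character(s), sub("\\s.*", "", names(s)))
}
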