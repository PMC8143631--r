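#' Simulate a proteome with planted degron motifs
#'
#' Generates random protein sequences (uniform residue background over a
#' configurable alphabet) and plants degron motifs -- minimal D-boxes
#' (`RxxL`), extended D-boxes (`RxxLxxxxN`) and KEN-boxes -- at random
#' non-overlapping positions.  Planted motif sequences are sampled from the
#' packaged reference alignment (see [referenceDegrons()]) so that they score
#' highly under [similarityScore()].  Per-residue disorder tracks are
#' generated such that planted spans sit in disordered regions (score >=
#' 0.4), and a localization table marks every protein intracellular and
#' non-secreted unless `fracSecreted > 0`.
#'
#' @param nProteins number of proteins.
#' @param lengthRange integer range of protein lengths.
#' @param plantedDegrons named integer vector, e.g.
#'   `c(D_ext = 5, KEN = 3)`: number of proteins receiving one planted
#'   motif of each class.  A protein may receive motifs of several classes.
#' @param alphabet residue alphabet for the background sequence.
#' @param fracSecreted fraction of proteins flagged secreted.
#' @param seed integer seed.
#' @param plantOn optional protein identifiers to restrict planting to.
#' @return list with `proteome` (named `AAStringSet`), `disorder`
#'   (data.frame `protein`, `position`, `score`), `localization`
#'   (data.frame `protein`, `intracellular`, `secreted`) and `truth`
#'   (data.frame of planted spans: `protein`, `class`, `start`, `end`,
#'   `seq`).
#' @examples
#' sim <- simulateProteome(10, plantedDegrons = c(D_ext = 3), seed = 2)
#' sim$truth
#' @export
simulateProteome <- function(nProteins, lengthRange = c(200L, 600L),
                             plantedDegrons = c(D_ext = 0L, KEN = 0L),
                             alphabet = .AA20, fracSecreted = 0,
                             seed = 1, plantOn = NULL) {
  stopifnot(nProteins >= 0, length(lengthRange) == 2L,
            lengthRange[1] >= 1, fracSecreted >= 0, fracSecreted <= 1)
  set.seed(as.integer(seed))
  proteins <- sprintf("P%05d", seq_len(nProteins))
  lens <- if (nProteins)
    sample(lengthRange[1]:lengthRange[2], nProteins, replace = TRUE)
  else integer()
  seqs <- vapply(lens, function(l)
    paste(sample(alphabet, l, replace = TRUE), collapse = ""), "")
  names(seqs) <- proteins

  motifLens <- c(D_min = 4L, D_ext = 9L, KEN = 3L)
  plantedDegrons <- plantedDegrons[plantedDegrons > 0]
  if (length(plantedDegrons) &&
      !all(names(plantedDegrons) %in% names(motifLens)))
    stop("unknown degron class in plantedDegrons")

  refs <- referenceDegrons()
  truth <- list()
  occupied <- lapply(seq_len(nProteins), function(i) integer())
  eligible <- if (is.null(plantOn)) proteins else intersect(proteins, plantOn)

  for (cls in names(plantedDegrons)) {
    mlen <- motifLens[[cls]]
    pool <- eligible[lens[match(eligible, proteins)] >= mlen]
    cnt <- plantedDegrons[[cls]]
    if (length(pool) < cnt)
      stop("not enough proteins long enough to plant ", cls, " motifs")
    chosen <- sample(pool, cnt)
    for (p in chosen) {
      i <- match(p, proteins)
      start <- .freePosition(lens[i], mlen, occupied[[i]])
      if (is.na(start))
        stop("requested motif does not fit in protein ", p)
      motif <- sample(refs[[cls]], 1L)
      substr(seqs[i], start, start + mlen - 1L) <- motif
      occupied[[i]] <- c(occupied[[i]], seq(start, start + mlen - 1L))
      truth[[length(truth) + 1L]] <- data.frame(
        protein = p, class = cls, start = start, end = start + mlen - 1L,
        seq = motif, stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(protein = character(), class = character(),
               start = integer(), end = integer(), seq = character(),
               stringsAsFactors = FALSE)

  disorder <- .simulateDisorder(proteins, lens, truth)
  secreted <- if (nProteins) runif(nProteins) < fracSecreted else logical()
  if (nrow(truth)) secreted[match(unique(truth$protein), proteins)] <- FALSE
  localization <- data.frame(protein = proteins,
                             intracellular = !secreted,
                             secreted = secreted, stringsAsFactors = FALSE)

  proteome <- Biostrings::AAStringSet(seqs)
  list(proteome = proteome, disorder = disorder,
       localization = localization, truth = truth)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.freePosition <- function(len, mlen, occupied, tries = 200L) {
  if (len < mlen) return(NA_integer_)
  for (k in seq_len(tries)) {
    s <- sample.int(len - mlen + 1L, 1L)
    if (!any(seq(s, s + mlen - 1L) %in% occupied)) return(s)
  }
  NA_integer_
}

# smooth per-residue disorder; planted spans forced into disordered regions
.simulateDisorder <- function(proteins, lens, truth) {
  if (!length(proteins))
    return(data.frame(protein = character(), position = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    l <- lens[i]
    base <- runif(1, 0.1, 0.6)
    sc <- pmin(1, pmax(0, base + cumsum(rnorm(l, 0, 0.03))))
    spans <- truth[truth$protein == proteins[i], , drop = FALSE]
    if (nrow(spans)) {
      for (j in seq_len(nrow(spans)))
        sc[spans$start[j]:spans$end[j]] <-
          runif(spans$end[j] - spans$start[j] + 1L, 0.6, 0.9)
    }
    out[[i]] <- data.frame(protein = proteins[i], position = seq_len(l),
                           score = sc, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
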