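# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# exhaustive sliding-window motif matcher (position constraints only)
bruteScan <- function(seq, anchors, len) {
  res <- strsplit(seq, "")[[1L]]
  n <- length(res)
  hits <- integer()
  if (n < len) return(hits)
  for (s in seq_len(n - len + 1L)) {
    ok <- TRUE
    for (off in names(anchors)) {
      if (res[s + as.integer(off) - 1L] != anchors[[off]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

degronAnchors <- list(
  D_min = list(anchors = c("1" = "R", "4" = "L"), len = 4L),
  D_ext = list(anchors = c("1" = "R", "4" = "L", "9" = "N"), len = 9L),
  KEN   = list(anchors = c("1" = "K", "2" = "E", "3" = "N"), len = 3L)
)

# exhaustive minimum set cover; returns the lexicographically smallest
# minimum cover (elements of `pepSets` are character vectors of proteins)
bruteSetCover <- function(pepSets) {
  prots <- sort(unique(unlist(pepSets)))
  m <- length(prots)
  best <- NULL
  for (k in seq_len(m)) {
    for (s in utils::combn(m, k, simplify = FALSE)) {
      cand <- prots[s]
      if (all(vapply(pepSets, function(p) any(p %in% cand), TRUE))) {
        best <- cand
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

# target-decoy FDR by exhaustive threshold sweep over every picked score
bruteFdrAccept <- function(picked, fdrTarget) {
  # picked: data.frame(protein, is_decoy, score) after picking
  qs <- vapply(seq_len(nrow(picked)), function(i) {
    cut <- picked$score[i]
    fdrs <- vapply(sort(unique(picked$score)), function(th) {
      nd <- sum(picked$is_decoy & picked$score >= th)
      nt <- sum(!picked$is_decoy & picked$score >= th)
      if (nt == 0) Inf else nd / nt
    }, 0)
    ths <- sort(unique(picked$score))
    min(fdrs[ths <= cut])  # best attainable FDR at a cutoff including i
  }, 0)
  sort(picked$protein[!picked$is_decoy & qs <= fdrTarget])
}

# direct PWM log-odds summation (pseudocount 1, uniform 1/20 background)
brutePwmScore <- function(seq, refs) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  L <- nchar(refs[1])
  counts <- matrix(0, 20, L, dimnames = list(aa, NULL))
  for (r in refs) {
    rs <- strsplit(r, "")[[1]]
    for (j in 1:L) counts[rs[j], j] <- counts[rs[j], j] + 1
  }
  lo <- log(((counts + 1) / (length(refs) + 20)) * 20)
  rs <- strsplit(seq, "")[[1]]
  sum(vapply(1:L, function(j) lo[rs[j], j], 0))
}

randomSeq <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  paste(sample(alphabet, len, replace = TRUE), collapse = "")

binomSE <- function(p, n) sqrt(p * (1 - p) / n)
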