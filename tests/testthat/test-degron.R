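test_that("motif scanning finds constructed KEN and D-box examples", {
  ken <- scanMotifs(c(A = "AAKENAA"), "KEN")
  expect_equal(nrow(ken), 1L)
  expect_equal(ken$start, 3L)
  expect_equal(ken$end, 5L)
  expect_equal(ken$matched_seq, "KEN")

  both <- scanMotifs(c(B = "ARVALHEQSNG"), c("D_min", "D_ext"))
  dmin <- both[both$class == "D_min", ]
  dext <- both[both$class == "D_ext", ]
  expect_equal(c(dmin$start, dmin$end), c(2L, 5L))
  expect_equal(dmin$matched_seq, "RVAL")
  expect_equal(c(dext$start, dext$end), c(2L, 10L))
  expect_equal(dext$matched_seq, "RVALHEQSN")
  expect_true(dmin$nested_in_ext)

  expect_equal(nrow(scanMotifs(c(E = ""), "KEN")), 0L)
  # X never matches an anchored position
  expect_equal(nrow(scanMotifs(c(X = "XENAKEX"), "KEN")), 0L)
})

test_that("overlapping occurrences are all reported", {
  s <- c(S = "RRRLLL")  # RxxL matches at 1, 2 and 3, all overlapping
  hits <- scanMotifs(s, "D_min")
  expect_equal(hits$start, c(1L, 2L, 3L))
})

test_that("scanner agrees with a brute-force window matcher on random sequences", {
  set.seed(17)
  for (i in 1:250) {
    s <- randomSeq(sample(30:120, 1))
    hits <- scanMotifs(setNames(s, "q"))
    for (cls in names(degronAnchors)) {
      got <- sort(hits$start[hits$class == cls])
      ora <- bruteScan(s, degronAnchors[[cls]]$anchors,
                       degronAnchors[[cls]]$len)
      expect_equal(got, ora)
    }
  }
})

test_that("hit count is invariant under sequence + pattern reversal", {
  revStr <- function(x) paste(rev(strsplit(x, "")[[1]]), collapse = "")
  revPatterns <- list(
    D_min_rev = list(regex = "L..R", length = 4L),
    D_ext_rev = list(regex = "N....L..R", length = 9L),
    KEN_rev = list(regex = "NEK", length = 3L))
  set.seed(23)
  for (i in 1:50) {
    s <- randomSeq(80)
    fwd <- scanMotifs(setNames(s, "a"))
    bwd <- scanMotifs(setNames(revStr(s), "a"),
                      classes = names(revPatterns), custom = revPatterns)
    for (cls in c("D_min", "D_ext", "KEN")) {
      expect_equal(sum(fwd$class == cls),
                   sum(bwd$class == paste0(cls, "_rev")))
    }
  }
})

test_that("similarity score honors its normalization contract", {
  refs <- referenceDegrons()
  # the best-scoring reference itself maps to 1
  h <- data.frame(protein = "r", class = "D_ext", start = 1, end = 9,
                  matched_seq = refs$D_ext, stringsAsFactors = FALSE)
  sc <- similarityScore(h)
  expect_equal(max(sc$similarity), 1)
  expect_true(all(sc$similarity >= 0 & sc$similarity <= 1))
  # worst possible sequence maps to 0 (anchors only, worst wildcards)
  lo <- degronScreen:::.pwmLogOdds(refs$D_ext)
  worstSeq <- paste(rownames(lo)[apply(lo, 2, which.min)], collapse = "")
  hw <- data.frame(protein = "w", class = "D_ext", start = 1, end = 9,
                   matched_seq = worstSeq, stringsAsFactors = FALSE)
  expect_equal(similarityScore(hw)$similarity, 0)
  # random 9-mers agree with a direct log-odds oracle
  set.seed(9)
  best <- max(vapply(refs$D_ext, brutePwmScore, 0, refs = refs$D_ext))
  worst <- brutePwmScore(worstSeq, refs$D_ext)
  for (i in 1:50) {
    seq9 <- paste0("R", randomSeq(2), "L", randomSeq(4), "N")
    hq <- data.frame(protein = "q", class = "D_ext", start = 1, end = 9,
                     matched_seq = seq9, stringsAsFactors = FALSE)
    oracle <- min(1, max(0, (brutePwmScore(seq9, refs$D_ext) - worst) /
                              (best - worst)))
    expect_equal(similarityScore(hq)$similarity, oracle, tolerance = 1e-12)
  }
  expect_error(similarityScore(data.frame(protein = "b", class = "D_ext",
                                          start = 1, end = 4,
                                          matched_seq = "RAAL")),
               "length")
})

test_that("disorder annotation averages the track over the hit span", {
  hit <- data.frame(protein = "P", class = "KEN", start = 3, end = 5,
                    matched_seq = "KEN", stringsAsFactors = FALSE)
  track <- data.frame(protein = "P", position = 1:10, score = rep(0.68, 10))
  expect_equal(annotateDisorder(hit, track)$disorder, 0.68)
  two <- data.frame(protein = "P", class = "X", start = 1, end = 2,
                    matched_seq = "AB")
  tr2 <- data.frame(protein = "P", position = 1:2, score = c(0, 1))
  expect_equal(annotateDisorder(two, tr2)$disorder, 0.5)
  short <- data.frame(protein = "P", position = 1:4, score = 0.5)
  expect_error(annotateDisorder(hit, short), "cover")
  expect_error(annotateDisorder(data.frame(protein = "Q", class = "KEN",
                                           start = 1, end = 3,
                                           matched_seq = "KEN"), track),
               "no disorder track")
})

test_that("hit filters apply the four rules with inclusive boundaries", {
  mkHit <- function(sim, dis, prot = "P") {
    h <- data.frame(protein = prot, class = "D_ext", start = 1, end = 9,
                    matched_seq = "RAALSEIGN", similarity = sim,
                    stringsAsFactors = FALSE)
    h$consensus_class <- assignConsensusClass(sim)
    h$disorder <- dis
    h
  }
  loc <- data.frame(protein = c("P", "S"), intracellular = c(TRUE, TRUE),
                    secreted = c(FALSE, TRUE))
  expect_true(filterHits(mkHit(0.87, 0.68), loc)$passes)    # Table-style row
  expect_true(filterHits(mkHit(0.75, 0.4), loc)$passes)     # boundaries
  expect_false(filterHits(mkHit(0.7499, 0.68), loc)$passes)
  expect_false(filterHits(mkHit(0.87, 0.399), loc)$passes)
  expect_false(filterHits(mkHit(0.87, 0.68, "S"), loc)$passes)  # secreted
  expect_warning(out <- filterHits(mkHit(0.87, 0.68, "Z"), loc),
                 "localization")
  expect_true(out$passes)  # absent -> intracellular, non-secreted
  # low consensus class blocks even if similarity filter is relaxed
  relax <- filterHits(mkHit(0.6, 0.9), loc, minSimilarity = 0.5)
  expect_false(relax$passes)
})

test_that("the packaged surrogate has its extended D-box at 972-980 and loses it under R972A", {
  seqs <- irs2SyntheticSequence()
  hits <- scanMotifs(seqs, "D_ext")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 972L)
  expect_equal(hits$end, 980L)
  mutant <- seqs
  substr(mutant, 972, 972) <- "A"
  expect_equal(nrow(scanMotifs(mutant, "D_ext")), 0L)
})

test_that("the built-in disorder heuristic is bounded and length-preserving", {
  s <- randomSeq(100)
  d <- predictDisorder(s)
  expect_length(d, 100)
  expect_true(all(d >= 0 & d <= 1))
  # poly-charged sequences score as more disordered than poly-hydrophobic
  expect_gt(mean(predictDisorder(strrep("KE", 30))),
            mean(predictDisorder(strrep("VI", 30))))
})
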