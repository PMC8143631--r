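makePsm <- function(sn, peptide = NULL, proteins = NULL, posterior = 0.99,
                    is_decoy = FALSE) {
  sn <- if (is.matrix(sn)) sn else matrix(sn, nrow = 1)
  n <- nrow(sn)
  df <- data.frame(psm_id = sprintf("p%03d", seq_len(n)),
                   peptide = peptide %||% sprintf("PEP%03dK", seq_len(n)),
                   proteins = proteins %||% rep("P1", n),
                   is_decoy = rep_len(is_decoy, n),
                   posterior = rep_len(posterior, n),
                   stringsAsFactors = FALSE)
  colnames(sn) <- paste0("ch", seq_len(ncol(sn)))
  cbind(df, as.data.frame(sn))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("column normalization equalizes channel totals (hand-computed cases)", {
  # two PSMs, totals [200, 100]; mean 150 -> factors 0.75 and 1.5
  psm <- makePsm(rbind(c(120, 40), c(80, 60)))
  out <- columnNormalize(psm)
  expect_equal(colSums(out[, c("ch1", "ch2")]), c(ch1 = 150, ch2 = 150))
  expect_equal(out$ch1, c(90, 60))
  expect_equal(out$ch2, c(60, 90))
  # single PSM [2, 4] -> [3, 3]
  one <- columnNormalize(makePsm(c(2, 4)))
  expect_equal(unlist(one[, c("ch1", "ch2")], use.names = FALSE), c(3, 3))
  # fixed point: already-equal totals unchanged
  eq <- makePsm(rbind(c(1, 2), c(3, 2)))
  expect_equal(columnNormalize(eq), eq)
  expect_error(columnNormalize(makePsm(c(0, 5))), "ch1")
})

test_that("column totals become equal to machine precision on random tables", {
  set.seed(1)
  for (i in 1:20) {
    psm <- makePsm(matrix(rlnorm(8 * 10, 3, 1), nrow = 8))
    tot <- colSums(as.matrix(columnNormalize(psm)[, paste0("ch", 1:10)]))
    expect_lt(diff(range(tot)) / mean(tot), 1e-12)
  }
})

test_that("summed-S/N filter uses a strict less-than-100 exclusion", {
  psm <- makePsm(rbind(c(50, 49.9), c(50, 50), c(60, 50)))
  out <- filterLowSN(psm)
  expect_equal(out$psm_id, c("p002", "p003"))  # 99.9 dropped, 100 retained
  expect_equal(nrow(filterLowSN(psm[0, ])), 0L)
})

test_that("protein probability is the posterior product, stable in log space", {
  expect_equal(proteinProbability(c(0.9, 0.8)), 0.72)
  expect_equal(proteinProbability(0.37), 0.37)
  # 100 peptides at 0.99: log-space result matches the closed form
  expect_equal(proteinProbability(rep(0.99, 100)), exp(100 * log(0.99)))
  # best posterior per distinct peptide
  expect_equal(proteinProbability(c(0.5, 0.9, 0.8),
                                  peptides = c("A", "A", "B")), 0.72)
  expect_warning(p0 <- proteinProbability(c(0.9, 0)), "zero")
  expect_equal(p0, 0)
  expect_error(proteinProbability(1.2), "0, 1")
})

test_that("picked FDR reproduces the worked example", {
  tab <- data.frame(protein = rep(c("A", "B", "C"), 2),
                    is_decoy = rep(c(FALSE, TRUE), each = 3),
                    score = c(0.99, 0.95, 0.60, 0.50, 0.97, 0.55))
  out <- pickedProteinFdr(tab, 0.01)
  expect_equal(out$protein, c("A", "B", "C"))
  expect_equal(out$is_decoy, c(FALSE, TRUE, FALSE))
  expect_equal(out$fdr, c(0, 1, 0.5))
  expect_equal(out$q, c(0, 0.5, 0.5))
  expect_equal(out$protein[out$accepted], "A")
  # no surviving decoys: all targets accepted at any positive target
  clean <- data.frame(protein = c("A", "B"), is_decoy = FALSE,
                      score = c(0.9, 0.1))
  expect_true(all(pickedProteinFdr(clean, 0.001)$accepted))
  expect_error(pickedProteinFdr(tab, 0), "fdrTarget")
})

test_that("picked FDR agrees with a threshold-sweep enumeration and is monotone", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:20, 1)
    prot <- paste0("P", seq_len(n))
    tab <- data.frame(
      protein = rep(prot, 2),
      is_decoy = rep(c(FALSE, TRUE), each = n),
      score = c(runif(n, 0.3, 1), runif(n, 0, 0.9)))
    target <- sample(c(0.05, 0.2, 0.5), 1)
    out <- pickedProteinFdr(tab, target)
    picked <- out[, c("protein", "is_decoy", "score")]
    expect_equal(sort(out$protein[out$accepted]),
                 bruteFdrAccept(picked, target))
    # accepted set shrinks monotonically with the target
    acc5 <- pickedProteinFdr(tab, 0.05)
    acc1 <- pickedProteinFdr(tab, 0.01)
    expect_true(all(acc1$protein[acc1$accepted] %in%
                    acc5$protein[acc5$accepted]))
  }
})

test_that("parsimony collapse solves the worked set-cover example", {
  psm <- data.frame(peptide = c("p1", "p2", "p3", "p4"),
                    proteins = c("X;Y", "X", "Y;Z", "Z"))
  out <- parsimonyCollapse(psm)
  expect_equal(out$proteins, c("X", "Z"))
  expect_equal(unname(out$assignment[c("p1", "p3")]), c("X", "Z"))
  # unique peptides: identity mapping
  uni <- data.frame(peptide = c("a", "b"), proteins = c("P1", "P2"))
  expect_equal(unname(parsimonyCollapse(uni)$assignment[c("a", "b")]),
               c("P1", "P2"))
  # identical peptide sets: lexicographically smallest identifier retained
  tie <- data.frame(peptide = c("a", "a", "b", "b"),
                    proteins = c("Q2;Q1", "Q2;Q1", "Q1;Q2", "Q1;Q2"))
  expect_equal(parsimonyCollapse(tie)$proteins, "Q1")
})

test_that("parsimony collapse matches exhaustive minimum set cover", {
  set.seed(11)
  for (i in 1:100) {
    nProt <- sample(3:9, 1)
    nPep <- sample(4:12, 1)
    prots <- paste0("P", sample(LETTERS, nProt))
    peps <- lapply(seq_len(nPep), function(j)
      sort(sample(prots, sample(1:min(3, nProt), 1))))
    names(peps) <- paste0("pep", seq_len(nPep))
    out <- parsimonyCollapse(peps)
    oracle <- bruteSetCover(peps)
    expect_equal(length(out$proteins), length(oracle))
    # every peptide covered by its assigned protein
    expect_true(all(vapply(names(peps), function(p)
      out$assignment[[p]] %in% peps[[p]], TRUE)))
  }
})

test_that("rollup scales protein vectors to sum to 100", {
  psm <- makePsm(rbind(c(2, 3, 5)))
  se <- rollupToRA(psm)
  expect_equal(as.numeric(SummarizedExperiment::assay(se, "ra")),
               c(20, 30, 50))
  # 3 ctrl + 3 treated at 1:2 -> 100/9 and 200/9
  psm2 <- makePsm(rbind(c(1, 1, 1, 2, 2, 2)))
  expect_equal(as.numeric(SummarizedExperiment::assay(rollupToRA(psm2), "ra")),
               c(rep(100 / 9, 3), rep(200 / 9, 3)))
  # invariance to global rescaling of the input S/N
  set.seed(2)
  m <- matrix(rlnorm(5 * 6), nrow = 5)
  p1 <- makePsm(m, proteins = rep(c("A", "B"), c(2, 3)))
  p2 <- makePsm(m * 1234, proteins = rep(c("A", "B"), c(2, 3)))
  expect_equal(SummarizedExperiment::assay(rollupToRA(p1), "ra"),
               SummarizedExperiment::assay(rollupToRA(p2), "ra"))
  expect_error(rollupToRA(makePsm(c(1, 2), proteins = "A;B")), "single")
})

test_that("RA vectors sum to 100 within 1e-9 across the full chain", {
  sim <- simulateTmt(tmtSimConfig(nProteins = 300, seed = 9))
  se <- quantifyProteins(sim$psm, sim$channels)
  sums <- rowSums(SummarizedExperiment::assay(se, "ra"))
  expect_true(all(abs(sums - 100) < 1e-9))
  expect_true(all(SummarizedExperiment::rowData(se)$n_peptides >= 1))
  # accepted proteins carry q-values at or under the target
  expect_true(all(SummarizedExperiment::rowData(se)$q_value <= 0.01))
  # no decoys get quantified
  expect_false(any(startsWith(rownames(se), "decoy_")))
})
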