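test_that("pooled-variance t-test matches a numeric-integration oracle", {
  out <- proteinTTest(c(1, 2, 3), c(2, 3, 4))
  expect_equal(out$statistic, -sqrt(1.5), tolerance = 1e-12)
  expect_equal(out$df, 4)
  # two-tailed p by numerical integration of the central t density
  dens <- function(t, df) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  pOracle <- 2 * stats::integrate(dens, abs(out$statistic), Inf,
                                  df = 4)$value
  expect_equal(out$p.value, pOracle, tolerance = 1e-6)
  expect_equal(out$p.value, 0.2878641, tolerance = 1e-4)

  ident <- proteinTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  expect_error(proteinTTest(c(5, 5, 5), c(5, 5, 5)), "variance")
  expect_error(proteinTTest(1, c(1, 2)), "two replicates")
})

test_that("t-test p-values agree with a permutation test on exchangeable data", {
  set.seed(21)
  x <- rlnorm(3, 0, 0.1); y <- rlnorm(3, 0, 0.1)
  obs <- proteinTTest(x, y)
  pool <- c(x, y)
  perms <- combn(6, 3, simplify = FALSE)
  tPerm <- vapply(perms, function(id) {
    a <- pool[id]; b <- pool[-id]
    (mean(a) - mean(b)) /
      sqrt((var(a) + var(b)) / 2 * (2 / 3))
  }, 0)
  pPerm <- mean(abs(tPerm) >= abs(obs$statistic) - 1e-12)
  # exact permutation p on 20 splits is coarse (granularity 0.05)
  expect_lt(abs(obs$p.value - pPerm), 0.15)
})

test_that("fold change is the ratio of arm means", {
  expect_equal(foldChange(c(115, 115, 115), c(100, 100, 100)), 1.15)
  expect_equal(foldChange(c(1, 2), c(1, 2)), 1)
  expect_equal(foldChange(c(10, 12, 14), c(5, 6, 7)), 2)
  expect_error(foldChange(c(1, 2), c(0, 0)), "control mean")
})

test_that("threshold calibration takes the median over detected known substrates", {
  res <- data.frame(protein = c("a", "b", "c", "d"),
                    fc = c(1.0, 1.15, 3.6, 9))
  expect_equal(calibrateFcThreshold(res, c("a", "b", "c")), 1.15)
  expect_equal(calibrateFcThreshold(res, c("a", "b")), 1.075)
  expect_error(calibrateFcThreshold(res, "nope"), "manual")
})

test_that("requiredN solves the noncentral-t power equation", {
  # effect so large the floor applies
  expect_equal(requiredN(sd = 1e-9, mean = 100), 2)
  # moderate effects: close to the normal approximation
  # 2 (z_.975 + z_.95)^2 / d^2 (small-sample t correction still modest)
  for (d in c(0.5, 1, 2)) {
    nd <- requiredN(sd = 1, mean = d / 0.15)
    approx <- 2 * (qnorm(0.975) + qnorm(0.95))^2 / d^2
    expect_lt(abs(nd - approx) / approx, 0.25)
  }
  # d = 3: the exact noncentral-t solution, pinned by simulation below
  n3 <- requiredN(sd = 0.05, mean = 1)  # d = 0.15/0.05 = 3
  expect_gt(n3, 2)
  expect_lt(n3, 6)
  # Monte-Carlo power at ceiling(n) reaches the target
  set.seed(5)
  n <- ceiling(n3)
  reps <- 2000
  hit <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n, 0.15, 0.05); y <- rnorm(n, 0, 0.05)
    t.test(x, y, var.equal = TRUE)$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hit), 0.95 - 2 * binomSE(0.95, reps))
  # monotone non-increasing in the effect size
  ds <- c(0.5, 1, 2, 3, 5)
  ns <- vapply(ds, function(d) requiredN(sd = 1, mean = d / 0.15), 0)
  expect_true(all(diff(ns) <= 1e-9))
  expect_error(requiredN(sd = 0, mean = 1), "positive")
})

test_that("screen filter applies the three nomination rules with stated boundaries", {
  res <- data.frame(protein = c("in", "onePep", "pAt05", "lowFc"),
                    fc = c(1.15, 1.3, 1.3, 1.1499),
                    p = c(0.01, 0.01, 0.05, 0.01),
                    n_peptides = c(3, 1, 3, 3))
  out <- screenFilter(res, fcThreshold = 1.15)
  expect_equal(out$protein, "in")  # fc boundary inclusive, p strict, >1 pep
})

test_that("knockout intersection requires direction-consistent significant changes", {
  mk <- function(fc, p) data.frame(protein = c("x", "y", "z"), fc = fc, p = p)
  r1 <- mk(c(0.70, 0.70, 0.79), c(0.01, 0.01, 0.01))
  r2 <- mk(c(0.75, 1.30, 0.79), c(0.02, 0.02, 0.06))
  out <- koIntersection(r1, r2)
  expect_equal(out$decreased, "x")   # y: directions disagree; z: one p fails
  expect_length(out$increased, 0)
  up <- koIntersection(mk(c(1.3, 1.19, 1.3), c(0.01, 0.01, 0.01)),
                       mk(c(1.25, 1.3, 1.3), c(0.01, 0.01, 0.2)))
  expect_equal(up$increased, "x")    # 1.19 fails the >1.2 bound; z fails p
})

test_that("planted fold changes are recovered by the median estimate", {
  # simulated loading is equal by construction: skip the total-S/N
  # normalization, whose compositional bias would compress large effects
  sim <- simulateTmt(tmtSimConfig(nProteins = 600, fracRegulated = 0.4,
                                  cv = 0.05, seed = 31))
  se <- quantifyProteins(sim$psm, sim$channels, normalize = "none")
  d <- runDifferential(se, tmtContrast("treated", "control", x = se))
  truthFc <- sim$truth$foldChange[d$protein]
  reg <- truthFc > 1
  expect_gte(sum(reg), 200)
  ratio <- d$fc[reg] / truthFc[reg]
  expect_lt(abs(median(ratio) - 1), 0.05)
  expect_gt(median(d$fc[reg]), median(d$fc[!reg]))
})

test_that("column normalization compresses fold changes when regulated mass is large", {
  sim <- simulateTmt(tmtSimConfig(nProteins = 400, fracRegulated = 0.4,
                                  cv = 0.05, seed = 32))
  seN <- quantifyProteins(sim$psm, sim$channels, normalize = "total")
  seR <- quantifyProteins(sim$psm, sim$channels, normalize = "none")
  dN <- runDifferential(seN, tmtContrast("treated", "control", x = seN))
  dR <- runDifferential(seR, tmtContrast("treated", "control", x = seR))
  reg <- sim$truth$foldChange[dN$protein] > 1
  expect_lt(median(dN$fc[reg]),
            median(dR$fc[match(dN$protein, dR$protein)][reg]))
})
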