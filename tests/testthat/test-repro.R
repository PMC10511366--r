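# Repeat-scan reproducibility statistics.

mkSummary <- function(la, wap, pi10 = 3.9, tlv = 5.5) {
  gn <- as.character(seq_along(la) - 1)
  scanSummary(genLA = stats::setNames(la, gn),
              genWAP = stats::setNames(wap, gn), pi10 = pi10, tac = 100,
              tlv = tlv)
}

test_that("TLV exclusion uses the mean-of-pair denominator", {
  mk <- function(t1, t2) list(id = 1, scan1 = mkSummary(10, 50, tlv = t1),
                              scan2 = mkSummary(10, 50, tlv = t2))
  co <- pairedCohort(list(mk(5.0, 5.5), mk(5.0, 6.0), mk(5.0, 5.0)))
  kept <- tlvExclusion(co, threshold = 0.15)
  # |5.5-5|/5.25 = 9.5% kept; |6-5|/5.5 = 18.2% excluded; identical kept
  expect_equal(length(kept@participants), 2)
  tlvs <- sapply(kept@participants, function(p) p$scan2@tlv)
  expect_equal(sort(tlvs), c(5.0, 5.5))
  bad <- pairedCohort(list(mk(5, 5)))
  bad@participants[[1]]$scan1@tlv <- -1
  expect_error(tlvExclusion(bad), "non-positive")
})

test_that("R-squared is affine-invariant, symmetric, and null under noise", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(rSquared(x, x), 1.0)
  expect_equal(rSquared(x, 2 * x + 3), 1.0)
  expect_equal(rSquared(x, -x + 10), 1.0)
  y <- c(2, 1, 5, 4, 9)
  expect_equal(rSquared(x, y), rSquared(y, x), tolerance = 1e-12)
  expect_equal(rSquared(x, 5 - 2 * y), rSquared(x, y), tolerance = 1e-12)
  set.seed(8)
  expect_lt(rSquared(rnorm(1e4), rnorm(1e4)), 0.01)
  expect_true(is.na(rSquared(x, rep(1, 5))))
})

test_that("Bland-Altman matches closed forms", {
  x <- c(1, 2, 3, 4, 5)
  same <- blandAltman(x, x)
  expect_equal(same$md, 0)
  expect_equal(same$loa, 0)
  expect_equal(same$loaPercent, 0)
  shift <- blandAltman(x, x + 1)
  expect_equal(shift$md, 1)
  expect_equal(shift$loa, 0)
  # Monte-Carlo: unit-normal differences give LoA ~ 1.96
  set.seed(12)
  base <- rnorm(1e5, 100, 5)
  ba <- blandAltman(base, base + rnorm(1e5))
  expect_lt(abs(ba$loa - 1.96) / 1.96, 0.01)
  # antisymmetry
  y <- x + c(0.1, -0.2, 0.3, 0, -0.1)
  expect_equal(blandAltman(x, y)$md, -blandAltman(y, x)$md)
  expect_equal(blandAltman(x, y)$loa, blandAltman(y, x)$loa)
  expect_error(blandAltman(1:2, 1:2), "3")
})

test_that("identical scan pairs give a perfect agreement report", {
  parts <- lapply(1:5, function(i) {
    s <- mkSummary(c(50, 30, 20) + i, c(40, 45, 50) + i, pi10 = 3.5 + i / 10)
    list(id = i, scan1 = s, scan2 = s)
  })
  rep <- agreementReport(pairedCohort(parts))
  expect_equal(rep$r2, rep(1, nrow(rep)), tolerance = 1e-12)
  expect_equal(rep$md, rep(0, nrow(rep)), tolerance = 1e-12)
  expect_equal(rep$loa, rep(0, nrow(rep)), tolerance = 1e-12)
  expect_setequal(unique(rep$parameter), c("LA", "WAP", "Pi10"))
})

test_that("participants missing a generation are dropped pairwise", {
  set.seed(2)
  parts <- lapply(1:10, function(i) {
    la <- c(50, 30, 20) + rnorm(3)
    s1 <- mkSummary(la, c(40, 45, 50))
    s2 <- mkSummary(la + rnorm(3, 0, 0.5), c(40, 45, 50) + rnorm(3, 0, 0.5))
    list(id = i, scan1 = s1, scan2 = s2)
  })
  # participant 10 lacks generation 2 in scan 2
  s2 <- parts[[10]]$scan2
  parts[[10]]$scan2 <- scanSummary(genLA = s2@genLA[1:2],
                                   genWAP = s2@genWAP[1:2], pi10 = s2@pi10,
                                   tac = 100, tlv = 5.5)
  rep <- agreementReport(pairedCohort(parts))
  g2 <- rep[rep$parameter == "LA" & rep$generation == "2", ]
  expect_equal(g2$n, 9)
  g1 <- rep[rep$parameter == "LA" & rep$generation == "1", ]
  expect_equal(g1$n, 10)
})

test_that("rows too small to estimate agreement are absent, not zero", {
  parts <- lapply(1:5, function(i) {
    gen <- if (i <= 2) c(50, 30, 20) else c(50, 30)
    nm <- as.character(seq_along(gen) - 1)
    s <- scanSummary(stats::setNames(gen, nm),
                     stats::setNames(rep(45, length(gen)), nm),
                     pi10 = 3.9, tac = 50, tlv = 5.5)
    list(id = i, scan1 = s, scan2 = s)
  })
  rep <- agreementReport(pairedCohort(parts))
  expect_false("2" %in% rep$generation)   # only 2 participants have it
})

test_that("simulated cohorts reproduce the injected measurement noise", {
  sigmaLA <- c(4, 3, 2.5, 2, 1.5, 1, 0.8)
  co <- simulateSummaryCohort(n = 400, generations = 0:6, sigmaLA = sigmaLA,
                              sigmaWAP = 1, seed = 21)
  rep <- agreementReport(tlvExclusion(co))
  la <- rep[rep$parameter == "LA", ]
  la <- la[order(as.integer(la$generation)), ]
  theo <- 1.96 * sqrt(2) * sigmaLA
  expect_equal(nrow(la), 7)
  expect_lt(max(abs(la$loa - theo) / theo), 0.10)
})
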