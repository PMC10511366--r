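# Repeat-scan reproducibility statistics: TLV-based exclusion, per-generation
# coefficients of determination, and Bland-Altman agreement.

#' Construct a scan summary
#'
#' @param genLA,genWAP named numeric vectors of per-generation mean LA (mm^2)
#'   and WAP (%), names "0", "1", ...
#' @param pi10 Pi10 (mm), NA when undefined.
#' @param tac total airway count.
#' @param tlv total lung volume, litres.
#' @return A \linkS4class{ScanSummary}.
#' @export
scanSummary <- function(genLA, genWAP, pi10 = NA_real_, tac = length(genLA),
                        tlv = NA_real_) {
  new("ScanSummary", genLA = genLA, genWAP = genWAP, pi10 = pi10,
      tac = tac, tlv = tlv,
      maxGeneration = max(as.integer(names(genLA))))
}

#' Construct a paired repeat-scan cohort
#'
#' @param participants list of lists with fields \code{id}, \code{scan1},
#'   \code{scan2} (\linkS4class{ScanSummary}) and optional
#'   \code{daysBetween}.
#' @return A \linkS4class{PairedCohort}.
#' @export
pairedCohort <- function(participants) {
  new("PairedCohort", participants = participants)
}

#' Exclude participants with mismatched inspiration
#'
#' Retains participants whose total-lung-volume difference between the two
#' scans, relative to the mean of the two TLVs, is at most the threshold.
#'
#' @param cohort a \linkS4class{PairedCohort}.
#' @param threshold maximum relative TLV difference (default 0.15).
#' @return The filtered \linkS4class{PairedCohort}.
#' @export
tlvExclusion <- function(cohort, threshold = 0.15) {
  keep <- vapply(cohort@participants, function(pp) {
    t1 <- pp$scan1@tlv; t2 <- pp$scan2@tlv
    if (t1 <= 0 || t2 <= 0) stop("non-positive TLV")
    abs(t2 - t1) / ((t1 + t2) / 2) <= threshold
  }, TRUE)
  pairedCohort(cohort@participants[keep])
}

#' Coefficient of determination between paired measurements
#'
#' Squared Pearson correlation of the pairs (invariant to affine rescaling
#' of either argument).
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return R^2 in [0, 1]; NA when either variance is zero.
#' @export
rSquared <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are taken scan2 - scan1. MD is their mean, LoA the half-width
#' 1.96 x SD of the differences (the limits are MD +/- LoA), and LoA% is
#' 100 x LoA divided by either the mean of the pairwise means (default) or
#' half the range of the pairwise means.
#'
#' @param x,y scan-1 and scan-2 values, n >= 3.
#' @param percentOf denominator for LoA%: "mean" (of pairwise means) or
#'   "range" (half the overall range of pairwise means).
#' @return list with md, loa, loaPercent, n.
#' @export
blandAltman <- function(x, y, percentOf = c("mean", "range")) {
  percentOf <- match.arg(percentOf)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- y - x
  md <- mean(d)
  loa <- 1.96 * stats::sd(d)
  mids <- (x + y) / 2
  den <- if (percentOf == "mean") mean(mids) else diff(range(mids)) / 2
  list(md = md, loa = loa,
       loaPercent = if (den != 0) 100 * loa / den else NA_real_,
       n = length(x))
}

# pull a per-generation value from a summary, NA when the generation is absent
.genValue <- function(summary, slot, gen) {
  v <- methods::slot(summary, slot)
  if (as.character(gen) %in% names(v)) v[[as.character(gen)]] else NA_real_
}

#' Per-generation agreement report for a paired cohort
#'
#' For every generation present in the cohort and each of LA and WAP, pairs
#' each participant's per-scan generation means and computes R^2 and
#' Bland-Altman agreement across participants, plus a Pi10 row. Participants
#' missing a generation in either scan are dropped pairwise for that row;
#' rows with fewer than 3 contributing participants are omitted.
#'
#' @param cohort a \linkS4class{PairedCohort} (apply
#'   \code{\link{tlvExclusion}} first).
#' @param percentOf passed to \code{\link{blandAltman}}.
#' @return data.frame with columns parameter, generation ("overall" for
#'   Pi10), n, r2, md, loa, loaPercent.
#' @export
agreementReport <- function(cohort, percentOf = "mean") {
  pp <- cohort@participants
  if (!length(pp)) stop("empty cohort")
  gens <- sort(unique(unlist(lapply(pp, function(p)
    c(names(p$scan1@genLA), names(p$scan2@genLA))))))
  rows <- list()
  addRow <- function(parameter, generation, x, y) {
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return()
    ba <- blandAltman(x[ok], y[ok], percentOf = percentOf)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = parameter, generation = generation, n = ba$n,
      r2 = rSquared(x[ok], y[ok]), md = ba$md, loa = ba$loa,
      loaPercent = ba$loaPercent)
  }
  for (g in gens) {
    for (par in c("LA", "WAP")) {
      slotName <- if (par == "LA") "genLA" else "genWAP"
      x <- vapply(pp, function(p) .genValue(p$scan1, slotName, g), 0)
      y <- vapply(pp, function(p) .genValue(p$scan2, slotName, g), 0)
      addRow(par, g, x, y)
    }
  }
  addRow("Pi10", "overall",
         vapply(pp, function(p) p$scan1@pi10, 0),
         vapply(pp, function(p) p$scan2@pi10, 0))
  do.call(rbind, rows)
}

#' Simulate a summary-level repeat-scan cohort
#'
#' Draws per-participant true generation-level LA and WAP profiles from
#' population distributions, then adds independent per-scan Gaussian
#' measurement noise with known per-generation SDs - the summary-level
#' counterpart of scanning the same airway tree twice. Useful for validating
#' the agreement statistics against closed forms: the expected LA limit of
#' agreement at generation g is 1.96 sqrt(2) sigmaLA[g].
#'
#' @param n participants.
#' @param generations integer vector of generations present.
#' @param sigmaLA per-generation LA measurement SD (mm^2), recycled.
#' @param sigmaWAP per-generation WAP measurement SD (percentage points).
#' @param sigmaPi10 per-scan Pi10 measurement SD (mm).
#' @param tlvJitter relative SD of the scan-2 TLV around scan 1's.
#' @param seed RNG seed.
#' @return A \linkS4class{PairedCohort}.
#' @export
simulateSummaryCohort <- function(n = 100, generations = 0:6,
                                  sigmaLA = 2, sigmaWAP = 1,
                                  sigmaPi10 = 0.05, tlvJitter = 0.03,
                                  seed = 1L) {
  ng <- length(generations)
  sigmaLA <- rep(sigmaLA, length.out = ng)
  sigmaWAP <- rep(sigmaWAP, length.out = ng)
  gnames <- as.character(generations)
  withSeed(seed, {
    laBase <- 254 * 0.55^generations          # trachea ~254 mm^2, shrinking
    wapBase <- 45 + 4 * pmin(generations, 6)
    parts <- lapply(seq_len(n), function(i) {
      laTrue <- laBase * exp(stats::rnorm(ng, 0, 0.15))
      wapTrue <- wapBase + stats::rnorm(ng, 0, 2)
      pi10True <- stats::rnorm(1, 3.92, 0.12)
      tlv1 <- stats::rnorm(1, 5.5, 1.2)
      tlv1 <- max(tlv1, 2.5)
      tlv2 <- tlv1 * (1 + stats::rnorm(1, 0, tlvJitter))
      mkScan <- function(tlv) scanSummary(
        genLA = stats::setNames(laTrue + stats::rnorm(ng, 0, sigmaLA), gnames),
        genWAP = stats::setNames(wapTrue + stats::rnorm(ng, 0, sigmaWAP),
                                 gnames),
        pi10 = pi10True + stats::rnorm(1, 0, sigmaPi10),
        tac = 250, tlv = tlv)
      list(id = i, scan1 = mkScan(tlv1), scan2 = mkScan(tlv2),
           daysBetween = 90)
    })
    pairedCohort(parts)
  })
}
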