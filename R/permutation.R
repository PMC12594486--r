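# Permutation-based group sensitivity procedure.
#
# Outer loop: subjects are repeatedly split at random into a "control" half
# (contributing healthy-variant metrics) and a "patient" half (contributing
# damaged-variant metrics); the inner two-sided difference-in-means
# permutation test produces one p value per split. The reported quantity is
# the proportion of splits whose p value exceeds 0.05 - high under the null,
# dropping towards 0 as the method becomes sensitive to the damage.

# Fast Monte-Carlo inner test used by the sensitivity loop; `z` pools both
# groups with the first `nA` entries forming group A.
.permPvalue <- function(z, nA, nResamples, tol) {
  n <- length(z)
  nB <- n - nA
  obs <- abs(mean(z[seq_len(nA)]) - mean(z[nA + seq_len(nB)]))
  if (max(z) - min(z) <= tol) return(1)
  sumZ <- sum(z)
  idx <- vapply(seq_len(nResamples), function(k) sample.int(n, nA),
                integer(nA))
  sA <- .colSums(matrix(z[idx], nrow = nA), nA, nResamples)
  stat <- abs(sA / nA - (sumZ - sA) / nB)
  (1 + sum(stat >= obs - tol)) / (nResamples + 1)
}

#' Two-sided permutation test for a difference in means
#'
#' Enumerates all group-A index sets exactly when the number of distinct
#' splits `choose(nA + nB, nA)` is at most `exactLimit`; otherwise draws
#' `nResamples` Monte-Carlo resamples and applies the add-one correction
#' `p = (1 + #extreme) / (nResamples + 1)`. Samples that are identical across
#' both groups give `p = 1`.
#'
#' @param a,b numeric samples with at least 2 values each.
#' @param nResamples Monte-Carlo resamples (default 1000).
#' @param seed optional integer seed for the Monte-Carlo path.
#' @param exactLimit largest number of splits enumerated exactly
#'   (default `1e5`).
#' @return p value in `(0, 1]`.
#' @examples
#' permTestMeans(1:5, 6:10)  # 2/252
#' @export
permTestMeans <- function(a, b, nResamples = 1000, seed = NULL,
                          exactLimit = 1e5) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  z <- c(a, b)
  nA <- length(a); n <- length(z)
  tol <- 1e-12 * max(1, max(abs(z)))
  if (max(z) - min(z) <= tol) return(1)
  if (choose(n, nA) <= exactLimit) {
    idx <- combn(n, nA)
    sA <- .colSums(matrix(z[idx], nrow = nA), nA, ncol(idx))
    stat <- abs(sA / nA - (sum(z) - sA) / (n - nA))
    obs <- abs(mean(a) - mean(b))
    mean(stat >= obs - tol)
  } else {
    withSeed(seed, .permPvalue(z, nA, nResamples, tol))
  }
}

#' Permutation-based sensitivity of a metric to simulated damage
#'
#' Implements the outer randomization: in each of `nIterations` iterations
#' the subjects are split at random into controls (using their
#' healthy-variant metric) and patients (using their damaged-variant metric;
#' for an odd cohort the larger half is assigned to controls), and the inner
#' Monte-Carlo permutation test records one p value. Returns the proportion
#' of iterations with `p > 0.05`: about 0.95 when the two variants are
#' identical (null calibration of a level-0.05 test), approaching 0 for a
#' large effect.
#'
#' @param healthy numeric vector: per-subject metric from healthy-variant
#'   connectomes.
#' @param damaged numeric vector, same subjects: metric from damaged-variant
#'   connectomes.
#' @param nIterations outer random splits (default 5000).
#' @param innerResamples inner Monte-Carlo resamples (default 1000).
#' @param seed optional integer seed.
#' @param alpha inner significance level (default 0.05).
#' @return list with `proportion` (share of `p > alpha`), `pValues`,
#'   `nIterations`.
#' @export
sensitivityExperiment <- function(healthy, damaged, nIterations = 5000,
                                  innerResamples = 1000, seed = NULL,
                                  alpha = 0.05) {
  n <- length(healthy)
  if (length(damaged) != n)
    stop("'healthy' and 'damaged' must cover the same subjects")
  if (n < 4L) stop("need at least 4 subjects")
  nA <- as.integer(ceiling(n / 2))   # odd cohorts: larger half = controls
  tol <- 1e-12 * max(1, max(abs(c(healthy, damaged))))
  withSeed(seed, {
    p <- vapply(seq_len(nIterations), function(it) {
      perm <- sample.int(n)
      z <- c(healthy[perm[seq_len(nA)]], damaged[perm[nA + seq_len(n - nA)]])
      .permPvalue(z, nA, innerResamples, tol)
    }, numeric(1))
    list(proportion = mean(p > alpha), pValues = p, nIterations = nIterations)
  })
}

#' Full synthetic sensitivity simulation
#'
#' Generates a cohort from a base phantom, runs the whole estimation pipeline
#' per subject and damage level (standard fit; augmented fit plus reduction
#' map plus weakest-link adjustment for the multi-compartment variant),
#' computes the three global network metrics for every connectome, and runs
#' [sensitivityExperiment()] for every variant, metric and damage level.
#'
#' @param nSubjects cohort size (default 44).
#' @param damageLevels damage fractions to simulate
#'   (default `c(0, 0.25, 0.5, 0.75, 1)`).
#' @param variants connectome variants to evaluate.
#' @param metrics subset of `c("meanStrength", "globalEfficiency",
#'   "modularity")`.
#' @param nIterations outer permutation iterations (default 5000).
#' @param innerResamples inner Monte-Carlo resamples (default 1000).
#' @param weightCv between-subject weight coefficient of variation
#'   (default 0.1).
#' @param lesionFraction WM fraction covered by lesions (default 0.05).
#' @param densityThreshold optional target density applied to every
#'   connectome before computing metrics (`NULL` = no thresholding).
#' @param phantom base [Phantom-class]; default [makeBundlePhantom()].
#' @param seed optional integer master seed.
#' @return data.frame with columns `variant`, `metric`, `damageLevel`,
#'   `proportion` (share of inner tests with `p > 0.05`).
#' @export
sensitivitySimulation <- function(nSubjects = 44,
                                  damageLevels = c(0, 0.25, 0.5, 0.75, 1),
                                  variants = c("standard", "multicompartment"),
                                  metrics = c("meanStrength",
                                              "globalEfficiency",
                                              "modularity"),
                                  nIterations = 5000, innerResamples = 1000,
                                  weightCv = 0.1, lesionFraction = 0.05,
                                  densityThreshold = NULL,
                                  phantom = NULL, seed = NULL) {
  variants <- match.arg(variants, several.ok = TRUE)
  metrics <- match.arg(metrics, several.ok = TRUE)
  withSeed(seed, {
    if (is.null(phantom)) phantom <- makeBundlePhantom()
    cohort <- synthesizeCohort(phantom, nSubjects, weightCv = weightCv,
                               damageLevels = damageLevels,
                               lesionFraction = lesionFraction)
    segs <- segmentTable(phantom)
    asn <- assignNodes(tractogram(phantom), phantom@parcellation,
                       voxelSize = phantom@voxelSize)
    nN <- max(phantom@parcellation)
    A <- buildOperator(segs)
    opStd <- augmentWithLesions(A, array(FALSE, phantom@gridDim))

    metricsOf <- function(weights, variant) {
      conn <- buildConnectome(weights, asn, nN, variant)
      if (!is.null(densityThreshold))
        conn <- thresholdDensity(conn, densityThreshold)
      vapply(metrics, function(mm) switch(mm,
        meanStrength = meanStrength(conn),
        globalEfficiency = globalEfficiency(conn),
        modularity = modularityQ(conn)), numeric(1))
    }

    nL <- length(damageLevels)
    healthyM <- array(NA_real_, c(nSubjects, length(metrics)),
                      dimnames = list(NULL, metrics))
    damagedM <- array(NA_real_,
                      c(nSubjects, nL, length(variants), length(metrics)),
                      dimnames = list(NULL, as.character(damageLevels),
                                      variants, metrics))
    for (s in seq_len(nSubjects)) {
      subj <- cohort$subjects[[s]]
      opAug <- augmentWithLesions(A, subj$lesionMask)
      fitH <- fitWeights(opStd, subj$healthySignal)
      healthyM[s, ] <- metricsOf(streamlineWeights(fitH), "standard")
      for (li in seq_len(nL)) {
        y <- subj$signals[[li]]
        if ("standard" %in% variants) {
          fitS <- fitWeights(opStd, y)
          damagedM[s, li, "standard", ] <-
            metricsOf(streamlineWeights(fitS), "standard")
        }
        if ("multicompartment" %in% variants) {
          fitA <- fitWeights(opAug, y)
          rmap <- reductionMap(fitA, opAug)
          cHat <- adjustWeights(streamlineWeights(fitA), segs, rmap)
          damagedM[s, li, "multicompartment", ] <-
            metricsOf(cHat, "multicompartment")
        }
      }
    }

    rows <- expand.grid(variant = variants, metric = metrics,
                        damageLevel = damageLevels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows$proportion <- vapply(seq_len(nrow(rows)), function(r) {
      sensitivityExperiment(
        healthyM[, rows$metric[r]],
        damagedM[, as.character(rows$damageLevel[r]), rows$variant[r],
                 rows$metric[r]],
        nIterations = nIterations,
        innerResamples = innerResamples)$proportion
    }, numeric(1))
    rows[order(rows$variant, rows$metric, rows$damageLevel), ]
  })
}
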