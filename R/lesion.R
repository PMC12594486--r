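# Relative signal reduction and weakest-link weight adjustment.

#' Relative signal reduction map R(v)
#'
#' For every voxel that carried a lesion column,
#' `R(v) = (sum_i x_i l(i, v) - xL_k(v)) / sum_i x_i l(i, v)`,
#' the fraction of the tractogram-predicted intra-axonal signal surviving the
#' fitted absolute loss. `R` is clamped into `[0, 1]` (an overshooting loss
#' under noise maps to 0) and equals 1 everywhere outside lesions. A lesioned
#' voxel traversed by no streamline has a zero denominator; its `R` is set to
#' 1 with a warning, since no streamline weight can be modulated there.
#'
#' @param fit a [LesionFit-class] produced with the augmented operator.
#' @param operator the same [LesionOperator-class] used for the fit.
#' @return a [ReductionMap-class].
#' @examples
#' ph <- makeCrossingPhantom(lesion = TRUE)
#' op <- lesionOperator(segmentTable(ph$phantom), ph$lesionMask)
#' fit <- fitWeights(op, ph$signal)
#' rmap <- reductionMap(fit, op)
#' rmap@R[2, 3, 1]  # 0.5
#' @export
reductionMap <- function(fit, operator) {
  stopifnot(is(fit, "LesionFit"), is(operator, "LesionOperator"))
  if (!identical(fit@lesionVoxels, operator@lesionVoxels) ||
      !identical(fit@gridDim, operator@gridDim))
    stop("fit was not produced with this operator")
  R <- array(1, dim = fit@gridDim)
  les <- fit@lesionVoxels
  if (length(les)) {
    predicted <- as.numeric(operator@A %*% fit@x)
    denom <- predicted[les]
    uncovered <- denom <= 0
    if (any(uncovered))
      warning(sum(uncovered), " lesioned voxel(s) have no streamline ",
              "coverage; R set to 1 there")
    r <- rep(1, length(les))
    r[!uncovered] <- (denom[!uncovered] - fit@xL[!uncovered]) /
      denom[!uncovered]
    R[les] <- pmin(1, pmax(0, r))
  }
  new("ReductionMap", R = R, lesionVoxels = les)
}

#' Weakest-link adjustment of streamline weights
#'
#' The local cross-sectional area of streamline `i` at position `t` is
#' `c_i * R(s_i(t))`; since `R` is piecewise constant per voxel, the
#' continuous minimum over the trajectory equals the minimum over the
#' discrete set of traversed voxels. The adjusted weight is therefore
#' `c_hat_i = c_i * min_v R(v)` over the voxels the streamline visits -
#' the weakest link of the axonal connection. Streamlines avoiding all
#' lesions keep their weight unchanged.
#'
#' @param weights numeric vector of streamline weights `c_i`.
#' @param segments the [SegmentTable-class] of the same tractogram.
#' @param rmap a [ReductionMap-class] on the tractogram grid.
#' @return numeric vector of adjusted weights `c_hat` with
#'   `0 <= c_hat_i <= c_i`.
#' @examples
#' ph <- makeCrossingPhantom(lesion = TRUE)
#' segs <- segmentTable(ph$phantom)
#' op <- lesionOperator(segs, ph$lesionMask)
#' fit <- fitWeights(op, ph$signal)
#' adjustWeights(streamlineWeights(fit), segs, reductionMap(fit, op))
#' @export
adjustWeights <- function(weights, segments, rmap) {
  stopifnot(is(segments, "SegmentTable"), is(rmap, "ReductionMap"))
  if (!identical(as.integer(dim(rmap@R)), segments@gridDim))
    stop("reduction map grid does not match the segment table")
  if (length(weights) != segments@nStreamlines)
    stop("need one weight per streamline")
  if (any(weights < 0)) stop("weights must be nonnegative")
  minR <- rep(1, length(weights))
  if (length(segments@voxel)) {
    rv <- rmap@R[segments@voxel]
    agg <- tapply(rv, segments@streamline, min)
    minR[as.integer(names(agg))] <- as.numeric(agg)
  }
  weights * minR
}
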