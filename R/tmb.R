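#' Sample-level NGS quality gate
#'
#' A sample is contributive for TMB evaluation unless it has fewer than 20
#' million sequencing reads or less than 15% of the captured regions
#' sequenced above 1000X. Comparisons are strict on the fail side, so a
#' sample at exactly 20 million reads and exactly 15% coverage passes.
#'
#' @param totalReads Total sequencing reads.
#' @param fracCaptured1000x Fraction of captured regions covered above
#'   1000X, in \[0, 1\].
#' @return Logical vector: `TRUE` = contributive.
#' @examples
#' sampleQC(25e6, 0.5)   # TRUE
#' sampleQC(19e6, 0.5)   # FALSE: too few reads
#' @export
sampleQC <- function(totalReads, fracCaptured1000x) {
  if (anyNA(totalReads) || anyNA(fracCaptured1000x))
    stop("QC metrics are mandatory; the gate cannot be skipped silently")
  if (any(fracCaptured1000x < 0 | fracCaptured1000x > 1))
    stop("'fracCaptured1000x' must lie in [0, 1]")
  !(totalReads < 20e6 | fracCaptured1000x < 0.15)
}

#' Compute the TMB score from a filter report
#'
#' TMB is the number of retained variants divided by the panel footprint in
#' megabases. The score is returned unrounded; round only for display.
#'
#' @param report A [FilterReport-class] produced under `profile`.
#' @param profile The [FilterProfile-class] used (supplies the footprint).
#' @return A [TMBResult-class].
#' @export
computeTMB <- function(report, profile) {
  stopifnot(is(report, "FilterReport"), is(profile, "FilterProfile"))
  if (profile@panelSizeMb <= 0) stop("'panelSizeMb' must be positive")
  if (!identical(report@profileName, profile@name))
    stop("report was generated under profile '", report@profileName,
         "', not '", profile@name, "'")
  nRet <- sum(report@verdicts$retained)
  new("TMBResult", sampleId = report@sampleId, profileName = profile@name,
      nRetained = as.integer(nRet), panelSizeMb = profile@panelSizeMb,
      tmb = nRet / profile@panelSizeMb, report = report)
}

#' TMB as a function of the minimum-VAF cutoff
#'
#' Recomputes the full cascade for each cutoff on an ascending grid, with
#' the profile's minimum VAF overridden by the cutoff for this sample's
#' preservation; all other filters are unchanged. Because raising the
#' cutoff can only remove variants, the resulting curve is non-increasing.
#' The sweep reveals where a sample's score stabilizes: frozen tumors
#' typically plateau by 5% VAF, well-preserved FFPE around 10%, while
#' heavily deaminated FFPE keeps falling.
#'
#' @inheritParams applyProfile
#' @param grid Strictly ascending VAF cutoffs in (0, 1). Default
#'   `seq(0.01, 0.30, by = 0.01)`.
#' @return A data.frame with columns `sample_id`, `cutoff`, `n_retained`,
#'   `tmb`.
#' @export
vafSweep <- function(variants, preservation, profile, run = NULL,
                     grid = seq(0.01, 0.30, by = 0.01),
                     externalGermline = NULL) {
  if (!length(grid)) stop("'grid' must contain at least one VAF cutoff")
  if (any(grid <= 0 | grid >= 1) || is.unsorted(grid, strictly = TRUE))
    stop("'grid' must be strictly ascending within (0, 1)")
  base <- applyProfile(variants, preservation, profile, run = run,
                       externalGermline = externalGermline)
  v <- base@verdicts
  # every stage except VAF/depth is cutoff-independent; reuse those masks
  others <- if (nrow(v)) {
    v$pass_quality & v$pass_recurrence & v$pass_germline &
      v$pass_class_driver
  } else logical()
  depthOk <- if (nrow(v))
    .above(variants$depth, profile@minDepth, profile@strict) else logical()
  nRet <- vapply(grid, function(cut) {
    sum(others & depthOk & .above(variants$vaf, cut, profile@strict))
  }, numeric(1))
  data.frame(
    sample_id = base@sampleId,
    cutoff = grid,
    n_retained = as.integer(nRet),
    tmb = nRet / profile@panelSizeMb,
    stringsAsFactors = FALSE
  )
}

#' Locate the VAF plateau of a sweep curve
#'
#' Returns the smallest grid cutoff from which every successive relative
#' decrease of the TMB curve is at most `relTol`; `NA` if the curve never
#' stabilizes before its last point. A plateau reached early suggests the
#' score at that cutoff reflects the true burden; a late or absent plateau
#' is the signature of low-VAF artifact contamination (typical of
#' formalin-damaged DNA).
#'
#' @param sweep A sweep data.frame from [vafSweep()] (one sample).
#' @param relTol Maximum tolerated relative decrease per grid step
#'   (default 0.05).
#' @return The plateau cutoff, or `NA_real_`.
#' @export
plateauVaf <- function(sweep, relTol = 0.05) {
  stopifnot(all(c("cutoff", "tmb") %in% names(sweep)))
  if (length(unique(sweep$sample_id %||% "x")) > 1L)
    stop("plateauVaf() expects a single sample's sweep")
  sweep <- sweep[order(sweep$cutoff), , drop = FALSE]
  t <- sweep$tmb
  n <- length(t)
  if (n < 2L) return(sweep$cutoff[1] %||% NA_real_)
  dec <- (t[-n] - t[-1]) / ifelse(t[-n] > 0, t[-n], 1)
  ok <- dec <= relTol
  # smallest start from which all later steps are flat; a candidate must
  # have at least one successor, otherwise any decreasing curve would
  # trivially "plateau" at its final grid point
  flatFrom <- rev(cumprod(rev(ok))) > 0
  idx <- which(flatFrom)
  if (!length(idx)) NA_real_ else sweep$cutoff[idx[1]]
}
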