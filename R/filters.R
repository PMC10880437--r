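#' Flag a variant as a germline polymorphism
#'
#' A variant is treated as germline — and removed from TMB — when any of the
#' profile's configured population databases reports an allele frequency
#' strictly greater than the profile's MAF cutoff (0.1% in both built-ins;
#' "higher than", so a frequency exactly at the cutoff is kept). A database
#' in which the variant was never observed contributes nothing: absence is
#' informative and never triggers removal.
#'
#' @param variants A variant table (or any data.frame with the `af_*`
#'   columns).
#' @param profile A [FilterProfile-class].
#' @return Logical vector, `TRUE` = germline, remove.
#' @export
germlineFlag <- function(variants, profile) {
  stopifnot(is(profile, "FilterProfile"))
  if (!length(profile@germlineDbs))
    stop("profile has no germline databases configured")
  cols <- .DB_COLUMNS[profile@germlineDbs]
  flag <- rep(FALSE, nrow(variants))
  for (cl in cols) {
    af <- variants[[cl]]
    flag <- flag | (!is.na(af) & .above(af, profile@mafCutoff,
                                        profile@strict))
  }
  flag
}

#' Flag a variant as an intra-run recurrent artifact
#'
#' Variants carried by more than `recurrenceThreshold` (15% in the IC
#' built-in) of the samples sequenced in the same run are treated as
#' systematic false positives. The comparison is strict: a variant in
#' exactly 15% of the run's samples is kept. In degenerate runs (fewer
#' than 7 samples, where 15% of the run is less than one sample) the
#' predicate removes every variant shared by two samples — and with a
#' single-sample run, every variant; a warning is emitted for such runs.
#'
#' @param keys Character vector of variant keys (see [variantKey()]).
#' @param run A [RunContext-class]; keys absent from the context count as
#'   present in zero samples.
#' @param profile A [FilterProfile-class].
#' @return Logical vector, `TRUE` = artifact, remove.
#' @export
recurrenceFlag <- function(keys, run, profile) {
  stopifnot(is(run, "RunContext"), is(profile, "FilterProfile"))
  if (run@sampleCount < 1L) stop("run has no samples")
  if (run@sampleCount < 7L)
    warning("run '", run@runId, "' has only ", run@sampleCount,
            " sample(s); the recurrence filter removes any variant shared ",
            "by ", if (run@sampleCount == 1L) "even one sample" else
              "two samples", call. = FALSE)
  count <- run@presence[keys]
  count[is.na(count)] <- 0L
  .above(count / run@sampleCount, profile@recurrenceThreshold,
         profile@strict)
}

#' VAF and depth threshold predicate
#'
#' `TRUE` when the call's VAF exceeds the profile's minimum for the sample's
#' preservation (10% FFPE / 5% frozen under IC, 5% under FO) and its
#' depth of coverage exceeds the minimum (100X in both built-ins).
#' Comparisons are strict by default ("higher than"): VAF exactly at the
#' bound, or depth exactly 100, fails.
#'
#' @param variants A variant table (columns `vaf`, `depth`).
#' @param preservation `"FFPE"` or `"frozen"`.
#' @param profile A [FilterProfile-class].
#' @param vafCutoff Optional override of the profile's minimum VAF (used by
#'   [vafSweep()]).
#' @return Logical vector, `TRUE` = passes.
#' @export
vafDepthPass <- function(variants, preservation, profile,
                         vafCutoff = NULL) {
  stopifnot(is(profile, "FilterProfile"))
  preservation <- match.arg(preservation, .PRESERVATIONS)
  cut <- vafCutoff %||% profile@minVaf[[preservation]]
  .above(variants$vaf, cut, profile@strict) &
    .above(variants$depth, profile@minDepth, profile@strict)
}

#' Consequence-class and driver policy predicate
#'
#' Applies the profile's include/exclude table over the variant's effective
#' class (its consequence, or the pooled `"noncoding"` class for variants
#' outside exonic/splicing regions; `"unknown"` is excluded by both
#' built-ins). The COSMIC driver policy is applied at the same decision
#' point: under `"exclude_cosmic"` any variant seen at least once in COSMIC
#' is removed regardless of class; under `"include_cosmic"` COSMIC
#' membership is ignored.
#'
#' @param variants A variant table.
#' @param profile A [FilterProfile-class].
#' @return Logical vector, `TRUE` = counted toward TMB.
#' @export
classPass <- function(variants, profile) {
  stopifnot(is(profile, "FilterProfile"))
  eff <- .effectiveClass(variants$region_class, variants$consequence)
  ok <- unname(profile@classPolicy[eff])
  ok[is.na(ok)] <- FALSE
  if (profile@driverPolicy == "exclude_cosmic")
    ok <- ok & !(variants$cosmic_hit %in% TRUE)
  ok
}

#' Build the intra-run recurrence context
#'
#' Counts, for every variant key, the number of distinct samples in one
#' sequencing run that carry it. Presence is counted among the raw parsed
#' variants (before any filtering).
#'
#' @param variants Variant table(s) of all the run's samples — either one
#'   data.frame covering every sample or a list of per-sample tables.
#' @param runId Run identifier.
#' @param sampleCount Number of samples in the run; defaults to the number
#'   of distinct `sample_id` values seen.
#' @return A [RunContext-class].
#' @export
buildRunContext <- function(variants, runId = "run1", sampleCount = NULL) {
  if (is.list(variants) && !is.data.frame(variants))
    variants <- do.call(rbind, variants)
  .checkVariantTable(variants)
  ids <- unique(variants$sample_id)
  sampleCount <- as.integer(sampleCount %||% length(ids))
  if (sampleCount < 1L) stop("run must contain at least one sample")
  key <- variantKey(variants$chrom, variants$pos, variants$ref,
                    variants$alt)
  u <- unique(data.frame(key = key, sample = variants$sample_id,
                         stringsAsFactors = FALSE))
  presence <- table(u$key)
  new("RunContext", runId = as.character(runId),
      sampleCount = sampleCount,
      presence = stats::setNames(as.integer(presence), names(presence)))
}

#' Run the full filter cascade over one sample
#'
#' Evaluates every applicable filter predicate against every variant and
#' assembles a [FilterReport-class]. A variant is retained only if it passes
#' all stages; because each stage is a pure per-variant predicate (given a
#' fixed run context), the retained set does not depend on evaluation
#' order. Attrition is reported in the fixed order quality -> recurrence ->
#' germline -> class/driver -> VAF/depth by attributing each removed variant
#' to its first failing stage.
#'
#' The caller-quality stage depends on the profile: `"require_pass"` keeps
#' only PASS records, `"intra_run_recurrence"` applies the run-level
#' recurrence filter, `"both"` applies both, `"none"` neither.
#' `externalGermline` is a hook for verdicts from an external
#' somatic/germline classifier (e.g. a zygosity-based caller): variant keys
#' listed there are removed at the germline stage in addition to the
#' population-database rule.
#'
#' @param variants Variant table of one sample.
#' @param preservation `"FFPE"` or `"frozen"`.
#' @param profile A [FilterProfile-class].
#' @param run A [RunContext-class]; required when the profile's quality
#'   policy involves intra-run recurrence.
#' @param externalGermline Optional character vector of variant keys called
#'   germline by an external algorithm.
#' @return A [FilterReport-class].
#' @export
applyProfile <- function(variants, preservation, profile, run = NULL,
                         externalGermline = NULL) {
  .checkVariantTable(variants)
  stopifnot(is(profile, "FilterProfile"))
  sid <- if (nrow(variants)) unique(variants$sample_id) else "empty"
  if (length(sid) > 1L)
    stop("applyProfile() operates on one sample; found: ",
         paste(sid, collapse = ", "))
  n <- nrow(variants)
  keys <- if (n) variantKey(variants$chrom, variants$pos, variants$ref,
                            variants$alt) else character()

  needRec <- profile@qualityPolicy %in% c("intra_run_recurrence", "both")
  needPass <- profile@qualityPolicy %in% c("require_pass", "both")
  if (needRec && is.null(run))
    stop("profile '", profile@name,
         "' requires a RunContext for the recurrence filter")

  passQuality <- if (needPass) variants$pass %in% TRUE else rep(TRUE, n)
  passRecurrence <- if (needRec && n)
    !recurrenceFlag(keys, run, profile) else rep(TRUE, n)
  passGermline <- if (n) !germlineFlag(variants, profile) else logical()
  if (!is.null(externalGermline) && n)
    passGermline <- passGermline & !(keys %in% externalGermline)
  passClass <- if (n) classPass(variants, profile) else logical()
  passVafDepth <- if (n)
    vafDepthPass(variants, preservation, profile) else logical()

  verdicts <- data.frame(
    key = keys,
    pass_quality = passQuality,
    pass_recurrence = passRecurrence,
    pass_germline = passGermline,
    pass_class_driver = passClass,
    pass_vaf_depth = passVafDepth,
    stringsAsFactors = FALSE
  )
  stageCols <- paste0("pass_", .FILTER_STAGES)
  verdicts$retained <- Reduce(`&`, verdicts[stageCols]) %||% logical()
  firstFail <- rep(NA_character_, n)
  remaining <- !verdicts$retained
  for (s in .FILTER_STAGES) {
    hit <- remaining & !verdicts[[paste0("pass_", s)]] & is.na(firstFail)
    firstFail[hit] <- s
  }
  verdicts$first_fail <- firstFail
  att <- vapply(.FILTER_STAGES,
                function(s) sum(firstFail == s, na.rm = TRUE), integer(1))
  new("FilterReport", sampleId = as.character(sid),
      profileName = profile@name, verdicts = verdicts,
      attrition = att)
}
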