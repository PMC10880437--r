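#' @import methods
NULL

## Controlled vocabularies used throughout the filter cascade.

#' Consequence classes recognised by the filter engine
#'
#' `consequenceClasses()` returns the functional consequence terms a variant
#' can carry after annotation normalization; `effectiveClasses()` returns the
#' categories a class policy must cover (consequences plus the pooled
#' `"noncoding"` category derived from the region class).
#'
#' @return Character vector of class labels.
#' @export
consequenceClasses <- function() {
  c("synonymous", "missense", "nonsense", "frameshift_indel",
    "inframe_indel", "splice_site", "unknown")
}

#' @rdname consequenceClasses
#' @export
effectiveClasses <- function() {
  c("synonymous", "missense", "nonsense", "frameshift_indel",
    "inframe_indel", "splice_site", "noncoding", "unknown")
}

#' @rdname consequenceClasses
#' @export
regionClasses <- function() {
  c("exonic", "splicing", "intronic", "UTR", "intergenic",
    "other_noncoding", "unknown")
}

.QUALITY_POLICIES <- c("require_pass", "intra_run_recurrence", "both", "none")
.DRIVER_POLICIES <- c("include_cosmic", "exclude_cosmic")
.PRESERVATIONS <- c("FFPE", "frozen")
.GERMLINE_DBS <- c("1000G", "gnomAD", "ExAC")

#' FilterProfile: a complete parameterization of one TMB algorithm
#'
#' A `FilterProfile` freezes every tunable of the variant-filter cascade:
#' preservation-specific minimum VAF, minimum depth, the population-database
#' MAF cutoff used for germline removal, the caller-quality policy
#' (PASS-tag and/or intra-run recurrence), the per-consequence include /
#' exclude table, the COSMIC driver policy, and the panel footprint used as
#' the TMB denominator. Two built-ins are provided by [builtinProfile()].
#'
#' @slot name Profile identifier.
#' @slot minVaf Named numeric, elements `FFPE` and `frozen`, fractions in (0,1).
#' @slot minDepth Minimum read depth (comparison is strict by default).
#' @slot mafCutoff Population minor-allele-frequency bound above which a
#'   variant is considered a germline polymorphism and removed.
#' @slot germlineDbs Databases consulted for germline removal (subset of
#'   `"1000G"`, `"gnomAD"`, `"ExAC"`).
#' @slot qualityPolicy One of `"require_pass"`, `"intra_run_recurrence"`,
#'   `"both"`, `"none"`.
#' @slot recurrenceThreshold Fraction of samples within one sequencing run
#'   above which a recurrent variant is treated as a systematic artifact.
#' @slot classPolicy Named logical over [effectiveClasses()]; `TRUE` = counted.
#' @slot driverPolicy `"include_cosmic"` or `"exclude_cosmic"`.
#' @slot panelSizeMb Captured footprint in megabases (TMB denominator).
#' @slot strict If `TRUE` (default) all threshold comparisons are strict
#'   (`>` / `<`), mirroring the "higher than" wording of the algorithms; set
#'   `FALSE` for `>=` interoperability.
#' @export
setClass("FilterProfile",
  representation(
    name = "character",
    minVaf = "numeric",
    minDepth = "numeric",
    mafCutoff = "numeric",
    germlineDbs = "character",
    qualityPolicy = "character",
    recurrenceThreshold = "numeric",
    classPolicy = "logical",
    driverPolicy = "character",
    panelSizeMb = "numeric",
    strict = "logical"
  )
)

setValidity("FilterProfile", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!setequal(names(object@minVaf), .PRESERVATIONS))
    msg <- c(msg, "'minVaf' must be named with exactly 'FFPE' and 'frozen'")
  if (any(object@minVaf <= 0 | object@minVaf >= 1))
    msg <- c(msg, "'minVaf' values must lie in (0, 1)")
  if (object@mafCutoff <= 0 || object@mafCutoff >= 1)
    msg <- c(msg, "'mafCutoff' must lie in (0, 1)")
  if (object@recurrenceThreshold <= 0 || object@recurrenceThreshold > 1)
    msg <- c(msg, "'recurrenceThreshold' must lie in (0, 1]")
  if (object@minDepth < 0)
    msg <- c(msg, "'minDepth' must be non-negative")
  if (object@panelSizeMb <= 0)
    msg <- c(msg, "'panelSizeMb' must be positive")
  if (!object@qualityPolicy %in% .QUALITY_POLICIES)
    msg <- c(msg, paste0("'qualityPolicy' must be one of: ",
                         paste(.QUALITY_POLICIES, collapse = ", ")))
  if (!object@driverPolicy %in% .DRIVER_POLICIES)
    msg <- c(msg, paste0("'driverPolicy' must be one of: ",
                         paste(.DRIVER_POLICIES, collapse = ", ")))
  if (!setequal(names(object@classPolicy), effectiveClasses()))
    msg <- c(msg, "'classPolicy' must cover every effective consequence class")
  if (anyNA(object@classPolicy))
    msg <- c(msg, "'classPolicy' entries must be TRUE/FALSE, not NA")
  if (!all(object@germlineDbs %in% .GERMLINE_DBS))
    msg <- c(msg, paste0("'germlineDbs' must be drawn from: ",
                         paste(.GERMLINE_DBS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' FilterReport: per-variant verdicts and attrition for one sample
#'
#' Produced by [applyProfile()]. The `verdicts` table holds one row per input
#' variant with the outcome of each filter stage, the final `retained` flag,
#' and the first failing stage (in the fixed reporting order quality ->
#' recurrence -> germline -> class/driver -> VAF/depth). `attrition` counts,
#' per stage, the variants whose first failure occurred there; final
#' retention itself is order-independent because every stage is a pure
#' per-variant predicate.
#'
#' @slot sampleId Sample identifier.
#' @slot profileName Name of the profile the report was generated under.
#' @slot verdicts data.frame of per-variant filter outcomes.
#' @slot attrition Named integer of first-failure counts per stage.
#' @export
setClass("FilterReport",
  representation(
    sampleId = "character",
    profileName = "character",
    verdicts = "data.frame",
    attrition = "integer"
  )
)

.FILTER_STAGES <- c("quality", "recurrence", "germline", "class_driver",
                    "vaf_depth")

setValidity("FilterReport", function(object) {
  msg <- character()
  if (!setequal(names(object@attrition), .FILTER_STAGES))
    msg <- c(msg, "'attrition' must have one entry per filter stage")
  v <- object@verdicts
  if (nrow(v)) {
    need <- c(paste0("pass_", .FILTER_STAGES), "retained", "first_fail")
    if (!all(need %in% names(v)))
      msg <- c(msg, "'verdicts' is missing per-stage outcome columns")
    else {
      conj <- Reduce(`&`, v[paste0("pass_", .FILTER_STAGES)])
      if (!identical(as.logical(conj), as.logical(v$retained)))
        msg <- c(msg, "'retained' must equal the conjunction of stage passes")
      if (sum(object@attrition) + sum(v$retained) != nrow(v))
        msg <- c(msg, "attrition counts must sum to n - retained")
    }
  } else if (sum(object@attrition) != 0L) {
    msg <- c(msg, "empty verdicts require zero attrition")
  }
  if (length(msg)) msg else TRUE
})

#' TMBResult: the mutational-burden score for one sample
#'
#' @slot sampleId Sample identifier.
#' @slot profileName Profile under which the score was computed.
#' @slot nRetained Number of variants surviving the full cascade.
#' @slot panelSizeMb Footprint used as denominator.
#' @slot tmb Mutations per megabase, `nRetained / panelSizeMb`, unrounded.
#' @slot report The [FilterReport-class] the score was derived from.
#' @export
setClass("TMBResult",
  representation(
    sampleId = "character",
    profileName = "character",
    nRetained = "integer",
    panelSizeMb = "numeric",
    tmb = "numeric",
    report = "FilterReport"
  )
)

setValidity("TMBResult", function(object) {
  msg <- character()
  if (object@nRetained < 0L) msg <- c(msg, "'nRetained' must be >= 0")
  if (object@panelSizeMb <= 0) msg <- c(msg, "'panelSizeMb' must be > 0")
  if (!isTRUE(all.equal(object@tmb, object@nRetained / object@panelSizeMb)))
    msg <- c(msg, "'tmb' must equal nRetained / panelSizeMb")
  if (length(msg)) msg else TRUE
})

#' RunContext: intra-run variant recurrence bookkeeping
#'
#' Records, for one sequencing run, how many samples carry each variant key.
#' Built by [buildRunContext()] from the raw (pre-filter) parsed variant
#' tables of all samples in the run; consumed by the recurrence filter.
#'
#' @slot runId Run identifier.
#' @slot sampleCount Number of samples in the run.
#' @slot presence Named integer: variant key -> number of samples carrying it.
#' @export
setClass("RunContext",
  representation(
    runId = "character",
    sampleCount = "integer",
    presence = "integer"
  )
)

setValidity("RunContext", function(object) {
  msg <- character()
  if (object@sampleCount < 1L)
    msg <- c(msg, "'sampleCount' must be >= 1")
  if (length(object@presence) &&
      any(object@presence > object@sampleCount))
    msg <- c(msg, "presence counts cannot exceed the run's sample count")
  if (length(object@presence) && is.null(names(object@presence)))
    msg <- c(msg, "'presence' must be named by variant key")
  if (length(msg)) msg else TRUE
})

#' SimConfig: generative parameters of a synthetic annotated cohort
#'
#' Use the [simConfig()] constructor, which supplies study-condition
#' defaults and validates the fields; see that help page for the meaning,
#' units and default of every parameter.
#'
#' @slot seed,nSamples,ffpeFraction,samplesPerRun,somaticDensity,msiFraction,msiMultiplier,classMixture,germlineLeakRate,germlineAboveFraction,ffpeArtifactRate,artifactVafShape,lowQualityVafShape,lowQualityFraction,somaticVafShape,somaticVafRange,depthMean,depthSize,depthFloor,panelSizeMb,cosmicFraction,annotator,caller,recurrentPerRun,recurrentSampleFraction,qcFailFraction,artifactNonPassFraction,tumorTypes See [simConfig()].
#' @export
setClass("SimConfig",
  representation(
    seed = "integer",
    nSamples = "integer",
    ffpeFraction = "numeric",
    samplesPerRun = "integer",
    somaticDensity = "numeric",
    msiFraction = "numeric",
    msiMultiplier = "numeric",
    classMixture = "numeric",
    germlineLeakRate = "numeric",
    germlineAboveFraction = "numeric",
    ffpeArtifactRate = "numeric",
    artifactVafShape = "numeric",
    lowQualityVafShape = "numeric",
    lowQualityFraction = "numeric",
    somaticVafShape = "numeric",
    somaticVafRange = "numeric",
    depthMean = "numeric",
    depthSize = "numeric",
    depthFloor = "integer",
    panelSizeMb = "numeric",
    cosmicFraction = "numeric",
    annotator = "character",
    caller = "character",
    recurrentPerRun = "integer",
    recurrentSampleFraction = "numeric",
    qcFailFraction = "numeric",
    artifactNonPassFraction = "numeric",
    tumorTypes = "character"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "'nSamples' must be >= 1")
  if (object@samplesPerRun < 1L) msg <- c(msg, "'samplesPerRun' must be >= 1")
  mix <- object@classMixture
  if (!setequal(names(mix),
                setdiff(effectiveClasses(), "unknown")))
    msg <- c(msg, "'classMixture' must name every non-unknown effective class")
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8)
    msg <- c(msg, "'classMixture' must be non-negative and sum to 1")
  rates <- c(object@somaticDensity, object@germlineLeakRate,
             object@ffpeArtifactRate)
  if (any(rates < 0)) msg <- c(msg, "rates must be >= 0")
  fracs <- c(object@ffpeFraction, object@msiFraction,
             object@germlineAboveFraction, object@lowQualityFraction,
             object@cosmicFraction, object@recurrentSampleFraction,
             object@qcFailFraction, object@artifactNonPassFraction)
  if (any(fracs < 0 | fracs > 1))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@panelSizeMb <= 0) msg <- c(msg, "'panelSizeMb' must be > 0")
  if (!object@annotator %in% c("annovar", "snpeff", "both"))
    msg <- c(msg, "'annotator' must be 'annovar', 'snpeff' or 'both'")
  if (!object@caller %in% c("mutect2", "varscan2"))
    msg <- c(msg, "'caller' must be 'mutect2' or 'varscan2'")
  if (length(object@somaticVafRange) != 2L ||
      object@somaticVafRange[1] >= object@somaticVafRange[2])
    msg <- c(msg, "'somaticVafRange' must be an increasing pair")
  if (length(msg)) msg else TRUE
})
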