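#' Accessors for panelTMB S4 objects
#'
#' Standard slot accessors. `profileName()`, `minVaf()`, `minDepth()`,
#' `mafCutoff()`, `germlineDbs()`, `qualityPolicy()`,
#' `recurrenceThreshold()`, `classPolicy()`, `driverPolicy()` and
#' `panelSizeMb()` read [FilterProfile-class] settings; `sampleId()`,
#' `nRetained()`, `tmbScore()`, `verdicts()` and `attrition()` read
#' [FilterReport-class] / [TMBResult-class] contents; `runId()`,
#' `sampleCount()` and `presenceCounts()` read a [RunContext-class].
#'
#' @param x An object of the appropriate class.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("profileName", function(x) standardGeneric("profileName"))
#' @rdname accessors
#' @export
setGeneric("minVaf", function(x) standardGeneric("minVaf"))
#' @rdname accessors
#' @export
setGeneric("minDepth", function(x) standardGeneric("minDepth"))
#' @rdname accessors
#' @export
setGeneric("mafCutoff", function(x) standardGeneric("mafCutoff"))
#' @rdname accessors
#' @export
setGeneric("germlineDbs", function(x) standardGeneric("germlineDbs"))
#' @rdname accessors
#' @export
setGeneric("qualityPolicy", function(x) standardGeneric("qualityPolicy"))
#' @rdname accessors
#' @export
setGeneric("recurrenceThreshold",
           function(x) standardGeneric("recurrenceThreshold"))
#' @rdname accessors
#' @export
setGeneric("classPolicy", function(x) standardGeneric("classPolicy"))
#' @rdname accessors
#' @export
setGeneric("driverPolicy", function(x) standardGeneric("driverPolicy"))
#' @rdname accessors
#' @export
setGeneric("panelSizeMb", function(x) standardGeneric("panelSizeMb"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))
#' @rdname accessors
#' @export
setGeneric("tmbScore", function(x) standardGeneric("tmbScore"))
#' @rdname accessors
#' @export
setGeneric("verdicts", function(x) standardGeneric("verdicts"))
#' @rdname accessors
#' @export
setGeneric("attrition", function(x) standardGeneric("attrition"))
#' @rdname accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))
#' @rdname accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))
#' @rdname accessors
#' @export
setGeneric("sampleCount", function(x) standardGeneric("sampleCount"))
#' @rdname accessors
#' @export
setGeneric("presenceCounts", function(x) standardGeneric("presenceCounts"))

#' @rdname accessors
setMethod("profileName", "FilterProfile", function(x) x@name)
#' @rdname accessors
setMethod("minVaf", "FilterProfile", function(x) x@minVaf)
#' @rdname accessors
setMethod("minDepth", "FilterProfile", function(x) x@minDepth)
#' @rdname accessors
setMethod("mafCutoff", "FilterProfile", function(x) x@mafCutoff)
#' @rdname accessors
setMethod("germlineDbs", "FilterProfile", function(x) x@germlineDbs)
#' @rdname accessors
setMethod("qualityPolicy", "FilterProfile", function(x) x@qualityPolicy)
#' @rdname accessors
setMethod("recurrenceThreshold", "FilterProfile",
          function(x) x@recurrenceThreshold)
#' @rdname accessors
setMethod("classPolicy", "FilterProfile", function(x) x@classPolicy)
#' @rdname accessors
setMethod("driverPolicy", "FilterProfile", function(x) x@driverPolicy)
#' @rdname accessors
setMethod("panelSizeMb", "FilterProfile", function(x) x@panelSizeMb)

#' @rdname accessors
setMethod("sampleId", "FilterReport", function(x) x@sampleId)
#' @rdname accessors
setMethod("profileName", "FilterReport", function(x) x@profileName)
#' @rdname accessors
setMethod("verdicts", "FilterReport", function(x) x@verdicts)
#' @rdname accessors
setMethod("attrition", "FilterReport", function(x) x@attrition)
#' @rdname accessors
setMethod("nRetained", "FilterReport",
          function(x) sum(x@verdicts$retained))

#' @rdname accessors
setMethod("sampleId", "TMBResult", function(x) x@sampleId)
#' @rdname accessors
setMethod("profileName", "TMBResult", function(x) x@profileName)
#' @rdname accessors
setMethod("nRetained", "TMBResult", function(x) x@nRetained)
#' @rdname accessors
setMethod("tmbScore", "TMBResult", function(x) x@tmb)
#' @rdname accessors
setMethod("panelSizeMb", "TMBResult", function(x) x@panelSizeMb)
#' @rdname accessors
setMethod("filterReport", "TMBResult", function(x) x@report)

#' @rdname accessors
setMethod("runId", "RunContext", function(x) x@runId)
#' @rdname accessors
setMethod("sampleCount", "RunContext", function(x) x@sampleCount)
#' @rdname accessors
setMethod("presenceCounts", "RunContext", function(x) x@presence)

setMethod("show", "FilterProfile", function(object) {
  cat("FilterProfile '", object@name, "'\n", sep = "")
  cat("  min VAF      : FFPE ", object@minVaf[["FFPE"]],
      ", frozen ", object@minVaf[["frozen"]],
      if (object@strict) " (strict >)" else " (>=)", "\n", sep = "")
  cat("  min depth    :", object@minDepth, "\n")
  cat("  germline     : MAF >", object@mafCutoff, "in",
      paste(object@germlineDbs, collapse = "/"), "\n")
  cat("  quality      :", object@qualityPolicy,
      if (object@qualityPolicy %in% c("intra_run_recurrence", "both"))
        paste0("(recurrence > ", object@recurrenceThreshold, ")") else "",
      "\n")
  inc <- names(object@classPolicy)[object@classPolicy]
  cat("  classes kept :", paste(inc, collapse = ", "), "\n")
  cat("  drivers      :", object@driverPolicy, "\n")
  cat("  panel        :", object@panelSizeMb, "Mb\n")
})

setMethod("show", "FilterReport", function(object) {
  n <- nrow(object@verdicts)
  cat("FilterReport for sample '", object@sampleId, "' (profile ",
      object@profileName, ")\n", sep = "")
  cat("  input variants :", n, "\n")
  cat("  retained       :", sum(object@verdicts$retained), "\n")
  for (s in names(object@attrition))
    cat(sprintf("  removed at %-12s: %d\n", s, object@attrition[[s]]))
})

setMethod("show", "TMBResult", function(object) {
  cat("TMBResult: sample '", object@sampleId, "', profile ",
      object@profileName, "\n", sep = "")
  cat("  retained variants:", object@nRetained, "over",
      object@panelSizeMb, "Mb\n")
  cat("  TMB:", signif(object@tmb, 3), "mut/Mb\n")
})

setMethod("show", "RunContext", function(object) {
  cat("RunContext '", object@runId, "': ", object@sampleCount,
      " samples, ", length(object@presence),
      " distinct variant keys\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nSamples, " samples (",
      round(100 * object@ffpeFraction), "% FFPE), ",
      object@samplesPerRun, " per run, seed ", object@seed, "\n", sep = "")
  cat("  somatic density  :", object@somaticDensity, "/Mb (MSI x",
      object@msiMultiplier, ")\n")
  cat("  germline leak    :", object@germlineLeakRate, "per sample\n")
  cat("  FFPE artifacts   :", object@ffpeArtifactRate, "/Mb\n")
  cat("  panel            :", object@panelSizeMb, "Mb;",
      object@annotator, "annotation;", object@caller, "dialect\n")
})
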