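#' Construct a filter profile
#'
#' Builds a [FilterProfile-class] from explicit settings. Most users want
#' [builtinProfile()]; this constructor exists for custom panels and for
#' deserialization via [readFilterProfile()].
#'
#' @param name Profile identifier.
#' @param minVaf Named numeric `c(FFPE = , frozen = )`, fractions in (0,1).
#' @param minDepth Minimum depth of coverage in reads.
#' @param mafCutoff Population MAF above which a variant is removed as
#'   germline (fraction; the built-ins use 0.001, i.e. 0.1%).
#' @param germlineDbs Character vector among `"1000G"`, `"gnomAD"`, `"ExAC"`.
#' @param qualityPolicy `"require_pass"`, `"intra_run_recurrence"`, `"both"`
#'   or `"none"`.
#' @param recurrenceThreshold Fraction of a run's samples above which a
#'   shared variant is discarded as a systematic artifact.
#' @param include Character vector of [effectiveClasses()] counted toward
#'   TMB; everything else is excluded.
#' @param driverPolicy `"include_cosmic"` (COSMIC membership ignored) or
#'   `"exclude_cosmic"` (any COSMIC hit removed regardless of class).
#' @param panelSizeMb Captured footprint in megabases.
#' @param strict Use strict `>` comparisons for VAF/depth/MAF/recurrence
#'   (default `TRUE`).
#' @return A validated [FilterProfile-class].
#' @export
filterProfile <- function(name, minVaf, minDepth = 100,
                          mafCutoff = 0.001,
                          germlineDbs = c("1000G", "gnomAD", "ExAC"),
                          qualityPolicy = "none",
                          recurrenceThreshold = 0.15,
                          include = c("missense", "nonsense",
                                      "frameshift_indel", "inframe_indel"),
                          driverPolicy = "include_cosmic",
                          panelSizeMb = 1.6,
                          strict = TRUE) {
  bad <- setdiff(include, effectiveClasses())
  if (length(bad))
    stop("unknown consequence class(es) in 'include': ",
         paste(bad, collapse = ", "))
  policy <- stats::setNames(effectiveClasses() %in% include,
                            effectiveClasses())
  if (length(minVaf) == 1L && is.null(names(minVaf)))
    minVaf <- c(FFPE = unname(minVaf), frozen = unname(minVaf))
  new("FilterProfile", name = name,
      minVaf = minVaf[c("FFPE", "frozen")],
      minDepth = as.numeric(minDepth), mafCutoff = mafCutoff,
      germlineDbs = germlineDbs, qualityPolicy = qualityPolicy,
      recurrenceThreshold = recurrenceThreshold, classPolicy = policy,
      driverPolicy = driverPolicy, panelSizeMb = panelSizeMb,
      strict = strict)
}

#' Built-in TMB algorithm profiles
#'
#' Two complete parameterizations of the filter cascade are frozen into the
#' package:
#'
#' * `"IC"` — low-quality calls removed by intra-run recurrence (variants in
#'   more than 15% of a run's samples); germline removal at MAF > 0.1% in
#'   1000 Genomes, gnomAD and ExAC; counts missense, nonsense and indels
#'   only (synonymous, splice-site and non-coding excluded); COSMIC hotspot
#'   status ignored; minimum VAF 10% for FFPE and 5% for frozen tumors;
#'   depth > 100X; 1.6 Mb footprint.
#' * `"FO"` — low-quality calls removed by the caller's PASS tag; germline
#'   removal at MAF > 0.1% in 1000 Genomes and ExAC; counts all coding
#'   classes including synonymous and splice-site; COSMIC drivers excluded;
#'   minimum VAF 5% for both preservations; depth > 100X; 1.6 Mb footprint.
#'
#' @param name `"IC"` or `"FO"`.
#' @return A [FilterProfile-class].
#' @examples
#' builtinProfile("IC")
#' @export
builtinProfile <- function(name) {
  switch(name,
    IC = filterProfile(
      name = "IC",
      minVaf = c(FFPE = 0.10, frozen = 0.05),
      minDepth = 100,
      mafCutoff = 0.001,
      germlineDbs = c("1000G", "gnomAD", "ExAC"),
      qualityPolicy = "intra_run_recurrence",
      recurrenceThreshold = 0.15,
      include = c("missense", "nonsense", "frameshift_indel",
                  "inframe_indel"),
      driverPolicy = "include_cosmic",
      panelSizeMb = 1.6
    ),
    FO = filterProfile(
      name = "FO",
      minVaf = c(FFPE = 0.05, frozen = 0.05),
      minDepth = 100,
      mafCutoff = 0.001,
      germlineDbs = c("1000G", "ExAC"),
      qualityPolicy = "require_pass",
      recurrenceThreshold = 0.15,
      include = c("missense", "nonsense", "frameshift_indel",
                  "inframe_indel", "synonymous", "splice_site"),
      driverPolicy = "exclude_cosmic",
      panelSizeMb = 1.6
    ),
    stop("unknown profile '", name, "'; built-ins are: IC, FO")
  )
}

#' Serialize a filter profile to / from a YAML configuration
#'
#' `writeFilterProfile()` writes every profile field to a plain-text YAML
#' file; `readFilterProfile()` reads one back (or accepts a built-in name).
#'
#' @param profile A [FilterProfile-class].
#' @param path File path.
#' @return `readFilterProfile()` returns a [FilterProfile-class];
#'   `writeFilterProfile()` returns `path` invisibly.
#' @export
writeFilterProfile <- function(profile, path) {
  stopifnot(is(profile, "FilterProfile"))
  x <- list(
    name = profile@name,
    min_vaf = as.list(profile@minVaf),
    min_depth = profile@minDepth,
    maf_cutoff = profile@mafCutoff,
    germline_dbs = as.list(profile@germlineDbs),
    quality_policy = profile@qualityPolicy,
    recurrence_threshold = profile@recurrenceThreshold,
    class_policy = as.list(profile@classPolicy),
    driver_policy = profile@driverPolicy,
    panel_size_mb = profile@panelSizeMb,
    strict = profile@strict
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeFilterProfile
#' @param x A built-in profile name (`"IC"`/`"FO"`) or a YAML file path.
#' @export
readFilterProfile <- function(x) {
  if (x %in% c("IC", "FO")) return(builtinProfile(x))
  if (!file.exists(x))
    stop("'", x, "' is neither a built-in profile (IC, FO) nor a file")
  y <- yaml::read_yaml(x)
  policy <- unlist(y$class_policy)
  new("FilterProfile",
      name = y$name,
      minVaf = unlist(y$min_vaf)[c("FFPE", "frozen")],
      minDepth = as.numeric(y$min_depth),
      mafCutoff = y$maf_cutoff,
      germlineDbs = as.character(unlist(y$germline_dbs)),
      qualityPolicy = y$quality_policy,
      recurrenceThreshold = y$recurrence_threshold,
      classPolicy = policy[effectiveClasses()],
      driverPolicy = y$driver_policy,
      panelSizeMb = y$panel_size_mb,
      strict = isTRUE(y$strict))
}
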