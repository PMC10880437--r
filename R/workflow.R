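#' Read and validate a run manifest
#'
#' The manifest is a TSV with one row per sample: `sample_id`, `vcf`,
#' `caller`, `annotator`, `preservation`, `run_id`, `tumor_type`,
#' `total_reads`, `frac_captured_1000x`, and optionally `msi_status`,
#' `pole_status`, `dna_quality`, `tumor_column`. Sample ids must be unique
#' and every referenced VCF must exist; relative VCF paths are resolved
#' against the manifest's directory.
#'
#' @param path Manifest TSV path, or an equivalent data.frame.
#' @return The validated manifest data.frame.
#' @export
readManifest <- function(path) {
  if (is.data.frame(path)) {
    m <- path
    base <- "."
  } else {
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
    base <- dirname(path)
  }
  need <- c("sample_id", "vcf", "caller", "annotator", "preservation",
            "run_id", "tumor_type", "total_reads", "frac_captured_1000x")
  missing <- setdiff(need, names(m))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("manifest sample_ids must be unique")
  rel <- !file.exists(m$vcf)
  m$vcf[rel] <- file.path(base, m$vcf[rel])
  gone <- !file.exists(m$vcf)
  if (any(gone))
    stop("manifest references missing file(s): ",
         paste(m$vcf[gone], collapse = ", "))
  m$msi_status <- m$msi_status %||% "unknown"
  m$pole_status <- m$pole_status %||% "unknown"
  m
}

.parseManifestVariants <- function(manifest) {
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$sample_id
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    ts <- row$tumor_column
    if (is.null(ts) || is.na(ts) || !nzchar(ts)) ts <- NULL
    out[[i]] <- tryCatch(
      readVariantVcf(row$vcf, caller = row$caller,
                     annotator = row$annotator,
                     tumorSample = ts,
                     sampleId = row$sample_id),
      error = function(e) {
        warning("sample '", row$sample_id, "' skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
  }
  out
}

#' Score a whole manifest: QC gate, filter cascade, TMB
#'
#' Runs the full per-sample workflow over a manifest: the NGS quality gate,
#' VCF parsing, run-context construction per sequencing run (over
#' contributive samples), the filter cascade under `profile`, and the TMB
#' score. Non-contributive samples are reported with `NA` scores but not
#' filtered variants; malformed samples are skipped with a warning and the
#' run continues.
#'
#' @param manifest A manifest path or data.frame (see [readManifest()]).
#' @param profile A [FilterProfile-class], or a name/path accepted by
#'   [readFilterProfile()].
#' @param outDir Optional directory: writes `tmb_<profile>.tsv` (per-sample
#'   scores and attrition) there.
#' @return A list with `tmb` (the cohort data.frame incl. QC flags and
#'   per-stage attrition columns), `results` (named list of
#'   [TMBResult-class]) and `runContexts`.
#' @export
runTmbWorkflow <- function(manifest, profile = "IC", outDir = NULL) {
  manifest <- readManifest(manifest)
  if (!is(profile, "FilterProfile")) profile <- readFilterProfile(profile)
  manifest$contributive <- sampleQC(manifest$total_reads,
                                    manifest$frac_captured_1000x)
  variants <- .parseManifestVariants(manifest)
  parsed <- !vapply(variants, is.null, logical(1))

  runs <- unique(manifest$run_id)
  contexts <- list()
  for (r in runs) {
    inRun <- manifest$sample_id[manifest$run_id == r &
                                  manifest$contributive & parsed]
    if (!length(inRun)) next
    contexts[[r]] <- buildRunContext(variants[inRun], runId = r,
                                     sampleCount = length(inRun))
  }

  results <- list()
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    scored <- row$contributive && parsed[[row$sample_id]]
    if (scored) {
      rep_ <- applyProfile(variants[[row$sample_id]], row$preservation,
                           profile, run = contexts[[row$run_id]])
      res <- computeTMB(rep_, profile)
      results[[row$sample_id]] <- res
      att <- attrition(rep_)
    } else {
      res <- NULL
      att <- stats::setNames(rep(NA_integer_, length(.FILTER_STAGES)),
                             .FILTER_STAGES)
    }
    rows[[i]] <- cbind(
      data.frame(sample_id = row$sample_id, profile = profile@name,
                 preservation = row$preservation, run_id = row$run_id,
                 tumor_type = row$tumor_type,
                 msi_status = row$msi_status,
                 pole_status = row$pole_status,
                 contributive = row$contributive,
                 n_input = if (scored)
                   nrow(variants[[row$sample_id]]) else NA_integer_,
                 n_retained = if (scored) nRetained(res) else NA_integer_,
                 tmb = if (scored) tmbScore(res) else NA_real_,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(att))
    )
  }
  tmb <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.table(tmb,
                       file.path(outDir,
                                 paste0("tmb_", profile@name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(tmb = tmb, results = results, runContexts = contexts)
}

#' VAF sweep over a manifest
#'
#' Computes [vafSweep()] for every contributive sample of a manifest and
#' returns (optionally writes) the long-format table.
#'
#' @inheritParams runTmbWorkflow
#' @param grid Ascending VAF cutoffs.
#' @return Long-format data.frame `sample_id`, `preservation`, `cutoff`,
#'   `n_retained`, `tmb`.
#' @export
runSweepWorkflow <- function(manifest, profile = "IC",
                             grid = seq(0.01, 0.30, by = 0.01),
                             outDir = NULL) {
  manifest <- readManifest(manifest)
  if (!is(profile, "FilterProfile")) profile <- readFilterProfile(profile)
  manifest$contributive <- sampleQC(manifest$total_reads,
                                    manifest$frac_captured_1000x)
  manifest <- manifest[manifest$contributive, , drop = FALSE]
  variants <- .parseManifestVariants(manifest)
  contexts <- list()
  for (r in unique(manifest$run_id)) {
    inRun <- manifest$sample_id[manifest$run_id == r]
    inRun <- inRun[!vapply(variants[inRun], is.null, logical(1))]
    if (length(inRun))
      contexts[[r]] <- buildRunContext(variants[inRun], runId = r,
                                       sampleCount = length(inRun))
  }
  sweeps <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    if (is.null(variants[[row$sample_id]])) return(NULL)
    s <- vafSweep(variants[[row$sample_id]], row$preservation, profile,
                  run = contexts[[row$run_id]], grid = grid)
    s$preservation <- row$preservation
    s
  })
  out <- do.call(rbind, sweeps)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    utils::write.table(out,
                       file.path(outDir,
                                 paste0("sweep_", profile@name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
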