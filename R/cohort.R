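#' Assemble a cohort table from metadata and TMB results
#'
#' Joins per-sample metadata with [TMBResult-class] objects into the flat
#' cohort table the summary layer operates on: one row per sample per
#' profile, with columns `sample_id`, `tumor_type`, `preservation`,
#' `msi_status`, `pole_status`, `contributive`, `profile`, `n_retained`,
#' `tmb`.
#'
#' @param meta data.frame with at least `sample_id`, `tumor_type`,
#'   `preservation`; optional `msi_status`, `pole_status`, `contributive`.
#' @param results List of [TMBResult-class] objects (or a data.frame that
#'   already has `sample_id`, `profile`, `n_retained`, `tmb`).
#' @return The cohort data.frame.
#' @export
cohortTable <- function(meta, results) {
  stopifnot(is.data.frame(meta), "sample_id" %in% names(meta))
  if (is.data.frame(results)) {
    res <- results
  } else {
    res <- do.call(rbind, lapply(results, function(r) {
      stopifnot(is(r, "TMBResult"))
      data.frame(sample_id = sampleId(r), profile = profileName(r),
                 n_retained = nRetained(r), tmb = tmbScore(r),
                 stringsAsFactors = FALSE)
    }))
  }
  meta$msi_status <- meta$msi_status %||% "unknown"
  meta$pole_status <- meta$pole_status %||% "unknown"
  meta$contributive <- meta$contributive %||% TRUE
  out <- merge(meta, res, by = "sample_id")
  if (any(duplicated(out[c("sample_id", "profile")])))
    stop("cohort table must have one row per sample per profile")
  out[order(out$profile, out$sample_id), , drop = FALSE]
}

.stratify <- function(cohort, msi = NULL, pole = NULL, preservation = NULL,
                      contributiveOnly = TRUE) {
  keep <- rep(TRUE, nrow(cohort))
  if (contributiveOnly && "contributive" %in% names(cohort))
    keep <- keep & cohort$contributive %in% TRUE
  if (!is.null(msi)) keep <- keep & cohort$msi_status %in% msi
  if (!is.null(pole)) keep <- keep & cohort$pole_status %in% pole
  if (!is.null(preservation))
    keep <- keep & cohort$preservation %in% preservation
  cohort[keep, , drop = FALSE]
}

#' Per-tumor-type TMB summary
#'
#' Median and observed range of TMB per tumor type over an optional stratum
#' (e.g. the microsatellite-stable, POLE wild-type subset, which is the
#' usual reporting stratum since hypermutators dominate any pooled median).
#'
#' @param cohort A cohort table (one profile).
#' @param msi,pole,preservation Optional stratum filters (character vectors
#'   of accepted values; `NULL` = no filter).
#' @param contributiveOnly Drop samples failing the NGS quality gate
#'   (default `TRUE`).
#' @return data.frame with `tumor_type`, `n`, `median_tmb`, `min_tmb`,
#'   `max_tmb`, sorted by decreasing median. Empty stratum gives an empty
#'   summary.
#' @export
summarizeByType <- function(cohort, msi = NULL, pole = NULL,
                            preservation = NULL, contributiveOnly = TRUE) {
  stopifnot(all(c("tumor_type", "tmb") %in% names(cohort)))
  x <- .stratify(cohort, msi, pole, preservation, contributiveOnly)
  if (!nrow(x))
    return(data.frame(tumor_type = character(), n = integer(),
                      median_tmb = numeric(), min_tmb = numeric(),
                      max_tmb = numeric(), stringsAsFactors = FALSE))
  sp <- split(x$tmb, x$tumor_type)
  out <- data.frame(
    tumor_type = names(sp),
    n = vapply(sp, length, integer(1)),
    median_tmb = vapply(sp, stats::median, numeric(1)),
    min_tmb = vapply(sp, min, numeric(1)),
    max_tmb = vapply(sp, max, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$median_tmb, out$tumor_type), , drop = FALSE]
}

#' TMB bin counts per preservation
#'
#' Counts samples per TMB bin, split by preservation. The default edges
#' give the bins \[0, 10\], (10, 30\], (30, 100\], (100, Inf): the low bin
#' is closed at 10 so that "between 0 and 10 mut/Mb" counts a sample at
#' exactly 10, and "greater than 100" starts strictly above 100.
#'
#' @param cohort A cohort table (one profile).
#' @param edges Ascending interior bin edges, default `c(10, 30, 100)`.
#' @param contributiveOnly Drop non-contributive samples (default `TRUE`).
#' @return data.frame with `preservation`, `bin`, `count`; counts partition
#'   the cohort.
#' @export
binCounts <- function(cohort, edges = c(10, 30, 100),
                      contributiveOnly = TRUE) {
  stopifnot(all(c("preservation", "tmb") %in% names(cohort)))
  if (is.unsorted(edges, strictly = TRUE))
    stop("'edges' must be strictly ascending")
  x <- .stratify(cohort, contributiveOnly = contributiveOnly)
  breaks <- c(0, edges, Inf)
  labs <- c(paste0("[0,", edges[1], "]"),
            if (length(edges) > 1)
              paste0("(", edges[-length(edges)], ",", edges[-1], "]"),
            paste0(">", edges[length(edges)]))
  bins <- cut(x$tmb, breaks = breaks, labels = labs,
              include.lowest = TRUE, right = TRUE)
  pres <- factor(x$preservation, levels = .PRESERVATIONS)
  tab <- table(preservation = pres, bin = bins)
  out <- as.data.frame(tab, responseName = "count",
                       stringsAsFactors = FALSE)
  out$count <- as.integer(out$count)
  out
}

#' Top-decile TMB threshold
#'
#' The 90th percentile of the supplied TMB scores, computed by linear
#' interpolation between closest order statistics; samples strictly above
#' it form the top-decile set used for biological curation of TMB-high
#' cases.
#'
#' @param values Numeric TMB scores; at least 10 are required.
#' @return The threshold (scalar).
#' @examples
#' topDecileThreshold(1:10)  # 9.1
#' @export
topDecileThreshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 10L)
    stop("at least 10 TMB values are required for a top-decile threshold")
  unname(stats::quantile(values, probs = 0.9, type = 7))
}

#' Biological curation of TMB-high cases
#'
#' Classifies each TMB-high sample by the evidence behind its elevated
#' score:
#'
#' * `reclassified_msi_pole` ("true TMB high") — MSIsensor score at or above
#'   10%, a pathogenic mismatch-repair gene variant, an MSI mutational
#'   signature, a POLE proofreading-domain mutation, or an APOBEC signature;
#' * `ddr_candidate_explained` — otherwise, a pathogenic variant with
#'   allelic ratio at or above 10% in one of the DNA-damage-repair
#'   candidate genes TP53, PTEN or ARID1A;
#' * `unexplained` — none of the above.
#'
#' Note the MSI-score and allelic-ratio bounds are inclusive, unlike the
#' strict thresholds of the variant filters.
#'
#' @param features data.frame with one row per sample and columns
#'   `sample_id`, `msi_sensor_score` (percent), `mmr_pathogenic_variant`,
#'   `msi_signature`, `pole_proofreading_mut`, `apobec_signature`
#'   (logicals; absent evidence encoded as `FALSE`/0).
#' @param ddrHits Optional data.frame of candidate-gene hits with columns
#'   `sample_id`, `gene` (TP53/PTEN/ARID1A), `vaf` (fraction), `pathogenic`.
#' @return data.frame with `sample_id`, `category` and the semicolon-joined
#'   `evidence` labels of every satisfied clause.
#' @export
curateHighTmb <- function(features, ddrHits = NULL) {
  need <- c("sample_id", "msi_sensor_score", "mmr_pathogenic_variant",
            "msi_signature", "pole_proofreading_mut", "apobec_signature")
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop("curation features missing columns: ",
         paste(missing, collapse = ", "))
  if (any(features$msi_sensor_score < 0, na.rm = TRUE))
    stop("'msi_sensor_score' must be >= 0")
  if (!is.null(ddrHits) && nrow(ddrHits)) {
    bad <- setdiff(unique(ddrHits$gene), c("TP53", "PTEN", "ARID1A"))
    if (length(bad))
      stop("DDR candidate genes are restricted to TP53/PTEN/ARID1A; got: ",
           paste(bad, collapse = ", "))
  }
  asBool <- function(x) !is.na(x) & as.logical(x)

  out <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    ev <- character()
    if (!is.na(f$msi_sensor_score) && f$msi_sensor_score >= 10)
      ev <- c(ev, "msi_sensor_score>=10")
    if (asBool(f$mmr_pathogenic_variant)) ev <- c(ev, "mmr_pathogenic")
    if (asBool(f$msi_signature)) ev <- c(ev, "msi_signature")
    if (asBool(f$pole_proofreading_mut)) ev <- c(ev, "pole_proofreading")
    if (asBool(f$apobec_signature)) ev <- c(ev, "apobec_signature")
    if (length(ev)) {
      cat_ <- "reclassified_msi_pole"
    } else {
      hits <- if (is.null(ddrHits)) NULL else
        ddrHits[ddrHits$sample_id == f$sample_id &
                  asBool(ddrHits$pathogenic) & ddrHits$vaf >= 0.10, ,
                drop = FALSE]
      if (!is.null(hits) && nrow(hits)) {
        cat_ <- "ddr_candidate_explained"
        ev <- paste0("ddr:", hits$gene)
      } else {
        cat_ <- "unexplained"
      }
    }
    data.frame(sample_id = f$sample_id, category = cat_,
               evidence = paste(ev, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
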