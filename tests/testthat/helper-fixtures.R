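# Fixture builders and an independent reference implementation of the
# filter cascade, used to cross-check applyProfile().

# Build a variant table from partial columns; defaults describe a clean
# clonal somatic missense call that passes every built-in filter.
makeVariants <- function(n = 1, ...) {
  if (n == 0) return(emptyVariantTable())
  args <- list(...)
  base <- list(
    sample_id = "S1", chrom = "1", pos = seq_len(n) * 100L,
    ref = "A", alt = "T", vaf = 0.35, depth = 500L,
    caller = "mutect2", pass = TRUE,
    region_class = "exonic", consequence = "missense", gene = "TP53",
    af_1000g = NA_real_, af_gnomad = NA_real_, af_exac = NA_real_,
    cosmic_hit = FALSE, pathogenic = NA
  )
  base[names(args)] <- args
  out <- do.call(data.frame,
                 c(base, list(stringsAsFactors = FALSE)))
  out[rep(seq_len(nrow(out)), length.out = n), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

# Random variant tables exercising threshold edges (VAF exactly at 5%/10%,
# depth exactly 100, database AF exactly at the 0.1% bound, shared keys).
randomVariants <- function(n, sampleIds = "S1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classes <- c("synonymous", "missense", "nonsense", "frameshift_indel",
               "inframe_indel", "splice_site", "unknown")
  regions <- c("exonic", "splicing", "intronic", "UTR", "intergenic",
               "other_noncoding", "unknown")
  pickAf <- function(n) {
    sample(c(NA_real_, 5e-04, 0.001, 0.002, 0.02), n, replace = TRUE,
           prob = c(0.55, 0.1, 0.1, 0.15, 0.1))
  }
  region <- sample(regions, n, replace = TRUE)
  consequence <- ifelse(region == "splicing", "splice_site",
                 ifelse(region == "exonic",
                        sample(classes[1:5], n, replace = TRUE),
                        "unknown"))
  data.frame(
    sample_id = sample(sampleIds, n, replace = TRUE),
    chrom = sample(c("1", "2"), n, replace = TRUE),
    # small position space so that run-level recurrence actually occurs
    pos = sample(1:40, n, replace = TRUE) * 10L,
    ref = "A", alt = sample(c("T", "G"), n, replace = TRUE),
    vaf = sample(c(0.02, 0.05, 0.07, 0.10, 0.12, 0.35, 0.6), n,
                 replace = TRUE),
    depth = sample(c(50L, 100L, 101L, 400L, 1200L), n, replace = TRUE),
    caller = "mutect2",
    pass = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.8, 0.2)),
    region_class = region,
    consequence = consequence,
    gene = sample(c("TP53", "KRAS", ""), n, replace = TRUE),
    af_1000g = pickAf(n), af_gnomad = pickAf(n), af_exac = pickAf(n),
    cosmic_hit = sample(c(TRUE, FALSE), n, replace = TRUE,
                        prob = c(0.15, 0.85)),
    pathogenic = NA,
    stringsAsFactors = FALSE
  )
}

# Reference implementation: one explicit per-variant loop over the five
# predicates, written directly from the filter definitions and kept
# independent of the package's vectorized code paths.
naiveRetained <- function(variants, preservation, profile, run = NULL) {
  dbCols <- c("1000G" = "af_1000g", "gnomAD" = "af_gnomad",
              "ExAC" = "af_exac")
  incl <- classPolicy(profile)
  out <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    qp <- qualityPolicy(profile)

    okQual <- if (qp %in% c("require_pass", "both")) isTRUE(v$pass) else TRUE

    okRec <- TRUE
    if (qp %in% c("intra_run_recurrence", "both")) {
      key <- paste0(sub("^chr", "", v$chrom), ":", v$pos, ":", v$ref,
                    ">", v$alt)
      cnt <- presenceCounts(run)[key]
      if (is.na(cnt)) cnt <- 0
      okRec <- !(cnt / sampleCount(run) > recurrenceThreshold(profile))
    }

    okGerm <- TRUE
    for (db in germlineDbs(profile)) {
      af <- v[[dbCols[[db]]]]
      if (!is.na(af) && af > mafCutoff(profile)) okGerm <- FALSE
    }

    eff <- if (v$region_class %in% c("intronic", "UTR", "intergenic",
                                     "other_noncoding")) "noncoding"
           else v$consequence
    okClass <- isTRUE(incl[[eff]])
    if (driverPolicy(profile) == "exclude_cosmic" && isTRUE(v$cosmic_hit))
      okClass <- FALSE

    okVaf <- v$vaf > minVaf(profile)[[preservation]] &&
      v$depth > minDepth(profile)

    out[i] <- okQual && okRec && okGerm && okClass && okVaf
  }
  out
}

# A short random grab-bag of profiles for property tests.
randomProfile <- function(seed) {
  set.seed(seed)
  filterProfile(
    name = paste0("rand", seed),
    minVaf = c(FFPE = sample(c(0.05, 0.10), 1),
               frozen = sample(c(0.03, 0.05), 1)),
    minDepth = sample(c(50, 100), 1),
    mafCutoff = 0.001,
    germlineDbs = sample(c("1000G", "gnomAD", "ExAC"),
                         sample(1:3, 1)),
    qualityPolicy = sample(c("require_pass", "intra_run_recurrence",
                             "both", "none"), 1),
    recurrenceThreshold = sample(c(0.15, 0.3), 1),
    include = sample(c("synonymous", "missense", "nonsense",
                       "frameshift_indel", "inframe_indel",
                       "splice_site"), sample(2:6, 1)),
    driverPolicy = sample(c("include_cosmic", "exclude_cosmic"), 1)
  )
}
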