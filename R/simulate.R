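#' Configure a synthetic annotated cohort
#'
#' Builds a [SimConfig-class] describing a cohort of targeted-panel somatic
#' VCFs with known ground truth. The generator emulates the statistical
#' structure of clinical panel data: clonal somatic coding variants at a
#' per-sample density, germline polymorphism leakage carrying database
#' allele frequencies straddling the 0.1% removal bound, low-VAF C>T
#' deamination artifacts in FFPE samples (with a heavier high-VAF tail for
#' low-quality DNA), and run-recurrent systematic artifacts shared by more
#' than the recurrence threshold of a run's samples. Frozen samples receive
#' no deamination artifacts. The seed fully determines the output.
#'
#' @param seed Integer seed; identical configs produce byte-identical VCFs.
#' @param nSamples Number of samples.
#' @param ffpeFraction Fraction of samples that are FFPE (rest frozen).
#' @param samplesPerRun Samples per sequencing run.
#' @param somaticDensity True somatic countable (coding non-synonymous +
#'   indel) variants per Mb for microsatellite-stable samples.
#' @param msiFraction Fraction of hypermutated (MSI) samples.
#' @param msiMultiplier Density multiplier for MSI samples.
#' @param classMixture Named proportions over the non-unknown effective
#'   classes; must sum to 1.
#' @param germlineLeakRate Expected germline variants per sample surviving
#'   upstream matched-normal-free calling.
#' @param germlineAboveFraction Fraction of germline variants whose
#'   database allele frequency exceeds the 0.1% bound (the rest sit at or
#'   below it and will slip through the database filter).
#' @param ffpeArtifactRate Expected deamination artifacts per Mb in FFPE
#'   samples.
#' @param artifactVafShape Beta(shape1, shape2) of artifact VAFs for
#'   high-quality FFPE (mass below 0.10).
#' @param lowQualityVafShape Beta shape for low-quality FFPE (heavier tail
#'   above 0.10).
#' @param lowQualityFraction Fraction of FFPE samples with low-quality DNA.
#' @param somaticVafShape,somaticVafRange Beta shape and truncation range
#'   of clonal somatic VAFs (kept above 0.10 so VAF-threshold experiments
#'   never clip true variants).
#' @param depthMean,depthSize,depthFloor Negative-binomial depth model
#'   (mean, dispersion) with a hard floor in reads.
#' @param panelSizeMb Captured footprint in megabases.
#' @param cosmicFraction Fraction of somatic missense variants present in
#'   COSMIC.
#' @param annotator `"annovar"`, `"snpeff"`, or `"both"` (paired files for
#'   dialect-equivalence checks).
#' @param caller Genotype dialect to emit (`"mutect2"` or `"varscan2"`).
#' @param recurrentPerRun Run-recurrent artifact keys injected per run.
#' @param recurrentSampleFraction Fraction of a run's samples carrying each
#'   recurrent key (must exceed the recurrence threshold to be filterable).
#' @param qcFailFraction Fraction of samples given failing NGS QC metrics.
#' @param artifactNonPassFraction Fraction of artifacts the caller itself
#'   flags as non-PASS.
#' @param tumorTypes Tumor-type labels sampled uniformly.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      nSamples = 40L,
                      ffpeFraction = 0.55,
                      samplesPerRun = 20L,
                      somaticDensity = 8.8,
                      msiFraction = 0,
                      msiMultiplier = 5,
                      classMixture = c(synonymous = 0.18, missense = 0.55,
                                       nonsense = 0.05,
                                       frameshift_indel = 0.06,
                                       inframe_indel = 0.03,
                                       splice_site = 0.05,
                                       noncoding = 0.08),
                      germlineLeakRate = 10,
                      germlineAboveFraction = 0.8,
                      ffpeArtifactRate = 30,
                      artifactVafShape = c(1.5, 40),
                      lowQualityVafShape = c(1.2, 10),
                      lowQualityFraction = 0,
                      somaticVafShape = c(8, 14),
                      somaticVafRange = c(0.12, 0.95),
                      depthMean = 800,
                      depthSize = 8,
                      depthFloor = 150L,
                      panelSizeMb = 1.6,
                      cosmicFraction = 0.15,
                      annotator = "annovar",
                      caller = "mutect2",
                      recurrentPerRun = 2L,
                      recurrentSampleFraction = 0.25,
                      qcFailFraction = 0,
                      artifactNonPassFraction = 0,
                      tumorTypes = c("breast", "colorectal", "sarcoma",
                                     "ovarian", "CNS", "lung", "lymphoma",
                                     "endometrial")) {
  new("SimConfig",
      seed = as.integer(seed), nSamples = as.integer(nSamples),
      ffpeFraction = ffpeFraction,
      samplesPerRun = as.integer(samplesPerRun),
      somaticDensity = somaticDensity, msiFraction = msiFraction,
      msiMultiplier = msiMultiplier, classMixture = classMixture,
      germlineLeakRate = germlineLeakRate,
      germlineAboveFraction = germlineAboveFraction,
      ffpeArtifactRate = ffpeArtifactRate,
      artifactVafShape = artifactVafShape,
      lowQualityVafShape = lowQualityVafShape,
      lowQualityFraction = lowQualityFraction,
      somaticVafShape = somaticVafShape,
      somaticVafRange = somaticVafRange,
      depthMean = depthMean, depthSize = depthSize,
      depthFloor = as.integer(depthFloor), panelSizeMb = panelSizeMb,
      cosmicFraction = cosmicFraction, annotator = annotator,
      caller = caller, recurrentPerRun = as.integer(recurrentPerRun),
      recurrentSampleFraction = recurrentSampleFraction,
      qcFailFraction = qcFailFraction,
      artifactNonPassFraction = artifactNonPassFraction,
      tumorTypes = tumorTypes)
}

#' Serialize a simulation configuration to / from YAML
#'
#' @param config A [SimConfig-class].
#' @param path File path.
#' @return `readSimConfig()` returns a [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimConfig"))
  x <- lapply(slotNames(config), function(s) slot(config, s))
  names(x) <- slotNames(config)
  x$classMixture <- as.list(x$classMixture)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  y <- yaml::read_yaml(path)
  y$classMixture <- unlist(y$classMixture)
  do.call(simConfig, y)
}

## Internal generator pieces ------------------------------------------------

.GENE_POOL <- c("TP53", "PTEN", "ARID1A", "KRAS", "PIK3CA", "EGFR", "BRAF",
                "MSH2", "MLH1", "MSH6", "PMS2", "ATM", "BRCA1", "BRCA2",
                "POLE", "APC", "RB1", "NF1", "SMAD4", "FBXW7")

.CLASS_REGION <- c(synonymous = "exonic", missense = "exonic",
                   nonsense = "exonic", frameshift_indel = "exonic",
                   inframe_indel = "exonic", splice_site = "splicing")

.rtruncbeta <- function(n, shape, range) {
  lo <- stats::pbeta(range[1], shape[1], shape[2])
  hi <- stats::pbeta(range[2], shape[1], shape[2])
  stats::qbeta(stats::runif(n, lo, hi), shape[1], shape[2])
}

.simDepth <- function(n, config) {
  config@depthFloor +
    stats::rnbinom(n, size = config@depthSize,
                   mu = max(config@depthMean - config@depthFloor, 1))
}

# ref/alt pair for one variant of a given effective class
.simAlleles <- function(class) {
  bases <- c("A", "C", "G", "T")
  if (class == "frameshift_indel") {
    if (stats::runif(1) < 0.5) c("A", "AT") else c("AT", "A")
  } else if (class == "inframe_indel") {
    if (stats::runif(1) < 0.5) c("AGTC", "A") else c("A", "AGTC")
  } else {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    c(ref, alt)
  }
}

# one sample's variant rows + truth labels
.simSample <- function(sid, preservation, quality, msi, config,
                       recurrentKeys, posPool) {
  mix <- config@classMixture
  countable <- c("missense", "nonsense", "frameshift_indel",
                 "inframe_indel")
  pCount <- sum(mix[countable])
  dens <- config@somaticDensity * if (msi) config@msiMultiplier else 1
  nSomC <- stats::rpois(1, dens * config@panelSizeMb)
  nSomO <- stats::rpois(1, dens * config@panelSizeMb *
                          (1 - pCount) / pCount)
  nGerm <- stats::rpois(1, config@germlineLeakRate)
  nArt <- if (preservation == "FFPE")
    stats::rpois(1, config@ffpeArtifactRate * config@panelSizeMb) else 0L

  classes <- c(
    sample(countable, nSomC, replace = TRUE,
           prob = mix[countable] / pCount),
    if (nSomO) sample(setdiff(names(mix), countable), nSomO,
                      replace = TRUE,
                      prob = mix[setdiff(names(mix), countable)] /
                        (1 - pCount)),
    sample(names(mix), nGerm, replace = TRUE, prob = mix),
    sample(names(mix), nArt, replace = TRUE, prob = mix)
  )
  label <- c(rep("somatic", nSomC + nSomO), rep("germline", nGerm),
             rep("ffpe_artifact", nArt))
  n <- length(classes)
  pos <- sample(posPool, n)

  vaf <- numeric(n)
  som <- label == "somatic"
  vaf[som] <- .rtruncbeta(sum(som), config@somaticVafShape,
                          config@somaticVafRange)
  germ <- label == "germline"
  vaf[germ] <- pmin(pmax(stats::rnorm(sum(germ), 0.5, 0.05), 0.35), 0.65)
  art <- label == "ffpe_artifact"
  shape <- if (quality == "low") config@lowQualityVafShape else
    config@artifactVafShape
  vaf[art] <- pmax(stats::rbeta(sum(art), shape[1], shape[2]), 0.005)
  vaf <- round(vaf, 4)

  # database AFs: germline variants straddle the removal bound; everything
  # somatic or artifactual is absent from the population databases
  af1000g <- afGnomad <- afExac <- rep(NA_real_, n)
  if (nGerm) {
    above <- stats::runif(nGerm) < config@germlineAboveFraction
    afTrue <- ifelse(above, stats::runif(nGerm, 0.002, 0.05),
                     ifelse(stats::runif(nGerm) < 0.5, 0.001, 5e-04))
    idx <- which(germ)
    # each variant observed in 1-3 of the databases
    for (j in seq_along(idx)) {
      dbs <- sample(c("g1000", "gnomad", "exac"),
                    sample(1:3, 1, prob = c(0.2, 0.3, 0.5)))
      if ("g1000" %in% dbs) af1000g[idx[j]] <- afTrue[j]
      if ("gnomad" %in% dbs) afGnomad[idx[j]] <- afTrue[j]
      if ("exac" %in% dbs) afExac[idx[j]] <- afTrue[j]
    }
  }

  alleles <- vapply(seq_len(n), function(i) .simAlleles(classes[i]),
                    character(2))
  ref <- alleles[1, ]
  alt <- alleles[2, ]
  if (any(art)) { ref[art] <- "C"; alt[art] <- "T" }

  region <- ifelse(classes == "noncoding",
                   sample(c("intronic", "UTR", "intergenic",
                            "other_noncoding"), n, replace = TRUE),
                   .CLASS_REGION[classes])
  consequence <- ifelse(classes == "noncoding", "unknown", classes)
  gene <- ifelse(region %in% c("exonic", "splicing"),
                 sample(.GENE_POOL, n, replace = TRUE), "")
  cosmic <- som & classes == "missense" &
    stats::runif(n) < config@cosmicFraction
  patho <- ifelse(som & classes %in% c("nonsense", "frameshift_indel") &
                    stats::runif(n) < 0.3, TRUE, NA)
  pass <- rep(TRUE, n)
  if (config@artifactNonPassFraction > 0 && any(art))
    pass[art] <- stats::runif(sum(art)) >= config@artifactNonPassFraction

  tab <- data.frame(
    sample_id = sid, chrom = "1", pos = as.integer(pos),
    ref = ref, alt = alt, vaf = vaf,
    depth = as.integer(.simDepth(n, config)),
    caller = config@caller, pass = pass,
    region_class = region, consequence = consequence, gene = gene,
    af_1000g = af1000g, af_gnomad = afGnomad, af_exac = afExac,
    cosmic_hit = cosmic, pathogenic = patho,
    stringsAsFactors = FALSE
  )

  # run-recurrent systematic artifacts at fixed, shared positions
  if (nrow(recurrentKeys)) {
    rec <- data.frame(
      sample_id = sid, chrom = "1", pos = recurrentKeys$pos,
      ref = recurrentKeys$ref, alt = recurrentKeys$alt,
      vaf = round(stats::runif(nrow(recurrentKeys), 0.15, 0.35), 4),
      depth = as.integer(.simDepth(nrow(recurrentKeys), config)),
      caller = config@caller, pass = TRUE,
      region_class = "exonic", consequence = "missense",
      gene = sample(.GENE_POOL, nrow(recurrentKeys), replace = TRUE),
      af_1000g = NA_real_, af_gnomad = NA_real_, af_exac = NA_real_,
      cosmic_hit = FALSE, pathogenic = NA,
      stringsAsFactors = FALSE
    )
    tab <- rbind(tab, rec)
    label <- c(label, rep("recurrent_artifact", nrow(recurrentKeys)))
    classes <- c(classes, rep("missense", nrow(recurrentKeys)))
  }

  ord <- order(tab$pos)
  truth <- data.frame(
    sample_id = sid, chrom = tab$chrom, pos = tab$pos, ref = tab$ref,
    alt = tab$alt, label = label, class = classes,
    countable_ic = label == "somatic" & classes %in% countable,
    vaf = tab$vaf, stringsAsFactors = FALSE
  )
  list(variants = tab[ord, , drop = FALSE],
       truth = truth[ord, , drop = FALSE])
}

#' Generate a synthetic annotated cohort with ground truth
#'
#' Draws a cohort under `config`, writes one annotated VCF per sample plus
#' a sample manifest and truth tables into `dir`, and returns everything
#' in memory as well. Output is deterministic given the config (including
#' the seed); the global RNG state is left untouched.
#'
#' @param config A [SimConfig-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (sample metadata + file
#'   paths), `variants` (named list of per-sample variant tables as
#'   emitted), `truth` (per-variant labels), `truthSummary` (per-sample
#'   true countable density) and `dir`.
#' @export
simulateCohort <- function(config, dir = tempfile("simcohort")) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }, add = TRUE)
  set.seed(config@seed)

  n <- config@nSamples
  sids <- sprintf("S%03d", seq_len(n))
  nRuns <- ceiling(n / config@samplesPerRun)
  runIds <- sprintf("run%02d", rep(seq_len(nRuns),
                                   each = config@samplesPerRun)[seq_len(n)])
  nFFPE <- round(config@ffpeFraction * n)
  preservation <- sample(c(rep("FFPE", nFFPE), rep("frozen", n - nFFPE)))
  quality <- ifelse(preservation == "FFPE" &
                      stats::runif(n) < config@lowQualityFraction,
                    "low", "high")
  msi <- stats::runif(n) < config@msiFraction
  tumorType <- sample(config@tumorTypes, n, replace = TRUE)
  qcFail <- stats::runif(n) < config@qcFailFraction
  totalReads <- ifelse(qcFail,
                       round(stats::runif(n, 5e6, 19.5e6)),
                       round(stats::runif(n, 25e6, 60e6)))
  frac1000x <- ifelse(qcFail, stats::runif(n, 0.02, 0.14),
                      round(stats::runif(n, 0.30, 0.95), 3))

  # recurrent artifact keys live in a reserved coordinate block so they can
  # never collide with per-sample draws
  posPool <- 10001:as.integer(config@panelSizeMb * 1e6)
  recKeys <- lapply(seq_len(nRuns), function(r) {
    if (config@recurrentPerRun == 0L)
      return(data.frame(pos = integer(), ref = character(),
                        alt = character(), stringsAsFactors = FALSE))
    data.frame(pos = as.integer(100L * r + seq_len(config@recurrentPerRun)),
               ref = "G", alt = "A", stringsAsFactors = FALSE)
  })
  carrier <- matrix(FALSE, n, config@recurrentPerRun)
  for (r in seq_len(nRuns)) {
    inRun <- which(runIds == sprintf("run%02d", r))
    nCarry <- ceiling(config@recurrentSampleFraction * length(inRun))
    for (k in seq_len(config@recurrentPerRun))
      carrier[sample(inRun, nCarry), k] <- TRUE
  }

  variants <- vector("list", n)
  names(variants) <- sids
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    rk <- recKeys[[match(runIds[i], sprintf("run%02d", seq_len(nRuns)))]]
    rk <- rk[carrier[i, seq_len(nrow(rk))] %in% TRUE, , drop = FALSE]
    sim <- .simSample(sids[i], preservation[i], quality[i], msi[i],
                      config, rk, posPool)
    variants[[i]] <- sim$variants
    truths[[i]] <- sim$truth
  }
  truth <- do.call(rbind, truths)
  rownames(truth) <- NULL

  annotators <- if (config@annotator == "both") c("annovar", "snpeff")
                else config@annotator
  vcfPaths <- character(n)
  for (i in seq_len(n)) {
    for (a in annotators) {
      p <- file.path(dir, paste0(sids[i],
                                 if (a == "snpeff") ".snpeff", ".vcf"))
      writeVariantVcf(variants[[i]], p, annotator = a,
                      tumorSample = sids[i])
      if (a == annotators[1]) vcfPaths[i] <- p
    }
  }

  manifest <- data.frame(
    sample_id = sids, vcf = vcfPaths, caller = config@caller,
    annotator = annotators[1], preservation = preservation,
    run_id = runIds, tumor_type = tumorType, dna_quality = quality,
    total_reads = totalReads, frac_captured_1000x = frac1000x,
    msi_status = ifelse(msi, "MSI", "MSS"),
    pole_status = "WT", stringsAsFactors = FALSE
  )
  nCountable <- vapply(sids, function(s)
    sum(truth$countable_ic[truth$sample_id == s]), numeric(1))
  truthSummary <- data.frame(
    sample_id = sids,
    n_true_countable = as.integer(nCountable),
    true_ic_density = nCountable / config@panelSizeMb,
    stringsAsFactors = FALSE
  )

  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth_variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truthSummary, file.path(dir, "truth_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeSimConfig(config, file.path(dir, "sim_config.yaml"))

  invisible(list(manifest = manifest, variants = variants, truth = truth,
                 truthSummary = truthSummary, dir = dir))
}

#' Score pipeline output against simulation ground truth
#'
#' Joins the variants each [TMBResult-class] retained with the generator's
#' per-variant labels and reports, per sample: the TMB error against the
#' true countable density, how many artifacts and germline variants leaked
#' through the cascade, and how many true countable somatic variants were
#' lost to it.
#'
#' @param results List of [TMBResult-class] objects (one profile).
#' @param truth The `truth` data.frame from [simulateCohort()].
#' @return data.frame with one row per sample: `sample_id`, `tmb`,
#'   `true_density`, `abs_error`, `artifact_leak`, `germline_leak`,
#'   `somatic_lost`.
#' @export
evaluateAgainstTruth <- function(results, truth) {
  stopifnot(length(results) > 0)
  out <- lapply(results, function(r) {
    stopifnot(is(r, "TMBResult"))
    sid <- sampleId(r)
    tr <- truth[truth$sample_id == sid, , drop = FALSE]
    if (!nrow(tr))
      stop("sample '", sid, "' has no ground-truth entries")
    trKey <- variantKey(tr$chrom, tr$pos, tr$ref, tr$alt)
    v <- verdicts(filterReport(r))
    retained <- v$key[v$retained]
    lab <- tr$label[match(retained, trKey)]
    if (anyNA(lab))
      stop("retained variant(s) in sample '", sid,
           "' missing from ground truth")
    trueCount <- sum(tr$countable_ic)
    trueDensity <- trueCount / panelSizeMb(r)
    lostKeys <- setdiff(trKey[tr$countable_ic], retained)
    data.frame(
      sample_id = sid,
      tmb = tmbScore(r),
      true_density = trueDensity,
      abs_error = abs(tmbScore(r) - trueDensity),
      artifact_leak = sum(lab %in% c("ffpe_artifact",
                                     "recurrent_artifact")),
      germline_leak = sum(lab == "germline"),
      somatic_lost = length(lostKeys),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
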