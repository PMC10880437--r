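#' Annotation field names expected in the VCF INFO column
#'
#' Default INFO keys under which the reader looks for functional annotation,
#' population allele frequencies and COSMIC membership. Override any element
#' to match a different annotation pipeline.
#'
#' @param region ANNOVAR functional-region key.
#' @param exonicFunc ANNOVAR exonic-consequence key.
#' @param gene ANNOVAR gene-symbol key.
#' @param af Named character: database name (`"1000G"`, `"gnomAD"`,
#'   `"ExAC"`) to the INFO key holding its allele frequency.
#' @param cosmic INFO key holding a COSMIC identifier (any non-missing value
#'   counts as a hit; a record ID starting with `COSM` also counts).
#' @param pathogenic INFO flag marking a curated pathogenic call.
#' @param ann snpEff effect-annotation key.
#' @return A named list of key names.
#' @export
annotationKeys <- function(region = "Func_refGene",
                           exonicFunc = "ExonicFunc_refGene",
                           gene = "Gene_refGene",
                           af = c("1000G" = "AF_1000g",
                                  "gnomAD" = "AF_gnomad",
                                  "ExAC" = "AF_exac"),
                           cosmic = "cosmic86",
                           pathogenic = "PATHOGENIC",
                           ann = "ANN") {
  list(region = region, exonicFunc = exonicFunc, gene = gene, af = af,
       cosmic = cosmic, pathogenic = pathogenic, ann = ann)
}

## Frozen term tables mapping annotator vocabulary onto the internal
## region/consequence enums. Unmappable terms become "unknown" (and are
## thereby excluded from TMB), never silently coding.

.ANNOVAR_REGION <- c(
  "exonic" = "exonic",
  "splicing" = "splicing",
  "exonic;splicing" = "splicing",  # splice-boundary call wins
  "intronic" = "intronic",
  "UTR5" = "UTR", "UTR3" = "UTR", "UTR5;UTR3" = "UTR",
  "intergenic" = "intergenic",
  "upstream" = "intergenic", "downstream" = "intergenic",
  "upstream;downstream" = "intergenic",
  "ncRNA_exonic" = "other_noncoding", "ncRNA_intronic" = "other_noncoding",
  "ncRNA_splicing" = "other_noncoding", "ncRNA_UTR5" = "other_noncoding",
  "ncRNA_UTR3" = "other_noncoding"
)

.ANNOVAR_EXONIC <- c(
  "synonymous SNV" = "synonymous", "synonymous_SNV" = "synonymous",
  "nonsynonymous SNV" = "missense", "nonsynonymous_SNV" = "missense",
  "stopgain" = "nonsense",
  "stoploss" = "missense",  # protein-altering, not a premature stop
  "startloss" = "missense",
  "frameshift insertion" = "frameshift_indel",
  "frameshift_insertion" = "frameshift_indel",
  "frameshift deletion" = "frameshift_indel",
  "frameshift_deletion" = "frameshift_indel",
  "frameshift substitution" = "frameshift_indel",
  "frameshift_substitution" = "frameshift_indel",
  "nonframeshift insertion" = "inframe_indel",
  "nonframeshift_insertion" = "inframe_indel",
  "nonframeshift deletion" = "inframe_indel",
  "nonframeshift_deletion" = "inframe_indel",
  "nonframeshift substitution" = "inframe_indel",
  "nonframeshift_substitution" = "inframe_indel"
)

# snpEff sequence-ontology terms -> c(region_class, consequence).
# splice_region_variant (3-8 bp from the junction) is deliberately NOT
# splice_site: the splice definition here is within 2 bp of the boundary,
# which snpEff encodes as splice_acceptor/donor.
.SNPEFF_TERMS <- list(
  synonymous_variant = c("exonic", "synonymous"),
  stop_retained_variant = c("exonic", "synonymous"),
  missense_variant = c("exonic", "missense"),
  stop_lost = c("exonic", "missense"),
  start_lost = c("exonic", "missense"),
  initiator_codon_variant = c("exonic", "missense"),
  stop_gained = c("exonic", "nonsense"),
  frameshift_variant = c("exonic", "frameshift_indel"),
  inframe_insertion = c("exonic", "inframe_indel"),
  inframe_deletion = c("exonic", "inframe_indel"),
  conservative_inframe_insertion = c("exonic", "inframe_indel"),
  conservative_inframe_deletion = c("exonic", "inframe_indel"),
  disruptive_inframe_insertion = c("exonic", "inframe_indel"),
  disruptive_inframe_deletion = c("exonic", "inframe_indel"),
  splice_acceptor_variant = c("splicing", "splice_site"),
  splice_donor_variant = c("splicing", "splice_site"),
  splice_region_variant = c("intronic", "unknown"),
  intron_variant = c("intronic", "unknown"),
  `5_prime_UTR_variant` = c("UTR", "unknown"),
  `3_prime_UTR_variant` = c("UTR", "unknown"),
  `5_prime_UTR_premature_start_codon_gain_variant` = c("UTR", "unknown"),
  upstream_gene_variant = c("intergenic", "unknown"),
  downstream_gene_variant = c("intergenic", "unknown"),
  intergenic_region = c("intergenic", "unknown"),
  non_coding_transcript_exon_variant = c("other_noncoding", "unknown"),
  non_coding_transcript_variant = c("other_noncoding", "unknown")
)

#' Parse a VarScan2 FREQ percentage into a fraction
#'
#' VarScan2 reports allele frequency as a percent string (e.g. `"12.5%"`);
#' this converts it to a fraction in \[0, 1\].
#'
#' @param freq Character vector of percent strings.
#' @return Numeric fractions; invalid entries raise an error.
#' @examples
#' parseVarscanFreq(c("5%", "33.33%", "100%"))
#' @export
parseVarscanFreq <- function(freq) {
  x <- sub("%$", "", trimws(as.character(freq)))
  # some locales emit decimal commas
  x <- sub(",", ".", x, fixed = TRUE)
  val <- suppressWarnings(as.numeric(x))
  if (anyNA(val[!is.na(freq)]))
    stop("non-numeric FREQ field(s): ",
         paste(utils::head(freq[is.na(val) & !is.na(freq)], 3L),
               collapse = ", "))
  val / 100
}

# Map a vector of ANNOVAR region/exonic terms to the internal enums.
.annovarClasses <- function(regionTerm, exonicTerm) {
  region <- unname(.ANNOVAR_REGION[as.character(regionTerm)])
  region[is.na(region)] <- "unknown"
  consequence <- rep("unknown", length(region))
  consequence[region == "splicing"] <- "splice_site"
  ex <- unname(.ANNOVAR_EXONIC[as.character(exonicTerm)])
  take <- region == "exonic" & !is.na(ex)
  consequence[take] <- ex[take]
  data.frame(region_class = region, consequence = consequence,
             stringsAsFactors = FALSE)
}

# Map snpEff ANN entries (one string per record, entries comma-separated,
# fields pipe-separated) to region/consequence/gene for a given alt allele.
.snpeffClasses <- function(ann, alt) {
  n <- length(ann)
  region <- rep("unknown", n)
  consequence <- rep("unknown", n)
  gene <- rep("", n)
  for (i in seq_len(n)) {
    if (is.na(ann[i]) || !nzchar(ann[i])) next
    entries <- strsplit(ann[i], ",", fixed = TRUE)[[1]]
    fields <- strsplit(entries, "|", fixed = TRUE)
    alleles <- vapply(fields, function(f) f[1] %||% "", "")
    hit <- which(alleles == alt[i])
    if (!length(hit)) hit <- 1L  # fall back to the top (most severe) entry
    f <- fields[[hit[1]]]
    effects <- strsplit(f[2] %||% "", "&", fixed = TRUE)[[1]]
    for (eff in effects) {      # snpEff sorts effects by severity
      m <- .SNPEFF_TERMS[[eff]]
      if (!is.null(m)) {
        region[i] <- m[1]
        consequence[i] <- m[2]
        break
      }
    }
    if (length(f) >= 4 && !is.na(f[4])) gene[i] <- f[4]
  }
  data.frame(region_class = region, consequence = consequence, gene = gene,
             stringsAsFactors = FALSE)
}

#' Normalize annotator output for one record into the internal representation
#'
#' Maps an ANNOVAR or snpEff annotation payload onto the internal
#' region/consequence vocabulary through the package's frozen term tables.
#' Unmappable or absent terms yield `"unknown"` (which every built-in
#' profile excludes from TMB — a conservative default).
#'
#' @param payload Named list of annotation fields for one record: for
#'   ANNOVAR the keys named by `keys$region`, `keys$exonicFunc`,
#'   `keys$gene`; for snpEff the key named by `keys$ann` (plus `alt` to
#'   select the matching ANN entry). Population-frequency keys (`keys$af`)
#'   and the COSMIC key are honoured for both annotators.
#' @param annotator `"annovar"` or `"snpeff"`.
#' @param keys See [annotationKeys()].
#' @return One-row data.frame with columns `region_class`, `consequence`,
#'   `gene`, `af_1000g`, `af_gnomad`, `af_exac`, `cosmic_hit`, `pathogenic`.
#' @examples
#' parseAnnotation(list(Func_refGene = "exonic",
#'                      ExonicFunc_refGene = "synonymous_SNV"), "annovar")
#' @export
parseAnnotation <- function(payload, annotator = c("annovar", "snpeff"),
                            keys = annotationKeys()) {
  annotator <- match.arg(annotator)
  getv <- function(k) {
    v <- payload[[k]]
    if (is.null(v) || length(v) == 0L) NA else v[1]
  }
  if (annotator == "annovar") {
    cls <- .annovarClasses(getv(keys$region), getv(keys$exonicFunc))
    gene <- getv(keys$gene)
    cls$gene <- if (is.na(gene)) "" else as.character(gene)
  } else {
    cls <- .snpeffClasses(as.character(getv(keys$ann)),
                          as.character(getv("alt") %||% NA))
  }
  afs <- vapply(keys$af, function(k) {
    v <- getv(k)
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }, numeric(1))
  cos <- getv(keys$cosmic)
  cls$af_1000g <- unname(afs["1000G"])
  cls$af_gnomad <- unname(afs["gnomAD"])
  cls$af_exac <- unname(afs["ExAC"])
  cls$cosmic_hit <- !is.na(cos) && nzchar(as.character(cos)) &&
    as.character(cos) != "."
  patho <- getv(keys$pathogenic)
  cls$pathogenic <- if (isTRUE(patho)) TRUE else NA
  cls
}

#' Read an annotated somatic VCF into a variant table
#'
#' Parses a VCF produced by Mutect2 or VarScan2 and annotated with ANNOVAR
#' or snpEff into the canonical variant table (see [emptyVariantTable()]).
#' Multi-allelic records are split into one row per alternate allele before
#' anything else; chromosome labels lose any leading `"chr"`; a missing
#' FILTER value means the record is treated as not-PASS.
#'
#' VAF and depth come from the caller's dialect: VarScan2's `FREQ` percent
#' string and `DP`; Mutect2's allelic depths `AD` (VAF = alt reads / total
#' AD, depth = total AD summed over all alleles of the original record),
#' falling back to the `AF` and `DP` tags where `AD` is absent. Records
#' whose VAF or depth cannot be parsed are dropped with a counted warning.
#'
#' @param path VCF file (plain or bgzipped).
#' @param caller `"mutect2"` or `"varscan2"`.
#' @param annotator `"annovar"` or `"snpeff"`.
#' @param tumorSample Genotype column holding the tumor; may be omitted for
#'   single-sample VCFs. Naming an absent column is an error listing the
#'   available columns.
#' @param sampleId Sample identifier stored in the table (defaults to the
#'   genotype column name).
#' @param keys See [annotationKeys()].
#' @return A variant table data.frame, one row per (sample, allele).
#' @export
readVariantVcf <- function(path, caller = c("mutect2", "varscan2"),
                           annotator = c("annovar", "snpeff"),
                           tumorSample = NULL, sampleId = NULL,
                           keys = annotationKeys()) {
  caller <- match.arg(caller)
  annotator <- match.arg(annotator)
  vcf <- VariantAnnotation::readVcf(path)
  cols <- colnames(vcf)
  if (length(cols) == 0L)
    stop("VCF has no genotype columns; caller FORMAT fields are required")
  if (is.null(tumorSample)) {
    if (length(cols) > 1L)
      stop("multi-sample VCF: specify 'tumorSample' among: ",
           paste(cols, collapse = ", "))
    tumorSample <- cols[1]
  } else if (!tumorSample %in% cols) {
    stop("genotype column '", tumorSample, "' not found; available: ",
         paste(cols, collapse = ", "))
  }
  sampleId <- sampleId %||% tumorSample
  nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  ve <- VariantAnnotation::expand(vcf)
  if (length(ve) == 0L) return(emptyVariantTable())

  rr <- SummarizedExperiment::rowRanges(ve)
  chrom <- normalizeChrom(as.character(GenomicRanges::seqnames(rr)))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(ve))
  alt <- as.character(VariantAnnotation::alt(ve))
  filt <- as.character(rr$FILTER)
  pass <- !is.na(filt) & filt == "PASS"

  g <- VariantAnnotation::geno(ve)
  pick <- function(m) {
    if (length(dim(m)) == 3L) m[, tumorSample, , drop = FALSE]
    else m[, tumorSample]
  }
  if (caller == "varscan2") {
    if (!"FREQ" %in% names(g))
      stop("VarScan2 VCF lacks the FREQ genotype field")
    freq <- as.character(pick(g$FREQ))
    vaf <- suppressWarnings(
      as.numeric(sub(",", ".", sub("%$", "", trimws(freq)), fixed = TRUE))
    ) / 100
    depth <- if ("DP" %in% names(g)) as.numeric(pick(g$DP)) else NA_real_
  } else {
    vaf <- rep(NA_real_, length(ve))
    depth <- rep(NA_real_, length(ve))
    if ("AD" %in% names(g)) {
      adAll <- VariantAnnotation::geno(vcf)$AD[, tumorSample]
      if (is.list(adAll)) {
        totAD <- vapply(adAll, function(x) sum(as.numeric(x)), numeric(1))
      } else {
        totAD <- rowSums(matrix(as.numeric(adAll), nrow = length(vcf)))
      }
      totAD <- rep(totAD, nAlt)
      adExp <- g$AD
      altAD <- if (length(dim(adExp)) == 3L) {
        as.numeric(adExp[, tumorSample, 2])
      } else {
        vapply(adExp[, tumorSample],
               function(x) as.numeric(x)[2], numeric(1))
      }
      vaf <- ifelse(totAD > 0, altAD / totAD, NA_real_)
      depth <- totAD
    }
    if ("AF" %in% names(g)) {
      af <- as.numeric(pick(g$AF))
      vaf[is.na(vaf)] <- af[is.na(vaf)]
    }
    if ("DP" %in% names(g)) {
      dp <- as.numeric(pick(g$DP))
      depth[is.na(depth) | depth == 0] <- dp[is.na(depth) | depth == 0]
    }
  }

  inf <- VariantAnnotation::info(ve)
  infoCol <- function(k) {
    if (!is.null(k) && k %in% names(inf)) inf[[k]] else NULL
  }
  if (annotator == "annovar") {
    regionTerm <- infoCol(keys$region) %||% rep(NA_character_, length(ve))
    exonicTerm <- infoCol(keys$exonicFunc) %||% rep(NA_character_, length(ve))
    cls <- .annovarClasses(unlist(regionTerm), unlist(exonicTerm))
    geneV <- infoCol(keys$gene)
    cls$gene <- if (is.null(geneV)) "" else {
      gv <- as.character(unlist(geneV))
      ifelse(is.na(gv) | gv == ".", "", gv)
    }
    if (all(is.na(unlist(regionTerm))))
      warning("no '", keys$region,
              "' annotation found; all records classified unknown")
  } else {
    annV <- infoCol(keys$ann)
    if (is.null(annV)) {
      warning("no '", keys$ann,
              "' annotation found; all records classified unknown")
      annStr <- rep(NA_character_, length(ve))
    } else {
      # ANN is Number=. (CharacterList); entries for one record re-join
      annStr <- vapply(as.list(annV), function(x) {
        if (length(x) == 0L || all(is.na(x))) NA_character_
        else paste(x, collapse = ",")
      }, character(1))
    }
    cls <- .snpeffClasses(annStr, alt)
  }
  afCol <- function(k) {
    v <- infoCol(k)
    if (is.null(v)) rep(NA_real_, length(ve))
    else suppressWarnings(as.numeric(unlist(v)))
  }
  cls$af_1000g <- afCol(keys$af[["1000G"]])
  cls$af_gnomad <- afCol(keys$af[["gnomAD"]])
  cls$af_exac <- afCol(keys$af[["ExAC"]])
  cosV <- infoCol(keys$cosmic)
  cosHit <- if (is.null(cosV)) rep(FALSE, length(ve)) else {
    cv <- as.character(unlist(cosV))
    !is.na(cv) & nzchar(cv) & cv != "."
  }
  cosHit <- cosHit | grepl("^COSM", names(rr) %||% character(length(ve)))
  pathoV <- infoCol(keys$pathogenic)
  patho <- if (is.null(pathoV)) rep(NA, length(ve)) else {
    ifelse(as.logical(pathoV), TRUE, NA)
  }

  out <- data.frame(
    sample_id = sampleId, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, vaf = vaf, depth = depth,
    caller = caller, pass = pass,
    region_class = cls$region_class, consequence = cls$consequence,
    gene = cls$gene, af_1000g = cls$af_1000g, af_gnomad = cls$af_gnomad,
    af_exac = cls$af_exac, cosmic_hit = cosHit, pathogenic = patho,
    stringsAsFactors = FALSE, row.names = NULL
  )
  bad <- is.na(out$vaf) | is.na(out$depth) | out$ref == out$alt
  if (any(bad)) {
    warning("dropped ", sum(bad),
            " record(s) with unparsable VAF/depth in ", basename(path))
    out <- out[!bad, , drop = FALSE]
    rownames(out) <- NULL
  }
  out$depth <- as.integer(round(out$depth))
  .checkVariantTable(out, "parsed VCF")
}

## Inverse term tables used when emitting VCF text.
.REGION_TO_ANNOVAR <- c(
  exonic = "exonic", splicing = "splicing", intronic = "intronic",
  UTR = "UTR3", intergenic = "intergenic",
  other_noncoding = "ncRNA_exonic", unknown = "unclassified"
)
.CONSEQ_TO_ANNOVAR <- c(
  synonymous = "synonymous_SNV", missense = "nonsynonymous_SNV",
  nonsense = "stopgain", frameshift_indel = "frameshift_insertion",
  inframe_indel = "nonframeshift_deletion",
  splice_site = ".", unknown = "."
)
.REGION_TO_SNPEFF <- c(
  splicing = "splice_donor_variant", intronic = "intron_variant",
  UTR = "3_prime_UTR_variant", intergenic = "intergenic_region",
  other_noncoding = "non_coding_transcript_exon_variant",
  unknown = "sequence_feature"
)
.CONSEQ_TO_SNPEFF <- c(
  synonymous = "synonymous_variant", missense = "missense_variant",
  nonsense = "stop_gained", frameshift_indel = "frameshift_variant",
  inframe_indel = "conservative_inframe_deletion",
  splice_site = "splice_donor_variant", unknown = "sequence_feature"
)

#' Write a variant table back out as an annotated VCF
#'
#' Emits VCF 4.2 text carrying the caller's genotype dialect (VarScan2
#' `GT:DP:FREQ` or Mutect2 `GT:AD:AF:DP`) and the requested annotation
#' dialect in INFO, such that [readVariantVcf()] reproduces the table. Used
#' by the synthetic-cohort generator and for round-trip validation.
#'
#' @param variants A variant table (single caller).
#' @param path Output file path.
#' @param annotator `"annovar"` or `"snpeff"` INFO dialect.
#' @param keys See [annotationKeys()].
#' @param tumorSample Genotype column name to emit.
#' @return `path`, invisibly.
#' @export
writeVariantVcf <- function(variants, path, annotator = c("annovar", "snpeff"),
                            keys = annotationKeys(),
                            tumorSample = "TUMOR") {
  annotator <- match.arg(annotator)
  .checkVariantTable(variants)
  caller <- unique(variants$caller)
  if (length(caller) > 1L)
    stop("one VCF holds one caller's output; found: ",
         paste(caller, collapse = ", "))
  if (!length(caller)) caller <- "mutect2"

  num <- function(x) sprintf("%.10g", x)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panelTMB",
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Functional region (ANNOVAR dialect)\">", keys$region),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Exonic consequence (ANNOVAR dialect)\">", keys$exonicFunc),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"Gene symbol\">", keys$gene),
    sprintf("##INFO=<ID=%s,Number=.,Type=String,Description=\"Functional annotations (snpEff dialect)\">", keys$ann),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"1000 Genomes allele frequency, all ethnicities\">", keys$af[["1000G"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"gnomAD allele frequency, all ethnicities\">", keys$af[["gnomAD"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"ExAC allele frequency, all ethnicities\">", keys$af[["ExAC"]]),
    sprintf("##INFO=<ID=%s,Number=1,Type=String,Description=\"COSMIC identifier\">", keys$cosmic),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Curated pathogenic call\">", keys$pathogenic),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"Variant allele frequency (percent)\">",
    "##FILTER=<ID=lowqual,Description=\"Failed caller quality filters\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           tumorSample)
  )
  lines <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- character()
    if (annotator == "annovar") {
      info <- c(info,
        paste0(keys$region, "=", .REGION_TO_ANNOVAR[[v$region_class]]),
        paste0(keys$exonicFunc, "=",
               if (v$region_class == "exonic")
                 .CONSEQ_TO_ANNOVAR[[v$consequence]] else "."),
        paste0(keys$gene, "=", if (nzchar(v$gene)) v$gene else "."))
    } else {
      eff <- if (v$region_class %in% c("exonic", "splicing"))
        .CONSEQ_TO_SNPEFF[[v$consequence]]
      else .REGION_TO_SNPEFF[[v$region_class]]
      ann <- paste(v$alt, eff, "MODIFIER", v$gene, v$gene, "transcript",
                   paste0(v$gene, ".1"), "protein_coding", "1/1",
                   "c.1A>T", "", "", "", "", "", "", sep = "|")
      info <- c(info, paste0(keys$ann, "=", ann))
    }
    if (!is.na(v$af_1000g))
      info <- c(info, paste0(keys$af[["1000G"]], "=", num(v$af_1000g)))
    if (!is.na(v$af_gnomad))
      info <- c(info, paste0(keys$af[["gnomAD"]], "=", num(v$af_gnomad)))
    if (!is.na(v$af_exac))
      info <- c(info, paste0(keys$af[["ExAC"]], "=", num(v$af_exac)))
    if (isTRUE(v$cosmic_hit))
      info <- c(info, paste0(keys$cosmic, "=COSM",
                             abs(v$pos %% 1000000L) + 1L))
    if (isTRUE(v$pathogenic)) info <- c(info, keys$pathogenic)
    if (!length(info)) info <- "."

    if (caller == "varscan2") {
      fmt <- "GT:DP:FREQ"
      gt <- paste0("0/1:", v$depth, ":",
                   sprintf("%.10g%%", v$vaf * 100))
    } else {
      altAD <- as.integer(round(v$vaf * v$depth))
      fmt <- "GT:AD:AF:DP"
      gt <- paste0("0/1:", v$depth - altAD, ",", altAD, ":",
                   num(v$vaf), ":", v$depth)
    }
    lines[i] <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".",
                      if (v$pass) "PASS" else "lowqual",
                      paste(info, collapse = ";"), fmt, gt, sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
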