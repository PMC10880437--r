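## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Threshold comparison honouring a profile's strictness switch.
# strict = TRUE means the value must exceed the bound ("higher than").
.above <- function(x, bound, strict = TRUE) {
  if (strict) x > bound else x >= bound
}

#' Canonical key of one variant allele
#'
#' Keys identify a variant within one pipeline's own output; chromosome
#' labels are normalized (leading "chr" stripped) and multi-allelic records
#' are split before keying, so one key names one alternate allele.
#'
#' @param chrom,pos,ref,alt Vectors describing the variant allele(s).
#' @return Character vector of keys, `"chrom:pos:ref>alt"`.
#' @examples
#' variantKey("chr1", 100, "A", "T")  # "1:100:A>T"
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  paste0(normalizeChrom(chrom), ":", as.integer(pos), ":", ref, ">", alt)
}

#' @rdname variantKey
#' @export
normalizeChrom <- function(chrom) {
  sub("^chr", "", as.character(chrom))
}

# Required columns of a parsed variant table (the data.frame realisation of
# one sample's annotated calls).
.VARIANT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "vaf", "depth",
                   "caller", "pass", "region_class", "consequence", "gene",
                   "af_1000g", "af_gnomad", "af_exac", "cosmic_hit",
                   "pathogenic")

.DB_COLUMNS <- c("1000G" = "af_1000g", "gnomAD" = "af_gnomad",
                 "ExAC" = "af_exac")

#' An empty variant table with the canonical columns
#'
#' The package represents one sample's parsed, annotation-normalized calls
#' as a data.frame with a fixed column contract: identity (`sample_id`,
#' `chrom`, `pos`, `ref`, `alt`), measurement (`vaf` as a fraction in
#' \[0,1\], `depth` in reads, `caller`, `pass`), and normalized annotation
#' (`region_class`, `consequence`, `gene`, per-database population
#' frequencies `af_1000g` / `af_gnomad` / `af_exac` with `NA` meaning "not
#' observed in that database", `cosmic_hit`, `pathogenic`).
#'
#' @return A zero-row data.frame with the canonical columns.
#' @export
emptyVariantTable <- function() {
  data.frame(
    sample_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), vaf = numeric(),
    depth = integer(), caller = character(), pass = logical(),
    region_class = character(), consequence = character(),
    gene = character(), af_1000g = numeric(), af_gnomad = numeric(),
    af_exac = numeric(), cosmic_hit = logical(), pathogenic = logical(),
    stringsAsFactors = FALSE
  )
}

.checkVariantTable <- function(variants, what = "variants") {
  stopifnot(is.data.frame(variants))
  missing <- setdiff(.VARIANT_COLS, names(variants))
  if (length(missing))
    stop(what, " is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(variants)) {
    if (any(variants$vaf < 0 | variants$vaf > 1, na.rm = TRUE))
      stop("'vaf' must lie in [0, 1]", call. = FALSE)
    if (any(variants$depth < 0, na.rm = TRUE))
      stop("'depth' must be >= 0", call. = FALSE)
  }
  invisible(variants)
}

# Effective filter class of a variant: the consequence term, except that
# variants outside exonic/splicing regions pool into "noncoding".
.effectiveClass <- function(region_class, consequence) {
  ifelse(region_class %in% c("intronic", "UTR", "intergenic",
                             "other_noncoding"),
         "noncoding",
         ifelse(region_class == "unknown" & consequence == "unknown",
                "unknown", consequence))
}
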