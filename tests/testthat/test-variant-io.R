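test_that("VarScan2 FREQ percent strings parse to fractions", {
  expect_equal(parseVarscanFreq("5%"), 0.05)
  expect_equal(parseVarscanFreq("100%"), 1.0)
  expect_equal(parseVarscanFreq("33.33%"), 0.3333)
  expect_equal(parseVarscanFreq("12,5%"), 0.125)  # decimal-comma locale
  # parse inverts the percent encoding within float tolerance
  vals <- c("0.01%", "2.5%", "49.999%", "87.125%")
  expect_equal(parseVarscanFreq(vals) * 100,
               as.numeric(sub("%", "", vals)), tolerance = 1e-9)
  expect_error(parseVarscanFreq("n/a"), "non-numeric")
})

writeTestVcf <- function(lines, formats = "") {
  p <- tempfile(fileext = ".vcf")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=Func_refGene,Number=1,Type=String,Description=\"r\">",
    "##INFO=<ID=ExonicFunc_refGene,Number=1,Type=String,Description=\"c\">",
    "##INFO=<ID=Gene_refGene,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=AF_gnomad,Number=1,Type=Float,Description=\"af\">",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"ann\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=FREQ,Number=1,Type=String,Description=\"fq\">",
    "##FILTER=<ID=lowqual,Description=\"x\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
           formats)
  )
  writeLines(c(hdr, lines), p)
  p
}

test_that("caller dialects populate VAF and depth; multi-allelics split", {
  p <- writeTestVcf(c(
    "1\t100\t.\tA\tT\t.\tPASS\tFunc_refGene=exonic;ExonicFunc_refGene=nonsynonymous_SNV\tGT:AD:DP\t0/1:180,20:200",
    "chr2\t55\t.\tC\tT,G\t.\tPASS\tFunc_refGene=exonic;ExonicFunc_refGene=nonsynonymous_SNV\tGT:AD:DP\t0/1:160,30,10:200",
    "3\t77\t.\tG\tA\t.\t.\tFunc_refGene=exonic;ExonicFunc_refGene=synonymous_SNV\tGT:AD:DP\t0/1:90,10:100"
  ))
  v <- readVariantVcf(p, caller = "mutect2", annotator = "annovar")
  expect_equal(nrow(v), 4L)  # one multi-allelic record split in two
  expect_equal(v$vaf[1], 20 / 200)
  expect_equal(v$depth[1], 200L)
  # split alleles share the summed-AD depth of the original record
  expect_equal(v$chrom[2:3], c("2", "2"))  # "chr" prefix stripped
  expect_equal(v$alt[2:3], c("T", "G"))
  expect_equal(v$vaf[2:3], c(30, 10) / 200)
  expect_equal(v$depth[2:3], c(200L, 200L))
  # missing FILTER value means not-PASS
  expect_equal(v$pass, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(variantKey(v$chrom, v$pos, v$ref, v$alt)[2:3],
               c("2:55:C>T", "2:55:C>G"))

  pv <- writeTestVcf(
    "1\t10\t.\tA\tG\t.\tPASS\tFunc_refGene=exonic;ExonicFunc_refGene=nonsynonymous_SNV\tGT:DP:FREQ\t0/1:250:12.5%"
  )
  w <- readVariantVcf(pv, caller = "varscan2", annotator = "annovar")
  expect_equal(w$vaf, 0.125)
  expect_equal(w$depth, 250L)
})

test_that("naming an absent genotype column lists the available ones", {
  p <- writeTestVcf(
    "1\t100\t.\tA\tT\t.\tPASS\tFunc_refGene=exonic\tGT:AD:DP\t0/1:180,20:200"
  )
  expect_error(readVariantVcf(p, tumorSample = "NORMAL"), "TUMOR")
})

test_that("annotation term tables map both dialects onto one vocabulary", {
  a <- parseAnnotation(list(Func_refGene = "exonic",
                            ExonicFunc_refGene = "synonymous_SNV"),
                       "annovar")
  expect_equal(c(a$region_class, a$consequence), c("exonic", "synonymous"))
  # any variant in an ANNOVAR "splicing" region is a splice-site event
  s <- parseAnnotation(list(Func_refGene = "splicing"), "annovar")
  expect_equal(c(s$region_class, s$consequence),
               c("splicing", "splice_site"))
  g <- parseAnnotation(list(ANN = "T|stop_gained|HIGH|TP53|TP53|t|t.1|pc|1/1|c.1A>T|||||||"),
                       "snpeff")
  expect_equal(c(g$region_class, g$consequence), c("exonic", "nonsense"))
  # unmappable terms degrade to unknown, never silently to a coding class
  u <- parseAnnotation(list(Func_refGene = "fancy_new_region"), "annovar")
  expect_equal(c(u$region_class, u$consequence), c("unknown", "unknown"))
  u2 <- parseAnnotation(list(ANN = "T|regulatory_region_variant|LOW|||||||||||||||"),
                        "snpeff")
  expect_equal(u2$consequence, "unknown")
  # population AFs and COSMIC ride along for either annotator
  pa <- parseAnnotation(list(Func_refGene = "exonic",
                             ExonicFunc_refGene = "stopgain",
                             AF_gnomad = 0.002, cosmic86 = "COSM123"),
                        "annovar")
  expect_equal(pa$af_gnomad, 0.002)
  expect_true(pa$cosmic_hit)
  expect_true(is.na(pa$af_1000g))
})

test_that("write/read round-trips a parsed cohort field-for-field", {
  sim <- simulateCohort(simConfig(seed = 11, nSamples = 2,
                                  samplesPerRun = 2, ffpeFraction = 1,
                                  annotator = "annovar"),
                        dir = withr::local_tempdir())
  for (ann in c("annovar", "snpeff")) {
    v <- readVariantVcf(sim$manifest$vcf[1], caller = "mutect2",
                        annotator = "annovar", sampleId = "S001")
    p <- withr::local_tempfile(fileext = ".vcf")
    writeVariantVcf(v, p, annotator = ann, tumorSample = "S001")
    v2 <- readVariantVcf(p, caller = "mutect2", annotator = ann,
                         sampleId = "S001")
    expect_equal(v2, v, ignore_attr = TRUE)
  }
  # varscan dialect round-trip
  v <- readVariantVcf(sim$manifest$vcf[2], caller = "mutect2",
                      annotator = "annovar", sampleId = "S002")
  v$caller <- "varscan2"
  p <- withr::local_tempfile(fileext = ".vcf")
  writeVariantVcf(v, p, tumorSample = "S002")
  v2 <- readVariantVcf(p, caller = "varscan2", sampleId = "S002")
  expect_equal(v2, v, ignore_attr = TRUE)
})

test_that("paired ANNOVAR and snpEff emissions are annotation-equivalent", {
  sim <- simulateCohort(simConfig(seed = 3, nSamples = 3,
                                  samplesPerRun = 3, annotator = "both"),
                        dir = withr::local_tempdir())
  for (i in seq_len(3)) {
    a <- readVariantVcf(sim$manifest$vcf[i], annotator = "annovar",
                        sampleId = sim$manifest$sample_id[i])
    s <- readVariantVcf(sub("\\.vcf$", ".snpeff.vcf",
                            sim$manifest$vcf[i]),
                        annotator = "snpeff",
                        sampleId = sim$manifest$sample_id[i])
    expect_equal(s$region_class, a$region_class)
    expect_equal(s$consequence, a$consequence)
    expect_equal(s$vaf, a$vaf)
  }
})
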