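test_that("built-in profiles encode the two algorithms' settings", {
  ic <- builtinProfile("IC")
  fo <- builtinProfile("FO")

  expect_equal(minVaf(ic), c(FFPE = 0.10, frozen = 0.05))
  expect_equal(minVaf(fo), c(FFPE = 0.05, frozen = 0.05))
  expect_equal(qualityPolicy(ic), "intra_run_recurrence")
  expect_equal(qualityPolicy(fo), "require_pass")
  expect_equal(recurrenceThreshold(ic), 0.15)
  expect_setequal(germlineDbs(ic), c("1000G", "gnomAD", "ExAC"))
  expect_setequal(germlineDbs(fo), c("1000G", "ExAC"))
  expect_false("gnomAD" %in% germlineDbs(fo))
  expect_equal(driverPolicy(ic), "include_cosmic")
  expect_equal(driverPolicy(fo), "exclude_cosmic")
  expect_false(classPolicy(ic)[["synonymous"]])
  expect_true(classPolicy(fo)[["synonymous"]])
  expect_false(classPolicy(ic)[["splice_site"]])
  expect_true(classPolicy(fo)[["splice_site"]])

  # shared settings are identical; the profiles differ exactly in the
  # fields above
  expect_equal(minDepth(ic), minDepth(fo))
  expect_equal(mafCutoff(ic), mafCutoff(fo))
  expect_equal(panelSizeMb(ic), panelSizeMb(fo))
  for (cls in c("missense", "nonsense", "frameshift_indel",
                "inframe_indel"))
    expect_true(classPolicy(ic)[[cls]] && classPolicy(fo)[[cls]])
  expect_false(classPolicy(ic)[["noncoding"]] ||
                 classPolicy(fo)[["noncoding"]])
  expect_false(classPolicy(ic)[["unknown"]] ||
                 classPolicy(fo)[["unknown"]])

  expect_error(builtinProfile("XYZ"), "IC, FO")
})

test_that("germline removal is strict in MAF and treats absence as absent", {
  ic <- builtinProfile("IC")
  fo <- builtinProfile("FO")
  v <- makeVariants(4,
    af_gnomad = c(0.002, 0.001, NA, 0.002),
    af_exac = c(NA, NA, NA, NA)
  )
  flags <- germlineFlag(v, ic)
  expect_true(flags[1])           # 0.2% > 0.1%: removed
  expect_false(flags[2])          # exactly at the bound: kept
  expect_false(flags[3])          # never observed anywhere: kept
  # FO does not consult gnomAD at all
  expect_false(any(germlineFlag(v, fo)))
  vExac <- makeVariants(1, af_exac = 0.05)
  expect_true(germlineFlag(vExac, fo))
})

test_that("intra-run recurrence is strict at the threshold", {
  ic <- builtinProfile("IC")
  run <- new("RunContext", runId = "r", sampleCount = 20L,
             presence = c("1:100:A>T" = 4L, "1:200:A>T" = 3L))
  expect_true(recurrenceFlag("1:100:A>T", run, ic))    # 20% > 15%
  expect_false(recurrenceFlag("1:200:A>T", run, ic))   # exactly 15%
  expect_false(recurrenceFlag("1:999:A>T", run, ic))   # unseen key
  # degenerate single-sample run: every variant is "recurrent"
  run1 <- new("RunContext", runId = "tiny", sampleCount = 1L,
              presence = c("1:100:A>T" = 1L))
  expect_warning(f <- recurrenceFlag("1:100:A>T", run1, ic), "tiny")
  expect_true(f)
})

test_that("VAF/depth thresholds are strict and preservation-aware", {
  ic <- builtinProfile("IC")
  v <- makeVariants(1, vaf = 0.09, depth = 500L)
  expect_false(vafDepthPass(v, "FFPE", ic))
  expect_true(vafDepthPass(v, "frozen", ic))
  expect_false(vafDepthPass(makeVariants(1, vaf = 0.5, depth = 100L),
                            "FFPE", ic))   # depth not > 100
  expect_false(vafDepthPass(makeVariants(1, vaf = 0.10, depth = 500L),
                            "FFPE", ic))   # VAF not > 10%
  # the non-strict switch turns the bounds inclusive
  icGe <- filterProfile("ICge", minVaf = c(FFPE = 0.10, frozen = 0.05),
                        strict = FALSE)
  expect_true(vafDepthPass(makeVariants(1, vaf = 0.10, depth = 100L),
                           "FFPE", icGe))
})

test_that("class policy and driver rule decide retention together", {
  ic <- builtinProfile("IC")
  fo <- builtinProfile("FO")
  syn <- makeVariants(1, consequence = "synonymous")
  expect_false(classPass(syn, ic))
  expect_true(classPass(syn, fo))
  hot <- makeVariants(1, consequence = "missense", cosmic_hit = TRUE)
  expect_false(classPass(hot, fo))   # COSMIC driver excluded under FO
  expect_true(classPass(hot, ic))    # hotspots kept under IC
  unk <- makeVariants(1, region_class = "unknown", consequence = "unknown")
  expect_false(classPass(unk, ic))
  expect_false(classPass(unk, fo))
  nc <- makeVariants(1, region_class = "intronic", consequence = "unknown")
  expect_false(classPass(nc, ic) || classPass(nc, fo))
  spl <- makeVariants(1, region_class = "splicing",
                      consequence = "splice_site")
  expect_false(classPass(spl, ic))
  expect_true(classPass(spl, fo))
})

test_that("applyProfile assembles consistent verdicts and attrition", {
  fo <- builtinProfile("FO")
  rep0 <- applyProfile(emptyVariantTable(), "FFPE", fo)
  expect_equal(nRetained(rep0), 0L)
  expect_equal(sum(attrition(rep0)), 0L)

  # ten variants failing only the germline stage
  v <- makeVariants(10, af_exac = 0.02)
  repG <- applyProfile(v, "FFPE", fo)
  expect_equal(nRetained(repG), 0L)
  expect_equal(unname(attrition(repG)[["germline"]]), 10L)
  expect_equal(sum(attrition(repG)), 10L)

  # first-fail attribution follows the fixed stage order
  v2 <- makeVariants(1, pass = FALSE, af_exac = 0.02, vaf = 0.01)
  r2 <- applyProfile(v2, "FFPE", fo)
  expect_equal(verdicts(r2)$first_fail, "quality")
  expect_true(validObject(r2))
})

test_that("cascade matches a naive per-variant reference on random cohorts", {
  ic <- builtinProfile("IC")
  fo <- builtinProfile("FO")
  for (seed in 1:30) {
    vs <- randomVariants(120, sampleIds = paste0("S", 1:8), seed = seed)
    run <- buildRunContext(vs, runId = "r1", sampleCount = 8L)
    prof <- if (seed %% 3 == 0) ic else if (seed %% 3 == 1) fo
            else randomProfile(seed)
    pres <- if (seed %% 2 == 0) "FFPE" else "frozen"
    for (s in unique(vs$sample_id)) {
      one <- vs[vs$sample_id == s, , drop = FALSE]
      got <- suppressWarnings(
        applyProfile(one, pres, prof, run = run))
      want <- naiveRetained(one, pres, prof, run = run)
      expect_equal(verdicts(got)$retained, want,
                   info = paste("seed", seed, "sample", s))
    }
  }
})

test_that("retention is invariant to row order and monotone in strictness", {
  ic <- builtinProfile("IC")
  for (seed in 1:10) {
    vs <- randomVariants(80, sampleIds = "S1", seed = seed)
    run <- buildRunContext(vs, runId = "r1", sampleCount = 10L)
    base <- applyProfile(vs, "FFPE", ic, run = run)
    perm <- sample(nrow(vs))
    shuffled <- applyProfile(vs[perm, , drop = FALSE], "FFPE", ic,
                             run = run)
    expect_equal(verdicts(shuffled)$retained,
                 verdicts(base)$retained[perm])

    # raising any threshold can only shrink the retained set
    stricter <- filterProfile("strict",
                              minVaf = c(FFPE = 0.20, frozen = 0.10),
                              minDepth = 300,
                              germlineDbs = c("1000G", "gnomAD", "ExAC"),
                              qualityPolicy = "both",
                              recurrenceThreshold = 0.05,
                              include = c("missense", "nonsense",
                                          "frameshift_indel",
                                          "inframe_indel"),
                              driverPolicy = "exclude_cosmic")
    tight <- applyProfile(vs, "FFPE", stricter, run = run)
    expect_true(all(verdicts(base)$retained |
                      !verdicts(tight)$retained))
    expect_lte(nRetained(tight), nRetained(base))
  }
})

test_that("profiles survive YAML serialization", {
  p <- withr::local_tempfile(fileext = ".yaml")
  ic <- builtinProfile("IC")
  writeFilterProfile(ic, p)
  back <- readFilterProfile(p)
  for (s in slotNames(ic))
    expect_equal(slot(back, s), slot(ic, s), info = s)
  expect_error(readFilterProfile("no/such/file.yaml"), "built-in")
})
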