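mkCohort <- function(tmb, tumor_type = "breast", preservation = "FFPE",
                     msi = "MSS", pole = "WT", contributive = TRUE) {
  n <- length(tmb)
  if (n == 0)
    return(data.frame(sample_id = character(), tumor_type = character(),
                      preservation = character(), msi_status = character(),
                      pole_status = character(), contributive = logical(),
                      profile = character(), n_retained = integer(),
                      tmb = numeric(), stringsAsFactors = FALSE))
  data.frame(
    sample_id = sprintf("C%03d", seq_len(n)), tumor_type = tumor_type,
    preservation = preservation, msi_status = msi, pole_status = pole,
    contributive = contributive, profile = "IC",
    n_retained = as.integer(round(tmb * 1.6)), tmb = tmb,
    stringsAsFactors = FALSE
  )
}

test_that("per-type summaries report median and observed range", {
  co <- mkCohort(c(5, 11, 276), tumor_type = "lymphoma")
  s <- summarizeByType(co)
  expect_equal(s$median_tmb, 11)
  expect_equal(c(s$min_tmb, s$max_tmb), c(5, 276))
  one <- summarizeByType(mkCohort(7.5, tumor_type = "lung"))
  expect_equal(one$median_tmb, 7.5)
  expect_equal(one$n, 1L)

  # stratification: MSI samples drop out of the MSS/POLE-WT summary
  co2 <- rbind(mkCohort(c(5, 9), tumor_type = "colorectal"),
               mkCohort(c(80, 95), tumor_type = "colorectal", msi = "MSI"))
  s2 <- summarizeByType(co2, msi = "MSS", pole = "WT")
  expect_equal(s2$n, 2L)
  expect_equal(s2$median_tmb, 7)
  # empty stratum is an empty summary, not an error
  expect_equal(nrow(summarizeByType(co2, msi = "nope")), 0L)
  # non-contributive samples are excluded by default
  co3 <- mkCohort(c(5, 500), contributive = c(TRUE, FALSE))
  expect_equal(summarizeByType(co3)$max_tmb, 5)
})

test_that("TMB bins are right-closed at 10 and partition the cohort", {
  co <- mkCohort(c(5, 10, 11, 150))
  b <- binCounts(co)
  ffpe <- b[b$preservation == "FFPE", ]
  expect_equal(ffpe$count, c(2L, 1L, 0L, 1L))
  expect_equal(sum(b$count), nrow(co))

  expect_equal(sum(binCounts(mkCohort(numeric(0)))$count), 0L)

  # counts match a brute-force histogram on a random cohort
  set.seed(42)
  tmb <- round(stats::rexp(200, 1 / 20), 2)
  pres <- sample(c("FFPE", "frozen"), 200, replace = TRUE)
  co2 <- mkCohort(tmb, preservation = pres)
  b2 <- binCounts(co2)
  for (p in c("FFPE", "frozen")) {
    x <- tmb[pres == p]
    want <- c(sum(x <= 10), sum(x > 10 & x <= 30),
              sum(x > 30 & x <= 100), sum(x > 100))
    expect_equal(b2$count[b2$preservation == p], want)
  }
  expect_equal(sum(b2$count), 200L)
  expect_error(binCounts(co, edges = c(30, 10)), "ascending")
})

test_that("top-decile threshold interpolates order statistics", {
  expect_equal(topDecileThreshold(1:10), 9.1)
  expect_equal(topDecileThreshold(rep(7.3, 12)), 7.3)
  expect_error(topDecileThreshold(1:9), "at least 10")
  set.seed(9)
  x <- stats::rlnorm(50, 2, 1)
  expect_equal(topDecileThreshold(sample(x)), topDecileThreshold(x))
  # adding a new maximum cannot lower the threshold
  expect_gte(topDecileThreshold(c(x, max(x) + 10)),
             topDecileThreshold(x))
})

test_that("curation rules classify TMB-high cases as printed", {
  feat <- function(score = 0, mmr = FALSE, msiSig = FALSE, pole = FALSE,
                   apobec = FALSE, id = "X1") {
    data.frame(sample_id = id, msi_sensor_score = score,
               mmr_pathogenic_variant = mmr, msi_signature = msiSig,
               pole_proofreading_mut = pole, apobec_signature = apobec,
               stringsAsFactors = FALSE)
  }
  # MSI-score bound is inclusive
  expect_equal(curateHighTmb(feat(score = 12))$category,
               "reclassified_msi_pole")
  expect_equal(curateHighTmb(feat(score = 10))$category,
               "reclassified_msi_pole")
  expect_equal(curateHighTmb(feat(score = 9.9))$category, "unexplained")
  for (flag in c("mmr", "msiSig", "pole", "apobec")) {
    f <- do.call(feat, stats::setNames(list(TRUE), flag))
    expect_equal(curateHighTmb(f)$category, "reclassified_msi_pole",
                 info = flag)
  }

  ddr <- function(vaf, patho = TRUE, gene = "TP53")
    data.frame(sample_id = "X1", gene = gene, vaf = vaf,
               pathogenic = patho, stringsAsFactors = FALSE)
  expect_equal(curateHighTmb(feat(), ddr(0.25))$category,
               "ddr_candidate_explained")
  # allelic-ratio bound is inclusive at 10%
  expect_equal(curateHighTmb(feat(), ddr(0.10))$category,
               "ddr_candidate_explained")
  expect_equal(curateHighTmb(feat(), ddr(0.09))$category, "unexplained")
  expect_equal(curateHighTmb(feat(), ddr(0.25, patho = FALSE))$category,
               "unexplained")
  # MSI/POLE evidence outranks a DDR hit
  both <- curateHighTmb(feat(score = 15), ddr(0.25))
  expect_equal(both$category, "reclassified_msi_pole")
  expect_match(both$evidence, "msi_sensor")

  expect_error(curateHighTmb(feat(), ddr(0.2, gene = "KRAS")),
               "TP53/PTEN/ARID1A")
  expect_error(curateHighTmb(feat()[, -2]), "missing columns")

  # every sample gets exactly one category; counts sum to n
  set.seed(1)
  n <- 40
  fs <- data.frame(
    sample_id = sprintf("M%02d", 1:n),
    msi_sensor_score = sample(c(0, 5, 12), n, replace = TRUE),
    mmr_pathogenic_variant = sample(c(TRUE, FALSE), n, TRUE),
    msi_signature = FALSE, pole_proofreading_mut = FALSE,
    apobec_signature = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE
  )
  v <- curateHighTmb(fs)
  expect_equal(nrow(v), n)
  expect_equal(sum(table(v$category)), n)
  expect_true(all(v$category %in% c("reclassified_msi_pole",
                                    "ddr_candidate_explained",
                                    "unexplained")))
})

test_that("cohortTable joins metadata with results one row per sample", {
  fo <- builtinProfile("FO")
  res <- lapply(c("A1", "A2"), function(s) {
    v <- makeVariants(8, sample_id = s)
    computeTMB(applyProfile(v, "frozen", fo), fo)
  })
  meta <- data.frame(sample_id = c("A1", "A2"),
                     tumor_type = "lung", preservation = "frozen",
                     stringsAsFactors = FALSE)
  co <- cohortTable(meta, res)
  expect_equal(nrow(co), 2L)
  expect_equal(co$tmb, rep(8 / 1.6, 2))
  expect_error(cohortTable(meta, c(res, res[1])), "one row per sample")
})
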