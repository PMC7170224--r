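test_that("design files round-trip losslessly and toy designs parse", {
  d <- toyDesign()
  expect_equal(nrow(targetInfo(d)), 2)
  expect_equal(nrow(strainCatalog(d)), 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDesign(d, f)
  d2 <- readDesign(f)
  expect_equal(probeInfo(d2)[order(probeInfo(d2)$probe_id), ],
               probeInfo(d)[order(probeInfo(d)$probe_id), ],
               ignore_attr = TRUE)
  expect_equal(strainCatalog(d2), strainCatalog(d))
  expect_equal(sort(controlInfo(d2)$probe_id), sort(controlInfo(d)$probe_id))

  # a simulated design also survives the round trip
  ds <- simulateDesign(2, 2, c(3, 4), c(2, 2), seed = 5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeDesign(ds, f2)
  ds2 <- readDesign(f2)
  expect_equal(strainCatalog(ds2), strainCatalog(ds))
  expect_equal(sort(probeInfo(ds2)$probe_id), sort(probeInfo(ds)$probe_id))
})

test_that("malformed design files are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # probe mapped to a target with no annotation row: integrity error
  writeLines(c(
    "probe_id\ttarget_id\tgene_symbol\tprocess_label\tstrain_id\tphylogroup_id\tcontrol_role",
    "p1\tt1\tntcA\tN\ts1\tPro\t",
    "p2\t\t\t\t\t\t"), f)
  expect_error(readDesign(f), "target_id")
  # missing column
  writeLines(c("probe_id\ttarget_id", "p1\tt1"), f)
  expect_error(readDesign(f), "missing column")
  # duplicate probe ids
  writeLines(c(
    "probe_id\ttarget_id\tgene_symbol\tprocess_label\tstrain_id\tphylogroup_id\tcontrol_role",
    "p1\tt1\tntcA\tN\ts1\tPro\t",
    "p1\tt1\tntcA\tN\ts1\tPro\t"), f)
  expect_error(readDesign(f), "duplicate")
})

test_that("design invariants are enforced at construction", {
  expect_error(ArrayDesign(
    probes = data.frame(probe_id = "p1", target_id = "missing"),
    targets = toyDesign()@targets), "absent")
  # one strain in two phylogroups
  tg <- targetInfo(toyDesign())
  tg$strain_id <- "s1"
  expect_error(ArrayDesign(probes = probeInfo(toyDesign()), targets = tg),
               "phylogroup")
  # control probe that also maps to a target
  expect_error(ArrayDesign(
    probes = probeInfo(toyDesign()), targets = targetInfo(toyDesign()),
    controls = data.frame(probe_id = "p1", control_role = "negative")),
    "no target")
})

test_that("intensity reading enforces positivity and drops unknown probes", {
  d <- toyDesign()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "p1\t10\t20", "p2\t30\t40"), f)
  m <- readIntensities(f, d)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["p1", "s2"], 20)

  writeLines(c("probe_id\ts1\ts2", "p1\t0\t20", "p2\t30\t40"), f)
  expect_error(readIntensities(f, d), "positive")
  writeLines(c("probe_id\ts1\ts2", "p1\tx\t20", "p2\t30\t40"), f)
  expect_error(readIntensities(f, d))

  writeLines(c("probe_id\ts1\ts2", "p1\t10\t20", "zzz\t30\t40"), f)
  expect_message(m2 <- readIntensities(f, d), "dropped")
  expect_equal(rownames(m2), "p1")

  # write -> read round trip
  m3 <- matrix(c(1.5, 2.5, 3.5, 4.5), 2,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeIntensities(m3, f3)
  expect_equal(readIntensities(f3, d), m3)
})

test_that("sample sheets are validated", {
  good <- data.frame(
    sample_id = c("a1", "a2", "b1", "b2", "c1", "c2"),
    timepoint = c("T0", "T0", "T24", "T24", "T24", "T24"),
    treatment = c("control", "control", "control", "control", "urea",
                  "urea"),
    replicate_index = c(1, 2, 1, 2, 1, 2))
  sh <- sampleSheet(good)
  expect_s3_class(sh, "data.frame")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSampleSheet(sh, f)
  expect_equal(readSampleSheet(f), sh, ignore_attr = TRUE)

  bad <- good
  bad$treatment[5:6] <- c("urea", "NO3")  # singleton groups
  expect_error(sampleSheet(bad), ">= 2 samples")
  bad2 <- good[good$timepoint != "T0", ]
  expect_error(sampleSheet(bad2), "T0")
  bad3 <- good
  bad3$treatment[5] <- "sugar"
  expect_error(sampleSheet(bad3), "unknown treatment")
})

test_that("GEO series-matrix fixtures parse, including the title grammar", {
  m <- matrix(c(7.1, 8.2, 6.5, 7.7, 7.0, 8.1), 3,
              dimnames = list(c("t1", "t2", "t3"), NULL))
  titles <- c("T24 urea rep1", "T0 control rep2")
  f <- withr::local_tempfile(fileext = ".txt")
  writeToySeriesMatrix(f, m, titles)
  got <- suppressMessages(readGEOSeriesMatrix(f))
  expect_equal(dim(got$matrix), c(3L, 2L))
  expect_equal(got$sheet$treatment, c("urea", "control"))
  expect_equal(got$sheet$timepoint, c("T24", "T0"))
  expect_equal(got$sheet$replicate_index, c(1L, 2L))
  expect_equal(got$level, "processed")

  # N+Fe must not be read as Fe
  got2 <- local({
    f2 <- withr::local_tempfile(fileext = ".txt")
    writeToySeriesMatrix(f2, m[, c(1, 2)],
                         c("T24 N+Fe rep1", "T24 Fe rep1"))
    suppressMessages(readGEOSeriesMatrix(f2))
  })
  expect_equal(got2$sheet$treatment, c("NplusFe", "Fe"))

  # missing table delimiter is a format error
  lines <- readLines(f)
  writeLines(lines[!grepl("table_begin", lines)], f)
  expect_error(readGEOSeriesMatrix(f), "series_matrix_table")

  # unparseable titles are an error, not a guess
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeToySeriesMatrix(f3, m[, c(1, 2)], c("T24 urea rep1", "mystery"))
  expect_error(suppressMessages(readGEOSeriesMatrix(f3)), "could not parse")
})

test_that("configuration defaults, file round trip and overrides work", {
  cfg <- analysisConfig()
  expect_equal(cfg$fc_threshold, 1.2)
  expect_equal(cfg$alpha_gene, 0.05)
  expect_equal(cfg$alpha_set, 0.01)
  expect_equal(cfg$wilkinson_r, 2)
  expect_equal(cfg$detection_k, 2)

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fc_threshold: 1.5", "rng_seed: 99"), f)
  cfg2 <- readConfig(f)
  expect_equal(cfg2$fc_threshold, 1.5)
  expect_equal(cfg2$rng_seed, 99L)
  expect_equal(cfg2$alpha_set, 0.01)
  cfg3 <- readConfig(f, fc_threshold = 2)  # flag beats file
  expect_equal(cfg3$fc_threshold, 2)
  writeLines("not_a_key: 1", f)
  expect_error(readConfig(f), "unknown config key")
  expect_error(analysisConfig(fc_threshold = 0.5))
  expect_error(analysisConfig(alpha_gene = 1.5))
})
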