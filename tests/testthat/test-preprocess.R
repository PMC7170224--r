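test_that("probe summarization matches log2 identities and median polish", {
  # single-probe target: plain log2
  d <- ArrayDesign(
    probes = data.frame(probe_id = c("p1", "q1", "q2", "q3"),
                        target_id = c("t1", "t2", "t2", "t2")),
    targets = data.frame(target_id = c("t1", "t2"),
                         gene_symbol = c("ntcA", "rbcL"),
                         process_label = "x", strain_id = c("s1", "s2"),
                         phylogroup_id = c("A", "B")))
  raw <- matrix(2^c(10, 3, 4, 5,
                    5, 6, 7, 8,
                    6, 7, 8.5, 9), 4, byrow = FALSE,
                dimnames = list(c("p1", "q1", "q2", "q3"),
                                c("s1", "s2", "s3")))
  raw[1, 1] <- 1024
  got <- summarizeProbes(raw, d)
  expect_equal(got["t1", "s1"], 10)

  # identical probe rows collapse to their shared log2 profile
  v <- c(8, 9, 10)
  raw2 <- rbind(q1 = 2^v, q2 = 2^v)
  colnames(raw2) <- c("s1", "s2", "s3")
  d2 <- ArrayDesign(
    probes = data.frame(probe_id = c("q1", "q2"), target_id = "t"),
    targets = data.frame(target_id = "t", gene_symbol = "rbcL",
                         process_label = "x", strain_id = "s",
                         phylogroup_id = "A"))
  expect_equal(unname(summarizeProbes(raw2, d2)["t", ]), v)

  # 3 probes x 3 samples against the iterative median-polish oracle
  set.seed(31)
  m <- matrix(rnorm(9, 10, 1), 3,
              dimnames = list(c("q1", "q2", "q3"),
                              c("s1", "s2", "s3")))
  d3 <- ArrayDesign(
    probes = data.frame(probe_id = c("q1", "q2", "q3"), target_id = "t"),
    targets = data.frame(target_id = "t", gene_symbol = "rbcL",
                         process_label = "x", strain_id = "s",
                         phylogroup_id = "A"))
  expected <- oracleMedianPolish(m)$summary
  expect_equal(unname(summarizeProbes(2^m, d3)["t", ]),
               unname(expected), tolerance = 1e-7)

  # invariance to probe row order
  perm <- c("q3", "q1", "q2")
  expect_equal(summarizeProbes(2^m, d3), summarizeProbes(2^m[perm, ], d3))

  # target with no probe data is flagged and dropped
  expect_message(s4 <- summarizeProbes(raw[c("q1", "q2", "q3"), ], d),
                 "no probes with data")
  expect_false("t1" %in% rownames(s4))
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  got <- quantileNormalize(m)
  expect_equal(unname(got[, "a"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(got[, "b"]), c(2.5, 3.5, 4.5))

  # identical columns are a fixed point
  m2 <- cbind(a = c(5, 1, 3), b = c(5, 1, 3))
  expect_equal(quantileNormalize(m2), m2)

  set.seed(8)
  m3 <- matrix(rnorm(200), 50, 4)
  got3 <- quantileNormalize(m3)
  # all columns share one sorted multiset and one mean
  ref <- sort(got3[, 1])
  for (j in 2:4) expect_equal(sort(got3[, j]), ref)
  expect_equal(colMeans(got3), rep(mean(ref), 4), ignore_attr = TRUE)
  # within-column ranks are preserved
  for (j in 1:4) expect_equal(rank(got3[, j]), rank(m3[, j]))

  expect_warning(quantileNormalize(m3[, 1, drop = FALSE]), "fewer than 2")
  expect_error(quantileNormalize(matrix(c(1, NA), 1)), "missing")
})

test_that("detection calling applies the strict mean + k*sd rule", {
  d <- toyDesign()
  ctrl_log2 <- c(5.5, 6.5, 5.5, 6.5)  # mean 6, sd ~0.577
  raw <- rbind(matrix(2^10, 3, 2,
                      dimnames = list(c("p1", "p2", "p3"), c("s1", "s2"))),
               matrix(2^ctrl_log2, 4, 2, byrow = FALSE,
                      dimnames = list(sprintf("NEG_%02d", 1:4),
                                      c("s1", "s2"))))
  thr <- 6 + 2 * sd(ctrl_log2)
  m <- matrix(c(thr + 0.5, thr, thr - 0.5, thr + 0.1, thr, thr - 0.1),
              3, 2, dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  flags <- callDetection(m, raw, d, k = 2)
  expect_identical(unname(flags[, "s1"]), c(TRUE, FALSE, FALSE))
  expect_identical(unname(flags[, "s2"]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(attr(flags, "thresholds")), rep(thr, 2))

  d_noctrl <- ArrayDesign(probes = probeInfo(d), targets = targetInfo(d))
  expect_error(callDetection(m, raw, d_noctrl, k = 2),
               "negative-control")
})

test_that("detection calls agree with ground truth on the seeded fixture", {
  fx <- defaultFixture()
  flags <- detected(fx$pas)
  truth <- fx$sim$truth$cell_presence[rownames(flags), colnames(flags)]
  expect_gte(mean(flags == truth), 0.99)
})

test_that("the preprocessing pipeline recovers balanced implanted effects
           with small bias", {
  design <- simulateDesign(seed = 7)
  bal <- truthConfig(set_effects = data.frame(
    phylogroup = c("HLPro", "Syn"), response_label = "N stress",
    treatment = "urea", lfc = c(-0.6, 0.6)), seed = 7)
  sim <- simulateExperiment(design, bal)
  pas <- suppressMessages(preprocessExperiment(
    sim$intensities, design, sim$sheet, analysisConfig(rng_seed = 7)))
  v <- log2Values(pas)
  sheet <- sim$sheet
  eff <- sim$truth$effects
  ctl <- sheet$sample_id[sheet$timepoint == "T24" &
                         sheet$treatment == "control"]
  smp <- sheet$sample_id[sheet$treatment == "urea"]
  aff <- rownames(eff)[eff[, "T24.urea"] != 0]
  aff <- aff[rowSums(sim$truth$cell_presence[aff, c(smp, ctl)]) ==
             length(c(smp, ctl))]
  est <- rowMeans(v[aff, smp]) - rowMeans(v[aff, ctl])
  expect_lt(abs(mean(est - eff[aff, "T24.urea"])), 0.05)
})

test_that("preprocessExperiment assembles a valid PhytoArraySet", {
  fx <- defaultFixture()
  pas <- fx$pas
  expect_s4_class(pas, "PhytoArraySet")
  expect_true(all(c("log2", "detected") %in%
                  SummarizedExperiment::assayNames(pas)))
  expect_equal(ncol(pas), 23L)
  expect_true(is.logical(detected(pas)))
  prov <- S4Vectors::metadata(pas)$provenance
  expect_equal(prov$normalize_level, "target")
  expect_length(prov$detection_thresholds, 23L)
})
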