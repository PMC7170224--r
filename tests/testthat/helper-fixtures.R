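# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# a tiny hand-written design: 3 annotated probes over 2 targets/strains
# plus a roster of negative controls
toyDesign <- function() {
  ArrayDesign(
    probes = data.frame(probe_id = c("p1", "p2", "p3"),
                        target_id = c("t1", "t1", "t2")),
    targets = data.frame(
      target_id = c("t1", "t2"),
      gene_symbol = c("ntcA", "rbcL"),
      process_label = c("N stress", "RuBisCO"),
      strain_id = c("s1", "s2"),
      phylogroup_id = c("Pro", "Syn"),
      stringsAsFactors = FALSE),
    controls = data.frame(probe_id = sprintf("NEG_%02d", 1:4),
                          control_role = "negative"))
}

# build a PhytoArraySet directly from a log2 matrix for DE-level tests
exprSet <- function(v, detected = NULL, treatments = NULL,
                    timepoints = "T24", ann = NULL) {
  if (is.null(detected))
    detected <- matrix(TRUE, nrow(v), ncol(v), dimnames = dimnames(v))
  cd <- data.frame(sample_id = colnames(v),
                   timepoint = rep(timepoints, length.out = ncol(v)),
                   treatment = treatments,
                   replicate_index = seq_len(ncol(v)),
                   stringsAsFactors = FALSE)
  if (is.null(ann))
    ann <- data.frame(target_id = rownames(v), row.names = rownames(v),
                      stringsAsFactors = FALSE)
  PhytoArraySet(log2 = v, detected = detected, rowData = ann, colData = cd)
}

# the default synthetic study fixture at seed 7, preprocessed once
defaultFixture <- function() {
  if (is.null(.fixtures$default)) {
    cfg <- analysisConfig(rng_seed = 7)
    design <- simulateDesign(seed = 7)
    sim <- simulateExperiment(design, defaultTruthConfig(seed = 7))
    pas <- suppressMessages(
      preprocessExperiment(sim$intensities, design, sim$sheet, cfg))
    .fixtures$default <- list(cfg = cfg, design = design, sim = sim,
                              pas = pas)
  }
  .fixtures$default
}

# differential expression and set results on the default fixture
defaultFixtureResults <- function() {
  if (is.null(.fixtures$default_results)) {
    fx <- defaultFixture()
    de <- fitAllContrasts(fx$pas, fx$cfg)
    sets <- buildGeneSets(fx$design)
    set_results <- suppressMessages(testGeneSets(de, sets, fx$cfg))
    .fixtures$default_results <- list(de = de, sets = sets,
                                      set_results = set_results)
  }
  .fixtures$default_results
}

# a minimal GEO series-matrix text fixture (synthetic)
writeToySeriesMatrix <- function(path, m, titles) {
  stopifnot(ncol(m) == length(titles))
  accs <- sprintf("GSM%04d", seq_len(ncol(m)))
  lines <- c(
    "!Series_title\t\"synthetic incubation experiment\"",
    paste0("!Sample_title\t",
           paste(sprintf('"%s"', titles), collapse = "\t")),
    paste0("!Sample_geo_accession\t",
           paste(sprintf('"%s"', accs), collapse = "\t")),
    paste0("!Sample_data_processing\t",
           paste(rep('"quantile normalized log2"', ncol(m)),
                 collapse = "\t")),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf('"%s"', accs)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i)
      paste(c(sprintf('"%s"', rownames(m)[i]),
              format(m[i, ], digits = 10)), collapse = "\t"), ""),
    "!series_matrix_table_end")
  writeLines(lines, path)
  invisible(path)
}
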