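## File readers and writers. Dialect everywhere: UTF-8 tab-delimited,
## one header row, '#' comment lines allowed.

.readTSV <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and write an array design
#'
#' The design file is a single tab-delimited table with one row per probe.
#' Annotated probes carry their target, gene, strain and phylogroup
#' columns; control probes have an empty \code{target_id} and a
#' \code{control_role} of \code{"negative"} or \code{"spike_in"}.
#'
#' @param path file path.
#' @return \code{readDesign}: a validated [ArrayDesign].
#' @examples
#' d <- simulateDesign(2, 2, c(3, 4), c(2, 2), seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' writeDesign(d, f)
#' d2 <- readDesign(f)
#' identical(strainCatalog(d), strainCatalog(d2))
#' @export
readDesign <- function(path) {
  df <- .readTSV(path)
  need <- c("probe_id", "target_id", "gene_symbol", "process_label",
            "strain_id", "phylogroup_id", "control_role")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("design file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe ids in design file")
  is_ctrl <- !is.na(df$control_role) & nzchar(df$control_role)
  ctrl <- data.frame(probe_id = df$probe_id[is_ctrl],
                     control_role = df$control_role[is_ctrl],
                     stringsAsFactors = FALSE)
  ann <- df[!is_ctrl, , drop = FALSE]
  if (any(is.na(ann$target_id) | !nzchar(ann$target_id)))
    stop("annotated probe without a target_id")
  probes <- ann[, c("probe_id", "target_id")]
  tcols <- c("target_id", "gene_symbol", "process_label", "strain_id",
             "phylogroup_id")
  if ("ecotype_label" %in% names(ann)) tcols <- c(tcols, "ecotype_label")
  targets <- unique(ann[, tcols, drop = FALSE])
  if (anyDuplicated(targets$target_id))
    stop("inconsistent annotation: a target_id has conflicting annotation rows")
  ArrayDesign(probes = probes, targets = targets, controls = ctrl)
}

#' @param design an [ArrayDesign].
#' @rdname readDesign
#' @export
writeDesign <- function(design, path) {
  tg <- targetInfo(design)
  pr <- probeInfo(design)
  ann <- merge(pr, tg, by = "target_id", sort = FALSE)
  ann <- ann[, c("probe_id", "target_id", "gene_symbol", "process_label",
                 "strain_id", "phylogroup_id", "ecotype_label")]
  ann$control_role <- ""
  ct <- controlInfo(design)
  if (nrow(ct)) {
    ctrl <- data.frame(probe_id = ct$probe_id, target_id = "",
                       gene_symbol = "", process_label = "", strain_id = "",
                       phylogroup_id = "", ecotype_label = "",
                       control_role = ct$control_role,
                       stringsAsFactors = FALSE)
    ann$ecotype_label[is.na(ann$ecotype_label)] <- ""
    ann <- rbind(ann, ctrl)
  } else {
    ann$ecotype_label[is.na(ann$ecotype_label)] <- ""
  }
  ann <- ann[order(ann$probe_id), , drop = FALSE]
  .writeTSV(ann, path)
}

.treatments <- c("control", "NO3", "NH4", "urea", "Fe", "NplusFe", "FDW")

#' Validate a sample sheet
#'
#' The sheet names the experimental layout: one T0 control group and up
#' to seven T24 condition groups, each with at least two replicates.
#'
#' @param df data.frame with columns \code{sample_id}, \code{timepoint}
#'   (\code{"T0"} or \code{"T24"}), \code{treatment} (one of control,
#'   NO3, NH4, urea, Fe, NplusFe, FDW) and \code{replicate_index}.
#' @return The validated data.frame.
#' @export
sampleSheet <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("sample_id", "timepoint", "treatment", "replicate_index")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (!all(df$timepoint %in% c("T0", "T24")))
    stop("timepoint must be T0 or T24")
  if (!all(df$treatment %in% .treatments))
    stop("unknown treatment(s): ",
         paste(setdiff(df$treatment, .treatments), collapse = ", "))
  grp <- table(paste(df$timepoint, df$treatment))
  if (any(grp < 2))
    stop("each (timepoint, treatment) group needs >= 2 samples; short: ",
         paste(names(grp)[grp < 2], collapse = ", "))
  has_ctrl <- c("T0", "T24") %in% df$timepoint[df$treatment == "control"]
  if (!all(has_ctrl))
    stop("controls are required at both T0 and T24")
  df$replicate_index <- as.integer(df$replicate_index)
  rownames(df) <- df$sample_id
  df
}

#' @rdname sampleSheet
#' @param path file path.
#' @export
readSampleSheet <- function(path) sampleSheet(.readTSV(path))

#' @rdname sampleSheet
#' @param sheet a validated sample sheet.
#' @export
writeSampleSheet <- function(sheet, path) {
  .writeTSV(sheet, path)
}

#' Read a probe-level intensity matrix
#'
#' @param path tab-delimited file; first column probe ids, remaining
#'   columns one per sample, strictly positive numeric intensities.
#' @param design [ArrayDesign] used to check probe ids; probes absent
#'   from the design (annotated or control) are dropped with a message.
#' @return numeric matrix (probes x samples).
#' @export
readIntensities <- function(path, design = NULL) {
  df <- .readTSV(path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric intensity cell(s)")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (any(!is.finite(m)) || any(m <= 0))
    stop("intensities must be finite and strictly positive")
  if (!is.null(design)) {
    known <- c(probeInfo(design)$probe_id, controlInfo(design)$probe_id)
    unknown <- setdiff(ids, known)
    if (length(unknown)) {
      message(length(unknown),
              " probe(s) absent from the design were dropped")
      m <- m[!(ids %in% unknown), , drop = FALSE]
    }
  }
  m
}

#' @rdname readIntensities
#' @param m probe x sample intensity matrix.
#' @export
writeIntensities <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, path)
}

## --- GEO series matrix -----------------------------------------------

## Regex table mapping sample title/characteristics text to the sample
## sheet vocabulary. Order matters: N+Fe must match before Fe.
.geoTreatmentPatterns <- list(
  NplusFe = "N\\s*\\+\\s*Fe|NplusFe|N_Fe",
  control = "control|ctrl",
  NO3 = "NO3|nitrate",
  NH4 = "NH4|ammonium",
  urea = "urea",
  FDW = "FDW|deep\\s*water",
  Fe = "\\bFe\\b|iron"
)

.parseGeoSampleMeta <- function(titles, sample_ids) {
  n <- length(titles)
  timepoint <- ifelse(grepl("\\bT0\\b", titles), "T0",
                      ifelse(grepl("\\bT24\\b", titles), "T24", NA))
  treatment <- rep(NA_character_, n)
  for (tr in names(.geoTreatmentPatterns)) {
    hit <- is.na(treatment) &
      grepl(.geoTreatmentPatterns[[tr]], titles, ignore.case = TRUE)
    treatment[hit] <- tr
  }
  bad <- is.na(timepoint) | is.na(treatment)
  if (any(bad))
    stop("could not parse timepoint/treatment from sample title(s): ",
         paste(titles[bad], collapse = "; "))
  rep_idx <- suppressWarnings(
    as.integer(sub(".*rep(?:licate)?[ _]?([0-9]+).*", "\\1", titles,
                   ignore.case = TRUE)))
  # titles without an explicit replicate number: enumerate within group
  grp <- paste(timepoint, treatment)
  for (g in unique(grp)) {
    i <- which(grp == g)
    if (anyNA(rep_idx[i])) rep_idx[i] <- seq_along(i)
  }
  # vocabulary is enforced here; the full experimental-layout invariants
  # (replicate counts, controls at both timepoints) are checked by
  # sampleSheet() when the sheet enters an analysis, so that partial
  # series can still be inspected
  out <- data.frame(sample_id = sample_ids, timepoint = timepoint,
                    treatment = treatment,
                    replicate_index = as.integer(rep_idx),
                    stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  out
}

#' Read a GEO series-matrix file
#'
#' Parses the line-oriented series-matrix text format: \code{!Sample_*}
#' metadata lines followed by a numeric table delimited by
#' \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}.
#' Timepoint and treatment are extracted from the sample titles by a
#' fixed regex table; a title that matches neither is an error rather
#' than a guess. Whether the table holds raw or processed intensities is
#' recorded (from the \code{!Sample_data_processing} lines) but not
#' re-inferred.
#'
#' @param path path to an (uncompressed) series-matrix file.
#' @return list with elements \code{matrix} (numeric, rows = table ids),
#'   \code{sheet} (sample metadata in sample-sheet form; vocabulary is
#'   enforced here, full layout invariants when the sheet enters an
#'   analysis) and \code{level} (\code{"processed"} or \code{"raw"}).
#' @export
readGEOSeriesMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("malformed series matrix: missing or empty ",
         "!series_matrix_table_begin/!series_matrix_table_end block")
  .fields <- function(key) {
    ln <- grep(paste0("^!", key, "\\b"), lines, value = TRUE)
    if (!length(ln)) return(character(0))
    parts <- strsplit(ln[1], "\t", fixed = TRUE)[[1]][-1]
    gsub('^"|"$', "", parts)
  }
  titles <- .fields("Sample_title")
  accs <- .fields("Sample_geo_accession")
  tab <- utils::read.delim(text = lines[(beg + 1L):(end - 1L)],
                           header = TRUE, sep = "\t", quote = '"',
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  sample_ids <- if (length(accs) == ncol(m)) accs else colnames(m)
  colnames(m) <- sample_ids
  if (length(titles) != ncol(m))
    stop("malformed series matrix: ", length(titles), " sample titles for ",
         ncol(m), " matrix columns")
  sheet <- .parseGeoSampleMeta(titles, sample_ids)
  proc <- .fields("Sample_data_processing")
  level <- if (length(proc) &&
               any(grepl("normal|process", proc, ignore.case = TRUE)))
    "processed" else "raw"
  message("read series matrix: ", nrow(m), " rows x ", ncol(m),
          " samples (", level, " level)")
  list(matrix = m, sheet = sheet, level = level)
}

#' Write a numeric matrix as a TSV with an id column
#'
#' @param m matrix with row names.
#' @param path file path.
#' @param id_name header for the row-id column.
#' @export
writeMatrixTSV <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  .writeTSV(df, path)
}
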