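#' Read and write the screen's tabular interchange formats
#'
#' Plain TSV files key everything: the sample manifest (sample_id, mutant,
#' condition, bio_replicate, day_replicate, batch, run_order, od595), the
#' intensity table (first column sample_id, remaining columns one per ion
#' named by m/z), the two-column pathway map (pathway_id, metabolite_id)
#' and the JSON ground-truth ledger.
#'
#' @param path file path.
#' @name screen-io
NULL

#' @rdname screen-io
#' @export
readSampleManifest <- function(path) {
  man <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", MANIFEST_COLS), colnames(man))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  man
}

#' @rdname screen-io
#' @param manifest a sample manifest data.frame.
#' @export
writeSampleManifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname screen-io
#' @param manifestPath optional manifest TSV to attach as colData; when
#'   given, a \linkS4class{MetaboSet} is returned instead of a matrix.
#' @export
readIntensityTable <- function(path, manifestPath = NULL) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(tab)[1] != "sample_id")
    stop("intensity table must have 'sample_id' as its first column")
  ids <- tab$sample_id
  m <- t(as.matrix(tab[, -1, drop = FALSE]))  # ions x samples
  colnames(m) <- ids
  mz <- as.numeric(rownames(m))
  rownames(m) <- sprintf("ion%04d", seq_len(nrow(m)))
  if (is.null(manifestPath)) return(list(intensity = m, mz = mz))
  man <- readSampleManifest(manifestPath)
  man <- man[match(ids, man$sample_id), ]
  if (any(is.na(man$sample_id)))
    stop("manifest does not cover all samples in the intensity table")
  MetaboSet(m, man, mz = mz)
}

#' @rdname screen-io
#' @param mset a \linkS4class{MetaboSet}; raw intensities are written as
#'   samples x ions with m/z column headers.
#' @export
writeIntensityTable <- function(mset, path) {
  m <- t(intensities(mset))
  colnames(m) <- sprintf("%.4f", ionMz(mset))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen-io
#' @export
readPathways <- function(path) {
  pw <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "metabolite_id") %in% colnames(pw)))
    stop("pathway map needs columns pathway_id, metabolite_id")
  pw
}

#' @rdname screen-io
#' @param pathways two-column pathway map data.frame.
#' @export
writePathways <- function(pathways, path) {
  write.table(pathways[, c("pathway_id", "metabolite_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname screen-io
#' @param truth a \linkS4class{GroundTruth}.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    spikes = truth@spikes,
    baselines = as.list(truth@baselines),
    odExponents = as.list(truth@odExponents),
    drift = truth@drift,
    driftAmplitude = truth@driftAmplitude,
    noiseSigma = truth@noiseSigma,
    growth = truth@growth,
    seed = truth@seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname screen-io
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- as.data.frame(x$spikes)
  if (!nrow(sp))
    sp <- data.frame(mutant = character(), condition = character(),
                     ion = character(), log2_effect = numeric())
  new("GroundTruth", spikes = sp,
      baselines = unlist(x$baselines),
      odExponents = unlist(x$odExponents),
      drift = lapply(x$drift, function(co) setNames(unlist(co),
                                                    c("a", "b"))),
      driftAmplitude = x$driftAmplitude, noiseSigma = x$noiseSigma,
      growth = as.data.frame(x$growth), seed = as.integer(x$seed))
}

#' Write the report bundle of a screen
#'
#' Emits the long-format differential table (mutant, condition, ion_mz,
#' median_log2fc, p, q, significant), enrichment table, the two
#' correlation tables, the ranked score table (TSV and JSON) and, when
#' present, the growth table, into a directory.
#'
#' @param report a `ScreenReport` from [runScreen()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeReportBundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$differential[, c("mutant", "condition", "ion_mz",
                             "median_log2fc", "p", "q", "significant")],
     "differential.tsv")
  if (!is.null(report$enrichment)) wr(report$enrichment, "enrichment.tsv")
  wr(report$correlations$pairs, "correlation_pairs.tsv")
  wr(report$correlations$self[, setdiff(colnames(report$correlations$self),
                                        "flag")], "correlation_self.tsv")
  wr(report$scores, "scores.tsv")
  if (!is.null(report$growth)) wr(report$growth$tests, "growth.tsv")
  jp <- file.path(dir, "scores.json")
  jsonlite::write_json(report$scores, jp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, jp)
  invisible(paths)
}
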