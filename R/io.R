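#' Read and write time-course matrices as delimited text
#'
#' Matrices are stored samples x nodes with a header row of node labels.
#' Comma- and tab-delimited files are both accepted on read (chosen by file
#' extension: `.tsv`/`.txt` means tab); writes are CSV. As a binary
#' container option, paths ending in `.rds` are read and written with R's
#' native serialisation, preserving the full object (sampling rate
#' included) at double precision.
#'
#' @param path file path.
#' @param samplingRate sampling rate (Hz) to attach to the read object
#'   (ignored for `.rds`, which stores it).
#' @return `readTimecourses` returns a [Timecourses-class];
#'   `writeTimecourses` invisibly returns `path`.
#' @export
readTimecourses <- function(path, samplingRate) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    stopifnot(is(obj, "Timecourses") || is(obj, "EnvelopeMatrix"))
    return(obj)
  }
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE)
  Timecourses(as.matrix(df), samplingRate = samplingRate,
              nodeLabels = colnames(df))
}

#' @rdname readTimecourses
#' @param ts a [Timecourses-class] or [EnvelopeMatrix-class] object.
#' @export
writeTimecourses <- function(ts, path) {
  stopifnot(is(ts, "Timecourses") || is(ts, "EnvelopeMatrix"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(ts, path)
    return(invisible(path))
  }
  v <- ts@values
  colnames(v) <- ts@nodeLabels
  utils::write.csv(v, path, row.names = FALSE)
  invisible(path)
}

#' Write an edge table from calibrated scores
#'
#' Emits one row per upper-triangle node pair with the correlation-scale
#' estimate, the calibrated z-score, and whether the edge survives the
#' FDR threshold.
#'
#' @param estimate a [NetworkEstimate-class].
#' @param z the matching [CalibratedZ-class].
#' @param path output file; CSV with columns
#'   `node_i, node_j, r, z, survives_fdr`.
#' @param q FDR level (default 0.05).
#' @return the edge table, invisibly, as a data.frame.
#' @export
writeEdgeTable <- function(estimate, z, path, q = 0.05) {
  r <- if (estimate@metric == "full") stats::cov2cor(estimate@covariance)
       else estimate@partialCorrelation
  zm <- z@z
  ut <- which(upper.tri(zm), arr.ind = TRUE)
  fdr <- fdrThreshold(z, q = q)
  tab <- data.frame(node_i = ut[, 1L], node_j = ut[, 2L],
                    r = r[ut], z = zm[ut], survives_fdr = fdr$mask[ut])
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
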