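# Readers and writers for the plain-text interchange formats (FASTA,
# TSV, BED6, sample sheets) plus run configuration validation.  All
# tables are tab-separated UTF-8 with '#' comment/provenance headers;
# genomic coordinates are 0-based half-open (BED convention).

#' Read a FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences (names truncated at the
#'   first whitespace).  Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("FASTA file has no records: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  stats::setNames(as.character(ss), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a probe x array intensity matrix from TSV
#'
#' First column is the probe id; remaining columns are arrays.  Lines
#' starting with `#` are comments.  Any missing or non-numeric cell is an
#' error naming its row and column.
#'
#' @param path TSV path.
#' @return Numeric matrix with probe rownames and array colnames.
#' @export
read_intensity_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("intensity TSV needs a probe column plus arrays")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate probe ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2L, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric intensity at probe '%s', array '%s'",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("missing intensity at probe '%s', array '%s'",
                 ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  rownames(m) <- ids
  m
}

#' Write an intensity matrix to TSV
#'
#' @param intensities Probes x arrays numeric matrix.
#' @param path Output path.
#' @param provenance Optional character vector written as `#` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(intensities, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(c("probe_id", colnames(intensities)), collapse = "\t"),
             con)
  body <- apply(intensities, 1L, function(v)
    paste(sprintf("%.10g", v), collapse = "\t"))
  writeLines(paste(rownames(intensities), body, sep = "\t"), con)
  invisible(path)
}

#' Read a titration sample sheet
#'
#' TSV with columns `array_id`, `sample`, `replicate`.
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("array_id", "sample", "replicate")
  if (!all(need %in% names(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$array_id)) stop("duplicate array ids in ", path)
  df
}

#' Write a titration sample sheet
#'
#' @param sheet Data frame with `array_id`, `sample`, `replicate`.
#' @param path Output path.
#' @param provenance Optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(sheet, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write probes or probesets as BED6
#'
#' 0-based half-open coordinates, score column carries the self-affinity
#' (or 0), strand from the input.
#'
#' @param df Data frame with `source_contig` (or `locus_id`), `start`,
#'   `end`, `probe_id` (or `probeset_id`), optional `self_affinity` and
#'   `strand`.
#' @param path Output path.
#' @param provenance Optional `#` header lines (written as `track`-less
#'   comments).
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path, provenance = NULL) {
  contig <- if (!is.null(df$source_contig)) df$source_contig else df$locus_id
  name <- if (!is.null(df$probe_id)) df$probe_id else df$probeset_id
  start <- if (!is.null(df$start)) df$start else df$span_start
  end <- if (!is.null(df$end)) df$end else df$span_end
  score <- if (!is.null(df$self_affinity)) df$self_affinity else 0
  strand <- if (!is.null(df$strand)) df$strand else "+"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  writeLines(paste(contig, start, end, name, sprintf("%.4g", score),
                   strand, sep = "\t"), con)
  invisible(path)
}

#' Validate a run configuration
#'
#' Central validation of the pipeline's tunable parameters; the returned
#' list is suitable for serializing into provenance headers.
#'
#' @param probe_length Probe length (nt).
#' @param step Tiling step, in 1..4.
#' @param max_mm,max_gaps Hit-search budget.
#' @param window Probeset span (must exceed the probe length).
#' @param min_probes,max_probes Probeset size bounds (3..6 by default).
#' @param min_separation Minimum probe start separation.
#' @param n_folds LASSO cross-validation folds (>= 2).
#' @param tol,max_iter Fit convergence controls.
#' @param q_threshold,fc_threshold,floor Differential-expression filter
#'   thresholds.
#' @param seed Integer seed recorded in every output.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(probe_length = 25L, step = 1L, max_mm = 3L,
                       max_gaps = 1L, window = 400L, min_probes = 3L,
                       max_probes = 6L, min_separation = 8L,
                       n_folds = 10L, tol = 1e-6, max_iter = 100L,
                       q_threshold = 0.01, fc_threshold = 2, floor = 16,
                       seed = 1L) {
  if (!(step >= 1L && step <= 4L)) stop("step must be in 1..4")
  if (!(min_probes >= 1L && min_probes <= max_probes)) {
    stop("need 1 <= min_probes <= max_probes")
  }
  if (window <= probe_length) stop("window must exceed the probe length")
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (max_mm < 0L || max_gaps < 0L) stop("negative alignment budget")
  if (q_threshold <= 0 || q_threshold > 1) stop("q_threshold in (0, 1]")
  structure(as.list(environment()), class = "run_config")
}

#' Format a configuration as provenance header lines
#'
#' @param config A [run_config()].
#' @return Character vector of `key=value` lines, prefixed with the
#'   package version.
#' @export
format_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  kv <- vapply(names(config), function(k)
    paste0(k, "=", format(config[[k]])), character(1))
  c(paste0("pehm ", as.character(utils::packageVersion("pehm"))),
    unname(kv))
}
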