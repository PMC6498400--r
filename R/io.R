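#' Write / read a coupling matrix
#'
#' Square tab-delimited numeric matrix with a header row of channel labels,
#' full double precision.
#'
#' @param w coupling matrix from [coupling_matrix()].
#' @param path output file.
#' @export
write_coupling_matrix <- function(w, path) {
  labels <- if (is.null(colnames(w))) sprintf("ch%03d", seq_len(ncol(w))) else colnames(w)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  utils::write.table(format(w, digits = 17, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' @rdname write_coupling_matrix
#' @return `read_coupling_matrix` returns the matrix with channel labels as
#'   dimnames.
#' @export
read_coupling_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  dimnames(m) <- list(colnames(m), colnames(m))
  m
}

#' Write a subject to the delimited + sidecar container
#'
#' One tab-delimited matrix per subject (channels as rows, the subject's
#' epochs concatenated along columns) plus a small JSON sidecar holding the
#' reshape geometry (`fs`, `epoch_len`, `n_epochs`, `prestim_samples`) and
#' the subject's id and group label. [read_subject()] restores the
#' [epoched_recording()] exactly (values round-trip at full precision).
#'
#' @param rec an [epoched_recording()].
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @param id subject identifier.
#' @param group group label.
#' @return invisibly, the two file paths.
#' @export
write_subject <- function(rec, prefix, id = "S01", group = "A") {
  stopifnot(inherits(rec, "epoched_recording"))
  d <- dim(rec$data)
  flat <- matrix(rec$data, nrow = d[1])   # channels x (samples * epochs)
  data_path <- paste0(prefix, ".tsv")
  meta_path <- paste0(prefix, ".json")
  utils::write.table(format(flat, digits = 17, trim = TRUE), data_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(id = id, group = group, fs = rec$fs,
         channels = d[1], epoch_len = d[2], n_epochs = d[3],
         prestim_samples = rec$prestim_samples),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(data = data_path, meta = meta_path))
}

#' Read a subject from the delimited + sidecar container
#'
#' @param prefix path prefix used by [write_subject()].
#' @return list with `rec` ([epoched_recording()]), `id`, `group`.
#' @export
read_subject <- function(prefix) {
  data_path <- paste0(prefix, ".tsv")
  meta_path <- paste0(prefix, ".json")
  if (!file.exists(data_path) || !file.exists(meta_path)) {
    jdnet_stop("jdnet_missing_file", "missing subject files: %s{.tsv,.json}", prefix)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(data_path, sep = "\t", header = FALSE))
  arr <- array(flat, c(meta$channels, meta$epoch_len, meta$n_epochs))
  list(rec = epoched_recording(arr, meta$fs, meta$prestim_samples),
       id = meta$id, group = meta$group)
}

#' Write a synthetic cohort to a directory
#'
#' Emits every subject of a [generate_cohort()] result in the same
#' delimited + sidecar format the pipeline reads, so synthetic cohorts are
#' indistinguishable from real inputs.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of path prefixes.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefixes <- vapply(cohort, function(s) file.path(dir, s$id), "")
  for (i in seq_along(cohort)) {
    write_subject(cohort[[i]]$rec, prefixes[i], cohort[[i]]$id, cohort[[i]]$group)
  }
  invisible(prefixes)
}

#' Read a cohort directory
#'
#' @param dir directory of `<id>.tsv` / `<id>.json` pairs from
#'   [write_cohort()].
#' @return list of subjects suitable for [run_cohort()].
#' @export
read_cohort <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(metas) == 0) jdnet_stop("jdnet_missing_file", "no subject sidecars in %s", dir)
  lapply(sub("\\.json$", "", metas), read_subject)
}

#' Write the filtered averaged recording
#'
#' Channels x samples tab-delimited matrix, one file per subject.
#'
#' @param avg list with `data` and `fs` (from [bandpass_zero_phase()] or
#'   [preprocess_subject()]).
#' @param path output file.
#' @export
write_averaged_recording <- function(avg, path) {
  utils::write.table(format(avg$data, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Write the group comparison report
#'
#' The comparison table as TSV plus a JSON mirror laid out like a results
#' table (per metric: group means and SDs, test used, exact p,
#' significance), with the outlier report attached. The report notes that
#' no multiple-testing correction is applied across the four metrics.
#'
#' @param result list from [run_cohort()].
#' @param prefix path prefix; writes `<prefix>.tsv` and `<prefix>.json`.
#' @export
write_comparison_report <- function(result, prefix) {
  utils::write.table(result$comparisons, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(comparisons = result$comparisons,
         outliers = result$outliers,
         skipped = result$skipped,
         note = "p-values are per metric; no multiple-testing correction applied"),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

# ---- minimal EDF (European Data Format) support ------------------------
# Continuous multichannel int16 EDF: 256-byte fixed header, 256 bytes per
# signal, then data records of little-endian 16-bit integers scaled
# linearly between the digital and physical ranges. Annotations and
# discontinuous variants are not handled.

edf_pad <- function(x, width) {
  formatC(substr(as.character(x), 1, width), width = -width)
}

#' Write a continuous recording as EDF
#'
#' Minimal EDF writer for round-tripping continuous multichannel signals:
#' one data record holding the full signal, 16-bit quantization over each
#' channel's observed range.
#'
#' @param mat channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param path output file.
#' @param labels channel labels (default ch001, ch002, ...).
#' @export
write_edf <- function(mat, fs, path, labels = NULL) {
  nc <- nrow(mat)
  ns <- ncol(mat)
  if (is.null(labels)) labels <- sprintf("ch%03d", seq_len(nc))
  pmin_ <- apply(mat, 1, min)
  pmax_ <- apply(mat, 1, max)
  pmax_ <- ifelse(pmax_ > pmin_, pmax_, pmin_ + 1)  # avoid zero span
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic", 80), edf_pad("synthetic", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + nc), 8), edf_pad("", 44),
    edf_pad(1, 8),                      # one data record
    edf_pad(format(ns / fs, digits = 8), 8),
    edf_pad(nc, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  fld(substr(labels, 1, 16), 16)
  fld(rep("", nc), 80)                  # transducer
  fld(rep("uV", nc), 8)
  fld(format(pmin_, digits = 8), 8)
  fld(format(pmax_, digits = 8), 8)
  fld(rep("-32768", nc), 8)
  fld(rep("32767", nc), 8)
  fld(rep("", nc), 80)                  # prefiltering
  fld(rep(ns, nc), 8)
  fld(rep("", nc), 32)                  # reserved
  for (c in seq_len(nc)) {
    dig <- round((mat[c, ] - pmin_[c]) / (pmax_[c] - pmin_[c]) * 65535 - 32768)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' Minimal EDF reader: returns all signals as a channels x samples matrix
#' in physical units with the (common) sampling rate. Annotation channels
#' and per-signal rates are not supported; annotations are ignored by
#' design.
#'
#' @param path EDF file.
#' @return list with `data` (channels x samples), `fs`, `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8 + 80 + 80 + 8 + 8)
  rd(8)                                  # header bytes
  rd(44)
  ndr <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(nc), function(i) rd(16), ""))
  rd(80 * nc)
  rd(8 * nc)
  pmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(80 * nc)
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(32 * nc)
  if (length(unique(spr)) != 1) {
    jdnet_stop("jdnet_bad_input", "per-signal sampling rates are not supported")
  }
  out <- matrix(0, nc, spr[1] * ndr)
  for (r in seq_len(ndr)) {
    for (c in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[c], size = 2, endian = "little",
                     signed = TRUE)
      cols <- ((r - 1) * spr[c] + 1):(r * spr[c])
      out[c, cols] <- pmin_[c] +
        (dig - dmin_[c]) / (dmax_[c] - dmin_[c]) * (pmax_[c] - pmin_[c])
    }
  }
  list(data = out, fs = spr[1] / dur, labels = labels)
}
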