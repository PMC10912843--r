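#' ROI time-series container
#'
#' One subject's parcellated BOLD data: a regions x timepoints matrix of
#' signal amplitudes sampled every `tr_seconds` seconds. This is the
#' observation sequence the hidden Markov model is fitted to.
#'
#' @param data numeric matrix, regions in rows, timepoints in columns.
#' @param subject_id character scalar identifying the subject.
#' @param tr_seconds repetition time in seconds (sampling interval).
#' @param region_labels optional character vector of region names; defaults
#'   to `R001`, `R002`, ... Generated labels are zero-padded to sort
#'   lexically.
#' @return An object of class `roi_timeseries` with fields `subject_id`,
#'   `data`, `tr_seconds`, `region_labels`.
#' @examples
#' ts <- roi_timeseries(matrix(rnorm(40), 4, 10), "sub01", tr_seconds = 2)
#' dim(ts$data)
#' @export
roi_timeseries <- function(data, subject_id, tr_seconds = 2,
                           region_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop("need at least 2 regions and 2 timepoints, got ",
         nrow(data), " x ", ncol(data))
  if (any(!is.finite(data)))
    stop("non-finite values in time series for subject '", subject_id, "'")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar")
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(nrow(data)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(data))
    stop("region_labels length (", length(region_labels),
         ") does not match region count (", nrow(data), ")")
  if (anyDuplicated(region_labels))
    stop("region_labels must be unique")
  rownames(data) <- region_labels
  structure(
    list(subject_id = as.character(subject_id), data = data,
         tr_seconds = as.numeric(tr_seconds), region_labels = region_labels),
    class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat("<roi_timeseries> subject", x$subject_id, "-", nrow(x$data),
      "regions x", ncol(x$data), "timepoints, TR =", x$tr_seconds, "s\n")
  invisible(x)
}

#' Multi-subject cohort of ROI time series
#'
#' Couples a list of [roi_timeseries()] objects with a subject metadata table.
#' All series must share region count, region labels and TR; series and
#' metadata rows are matched one-to-one by `subject_id`.
#'
#' @param series list of `roi_timeseries` objects.
#' @param meta data.frame with at least a `subject_id` column; conventional
#'   columns are `group`, `age`, `sex`, `education`, `moca`.
#' @return An object of class `cohort` with fields `series` (named list) and
#'   `meta` (data.frame ordered like `series`).
#' @export
cohort <- function(series, meta) {
  if (!length(series)) stop("empty cohort")
  if (!all(vapply(series, inherits, logical(1), "roi_timeseries")))
    stop("series must be a list of roi_timeseries objects")
  meta <- as.data.frame(meta)
  if (!"subject_id" %in% names(meta)) stop("meta must have a subject_id column")
  meta$subject_id <- as.character(meta$subject_id)
  ids <- vapply(series, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject_id in series")
  if (anyDuplicated(meta$subject_id)) stop("duplicate subject_id in meta")
  if (!setequal(ids, meta$subject_id))
    stop("series and meta subject_ids differ: only-in-series {",
         paste(setdiff(ids, meta$subject_id), collapse = ", "),
         "}, only-in-meta {",
         paste(setdiff(meta$subject_id, ids), collapse = ", "), "}")
  ref <- series[[1L]]
  for (s in series[-1L]) {
    if (nrow(s$data) != nrow(ref$data))
      stop("subject '", s$subject_id, "' has ", nrow(s$data),
           " regions; expected ", nrow(ref$data))
    if (!identical(s$region_labels, ref$region_labels))
      stop("subject '", s$subject_id, "' has different region labels")
    if (s$tr_seconds != ref$tr_seconds)
      stop("subject '", s$subject_id, "' has TR ", s$tr_seconds,
           "; expected ", ref$tr_seconds)
  }
  names(series) <- ids
  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(series = series, meta = meta), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  ref <- x$series[[1L]]
  cat("<cohort>", length(x$series), "subjects,", nrow(ref$data),
      "regions x", ncol(ref$data), "timepoints, TR =", ref$tr_seconds, "s\n")
  if ("group" %in% names(x$meta)) print(table(x$meta$group))
  invisible(x)
}

#' Number of subjects in a cohort
#' @param x a `cohort`.
#' @export
n_subjects <- function(x) length(x$series)

read_matrix_file <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  raw <- utils::read.table(path, sep = sep, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "#")
  labels <- NULL
  # optional first column of region labels: non-numeric below the first row
  col1 <- as.character(raw[[1L]])
  if (any(is.na(suppressWarnings(as.numeric(col1[-1L]))))) {
    labels <- col1
    raw <- raw[, -1L, drop = FALSE]
  }
  # optional header row of timepoint indices: non-numeric cells in row 1
  row1 <- suppressWarnings(as.numeric(as.character(unlist(raw[1L, ]))))
  if (any(is.na(row1))) {
    raw <- raw[-1L, , drop = FALSE]
    if (!is.null(labels)) labels <- labels[-1L]
  }
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  nan_txt <- toupper(trimws(as.character(as.matrix(raw))))
  m[nan_txt %in% c("NAN", "NA", "INF", "-INF")] <- NA_real_
  if (any(is.na(m))) {
    bad <- which(matrix(is.na(m), nrow = nrow(m)), arr.ind = TRUE)[1L, ]
    stop("non-numeric or missing cell in '", basename(path), "' at row ",
         bad[1L], ", column ", bad[2L])
  }
  list(data = m, labels = labels)
}

#' Load a cohort from per-subject matrix files plus a metadata table
#'
#' Reads one delimited matrix file per subject (regions in rows, timepoints
#' in columns; an optional label column and header row are detected) and a
#' delimited metadata table with a `subject_id` column. Subjects present in
#' only one source are dropped with a warning. File base names (minus
#' extension) are the subject ids.
#'
#' @param matrix_dir directory of `.tsv`/`.csv`/`.txt` matrix files.
#' @param meta_table path to the metadata TSV/CSV.
#' @param tr_seconds repetition time in seconds to attach to every subject.
#' @param drop_initial_volumes number of leading timepoints to discard from
#'   every matrix (for raw exports that still contain dummy volumes); the
#'   default 0 assumes discarded volumes were already removed upstream.
#' @return A [cohort()].
#' @export
load_cohort <- function(matrix_dir, meta_table, tr_seconds = 2,
                        drop_initial_volumes = 0L) {
  files <- list.files(matrix_dir, pattern = "\\.(tsv|csv|txt)$",
                      full.names = TRUE)
  # skip the metadata table and ground-truth sidecars living alongside
  files <- files[!grepl("^(metadata\\.|true_paths|true_transition_)",
                        basename(files))]
  if (!length(files)) stop("no matrix files found under ", matrix_dir)
  ids <- sub("\\.[^.]+$", "", basename(files))
  first <- readLines(meta_table, n = 1L)
  msep <- if (grepl("\t", first)) "\t" else ","
  meta <- utils::read.table(meta_table, sep = msep, header = TRUE,
                            stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(meta))
    stop("metadata table lacks a subject_id column")
  meta$subject_id <- as.character(meta$subject_id)

  orphan_files <- setdiff(ids, meta$subject_id)
  orphan_meta <- setdiff(meta$subject_id, ids)
  if (length(orphan_files) || length(orphan_meta))
    warning("dropping subjects without both matrix and metadata: ",
            paste(c(orphan_files, orphan_meta), collapse = ", "))
  keep <- ids %in% meta$subject_id
  files <- files[keep]; ids <- ids[keep]
  meta <- meta[meta$subject_id %in% ids, , drop = FALSE]
  if (!length(files)) stop("no subject has both a matrix and metadata")

  series <- vector("list", length(files))
  nreg <- NULL
  for (i in seq_along(files)) {
    parsed <- read_matrix_file(files[[i]])
    m <- parsed$data
    if (drop_initial_volumes > 0L) {
      if (ncol(m) <= drop_initial_volumes)
        stop("subject '", ids[[i]], "': cannot drop ", drop_initial_volumes,
             " volumes from ", ncol(m), " timepoints")
      m <- m[, -seq_len(drop_initial_volumes), drop = FALSE]
    }
    if (is.null(nreg)) nreg <- nrow(m)
    else if (nrow(m) != nreg)
      stop("region count mismatch: '", basename(files[[i]]), "' has ",
           nrow(m), " regions; '", basename(files[[1L]]), "' has ", nreg)
    series[[i]] <- roi_timeseries(m, ids[[i]], tr_seconds = tr_seconds,
                                  region_labels = parsed$labels)
  }
  cohort(series, meta)
}

#' Write a cohort as per-subject TSV matrices plus a metadata TSV
#'
#' Inverse of [load_cohort()]: one `<subject_id>.tsv` per subject with a
#' leading region-label column, and `metadata.tsv`. Values are written with
#' 17 significant digits so a load/save/load cycle is bit-identical.
#'
#' @param x a [cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in x$series) {
    df <- data.frame(region = s$region_labels,
                     format(s$data, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(s$subject_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(x$meta, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Average voxel time courses within labelled ROIs
#'
#' Collapses a 4-D intensity array to a regions x timepoints matrix by
#' averaging, at each timepoint, the voxels sharing each atlas label.
#' Label 0 is background. Labels named in `label_names` but absent from
#' `label_volume` yield an all-NaN row and a warning.
#'
#' @param volume_4d 4-D numeric array (x, y, z, time).
#' @param label_volume 3-D integer array of atlas labels, same spatial dims.
#' @param label_names named character vector mapping label value to region
#'   name, e.g. `c("1" = "Precentral_L", ...)`; order defines row order.
#' @param subject_id,tr_seconds passed to [roi_timeseries()].
#' @return A [roi_timeseries()] (rows may contain NaN for empty ROIs, in
#'   which case construct-time validation is bypassed deliberately).
#' @export
extract_roi_timeseries <- function(volume_4d, label_volume, label_names,
                                   subject_id = "subject",
                                   tr_seconds = 2) {
  d4 <- dim(volume_4d); d3 <- dim(label_volume)
  if (length(d4) != 4L) stop("volume_4d must be a 4-D array")
  if (length(d3) != 3L || !all(d4[1:3] == d3))
    stop("spatial dimensions differ: volume ",
         paste(d4[1:3], collapse = "x"), " vs labels ",
         paste(d3, collapse = "x"))
  labels <- as.integer(names(label_names))
  Tn <- d4[4L]
  vox <- matrix(volume_4d, ncol = Tn)  # voxels x time
  lab <- as.integer(label_volume)
  out <- matrix(NA_real_, length(labels), Tn,
                dimnames = list(unname(label_names), NULL))
  for (i in seq_along(labels)) {
    sel <- which(lab == labels[[i]])
    if (!length(sel)) {
      warning("label ", labels[[i]], " ('", label_names[[i]],
              "') has no voxels; emitting NaN row")
      out[i, ] <- NaN
    } else {
      out[i, ] <- colMeans(vox[sel, , drop = FALSE])
    }
  }
  # Bypass the finite-value check: empty ROIs are flagged, not fatal here.
  ts <- structure(
    list(subject_id = as.character(subject_id), data = out,
         tr_seconds = as.numeric(tr_seconds),
         region_labels = unname(label_names)),
    class = "roi_timeseries")
  ts
}

#' Zero-phase band-pass filter of every region's time course
#'
#' Applies an order-4 Butterworth band-pass (order-2 design run forward and
#' backward with `signal::filtfilt`, so the magnitude response is squared and
#' the phase response is zero -- state timing is not shifted). Defaults to
#' the conventional resting-state band 0.01-0.08 Hz.
#'
#' @param ts a [roi_timeseries()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz < ` Nyquist (`1/(2 * tr_seconds)`).
#' @return A filtered `roi_timeseries` of the same shape.
#' @export
bandpass_filter <- function(ts, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("need 0 <= low_hz < high_hz")
  if (high_hz >= nyq)
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency ",
         nyq, " Hz at TR = ", ts$tr_seconds, " s")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  filtered <- t(apply(ts$data, 1L, function(x) {
    signal::filtfilt(bf, x - mean(x))
  }))
  roi_timeseries(filtered, ts$subject_id, ts$tr_seconds, ts$region_labels)
}

#' Z-score every region's time course
#'
#' Centres and scales each region to mean 0, sample SD 1 (denominator
#' `n - 1`). Standardization puts all regions on a common scale so that no
#' single high-variance region dominates the Gaussian emission likelihood.
#' Idempotent.
#'
#' @param ts a [roi_timeseries()].
#' @return A standardized `roi_timeseries`.
#' @export
standardize <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  sds <- apply(ts$data, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(ts$region_labels[sds == 0], collapse = ", "))
  z <- (ts$data - rowMeans(ts$data)) / sds
  roi_timeseries(z, ts$subject_id, ts$tr_seconds, ts$region_labels)
}

# Apply a per-subject transform across a cohort.
#' @rdname standardize
#' @param x a [cohort()].
#' @export
standardize_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  x$series <- lapply(x$series, standardize)
  x
}
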