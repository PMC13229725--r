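# Shared data containers and their on-disk format.
#
# A dataset is a JSON-Lines manifest (`dataset.jsonl`, one record per sample)
# plus a sidecar `dataset.meta.json` (class count, class names, provenance)
# and two CSV files per sample, one per stream.  Stream CSVs have a `t_index`
# first column (0-based frame index) and data columns `c0..c{d-1}`, written
# with 17 significant digits so values round-trip below 1e-9.  Motif windows
# are half-open `[t_start, t_end)` intervals in seconds.

#' Construct one labeled multimodal recording
#'
#' @param sample_id Unique string identifier.
#' @param video_stream Numeric matrix `T_v x d_v`: one embedding vector per
#'   video frame (precomputed or synthetic; the package never touches pixels).
#' @param sensor_stream Numeric matrix `T_s x d_s`: multi-channel wearable
#'   sensor signal at its own rate.
#' @param video_rate_hz,sensor_rate_hz Positive sampling rates (frames/s, Hz).
#' @param label Integer class index in `[0, class_count)` (0-based).
#' @param annotation Optional numeric `c(t_start, t_end)` in seconds: the
#'   half-open window carrying the class-informative movement segment.
#' @return An object of class `sequence_sample`.
#' @export
sequence_sample <- function(sample_id, video_stream, sensor_stream,
                            video_rate_hz = 30, sensor_rate_hz = 100,
                            label, annotation = NULL) {
  video_stream <- as.matrix(video_stream)
  sensor_stream <- as.matrix(sensor_stream)
  stopifnot(is.character(sample_id), length(sample_id) == 1,
            nrow(video_stream) >= 1, nrow(sensor_stream) >= 1,
            video_rate_hz > 0, sensor_rate_hz > 0,
            length(label) == 1, label == floor(label), label >= 0)
  if (!all(is.finite(video_stream)))
    stop("non-finite value in video stream of sample '", sample_id, "'",
         call. = FALSE)
  if (!all(is.finite(sensor_stream)))
    stop("non-finite value in sensor stream of sample '", sample_id, "'",
         call. = FALSE)
  duration <- nrow(video_stream) / video_rate_hz
  if (!is.null(annotation)) {
    annotation <- as.numeric(annotation[1:2])
    if (!(annotation[1] >= 0 && annotation[1] < annotation[2] &&
          annotation[2] <= duration + 1e-9))
      stop("annotation window [", annotation[1], ", ", annotation[2],
           ") outside sample duration ", duration, call. = FALSE)
  }
  structure(list(sample_id = sample_id,
                 video_stream = unname(video_stream),
                 sensor_stream = unname(sensor_stream),
                 video_rate_hz = video_rate_hz,
                 sensor_rate_hz = sensor_rate_hz,
                 label = as.integer(label),
                 annotation = annotation),
            class = "sequence_sample")
}

#' Construct a labeled dataset of multimodal recordings
#'
#' @param samples List of [sequence_sample()] objects.
#' @param class_count Number of classes `C` (>= 2); all labels must be `< C`.
#' @param split_tag One of `"train"`, `"val"`, `"test"`.
#' @param class_names Optional character vector of length `class_count`.
#' @param provenance Optional list recording how the data were generated.
#' @return An object of class `sequence_dataset`.
#' @export
sequence_dataset <- function(samples, class_count,
                             split_tag = c("train", "val", "test"),
                             class_names = NULL, provenance = NULL) {
  split_tag <- match.arg(split_tag)
  stopifnot(is.list(samples), class_count >= 2)
  ids <- vapply(samples, function(s) s$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample_id in dataset", call. = FALSE)
  labels <- vapply(samples, function(s) s$label, integer(1))
  if (length(labels) && any(labels >= class_count))
    stop("label ", max(labels), " >= class_count ", class_count,
         call. = FALSE)
  if (is.null(class_names))
    class_names <- paste0("class_", seq_len(class_count) - 1L)
  structure(list(samples = samples,
                 class_count = as.integer(class_count),
                 split_tag = split_tag,
                 class_names = class_names,
                 provenance = provenance),
            class = "sequence_dataset")
}

#' @export
length.sequence_dataset <- function(x) length(x$samples)

#' @export
print.sequence_dataset <- function(x, ...) {
  labels <- vapply(x$samples, function(s) s$label, integer(1))
  cat("<sequence_dataset> ", length(x$samples), " samples, ",
      x$class_count, " classes (", x$split_tag, " split)\n", sep = "")
  if (length(labels)) print(table(factor(labels, levels = 0:(x$class_count - 1))))
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

write_stream_csv <- function(stream, path) {
  d <- ncol(stream)
  header <- paste(c("t_index", paste0("c", seq_len(d) - 1L)), collapse = ",")
  rows <- vapply(seq_len(nrow(stream)), function(i) {
    paste(c(as.character(i - 1L), fmt17(stream[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

read_stream_csv <- function(path, sample_id) {
  if (!file.exists(path))
    stop("missing stream file '", path, "' for sample '", sample_id, "'",
         call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat) || anyNA(mat) || !all(is.finite(mat))) {
    suppressWarnings(storage.mode(mat) <- "double")
    bad <- which(!is.finite(mat), arr.ind = TRUE)
    stop("non-numeric or non-finite cell in '", basename(path), "' at row ",
         bad[1, 1], ", column ", colnames(mat)[bad[1, 2]],
         " (sample '", sample_id, "')", call. = FALSE)
  }
  unname(mat)
}

#' Write a dataset to disk
#'
#' Emits `dataset.jsonl` (one JSON record per sample, in order), a sidecar
#' `dataset.meta.json`, and two CSV stream files per sample.  The written
#' tree round-trips through [read_dataset()] to within 1e-9 per value.
#'
#' @param dataset A [sequence_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  manifest <- file.path(out_dir, "dataset.jsonl")
  lines <- character(length(dataset$samples))
  for (i in seq_along(dataset$samples)) {
    s <- dataset$samples[[i]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", s$sample_id)
    vfile <- paste0(safe, "_video.csv")
    sfile <- paste0(safe, "_sensor.csv")
    write_stream_csv(s$video_stream, file.path(out_dir, vfile))
    write_stream_csv(s$sensor_stream, file.path(out_dir, sfile))
    rec <- list(sample_id = s$sample_id, label = s$label,
                video_rate_hz = s$video_rate_hz,
                sensor_rate_hz = s$sensor_rate_hz,
                video_csv = vfile, sensor_csv = sfile)
    if (!is.null(s$annotation))
      rec$annotation <- list(t_start = s$annotation[1],
                             t_end = s$annotation[2])
    lines[i] <- as.character(jsonlite::toJSON(rec, auto_unbox = TRUE,
                                              digits = NA))
  }
  writeLines(lines, manifest)
  meta <- list(class_count = dataset$class_count,
               class_names = dataset$class_names,
               split_tag = dataset$split_tag,
               provenance = dataset$provenance)
  jsonlite::write_json(meta, file.path(out_dir, "dataset.meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Read a dataset from disk
#'
#' @param manifest_path Path to a `dataset.jsonl` manifest written by
#'   [write_dataset()] (the sidecar `dataset.meta.json` must sit next to it).
#' @return A [sequence_dataset()] with samples in manifest order.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path, call. = FALSE)
  dir <- dirname(manifest_path)
  meta_path <- file.path(dir, "dataset.meta.json")
  if (!file.exists(meta_path))
    stop("sidecar dataset.meta.json not found next to manifest", call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  lines <- readLines(manifest_path)
  lines <- lines[nzchar(lines)]
  samples <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
    if (rec$label >= meta$class_count)
      stop("schema error: sample '", rec$sample_id, "' has label ",
           rec$label, " >= class_count ", meta$class_count, call. = FALSE)
    v <- read_stream_csv(file.path(dir, rec$video_csv), rec$sample_id)
    s <- read_stream_csv(file.path(dir, rec$sensor_csv), rec$sample_id)
    ann <- if (!is.null(rec$annotation))
      c(rec$annotation$t_start, rec$annotation$t_end)
    samples[[i]] <- sequence_sample(rec$sample_id, v, s,
                                    rec$video_rate_hz, rec$sensor_rate_hz,
                                    rec$label, ann)
  }
  sequence_dataset(samples, meta$class_count,
                   split_tag = meta$split_tag,
                   class_names = meta$class_names,
                   provenance = meta$provenance)
}

#' Resample a multichannel stream to a new rate
#'
#' Linear interpolation on a uniform grid spanning the same duration as the
#' input; the new length is `round(T * dst / src)` and both endpoints are
#' preserved.  Exact on affine signals.
#'
#' @param stream Numeric matrix `T x d` (or vector, treated as `T x 1`).
#' @param src_rate_hz,dst_rate_hz Positive rates in Hz.
#' @return Numeric matrix `T' x d`.
#' @export
resample_stream <- function(stream, src_rate_hz, dst_rate_hz) {
  stream <- as.matrix(stream)
  stopifnot(src_rate_hz > 0, dst_rate_hz > 0)
  if (src_rate_hz == dst_rate_hz) return(stream)
  T0 <- nrow(stream)
  if (T0 < 2)
    stop("cannot resample a single-time-step stream between differing rates",
         call. = FALSE)
  T1 <- as.integer(round(T0 * dst_rate_hz / src_rate_hz))
  if (T1 < 2)
    stop("target rate too low: resampled length would be ", T1, call. = FALSE)
  src_t <- (seq_len(T0) - 1) / src_rate_hz
  dst_t <- seq(0, src_t[T0], length.out = T1)
  apply(stream, 2, function(col) approx(src_t, col, xout = dst_t)$y)
}

# Linear-interpolation kernel of `times_out` against the uniform source grid
# `(0:(T-1))/rate`; clamped at the ends.  Shared by fuse() and its gradient.
interp_weights <- function(T_src, src_rate_hz, times_out) {
  pos <- times_out * src_rate_hz           # fractional source index, 0-based
  pos <- pmin(pmax(pos, 0), T_src - 1)
  j0 <- pmin(floor(pos), T_src - 2)        # left neighbour, 0-based
  if (T_src == 1) j0 <- rep(0, length(pos))
  w <- pos - j0
  list(j0 = as.integer(j0) + 1L, w = w)    # j0 returned 1-based
}

interp_apply <- function(E, iw) {
  if (nrow(E) == 1) return(E[rep(1, length(iw$j0)), , drop = FALSE])
  (1 - iw$w) * E[iw$j0, , drop = FALSE] + iw$w * E[iw$j0 + 1L, , drop = FALSE]
}
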