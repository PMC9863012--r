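#' Construct a raw triaxial recording
#'
#' @param x,y,z equal-length numeric vectors of acceleration in g.
#' @param sampling_rate samples per second (> 0).
#' @param start_time `POSIXct` start timestamp of the first sample.
#' @param subject_id identifier string.
#' @param group_label one of `"C"`, `"CTF"`, `"PSF"`, `"UNKNOWN"`.
#' @param clip clip samples outside the +/-8 g measurement interval (with a
#'   warning reporting the count) instead of erroring.
#' @return An object of class `raw_recording`: a list with the above fields
#'   plus `n_samples` and `duration_s`.
#' @export
raw_recording <- function(x, y, z, sampling_rate, start_time,
                          subject_id = "subject",
                          group_label = c("UNKNOWN", "C", "CTF", "PSF"),
                          clip = TRUE) {
  group_label <- match.arg(group_label)
  if (!(is.numeric(sampling_rate) && length(sampling_rate) == 1L && sampling_rate > 0))
    stop("sampling_rate must be a positive scalar")
  if (!(length(x) == length(y) && length(y) == length(z) && length(x) >= 1L))
    stop("x, y, z must be equal-length, non-empty vectors")
  if (!inherits(start_time, "POSIXct"))
    start_time <- as.POSIXct(start_time, tz = "UTC")
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  out_of_range <- 0L
  for (nm in c("x", "y", "z")) {
    v <- get(nm, inherits = FALSE)
    r <- range(v)
    if (r[1] < -8 || r[2] > 8) {
      out_of_range <- out_of_range + sum(v < -8 | v > 8)
      assign(nm, pmin(pmax(v, -8), 8), inherits = FALSE)
    }
  }
  if (out_of_range > 0L) {
    if (!clip) stop(out_of_range, " samples outside the +/-8 g interval")
    warning(out_of_range, " sample(s) outside +/-8 g clipped to the range limit")
  }
  structure(list(
    subject_id = as.character(subject_id),
    group_label = group_label,
    start_time = start_time,
    sampling_rate = sampling_rate,
    x = x, y = y, z = z,
    n_samples = length(x),
    duration_s = length(x) / sampling_rate,
    clipped = out_of_range
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s [%s]  %d samples @ %g Hz (%.2f h) from %s\n",
              x$subject_id, x$group_label, x$n_samples, x$sampling_rate,
              x$duration_s / 3600, format(x$start_time, usetz = TRUE)))
  invisible(x)
}

# guess among comma / tab / semicolon from the first non-empty line
.detect_sep <- function(line) {
  counts <- vapply(c(",", "\t", ";"), function(s)
    lengths(regmatches(line, gregexpr(s, line, fixed = TRUE))), integer(1))
  if (all(counts == 0L)) stop("cannot detect delimiter (comma/tab/semicolon)")
  c(",", "\t", ";")[which.max(counts)]
}

#' Read a raw recording from delimited text
#'
#' The canonical interchange format is delimited text (comma, tab or
#' semicolon; auto-detected) with columns `t` (seconds or sample index),
#' `x`, `y`, `z` in g, with or without a header line. Values outside the
#' +/-8 g measurement interval are clipped with a warning.
#'
#' @param path file path.
#' @param sampling_rate samples per second.
#' @param start_time recording start timestamp.
#' @param subject_id,group_label recording metadata (see [raw_recording()]).
#' @return A validated [raw_recording()].
#' @export
read_raw_recording <- function(path, sampling_rate, start_time,
                               subject_id = sub("\\.[^.]*$", "", basename(path)),
                               group_label = "UNKNOWN") {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trimws(first)))
    stop("format error in ", path, ": empty file (line 1)")
  sep <- .detect_sep(first)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, sep, fixed = TRUE)[[1]][1])))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE)
  if (has_header) {
    names(df) <- tolower(trimws(names(df)))
    need <- c("x", "y", "z")
    if (!all(need %in% names(df)))
      stop("format error in ", path, ": missing column(s) ",
           paste(setdiff(need, names(df)), collapse = ", "), " (line 1)")
    tcol <- intersect(c("t", "time"), names(df))
    tvals <- if (length(tcol)) df[[tcol[1]]] else seq_len(nrow(df))
    df <- df[c(tcol[1][length(tcol) > 0], "x", "y", "z")]
  } else {
    if (ncol(df) < 4L)
      stop("format error in ", path, ": expected 4 columns t,x,y,z (line 1)")
    tvals <- df[[1]]
    df <- stats::setNames(df[, 1:4], c("t", "x", "y", "z"))
  }
  if (nrow(df) == 0L) stop("format error in ", path, ": no data rows (line 2)")
  if (is.unsorted(tvals, strictly = TRUE)) {
    bad <- which(diff(tvals) <= 0)[1] + 1L
    stop("format error in ", path, ": non-monotonic time at data row ", bad)
  }
  raw_recording(df$x, df$y, df$z, sampling_rate = sampling_rate,
                start_time = start_time, subject_id = subject_id,
                group_label = group_label)
}

#' Write a raw recording as delimited text
#'
#' @param rec a [raw_recording()].
#' @param path output file path (comma-separated `t,x,y,z`, `t` in seconds).
#' @param digits significant digits retained (default keeps full precision
#'   for round-tripping at 6 decimals and beyond).
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "raw_recording"))
  t <- (seq_len(rec$n_samples) - 1) / rec$sampling_rate
  df <- data.frame(t = t, x = rec$x, y = rec$y, z = rec$z)
  df[] <- lapply(df, function(v) formatC(v, digits = digits, format = "g"))
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a feature table
#'
#' @param values numeric matrix, one row per subject.
#' @param subject_ids,labels per-subject identifiers and group labels.
#' @param registry_version manifest version the columns must belong to.
#' @return A `feature_table`: a data.frame with columns `subject_id`,
#'   `group_label`, then the features in registry order.
#' @export
feature_table <- function(values, subject_ids, labels,
                          registry_version = "1.0") {
  values <- as.matrix(values)
  reg <- feature_registry(registry_version)
  cols <- colnames(values)
  if (is.null(cols) && ncol(values) > 0)
    stop("feature columns must be named")
  if (anyDuplicated(cols)) stop("duplicated feature columns")
  unknown <- setdiff(cols, reg)
  if (length(unknown))
    stop("columns not in registry manifest ", registry_version, ": ",
         paste(unknown, collapse = ", "))
  if (nrow(values) != length(subject_ids) || length(subject_ids) != length(labels))
    stop("one row, id and label per subject required")
  ord <- intersect(reg, cols)
  df <- data.frame(subject_id = as.character(subject_ids),
                   group_label = as.character(labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(values[, ord, drop = FALSE],
                                check.names = FALSE))
  attr(df, "registry_version") <- registry_version
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Extract the numeric feature matrix from a feature table
#' @param table a `feature_table`.
#' @return Numeric matrix (subjects x features) with subject ids as rownames.
#' @export
feature_matrix <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  m <- as.matrix(table[, setdiff(names(table), c("subject_id", "group_label")),
                       drop = FALSE])
  rownames(m) <- table$subject_id
  storage.mode(m) <- "double"
  m
}

#' Write / read a feature table as TSV
#'
#' Tab-separated, first column `subject_id`, second `group_label`, then the
#' features in registry order at full float precision.
#'
#' @param table a `feature_table`.
#' @param path file path.
#' @return `path` (write) or the re-read `feature_table` (read).
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table, check.names = FALSE)
  num <- setdiff(names(df), c("subject_id", "group_label"))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 17, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param registry_version manifest version for validation on read.
#' @export
read_feature_table <- function(path, registry_version = "1.0") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group_label") %in% names(df)[1:2]))
    stop("not a feature table: ", path)
  feats <- setdiff(names(df), c("subject_id", "group_label"))
  m <- as.matrix(df[, feats, drop = FALSE])
  storage.mode(m) <- "double"
  feature_table(m, df$subject_id, df$group_label,
                registry_version = registry_version)
}
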