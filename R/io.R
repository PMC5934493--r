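#' Read and write TRC marker files
#'
#' A tab-delimited motion-capture interchange format. The dialect written
#' here has three header lines:
#' \enumerate{
#'   \item `PathFileType<TAB>4<TAB>(X/Y/Z)<TAB><filename>`
#'   \item `DataRate=<hz><TAB>CameraRate=<hz><TAB>NumFrames=<n><TAB>NumMarkers=<m><TAB>Units=mm`
#'   \item `Frame#<TAB>Time` followed by `<label>_X<i>`, `<label>_Y<i>`,
#'     `<label>_Z<i>` triplets for each marker `i`.
#' }
#' Positions are stored in millimeters; the in-memory representation is
#' meters. Occluded samples are written as empty fields and read back as
#' `NaN`.
#'
#' @param traj a [marker_trajectory()].
#' @param path file path.
#' @return `read_trc` returns a [marker_trajectory()]; `write_trc` returns
#'   `path` invisibly.
#' @export
write_trc <- function(traj, path) {
  labels <- names(traj$markers)
  n <- length(traj$time)
  rate <- if (is.na(traj$rate)) 0 else traj$rate
  head1 <- paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t")
  head2 <- paste0("DataRate=", format(rate, digits = 12),
                  "\tCameraRate=", format(rate, digits = 12),
                  "\tNumFrames=", n, "\tNumMarkers=", length(labels),
                  "\tUnits=mm")
  cols <- unlist(lapply(seq_along(labels), function(i)
    paste0(labels[i], "_", c("X", "Y", "Z"), i)))
  head3 <- paste(c("Frame#", "Time", cols), collapse = "\t")
  mat <- do.call(cbind, traj$markers) * 1000  # m -> mm
  body <- vapply(seq_len(n), function(i) {
    vals <- sprintf("%.7f", mat[i, ])
    vals[!is.finite(mat[i, ])] <- ""
    paste(c(i, sprintf("%.9f", traj$time[i]), vals), collapse = "\t")
  }, "")
  writeLines(c(head1, head2, head3, body), path)
  invisible(path)
}

#' @rdname write_trc
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L)
    stop("TRC parse error at line ", length(lines),
         ": expected 3 header lines plus data", call. = FALSE)
  if (!startsWith(lines[1], "PathFileType"))
    stop("TRC parse error at line 1: missing PathFileType header", call. = FALSE)
  kv <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  req <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(req %in% names(vals)))
    stop("TRC parse error at line 2: need DataRate/NumFrames/NumMarkers/Units",
         call. = FALSE)
  if (vals[["Units"]] != "mm")
    stop("TRC parse error at line 2: only Units=mm supported", call. = FALSE)
  n_markers <- as.integer(vals[["NumMarkers"]])
  cols <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (cols[1] != "Frame#" || cols[2] != "Time")
    stop("TRC parse error at line 3: expected Frame# and Time columns", call. = FALSE)
  triplet_cols <- cols[-(1:2)]
  if (length(triplet_cols) != 3L * n_markers)
    stop("TRC parse error at line 3: NumMarkers=", n_markers,
         " inconsistent with ", length(triplet_cols), " coordinate columns",
         call. = FALSE)
  labels <- sub("_X[0-9]+$", "", triplet_cols[seq(1, length(triplet_cols), by = 3)])
  rows <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
  nf <- as.integer(vals[["NumFrames"]])
  if (length(rows) != nf)
    stop("TRC parse error: NumFrames=", nf, " but ", length(rows),
         " data rows found", call. = FALSE)
  width <- 2L + 3L * n_markers
  dat <- matrix(NA_real_, nrow = length(rows), ncol = width)
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != width)
      stop("TRC parse error at line ", i + 3L, ": expected ", width,
           " fields, found ", length(r), call. = FALSE)
    r[r == ""] <- "NaN"
    dat[i, ] <- as.numeric(r)
  }
  time <- dat[, 2L]
  markers <- stats::setNames(lapply(seq_len(n_markers), function(k) {
    dat[, 2L + (3L * (k - 1L) + 1L):(3L * k) + 0L, drop = FALSE] / 1000
  }), labels)
  marker_trajectory(time, markers)
}

#' Read and write joint-angle CSV files
#'
#' Plain CSV with a `time` column (seconds) and one column per angle
#' channel in degrees; the sagittal channels `hip_flexion`, `knee_flexion`
#' and `ankle_flexion` are required on read. Round trips are lossless to
#' better than 1e-9 degrees.
#'
#' @param traj a [joint_trajectory()].
#' @param path file path.
#' @param require_channels channels that must be present when reading.
#' @return `read_angles_csv` returns a [joint_trajectory()];
#'   `write_angles_csv` returns `path` invisibly.
#' @export
write_angles_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.12f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_angles_csv
#' @export
read_angles_csv <- function(path,
                            require_channels = c("hip_flexion", "knee_flexion",
                                                 "ankle_flexion")) {
  if (!file.size(path) > 0)
    stop("angle CSV schema error: file is empty", call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df)) stop("angle CSV schema error: no data rows", call. = FALSE)
  need <- c("time", require_channels)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("angle CSV schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  joint_trajectory(df$time, as.list(df[setdiff(names(df), "time")]))
}
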