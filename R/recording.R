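#' Multichannel time-series recording
#'
#' Container for a continuous multichannel physiological recording: a
#' numeric matrix (samples x channels) with a sampling rate and a role per
#' channel (`"sensor"`, `"ecg_ref"`, or `"eog_ref"`).
#'
#' @param data numeric matrix, samples in rows, channels in columns.
#' @param sfreq sampling frequency in Hz.
#' @param roles character vector of channel roles, one per column; each is
#'   one of `"sensor"`, `"ecg_ref"`, `"eog_ref"`.
#' @param channel_names optional channel names; defaults to the column
#'   names of `data` or `ch01, ch02, ...`.
#'
#' @return An object of class `ts_recording`: a list with elements `data`,
#'   `sfreq`, `roles`, `channel_names`.
#' @export
#' @examples
#' x <- matrix(rnorm(2000), ncol = 2)
#' rec <- ts_recording(x, sfreq = 100, roles = c("sensor", "ecg_ref"))
#' rec
ts_recording <- function(data, sfreq, roles = NULL, channel_names = NULL) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  if (!is.matrix(data) || !is.numeric(data))
    stop_invalid("`data` must be a numeric matrix (samples x channels)")
  assert_scalar_num(sfreq, "sfreq", lower = 0, strict_lower = TRUE)
  nch <- ncol(data)
  if (is.null(roles)) roles <- rep("sensor", nch)
  if (length(roles) != nch)
    stop_invalid("`roles` must have one entry per channel (%d)", nch)
  bad <- setdiff(unique(roles), c("sensor", "ecg_ref", "eog_ref"))
  if (length(bad))
    stop_invalid("unknown channel role(s): %s", paste(bad, collapse = ", "))
  if (is.null(channel_names)) {
    channel_names <- colnames(data)
    if (is.null(channel_names))
      channel_names <- sprintf("ch%02d", seq_len(nch))
  }
  colnames(data) <- channel_names
  structure(
    list(data = data, sfreq = as.numeric(sfreq), roles = as.character(roles),
         channel_names = as.character(channel_names)),
    class = "ts_recording"
  )
}

#' @export
print.ts_recording <- function(x, ...) {
  cat(sprintf(
    "<ts_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    ncol(x$data), nrow(x$data), x$sfreq, nrow(x$data) / x$sfreq))
  cat("  roles:", paste(sprintf("%s[%s]", x$channel_names, x$roles),
                        collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.ts_recording <- function(x) dim(x$data)

#' Extract channels by role
#'
#' @param rec a [ts_recording()].
#' @param role role to select.
#' @return numeric matrix of the matching channels (possibly 0 columns).
#' @export
channels_by_role <- function(rec, role = c("sensor", "ecg_ref", "eog_ref")) {
  role <- match.arg(role)
  rec$data[, rec$roles == role, drop = FALSE]
}

#' Write a recording to delimited text
#'
#' Plain-text interchange format: comment header lines carrying the
#' sampling rate and channel roles, then one tab-separated column per
#' channel.
#'
#' ```
#' # sfreq=250
#' # roles=sensor,sensor,ecg_ref
#' ch01  ch02  ecg
#' ...
#' ```
#'
#' @param rec a [ts_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ts_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sfreq=%.10g", rec$sfreq), con)
  writeLines(sprintf("# roles=%s", paste(rec$roles, collapse = ",")), con)
  utils::write.table(
    as.data.frame(rec$data), con, sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(path)
}

#' Read a recording from delimited text
#'
#' Counterpart of [write_recording()]. The header must declare `sfreq`;
#' a missing `roles` line defaults every channel to `"sensor"` except
#' channels whose name contains `"ecg"` or `"eog"` (case-insensitive),
#' which are mapped to the matching reference role.
#'
#' @param path file path.
#' @return a [ts_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  head_lines <- readLines(path, n = 10L)
  meta <- grep("^#", head_lines, value = TRUE)
  sfreq_line <- grep("sfreq=", meta, value = TRUE)
  if (!length(sfreq_line))
    stop_invalid("missing `# sfreq=<Hz>` header in %s", path)
  sfreq <- as.numeric(sub(".*sfreq=", "", sfreq_line[1]))
  if (!is.finite(sfreq) || sfreq <= 0)
    stop_invalid("invalid sfreq header in %s: %s", path, sfreq_line[1])
  roles_line <- grep("roles=", meta, value = TRUE)
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
  mat <- as.matrix(dat)
  if (length(roles_line)) {
    roles <- strsplit(sub(".*roles=", "", roles_line[1]), ",")[[1]]
    roles <- trimws(roles)
  } else {
    nm <- tolower(colnames(mat))
    roles <- ifelse(grepl("ecg", nm), "ecg_ref",
                    ifelse(grepl("eog", nm), "eog_ref", "sensor"))
  }
  ts_recording(mat, sfreq = sfreq, roles = roles,
               channel_names = colnames(mat))
}
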