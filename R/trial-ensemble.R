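#' Trial-ensemble container
#'
#' A set of repetition trials of one recording channel: a trials x samples
#' matrix with a common sampling rate. All estimators in the package treat
#' the trials as independent realizations of the same process and pool
#' embedded samples across them.
#'
#' @param data numeric matrix, trials x samples (signal units, e.g. mV).
#'   A vector is treated as a single trial.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_id label for the channel.
#' @return An object of class `trial_ensemble` with elements `data`, `fs`,
#'   `channel_id`.
#' @examples
#' te <- trial_ensemble(matrix(rnorm(300), 3, 100), fs = 100)
#' n_trials(te); n_samples(te)
#' @export
trial_ensemble <- function(data, fs, channel_id = "ch") {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)")
  if (anyNA(data) || !all(is.finite(data)))
    stop("`data` contains non-finite values")
  structure(list(data = data, fs = fs, channel_id = as.character(channel_id)),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat(sprintf("<trial_ensemble '%s': %d trial(s) x %d samples @ %g Hz>\n",
              x$channel_id, nrow(x$data), ncol(x$data), x$fs))
  invisible(x)
}

#' @rdname trial_ensemble
#' @param x a `trial_ensemble` or `phase_ensemble`.
#' @export
n_trials <- function(x) nrow(x$data %||% x$phase)

#' @rdname trial_ensemble
#' @export
n_samples <- function(x) ncol(x$data %||% x$phase)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrapped instantaneous-phase ensemble
#'
#' Phases (radians, wrapped to `[-pi, pi)`) of one frequency band, one row
#' per trial. Usually produced by [extract_phase()].
#'
#' @param phase numeric matrix of phases in radians, trials x samples.
#' @param band numeric length-2, the (low, high) band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param channel_id channel label carried through from the raw ensemble.
#' @return An object of class `phase_ensemble`.
#' @export
phase_ensemble <- function(phase, band, fs, channel_id = "ch") {
  if (is.vector(phase)) phase <- matrix(phase, nrow = 1)
  phase <- as.matrix(phase)
  storage.mode(phase) <- "double"
  if (anyNA(phase) || !all(is.finite(phase)))
    stop("`phase` contains non-finite values")
  if (any(phase < -pi | phase >= pi))
    stop("phases must be wrapped to [-pi, pi)")
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("`band` must be (low, high) with 0 < low < high")
  structure(list(phase = phase, band = as.numeric(band), fs = fs,
                 channel_id = as.character(channel_id)),
            class = "phase_ensemble")
}

#' @export
print.phase_ensemble <- function(x, ...) {
  cat(sprintf("<phase_ensemble '%s': %d trial(s) x %d samples, %g-%g Hz @ %g Hz>\n",
              x$channel_id, nrow(x$phase), ncol(x$phase),
              x$band[1], x$band[2], x$fs))
  invisible(x)
}

#' Read / write trial ensembles as delimited text
#'
#' One trial per row; the first line is a metadata comment
#' `# phasete fs=<Hz> channel_id=<label>`. Rows of unequal length raise a
#' shape error; a file without the sampling-rate header raises a metadata
#' error.
#'
#' @param path file path.
#' @param format `"csv"` or `"tsv"`.
#' @return `read_ensemble` returns a [trial_ensemble()];
#'   `write_ensemble` returns `path` invisibly.
#' @export
read_ensemble <- function(path, format = c("csv", "tsv", "h5")) {
  format <- match.arg(format)
  if (format == "h5")
    stop("HDF5 containers are not supported by this build; use delimited text")
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty file")
  fs <- NA_real_; channel_id <- "ch"
  if (startsWith(lines[1], "#")) {
    m <- regmatches(lines[1], regexec("fs=([0-9.eE+-]+)", lines[1]))[[1]]
    if (length(m) == 2L) fs <- as.numeric(m[2])
    m <- regmatches(lines[1], regexec("channel_id=([^ ]+)", lines[1]))[[1]]
    if (length(m) == 2L) channel_id <- m[2]
    lines <- lines[-1]
  }
  if (!is.finite(fs))
    stop("metadata error: sampling rate `fs` missing from file header")
  lines <- lines[nzchar(lines)]
  rows <- strsplit(lines, sep, fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("shape error: rows have unequal length")
  data <- matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  if (anyNA(data)) stop("non-numeric entries in ensemble file")
  trial_ensemble(data, fs = fs, channel_id = channel_id)
}

#' @rdname read_ensemble
#' @param ensemble a [trial_ensemble()].
#' @export
write_ensemble <- function(ensemble, path, format = c("csv", "tsv", "h5")) {
  format <- match.arg(format)
  if (format == "h5")
    stop("HDF5 containers are not supported by this build; use delimited text")
  sep <- if (format == "csv") "," else "\t"
  stopifnot(inherits(ensemble, "trial_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# phasete fs=%.10g channel_id=%s",
                     ensemble$fs, ensemble$channel_id), con)
  write.table(format(ensemble$data, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = sep, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
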