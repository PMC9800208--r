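#' Construct a (time, signal) trace with assay metadata
#'
#' Light container used throughout: a data.frame with columns \code{time}
#' (seconds) and \code{signal}, class \code{myo_trace}, and a \code{meta}
#' attribute (named list: concentrations, temperature, units, ground truth).
#'
#' @param time Numeric time vector (s), nondecreasing.
#' @param signal Numeric signal vector, same length.
#' @param meta Named list of metadata.
#' @return A \code{myo_trace} data.frame.
#' @export
new_trace <- function(time, signal, meta = list()) {
  stopifnot(is.numeric(time), is.numeric(signal), length(time) == length(signal))
  if (is.unsorted(time)) stop("trace time must be nondecreasing")
  structure(data.frame(time = time, signal = signal),
            class = c("myo_trace", "data.frame"), meta = meta)
}

#' Metadata of a trace
#' @param x A \code{myo_trace}.
#' @return The named metadata list.
#' @export
trace_meta <- function(x) attr(x, "meta")

#' Write / read a trace as CSV with header metadata
#'
#' Metadata are serialized as leading \code{# key: value} comment lines, then
#' a standard two-column CSV (time, signal) follows.
#'
#' @param x A \code{myo_trace}.
#' @param path Output file path.
#' @return \code{write_trace_csv}: \code{path}, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  meta <- trace_meta(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) {
    v <- meta[[k]]
    if (is.numeric(v) && length(v) == 1)
      writeLines(sprintf("# %s: %.17g", k, v), con)
    else if (is.character(v) && length(v) == 1)
      writeLines(sprintf("# %s: %s", k, v), con)
  }
  writeLines("time,signal", con)
  utils::write.table(data.frame(x$time, x$signal), con, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    m <- regmatches(l, regexec("^#\\s*([^:]+):\\s*(.*)$", l))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      meta[[trimws(m[2])]] <- if (is.na(val)) m[3] else val
    }
  }
  df <- utils::read.csv(text = lines[-hdr])
  new_trace(df$time, df$signal, meta)
}
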