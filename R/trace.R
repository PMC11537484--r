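#' Uniformly sampled time series
#'
#' The basic container used throughout the package for stimuli
#' (isomerizations per second, \code{"R*/s"}), photocurrents (\code{"pA"}),
#' and the internal cascade variables. Time starts at 0 and advances in
#' steps of \code{dt}.
#'
#' @param values Numeric vector of samples; all values must be finite.
#' @param dt Sample interval in seconds (single positive number).
#' @param units Unit label; one of \code{"R*/s"}, \code{"pA"}, \code{"uM"},
#'   \code{"s^-1"}, \code{"mV"}, \code{"a.u."}. Stimulus traces
#'   (\code{"R*/s"}) must be nonnegative unless \code{strict = FALSE}
#'   (used internally to report, rather than hide, negative recovered
#'   stimuli from model inversion).
#' @param strict Enforce nonnegativity for \code{"R*/s"} traces.
#' @return An object of class \code{"ptrace"}: a list with elements
#'   \code{values}, \code{dt}, and \code{units}.
#' @examples
#' s <- new_trace(rep(1000, 100), dt = 1e-3, units = "R*/s")
#' head(trace_time(s))
#' @export
new_trace <- function(values, dt, units = "a.u.", strict = TRUE) {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a non-empty numeric vector")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (seconds)")
  values <- as.numeric(values)
  if (!all(is.finite(values)))
    stop("all trace samples must be finite; first bad sample at index ",
         which(!is.finite(values))[1L])
  if (strict && identical(units, "R*/s") && any(values < 0))
    stop("stimulus traces (units 'R*/s') must be nonnegative; ",
         "first negative sample at index ", which(values < 0)[1L])
  structure(list(values = values, dt = as.numeric(dt), units = units),
            class = "ptrace")
}

#' Time axis of a trace
#'
#' @param x A \code{"ptrace"}.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "ptrace"))
  (seq_along(x$values) - 1) * x$dt
}

#' @export
print.ptrace <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<trace> %d samples, dt = %g s (%.4g s), units = %s\n",
              n, x$dt, n * x$dt, x$units))
  cat(sprintf("  range [%.6g, %.6g], mean %.6g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
length.ptrace <- function(x) length(x$values)

#' @export
as.data.frame.ptrace <- function(x, ...) {
  data.frame(time_s = trace_time(x), value = x$values)
}

# Coerce numeric input to a trace, or pass a trace through (internal).
as_trace <- function(x, dt = NULL, units = "a.u.", strict = TRUE) {
  if (inherits(x, "ptrace")) return(x)
  if (is.null(dt)) stop("`dt` is required when passing a bare numeric vector")
  new_trace(x, dt, units, strict = strict)
}

#' Read / write traces as delimited text
#'
#' Traces are stored as plain text: a header block of \code{# key: value}
#' lines (at least \code{units} and \code{dt}; optionally \code{cell_type},
#' \code{seed}, and free-form provenance), followed by a two-column body
#' \code{time_s value}. Values are serialized at full precision, so
#' \code{write_trace()} then \code{read_trace()} reproduces the samples
#' bit-exactly.
#'
#' @param path File path.
#' @return \code{read_trace()} returns a \code{"ptrace"}; header fields
#'   other than \code{units}/\code{dt} are attached as attributes.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  hdr_idx <- grep("^#", lines)
  if (length(hdr_idx) && !identical(hdr_idx, seq_along(hdr_idx)))
    stop("malformed trace file: header lines ('#') must precede the body")
  header <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) header[[m[2L]]] <- trimws(m[3L])
  }
  required <- c("units", "dt")
  missing_keys <- setdiff(required, names(header))
  if (length(missing_keys))
    stop("trace header is missing required key(s): ",
         paste(missing_keys, collapse = ", "),
         " (required: ", paste(required, collapse = ", "), ")")
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  body <- body[nzchar(trimws(body))]
  if (length(body) && grepl("^\\s*time_s\\b", body[1L])) body <- body[-1L]
  if (!length(body)) stop("trace file has no data rows: ", path)
  dat <- utils::read.table(text = body, col.names = c("time_s", "value"),
                           colClasses = "numeric")
  dt <- as.numeric(header$dt)
  if (!is.finite(dt) || dt <= 0) stop("invalid dt in header: ", header$dt)
  expected <- (seq_len(nrow(dat)) - 1) * dt
  bad <- which(abs(dat$time_s - expected) > 1e-9)
  if (length(bad))
    stop("irregular sampling: row ", bad[1L], " has time ", dat$time_s[bad[1L]],
         " but header dt = ", dt, " implies ", expected[bad[1L]])
  tr <- new_trace(dat$value, dt, header$units,
                  strict = !identical(header$strict, "false"))
  for (key in setdiff(names(header), c("units", "dt", "strict")))
    attr(tr, key) <- header[[key]]
  tr
}

#' @param trace A \code{"ptrace"} to serialize.
#' @param extra Named character list of additional header fields.
#' @rdname read_trace
#' @export
write_trace <- function(trace, path, extra = list()) {
  stopifnot(inherits(trace, "ptrace"))
  hdr <- c("# photoclamp trace v1",
           sprintf("# units: %s", trace$units),
           sprintf("# dt: %s", formatC(trace$dt, digits = 17, format = "g")))
  if (identical(trace$units, "R*/s") && any(trace$values < 0))
    hdr <- c(hdr, "# strict: false")
  for (key in names(extra))
    hdr <- c(hdr, sprintf("# %s: %s", key, as.character(extra[[key]])))
  body <- sprintf("%s %s",
                  formatC(trace_time(trace), digits = 17, format = "g"),
                  formatC(trace$values, digits = 17, format = "g"))
  writeLines(c(hdr, "time_s value", body), path)
  invisible(path)
}
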