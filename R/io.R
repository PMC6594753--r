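#' Read and write current traces as delimited text
#'
#' Traces are stored as two-column whitespace-delimited text (time_s, then
#' the current or normalized-current column) with optional `#`-prefixed
#' header lines of the form `# key: value`; a `protocol` header holds the
#' drug protocol as inline JSON. The round trip is lossless at full double
#' precision (17 significant digits).
#'
#' @param path File path.
#' @param data For writing: a data frame whose first two columns are time and
#'   signal (e.g. an [integrate_protocol()] or [sim_macroscopic_trace()]
#'   output).
#' @param metadata Named list of header fields to write; a `drug_protocol`
#'   element is serialized as JSON.
#'
#' @return `read_trace()`: a tibble with the file's two columns and any
#'   headers in attribute `"metadata"` (a parsed `protocol` becomes a
#'   [drug_protocol()]); `write_trace()`: the path, invisibly.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_head <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[is_head]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  body <- lines[!is_head & nzchar(trimws(lines))]
  if (length(body) == 0) abort(sprintf("no data rows in '%s'", path))
  header <- strsplit(trimws(body[1]), "\\s+")[[1]]
  has_names <- suppressWarnings(any(is.na(as.numeric(header))))
  start <- if (has_names) 2L else 1L
  cols <- if (has_names) header else c("time_s", "value")
  rows <- body[seq.int(start, length(body))]
  parsed <- strsplit(trimws(rows), "\\s+")
  bad <- which(vapply(parsed, function(p) {
    length(p) != length(cols) || suppressWarnings(any(is.na(as.numeric(p))))
  }, logical(1)))
  if (length(bad) > 0) {
    line_no <- which(!is_head)[if (has_names) bad + 1L else bad]
    abort(sprintf("malformed row(s) in '%s' at line(s) %s", path,
                  paste(line_no, collapse = ", ")))
  }
  m <- do.call(rbind, lapply(parsed, as.numeric))
  out <- as_tibble(setNames(as.data.frame(m), cols))
  if (!is.null(meta$protocol)) {
    pj <- jsonlite::fromJSON(meta$protocol)
    meta$protocol <- drug_protocol(pj$duration_s, pj$conc_M)
  }
  attr(out, "metadata") <- meta
  out
}

#' @rdname read_trace
#' @export
write_trace <- function(data, path, metadata = list()) {
  proto <- attr(data, "protocol")
  if (!is.null(proto) && is.null(metadata$protocol)) metadata$protocol <- proto
  scheme <- attr(data, "scheme")
  if (!is.null(scheme) && is.null(metadata$scheme)) metadata$scheme <- scheme
  lines <- character(0)
  for (nm in names(metadata)) {
    v <- metadata[[nm]]
    v <- if (inherits(v, "drug_protocol") || is.data.frame(v)) {
      as.character(jsonlite::toJSON(as.data.frame(v), digits = NA))
    } else if (inherits(v, "gating_params")) {
      as.character(jsonlite::toJSON(v[!vapply(v, is.null, logical(1))],
                                    auto_unbox = TRUE, digits = NA))
    } else {
      paste(format(v, digits = 17), collapse = " ")
    }
    lines <- c(lines, sprintf("# %s: %s", nm, v))
  }
  df <- as.data.frame(data)[, 1:2]
  lines <- c(lines, paste(names(df), collapse = "\t"),
             paste(format(df[[1]], digits = 17, trim = TRUE, scientific = FALSE),
                   format(df[[2]], digits = 17, trim = TRUE),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write drug protocols as JSON
#'
#' A protocol serializes as a JSON array of `{duration_s, conc_M}` objects.
#'
#' @param protocol A [drug_protocol()].
#' @param path File path.
#' @return `read_protocol()`: a [drug_protocol()]; `write_protocol()`: the
#'   path, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  protocol <- check_protocol(protocol)
  jsonlite::write_json(as.data.frame(protocol), path, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  pj <- jsonlite::fromJSON(path)
  drug_protocol(pj$duration_s, pj$conc_M)
}

#' Read and write idealized event lists
#'
#' Event lists are stored as two-column delimited text (`level`,
#' `duration_s`) with `# dead_time_s:` and `# n_channels:` headers.
#'
#' @param events An `event_list`.
#' @param path File path.
#' @return `read_events()`: an `event_list`; `write_events()`: the path,
#'   invisibly.
#' @export
write_events <- function(events, path) {
  check_events(events)
  lines <- c(sprintf("# dead_time_s: %s",
                     format(attr(events, "dead_time"), digits = 17)),
             sprintf("# n_channels: %d", attr(events, "n_channels")),
             "level\tduration_s",
             paste(events$level,
                   format(events$duration_s, digits = 17, trim = TRUE),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  raw <- read_trace(path)
  meta <- attr(raw, "metadata")
  new_event_list(raw$level, raw$duration_s,
                 dead_time = as.numeric(meta$dead_time_s %||% 0),
                 n_channels = as.integer(meta$n_channels %||% 1))
}

#' Write an ensemble-fit result as self-describing JSON
#'
#' Serializes a [fit_ensemble()] result together with every fixed constant
#' that entered the fit (partition ratio, compartment volume, channel count,
#' integration step, seed), so the file alone reproduces the analysis.
#'
#' @param fit An `ensemble_fit`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  if (!inherits(fit, "ensemble_fit")) abort("`fit` must be an ensemble_fit")
  p <- fit$params
  out <- list(
    scheme = fit$config$scheme,
    params = list(k_in = p$k_in, k_out = p$k_out, k_on = p$k_on,
                  k_off = p$k_off, k_flip = p$k_flip, po_ratio = p$po_ratio,
                  c_t = p$c_t),
    derived = as.list(fit$derived),
    sse = fit$sse,
    converged = fit$converged,
    n_evaluations = fit$n_evaluations,
    constants = list(d_ratio = fit$config$d_ratio,
                     volume_L = fit$config$volume,
                     n_channels = fit$config$n_channels,
                     dt_s = fit$config$dt,
                     seed = fit$config$seed)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read and write dose-response tables
#'
#' Dose-response tables are tab-delimited text with columns `conc_M`,
#' `stimulation`, and optionally `sem`, `n`.
#'
#' @param data A dose-response tibble.
#' @param path File path.
#' @return `read_dose_response()`: a tibble; `write_dose_response()`: the
#'   path, invisibly.
#' @export
write_dose_response <- function(data, path) {
  utils::write.table(as.data.frame(data), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t"))
}
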