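#' Read a GROMACS .xvg time-series file
#'
#' Lines starting `#` are comments; lines starting `@` are Grace directives,
#' parsed for axis and legend labels into the metadata. The remaining lines
#' are whitespace-separated numeric columns with time first. The time unit
#' is assumed to be ps (the GROMACS default) and converted to ns, unless an
#' `@ xaxis label` names ns or the caller overrides it.
#'
#' @param path file path.
#' @param time_unit `"auto"`, `"ps"` or `"ns"`.
#' @return data.frame with `time` (ns) plus one named column per data
#'   series (legend names when present, else `y1`, `y2`, ...); metadata in
#'   attributes `title`, `xaxis`, `yaxis`, `source_time_unit`.
#' @export
read_xvg <- function(path, time_unit = c("auto", "ps", "ns")) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(lines, "#")
  is_meta <- startsWith(lines, "@")
  meta <- lines[is_meta]
  data_lines <- lines[!is_comment & !is_meta & nzchar(trimws(lines))]
  if (!length(data_lines)) stop("no data rows in ", path, call. = FALSE)
  grab <- function(pattern) {
    m <- regmatches(meta, regexec(pattern, meta))
    hits <- vapply(m, length, 1L) > 1L
    if (any(hits)) m[[which(hits)[1L]]][2L] else NA_character_
  }
  title <- grab('^@\\s*title\\s+"([^"]*)"')
  xaxis <- grab('^@\\s*xaxis\\s+label\\s+"([^"]*)"')
  yaxis <- grab('^@\\s*yaxis\\s+label\\s+"([^"]*)"')
  leg_m <- regmatches(meta, regexec('^@\\s*s(\\d+)\\s+legend\\s+"([^"]*)"', meta))
  legends <- Filter(function(x) length(x) == 3L, leg_m)
  parsed <- strsplit(trimws(data_lines), "\\s+")
  ncol <- length(parsed[[1L]])
  bad <- which(vapply(parsed, length, 1L) != ncol)
  line_no <- function(i) which(!is_comment & !is_meta &
                                 nzchar(trimws(lines)))[i]
  if (length(bad))
    stop(sprintf("ragged row at line %d of %s", line_no(bad[1L]), path),
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(parsed)))
  if (anyNA(vals)) {
    bad_row <- ceiling(which(is.na(vals))[1L] / ncol)
    stop(sprintf("non-numeric value at line %d of %s", line_no(bad_row), path),
         call. = FALSE)
  }
  m <- matrix(vals, ncol = ncol, byrow = TRUE)
  unit <- if (time_unit == "auto") {
    if (!is.na(xaxis) && grepl("\\(ns\\)", xaxis)) "ns" else "ps"
  } else time_unit
  time <- if (unit == "ps") m[, 1L] / 1000 else m[, 1L]
  out <- data.frame(time = time)
  cn <- paste0("y", seq_len(ncol - 1L))
  for (lg in legends) {
    k <- as.integer(lg[2L]) + 1L
    if (k <= length(cn)) cn[k] <- lg[3L]
  }
  for (j in seq_len(ncol - 1L)) out[[cn[j]]] <- m[, j + 1L]
  attr(out, "title") <- title
  attr(out, "xaxis") <- xaxis
  attr(out, "yaxis") <- yaxis
  attr(out, "source_time_unit") <- unit
  out
}

#' Write a time-series table as a GROMACS-compatible .xvg file
#'
#' @param x data.frame with `time` (ns) first plus numeric columns.
#' @param path output path.
#' @param title,xaxis,yaxis Grace labels; column names become legends.
#' @param time_unit unit to write the time column in.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(x, path, title = "", xaxis = "Time (ns)",
                      yaxis = "", time_unit = c("ns", "ps")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.data.frame(x), names(x)[1L] == "time")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# written by sfgating",
               sprintf('@    title "%s"', title),
               sprintf('@    xaxis  label "%s"',
                       if (time_unit == "ns") sub("\\(ps\\)", "(ns)", xaxis)
                       else sub("\\(ns\\)", "(ps)", xaxis)),
               sprintf('@    yaxis  label "%s"', yaxis)), con)
  cols <- names(x)[-1L]
  writeLines(sprintf('@ s%d legend "%s"', seq_along(cols) - 1L, cols), con)
  t_out <- if (time_unit == "ps") x$time * 1000 else x$time
  m <- cbind(t_out, as.matrix(x[, -1L, drop = FALSE]))
  writeLines(apply(format(m, digits = 9, scientific = FALSE, trim = TRUE),
                   1L, paste, collapse = "  "), con)
  invisible(path)
}

#' Read a current trace from a two-column delimited file
#'
#' Columns are time and current (pA); a header row is detected and skipped.
#' The sampling rate is inferred from the median time step; non-uniform
#' sampling (relative spread above 1e-6) is rejected.
#'
#' @param path file path (TSV or CSV; the delimiter is sniffed).
#' @param time_unit unit of the time column, `"s"` or `"ms"`.
#' @param filter_cutoff optional filter cutoff (Hz) to record on the trace.
#' @return a [current_trace()].
#' @export
read_trace_csv <- function(path, time_unit = c("s", "ms"),
                           filter_cutoff = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- is.na(suppressWarnings(as.numeric(strsplit(
    trimws(first), if (sep == ",") "," else "\\s+")[[1L]][1L])))
  d <- utils::read.table(path, header = header, sep = sep)
  if (ncol(d) < 2L) stop("need two columns (time, current)", call. = FALSE)
  if (nrow(d) < 2L) stop("need >= 2 samples", call. = FALSE)
  t <- as.numeric(d[[1L]]); cur <- as.numeric(d[[2L]])
  if (anyNA(t) || anyNA(cur)) stop("non-numeric payload", call. = FALSE)
  if (time_unit == "ms") t <- t / 1000
  dt <- diff(t)
  mdt <- stats::median(dt)
  if (mdt <= 0 || any(abs(dt - mdt) > 1e-6 * mdt))
    stop("non-uniform sampling; resample the trace first", call. = FALSE)
  current_trace(cur, sampling_rate = 1 / mdt, filter_cutoff = filter_cutoff,
                t0 = t[1L])
}

#' Write a current trace as two-column TSV
#'
#' @param trace a [current_trace()].
#' @param path output path; columns `time_s`, `current_pA`.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "current_trace"))
  d <- data.frame(time_s = format(trace_times(trace), digits = 12,
                                  scientific = FALSE, trim = TRUE),
                  current_pA = format(trace$current, digits = 9, trim = TRUE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an idealized event table
#'
#' CSV with columns `level`, `start`, `duration`, `amplitude` (seconds and
#' pA), numeric round trip lossless to 9 significant digits; `n_levels` and
#' `dead_time` travel in `#`-prefixed header comments.
#'
#' @param events an [event_list()].
#' @param path file path.
#' @return `path` invisibly (write); an [event_list()] (read).
#' @export
write_event_table <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_levels=%d", attr(events, "n_levels")),
               sprintf("# dead_time=%.12g", attr(events, "dead_time")),
               "level,start,duration,amplitude"), con)
  if (nrow(events)) {
    fmt <- function(x) ifelse(is.na(x), "NA",
                              format(x, digits = 12, scientific = TRUE,
                                     trim = TRUE))
    writeLines(paste(events$level, fmt(events$start), fmt(events$duration),
                     fmt(events$amplitude), sep = ","), con)
  }
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^#\\s*", key, "="), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^#\\s*", key, "="), "", hit[1L]))
    else default
  }
  header <- strsplit(body[1L], ",")[[1L]]
  expected <- c("level", "start", "duration", "amplitude")
  if (!identical(header, expected))
    stop("unknown column(s): ", paste(setdiff(header, expected),
                                      collapse = ", "), call. = FALSE)
  if (length(body) < 2L)
    return(event_list(n_levels = as.integer(get_meta("n_levels", 1)),
                      dead_time = get_meta("dead_time", NA_real_)))
  d <- utils::read.csv(text = body)
  if (any(!is.finite(d$duration)) || any(d$duration <= 0))
    stop("invalid duration (must be > 0) in ", path, call. = FALSE)
  event_list(level = d$level, start = d$start, duration = d$duration,
             amplitude = d$amplitude,
             n_levels = as.integer(get_meta("n_levels", max(d$level, 1))),
             dead_time = get_meta("dead_time", NA_real_))
}

#' Write an analysis result document as JSON
#'
#' @param x a named list of results.
#' @param path output path.
#' @param schema_version schema tag written alongside the payload.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(x, path, schema_version = "1.0") {
  doc <- c(list(schema_version = schema_version), x)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
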