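#' Read a unit audit-log export
#'
#' Reads a central-station audit-log export (CSV/TSV or XLSX) into a tibble of
#' audit records. The export dialect has columns Date, Bed label, MRN,
#' "Alarm and Action" and Device name; MRN may be absent (some exports omit
#' it) or masked to all zeros. Timestamps in either `M/D/YY H:MM:SS` or
#' `M/D/YY H:MM` form (missing seconds read as `:00`) are normalized to a
#' single POSIXct (UTC) representation; ISO-8601 timestamps, as written by
#' [write_normalized()], are also accepted, so write-then-read is the
#' identity.
#'
#' Two-digit years map to 2000--2099 (these central stations postdate 2000).
#' Typographic noise is removed from the message text before storage:
#' footnote markers of the form `^x^`, smart quotes, and the Unicode minus
#' sign are normalized to plain ASCII; subscript markup such as `SpO_2_`
#' collapses to `SpO2`. Encoding is UTF-8 with a Latin-1 fallback.
#'
#' @param source Path to a CSV, TSV or XLSX export file.
#' @param dialect Optional format hint: `"csv"`, `"tsv"` or `"xlsx"`.
#'   Default `NULL` sniffs the delimiter (and the extension for XLSX).
#' @param sheet Sheet to read from an XLSX source (default first).
#' @param on_error How to treat rows whose timestamp cannot be parsed:
#'   `"skip"` (default) drops them with a warning and records them in the
#'   `"skipped"` attribute; `"strict"` raises an error naming the row.
#' @param dedupe Drop consecutive identical rows? Devices may legitimately
#'   emit duplicates, so the default is `FALSE`.
#'
#' @return A tibble with one row per data row, in file order, and columns
#'   `timestamp` (POSIXct, UTC), `bed_label`, `mrn`, `raw_message`,
#'   `device_name`, `row_index`. An empty export yields a zero-row tibble.
#' @export
#' @examples
#' path <- system.file("extdata", "unit_log_example.csv", package = "alarmaudit")
#' log <- read_audit_log(path)
#' head(log)
read_audit_log <- function(source, dialect = NULL, sheet = 1,
                           on_error = c("skip", "strict"), dedupe = FALSE) {
  on_error <- match.arg(on_error)
  if (!file.exists(source)) {
    stop("cannot read audit log: no such file: ", source, call. = FALSE)
  }

  is_xlsx <- identical(dialect, "xlsx") ||
    (is.null(dialect) && grepl("\\.xlsx?$", source, ignore.case = TRUE))
  raw <- if (is_xlsx) read_cells_xlsx(source, sheet) else read_cells_text(source, dialect)

  if (nrow(raw) == 0) {
    return(empty_audit_log())
  }

  cols <- locate_columns(raw)
  if (cols$has_header) raw <- raw[-1, , drop = FALSE]
  if (nrow(raw) == 0) {
    return(empty_audit_log())
  }

  get_col <- function(idx) {
    if (is.na(idx)) rep(NA_character_, nrow(raw)) else as.character(raw[[idx]])
  }
  out <- tibble::tibble(
    timestamp = parse_log_timestamp(get_col(cols$timestamp)),
    bed_label = str_trim2(get_col(cols$bed_label)),
    mrn = str_trim2(get_col(cols$mrn)),
    raw_message = normalize_message_text(get_col(cols$message)),
    device_name = str_trim2(get_col(cols$device_name)),
    row_index = seq_len(nrow(raw))
  )

  bad <- which(is.na(out$timestamp) | is.na(out$raw_message) | out$raw_message == "")
  if (length(bad) > 0) {
    if (on_error == "strict") {
      stop("unparseable audit-log row(s) at source row ", paste(bad, collapse = ", "),
           " in ", source, call. = FALSE)
    }
    warning("skipped ", length(bad), " unparseable audit-log row(s): ",
            paste(head(bad, 10), collapse = ", "), call. = FALSE)
    skipped <- out[bad, ]
    out <- out[-bad, ]
    out$row_index <- seq_len(nrow(out))
    attr(out, "skipped") <- skipped
  }
  if (dedupe && nrow(out) > 1) {
    same <- vapply(seq_len(nrow(out))[-1], function(i) {
      identical(out[i, -6], out[i - 1, -6])
    }, logical(1))
    out <- out[c(TRUE, !same), ]
    out$row_index <- seq_len(nrow(out))
  }
  out
}

empty_audit_log <- function() {
  tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    bed_label = character(), mrn = character(),
    raw_message = character(), device_name = character(),
    row_index = integer()
  )
}

read_cells_text <- function(source, dialect) {
  bytes <- readBin(source, "raw", n = file.size(source))
  txt <- rawToChar(bytes)
  if (!all(validUTF8(txt))) {
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  }
  Encoding(txt) <- "UTF-8"
  if (nchar(str_trim2(txt)) == 0) {
    return(tibble::tibble())
  }
  delim <- if (identical(dialect, "tsv")) "\t" else if (identical(dialect, "csv")) "," else {
    first <- strsplit(txt, "\r?\n")[[1]][1]
    if (stringr::str_count(first, "\t") >= stringr::str_count(first, ",")  &&
        grepl("\t", first)) "\t" else ","
  }
  readr::read_delim(I(txt), delim = delim, col_names = FALSE,
                    col_types = readr::cols(.default = "c"),
                    trim_ws = TRUE, progress = FALSE,
                    show_col_types = FALSE)
}

read_cells_xlsx <- function(source, sheet) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading XLSX requires the 'readxl' package", call. = FALSE)
  }
  df <- readxl::read_excel(source, sheet = sheet, col_names = FALSE,
                           col_types = "text", .name_repair = "minimal")
  tibble::as_tibble(df, .name_repair = "minimal")
}

# Identify columns by header text when present, else by position
# (5 columns: Date/Bed/MRN/Message/Device; 4 columns: MRN absent).
locate_columns <- function(raw) {
  first <- tolower(str_trim2(as.character(unlist(raw[1, ], use.names = FALSE))))
  find <- function(pattern) {
    hit <- which(grepl(pattern, first))
    if (length(hit) > 0) hit[1] else NA_integer_
  }
  ts_col <- find("^date$|^date.?time$|^timestamp$")
  header_like <- !is.na(ts_col) || any(grepl("alarm|action|message", first))
  if (header_like) {
    list(
      has_header = TRUE,
      timestamp = if (!is.na(ts_col)) ts_col else find("date|time"),
      bed_label = find("bed"),
      mrn = find("mrn|record"),
      message = find("alarm|action|message"),
      device_name = find("device")
    )
  } else {
    n <- ncol(raw)
    if (n >= 5) {
      list(has_header = FALSE, timestamp = 1L, bed_label = 2L, mrn = 3L,
           message = 4L, device_name = 5L)
    } else if (n == 4) {
      list(has_header = FALSE, timestamp = 1L, bed_label = 2L, mrn = NA_integer_,
           message = 3L, device_name = 4L)
    } else {
      stop("audit-log export must have at least 4 columns, found ", n, call. = FALSE)
    }
  }
}

#' Normalize audit-log timestamps
#'
#' Accepts the export forms `M/D/YY H:MM:SS` and `M/D/YY H:MM` (seconds
#' default to `:00`), four-digit-year variants, and ISO-8601
#' (`YYYY-MM-DDTHH:MM:SS` or with a space). Two-digit years are pivoted to
#' 2000--2099. Already-parsed POSIXct input passes through unchanged, so
#' normalization is idempotent.
#'
#' @param x Character (or POSIXct) vector of timestamps.
#' @return POSIXct vector (UTC); `NA` where unparseable.
#' @export
parse_log_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- str_trim2(as.character(x))
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))

  mdy <- stringr::str_match(
    x, "^(\\d{1,2})/(\\d{1,2})/(\\d{2,4})[ T](\\d{1,2}):(\\d{2})(?::(\\d{2}))?$")
  ok <- !is.na(mdy[, 1])
  if (any(ok)) {
    yr <- as.integer(mdy[ok, 4])
    yr <- ifelse(yr < 100, 2000L + yr, yr)
    out[ok] <- ISOdatetime(
      yr, as.integer(mdy[ok, 2]), as.integer(mdy[ok, 3]),
      as.integer(mdy[ok, 5]), as.integer(mdy[ok, 6]),
      ifelse(is.na(mdy[ok, 7]), 0L, as.integer(mdy[ok, 7])), tz = "UTC")
  }

  iso <- stringr::str_match(
    x, "^(\\d{4})-(\\d{2})-(\\d{2})[ T](\\d{2}):(\\d{2})(?::(\\d{2}))?Z?$")
  ok <- !is.na(iso[, 1]) & is.na(out)
  if (any(ok)) {
    out[ok] <- ISOdatetime(
      as.integer(iso[ok, 2]), as.integer(iso[ok, 3]), as.integer(iso[ok, 4]),
      as.integer(iso[ok, 5]), as.integer(iso[ok, 6]),
      ifelse(is.na(iso[ok, 7]), 0L, as.integer(iso[ok, 7])), tz = "UTC")
  }
  out
}

#' Clean message text of typographic noise
#'
#' Strips footnote markers (`^x^`), normalizes smart quotes and the Unicode
#' minus/dashes to ASCII, collapses subscript markup (`SpO_2_` to `SpO2`),
#' and trims whitespace. Idempotent.
#'
#' @param x Character vector of raw "Alarm and Action" cells.
#' @return Cleaned character vector.
#' @export
normalize_message_text <- function(x) {
  x <- as.character(x)
  x <- stringr::str_replace_all(x, "\\^[A-Za-z0-9]{1,3}\\^", "")
  x <- stringr::str_replace_all(x, "[−–—]", "-")
  x <- stringr::str_replace_all(x, "[‘’]", "'")
  x <- stringr::str_replace_all(x, "[“”]", "\"")
  # subscript/superscript markup: SpO_2_ -> SpO2
  x <- stringr::str_replace_all(x, "_([A-Za-z0-9]+)_", "\\1")
  x <- stringr::str_replace_all(x, "\\s+", " ")
  str_trim2(x)
}

#' Write audit records in the canonical normalized dialect
#'
#' Writes a CSV with header `date,bed_label,mrn,message,device_name` and
#' ISO-8601 timestamps. [read_audit_log()] on the result reproduces the
#' input records field-for-field, and repeated writes of the same records
#' are byte-identical.
#'
#' @param records Tibble of audit records as returned by [read_audit_log()].
#' @param sink Output file path.
#' @return `sink`, invisibly.
#' @export
write_normalized <- function(records, sink) {
  stopifnot(all(c("timestamp", "bed_label", "mrn", "raw_message", "device_name")
                %in% names(records)))
  out <- tibble::tibble(
    date = format(records$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    bed_label = records$bed_label,
    mrn = records$mrn,
    message = records$raw_message,
    device_name = records$device_name
  )
  tryCatch(
    readr::write_csv(out, sink, progress = FALSE),
    error = function(e) stop("cannot write normalized log to ", sink, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  invisible(sink)
}

str_trim2 <- function(x) stringr::str_trim(x)
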