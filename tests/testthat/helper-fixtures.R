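fixture_path <- function(name) {
  system.file("extdata", name, package = "alarmaudit", mustWork = TRUE)
}

unit_log_events <- function() {
  parse_events(read_audit_log(fixture_path("unit_log_example.csv")))
}

desat_limit_events <- function() {
  parse_events(read_audit_log(fixture_path("desat_limit_examples.csv")))
}

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

# build a parsed-event tibble directly from message strings
events_from_messages <- function(messages, timestamps,
                                 bed_label = "9115-S1", mrn = "0000000",
                                 device_name = "PIIC iX: ixsurv006") {
  n <- length(messages)
  parse_events(tibble::tibble(
    timestamp = rep(parse_log_timestamp(timestamps), length.out = n),
    bed_label = rep_len(bed_label, n),
    mrn = rep_len(mrn, n),
    raw_message = messages,
    device_name = rep_len(device_name, n),
    row_index = seq_len(n)
  ))
}
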