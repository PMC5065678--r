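Package: alarmaudit
Title: Alarm-Safety Analytics for Physiologic Monitor Audit Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the audit log exported by central-station
    physiologic monitoring systems (Philips IntelliVue / PIIC iX dialect).
    Reads unit audit-log exports, parses the "Alarm and Action" message
    grammar (physiologic alarm priorities, numerical value/limit/direction
    fields, technical INOP alarms, sound events and the clinician action
    taxonomy), pairs generation/end events into alarm episodes with
    durations and censoring, computes alarm-rate and action reports with
    pre/post-intervention comparisons, audits logs for unsafe limit
    settings, priority inconsistencies and unit-configuration
    non-compliance, plans retrievals under the retention and window
    constraints of the Information Center, simulates the monitor's
    announcement priority chain, and generates synthetic audit logs with
    known ground truth so alarm-safety analyses are reproducible without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
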