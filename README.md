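# alarmaudit

Alarm-safety analytics for the audit logs of central-station physiologic
monitors (Philips IntelliVue / PIIC iX export dialect).

## The problem

Intensive-care monitors generate enormous volumes of alarms, and alarm
fatigue — clinician desensitization to the noise — is a recognized patient
safety hazard. The central station ("Information Center") keeps an audit
log: a chronological record of every alarm and every clinician interaction
with the monitors. That log is a far better data source than bedside
observation (complete, objective, time-stamped), but it is painful to work
with: the message text packs up to six variables into one cell, the
generation and end of an alarm are logged as two unconnected rows (and in
reversed order for alarms shorter than a second), storage is capped at 90
days and one retrieval at 50 days.

`alarmaudit` turns that export into analyzable data, for unit managers,
alarm-safety researchers and clinical engineers:

* **Parsing** — the "Alarm and Action" message grammar. Physiologic alarm
  priority is the leading star count (`*` advisory, `**` yellow, `***`
  red); technical INOP priority is the exclamation-mark count (none =
  soft, `!!` moderate, `!!!` hard). A numerical alarm message
  `**PAPd 18 >16 Generated.` carries parameter, triggering value,
  programmed limit, crossing direction and status; categorical alarms
  (arrhythmia classes, all INOPs) carry only a status. Sound events and
  the 21-category clinician action taxonomy (Silence, Pause/Resume, limit
  changes, transfers, ...) are recognized as their own event types.
* **Episodes** — each `Ended` row is matched to the nearest preceding
  unmatched `Generated` with the same (patient, bed, device, parameter,
  priority) key; sub-second inversions pair as zero-duration episodes and
  endpoints missing from the window are censored, so alarm duration — the
  proxy for clinician response time — is computable.
* **Metrics** — alarm rates per bed-day / patient-day / hour / minute by
  parameter, priority, bed or audibility; action summaries; pre/post
  intervention comparisons.
* **Audits** — observed alarm-limit extrema against a safe-range policy,
  inconsistent priorities for the same alarm condition, beds that missed a
  unit-wide settings change, and retrieval planning under the 90-day
  retention / 50-day window limits.
* **Announcement simulation** — the priority-chain behaviour that decides
  which of several concurrent alarms actually sounds (red > long yellow >
  short yellow > hard INOP > soft INOP, one announcement per chain, a
  10-alarm display cap, silence/pause semantics, latching red alarms).
* **Synthetic logs** — a seeded generator emitting realistic audit logs
  with known ground truth, so every pipeline stage is testable without
  patient data.

## Worked example

```r
library(alarmaudit)

log <- read_audit_log(system.file("extdata", "unit_log_example.csv",
                                  package = "alarmaudit"))
events <- parse_events(log)
pairing <- pair_episodes(events)
pairing$episodes[, c("bed_label", "parameter", "duration_s")]
#> # A tibble: 7 × 3
#>   bed_label parameter      duration_s
#>   <chr>     <chr>               <dbl>
#> 1 9115-S1   PAPd                    0
#> 2 9117-S1   RR                    100
#> 3 9115-S1   ABPs                   74
#> 4 9123-S1   Desat                   7
#> 5 9115-S1   Multiform PVCs         20
#> 6 9123-S1   ECG Leads Off          15
#> 7 9115-S1   PAPd                    0
```

The first PAPd row is the zero-duration episode the device logged
end-before-generation; the Desat alarm on bed 9123-S1 lasted 7 seconds
(generated at 0:01:05 with SpO₂ at 70%, ended at 0:01:12 at 73%). The
unmatched report lists the censored endpoints with their source rows.

Auditing the example of divergent Desat lower limits:

```r
desat <- parse_events(read_audit_log(system.file(
  "extdata", "desat_limit_examples.csv", package = "alarmaudit")))
scan_limit_settings(desat)$observed
#> # A tibble: 1 × 5
#>   parameter side  min_limit max_limit     n
#>   <chr>     <chr>     <dbl>     <dbl> <int>
#> 1 Desat     lower        50        90     6
```

A lower desaturation limit of 50% is plainly unsafe; feeding a safe-range
policy (`spec`) turns each offending (bed, limit) into a finding with its
source rows.

From a shell, the same pipeline is available as subcommands:

```sh
inst/cli/alarmaudit plan --days 90
#> 2 windows: 50 + 40 (span 90 days)
inst/cli/alarmaudit synth --seed 1 --output /tmp/log.csv
inst/cli/alarmaudit episodes --input /tmp/log.csv --output /tmp/episodes.csv
```

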