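---
title: "Audit-log alarm analytics: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Audit-log alarm analytics: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alarmaudit)
```

## What the package models

A central-station audit log is a chronological table with five columns:
timestamp, bed label, MRN (usually masked to zeros in exports), a free-text
"Alarm and Action" cell, and the Information Center host name. The free
text is the hard part: one cell encodes between three variables (priority,
parameter, status — for categorical alarms) and six (adding triggering
value, programmed limit and crossing direction — for numerical alarms),
plus sound events and a taxonomy of clinician actions. `alarmaudit` treats
the log as an event stream, parses each message into exactly one typed
variant, and builds everything else — episodes, rates, audits, simulations
— on top of that typed stream.

## The message grammar

Priority is encoded typographically: one to three leading asterisks for
physiologic alarms (advisory, yellow/moderate, red/high) and exclamation
marks for technical INOP alarms, where *no* mark means a soft INOP. Status
is a trailing `Generated`/`Ended`, matched case-insensitively because real
exports print both `Ended` and `ended`. Numerical messages match
`<marks> <parameter> <value> <comparator> <limit>`, with whitespace around
the comparator optional (`153>150` and `153 >150` both occur in practice).
Anything that matches no rule becomes an `unparsed` event that keeps its
raw text: the parser is total and never drops a row silently.

Decisions worth recording:

* **Open parameter vocabulary.** The parameter registry seeds the names a
  cardiac ICU actually sees (HR, RR, SpO2, Desat, Apnea, ABP/NBP/PAP
  variants, PVC classes, AFIB, the common INOPs), but an unknown parameter
  still parses generically. A closed enum would make the parser fail
  exactly where a new unit configuration makes it most needed.
* **Apnea.** The device prints apnea three ways: a plain `***Apnea`
  (categorical), `***Apnea X:YY` (a measured duration, stored as
  `apnea_seconds = 60·X + YY`), and `***Apnea > 20 sec` (a threshold
  flag). The latter two are classified as numerical — they report a
  measurement — but the measurement lives in `apnea_seconds` /
  `apnea_gt20` rather than value/limit/direction, and the `> 20` text is
  deliberately not read as a limit comparison. The invariant "numerical
  alarms carry value, limit and direction" therefore holds for every
  numerical parameter except Apnea, whose displays are genuinely
  different.
* **Typographic noise.** Exports that passed through documents can carry
  footnote markers (`^x^`), Unicode minus signs, smart quotes and
  subscript markup (`SpO_2_`). All are normalized before parsing, and the
  normalization is idempotent, so re-reading a normalized file changes
  nothing. Two-digit years pivot to 2000–2099; these central stations
  postdate 2000, so the ambiguity is theoretical.
* **Single-bound limit changes** (`SpO2: Desat Limit 78.`) are recorded as
  lower limits: the only single-bound settings message the export dialect
  prints programs the desaturation lower limit. Paired forms
  (`... High: 1.6 ... Low: -1.6`) keep both bounds with signs.

## Episode pairing

The log records alarm generation and end as separate rows, and for alarms
shorter than one second it records the end *first*. Pairing sorts events
by (identity, bed, device, parameter, priority, time, file order) and
matches each `Ended` to the nearest preceding unmatched `Generated` in its
key. An `Ended` with no open `Generated` pairs with a `Generated` in the
same second (the inversion path, yielding a zero-duration episode) or is
left-censored at the window start; a `Generated` never ended is
right-censored at the window end. Censored rows also appear in an
unmatched report so no anomaly is silent.

Choices made where the device documentation is silent:

* **Priority is part of the matching key.** The same parameter can alarm
  at different priorities (`*HR` vs `**HR` both occur); these are distinct
  audible experiences and are kept as distinct episode streams.
* **Masked MRNs** (all zeros) identify nothing, so identity falls back to
  bed + device. This makes "patient-days" coincide with "bed-days" on
  masked exports, which is reported as such.
* **Nearest-preceding (stack) matching** resolves overlapping same-key
  alarms. Whether the device ever reuses a single `Ended` for overlapping
  same-key conditions is unknowable from the log; nearest-preceding is the
  documented choice, and the test suite checks it against an exhaustive
  interval matcher (minimum censoring, no crossing intervals, minimum
  total duration, end-before-generation pairs only when nothing was open)
  on a thousand randomized small logs.
* **Audible reminders** are separate alarm events in the log and are kept
  separate; merging them into their parent episode would require latching
  configuration knowledge the log does not carry.

## Rates, actions, comparisons

The counting unit is the alarm generation event, matching how counts
appear in the log; episode-based counting is a flag. The default
denominator is bed-days inferred from observed bed-by-calendar-day pairs —
an approximation (a monitored but unoccupied bed contributes no exposure,
a partial day counts in full) documented in `?compute_rates`; a
user-supplied census number can replace it. The audible filter drops
soft INOPs, which have no sound. Pre/post comparisons split the stream at
a boundary, compute both sides with identical definitions, and report
absolute and percent deltas; an empty side is flagged as absent, never as
a zero rate. No hypothesis test is attached: published intervention
effects depend on a unit's real data, and the package deliberately reports
description, not inference.

## Safety audits

* **Limit scanning** harvests programmed limits from two sources: the
  limit field of numerical alarm messages (`< limit` reveals a lower
  bound, `> limit` an upper bound) and Alarm Limit Change actions. The
  safe-range policy ships empty: what counts as unsafe is clinical
  policy, so the tool never hard-codes thresholds.
* **Priority consistency** groups physiologic alarms by the condition
  signature (parameter, direction, limit) — the triggering circumstances
  held fixed while the star count varies — and technical alarms by INOP
  name alone, since INOP messages carry no limits. Two or more distinct
  levels in one signature is one finding.
* **Compliance** uses alarm occurrence as primary evidence — an alarm of a
  supposedly disabled type after the rollout date names the missed bed —
  with absence of the corresponding Alarm Off action available as
  stricter, opt-in secondary evidence (opt-in because an action logged
  before the retrieval window is invisible, so absence is weak evidence).
* **Retrieval planning** is arithmetic under the device's constraints:
  windows of at most 50 days and at least 15 minutes, greedily 50-day
  windows plus a remainder (a remainder under 15 minutes folds into the
  last window), and spans beyond the 90-day retention period flagged as
  requiring prospective scheduled pulls.

## The announcement simulator

Concurrent alarms compete: the monitor groups them into chains (PVC, beat
detection, rate; everything else independent), announces only the top
alarm per chain, and resolves equal severity across chains to the more
recent alarm. The severity ladder is red > long yellow > short yellow >
hard INOP > soft INOP; a long yellow outranks short yellows only in the
presence of another yellow or INOP, otherwise it behaves as an ordinary
yellow. Two classes the ladder does not place — advisory (`*`) physiologic
alarms and moderate (`!!`) INOPs — are slotted between their neighbours,
patient-related above technical; both slots are registry-visible
decisions. The display list holds at most ten alarms ordered by severity
then recency. Silencing acknowledges the announced alarm (audio off,
display kept); pausing suppresses audio for one or two minutes or
indefinitely, and a site configuration limits the pause to yellow alarms
so reds keep sounding. Latching alarms — red alarms such as asystole and
ventricular fibrillation — keep sounding after their condition resolves
until explicitly silenced. Chain membership, latching and yellow-length
classes are registry data with documented defaults, overridable per site,
because the vendor names the classes but not their full membership.

The arrhythmia registries expose 10 classes in basic mode and 13 more in
enhanced mode; beyond the handful of vendor-named classes, the remaining
entries are standard arrhythmia classes chosen as placeholders and
flagged as such in `?default_registry`.

## The synthetic generator

`generate_log()` emulates the record mix of a real unit export: numerical
yellow/red limit alarms, categorical advisory arrhythmias, a soft and a
moderate INOP, sound events after audible generations, and interleaved
clinician actions, all stamped with masked MRNs. Events are Poisson per
parameter and bed; the default catalogue (62 events/bed-day across 11
parameters, 20 beds) is of the order a busy cardiac ICU logs. Episode
durations are exponential with a 30-second mean plus a 10% sub-second
fraction that reproduces the end-before-generation inversion; same-stream
episodes never overlap, because a condition cannot regenerate while its
alarm is active. Planted anomalies (unsafe limits, split priorities,
disabled-alarm occurrences, connectivity gaps) are recorded in a ground
truth manifest, and the seed fully determines the output.

What the generator does *not* emulate: physiologic trajectories (values
are limit-plus-noise, not vital signs), clinician behaviour correlated
with alarms (actions are independent Poisson), bed transfers mid-episode,
or latching audio in the emitted log. Tests passing on synthetic data
therefore demonstrate the pipeline's bookkeeping — parsing fidelity,
pairing correctness, rate recovery — not clinical realism.

## Problem sizes and numerical choices

The test suite runs the full round-trip on 100 seeded small-unit logs
(2 beds, 6 hours), checks pairing against the exhaustive matcher on 1,000
randomized logs of at most 50 events, and recovers a planted halving of
all alarm rates (about −50%) within three Monte-Carlo standard errors on
a combined stream of over 10,000 alarm events (20 beds, 5.5 days per
period). Rate-recovery checks use three-standard-error bands under the
Poisson model. Timestamps are held at one-second resolution throughout,
matching the export; durations are therefore integers of seconds and a
sub-second alarm has duration zero, not a fraction.

## Known limitations

* The export dialect's delimiter, header text and encoding are not
  standardized; the reader sniffs CSV/TSV and accepts XLSX, but unusual
  exports may need the explicit `dialect` hint.
* Bed transfers are reported as actions, not resolved into patient
  identity across beds.
* "Patient days" equal bed-days whenever MRNs are masked.
* The vendor's non-editable hard stops (TachyClamp, BradyClamp, ...) are
  listed in the registry as unchangeable settings but not modeled
  quantitatively, and Smart Alarm Delay timing is a configuration
  passthrough only.
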