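#' Default alarm registry
#'
#' The registry is configuration data describing the monitor vocabulary the
#' parser and simulator work against: known parameter names, the arrhythmia
#' class sets of the basic and enhanced analysis modes, the clinician action
#' taxonomy, audibility flags, announcement-chain membership, latching
#' alarms, and yellow-alarm length classes. It is an open vocabulary:
#' unknown parameters still parse generically, and every list here can be
#' overridden from a YAML file via [read_registry()].
#'
#' The basic arrhythmia analysis mode exposes 10 alarm classes and the
#' enhanced mode adds 13 more. The vendor documents only a handful of class
#' names (asystole, ventricular fibrillation, ventricular tachycardia for
#' basic; nonsustained ventricular tachycardia, supraventricular
#' tachycardia, run PVCs for enhanced); the remaining entries are standard
#' arrhythmia classes chosen as documented placeholders and can be replaced
#' per site.
#'
#' Soft INOP technical alarms carry no sound, so audibility is a function of
#' event family and priority, not a fixed per-message attribute.
#'
#' @return A named list with elements `parameters`, `arrhythmia_basic`,
#'   `arrhythmia_enhanced`, `actions`, `chains`, `latching`, `yellow_long`,
#'   `hard_stops`, `inaudible`.
#' @export
#' @examples
#' reg <- default_registry()
#' length(reg$arrhythmia_basic)   # 10 classes in basic mode
#' length(reg$arrhythmia_enhanced) # 13 additional classes in enhanced mode
default_registry <- function() {
  list(
    # open vocabulary of alarming parameters; unknown names parse generically
    parameters = c(
      "HR", "RR", "SpO2", "Desat", "Apnea", "NBP", "NBPs", "NBPd",
      "ABP", "ABPs", "ABPd", "ABPm", "PAP", "PAPs", "PAPd", "PAPm",
      "PVCs/min", "ST", "Temp", "etCO2",
      "Multiform PVCs", "Pair PVCs", "Paired PVCs", "Run PVCs High",
      "AFIB", "Irregular Heart Rate", "Pause",
      "ECG Leads Off", "Leads Off", "Check Patient ID", "Check Equipment",
      "Batt Empty", "Noisy ECG"
    ),
    # 10 classes analysed in basic mode (first three are vendor-named)
    arrhythmia_basic = c(
      "Asystole", "Ventricular Fibrillation", "Ventricular Tachycardia",
      "Extreme Tachycardia", "Extreme Bradycardia", "Pause",
      "Missed Beat", "PVCs/min High", "Irregular Heart Rate", "Pacer Not Capture"
    ),
    # 13 additional classes in enhanced mode (first three are vendor-named)
    arrhythmia_enhanced = c(
      "Nonsustained Ventricular Tachycardia", "Supraventricular Tachycardia",
      "Run PVCs High", "Pair PVCs", "Multiform PVCs", "Bigeminy PVCs",
      "Trigeminy PVCs", "R-on-T PVCs", "Ventricular Rhythm", "AFIB",
      "SVT Rate High", "Ventricular Bradycardia", "Pacer Not Pace"
    ),
    # clinician action taxonomy: the vendor's search categories (21 types);
    # the named subset is seeded, the rest are extensible entries
    actions = c(
      "Silence", "Pause All Alarms", "Resume All Alarms",
      "Measurement On", "Measurement Off", "Alarm On", "Alarm Off",
      "Alarm Limit Change", "Stand By On", "Stand By Off",
      "Admission", "Discharge", "Transfer", "Paced Status Changed",
      "Patient Category Changed", "Equipment Offline", "Equipment Online",
      "Alarms Off", "Alarm Volume Change", "Print/Record", "Other"
    ),
    # announcement-chain membership; parameters not listed announce
    # independently (chain "none")
    chains = list(
      pvc = c("Multiform PVCs", "Pair PVCs", "Paired PVCs", "Bigeminy PVCs",
              "Trigeminy PVCs", "Run PVCs High", "R-on-T PVCs", "PVCs/min"),
      beat_detection = c("Asystole", "Ventricular Fibrillation",
                         "Ventricular Tachycardia", "Pause", "Missed Beat",
                         "Nonsustained Ventricular Tachycardia"),
      rate = c("HR", "Extreme Tachycardia", "Extreme Bradycardia",
               "SVT Rate High", "Irregular Heart Rate")
    ),
    # red alarms that keep sounding after the condition resolves until silenced
    latching = c("Asystole", "Ventricular Fibrillation", "Desat",
                 "Extreme Bradycardia", "Extreme Tachycardia"),
    # yellow alarms announced ahead of other yellows when any yellow/INOP is
    # also active ("long" class); yellows not listed are "short"
    yellow_long = c("Apnea", "HR", "RR", "SpO2", "ABPs", "ABPd", "ABPm",
                    "NBPs", "NBPd", "PAPd", "PAPs", "PAPm"),
    # defaults only a vendor representative can change
    hard_stops = c("TachyClamp", "BradyClamp", "TachyExtract", "BradyExtract"),
    # technical alarms with no sound even when generated
    inaudible = c("Noisy ECG")
  )
}

#' Arrhythmia classes exposed by an analysis mode
#'
#' @param mode `"basic"` (10 classes) or `"enhanced"` (the basic 10 plus 13
#'   additional classes).
#' @param registry Registry list, default [default_registry()].
#' @return Character vector of class names.
#' @export
arrhythmia_classes <- function(mode = c("basic", "enhanced"),
                               registry = default_registry()) {
  mode <- match.arg(mode)
  if (mode == "basic") registry$arrhythmia_basic
  else c(registry$arrhythmia_basic, registry$arrhythmia_enhanced)
}

#' Load a registry from a YAML file
#'
#' Entries present in the file override the corresponding entries of the
#' default registry; everything else keeps its default.
#'
#' @param path YAML file with any subset of the registry keys.
#' @return A registry list as from [default_registry()].
#' @export
read_registry <- function(path) {
  user <- yaml::read_yaml(path)
  reg <- default_registry()
  for (key in names(user)) {
    reg[[key]] <- user[[key]]
  }
  reg
}

#' Announcement-chain membership of a parameter
#'
#' @param parameter Character vector of parameter names.
#' @param registry Registry list, default [default_registry()].
#' @return Character vector: `"pvc"`, `"beat_detection"`, `"rate"`, or
#'   `"none"` for parameters that announce independently.
#' @export
chain_of <- function(parameter, registry = default_registry()) {
  vapply(parameter, function(p) {
    for (ch in names(registry$chains)) {
      if (p %in% registry$chains[[ch]]) return(ch)
    }
    "none"
  }, character(1), USE.NAMES = FALSE)
}
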