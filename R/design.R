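#' Injection protocol
#'
#' Describes one programmed injection: contrast medium, volume, flow rate,
#' and the protocol group it belongs to. The expected (programmed) bolus
#' injection time is `cm_volume_ml / flow_rate_ml_s`. Protocol groups follow
#' the bench convention: `vVol` varies the injected volume at a constant
#' 5 ml/s flow, `cVol` holds the volume at 10 ml and varies the flow, and
#' `mVol` injects micro volumes (2 ml).
#'
#' @param protocol_id Unique identifier string.
#' @param cm_type `"Gadoterate"` or `"Gadoteridol"`.
#' @param cm_volume_ml Injected contrast volume in ml (> 0).
#' @param flow_rate_ml_s Programmed flow rate in ml/s (> 0).
#' @param group Protocol group label: `"vVol"`, `"cVol"` or `"mVol"`.
#' @param injection_delay_s Pre-injection baseline delay in seconds
#'   (default 10): the recording starts this long before the pump.
#' @param saline_flush_ml Saline flushed after the contrast volume, beyond
#'   the tube-line filling volume (default 25 ml).
#' @return An object of class `injection_protocol`.
#' @export
injection_protocol <- function(protocol_id, cm_type = c("Gadoterate", "Gadoteridol"),
                               cm_volume_ml, flow_rate_ml_s,
                               group = c("vVol", "cVol", "mVol"),
                               injection_delay_s = 10, saline_flush_ml = 25) {
  cm_type <- match.arg(cm_type)
  group <- match.arg(group)
  if (!is.numeric(cm_volume_ml) || length(cm_volume_ml) != 1L || cm_volume_ml <= 0) {
    stop("cm_volume_ml must be a single positive number")
  }
  if (!is.numeric(flow_rate_ml_s) || length(flow_rate_ml_s) != 1L || flow_rate_ml_s <= 0) {
    stop("flow_rate_ml_s must be a single positive number")
  }
  if (injection_delay_s < 0) stop("injection_delay_s must be >= 0")
  if (saline_flush_ml < 0) stop("saline_flush_ml must be >= 0")
  t_exp <- cm_volume_ml / flow_rate_ml_s
  if (!is.finite(t_exp) || t_exp <= 0) stop("expected injection time must be finite and positive")
  structure(
    list(protocol_id = as.character(protocol_id), cm_type = cm_type,
         cm_volume_ml = cm_volume_ml, flow_rate_ml_s = flow_rate_ml_s,
         group = group, injection_delay_s = injection_delay_s,
         saline_flush_ml = saline_flush_ml),
    class = "injection_protocol")
}

#' Expected bolus injection time
#'
#' The programmed injection time at the sensor: contrast volume divided by
#' flow rate, in seconds. E.g. 15 ml at 5 ml/s gives 3.0 s; 2 ml at 5 ml/s
#' gives 0.4 s.
#'
#' @param protocol An [injection_protocol()].
#' @return Expected injection time in seconds.
#' @export
expected_injection_time <- function(protocol) {
  stopifnot(inherits(protocol, "injection_protocol"))
  protocol$cm_volume_ml / protocol$flow_rate_ml_s
}

#' Injector configuration
#'
#' Technical description of one power injector as it enters the analysis:
#' pump mechanism (piston-syringe `PS` or roller-pump `RP`), the filling
#' volume of the attached tube-line system, a relative maximum
#' injection-power scalar, and whether the line configuration is the
#' vendor-approved `regular` one or an `experimental` line swap.
#'
#' @param injector_id Unique identifier string.
#' @param pump_type `"PS"` (piston-syringe) or `"RP"` (roller-pump).
#' @param line_volume_ml Filling volume of the attached tube line in ml (> 0).
#' @param max_pressure Relative maximum injection power (> 0, unitless).
#' @param line_config `"regular"` or `"experimental"`.
#' @return An object of class `injector_config`.
#' @export
injector_config <- function(injector_id, pump_type = c("PS", "RP"),
                            line_volume_ml, max_pressure = 1,
                            line_config = c("regular", "experimental")) {
  pump_type <- match.arg(pump_type)
  line_config <- match.arg(line_config)
  if (!is.numeric(line_volume_ml) || length(line_volume_ml) != 1L || line_volume_ml <= 0) {
    stop("line_volume_ml must be a single positive number")
  }
  if (!is.numeric(max_pressure) || length(max_pressure) != 1L || max_pressure <= 0) {
    stop("max_pressure must be a single positive number")
  }
  structure(
    list(injector_id = as.character(injector_id), pump_type = pump_type,
         line_volume_ml = line_volume_ml, max_pressure = max_pressure,
         line_config = line_config),
    class = "injector_config")
}

#' Study design
#'
#' A study design couples a set of injectors with a set of injection
#' protocols, each protocol run once per injector on each of `days`
#' measurement days.
#'
#' @param injectors List of [injector_config()] objects (unique ids).
#' @param protocols List of [injection_protocol()] objects (unique ids).
#' @param days Number of replicate measurement days (default 2).
#' @return An object of class `study_design`.
#' @export
study_design <- function(injectors, protocols, days = 2L) {
  if (length(injectors) < 1L) stop("study design needs at least one injector")
  if (length(protocols) < 1L) stop("study design needs at least one protocol")
  stopifnot(all(vapply(injectors, inherits, TRUE, "injector_config")),
            all(vapply(protocols, inherits, TRUE, "injection_protocol")))
  inj_ids <- vapply(injectors, `[[`, "", "injector_id")
  prot_ids <- vapply(protocols, `[[`, "", "protocol_id")
  if (anyDuplicated(inj_ids)) stop("duplicate injector_id: ", inj_ids[duplicated(inj_ids)][1L])
  if (anyDuplicated(prot_ids)) stop("duplicate protocol_id: ", prot_ids[duplicated(prot_ids)][1L])
  days <- as.integer(days)
  if (is.na(days) || days < 1L) stop("days must be an integer >= 1")
  structure(
    list(injectors = setNames(injectors, inj_ids),
         protocols = setNames(protocols, prot_ids),
         days = days),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  pt <- vapply(x$injectors, `[[`, "", "pump_type")
  cat("<study_design> ", length(x$injectors), " injectors (",
      sum(pt == "PS"), " PS, ", sum(pt == "RP"), " RP), ",
      length(x$protocols), " protocols, ", x$days, " days\n", sep = "")
  invisible(x)
}

#' Read a study design from a YAML file
#'
#' The schema has three top-level keys:
#' \preformatted{
#' days: 2
#' injectors:
#'   - injector_id: MedAcc
#'     pump_type: PS            # PS or RP
#'     line_volume_ml: 6.0
#'     max_pressure: 10         # relative injection power
#'     line_config: regular     # optional; regular or experimental
#' protocols:
#'   - protocol_id: vVol_15_Gadoterate
#'     cm_type: Gadoterate      # Gadoterate or Gadoteridol
#'     cm_volume_ml: 15
#'     flow_rate_ml_s: 5
#'     group: vVol              # vVol, cVol or mVol
#'     injection_delay_s: 10    # optional
#'     saline_flush_ml: 25      # optional
#' }
#'
#' @param path Path to a YAML study-design file.
#' @return A [study_design()].
#' @export
read_study_design <- function(path) {
  if (!file.exists(path)) stop("study design file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (key in c("injectors", "protocols")) {
    if (is.null(raw[[key]])) stop("study design is missing required field '", key, "'")
  }
  need <- function(entry, field, where) {
    if (is.null(entry[[field]])) stop("missing required field '", field, "' in ", where)
    entry[[field]]
  }
  opt <- function(entry, field, default) {
    if (is.null(entry[[field]])) default else entry[[field]]
  }
  injectors <- lapply(raw$injectors, function(e) {
    injector_config(
      injector_id = need(e, "injector_id", "an injector entry"),
      pump_type = as.character(need(e, "pump_type", "an injector entry")),
      line_volume_ml = need(e, "line_volume_ml", "an injector entry"),
      max_pressure = need(e, "max_pressure", "an injector entry"),
      line_config = opt(e, "line_config", "regular"))
  })
  protocols <- lapply(raw$protocols, function(e) {
    injection_protocol(
      protocol_id = need(e, "protocol_id", "a protocol entry"),
      cm_type = as.character(need(e, "cm_type", "a protocol entry")),
      cm_volume_ml = need(e, "cm_volume_ml", "a protocol entry"),
      flow_rate_ml_s = need(e, "flow_rate_ml_s", "a protocol entry"),
      group = as.character(need(e, "group", "a protocol entry")),
      injection_delay_s = opt(e, "injection_delay_s", 10),
      saline_flush_ml = opt(e, "saline_flush_ml", 25))
  })
  study_design(injectors, protocols, days = opt(raw, "days", 2L))
}

#' Default synthetic study design
#'
#' The bundled design mirrors a five-injector bench study: three
#' piston-syringe models (small-volume lines, higher injection power) and
#' two roller-pump models (large-volume lines), crossed with 14 injection
#' protocols — the vVol grid (15/10/5 ml at 5 ml/s), the cVol grid (10 ml at
#' 2.5/1 ml/s; 10 ml at 5 ml/s is shared with vVol and listed once) and the
#' mVol grid (2 ml at 5/1 ml/s), each with both Gadoterate and Gadoteridol —
#' repeated on two days. Line volumes and power scalars are illustrative
#' placeholders with the right orders of magnitude, not vendor data.
#'
#' @return A [study_design()] with 5 injectors, 14 protocols, 2 days.
#' @export
default_study_design <- function() {
  read_study_design(system.file("extdata", "default_design.yaml",
                                package = "bolusqc", mustWork = TRUE))
}

#' Protocol-group membership
#'
#' Group membership used for sub-group testing. A protocol can belong to
#' more than one group: the 10 ml at 5 ml/s protocols are shared between the
#' variable-volume (vVol) and constant-volume (cVol) grids. Membership is
#' derived from volume and flow, not from the protocol's primary `group`
#' label: `vVol` = 5 ml/s flow and volume >= 5 ml; `cVol` = 10 ml volume;
#' `mVol` = 2 ml volume; `all` = everything.
#'
#' @param protocol An [injection_protocol()].
#' @param group One of `"all"`, `"vVol"`, `"cVol"`, `"mVol"`.
#' @return `TRUE` if the protocol belongs to the group.
#' @export
in_protocol_group <- function(protocol, group = c("all", "vVol", "cVol", "mVol")) {
  stopifnot(inherits(protocol, "injection_protocol"))
  group <- match.arg(group)
  switch(group,
         all = TRUE,
         vVol = protocol$flow_rate_ml_s == 5 && protocol$cm_volume_ml >= 5,
         cVol = protocol$cm_volume_ml == 10,
         mVol = protocol$cm_volume_ml == 2)
}

#' Contrast-medium dynamic viscosity
#'
#' Dynamic viscosities at 20 degrees C used by the simulator: Gadoterate
#' 3.4 mPa.s, Gadoteridol 2.0 mPa.s (water is 1.0 mPa.s).
#'
#' @param cm_type `"Gadoterate"` or `"Gadoteridol"`.
#' @return Viscosity in mPa.s.
#' @export
cm_viscosity <- function(cm_type) {
  switch(match.arg(cm_type, c("Gadoterate", "Gadoteridol")),
         Gadoterate = 3.4, Gadoteridol = 2.0)
}
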