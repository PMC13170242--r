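#' Duty-cycle phase
#'
#' One phase of an acquire--upload--sleep operating cycle: the system draws
#' `current` at `voltage` for `duration` seconds.
#'
#' @param name Phase name.
#' @param voltage Rail voltage (V, >= 0).
#' @param current Phase current (mA, >= 0).
#' @param duration Phase duration (s, >= 0).
#' @return An object of class `duty_cycle_phase`.
#' @export
duty_cycle_phase <- function(name, voltage, current, duration) {
  assert_scalar_num(voltage, "voltage", lower = 0)
  assert_scalar_num(current, "current", lower = 0)
  assert_scalar_num(duration, "duration", lower = 0)
  structure(list(name = as.character(name), voltage = voltage,
                 current = current, duration = duration),
            class = "duty_cycle_phase")
}

#' Energy-harvesting parameters
#'
#' @param effective_power Matched-load output power of the foot-strike
#'   harvester (mW, >= 0).
#' @param contact_duration Single-step contact duration (s/step, >= 0).
#' @param conversion_efficiency Rectification/regulation efficiency,
#'   in (0, 1].
#' @return An object of class `harvest_params`.
#' @export
harvest_params <- function(effective_power, contact_duration,
                           conversion_efficiency) {
  assert_scalar_num(effective_power, "effective_power", lower = 0)
  assert_scalar_num(contact_duration, "contact_duration", lower = 0)
  assert_scalar_num(conversion_efficiency, "conversion_efficiency",
                    lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(effective_power = effective_power,
                 contact_duration = contact_duration,
                 conversion_efficiency = conversion_efficiency),
            class = "harvest_params")
}

#' Telemetry frame specification
#'
#' @param payload_bytes Payload size per frame (bytes, > 0).
#' @param overhead_bytes Identifier/checksum overhead per frame (bytes, >= 0).
#' @param frame_rate Frame rate (Hz, >= 0).
#' @param wire_bits_per_byte Serial wire bits per byte; default 10
#'   (8N1 UART: start + 8 data + stop).
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(payload_bytes, overhead_bytes = 0, frame_rate,
                       wire_bits_per_byte = 10) {
  assert_scalar_num(payload_bytes, "payload_bytes", lower = 0,
                    strict_lower = TRUE)
  assert_scalar_num(overhead_bytes, "overhead_bytes", lower = 0)
  assert_scalar_num(frame_rate, "frame_rate", lower = 0)
  assert_scalar_num(wire_bits_per_byte, "wire_bits_per_byte", lower = 0,
                    strict_lower = TRUE)
  structure(list(payload_bytes = payload_bytes, overhead_bytes = overhead_bytes,
                 frame_rate = frame_rate,
                 wire_bits_per_byte = wire_bits_per_byte),
            class = "frame_spec")
}

#' Energy consumed over one duty cycle
#'
#' Sum over phases of V * I * t, in millijoules (V x mA x s = mJ).
#'
#' @param phases A list of [duty_cycle_phase()] objects (may be empty).
#' @return Energy in mJ.
#' @export
cycle_energy <- function(phases) {
  if (length(phases) == 0) return(0)
  if (inherits(phases, "duty_cycle_phase")) phases <- list(phases)
  stopifnot(all(vapply(phases, inherits, logical(1), "duty_cycle_phase")))
  sum(vapply(phases, function(p) p$voltage * p$current * p$duration,
             numeric(1)))
}

#' Harvested energy per step
#'
#' `effective_power * contact_duration * conversion_efficiency`, in mJ/step
#' (mW x s = mJ).
#'
#' @param h A [harvest_params()] object.
#' @return Energy per step in mJ.
#' @export
per_step_energy <- function(h) {
  stopifnot(inherits(h, "harvest_params"))
  h$effective_power * h$contact_duration * h$conversion_efficiency
}

#' Net energy balance over an operating cycle
#'
#' Harvest minus consumption; the system is sustainable over the cycle when
#' the surplus is nonnegative.
#'
#' @param phases A list of [duty_cycle_phase()] objects.
#' @param h A [harvest_params()] object.
#' @param n_steps Number of steps taken during the cycle (>= 0).
#' @return A list with `harvest_mJ`, `consumption_mJ`, `surplus_mJ`, and
#'   logical `sustainable`.
#' @export
net_balance <- function(phases, h, n_steps) {
  assert_scalar_num(n_steps, "n_steps", lower = 0)
  harvest <- n_steps * per_step_energy(h)
  consumption <- cycle_energy(phases)
  list(harvest_mJ = harvest, consumption_mJ = consumption,
       surplus_mJ = harvest - consumption,
       sustainable = harvest - consumption >= 0)
}

#' Telemetry link throughput
#'
#' `(payload + overhead) bytes x wire bits/byte x frame rate / 1000`, in kbps.
#'
#' @param f A [frame_spec()] object.
#' @return Throughput in kbps.
#' @export
link_throughput <- function(f) {
  stopifnot(inherits(f, "frame_spec"))
  (f$payload_bytes + f$overhead_bytes) * f$wire_bits_per_byte *
    f$frame_rate / 1000
}

#' Default duty-cycle energy scenario
#'
#' The representative 10-minute operating cycle of the wearable: 480 s of
#' local acquisition at 0.2 mA, 20 s of Bluetooth upload at 1.8 mA, and 100 s
#' of sleep at 0.007 mA, all at a 3.2 V rail; harvesting 3.92 mW per foot
#' strike for 0.25 s at 72\% conversion efficiency; 67-byte frames (64-byte
#' payload + 3 bytes identifier/checksum) at 10 Hz over an 8N1 serial link.
#'
#' @return A list with elements `phases`, `harvest`, `frame`, `n_steps`.
#' @export
default_energy_scenario <- function() {
  list(
    phases = list(
      duty_cycle_phase("acquisition", voltage = 3.2, current = 0.2,
                       duration = 480),
      duty_cycle_phase("upload", voltage = 3.2, current = 1.8, duration = 20),
      duty_cycle_phase("sleep", voltage = 3.2, current = 0.007,
                       duration = 100)),
    harvest = harvest_params(effective_power = 3.92, contact_duration = 0.25,
                             conversion_efficiency = 0.72),
    frame = frame_spec(payload_bytes = 64, overhead_bytes = 3,
                       frame_rate = 10, wire_bits_per_byte = 10),
    n_steps = 1000)
}

#' Full energy/telemetry budget report
#'
#' @param scenario A scenario list as returned by [default_energy_scenario()].
#' @return A list with the four budget quantities (mJ, 2-decimal formatting is
#'   applied only when printing), throughput (kbps), and the sustainability
#'   verdict.
#' @export
energy_report <- function(scenario = default_energy_scenario()) {
  bal <- net_balance(scenario$phases, scenario$harvest, scenario$n_steps)
  structure(list(
    cycle_consumption_mJ = bal$consumption_mJ,
    per_step_harvest_mJ = per_step_energy(scenario$harvest),
    total_harvest_mJ = bal$harvest_mJ,
    net_surplus_mJ = bal$surplus_mJ,
    throughput_kbps = link_throughput(scenario$frame),
    sustainable = bal$sustainable,
    n_steps = scenario$n_steps), class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("<energy_report>\n")
  cat(sprintf("  cycle consumption : %.2f mJ\n", x$cycle_consumption_mJ))
  cat(sprintf("  harvest per step  : %.4f mJ\n", x$per_step_harvest_mJ))
  cat(sprintf("  harvest (%d steps): %.2f mJ\n", x$n_steps,
              x$total_harvest_mJ))
  cat(sprintf("  net surplus       : %.2f mJ (%s)\n", x$net_surplus_mJ,
              if (x$sustainable) "sustainable" else "deficit"))
  cat(sprintf("  link throughput   : %.2f kbps\n", x$throughput_kbps))
  invisible(x)
}
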