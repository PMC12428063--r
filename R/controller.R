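# Temperature-feedback energy delivery.
#
# The generator delivers symmetric bipolar nanosecond waveforms continuously;
# the controller modulates the delay between waveforms, summarised here (as
# in the source numerical model) by the instantaneous energy delivery rate
# R(t) in microseconds of pulse on-time per second.  Electrical dose is the
# sum of all delivered pulse durations, so dose accumulates at
# R(t) * 1e-6 s per second and delivery terminates exactly when the
# prescribed dose is reached.

#' Pulse protocol
#'
#' @param applied_voltage Pulse amplitude, V.
#' @param pulse_width_ns Single-pulse duration, ns.
#' @param interphase_delay_ns Delay between the positive and negative phase,
#'   ns (bookkeeping only; it carries no energy).
#' @param pulses_per_waveform Pulses per waveform (2: one positive, one
#'   negative).
#' @param prescribed_dose_s Electrical dose, s of cumulative pulse on-time.
#' @return A `pulse_protocol` object.
#' @export
pulse_protocol <- function(applied_voltage = 6000, pulse_width_ns = 1000,
                           interphase_delay_ns = 1000,
                           pulses_per_waveform = 2,
                           prescribed_dose_s = 0.02) {
  stopifnot(applied_voltage >= 0, pulse_width_ns > 0,
            pulses_per_waveform >= 1, prescribed_dose_s >= 0)
  structure(list(applied_voltage = applied_voltage,
                 pulse_width_ns = pulse_width_ns,
                 interphase_delay_ns = interphase_delay_ns,
                 pulses_per_waveform = pulses_per_waveform,
                 prescribed_dose_s = prescribed_dose_s),
            class = "pulse_protocol")
}

#' Pulse count for a prescribed dose
#'
#' Number of pulses whose durations sum to the prescribed dose: a 0.02 s
#' dose at 1000 ns per pulse is 20,000 pulses (10,000 bipolar waveforms).
#'
#' @param protocol A [pulse_protocol()].
#' @return Integer pulse count, with the waveform count as attribute
#'   `waveforms`.
#' @export
pulse_count <- function(protocol) {
  width_s <- protocol$pulse_width_ns * 1e-9
  n <- protocol$prescribed_dose_s / width_s
  if (abs(n - round(n)) > 1e-6)
    stop("prescribed dose is not divisible by the pulse width (remainder ",
         signif((n - floor(n)) * width_s, 3), " s)")
  n <- round(n)
  structure(n, waveforms = n / protocol$pulses_per_waveform)
}

#' Controller configuration
#'
#' Proportional-band throttle standing in for the proprietary control law:
#' rate(T) = max_rate * clamp((setpoint - T) / band, floor, 1).  The rate is
#' continuous and non-increasing in the probe temperature and never drops
#' below `floor * max_rate`, which guarantees the dose always completes.
#' Defaults are chosen for a stable plateau within 1 degC of the setpoint;
#' absolute treatment durations are governed by the thermal balance at the
#' probe, not by these gains (see the methods vignette).
#'
#' @param setpoint Target probe temperature, degC.
#' @param max_rate Maximum delivery rate, microseconds/second.
#' @param band Proportional band, degC.
#' @param floor Minimum rate as a fraction of `max_rate` (0 < floor <= 1).
#' @param control_interval Controller update (and thermal step) interval, s.
#' @param rate_tau First-order smoothing time constant applied to the
#'   commanded rate, s (0 disables smoothing).  The generator cannot step
#'   its inter-waveform delay instantaneously; smoothing also damps the
#'   feedback loop against the sharp field gradient at the probe.
#' @return A `controller_config` object.
#' @export
controller_config <- function(setpoint = 45, max_rate = 100, band = 2,
                              floor = 0.02, control_interval = 0.25,
                              rate_tau = 3) {
  stopifnot(max_rate > 0, band > 0, floor > 0, floor <= 1,
            control_interval > 0, rate_tau >= 0)
  structure(list(setpoint = setpoint, max_rate = max_rate, band = band,
                 floor = floor, control_interval = control_interval,
                 rate_tau = rate_tau), class = "controller_config")
}

#' Throttled delivery rate for a probe temperature
#'
#' @param probe_T Probe temperature(s), degC.
#' @param config A [controller_config()].
#' @return Delivery rate(s), microseconds/second.
#' @export
update_rate <- function(probe_T, config) {
  stopifnot(all(is.finite(probe_T)))
  frac <- (config$setpoint - probe_T) / config$band
  config$max_rate * pmin(1, pmax(config$floor, frac))
}

#' Simulate a temperature-controlled treatment
#'
#' Couples the electrostatic solution (solved once in baseline mode, or
#' re-solved with temperature-dependent conductivity every
#' `resolve_interval` steps in coupled mode), the transient bioheat stepper
#' and the feedback law.  Each control interval the probe temperature sets
#' the delivery rate, the Joule source is scaled accordingly, and the dose
#' advances by rate x dt x 1e-6 s; the final step is shortened so the
#' delivered dose equals the prescription exactly.
#'
#' @param geometry An `ablation_geometry`.
#' @param materials A [material_properties()].
#' @param boundary A [thermal_boundary()].
#' @param protocol A [pulse_protocol()].
#' @param config A [controller_config()].
#' @param mesh Optional prebuilt `axi_mesh`; by default a treatment-scale
#'   mesh is generated with `max_size_near`/`max_size_far`.
#' @param max_size_near,max_size_far Mesh sizes (cm) used when `mesh` is
#'   NULL.  The treatment solver default (0.04 cm near) is coarser than the
#'   calibration meshes because thousands of time steps are taken.
#' @param probe Probe sampling point `c(r, z)` in cm; default
#'   [probe_location()] of the geometry.
#' @param coupled_sigma Re-solve the field with sigma(T) during treatment.
#' @param resolve_interval Steps between field re-solves in coupled mode.
#' @param max_duration_s Abort horizon, simulated seconds.
#' @return A `treatment_log`: data frame `log` (time_s, T_probe_C,
#'   rate_us_per_s, cumulative_dose_s), `duration_s`, `waveforms`,
#'   final `state`, the `mesh` and baseline `field`.
#' @export
simulate_treatment <- function(geometry, materials = material_properties(),
                               boundary = thermal_boundary(),
                               protocol = pulse_protocol(),
                               config = controller_config(),
                               mesh = NULL, probe = NULL,
                               max_size_near = 0.04, max_size_far = 0.8,
                               coupled_sigma = FALSE, resolve_interval = 40L,
                               max_duration_s = 7200) {
  if (is.null(mesh))
    mesh <- generate_mesh(geometry, max_size_near = max_size_near,
                          max_size_far = max_size_far)
  field <- solve_potential(mesh, materials, protocol$applied_voltage)
  stepper <- make_thermal_stepper(mesh, materials, boundary,
                                  dt = config$control_interval)
  fq_full <- .source_load(mesh, field$JdotE)  # duty-cycle-1 load vector
  state <- thermal_init(stepper)
  if (is.null(probe)) probe <- probe_location(geometry)

  dose <- 0
  target <- protocol$prescribed_dose_s
  tp <- probe_temperature(state, mesh, probe)
  log_t <- log_T <- log_r <- log_d <- numeric(0)
  step_i <- 0L

  rate_state <- NULL
  while (dose < target) {
    rate <- update_rate(tp, config)
    if (config$rate_tau > 0 && !is.null(rate_state)) {
      a <- min(1, stepper$dt / config$rate_tau)
      rate <- rate_state + a * (rate - rate_state)
    }
    rate_state <- rate
    dt <- stepper$dt
    inc <- rate * 1e-6 * dt
    if (dose + inc >= target) {
      dt <- (target - dose) * 1e6 / rate
      inc <- target - dose
    }
    # one implicit step with the duty-scaled Joule load
    s <- stepper
    if (abs(dt - stepper$dt) > 1e-12) {
      s <- make_thermal_stepper(mesh, materials, boundary, dt = dt)
    }
    b <- s$M / s$dt * state$T + rate * 1e-6 * fq_full + s$robin$f
    temp <- state$T
    temp[s$fixed] <- s$t_fixed
    rhs <- b[s$free] - as.numeric(s$Afd %*% s$t_fixed)
    temp[s$free] <- as.numeric(Matrix::solve(s$fact, rhs))
    if (any(!is.finite(temp)))
      stop("treatment simulation produced non-finite temperatures")
    state <- structure(list(T = temp, time = state$time + dt),
                       class = "thermal_state")

    dose <- dose + inc
    tp <- probe_temperature(state, mesh, probe)
    step_i <- step_i + 1L
    log_t <- c(log_t, state$time)
    log_T <- c(log_T, tp)
    log_r <- c(log_r, rate)
    log_d <- c(log_d, dose)

    if (coupled_sigma && step_i %% resolve_interval == 0L) {
      field <- solve_potential(mesh, materials, protocol$applied_voltage,
                               temperature = state$T)
      fq_full <- .source_load(mesh, field$JdotE)
    }
    if (state$time > max_duration_s)
      stop("treatment failed to reach the prescribed dose within ",
           max_duration_s, " simulated seconds (check the rate floor)")
  }

  structure(list(
    log = data.frame(time_s = log_t, T_probe_C = log_T,
                     rate_us_per_s = log_r, cumulative_dose_s = log_d),
    duration_s = state$time,
    delivered_dose_s = dose,
    waveforms = as.numeric(pulse_count(protocol)) / protocol$pulses_per_waveform,
    state = state,
    mesh = mesh,
    field = field,
    geometry = geometry,
    protocol = protocol,
    config = config
  ), class = "treatment_log")
}

#' @export
print.treatment_log <- function(x, ...) {
  cat(sprintf("Treatment: %.2f cm exposure, %.0f V, dose %.3f s delivered in %.1f s\n",
              x$geometry$applicator$exposure_length,
              x$protocol$applied_voltage, x$delivered_dose_s, x$duration_s))
  cat(sprintf("  probe: final %.1f degC (setpoint %.1f degC)\n",
              utils::tail(x$log$T_probe_C, 1), x$config$setpoint))
  invisible(x)
}
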