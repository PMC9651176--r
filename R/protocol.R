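#' Ca-Pra maneuver recording protocol
#'
#' Describes the timing of a Candlestick-Prayer (Ca-Pra) VPPG recording:
#' a short rest window with the arms alongside the torso (defines zero
#' volume), a candlestick ("Ca", 90 degree abduction) phase, a prayer
#' ("Pra", elbows forward with hands kept elevated) phase, and a trailing
#' post-maneuver segment during which the arms are lowered.  The default
#' protocol is the clinical one: 2 s rest, Ca until second 30, Pra until
#' second 45, recording stops at 60 s, sampled at 4 Hz.
#'
#' @param rest_duration Length of the rest (baseline) window in seconds.
#' @param ca_end End of the candlestick phase, seconds from recording start.
#' @param pra_end End of the prayer phase, seconds from recording start.
#' @param total_duration Total recording length in seconds.
#' @param sample_rate Sampling frequency in Hz.
#'
#' @return An object of class `maneuver_protocol`.
#' @examples
#' p <- maneuver_protocol()
#' length(protocol_times(p))  # 240 samples at 4 Hz for 60 s
#' @export
maneuver_protocol <- function(rest_duration = 2, ca_end = 30, pra_end = 45,
                              total_duration = 60, sample_rate = 4) {
  vals <- c(rest_duration = rest_duration, ca_end = ca_end, pra_end = pra_end,
            total_duration = total_duration, sample_rate = sample_rate)
  if (!all(is.finite(vals))) {
    stop("maneuver_protocol: all timing fields must be finite numbers")
  }
  if (sample_rate <= 0) stop("maneuver_protocol: sample_rate must be > 0")
  if (!(0 < rest_duration && rest_duration < ca_end && ca_end < pra_end &&
        pra_end <= total_duration)) {
    stop("maneuver_protocol: need 0 < rest_duration < ca_end < pra_end <= total_duration")
  }
  n <- total_duration * sample_rate
  if (abs(n - round(n)) > 1e-8) {
    stop("maneuver_protocol: total_duration * sample_rate must be a whole number of samples")
  }
  structure(
    list(rest_duration = rest_duration, ca_end = ca_end, pra_end = pra_end,
         total_duration = total_duration, sample_rate = sample_rate),
    class = "maneuver_protocol"
  )
}

#' Sample grid of a protocol
#'
#' @param protocol A [maneuver_protocol()].
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
protocol_times <- function(protocol) {
  stopifnot(inherits(protocol, "maneuver_protocol"))
  n <- round(protocol$total_duration * protocol$sample_rate)
  seq(0, by = 1 / protocol$sample_rate, length.out = n)
}

#' Maneuver phase of each sample time
#'
#' @param protocol A [maneuver_protocol()].
#' @param time Numeric vector of times in seconds.
#' @return Factor with levels `rest`, `ca`, `pra`, `post`.
#' @export
protocol_phase <- function(protocol, time = protocol_times(protocol)) {
  stopifnot(inherits(protocol, "maneuver_protocol"))
  phase <- ifelse(time < protocol$rest_duration, "rest",
           ifelse(time < protocol$ca_end, "ca",
           ifelse(time < protocol$pra_end, "pra", "post")))
  factor(phase, levels = c("rest", "ca", "pra", "post"))
}

#' @export
print.maneuver_protocol <- function(x, ...) {
  cat(sprintf(
    "Ca-Pra maneuver protocol: rest 0-%g s | Ca %g-%g s | Pra %g-%g s | stop %g s @ %g Hz\n",
    x$rest_duration, x$rest_duration, x$ca_end, x$ca_end, x$pra_end,
    x$total_duration, x$sample_rate))
  invisible(x)
}

#' Hemodynamic simulation parameters for one limb
#'
#' Parameters of the single-compartment venous model used by
#' [simulate_trace()].  Venous volume sits at `v_full` while the arm is
#' down, empties towards `v_empty` with first-order rate `outflow_rate`
#' once elevated, and is continuously refilled by arterial inflow
#' `inflow`.  Positional compression during the Ca phase is expressed as
#' fractional blocks of the outflow conductance (`outflow_block`) and of
#' the arterial inflow (`inflow_block`).  Moving to Pra releases the
#' outflow block; if arterial inflow was impaired during Ca, release
#' triggers a transient reactive-hyperemia inflow surge and a venodilated
#' (larger) empty volume controlled by `venodilation`.
#'
#' @param outflow_block Fraction in `[0, 1]` of venous outflow conductance
#'   lost during Ca (0 = patent outflow, 1 = arrested outflow).
#' @param inflow_block Fraction in `[0, 1]` of arterial inflow lost during
#'   Ca (drives post-ischemic hyperemia and venodilation in Pra).
#' @param venodilation Dimensionless magnitude (>= 0) of the post-ischemic
#'   increase of the empty volume; active only when `inflow_block > 0`.
#' @param outflow_rate First-order emptying rate constant (1/s) with the
#'   outflow fully patent.  Keep below 2/s: the explicit Euler step on a
#'   4 Hz grid is stable for `outflow_rate * 0.25 < 1`.
#' @param inflow Resting arterial inflow (volume-units/s).
#' @param gain Photoplethysmographic gain (AU per volume-unit); VPPG is
#'   semi-quantitative, so gain varies across limbs and probe placements.
#' @param noise_sd Standard deviation (AU) of additive Gaussian sensor noise.
#' @param seed Optional integer seed for the noise stream; the ambient RNG
#'   state is left untouched.
#' @param v_full,v_empty Full (resting, arm down) and empty venous volume
#'   in arbitrary volume-units.
#' @param onset_ramp Seconds over which the Ca outflow block develops after
#'   abduction (0 = instantaneous).  A slow onset lets a limb empty briefly
#'   before compression engages, producing the "refill after initial
#'   emptying" morphology.
#' @param surge_gain Peak relative amplitude of the reactive-hyperemia
#'   inflow surge at the start of Pra (multiplies `inflow * inflow_block`).
#' @param surge_tau Exponential decay time (s) of the inflow surge.
#' @param refill_rate Rate constant (1/s) of the rapid refill once the arms
#'   are lowered after the Pra phase (samples flagged post-maneuver).
#' @param resolution Display resolution of the device in AU; emitted
#'   samples are quantized to this grid (0 disables quantization).  The
#'   default 0.1 AU matches clinical devices that print values such as
#'   "6.0" and makes exact ties — including %PPGmax of exactly 100 —
#'   possible, as observed in real recordings.
#'
#' @return An object of class `sim_params`.
#' @seealso [simulate_trace()], [preset_pattern()]
#' @export
sim_params <- function(outflow_block = 0, inflow_block = 0, venodilation = 0,
                       outflow_rate = 0.3, inflow = 0.02, gain = 10,
                       noise_sd = 0, seed = NULL,
                       v_full = 1, v_empty = 0.1, onset_ramp = 0,
                       surge_gain = 6, surge_tau = 5, refill_rate = 0.6,
                       resolution = 0.1) {
  num <- c(outflow_block = outflow_block, inflow_block = inflow_block,
           venodilation = venodilation, outflow_rate = outflow_rate,
           inflow = inflow, gain = gain, noise_sd = noise_sd,
           v_full = v_full, v_empty = v_empty, onset_ramp = onset_ramp,
           surge_gain = surge_gain, surge_tau = surge_tau,
           refill_rate = refill_rate, resolution = resolution)
  if (!all(is.finite(num))) {
    bad <- names(num)[!is.finite(num)]
    stop("sim_params: non-finite value for ", paste(bad, collapse = ", "))
  }
  if (outflow_block < 0 || outflow_block > 1) {
    stop("sim_params: outflow_block must lie in [0, 1]")
  }
  if (inflow_block < 0 || inflow_block > 1) {
    stop("sim_params: inflow_block must lie in [0, 1]")
  }
  if (any(num[c("venodilation", "outflow_rate", "inflow", "gain", "noise_sd",
                "onset_ramp", "surge_tau", "refill_rate", "resolution")] < 0)) {
    stop("sim_params: rates, gains and durations must be >= 0")
  }
  if (v_empty >= v_full) stop("sim_params: v_empty must be < v_full")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(as.list(c(num, list(seed = seed))), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("VPPG simulation parameters:\n")
  cat(sprintf("  outflow block c = %.3g, inflow block a = %.3g, venodilation d = %.3g\n",
              x$outflow_block, x$inflow_block, x$venodilation))
  cat(sprintf("  outflow rate k0 = %.3g /s, inflow q = %.3g vol/s, gain = %.3g AU/vol\n",
              x$outflow_rate, x$inflow, x$gain))
  cat(sprintf("  noise sd = %.3g AU, onset ramp = %.3g s, seed = %s\n",
              x$noise_sd, x$onset_ramp,
              if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
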