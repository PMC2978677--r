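#' Action-potential waveform template
#'
#' Parametric template for the presynaptic action potential that depolarises
#' the bouton membrane. The default is a double-exponential (alpha-like)
#' spike of roughly 1 ms total width riding on a -70 mV resting potential,
#' chosen so that the downstream channel-gating latency reproduces the
#' typical ~3 ms delay between stimulus onset and peak release. All
#' parameters are exposed so a digitised experimental waveform can be
#' substituted via [voltage_trace()].
#'
#' @param baseline_mv resting membrane potential (mV)
#' @param peak_mv peak potential at the spike crest (mV)
#' @param onset_ms time at which the stimulus starts (ms)
#' @param delay_ms conduction/foot delay between the stimulus onset and the
#'   start of the spike upstroke (ms); calibrated so that downstream
#'   vesicular release peaks about 3 ms after the stimulus onset
#' @param rise_ms rise time constant (ms)
#' @param fall_ms repolarisation time constant (ms)
#' @return an object of class `ap_waveform`
#' @export
#' @examples
#' ap <- ap_waveform()
#' generate_ap_waveform(ap, seq(0, 5, by = 0.01))
ap_waveform <- function(baseline_mv = -70, peak_mv = 34, onset_ms = 0,
                        delay_ms = 0.8, rise_ms = 0.4, fall_ms = 0.6) {
  stopifnot(rise_ms > 0, fall_ms > 0, peak_mv > baseline_mv, delay_ms >= 0)
  structure(
    list(baseline_mv = baseline_mv, peak_mv = peak_mv, onset_ms = onset_ms,
         delay_ms = delay_ms, rise_ms = rise_ms, fall_ms = fall_ms,
         shape = "biexp"),
    class = "ap_waveform")
}

#' @export
print.ap_waveform <- function(x, ...) {
  cat(sprintf(
    "<ap_waveform> %s: %.0f -> %.0f mV, onset %.2f ms, rise %.2f / fall %.2f ms\n",
    x$shape, x$baseline_mv, x$peak_mv, x$onset_ms, x$rise_ms, x$fall_ms))
  invisible(x)
}

# normalised biexponential bump, peak exactly 1 at t_peak;
# degenerates to the alpha function when rise == fall
biexp_bump <- function(t, rise, fall) {
  if (abs(fall - rise) < 1e-9 * fall) {
    out <- (t / rise) * exp(1 - t / rise)
  } else {
    t_peak <- rise * fall / (fall - rise) * log(fall / rise)
    peak <- exp(-t_peak / fall) - exp(-t_peak / rise)
    out <- (exp(-t / fall) - exp(-t / rise)) / peak
  }
  out[t < 0] <- 0
  out
}

#' Evaluate an action-potential waveform on a time grid
#'
#' Deterministic evaluation of the voltage template; before `onset_ms` the
#' trace equals the baseline exactly and it returns to within 1 mV of
#' baseline within a few ms of the spike.
#'
#' @param ap an [ap_waveform()]
#' @param t_grid sorted, nonnegative time samples (ms)
#' @return a tibble with columns `time_ms`, `v_mv`
#' @export
generate_ap_waveform <- function(ap, t_grid) {
  stopifnot(inherits(ap, "ap_waveform"))
  if (is.unsorted(t_grid, strictly = FALSE)) {
    stop("t_grid must be sorted in increasing order", call. = FALSE)
  }
  if (any(t_grid < 0)) stop("t_grid must be nonnegative", call. = FALSE)
  amp <- ap$peak_mv - ap$baseline_mv
  v <- ap$baseline_mv + amp * biexp_bump(t_grid - ap$onset_ms - ap$delay_ms,
                                         ap$rise_ms, ap$fall_ms)
  tibble::tibble(time_ms = as.double(t_grid), v_mv = v)
}

#' Stimulus protocol: single action potentials and trains
#'
#' Builds the ordered list of action-potential onsets for a train of given
#' rate, e.g. 10 Hz over 400 ms gives 4 triggers and 100 Hz over 200 ms
#' gives 20.
#'
#' @param frequency_hz train rate; 0 yields an empty (no-stimulus) protocol
#' @param duration_ms total simulated time (ms)
#' @param first_onset_ms onset of the first action potential (ms)
#' @return an object of class `stimulus_protocol` with fields `onsets_ms`,
#'   `duration_ms`, `frequency_hz`
#' @export
#' @examples
#' make_train(10, 400)  # 4 onsets
make_train <- function(frequency_hz, duration_ms, first_onset_ms = 0) {
  if (frequency_hz < 0) stop("frequency must be nonnegative", call. = FALSE)
  stopifnot(duration_ms > 0)
  if (frequency_hz == 0) {
    onsets <- numeric(0)
  } else {
    period <- 1000 / frequency_hz
    k <- 0:floor((duration_ms - first_onset_ms) / period + 1e-9)
    onsets <- first_onset_ms + k * period
    onsets <- onsets[onsets < duration_ms - 1e-9 * duration_ms]
  }
  structure(list(onsets_ms = onsets, duration_ms = duration_ms,
                 frequency_hz = frequency_hz),
            class = "stimulus_protocol")
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %g Hz, %g ms, %d onset(s)\n",
              x$frequency_hz, x$duration_ms, length(x$onsets_ms)))
  invisible(x)
}

#' Voltage trace for a whole protocol
#'
#' Superposes the above-baseline part of the action-potential template at
#' every onset of the protocol. Voltage is spatially uniform over the
#' bouton: the only information passed from axon shaft to bouton is this
#' trace.
#'
#' @param protocol a [make_train()] protocol
#' @param ap an [ap_waveform()]; its own `onset_ms` is ignored in favour of
#'   the protocol onsets
#' @param dt_ms sample interval (ms)
#' @return a tibble with columns `time_ms`, `v_mv`
#' @export
voltage_trace <- function(protocol, ap = ap_waveform(), dt_ms = 0.01) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  t <- seq(0, protocol$duration_ms, by = dt_ms)
  amp <- ap$peak_mv - ap$baseline_mv
  v <- rep(ap$baseline_mv, length(t))
  for (on in protocol$onsets_ms) {
    v <- v + amp * biexp_bump(t - on - ap$delay_ms, ap$rise_ms, ap$fall_ms)
  }
  tibble::tibble(time_ms = t, v_mv = v)
}

#' Read or write a two-column voltage trace
#'
#' Plain-text interchange format: two columns, `time_ms` and `v_mv`.
#'
#' @param trace a tibble as produced by [voltage_trace()]
#' @param path file path
#' @return `read_voltage_trace()` returns the trace tibble
#' @export
write_voltage_trace <- function(trace, path) {
  stopifnot(all(c("time_ms", "v_mv") %in% names(trace)))
  readr::write_csv(trace[, c("time_ms", "v_mv")], path)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time_ms = readr::col_double(), v_mv = readr::col_double()))
}
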