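#' Voltage-dependent calcium channel (VDCC) parameters
#'
#' Kinetics of the P/Q-type presynaptic calcium channel, modelled as a
#' five-state linear chain C1-C2-C3-C4-O with four voltage-dependent rate
#' pairs: forward `a_i(v) = a0_i * exp(v / v_i)` and backward
#' `b_i(v) = b0_i * exp(-v / v_i)` (rates in /ms, voltages in mV). Only the
#' terminal O state conducts. Channels are immobile on the membrane
#' (zero surface diffusion) and clustered within a disc of at most 66 nm
#' radius.
#'
#' @param a0,b0 forward / backward rate prefactors, length 4 (/ms)
#' @param v voltage constants, length 4 (mV)
#' @param n_channels number of channels in the cluster (1-208)
#' @param cluster_radius_nm radius of the channel cluster disc (<= 66 nm)
#' @param flux_open calcium influx through one open channel (ions/ms);
#'   a calibration parameter, see [calibrate_channel_flux()]
#' @return an object of class `vdcc_params`
#' @export
vdcc_params <- function(a0 = c(4.04, 6.70, 4.39, 17.33),
                        b0 = c(2.88, 6.30, 8.16, 1.84),
                        v = c(49.14, 42.08, 55.31, 26.55),
                        n_channels = 48,
                        cluster_radius_nm = 35,
                        flux_open = NULL) {
  stopifnot(length(a0) == 4, length(b0) == 4, length(v) == 4,
            all(a0 > 0), all(b0 > 0), all(v > 0))
  if (n_channels < 1 || n_channels > 208) {
    stop("n_channels must be between 1 and 208", call. = FALSE)
  }
  if (cluster_radius_nm > 66) {
    stop("cluster_radius_nm must not exceed 66 nm", call. = FALSE)
  }
  if (is.null(flux_open)) flux_open <- default_flux_open()
  stopifnot(flux_open >= 0)
  structure(list(a0 = a0, b0 = b0, v = v, n_channels = n_channels,
                 cluster_radius_nm = cluster_radius_nm,
                 flux_open = flux_open, mobility = 0),
            class = "vdcc_params")
}

# Single-channel flux (ions/ms while open) fixed once by calibrating the
# simulated mean local calcium peak at the 48-channel, l_c = 250 nm
# configuration against its 12 uM reference value, then frozen.
default_flux_open <- function() 112.5

#' @export
print.vdcc_params <- function(x, ...) {
  cat(sprintf("<vdcc_params> %d channel(s), cluster radius %g nm, flux %g ions/ms\n",
              x$n_channels, x$cluster_radius_nm, x$flux_open))
  invisible(x)
}

#' Voltage-dependent gating rates
#'
#' Evaluates the forward and backward rates of the four gating transitions
#' at a membrane potential. At 0 mV the rates equal the prefactors.
#'
#' @param v_mv membrane potential (mV), scalar
#' @param params a [vdcc_params()]
#' @return a tibble with columns `gate` (1-4), `a` and `b` (/ms)
#' @export
#' @examples
#' vdcc_rates(0, vdcc_params())
vdcc_rates <- function(v_mv, params = vdcc_params()) {
  stopifnot(is.finite(v_mv), length(v_mv) == 1)
  tibble::tibble(
    gate = 1:4,
    a = params$a0 * exp(v_mv / params$v),
    b = params$b0 * exp(-v_mv / params$v))
}

#' Stochastic channel gating along a voltage trace
#'
#' Simulates exact jump trajectories of the five-state chain for each
#' channel, with the voltage held piecewise constant between trace samples.
#' States are coded 0 (C1) to 4 (O). Channels start from C1.
#'
#' @param voltage a tibble with `time_ms`, `v_mv` (e.g. [voltage_trace()])
#' @param params a [vdcc_params()]
#' @param n_channels number of independent channels (defaults to the
#'   parameter set's count)
#' @param seed integer seed; trajectories are reproducible given the seed
#' @return an object of class `channel_trajectory`: a tibble of jumps with
#'   columns `channel`, `time_ms`, `state`, plus attributes `t_end` and
#'   `n_channels`
#' @export
simulate_channels <- function(voltage, params = vdcc_params(),
                              n_channels = params$n_channels, seed = 1) {
  if (nrow(voltage) < 2) stop("voltage trace is empty", call. = FALSE)
  t <- voltage$time_ms
  v <- voltage$v_mv[-length(voltage$v_mv)]
  seeds <- derive_seeds(seed, n_channels, stream = 7L)
  jumps <- cpp_simulate_vdcc(t, v, params$a0, params$b0, params$v,
                             n_channels, seeds, 0L)
  out <- tibble::as_tibble(jumps)
  attr(out, "t_end") <- max(t)
  attr(out, "n_channels") <- n_channels
  class(out) <- c("channel_trajectory", class(out))
  out
}

#' Open intervals of simulated channels
#'
#' Collapses a jump trajectory into the disjoint intervals during which each
#' channel occupied the conducting O state.
#'
#' @param trajectory a [simulate_channels()] result
#' @return a tibble with columns `channel`, `t_open`, `t_close` (ms)
#' @export
open_intervals <- function(trajectory) {
  t_end <- attr(trajectory, "t_end")
  df <- dplyr::arrange(tibble::as_tibble(trajectory), .data$channel, .data$time_ms)
  res <- df |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_modify(function(g, key) {
      open_t <- NA_real_
      out_open <- c(); out_close <- c()
      for (i in seq_len(nrow(g))) {
        if (g$state[i] == 4 && is.na(open_t)) {
          open_t <- g$time_ms[i]
        } else if (g$state[i] != 4 && !is.na(open_t)) {
          out_open <- c(out_open, open_t); out_close <- c(out_close, g$time_ms[i])
          open_t <- NA_real_
        }
      }
      if (!is.na(open_t)) {
        out_open <- c(out_open, open_t); out_close <- c(out_close, t_end)
      }
      tibble::tibble(t_open = as.double(out_open), t_close = as.double(out_close))
    }) |>
    dplyr::ungroup()
  res
}

#' Ion-injection schedule from channel openings
#'
#' Draws Poisson ion counts at resolution `dt_ms` during each open interval;
#' the expected total equals `flux_open` times the total open time.
#'
#' @param intervals an [open_intervals()] tibble
#' @param flux_open ions per ms through an open channel (>= 0)
#' @param dt_ms schedule resolution (ms)
#' @param t_end_ms truncate the schedule at this time
#' @param seed integer seed
#' @return a tibble with columns `channel`, `time_ms`, `ions`
#' @export
channel_flux_events <- function(intervals, flux_open, dt_ms = 0.01,
                                t_end_ms = Inf, seed = 1) {
  if (dt_ms <= 0) stop("dt must be positive", call. = FALSE)
  if (flux_open < 0) stop("flux must be nonnegative", call. = FALSE)
  m <- as.matrix(intervals[, c("channel", "t_open", "t_close")])
  if (nrow(m) == 0) {
    return(tibble::tibble(channel = integer(), time_ms = double(),
                          ions = integer()))
  }
  tibble::as_tibble(cpp_flux_events(m, flux_open, dt_ms, t_end_ms,
                                    derive_seeds(seed, 1, stream = 11L)))
}

#' Deterministic open probability from the master equation
#'
#' Integrates the chemical master equation of the five-state chain along a
#' voltage trace (an ODE in the five state probabilities). Serves as the
#' deterministic reference for the stochastic gating simulation.
#'
#' @param voltage a tibble with `time_ms`, `v_mv`
#' @param params a [vdcc_params()]
#' @return a tibble with `time_ms`, state probabilities `p1`-`p4`, `p_open`
#' @export
vdcc_open_probability <- function(voltage, params = vdcc_params()) {
  t <- voltage$time_ms
  vfun <- stats::approxfun(t, voltage$v_mv, method = "constant", rule = 2)
  deriv <- function(tt, y, parms) {
    v <- vfun(tt)
    a <- params$a0 * exp(v / params$v)
    b <- params$b0 * exp(-v / params$v)
    dy <- numeric(5)
    for (i in 1:4) {
      f <- a[i] * y[i] - b[i] * y[i + 1]
      dy[i] <- dy[i] - f
      dy[i + 1] <- dy[i + 1] + f
    }
    list(dy)
  }
  y0 <- c(1, 0, 0, 0, 0)
  sol <- deSolve::lsoda(y0, t, deriv, parms = NULL,
                        rtol = 1e-8, atol = 1e-10)
  tibble::tibble(time_ms = sol[, 1],
                 p1 = sol[, 2], p2 = sol[, 3], p3 = sol[, 4], p4 = sol[, 5],
                 p_open = sol[, 6])
}

#' Empirical state occupancy of a channel ensemble
#'
#' Fraction of channels in each state at a set of query times, computed from
#' a jump trajectory.
#'
#' @param trajectory a [simulate_channels()] result
#' @param times query times (ms)
#' @return a tibble with `time_ms`, `state`, `fraction`
#' @export
channel_occupancy <- function(trajectory, times) {
  n_ch <- attr(trajectory, "n_channels")
  df <- tibble::as_tibble(trajectory)
  purrr::map_dfr(times, function(tt) {
    st <- df |>
      dplyr::filter(.data$time_ms <= tt) |>
      dplyr::group_by(.data$channel) |>
      dplyr::slice_tail(n = 1) |>
      dplyr::ungroup()
    counts <- table(factor(st$state, levels = 0:4))
    counts["0"] <- counts["0"] + (n_ch - nrow(st)) # channels still in C1
    tibble::tibble(time_ms = tt, state = 0:4,
                   fraction = as.vector(counts) / n_ch)
  })
}

#' Sample channel positions within the cluster disc
#'
#' Channel positions are uniform within a disc of the cluster radius centred
#' at the cluster location on the membrane face (y = 0), re-sampled per trial.
#'
#' @param params a [vdcc_params()]
#' @param center_xz cluster centre, c(x, z) in nm on the membrane
#' @param seed integer seed
#' @return a tibble with `x`, `y`, `z` (nm); `y` is just inside the membrane
#' @export
sample_channel_positions <- function(params, center_xz, seed = 1) {
  s <- derive_seeds(seed, 2 * params$n_channels, stream = 3L) / 2147483647
  u <- s[seq_len(params$n_channels)]
  th <- 2 * pi * s[params$n_channels + seq_len(params$n_channels)]
  r <- params$cluster_radius_nm * sqrt(u)
  tibble::tibble(x = center_xz[1] + r * cos(th), y = 0.5,
                 z = center_xz[2] + r * sin(th))
}
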