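#' Parameterised local calcium transient (hybrid engine)
#'
#' Fast surrogate for the spatially explicit engine: the local calcium
#' concentration at the active zone is described by a three-component
#' template per action potential — a sharp spike tracking channel openings,
#' an intermediate shoulder from late channel openings and local buffer
#' unloading, and a small slow residue that decays as bulk calcium is
#' cleared to the boundary clamps and pumps. Component amplitudes and time
#' constants are calibrated against the spatial engine at the reference
#' configuration (48 channels, l_c = 250 nm) and frozen; see the methods
#' vignette for the calibration record.
#'
#' @param peak_uM mean spike amplitude above baseline (uM)
#' @param rise_ms spike rise time constant (ms)
#' @param decay_ms spike decay time constant (ms)
#' @param latency_ms delay from action-potential onset to the start of the
#'   calcium spike (channel-gating latency)
#' @param mid_amp_uM,mid_tau_ms intermediate component amplitude and decay
#' @param res_amp_uM,res_tau_ms residual component amplitude and decay
#' @param cv trial-to-trial coefficient of variation of the transient
#'   amplitude (stochastic channel-opening count)
#' @param baseline_uM resting calcium (uM)
#' @return an object of class `hybrid_template`
#' @export
hybrid_template <- function(peak_uM = 11.2, rise_ms = 0.21, decay_ms = 0.38,
                            latency_ms = 1.63, mid_amp_uM = 0.161,
                            mid_tau_ms = 5.9, res_amp_uM = 0.070,
                            res_tau_ms = 690, cv = 0.12,
                            baseline_uM = 0.1) {
  if (peak_uM < 0) stop("peak amplitude must be nonnegative", call. = FALSE)
  structure(as.list(environment()), class = "hybrid_template")
}

#' @export
print.hybrid_template <- function(x, ...) {
  cat(sprintf(
    "<hybrid_template> peak %.3g uM (cv %.2f), rise/decay %.2f/%.2f ms, mid %.3g uM tau %.3g ms, residual %.3g uM tau %.3g ms\n",
    x$peak_uM, x$cv, x$rise_ms, x$decay_ms, x$mid_amp_uM, x$mid_tau_ms,
    x$res_amp_uM, x$res_tau_ms))
  invisible(x)
}

# stimulus component (uM above baseline) of one AP at elapsed time t >= 0
hybrid_bump <- function(t, tpl) {
  tpl$peak_uM * biexp_bump(t, tpl$rise_ms, tpl$decay_ms) +
    tpl$mid_amp_uM * biexp_bump(t, 1.0, tpl$mid_tau_ms) +
    tpl$res_amp_uM * biexp_bump(t, 5.0, tpl$res_tau_ms)
}

# nonuniform grid: fine sampling around each AP, coarse elsewhere
hybrid_grid <- function(protocol, fine_dt = 0.02, fine_window = 30,
                        coarse_dt = 1) {
  edges <- seq(0, protocol$duration_ms, by = coarse_dt)
  for (on in protocol$onsets_ms) {
    fine <- seq(on, min(on + fine_window, protocol$duration_ms), by = fine_dt)
    edges <- c(edges, fine)
  }
  sort(unique(c(edges, protocol$duration_ms)))
}

#' Hybrid calcium trace for a stimulus protocol
#'
#' Evaluates the template transient, superposed over every action-potential
#' onset of the protocol, on a time grid that is fine around each stimulus
#' and coarse in between. The returned trace is the mean (scale = 1)
#' transient; per-trial amplitude variability is applied by the zone
#' simulator.
#'
#' @param protocol a [make_train()] protocol
#' @param template a [hybrid_template()]
#' @param fine_dt_ms grid step near each stimulus (ms)
#' @param coarse_dt_ms grid step away from stimuli (ms)
#' @return a tibble with `time_ms`, `conc_uM` (total concentration,
#'   baseline included)
#' @export
#' @examples
#' hybrid_ca_trace(make_train(10, 400))
hybrid_ca_trace <- function(protocol, template = hybrid_template(),
                            fine_dt_ms = 0.02, coarse_dt_ms = 1) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  t <- hybrid_grid(protocol, fine_dt_ms, coarse_dt = coarse_dt_ms)
  stim <- rep(0, length(t))
  for (on in protocol$onsets_ms) {
    el <- t - on - template$latency_ms
    stim <- stim + hybrid_bump(pmax(el, -1), template) * (el >= 0)
  }
  tibble::tibble(time_ms = t, conc_uM = template$baseline_uM + stim)
}

#' Per-trial amplitude factors for the hybrid engine
#'
#' Gamma-distributed multiplicative factors with unit mean and the
#' template's coefficient of variation, mimicking the trial-to-trial spread
#' of the local calcium peak caused by stochastic channel gating.
#'
#' @param template a [hybrid_template()]
#' @param n_trials number of factors
#' @param seed integer seed
#' @return numeric vector of length `n_trials`
#' @export
hybrid_trial_scales <- function(template, n_trials, seed = 1) {
  if (template$cv <= 0) return(rep(1, n_trials))
  shape <- 1 / template$cv^2
  u <- derive_seeds(seed, n_trials, stream = 17L) / 2147483647
  stats::qgamma(u, shape = shape, rate = shape)
}
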