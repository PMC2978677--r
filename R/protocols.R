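#' Named release-probability presets
#'
#' Channel-count / co-localization combinations that realise the reference
#' zone release probabilities: `pr02` (p_r = 0.2, 48 channels at 250 nm),
#' `pr06` (p_r = 0.6, 72 channels at 250 nm; the alternative `pr06_far`
#' realisation uses 128 channels at 400 nm), and `pr095` (p_r = 0.95,
#' 112 channels at 250 nm). In hybrid mode the calcium-transient amplitude
#' scales with the channel count relative to the calibrated 48-channel
#' reference.
#'
#' @param name preset name
#' @return a list with `n_channels`, `lc_nm`, `amp_scale`
#' @export
release_preset <- function(name = c("pr02", "pr06", "pr095", "pr06_far")) {
  name <- match.arg(name)
  switch(name,
    pr02 = list(name = name, n_channels = 48, lc_nm = 250, amp_scale = 1),
    pr06 = list(name = name, n_channels = 72, lc_nm = 250,
                amp_scale = 72 / 48),
    pr095 = list(name = name, n_channels = 112, lc_nm = 250,
                 amp_scale = 112 / 48),
    pr06_far = list(name = name, n_channels = 128, lc_nm = 400,
                    amp_scale = NA))
}

#' Experiment specification
#'
#' One fully parameterised experiment: zone configuration, stimulation
#' protocol, engine mode and ensemble size. The default desk-scale ensemble
#' is 2000 trials; the reference studies use 10000.
#'
#' @param label free-text label
#' @param preset a [release_preset()] name or list
#' @param protocol a [make_train()] protocol
#' @param zone a [zone_config()]
#' @param template a [hybrid_template()] (hybrid engine)
#' @param n_trials trials in the ensemble
#' @param engine "hybrid" (template calcium transients driving the sensor
#'   chain) or "spatial" (full particle engine)
#' @param seed master seed
#' @return an object of class `experiment_spec`
#' @export
experiment_spec <- function(label = "single AP", preset = "pr02",
                            protocol = single_ap_protocol(),
                            zone = zone_config(),
                            template = hybrid_template(),
                            n_trials = 2000,
                            engine = c("hybrid", "spatial"),
                            seed = 1) {
  if (is.character(preset)) preset <- release_preset(preset)
  engine <- match.arg(engine)
  stopifnot(n_trials >= 1)
  if (engine == "hybrid" && !is.na(preset$amp_scale)) {
    template$peak_uM <- template$peak_uM * preset$amp_scale
    template$mid_amp_uM <- template$mid_amp_uM * preset$amp_scale
    template$res_amp_uM <- template$res_amp_uM * preset$amp_scale
  }
  structure(list(label = label, preset = preset, protocol = protocol,
                 zone = zone, template = template,
                 n_trials = as.integer(n_trials), engine = engine,
                 seed = seed),
            class = "experiment_spec")
}

#' Single action potential over a 400 ms window
#' @param duration_ms observation window (ms)
#' @param onset_ms stimulus onset (ms)
#' @return a [make_train()] protocol with one onset
#' @export
single_ap_protocol <- function(duration_ms = 400, onset_ms = 0) {
  p <- make_train(0, duration_ms)
  p$onsets_ms <- onset_ms
  p
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("<experiment_spec> %s: %s, %d stimuli, %d trials, %s engine\n",
              x$label, x$preset$name, length(x$protocol$onsets_ms),
              x$n_trials, x$engine))
  invisible(x)
}

#' Run a trial ensemble
#'
#' Simulates `n_trials` independent trials of the specified experiment.
#' In hybrid mode a single template calcium trace drives all trials, with
#' per-trial amplitude factors; in spatial mode each trial runs the full
#' particle engine and feeds the measured per-vesicle traces to the sensor
#' chain. Per-trial seeds are derived deterministically from the master
#' seed, so identical specifications reproduce identical ensembles.
#'
#' @param spec an [experiment_spec()]
#' @param ... spatial-engine arguments (geometry etc.), hybrid mode ignores
#'   them
#' @return an object of class `ensemble_result`: list with `events`
#'   (release-event tibble), `spec`, `n_trials`
#' @export
run_ensemble <- function(spec, ...) {
  stopifnot(inherits(spec, "experiment_spec"))
  if (spec$engine == "hybrid") {
    ca <- hybrid_ca_trace(spec$protocol, spec$template)
    scales <- hybrid_trial_scales(spec$template, spec$n_trials,
                                  seed = spec$seed)
    events <- simulate_active_zone(ca, spec$zone, spec$n_trials,
                                   seed = spec$seed, trial_scale = scales)
  } else {
    events <- run_spatial_ensemble(spec, ...)
  }
  structure(list(events = events, spec = spec, n_trials = spec$n_trials),
            class = "ensemble_result")
}

run_spatial_ensemble <- function(spec, geometry = NULL,
                                 channels = NULL, buffer = buffer_params(),
                                 pumps = pump_params(),
                                 diffusion = diffusion_params(
                                   dt_ca_us = 1, dt_other_us = 10,
                                   t_fine_ms = 20)) {
  if (is.null(geometry)) geometry <- bouton_geometry(lc_nm = spec$preset$lc_nm)
  if (is.null(channels)) channels <- vdcc_params(n_channels = spec$preset$n_channels)
  evs <- purrr::map(seq_len(spec$n_trials), function(i) {
    run <- simulate_bouton_trial(spec$protocol, geometry, channels, buffer,
                                 pumps, diffusion,
                                 t_end_ms = spec$protocol$duration_ms,
                                 seed = spec$seed * 10000 + i)
    ves <- run$traces |>
      dplyr::filter(grepl("^vesicle_", .data$probe)) |>
      tidyr::pivot_wider(names_from = "probe", values_from = "conc_uM")
    ev <- simulate_active_zone(ves, spec$zone, n_trials = 1,
                               seed = spec$seed * 10000 + i)
    ev$trial <- i - 1L
    ev
  })
  dplyr::bind_rows(evs)
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> %s: %d events in %d trials\n",
              x$spec$label, nrow(x$events), x$n_trials))
  invisible(x)
}

#' Paired comparison with toggled zone flags
#'
#' Runs the same experiment twice with one or more zone flags toggled
#' (refractory on/off, variant switches), sharing the master seed so that
#' per-trial random streams pair up (common random numbers).
#'
#' @param spec an [experiment_spec()]
#' @param refractory length-2 logical, refractory flag per arm; NULL keeps
#'   the spec's flag in both arms
#' @param variant length-2 character, variant per arm; NULL keeps the
#'   spec's variant
#' @return a named list of two `ensemble_result`s (`a`, `b`)
#' @export
run_comparison <- function(spec, refractory = NULL, variant = NULL) {
  if (is.null(refractory) && is.null(variant)) {
    stop("toggle at least one of refractory or variant", call. = FALSE)
  }
  arm <- function(i) {
    s <- spec
    if (!is.null(refractory)) s$zone$refractory <- refractory[i]
    if (!is.null(variant)) s$zone <- apply_variant(s$zone, variant[i])
    run_ensemble(s)
  }
  list(a = arm(1), b = arm(2))
}

#' Depletion-free ensemble
#'
#' Variant in which a released vesicle is instantly replaced (infinite
#' readily-releasable pool); the refractory gate still applies. Used for
#' vesicle-count distributions.
#'
#' @param spec an [experiment_spec()]
#' @return an `ensemble_result`
#' @export
run_depletion_free <- function(spec) {
  spec$zone$depletion_free <- TRUE
  run_ensemble(spec)
}
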