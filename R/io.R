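#' Default simulation configuration
#'
#' Nested configuration mirroring the model's parameter blocks, with every
#' kinetic constant at its reference value (laboratory units as printed:
#' /M/s, /s, um^2/s, nm, ms). Unknown keys in a user file are rejected.
#'
#' @return a named list of sections: `stimulus`, `channels`, `spatial`,
#'   `sensor`, `protocol`, `run`
#' @export
default_config <- function() {
  list(
    stimulus = list(baseline_mv = -70, peak_mv = 34, rise_ms = 0.4,
                    fall_ms = 0.6),
    channels = list(n_channels = 48, cluster_radius_nm = 35,
                    flux_open = default_flux_open(),
                    a0 = c(4.04, 6.70, 4.39, 17.33),
                    b0 = c(2.88, 6.30, 8.16, 1.84),
                    v = c(49.14, 42.08, 55.31, 26.55)),
    spatial = list(lc_nm = 250, box_um = c(4, 0.5, 0.5),
                   D_ca_um2s = 220, D_cb_um2s = 28, D_glu_um2s = 200,
                   resting_uM = 0.1, calbindin_uM = 45,
                   kh_plus = 0.55e7, kh_minus = 2.6,
                   km_plus = 4.35e7, km_minus = 35.8,
                   pmca_density_um2 = 180,
                   kpm1 = 1.5e7, kpm2 = 20, kpm3 = 20, kpm4 = 100,
                   kpm_leak = 12.5,
                   dt_ca_us = 0.1, dt_other_us = 1.0,
                   probe_offset_nm = 10, probe_radius_nm = 50),
    sensor = list(ks_plus = 0.612e8, ks_minus = 2.32e3,
                  ka_plus = 3.82e6, ka_minus = 13,
                  b = 0.25, gamma = 2e3, delta = 0.417e-3,
                  epsilon_ms = 6.34, a = 0.025,
                  n_sync_sites = 5, n_async_sites = 2, rrp = 7),
    protocol = list(frequency_hz = 0, duration_ms = 400, first_onset_ms = 0,
                    n_trials = 2000),
    run = list(engine = "hybrid", seed = 1, variant = "wild-type",
               refractory = TRUE, depletion_free = FALSE))
}

validate_config <- function(cfg) {
  ref <- default_config()
  bad_sections <- setdiff(names(cfg), names(ref))
  if (length(bad_sections)) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), names(ref[[sec]]))
    if (length(bad)) {
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    ref[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
  }
  n <- ref$channels$n_channels
  if (n < 1 || n > 208) {
    stop("channels.n_channels must be between 1 and 208", call. = FALSE)
  }
  if (ref$spatial$lc_nm < 10 || ref$spatial$lc_nm > 400) {
    stop("spatial.lc_nm must lie within [10, 400] nm", call. = FALSE)
  }
  if (ref$channels$cluster_radius_nm > 66) {
    stop("channels.cluster_radius_nm must not exceed 66 nm", call. = FALSE)
  }
  ref
}

#' Load a simulation configuration file
#'
#' JSON (or YAML, if the yaml package is installed) configuration with any
#' subset of the keys of [default_config()]; missing keys take the
#' reference defaults, unknown keys raise a validation error.
#'
#' @param path file path; an empty or absent body yields the full default
#'   configuration
#' @return the validated, completed configuration list
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!nzchar(trimws(txt))) return(default_config())
  cfg <- if (grepl("\\.ya?ml$", path) &&
             requireNamespace("yaml", quietly = TRUE)) {
    yaml::yaml.load(txt)
  } else {
    jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

#' Write and read release events as CSV
#'
#' Lossless plain-text round trip of a release-event table with a schema
#' header comment.
#'
#' @param events release-event tibble (`trial`, `time_ms`, `vesicle`,
#'   `pathway`)
#' @param path file path
#' @return `read_events()` returns the events tibble
#' @export
write_events <- function(events, path) {
  ev <- as_events(events)
  stopifnot(all(c("trial", "time_ms", "vesicle", "pathway") %in% names(ev)))
  con <- file(path, "w")
  writeLines("# bouton release events v1", con)
  close(con)
  readr::write_csv(dplyr::mutate(ev, pathway = as.character(.data$pathway)),
                   path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    trial = readr::col_integer(), time_ms = readr::col_double(),
    vesicle = readr::col_integer(), pathway = readr::col_character()))
  probs <- readr::problems(out)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed events file at line %d", probs$row[1] + 2),
         call. = FALSE)
  }
  bad <- !out$pathway %in% c("synchronous", "asynchronous", "spontaneous")
  if (any(bad)) {
    stop(sprintf("malformed events file at line %d (unknown pathway)",
                 which(bad)[1] + 2), call. = FALSE)
  }
  dplyr::mutate(out, pathway = factor(.data$pathway,
    levels = c("synchronous", "asynchronous", "spontaneous")))
}

#' Write a release histogram as CSV
#'
#' Columns `t_start_ms`, `rate_per_ms`, `std`.
#'
#' @param hist a [release_histogram()]
#' @param path file path
#' @export
write_histogram <- function(hist, path) {
  readr::write_csv(
    tibble::tibble(t_start_ms = hist$t_start_ms,
                   rate_per_ms = hist$rate_per_ms,
                   std = hist$std_per_ms), path)
  invisible(path)
}

#' Synthetic fixtures with known generating parameters
#'
#' Test-support generator producing data with stored ground truth:
#' `ca_transient` (a template calcium trace plus Gaussian noise),
#' `multi_exp_events` (release events drawn from a two-exponential-plus-
#' constant rate profile) and `constant_ca_events` (a homogeneous Poisson
#' event stream).
#'
#' @param kind fixture kind
#' @param params named list overriding the generating parameters
#' @param seed integer seed
#' @return a list with `kind`, `params` (ground truth) and `data`
#' @export
generate_fixture <- function(kind = c("ca_transient", "multi_exp_events",
                                      "constant_ca_events"),
                             params = list(), seed = 1) {
  kind <- match.arg(kind)
  # use R's RNG under a local seed, restoring the caller's stream afterwards
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  if (kind == "ca_transient") {
    p <- utils::modifyList(list(peak_uM = 12, rise_ms = 0.45,
                                decay_ms = 0.65, noise_uM = 0.05,
                                duration_ms = 20, dt_ms = 0.02), params)
    t <- seq(0, p$duration_ms, by = p$dt_ms)
    conc <- 0.1 + p$peak_uM * biexp_bump(t - 2, p$rise_ms, p$decay_ms) +
      rnorm(length(t), sd = p$noise_uM)
    data <- tibble::tibble(time_ms = t, conc_uM = pmax(conc, 0))
  } else if (kind == "multi_exp_events") {
    p <- utils::modifyList(list(a0 = 0.025, tau_fast = 6, a1 = 0.00023,
                                tau_slow = 160, a2 = 0.00012,
                                n_trials = 10000, duration_ms = 400), params)
    rate <- function(t) {
      p$a0 * exp(-t / p$tau_fast) + p$a1 * exp(-t / p$tau_slow) + p$a2
    }
    # thinned homogeneous process, vectorised over the whole ensemble
    lam <- rate(0) # bound (the rate profile is decreasing)
    n_cand <- rpois(1, lam * p$duration_ms * p$n_trials)
    cand_t <- runif(n_cand) * p$duration_ms
    cand_trial <- sample.int(p$n_trials, n_cand, replace = TRUE) - 1L
    keep <- runif(n_cand) < rate(cand_t) / lam
    ord <- order(cand_trial[keep], cand_t[keep])
    times <- cand_t[keep][ord]; trials <- cand_trial[keep][ord]
    data <- tibble::tibble(trial = as.integer(trials), time_ms = times,
                           vesicle = 0L,
                           pathway = factor("synchronous",
                             levels = c("synchronous", "asynchronous",
                                        "spontaneous")))
  } else {
    p <- utils::modifyList(list(rate_per_ms = 0.01, n_trials = 1000,
                                duration_ms = 400), params)
    counts <- rpois(p$n_trials, p$rate_per_ms * p$duration_ms)
    total <- sum(counts)
    data <- tibble::tibble(
      trial = rep(seq_len(p$n_trials) - 1L, counts),
      time_ms = runif(total) * p$duration_ms, vesicle = 0L,
      pathway = factor("spontaneous",
        levels = c("synchronous", "asynchronous", "spontaneous")))
  }
  list(kind = kind, params = p, data = data)
}
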